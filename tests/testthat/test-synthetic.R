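# Synthetic cohort generator: learning curves, sources, mixing, cohorts.

test_that("learning curve follows the exponential decay closed form", {
  cfg <- sim_config(n_trials = 100,
                    learning_curve = list(initial = 40, asymptote = 10,
                                          decay = 50, noise_sd = 0))
  lc <- generate_learning_curve(cfg, 1)
  # latent anchored at 1 on trial 1, so trial 51 sits one time constant in
  expect_equal(lc$ttt[1], 40)
  expect_equal(lc$ttt[51], 10 + 30 * exp(-1), tolerance = 1e-10)
  expect_true(all(diff(lc$ttt) < 0))
  expect_true(all(lc$ttt > 10))
  expect_equal(lc$latent[1], 1)
})

test_that("infinite decay constant gives a constant series at the initial value", {
  cfg <- sim_config(learning_curve = list(initial = 40, asymptote = 10,
                                          decay = Inf, noise_sd = 0))
  lc <- generate_learning_curve(cfg, 1)
  expect_equal(lc$ttt, rep(40, cfg$n_trials))
})

test_that("non-positive decay constants are rejected", {
  expect_error(sim_config(learning_curve = list(initial = 40, asymptote = 10,
                                                decay = -1, noise_sd = 0)),
               "decay")
})

test_that("observed TTT is expectation plus noise, strictly positive", {
  cfg <- sim_config(learning_curve = list(initial = 5, asymptote = 1,
                                          decay = 40, noise_sd = 4))
  lc <- generate_learning_curve(cfg, 2)
  expect_true(all(lc$ttt > 0))
  expect_false(all(diff(lc$ttt) < 0))   # noise breaks strict monotonicity
})

test_that("zero coupling makes informative sources statistically like the rest", {
  cfg <- small_sim_config(strength = 0)
  s1 <- generate_session(cfg, 1)
  cfg_pos <- small_sim_config(strength = 0.8)
  s2 <- generate_session(cfg_pos, 1)
  # same seeds underneath: zero-strength sources equal non-informative
  # generation exactly, while positive strength changes them
  expect_equal(dim(s1$eeg$data), dim(s2$eeg$data))
  ep1 <- extract_epochs(rereference_car(s1$eeg), s1$events, "baseline")
  alpha <- band_definitions()[3, ]
  bp <- vapply(seq_len(dim(ep1$epochs)[1]), function(t) {
    log_bandpower(ep1$epochs[t, 1, ], cfg$fs, alpha)
  }, 0)
  expect_lt(abs(cor(bp, s1$latent_curve, method = "spearman")), 0.45)
})

test_that("informative-source bandpower tracks the latent state with the configured sign", {
  coh <- small_cohort()
  cfg <- attr(coh, "config")
  s <- coh[[1]]
  alpha <- band_definitions()[3, ]
  # bandpower measured on the source signals themselves (pre-mixing truth
  # is not stored, so use a noiseless re-generation)
  curve <- generate_learning_curve(cfg, 1)
  S <- generate_sources(cfg, curve$latent, s$events,
                        ncol(s$eeg$data), 1)
  on <- s$events$baseline_onset
  bp <- vapply(seq_len(nrow(s$events)), function(t) {
    log_bandpower(S[1, (on[t] + 1):(on[t] + 5 * cfg$fs)], cfg$fs, alpha)
  }, 0)
  rho <- cor(bp, curve$latent, method = "spearman")
  # sign = -1: more alpha power late in learning (low latent)
  expect_lt(rho, -0.5)
})

test_that("sources with disjoint bands are near-uncorrelated", {
  cfg <- sim_config(n_subjects = 1, n_trials = 20, block_size = 20,
                    n_channels = 4, n_sources = 2,
                    informative_sources = data.frame(source = integer(0),
                                                     band = character(0),
                                                     sign = numeric(0),
                                                     strength = numeric(0)),
                    source_bands = c("alpha_mu", "beta"), seed = 3)
  n <- 60 * cfg$fs
  ev <- trial_events(data.frame(trial = 1, baseline_onset = 0,
                                planning_onset = 10, go_onset = 20,
                                reached_sample = 30, timeout = FALSE,
                                start_x = 0, start_y = 0, start_z = 0,
                                target_x = 0.2, target_y = 0, target_z = 0))
  S <- generate_sources(cfg, rep(1, 20)[1:20], ev, n, 1)
  expect_lt(abs(cor(S[1, ], S[2, ])), 0.1)
})

test_that("band edges beyond Nyquist are rejected", {
  cfg <- sim_config(n_subjects = 1, n_trials = 1, block_size = 1,
                    n_channels = 4, n_sources = 2,
                    informative_sources = data.frame(source = integer(0),
                                                     band = character(0),
                                                     sign = numeric(0),
                                                     strength = numeric(0)),
                    source_bands = c("gamma", "beta"), seed = 3)
  cfg$fs <- 160   # gamma band (55-85 Hz) now exceeds the 80 Hz Nyquist
  ev <- trial_events(data.frame(trial = 1, baseline_onset = 0,
                                planning_onset = 10, go_onset = 20,
                                reached_sample = 30, timeout = FALSE,
                                start_x = 0, start_y = 0, start_z = 0,
                                target_x = 0.2, target_y = 0, target_z = 0))
  expect_error(generate_sources(cfg, 1, ev, 5000, 1), "Nyquist")
})

test_that("mixing is linear-instantaneous and deterministic given the seed", {
  set.seed(5)
  S <- matrix(rnorm(3 * 500), 3, 500)
  rec <- mix_and_record(S, diag(3), sensor_noise_sd = 0, fs = 250, seed = 1)
  expect_equal(rec$data, S)
  r1 <- mix_and_record(S, diag(3), 0.7, 250, seed = 9)
  r2 <- mix_and_record(S, diag(3), 0.7, 250, seed = 9)
  expect_identical(r1$data, r2$data)
  zero <- mix_and_record(matrix(0, 3, 20000), diag(3), 0.7, 250, seed = 2)
  expect_equal(sd(as.numeric(zero$data)), 0.7, tolerance = 0.02)
})

test_that("rank-deficient mixing matrices are rejected", {
  S <- matrix(rnorm(2 * 100), 2, 100)
  A <- cbind(c(1, 1, 0), c(2, 2, 0))   # rank 1
  expect_error(mix_and_record(S, A, 0, 250, 1), "rank")
})

test_that("cohort layout matches the configured design", {
  coh <- small_cohort()
  cfg <- attr(coh, "config")
  expect_length(coh, 3)
  for (s in coh) {
    expect_equal(nrow(s$events), cfg$n_trials)
    expect_true(all(s$ttt_true > 0))
    # recording covers all trial phases
    expect_gt(ncol(s$eeg$data), max(s$events$reached_sample))
  }
  # distinct subjects get distinct noise realizations
  expect_false(isTRUE(all.equal(coh[[1]]$eeg$data[, 1:1000],
                                coh[[2]]$eeg$data[, 1:1000])))
})

test_that("cohort generation is reproducible and jitter-free mixing is shared", {
  cfg <- small_sim_config(seed = 13)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1[[2]]$eeg$data, c2[[2]]$eeg$data)
  expect_identical(c1[[1]]$ttt_true, c2[[1]]$ttt_true)
  cfg0 <- cfg
  cfg0$mixing_jitter <- 0
  c3 <- generate_cohort(cfg0)
  expect_identical(c3[[1]]$true_mixing, c3[[2]]$true_mixing)
})

test_that("generate_cohort leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(small_sim_config(seed = 99)))
  expect_identical(before, .Random.seed)
})
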