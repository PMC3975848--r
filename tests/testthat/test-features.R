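# Log-bandpower, feature tables, trial-domain filtering, TTT, PSD.

test_that("the five analysis bands carry their conventional edges", {
  b <- band_definitions()
  expect_equal(b$name, c("delta", "theta", "alpha_mu", "beta", "gamma"))
  expect_equal(b$lower, c(0.1, 4, 8, 20, 55))
  expect_equal(b$upper, c(4, 7, 14, 30, 85))
})

test_that("a pure 10 Hz tone concentrates its power in alpha/mu", {
  fs <- 250
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  b <- band_definitions()
  lp_alpha <- log_bandpower(x, fs, b[b$name == "alpha_mu", ])
  lp_beta <- log_bandpower(x, fs, b[b$name == "beta", ])
  expect_gt(lp_alpha - lp_beta, 3)
})

test_that("white-noise bandpower scales with bandwidth (alpha:theta = 2)", {
  # 1000 one-second epochs; ratio of mean linear powers ~ 6 Hz / 3 Hz
  set.seed(9)
  fs <- 250
  epochs <- matrix(rnorm(1000 * fs), 1000, fs)
  b <- band_definitions()
  p_alpha <- exp(log_bandpower(epochs, fs, b[b$name == "alpha_mu", ]))
  p_theta <- exp(log_bandpower(epochs, fs, b[b$name == "theta", ]))
  expect_equal(mean(p_alpha) / mean(p_theta), 2, tolerance = 0.1)
})

test_that("zero epochs hit the documented power floor with a warning", {
  expect_warning(lp <- log_bandpower(numeric(500), 250,
                                     band_definitions()[3, ]),
                 "floor")
  expect_equal(lp, log(1e-12))
})

test_that("bands above Nyquist are rejected", {
  expect_error(log_bandpower(rnorm(500), 100, band_definitions()[5, ]),
               "Nyquist")
})

test_that("feature tables have one (IC, band) column pair per kept component", {
  fs <- 250
  mk_epochs <- function(n_ic) {
    structure(list(epochs = array(rnorm(20 * n_ic * fs),
                                  c(20, n_ic, fs)),
                   phase = "baseline", fs = fs, trials = 1:20),
              class = "epoch_set")
  }
  ft14 <- build_feature_table(mk_epochs(14))
  expect_equal(ncol(ft14), 70)
  expect_equal(nrow(ft14), 20)
  ft10 <- build_feature_table(mk_epochs(10))
  expect_equal(ncol(ft10), 50)
  # fixed IC-major, band-minor order
  expect_equal(colnames(ft14)[1:6],
               c("IC01_delta", "IC01_theta", "IC01_alpha_mu",
                 "IC01_beta", "IC01_gamma", "IC02_delta"))
})

test_that("trial-domain low-pass passes constants and slow components, kills fast ones", {
  expect_equal(trial_domain_lowpass(rep(2.5, 100), 0.1), rep(2.5, 100),
               tolerance = 1e-9)
  n <- 500
  fast <- rep(c(1, -1), n / 2)                 # pi radians/trial
  slow <- sin(0.02 * seq_len(n))               # 0.02 radians/trial
  mid <- seq(n * 0.2, n * 0.8)
  expect_lt(max(abs(trial_domain_lowpass(fast, 0.1)[mid])), 0.05)
  y <- trial_domain_lowpass(slow, 0.1)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.05)
})

test_that("trial-domain low-pass is linear and idempotent in the deep passband", {
  set.seed(10)
  a <- rnorm(100)
  b <- rnorm(100)
  expect_equal(trial_domain_lowpass(a + 2 * b, 0.1),
               trial_domain_lowpass(a, 0.1) + 2 * trial_domain_lowpass(b, 0.1),
               tolerance = 1e-9)
  slow <- sin(0.01 * seq_len(500))
  once <- trial_domain_lowpass(slow, 0.1)
  twice <- trial_domain_lowpass(once, 0.1)
  mid <- 100:400
  expect_equal(twice[mid], once[mid], tolerance = 0.02)
})

test_that("cut-offs outside (0, pi) are rejected", {
  expect_error(trial_domain_lowpass(rnorm(50), 0), "\\(0, pi\\)")
  expect_error(trial_domain_lowpass(rnorm(50), 3.2), "\\(0, pi\\)")
  expect_error(trial_domain_lowpass(rnorm(10), 0.1), "20 trials")
})

test_that("normalized TTT divides movement time by distance", {
  ev <- trial_events(data.frame(
    trial = 1:2,
    baseline_onset = c(0, 5000), planning_onset = c(1250, 6250),
    go_onset = c(2000, 7000),
    reached_sample = c(2000 + 5 * 250, 7000 + 10 * 250),
    timeout = c(FALSE, TRUE),
    start_x = 0, start_y = 0, start_z = 0,
    target_x = c(0.25, 0.1), target_y = 0, target_z = 0))
  tt <- normalized_ttt(ev, fs = 250, go_limit = 10)
  expect_equal(tt$ttt[1], 5 / 0.25)        # 20 s/m
  expect_equal(tt$ttt[2], 10 / 0.1)        # timeout: full limit, flagged
  expect_true(tt$timeout[2])
})

test_that("degenerate TTT inputs are caught", {
  ev <- trial_events(data.frame(
    trial = 1, baseline_onset = 0, planning_onset = 10, go_onset = 20,
    reached_sample = 30, timeout = FALSE,
    start_x = 0, start_y = 0, start_z = 0,
    target_x = 0, target_y = 0, target_z = 0))
  expect_error(normalized_ttt(ev, 250), "distance")
  ev2 <- ev
  ev2$target_x <- 0.2
  ev2$reached_sample <- 20
  expect_error(trial_events(ev2), NA)   # equal go/reach is structurally legal
  expect_warning(tt <- normalized_ttt(ev2, 250), "zero movement")
  expect_equal(tt$ttt, 0)
})

test_that("the TTT periodogram localizes spectral mass correctly", {
  n <- 400
  # slow exponential decay: mass concentrated below 0.1 radians/trial
  decay <- 10 + 30 * exp(-(seq_len(n) - 1) / 50)
  ps <- ttt_psd(decay)
  below <- ps$omega <= 0.1
  expect_gte(sum(ps$psd[below]) / sum(ps$psd), 0.8)
  # a pure sinusoid at 0.5 radians/trial peaks there
  x <- sin(0.5 * seq_len(n))
  ps2 <- ttt_psd(x)
  expect_equal(ps2$omega[which.max(ps2$psd)], 0.5, tolerance = 0.02)
  expect_true(all(ps2$psd >= 0))
  expect_error(ttt_psd(rnorm(10)), ">= 32")
})

test_that("informative-component features correlate with filtered TTT at the configured sign", {
  rep <- small_report()
  ph <- rep$phases$planning
  m <- rep$source_matching
  ics <- m$component[m$source %in% 1:2]   # informative sources
  r <- vapply(seq_along(ph$cv$folds), function(s) {
    target <- ph$cv$folds[[s]]$target     # filtered z-scored TTT
    feats <- ph$feature_tables[[s]]
    cols <- sprintf("IC%02d_alpha_mu", ics)
    mean(vapply(cols, function(cl) cor(feats[, cl], target), 0))
  }, 0)
  # coupling sign is -1: more alpha/mu power, faster movements
  expect_true(all(r < -0.4))
})
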