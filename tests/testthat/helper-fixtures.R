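# Shared fixtures, built in code and memoized for the test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Desk-scale cohort configuration: 3 subjects x 60 trials keeps every
# stage exercised while staying fast.
small_sim_config <- function(strength = 0.8, seed = 7) {
  sim_config(
    n_subjects = 3, n_trials = 80, block_size = 20,
    n_channels = 12, n_sources = 6,
    informative_sources = data.frame(source = 1:2, band = "alpha_mu",
                                     sign = -1, strength = strength),
    seed = seed)
}

small_cohort <- function() {
  memo("small_cohort", generate_cohort(small_sim_config()))
}

# One pipeline run on the small cohort, reused across test files.
small_report <- function() {
  memo("small_report", {
    cfg <- pipeline_config(
      sim = small_sim_config(), phase = "planning", n_components = 6,
      forest = forest_spec(n_trees = 150), n_perm = 500,
      importance_repeats = 1, seed = 42)
    run_pipeline(cfg)
  })
}

# Whitened mixture of two AR(2) sources with distinct spectral peaks.
ar2_mixture <- function(n = 20000, seed = 11) {
  memo(paste0("ar2_", n, "_", seed), {
    set.seed(seed)
    make_ar2 <- function(f0, fs = 250, r = 0.98) {
      phi1 <- 2 * r * cos(2 * pi * f0 / fs)
      phi2 <- -r^2
      as.numeric(stats::arima.sim(list(ar = c(phi1, phi2)), n))
    }
    s <- rbind(make_ar2(10), make_ar2(25))
    s <- s / apply(s, 1, sd)
    th <- 0.6
    a <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    list(sources = s, mixing = a, mixed = a %*% s)
  })
}
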