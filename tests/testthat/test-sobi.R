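# Lagged covariances, joint diagonalization, SOBI, artifact rejection.

test_that("lagged covariances of white noise vanish off lag zero", {
  set.seed(4)
  n <- 20000
  x <- matrix(rnorm(3 * n), 3)
  x <- x / apply(x, 1, sd)
  cc <- lagged_covariances(x, c(0, 5))
  expect_equal(cc[[1]], diag(3), tolerance = 0.05)
  expect_lt(max(abs(cc[[2]])), 3 / sqrt(n))
  expect_equal(cc[[2]], t(cc[[2]]))   # symmetrized
})

test_that("AR(1) autocovariance at lag 1 equals phi times the variance", {
  set.seed(5)
  phi <- 0.8
  x <- matrix(as.numeric(arima.sim(list(ar = phi), 50000)), 1)
  cc <- lagged_covariances(x, 1)
  expect_equal(cc[[1]][1, 1] / var(x[1, ]), phi, tolerance = 0.03)
})

test_that("excessive lags are rejected", {
  expect_error(lagged_covariances(matrix(rnorm(20), 2), 10),
               "smaller than")
})

test_that("already-diagonal matrices need no rotation", {
  mats <- list(diag(c(3, 2, 1)), diag(c(1, 5, 2)))
  V <- joint_diagonalize(mats)
  # identity up to row permutation / sign
  expect_equal(abs(V)[order(max.col(abs(V))), ], diag(3),
               tolerance = 1e-7)
})

test_that("a commuting set is diagonalized in its shared eigenbasis", {
  set.seed(6)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  mats <- lapply(1:3, function(i) {
    d <- diag(sort(runif(4, 0.5, 3), decreasing = TRUE))
    Q %*% d %*% t(Q)
  })
  V <- joint_diagonalize(mats)
  # columns of V match columns of Q up to permutation and sign
  sim <- abs(crossprod(Q, V))
  expect_equal(apply(sim, 2, max), rep(1, 4), tolerance = 1e-6)
  expect_equal(apply(sim, 1, max), rep(1, 4), tolerance = 1e-6)
})

test_that("a shared 30-degree rotation is recovered (grid-search oracle)", {
  th0 <- 30 * pi / 180
  R <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2, 2)
  mats <- lapply(list(c(4, 1), c(2, 5)), function(d) {
    R %*% diag(d) %*% t(R)
  })
  off_sum <- function(th) {
    Vt <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum(vapply(mats, function(m) {
      mm <- t(Vt) %*% m %*% Vt
      sum(mm^2) - sum(diag(mm)^2)
    }, 0))
  }
  grid <- seq(0, pi / 2, length.out = 20001)
  th_oracle <- grid[which.min(vapply(grid, off_sum, 0))]
  V <- joint_diagonalize(mats, tol = 1e-10)
  th_est <- atan2(abs(V[2, 1]), abs(V[1, 1]))
  expect_equal(th_oracle, th0, tolerance = 1e-3)
  expect_equal(min(th_est, pi / 2 - th_est), min(th0, pi / 2 - th0),
               tolerance = 1e-6)
})

test_that("off-diagonal criterion is non-increasing across sweeps", {
  set.seed(7)
  mats <- lapply(1:5, function(i) {
    m <- matrix(rnorm(36), 6)
    m + t(m)
  })
  V <- joint_diagonalize(mats, tol = 1e-10)
  crit <- attr(V, "off_criterion")
  expect_true(all(diff(crit) <= 1e-8))
  expect_equal(crossprod(V), diag(6), tolerance = 1e-10)
})

test_that("dimension mismatch across matrices is rejected", {
  expect_error(joint_diagonalize(list(diag(2), diag(3))), "dimension")
})

test_that("SOBI unmixes an orthogonal mixture of AR(2) sources", {
  mix <- ar2_mixture()
  res <- sobi(mix$mixed, lags = 1:20)
  P <- res$model$unmixing %*% mix$mixing
  expect_lt(amari_index(P), 0.1)
})

test_that("a single embedded source's topography is recovered", {
  set.seed(8)
  n <- 30000
  src <- as.numeric(arima.sim(list(ar = c(1.6, -0.9)), n))
  src <- src / sd(src)
  a <- c(0.8, -0.5, 0.3, 0.1)
  a <- a / sqrt(sum(a^2))
  x <- outer(a, src) + matrix(rnorm(4 * n, 0, 1), 4)
  # whiten
  e <- eigen(tcrossprod(x) / n, symmetric = TRUE)
  wh <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  res <- sobi(wh %*% x, lags = 1:20)
  topo <- solve(wh) %*% res$model$mixing
  cosines <- abs(crossprod(a, topo)) /
    sqrt(colSums(topo^2))
  expect_gt(max(cosines), 0.95)
})

test_that("channel permutation permutes topographies identically", {
  mix <- ar2_mixture()
  res1 <- sobi(mix$mixed, lags = 1:20)
  res2 <- sobi(mix$mixed[2:1, ], lags = 1:20)
  expect_equal(res2$model$topographies,
               res1$model$topographies[2:1, ], tolerance = 1e-6)
})

test_that("time reversal leaves SOBI invariant up to permutation/sign", {
  mix <- ar2_mixture()
  res1 <- sobi(mix$mixed, lags = 1:20)
  res2 <- sobi(mix$mixed[, ncol(mix$mixed):1], lags = 1:20)
  P <- res1$model$unmixing %*% t(res2$model$unmixing)
  expect_lt(amari_index(P), 0.05)
})

test_that("artifact components are rejected and cortical ones kept", {
  # component 1: alpha-band source with 1/f background spread over
  # channels; component 2: broadband noise dominated by one channel
  fs <- 250
  n <- 60 * fs
  alpha <- vmil:::bandlimited_noise(n, fs, 8, 14, seed = 21)
  cortical <- alpha + vmil:::one_over_f_noise(n, fs, 1, 1, seed = 22)
  set.seed(23)
  broadband <- rnorm(n)
  acts <- rbind(cortical / sd(cortical), broadband)
  topo <- cbind(c(0.5, 0.5, 0.5, 0.5), c(0.99, 0.01, 0.1, 0.05))
  model <- structure(list(unmixing = diag(2), mixing = diag(2),
                          topographies = topo, lags = 1:10,
                          kept = 1:2, energy = c(1, 1),
                          converged = TRUE, rejection = NULL),
                     class = "sobi_model")
  out <- reject_artifact_ics(model, acts, fs)
  expect_identical(out$kept, 1L)
  expect_match(out$rejection$reason[2], "hf_power|dominance")
  # all-artifact case errors explicitly
  model2 <- model
  model2$topographies <- cbind(c(0.99, 0.01, 0.1, 0.05),
                               c(0.99, 0.01, 0.1, 0.05))
  acts2 <- rbind(broadband, broadband)
  expect_error(reject_artifact_ics(model2, acts2, fs), "rejected")
})

test_that("SOBI recovers the synthetic cohort's mixing", {
  coh <- small_cohort()
  recs <- lapply(coh, function(s) highpass(rereference_car(s$eeg), 3))
  red <- pool_and_reduce(recs, n_components = 6)
  res <- sobi(red$scores, lags = 1:50, reduction = red,
              boundaries = red$boundaries)
  # compare against the cohort-level topographies the subjects share
  m <- match_sources(res$model$topographies, attr(coh, "base_mixing"))
  expect_gt(mean(m$cosine), 0.7)
  expect_true(all(m$cosine > 0.4))
})

test_that("amari index is zero for a scaled permutation and large for ones", {
  P <- rbind(c(0, 2, 0), c(0, 0, -5), c(1, 0, 0))
  expect_equal(amari_index(P), 0)
  expect_gt(amari_index(matrix(1, 3, 3)), 0.9)
})
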