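test_that("Gaussian MI oracle evaluates the closed form", {
  expect_identical(gaussian_mi_oracle(0), 0)
  expect_equal(gaussian_mi_oracle(0.718), 0.5228, tolerance = 1e-3)
  expect_identical(gaussian_mi_oracle(0.6), gaussian_mi_oracle(-0.6))
  expect_error(gaussian_mi_oracle(1), "rho")
  expect_error(gaussian_mi_oracle(-1.2), "rho")
})

test_that("kernel density estimates are normalised and nonnegative", {
  set.seed(21)
  x1 <- rexp(400) # deliberately skewed
  k1 <- fit_kde(x1)
  expect_equal(kde_mass <- siginfo:::kde_mass(k1), 1, tolerance = 1e-3)
  grid <- seq(k1$support[1], k1$support[2], length.out = 200)
  expect_true(all(kde_evaluate(k1, grid) >= 0))

  pair <- rgauss_pair(500, 0.5, seed = 22)
  k2 <- fit_kde(cbind(pair$x, pair$y))
  expect_equal(siginfo:::kde_mass(k2), 1, tolerance = 1e-3)
  expect_error(fit_kde(rep(1, 10)), "distinct|constant|degenerate")
})

test_that("bandwidth follows Scott's covariance-scaled rule", {
  set.seed(23)
  X <- cbind(rnorm(100), rnorm(100))
  k <- fit_kde(X)
  expect_equal(k$H, 100^(-1 / 3) * cov(X), tolerance = 1e-12)
  # per-axis bandwidth scale at n = 6400 is half that at n = 100
  expect_equal(sqrt(6400^(-1 / 3)) / sqrt(100^(-1 / 3)), 0.5)
  # 1-D exponent: n^(-1/5)
  k1 <- fit_kde(X[, 1])
  expect_equal(k1$H[1, 1], 100^(-2 / 5) * var(X[, 1]), tolerance = 1e-12)
})

test_that("analytic marginals match the diagonal of the joint", {
  pair <- rgauss_pair(300, 0.4, seed = 31)
  kj <- fit_kde(cbind(pair$x, pair$y))
  km <- kde_marginal(kj, 1)
  expect_identical(km$dim, 1L)
  expect_equal(km$H[1, 1], kj$H[1, 1])
  # marginal density equals direct mixture over the kept axis
  grid <- seq(-2, 2, length.out = 11)
  direct <- rowMeans(outer(grid, pair$x, function(g, xi) {
    dnorm(g, xi, sqrt(kj$H[1, 1]))
  }))
  expect_equal(kde_evaluate(km, grid), direct, tolerance = 1e-12)
})

test_that("independent samples give MI indistinguishable from zero", {
  pair <- rgauss_pair(1e4, 0, seed = 41)
  est <- estimate_mi(pair$x, pair$y)
  expect_gt(est$mi_bits, -0.02)
  expect_lt(est$mi_bits, 0.05)
  expect_true(est$converged)
})

test_that("MI estimate is symmetric and affine invariant", {
  pair <- rgauss_pair(2000, 0.5, seed = 42)
  a <- estimate_mi(pair$x, pair$y)
  b <- estimate_mi(pair$y, pair$x)
  expect_equal(a$mi_bits, b$mi_bits,
    tolerance = max(1e-4, a$integration_error + b$integration_error)
  )
  shifted <- estimate_mi(3.2 * pair$x - 7, 0.01 * pair$y + 100)
  expect_equal(shifted$mi_bits, a$mi_bits, tolerance = 1e-6)
})

test_that("estimator error against the Gaussian oracle shrinks with n", {
  rho <- 0.5
  truth <- gaussian_mi_oracle(rho)
  mae <- vapply(c(500, 2000, 10000), function(n) {
    errs <- vapply(1:3, function(s) {
      pair <- rgauss_pair(n, rho, seed = 100 * s + n)
      abs(estimate_mi(pair$x, pair$y)$mi_bits - truth)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("degenerate MI inputs are refused", {
  expect_error(estimate_mi(1:5, rep(2, 5)), "constant")
  expect_error(estimate_mi(1:5, 1:4), "equal length")
  expect_error(estimate_mi(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("per-condition MI is replicate-wise bookkeeping with logged skips", {
  cfg <- synthetic_config(n_cells = 700)
  study <- generate_study(cfg,
    presets = c("wt", "dEx3"), doses = c(0, 150),
    times = "early", n_replicates = 2
  )
  mi <- mi_per_condition(study, min_events = 500)
  expect_identical(nrow(mi), 8L)
  expect_setequal(
    names(mi),
    c(
      "genotype", "dose_ng_ml", "time_min", "replicate", "mi_bits", "n",
      "integration_error"
    )
  )
  # undersized condition is skipped with a warning, not silently dropped
  small <- generate_study(synthetic_config(n_cells = 100),
    presets = "wt",
    doses = 0, times = "early", n_replicates = 1
  )
  expect_warning(
    mi2 <- mi_per_condition(c(study, small), min_events = 500),
    "skipped"
  )
  expect_identical(nrow(mi2), 8L)
})

test_that("robustness labelling is a pure interpretation layer", {
  mi <- data.frame(mi_bits = c(0.1, 0.9, 0.5))
  lab <- label_robustness(mi)
  expect_identical(lab$robustness_rank, c(1L, 3L, 2L))
  expect_identical(lab$interpretation[1], "robust (low MI)")
  expect_identical(lab$interpretation[2], "sensitive (high MI)")
  expect_identical(lab$mi_bits, mi$mi_bits)
})
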