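test_that("config invariants are enforced with named violations", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(beta = 1), "beta")
  expect_error(synthetic_config(delta_late = 0), "delta_late")
  expect_error(synthetic_config(K = 0), "K")
  expect_error(synthetic_config(h = -1), "h")
  expect_error(synthetic_config(sigma_eps = -0.1), "sigma_eps")
})

test_that("expression sampling recovers its log-normal moments", {
  cfg <- synthetic_config(mu_E = 2, sigma_E = 0.25)
  expect_identical(sample_expression(cfg, 0), numeric(0))
  expect_equal(sample_expression(synthetic_config(sigma_E = 0), 5),
    rep(100, 5),
    tolerance = 1e-12
  )
  n <- 1e5
  z <- log10(sample_expression(cfg, n, seed = 99))
  se_mean <- cfg$sigma_E / sqrt(n)
  se_sd <- cfg$sigma_E / sqrt(2 * (n - 1))
  expect_lt(abs(mean(z) - cfg$mu_E), 3 * se_mean)
  expect_lt(abs(sd(z) - cfg$sigma_E), 3 * se_sd)
})

test_that("response fraction follows the basal-plus-Hill form", {
  cfg <- synthetic_config(K = 20, h = 1.5, beta = 0.02, delta_late = 0.3)
  expect_equal(response_fraction(0, cfg, "early"), 0.02)
  cfg0 <- synthetic_config(K = 20, h = 2, beta = 0, delta_late = 0.3)
  expect_equal(response_fraction(20, cfg0, "early"), 0.5)
  expect_equal(response_fraction(1e9, cfg0, "late"), 0.3, tolerance = 1e-6)
  # nondecreasing in dose
  f <- response_fraction(seq(0, 200, by = 5), cfg, "early")
  expect_false(is.unsorted(f))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("zero gain decouples pSTAT3 from expression", {
  cfg <- synthetic_config(gain = 0, n_cells = 3000)
  tab <- log_transform(generate_condition(cfg, "wt", 150, "early", 1))
  est <- estimate_mi(tab$stat3, tab$pstat3)
  expect_lt(abs(est$mi_bits), 0.05)
})

test_that("noise-free saturated signal is exactly log-linear in expression", {
  cfg <- synthetic_config(sigma_eps = 0, mu_B = -Inf, n_cells = 500)
  tab <- log_transform(generate_condition(cfg, "wt", 1e6, "early", 1),
    floor = 1e-12
  )
  expect_equal(pearson_correlation(tab$stat3, tab$pstat3), 1, tolerance = 1e-9)
})

test_that("median pSTAT3 is nondecreasing in dose for the wt preset", {
  cfg <- synthetic_config(n_cells = 2000)
  med <- vapply(
    DEFAULT_DOSES,
    function(d) median(generate_condition(cfg, "wt", d, "early", 1)$pstat3),
    numeric(1)
  )
  expect_false(is.unsorted(med))
})

test_that("raising basal fraction raises dose-0 phosphorylation", {
  cfg <- synthetic_config(n_cells = 2000)
  meds <- vapply(c(0.02, 0.06, 0.12), function(b) {
    median(generate_condition(cfg, list(name = "wt", overrides = list(beta = b)),
      0, "early", 1
    )$pstat3)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("STAT3 expression draws are identical across the dose ladder", {
  cfg <- synthetic_config(n_cells = 1000)
  tabs <- lapply(c(0, 10, 150), function(d) {
    generate_condition(cfg, "wt", d, "early", 2)
  })
  expect_identical(tabs[[1]]$stat3, tabs[[2]]$stat3)
  expect_identical(tabs[[1]]$stat3, tabs[[3]]$stat3)
  # but the response stream differs by dose
  expect_false(identical(tabs[[1]]$pstat3, tabs[[3]]$pstat3))
})

test_that("wt_U0126 reproduces wt event-for-event", {
  cfg <- synthetic_config(n_cells = 500)
  for (d in c(0, 25)) {
    a <- generate_condition(cfg, "wt", d, "early", 1)
    b <- generate_condition(cfg, "wt_U0126", d, "early", 1)
    expect_identical(a$stat3, b$stat3)
    expect_identical(a$pstat3, b$pstat3)
  }
})

test_that("study generation is a deterministic full factorial", {
  cfg <- synthetic_config(n_cells = 50)
  study <- generate_study(cfg,
    presets = c("wt", "dEx3", "dEx3_SHP2", "wt_U0126"),
    doses = DEFAULT_DOSES, times = c("early", "late"), n_replicates = 3
  )
  expect_length(study, 4 * 7 * 2 * 3)
  expect_true(all(vapply(study, nrow, integer(1)) == 50L))
  study2 <- generate_study(cfg,
    presets = c("wt", "dEx3", "dEx3_SHP2", "wt_U0126"),
    doses = DEFAULT_DOSES, times = c("early", "late"), n_replicates = 3
  )
  expect_identical(study, study2)
  expect_error(
    generate_study(cfg, presets = c("wt", "wt"), doses = 0, times = "early"),
    "duplicate"
  )
})

test_that("replicates and genotypes get distinct substreams", {
  cfg <- synthetic_config(n_cells = 300)
  r1 <- generate_condition(cfg, "wt", 10, "early", 1)
  r2 <- generate_condition(cfg, "wt", 10, "early", 2)
  expect_false(identical(r1$stat3, r2$stat3))
  g2 <- generate_condition(cfg, "dEx3", 10, "early", 1)
  expect_false(identical(r1$pstat3, g2$pstat3))
})
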