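# Independent oracle: composite trapezoid on a fine grid containing the
# measurement knots, over the piecewise-linear utility trajectory that
# carries the 1-month value back to baseline.
qaly_numint <- function(u1, u6, u12) {
  tgrid <- seq(0, 12, by = 1 / 128)
  vals <- approx(x = c(0, 1, 6, 12), y = c(u1, u1, u6, u12),
                 xout = tgrid)$y
  sum((vals[-1] + vals[-length(vals)]) / 2 * diff(tgrid)) / 12
}

test_that("trapezoidal QALYs match hand values and the integration oracle", {
  expect_equal(qaly_auc(1, 1, 1), 1)
  expect_equal(qaly_auc(0.710, 0.685, 0.680), 0.691, tolerance = 1e-3)
  expect_equal(qaly_auc(0.745, 0.740, 0.735), 0.740, tolerance = 1e-3)
  expect_equal(round(qaly_auc(0.710, 0.685, 0.680), 2), 0.69)
  expect_equal(round(qaly_auc(0.745, 0.740, 0.735), 2), 0.74)

  set.seed(8)
  for (i in 1:50) {
    u <- runif(3)
    expect_equal(qaly_auc(u[1], u[2], u[3]), qaly_numint(u[1], u[2], u[3]),
                 tolerance = 1e-12)
    # bounded by the extreme utilities; translation adds the constant
    expect_gte(qaly_auc(u[1], u[2], u[3]), min(u))
    expect_lte(qaly_auc(u[1], u[2], u[3]), max(u))
    c0 <- min(1 - max(u), 0.1)
    expect_equal(qaly_auc(u[1] + c0, u[2] + c0, u[3] + c0),
                 qaly_auc(u[1], u[2], u[3]) + c0, tolerance = 1e-12)
  }
  expect_error(qaly_auc(0.5, NA, 0.5), "impute")
  expect_error(qaly_auc(0.5, 0.5, 1.5), "\\[0, 1\\]")
})

test_that("Rubin pooling combines estimates and variances correctly", {
  p <- pool_rubin(0.5, 0.01)
  expect_equal(p$estimate, 0.5)
  expect_equal(p$variance, 0.01)           # m = 1: within variance only

  p <- pool_rubin(rep(0.3, 4), rep(0.02, 4))
  expect_equal(p$between, 0)
  expect_equal(p$variance, 0.02)

  p <- pool_rubin(c(0.5, 0.7), c(0.01, 0.01))
  expect_equal(p$estimate, 0.6)
  expect_equal(p$variance, 0.01 + 1.5 * 0.02)
  expect_error(pool_rubin(c(1, 2), 1), "equal length")
})

test_that("imputation is the identity on complete data and local to missing cells", {
  rec <- apply_mitt_filter(generate_trial(mini_config(missing_prob = 0), seed = 2))
  done <- impute_utilities(rec, imputation_spec(m = 3, seed = 1))
  expect_length(done, 3)
  for (d in done) expect_identical(d, rec)

  hole <- rec
  hole$u12[5] <- NA
  done <- impute_utilities(hole, imputation_spec(m = 5, seed = 1))
  filled <- vapply(done, function(d) d$u12[5], numeric(1))
  expect_false(anyNA(filled))
  expect_true(all(filled >= 0 & filled <= 1))
  expect_gt(length(unique(filled)), 1)     # stochastic draws, not a point fill
  for (d in done) {
    d2 <- d; d2$u12[5] <- NA
    expect_identical(d2, hole)             # nothing but that cell changed
  }
  # reproducible from the spec seed
  again <- impute_utilities(hole, imputation_spec(m = 5, seed = 1))
  expect_identical(done, again)
})

test_that("imputation refuses a timepoint entirely missing within an arm", {
  rec <- apply_mitt_filter(generate_trial(mini_config(missing_prob = 0), seed = 2))
  rec$u6[rec$arm == "control"] <- NA
  expect_error(impute_utilities(rec, imputation_spec(m = 2)),
               "u6 entirely missing in the control arm")
})

test_that("MI recovers the generator's arm mean QALYs under 20% MAR missingness", {
  cfg <- mini_config(n = c(600L, 600L), dropouts = c(0L, 0L),
                     missing_prob = 0.2)
  full <- generate_trial(cfg, seed = 31)
  expect_gt(mean(is.na(full[, c("u1", "u6", "u12")])), 0.1)
  res <- trial_qaly(full, imputation_spec(m = 10, seed = 7))
  # no-missingness reference from the same config
  cfg0 <- mini_config(n = c(600L, 600L), dropouts = c(0L, 0L),
                      missing_prob = 0)
  ref <- generate_trial(cfg0, seed = 31)
  for (a in c("intervention", "control")) {
    r <- ref[ref$arm == a, ]
    q0 <- qaly_auc(r$u1, r$u6, r$u12)
    se <- sqrt(var(q0) / length(q0) + res$arm_means[[a]]$variance)
    expect_lt(abs(res$arm_means[[a]]$estimate - mean(q0)), 2 * se)
  }
})

test_that("utility scoring hook refuses the licensed algorithm but accepts the toy scorer", {
  expect_error(sf6d_scorer(matrix(50, 1, 8)), "licensed")
  sc <- toy_linear_scorer(matrix(c(100, 50, 0), 3, 8))
  expect_equal(sc, c(1, 0.5, 0))
  expect_error(toy_linear_scorer(matrix(120, 1, 8)), "0, 100")
})
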