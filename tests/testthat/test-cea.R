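test_that("pooled-variance t test matches the textbook formula", {
  a <- c(1, 2, 3)
  expect_equal(mean_diff_ttest(a, a)$difference, 0)
  expect_equal(mean_diff_ttest(a, a)$p_value, 1)

  b <- a + 1
  res <- mean_diff_ttest(a, b)
  # hand-computed pooled t: sp2 = 1, se = sqrt(1 * (1/3 + 1/3))
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  se <- sqrt(sp2 * (1 / 3 + 1 / 3))
  tcrit <- qt(0.975, 4)
  expect_equal(res$difference, -1)
  expect_equal(res$ci, c(-1 - tcrit * se, -1 + tcrit * se), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(-1 / se), 4), tolerance = 1e-12)
  # interval contains its point estimate
  expect_true(res$ci[1] <= res$difference && res$difference <= res$ci[2])
  expect_error(mean_diff_ttest(1, c(1, 2)), "at least 2")
})

test_that("bootstrap draws collapse to the point estimate when arms are homogeneous", {
  dat <- toy_completed(int_cost = rep(100, 4), ctl_cost = rep(300, 5),
                       int_qaly = rep(0.8, 4), ctl_qaly = rep(0.7, 5))
  draws <- bootstrap_ce(dat, B = 50, seed = 1)
  expect_equal(nrow(draws), 50)
  p <- attr(draws, "point")
  expect_true(all(draws$delta_cost == p[["delta_cost"]]))
  expect_true(all(draws$delta_qaly == p[["delta_qaly"]]))
  expect_equal(unname(p), c(-200, 0.1))
})

test_that("bootstrap is reproducible and requires both arms", {
  dat <- toy_completed(c(100, 900), c(200, 400), c(0.8, 0.6), c(0.7, 0.5))
  one <- bootstrap_ce(dat, B = 1, seed = 5)
  two <- bootstrap_ce(dat, B = 1, seed = 5)
  expect_identical(one, two)
  expect_error(bootstrap_ce(dat[dat$arm == "control", ], B = 1, seed = 1),
               "nonempty")
})

test_that("two-per-arm bootstrap matches brute-force enumeration of resamples", {
  dat <- toy_completed(c(0, 100), c(30, 170), c(0.9, 0.5), c(0.8, 0.4))
  # within-arm resampling of 2 patients: each arm mean is the low value
  # w.p. 1/4, the midpoint w.p. 1/2, the high value w.p. 1/4; the chosen
  # costs make all nine incremental values distinct
  arm_means <- function(x) c(x[1], mean(x), x[2])
  probs <- c(0.25, 0.5, 0.25)
  exp_dc <- outer(arm_means(c(0, 100)), arm_means(c(30, 170)), `-`)
  exp_p <- outer(probs, probs)
  draws <- bootstrap_ce(dat, B = 20000, seed = 3)
  for (i in 1:3) for (j in 1:3) {
    freq <- mean(draws$delta_cost == exp_dc[i, j])
    se <- sqrt(exp_p[i, j] * (1 - exp_p[i, j]) / 20000)
    expect_lt(abs(freq - exp_p[i, j]), 4 * se)
  }
  # every draw is one of the 9 enumerated values
  expect_true(all(draws$delta_cost %in% as.vector(exp_dc)))
})

test_that("bootstrap means converge to the point estimates", {
  set.seed(99)
  dat <- toy_completed(rnorm(40, 2400, 500), rnorm(50, 2900, 500),
                       rnorm(40, 0.74, 0.1), rnorm(50, 0.69, 0.1))
  draws <- bootstrap_ce(dat, B = 10000, seed = 2)
  p <- attr(draws, "point")
  se_c <- sd(draws$delta_cost) / sqrt(10000)
  se_q <- sd(draws$delta_qaly) / sqrt(10000)
  expect_lt(abs(mean(draws$delta_cost) - p[["delta_cost"]]), 3 * se_c)
  expect_lt(abs(mean(draws$delta_qaly) - p[["delta_qaly"]]), 3 * se_q)
})

test_that("CEAC counts strictly positive net benefit, with ties not cost-effective", {
  dom <- data.frame(delta_cost = c(-10, -5), delta_qaly = c(0.1, 0.2))
  expect_true(all(ceac(dom)$probability == 1))

  tie <- data.frame(delta_cost = c(-10, 10), delta_qaly = c(0.1, -0.1))
  curve <- ceac(tie, wtp_grid = c(0, 50, 100, 200))
  # at wtp 100 the second pair has nmb exactly 0: a tie, not cost-effective
  expect_equal(curve$probability, rep(0.5, 4))
  expect_error(ceac(tie, wtp_grid = c(0, 0, 10)), "strictly increasing")
})

test_that("CEAC limits equal the cost and effect dominance fractions", {
  set.seed(17)
  draws <- data.frame(delta_cost = rnorm(500, -100, 400),
                      delta_qaly = rnorm(500, 0.03, 0.05))
  curve <- ceac(draws, wtp_grid = c(0, 1e9))
  expect_equal(curve$probability[1], mean(draws$delta_cost < 0))
  expect_equal(curve$probability[2], mean(draws$delta_qaly > 0))
})

test_that("the CEAC agrees with the net-monetary-benefit path and ignores draw order", {
  set.seed(23)
  draws <- data.frame(delta_cost = rnorm(300, -471, 350),
                      delta_qaly = rnorm(300, 0.05, 0.02))
  grid <- seq(0, 100000, by = 2500)
  curve <- ceac(draws, grid)
  via_nmb <- vapply(grid, function(l)
    mean(nmb(l, draws$delta_qaly, draws$delta_cost) > 0), numeric(1))
  expect_identical(curve$probability, via_nmb)
  shuffled <- draws[sample(nrow(draws)), ]
  expect_equal(ceac(shuffled, grid)$probability, curve$probability)
})

test_that("ICER quadrants and net monetary benefit follow their definitions", {
  expect_equal(icer(-471, 0.05)$status, "dominant")
  expect_equal(icer(100, 0.05), list(icer = 2000, status = "ratio"))
  expect_equal(icer(100, 0)$status, "undefined")
  expect_equal(icer(100, -0.05)$status, "dominated")

  expect_equal(nmb(20000, 0.05, -471), 1471)
  expect_equal(nmb(0, 0.123, -471), 471)
  expect_equal(nmb(50000, 0, 0), 0)
  expect_error(nmb(-1, 0.1, 0), ">= 0")
})
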