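#' One-year QALY from a utility trajectory (area under the curve)
#'
#' Utilities measured at months 1, 6 and 12 are joined piecewise-linearly
#' and the area under the curve over months 0-12 is divided by 12.  The
#' first month, where no measurement exists, carries the 1-month utility
#' back to baseline, so
#' \deqn{QALY = \left[u_1 \cdot 1 + \frac{u_1+u_6}{2} \cdot 5 +
#'   \frac{u_6+u_{12}}{2} \cdot 6\right] / 12
#'   = (3.5\,u_1 + 5.5\,u_6 + 3\,u_{12})/12.}{
#'   QALY = (3.5 u1 + 5.5 u6 + 3 u12) / 12.}
#'
#' All inputs must be observed (run after imputation); the result always
#' lies between the smallest and largest of the three utilities.
#'
#' @param u1,u6,u12 Utilities in \[0, 1\] at months 1, 6, 12
#'   (vectorised).  Alternatively `u1` may be a data frame holding
#'   columns `u1`, `u6`, `u12`.
#' @return One-year QALYs (years, in \[0, 1\]).
#' @export
qaly_auc <- function(u1, u6 = NULL, u12 = NULL) {
  if (is.data.frame(u1)) {
    df <- u1
    u1 <- df$u1; u6 <- df$u6; u12 <- df$u12
  }
  if (anyNA(u1) || anyNA(u6) || anyNA(u12))
    stop("qaly_auc requires complete utilities; impute missing values first")
  if (any(c(u1, u6, u12) < 0) || any(c(u1, u6, u12) > 1))
    stop("utilities must lie in [0, 1]")
  (3.5 * u1 + 5.5 * u6 + 3 * u12) / 12
}

#' Multiple-imputation specification
#'
#' @param m Number of imputed datasets (>= 1); 20 by default.
#' @param predictors Covariates entering every imputation model;
#'   previously observed utilities are always added for later timepoints.
#'   The randomisation arm is included by default: leaving the analysis
#'   grouping out of the imputation model shrinks imputed values toward
#'   the pooled mean and attenuates the between-arm difference.
#' @param seed Integer RNG seed.
#' @return List of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20L,
                            predictors = c("arm", "age", "sex", "index_event",
                                           "log_troponin"),
                            seed = 1L) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  structure(list(m = m, predictors = predictors, seed = as.integer(seed)),
            class = "imputation_spec")
}

# Design matrix for the imputation regressions.
imputation_design <- function(records, predictors, earlier = character()) {
  df <- data.frame(row.names = seq_len(nrow(records)))
  for (p in predictors) {
    v <- switch(p,
      log_troponin = log(records$troponin),
      arm = as.numeric(records$arm == "intervention"),
      sex = as.numeric(records$sex == "male"),
      index_event = as.numeric(records$index_event == "STEMI"),
      records[[p]])
    df[[p]] <- v
  }
  for (e in earlier) df[[e]] <- records[[e]]
  as.matrix(cbind(`(Intercept)` = 1, df))
}

# One Bayesian linear-regression imputation draw (the classic normal
# model: sigma^2 from the scaled inverse chi-square, beta from its normal
# posterior, then a predictive draw per missing value), clipped to [0,1].
draw_imputation <- function(y_obs, X_obs, X_mis) {
  qrX <- qr(X_obs)
  beta_hat <- qr.coef(qrX, y_obs)
  res <- y_obs - X_obs %*% beta_hat
  df <- length(y_obs) - qrX$rank
  if (df < 1L) stop("too few observed utilities to fit the imputation model")
  sigma2 <- sum(res^2) / rchisq(1L, df)
  R <- qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank), drop = FALSE]
  keep <- qrX$pivot[seq_len(qrX$rank)]
  z <- rnorm(qrX$rank)
  beta_star <- beta_hat
  beta_star[keep] <- beta_hat[keep] + backsolve(R, z) * sqrt(sigma2)
  beta_star[is.na(beta_star)] <- 0
  mu <- drop(X_mis %*% beta_star)
  pmin(1, pmax(0, mu + rnorm(length(mu)) * sqrt(sigma2)))
}

#' Multiply impute missing utilities
#'
#' Replaces missing utilities by stochastic draws from Bayesian
#' normal-regression models fitted sequentially over the timepoints
#' (months 1, then 6, then 12), with baseline covariates as predictors
#' throughout and earlier (observed or just-imputed) utilities added for
#' the later timepoints.  Observed values are never touched; draws are
#' clipped to \[0, 1\]; the whole procedure is reproducible from the
#' spec's seed.  A fully observed dataset returns `m` identical copies
#' of the input.
#'
#' @param records Trial data frame (post modified-ITT filter) with
#'   utility columns `u1,u6,u12` and the imputation spec's predictor
#'   covariates.
#' @param spec An [imputation_spec()].
#' @return List of `m` completed data frames (class
#'   `imputed_datasets`).
#' @export
impute_utilities <- function(records, spec = imputation_spec()) {
  stopifnot(inherits(spec, "imputation_spec"))
  ucols <- c("u1", "u6", "u12")
  if (!all(ucols %in% names(records))) stop("records lack utility columns u1,u6,u12")
  for (arm in unique(records$arm)) {
    sub <- records[records$arm == arm, ucols, drop = FALSE]
    all_missing <- ucols[vapply(sub, function(v) all(is.na(v)), logical(1))]
    if (length(all_missing) > 0L)
      stop("cannot impute: timepoint(s) ", paste(all_missing, collapse = ", "),
           " entirely missing in the ", arm, " arm")
  }
  set.seed(spec$seed)
  completed <- vector("list", spec$m)
  for (k in seq_len(spec$m)) {
    dat <- records
    earlier <- character()
    for (uc in ucols) {
      mis <- is.na(dat[[uc]])
      if (any(mis)) {
        X <- imputation_design(dat, spec$predictors, earlier)
        dat[[uc]][mis] <- draw_imputation(dat[[uc]][!mis],
                                          X[!mis, , drop = FALSE],
                                          X[mis, , drop = FALSE])
      }
      earlier <- c(earlier, uc)
    }
    completed[[k]] <- dat
  }
  structure(completed, class = "imputed_datasets")
}

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is the mean within-imputation variance plus
#' \eqn{(1 + 1/m)} times the between-imputation variance.  Degrees of
#' freedom follow the classic large-sample formula.
#'
#' @param point_estimates Numeric vector of per-imputation estimates.
#' @param within_variances Numeric vector of per-imputation squared
#'   standard errors (same length).
#' @return List: `estimate`, `variance`, `within`, `between`, `m`, `df`.
#' @export
pool_rubin <- function(point_estimates, within_variances) {
  m <- length(point_estimates)
  if (m < 1L || length(within_variances) != m)
    stop("point_estimates and within_variances must have equal length >= 1")
  qbar <- mean(point_estimates)
  wbar <- mean(within_variances)
  b <- if (m > 1L) var(point_estimates) else 0
  total <- wbar + (1 + 1 / m) * b
  df <- if (m > 1L && b > 0) (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2 else Inf
  list(estimate = qbar, variance = total, within = wbar, between = b,
       m = m, df = df)
}

#' Arm QALY summary with multiple imputation
#'
#' Computes per-patient one-year QALYs by [qaly_auc()] within each
#' imputed dataset, then pools arm means and the between-arm difference
#' (intervention minus control) over imputations by [pool_rubin()],
#' with a t-based 95% confidence interval and two-sided p-value for the
#' difference using the pooled degrees of freedom.
#'
#' @param records Trial data frame (post modified-ITT filter), or an
#'   `imputed_datasets` list from [impute_utilities()].
#' @param spec An [imputation_spec()], used when `records` still needs
#'   imputing.
#' @param conf_level Confidence level for the difference interval.
#' @return List of class `qaly_result`: `arm_means` (pooled mean QALY
#'   per arm with Rubin variance), `difference` (estimate, `ci`,
#'   `p_value`), `m`, and `completed` (the imputed datasets, with a
#'   per-patient `qaly` column added).
#' @export
trial_qaly <- function(records, spec = imputation_spec(), conf_level = 0.95) {
  completed <- if (inherits(records, "imputed_datasets")) records
               else impute_utilities(records, spec)
  completed <- lapply(completed, function(dat) {
    dat$qaly <- qaly_auc(dat$u1, dat$u6, dat$u12)
    dat
  })
  m <- length(completed)
  arms <- c("intervention", "control")
  est <- sapply(completed, function(dat)
    vapply(arms, function(a) mean(dat$qaly[dat$arm == a]), numeric(1)))
  wvar <- sapply(completed, function(dat)
    vapply(arms, function(a) {
      q <- dat$qaly[dat$arm == a]
      var(q) / length(q)
    }, numeric(1)))
  est <- matrix(est, nrow = 2, dimnames = list(arms, NULL))
  wvar <- matrix(wvar, nrow = 2, dimnames = list(arms, NULL))
  arm_means <- lapply(arms, function(a) pool_rubin(est[a, ], wvar[a, ]))
  names(arm_means) <- arms
  dpool <- pool_rubin(est["intervention", ] - est["control", ],
                      wvar["intervention", ] + wvar["control", ])
  se <- sqrt(dpool$variance)
  tcrit <- qt(1 - (1 - conf_level) / 2, dpool$df)
  pval <- if (se == 0) as.numeric(dpool$estimate == 0) else
    2 * pt(-abs(dpool$estimate / se), dpool$df)
  if (se == 0) tcrit <- 0
  structure(list(arm_means = arm_means,
                 difference = list(estimate = dpool$estimate,
                                   ci = c(dpool$estimate - tcrit * se,
                                          dpool$estimate + tcrit * se),
                                   se = se, df = dpool$df, p_value = pval),
                 m = m, completed = structure(completed,
                                              class = "imputed_datasets")),
            class = "qaly_result")
}

#' @export
print.qaly_result <- function(x, ...) {
  cat("One-year QALYs (multiple imputation, m =", x$m, ")\n")
  for (a in names(x$arm_means))
    cat(sprintf("  %-13s %.3f (Rubin SE %.4f)\n", a,
                x$arm_means[[a]]$estimate, sqrt(x$arm_means[[a]]$variance)))
  d <- x$difference
  cat(sprintf("  difference (intervention - control) %.3f, 95%% CI %.3f to %.3f, p = %.3f\n",
              d$estimate, d$ci[1], d$ci[2], d$p_value))
  invisible(x)
}

#' Health-utility scorer hook
#'
#' Utilities enter the pipeline as numbers; deriving them from SF-36
#' questionnaire responses requires the SF-6D algorithm, which is
#' licensed by the University of Sheffield and therefore not shipped.
#' `sf6d_scorer()` is the default hook and refuses with a licensing
#' notice.  `toy_linear_scorer()` is an explicitly synthetic stand-in
#' (the mean of the eight 0-100 SF-36 domain scores rescaled to
#' \[0, 1\]) intended only for wiring tests; its values have no claim to
#' valuation validity.
#'
#' @param sf36 Data frame or matrix of SF-36 domain scores on the 0-100
#'   scale, one row per response.
#' @return Numeric utilities in \[0, 1\].
#' @export
sf6d_scorer <- function(sf36) {
  stop("SF-36 to SF-6D utility conversion is licensed (University of ",
       "Sheffield) and is not distributed with this package; supply ",
       "utilities directly or plug in a licensed scorer.")
}

#' @rdname sf6d_scorer
#' @export
toy_linear_scorer <- function(sf36) {
  m <- as.matrix(sf36)
  if (any(m < 0) || any(m > 100)) stop("SF-36 domain scores must be in [0, 100]")
  pmin(1, pmax(0, rowMeans(m) / 100))
}
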