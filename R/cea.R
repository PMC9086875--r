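#' Independent two-sample t test on means
#'
#' Pooled-variance (Student) t test of a difference in means, as used for
#' the per-item and total cost comparisons.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @param conf_level Confidence level.
#' @return List: `difference` (`mean(values_a) - mean(values_b)`), `ci`
#'   (two-sided interval), `p_value`, `df`.
#' @export
mean_diff_ttest <- function(values_a, values_b, conf_level = 0.95) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 observations")
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    return(list(difference = d, ci = c(d, d),
                p_value = if (d == 0) 1 else 0,
                df = length(values_a) + length(values_b) - 2))
  }
  tt <- t.test(values_a, values_b, var.equal = TRUE, conf.level = conf_level)
  list(difference = unname(tt$estimate[1] - tt$estimate[2]),
       ci = as.numeric(tt$conf.int), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Nonparametric bootstrap of incremental costs and effects
#'
#' Resamples patients with replacement within each arm at the original
#' arm sizes (stratified, preserving the randomisation structure) and
#' records the incremental mean cost and mean QALY (intervention minus
#' control) per replicate.  When several multiply-imputed completed
#' datasets are supplied, replicates cycle over them so that imputation
#' uncertainty propagates into the draws.
#'
#' @param completed A completed trial data frame with per-patient
#'   `total_cost` and `qaly` columns, or a list of such data frames (one
#'   per imputation, e.g. from [trial_qaly()] after attaching costs).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return Data frame of class `ce_draws` with `B` rows and columns
#'   `delta_cost`, `delta_qaly`; attributes `point` (the point estimates
#'   averaged over imputations) and `seed`.
#' @export
bootstrap_ce <- function(completed, B = 1000L, seed = 1L) {
  if (is.data.frame(completed)) completed <- list(completed)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  for (dat in completed)
    if (!all(c("arm", "total_cost", "qaly") %in% names(dat)))
      stop("completed datasets need columns arm, total_cost, qaly")
  m <- length(completed)
  idx <- lapply(completed, function(dat)
    list(int = which(dat$arm == "intervention"),
         ctl = which(dat$arm == "control")))
  if (any(vapply(idx, function(i) length(i$int) == 0L || length(i$ctl) == 0L,
                 logical(1))))
    stop("both arms must be nonempty")
  set.seed(as.integer(seed))
  dc <- dq <- numeric(B)
  for (b in seq_len(B)) {
    dat <- completed[[((b - 1L) %% m) + 1L]]
    ii <- idx[[((b - 1L) %% m) + 1L]]
    si <- sample(ii$int, length(ii$int), replace = TRUE)
    sc <- sample(ii$ctl, length(ii$ctl), replace = TRUE)
    dc[b] <- mean(dat$total_cost[si]) - mean(dat$total_cost[sc])
    dq[b] <- mean(dat$qaly[si]) - mean(dat$qaly[sc])
  }
  point <- rowMeans(vapply(completed, function(dat)
    c(delta_cost = mean(dat$total_cost[dat$arm == "intervention"]) -
        mean(dat$total_cost[dat$arm == "control"]),
      delta_qaly = mean(dat$qaly[dat$arm == "intervention"]) -
        mean(dat$qaly[dat$arm == "control"])), numeric(2)))
  structure(data.frame(delta_cost = dc, delta_qaly = dq),
            class = c("ce_draws", "data.frame"),
            point = point, seed = as.integer(seed))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value \eqn{\lambda} on the grid, the
#' proportion of bootstrap (incremental cost, incremental QALY) pairs for
#' which the intervention is cost-effective, i.e. has strictly positive
#' net monetary benefit \eqn{\lambda \Delta E - \Delta C > 0}; ties count
#' as not cost-effective.  At \eqn{\lambda = 0} the curve equals the
#' fraction of draws with negative incremental cost, and as
#' \eqn{\lambda \to \infty} it approaches the fraction with positive
#' incremental QALY.
#'
#' @param draws A `ce_draws` object (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid Strictly increasing willingness-to-pay grid in
#'   euros/QALY; by default 0 to 100,000 in steps of 500, covering the
#'   Dutch threshold range of 20,000-80,000 EUR/QALY.
#' @return Data frame of class `ceac_curve` with columns `wtp`,
#'   `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 100000, by = 500)) {
  if (nrow(draws) == 0L) stop("no bootstrap draws supplied")
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("wtp_grid must be strictly increasing")
  prob <- vapply(wtp_grid, function(lambda)
    mean(lambda * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' @param delta_cost Incremental cost (intervention minus control),
#'   euros.
#' @param delta_qaly Incremental effect, QALYs.
#' @return List: `icer` (euros/QALY, `NA` when flagged) and `status`,
#'   one of `"dominant"` (cheaper and more effective), `"dominated"`
#'   (costlier and less effective), `"undefined"` (zero incremental
#'   effect) or `"ratio"`.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0)
    return(list(icer = NA_real_, status = "undefined"))
  if (delta_cost < 0 && delta_qaly > 0)
    return(list(icer = NA_real_, status = "dominant"))
  if (delta_cost > 0 && delta_qaly < 0)
    return(list(icer = NA_real_, status = "dominated"))
  list(icer = delta_cost / delta_qaly, status = "ratio")
}

#' Incremental net monetary benefit
#'
#' @param wtp Willingness to pay per QALY, euros (>= 0, vectorised).
#' @param delta_qaly Incremental effect, QALYs.
#' @param delta_cost Incremental cost, euros.
#' @return Euros: `wtp * delta_qaly - delta_cost`.
#' @export
nmb <- function(wtp, delta_qaly, delta_cost) {
  if (any(wtp < 0)) stop("willingness to pay must be >= 0")
  wtp * delta_qaly - delta_cost
}

#' @export
print.ce_draws <- function(x, ...) {
  p <- attr(x, "point")
  cat(sprintf("CE bootstrap draws: B = %d, point estimate dCost %.1f EUR, dQALY %.4f\n",
              nrow(x), p["delta_cost"], p["delta_qaly"]))
  q <- c(mean(x$delta_cost < 0), mean(x$delta_qaly > 0))
  cat(sprintf("  P(dCost < 0) = %.3f, P(dQALY > 0) = %.3f\n", q[1], q[2]))
  invisible(x)
}

#' @export
print.ceac_curve <- function(x, ...) {
  cat(sprintf("CEAC over %d WTP values (%.0f to %.0f EUR/QALY): min %.3f, max %.3f\n",
              nrow(x), min(x$wtp), max(x$wtp), min(x$probability),
              max(x$probability)))
  invisible(x)
}
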