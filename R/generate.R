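# Mean of a N(mu, sd^2) variable clipped coordinate-wise to [0, 1].
clipped_normal_mean <- function(mu, sd) {
  if (sd == 0) return(pmin(1, pmax(0, mu)))
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b)) + (1 - pnorm(b))
}

# Latent mean such that the clipped draw has the target mean.  Clipping a
# normal utility to [0, 1] pulls the mean down (the mass above 1 is larger
# than the mass below 0 at these parameters); inverting the closed-form
# clipped mean keeps the generated arm means on target.
latent_utility_mean <- function(target, sd) {
  if (sd == 0) return(target)
  vapply(target, function(tg)
    uniroot(function(m) clipped_normal_mean(m, sd) - tg,
            lower = tg - 4 * sd, upper = tg + 4 * sd, tol = 1e-12)$root,
    numeric(1))
}

# One arm's item counts and costs under an item_model.
draw_item <- function(im, arm, n) {
  rate <- im$rate[[arm]]
  unit <- im$unit_cost[[arm]]
  count <- switch(im$count_dist,
    fixed = rep.int(as.integer(round(rate)), n),
    bernoulli = rbinom(n, 1L, rate),
    poisson = rpois(n, rate),
    visit = {
      base <- floor(rate)
      cnt <- base + rbinom(n, 1L, rate - base)
      if (im$jitter_prob > 0) {
        u <- runif(n)
        jit <- (u < im$jitter_prob) * -1L + (u > 1 - im$jitter_prob) * 1L
        cnt <- cnt + ifelse(cnt >= 1L, jit, 0L)
      }
      cnt
    })
  if (im$severity == "fixed" || unit == 0) {
    cost <- count * unit
  } else {
    shape1 <- 1 / im$severity_cv^2
    cost <- numeric(n)
    pos <- count > 0L
    # sum of k iid gamma(shape1, scale) draws is gamma(k * shape1, scale)
    cost[pos] <- rgamma(sum(pos), shape = count[pos] * shape1,
                        scale = unit * im$severity_cv^2)
  }
  list(count = count, cost = cost)
}

# Correlated utility triple for one arm, clipped to [0, 1], with latent
# means calibrated so post-clip means equal the configured targets.
draw_utilities <- function(n, means, sd, rho) {
  if (sd == 0) return(matrix(pmin(1, pmax(0, means)), n, 3, byrow = TRUE))
  lat <- latent_utility_mean(means, sd)
  sigma <- sd^2 * (diag(3) * (1 - rho) + rho)
  z <- matrix(rnorm(n * 3), n, 3)
  u <- z %*% chol(sigma) + matrix(lat, n, 3, byrow = TRUE)
  u[] <- pmin(1, pmax(0, u))
  u
}

#' Generate a synthetic trial dataset
#'
#' Simulates one realisation of the two-arm trial described by a
#' [trial_config()]: baseline covariates, early-dropout flags, per-item
#' resource counts and costs from the two-part item models, and utility
#' trajectories at months 1/6/12 from a correlated (exchangeable) normal
#' model clipped to \[0, 1\], with missing-at-random gaps whose
#' probability follows a logistic model in age and the most recent
#' observed utility.  Early dropouts carry no follow-up utilities.
#'
#' @param config A `trial_config`.
#' @param seed Integer RNG seed; defaults to `config$seed`.  The same
#'   `(config, seed)` pair always yields the identical dataset.
#' @return Data frame with one row per enrolled patient: `patient_id`,
#'   `arm`, `dropout`, `age`, `sex`, `index_event`, `troponin`, one
#'   `count_<item>` and one `cost_<item>` column per item, and `u1`,
#'   `u6`, `u12` (NA where missing).
#' @export
generate_trial <- function(config, seed = config$seed) {
  validate_trial_config(config)
  if (is.null(seed)) stop("a seed is required (in the config or as an argument)")
  set.seed(as.integer(seed))
  cov <- config$covariate_model
  arms <- c("intervention", "control")
  out <- vector("list", 2L)
  for (k in seq_along(arms)) {
    arm <- arms[k]
    n <- config$n_enrolled[[arm]]
    if (n == 0L) next
    df <- data.frame(
      patient_id = sprintf("%s-%03d", toupper(substr(arm, 1, 3)), seq_len(n)),
      arm = arm,
      dropout = FALSE,
      age = round(rnorm(n, cov$age_mean, cov$age_sd), 1),
      sex = ifelse(rbinom(n, 1L, cov$male_prob) == 1L, "male", "female"),
      index_event = ifelse(rbinom(n, 1L, cov$stemi_prob) == 1L, "STEMI", "NSTEMI"),
      troponin = exp(rnorm(n, cov$troponin_meanlog, cov$troponin_sdlog)),
      stringsAsFactors = FALSE)
    if (config$dropouts[[arm]] > 0L)
      df$dropout[sample.int(n, config$dropouts[[arm]])] <- TRUE
    for (im in config$item_models) {
      d <- draw_item(im, arm, n)
      df[[paste0("count_", im$item_id)]] <- d$count
      df[[paste0("cost_", im$item_id)]] <- d$cost
    }
    u <- draw_utilities(n, config$utility_means[arm, ], config$utility_sd,
                        config$utility_correlation)
    # sequential MAR missingness: logit depends on age and the previous
    # observed utility (age only where the previous one is itself missing)
    base_logit <- qlogis(config$missing_prob)
    age_term <- config$missing_beta_age * (df$age - 60)
    prev <- rep(NA_real_, n)
    for (j in 1:3) {
      lp <- base_logit + age_term +
        ifelse(is.na(prev), 0, config$missing_beta_prev * (prev - 0.7))
      miss <- runif(n) < plogis(lp)
      col <- c("u1", "u6", "u12")[j]
      df[[col]] <- ifelse(miss, NA_real_, u[, j])
      prev <- df[[col]]
    }
    df[df$dropout, c("u1", "u6", "u12")] <- NA_real_
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Modified intention-to-treat filter
#'
#' Removes patients who dropped out within two weeks of enrolment (the
#' pre-specified early-dropout criterion); patients who died during
#' follow-up are retained.  With the default configuration's 12/8
#' dropouts this leaves 88 intervention and 92 control patients.
#'
#' @param records Trial data frame with a logical `dropout` column.
#' @return The records with `dropout == FALSE`.  Warns if nothing
#'   remains.
#' @export
apply_mitt_filter <- function(records) {
  stopifnot(is.data.frame(records), "dropout" %in% names(records))
  kept <- records[!records$dropout, , drop = FALSE]
  if (nrow(kept) == 0L && nrow(records) > 0L)
    warning("all patients were flagged as early dropouts; no records remain")
  rownames(kept) <- NULL
  kept
}

#' Read / write patient-level trial records
#'
#' Records are exchanged as UTF-8 CSV with a header row, one row per
#' patient, item columns prefixed `count_` / `cost_`, and utilities in
#' columns `u1,u6,u12` where an empty cell means missing.
#'
#' @param records Trial data frame (as from [generate_trial()]).
#' @param path File path.
#' @return `write_trial_csv()` returns `path` invisibly;
#'   `read_trial_csv()` returns the records data frame.
#' @export
write_trial_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("patient_id", "arm", "dropout", "u1", "u6", "u12")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("malformed trial CSV; missing columns: ",
         paste(missing_cols, collapse = ", "))
  df$dropout <- as.logical(df$dropout)
  df
}
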