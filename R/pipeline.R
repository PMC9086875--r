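#' End-to-end cost-utility run (base case)
#'
#' Orchestrates the full analysis on either a supplied patient-level
#' dataset or a freshly simulated one: modified-ITT filter, per-patient
#' costing under the requested perspective, multiple imputation of
#' utilities, one-year QALYs with Rubin pooling, the incremental cost
#' t test, a within-arm bootstrap of incremental costs and effects, the
#' acceptability curve, and the ICER.  With `out_dir` set, the cost
#' table, QALY summary, CE-plane draws and CEAC are written as CSV
#' together with a JSON run manifest (seed, parameters, file hashes), and
#' identical `(input, seed)` pairs produce byte-identical files.
#'
#' @param config A [trial_config()] used to simulate the trial; ignored
#'   when `records` is given.
#' @param records Optional patient-level data frame (same layout as
#'   [generate_trial()] output) to analyse instead of simulating.
#' @param seed Integer seed driving simulation, imputation and bootstrap
#'   (distinct streams are derived internally).
#' @param B Bootstrap replicates.
#' @param m Number of imputations.
#' @param wtp_grid Willingness-to-pay grid, euros/QALY.
#' @param perspective `"department"` (base case) or `"combined"`
#'   (including patient-related costs).
#' @param params A [patient_cost_params()] (combined perspective).
#' @param prices A `price_table`; every record item must be priced.
#' @param currency `"EUR"`, `"USD"`, or `"both"` for the printed report.
#' @param out_dir Optional output directory.
#' @return List of class `cua_result`: `records` (post-filter),
#'   `cost_table`, `qaly`, `incremental_cost`, `draws`, `ceac`, `icer`,
#'   `perspective`, `manifest`.
#' @export
run_base_case <- function(config = default_config(), records = NULL,
                          seed = 1L, B = 1000L, m = 20L,
                          wtp_grid = seq(0, 100000, by = 500),
                          perspective = c("department", "combined"),
                          params = patient_cost_params(),
                          prices = default_price_table(),
                          currency = c("EUR", "USD", "both"),
                          out_dir = NULL) {
  perspective <- match.arg(perspective)
  currency <- match.arg(currency)
  seed <- as.integer(seed)
  if (B < 1L || m < 1L) stop("B and m must be >= 1")
  simulated <- is.null(records)
  if (simulated) records <- generate_trial(config, seed = seed)
  required <- c("patient_id", "arm", "dropout", "u1", "u6", "u12")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("malformed input records; missing columns: ",
         paste(missing_cols, collapse = ", "))
  mitt <- apply_mitt_filter(records)
  if (nrow(mitt) == 0L) stop("no patients remain after the modified-ITT filter")
  # price check: every item on the records must be priced
  invisible(patient_cost_breakdown(mitt[1, ], prices, params, perspective))

  mitt$total_cost <- total_costs(mitt, perspective, params)
  cost_table <- cost_comparison_table(mitt, perspective, params)
  inc_cost <- mean_diff_ttest(mitt$total_cost[mitt$arm == "intervention"],
                              mitt$total_cost[mitt$arm == "control"])

  qres <- trial_qaly(mitt, imputation_spec(m = m, seed = seed + 1000L))
  completed <- lapply(qres$completed, function(dat) {
    dat$total_cost <- total_costs(dat, perspective, params)
    dat
  })
  draws <- bootstrap_ce(completed, B = B, seed = seed + 2000L)
  curve <- ceac(draws, wtp_grid)
  point <- attr(draws, "point")
  ic <- icer(point[["delta_cost"]], point[["delta_qaly"]])

  cfg_file <- tempfile()
  saveRDS(if (simulated) config else records, cfg_file, version = 2)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  manifest <- list(
    seed = seed, B = as.integer(B), m = as.integer(m),
    input_hash = cfg_hash,
    perspective = perspective, currency = currency,
    simulated = simulated,
    n_enrolled = nrow(records), n_analysed = nrow(mitt),
    n_intervention = sum(mitt$arm == "intervention"),
    n_control = sum(mitt$arm == "control"),
    wtp_grid = c(min(wtp_grid), max(wtp_grid), length(wtp_grid)),
    package_version = as.character(utils::packageVersion("boxcua")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  res <- structure(list(records = mitt, cost_table = cost_table, qaly = qres,
                        incremental_cost = inc_cost, draws = draws,
                        ceac = curve, icer = ic, perspective = perspective,
                        currency = currency, manifest = manifest),
                   class = "cua_result")
  if (!is.null(out_dir)) res$manifest <- write_cua_outputs(res, out_dir)
  res
}

#' Sensitivity analysis including patient-related costs
#'
#' Re-runs the full analysis under the combined perspective: department
#' costs plus travel, parking, lost-productivity and device-time costs
#' borne by the patient.  The cost table gains a `patient_related` row,
#' and combined totals exceed department totals for every patient by
#' exactly that row.
#'
#' @inheritParams run_base_case
#' @return A `cua_result` (see [run_base_case()]), with
#'   `perspective == "combined"`.
#' @export
run_sensitivity <- function(config = default_config(), records = NULL,
                            seed = 1L, B = 1000L, m = 20L,
                            wtp_grid = seq(0, 100000, by = 500),
                            params = patient_cost_params(),
                            prices = default_price_table(),
                            currency = c("EUR", "USD", "both"),
                            out_dir = NULL) {
  run_base_case(config = config, records = records, seed = seed, B = B,
                m = m, wtp_grid = wtp_grid, perspective = "combined",
                params = params, prices = prices, currency = currency,
                out_dir = out_dir)
}

# Write report CSVs + JSON manifest; returns the manifest (with hashes).
write_cua_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cost_table = "cost_table.csv", qaly = "qaly_summary.csv",
             draws = "ce_draws.csv", ceac = "ceac.csv")
  fmt <- function(df) {
    df[] <- lapply(df, function(v) if (is.numeric(v)) round(v, 6) else v)
    df
  }
  write.csv(fmt(res$cost_table), file.path(out_dir, paths["cost_table"]),
            row.names = FALSE, na = "")
  qs <- data.frame(
    arm = c("intervention", "control", "difference"),
    qaly = c(res$qaly$arm_means$intervention$estimate,
             res$qaly$arm_means$control$estimate,
             res$qaly$difference$estimate),
    se = c(sqrt(res$qaly$arm_means$intervention$variance),
           sqrt(res$qaly$arm_means$control$variance),
           res$qaly$difference$se),
    ci_lower = c(NA, NA, res$qaly$difference$ci[1]),
    ci_upper = c(NA, NA, res$qaly$difference$ci[2]),
    p_value = c(NA, NA, res$qaly$difference$p_value))
  write.csv(fmt(qs), file.path(out_dir, paths["qaly"]), row.names = FALSE,
            na = "")
  write.csv(fmt(as.data.frame(res$draws)), file.path(out_dir, paths["draws"]),
            row.names = FALSE)
  write.csv(fmt(as.data.frame(res$ceac)), file.path(out_dir, paths["ceac"]),
            row.names = FALSE)
  manifest <- res$manifest
  manifest$files <- lapply(paths, function(p)
    list(path = p, md5 = unname(tools::md5sum(file.path(out_dir, p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.cua_result <- function(x, ...) {
  usd <- function(eur) eur_to_usd(eur)
  show <- function(eur, digits = 0) {
    e <- formatC(round(eur, digits), format = "f", digits = digits,
                 big.mark = ",")
    switch(x$currency,
           EUR = sprintf("€%s", e),
           USD = sprintf("US $%s", formatC(round(usd(eur), digits),
                                           format = "f", digits = digits,
                                           big.mark = ",")),
           both = sprintf("€%s (US $%s)", e,
                          formatC(round(usd(eur), digits), format = "f",
                                  digits = digits, big.mark = ",")))
  }
  tot <- x$cost_table[x$cost_table$item_id == "total", ]
  cat("Cost-utility analysis (", x$perspective, " perspective, ",
      x$manifest$n_intervention, " intervention / ",
      x$manifest$n_control, " control patients)\n", sep = "")
  cat("  mean total cost: ", show(tot$int_mean), " ± ", show(tot$int_sd),
      " intervention vs ", show(tot$ctl_mean), " ± ", show(tot$ctl_sd),
      " control\n", sep = "")
  cat("  cost difference (control - intervention): ", show(tot$difference),
      sprintf(" [95%% CI %s to %s], p = %.2f\n", show(tot$ci_lower),
              show(tot$ci_upper), tot$p_value), sep = "")
  cat(sprintf("  QALYs: %.2f intervention vs %.2f control (difference %.3f, p = %.3f)\n",
              x$qaly$arm_means$intervention$estimate,
              x$qaly$arm_means$control$estimate,
              x$qaly$difference$estimate, x$qaly$difference$p_value))
  cat("  ICER:", if (x$icer$status == "ratio")
        paste0(round(x$icer$icer), " EUR/QALY") else x$icer$status, "\n")
  cat(sprintf("  CEAC: minimum probability cost-effective %.3f over %d WTP values\n",
              min(x$ceac$probability), nrow(x$ceac)))
  invisible(x)
}

#' National annual savings extrapolation
#'
#' Scales the per-patient cost difference to the yearly national AMI
#' population (about 34,000 patients in the Netherlands).  Only a cost
#' reduction counts as savings; a cost increase yields zero savings with
#' a flag.
#'
#' @param delta_cost_per_patient Incremental cost per patient
#'   (intervention minus control), euros.
#' @param n_patients National annual patient count.
#' @return List: `savings_eur` (`n_patients * max(0, -delta)`),
#'   `savings_usd`, `cost_increase` (logical flag).
#' @export
extrapolate_national <- function(delta_cost_per_patient, n_patients = 34000) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  savings <- n_patients * max(0, -delta_cost_per_patient)
  list(savings_eur = savings, savings_usd = eur_to_usd(savings),
       cost_increase = delta_cost_per_patient > 0)
}
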