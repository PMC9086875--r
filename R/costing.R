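#' Price table: unit costs per resource item
#'
#' A price table maps each resource item to a unit cost (euros), the
#' calendar year those euros are expressed in (so they can be put on a
#' common 2020 price level through [inflate_to_2020()]), and a free-text
#' source.  The shipped default reproduces the trial's published unit
#' costs: the Box device from bills, follow-up procedures at hospital
#' prices, revascularisations from the Dutch Healthcare Authority (NZa)
#' lists, admissions and nurse-practitioner contacts from the Dutch
#' costing manual, and the in-hospital technical support salary share.
#'
#' @param path CSV file with columns `item_id,unit_cost_eur,price_year,source`.
#' @return Data frame of class `price_table`.
#' @export
read_price_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("item_id", "unit_cost_eur", "price_year", "source")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("malformed price table; missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(df$unit_cost_eur < 0)) stop("unit costs must be >= 0")
  if (anyDuplicated(df$item_id)) stop("duplicate item_id in price table")
  class(df) <- c("price_table", "data.frame")
  df
}

#' @rdname read_price_table
#' @export
default_price_table <- function() {
  read_price_table(system.file("extdata", "price_table.csv",
                               package = "boxcua", mustWork = TRUE))
}

#' Consumer price index for converting euros to 2020 price levels
#'
#' @param years Integer calendar years.
#' @param values Index values (any base; 2020 must be present).
#' @return Named numeric vector of class `cpi_index`.
#' @export
cpi_index <- function(years = 2020, values = 100) {
  stopifnot(length(years) == length(values))
  if (any(values <= 0)) stop("CPI index values must be > 0")
  if (!2020 %in% years) stop("the reference year 2020 must be present")
  structure(setNames(as.numeric(values), as.character(as.integer(years))),
            class = "cpi_index")
}

#' Convert an amount to 2020 euros with a consumer price index
#'
#' All costs in the analysis are expressed in 2020 euros; amounts quoted
#' in another year's euros are rescaled by the ratio of CPI index values.
#' Prices already in 2020 euros pass through unchanged (ratio 1), so a
#' single code path covers every entry of a price table.
#'
#' @param amount Euros, in `year` price levels.
#' @param year Calendar year of the amount.
#' @param cpi A [cpi_index()].
#' @return Euros at 2020 price levels.
#' @export
inflate_to_2020 <- function(amount, year, cpi = cpi_index()) {
  key <- as.character(as.integer(year))
  if (!all(key %in% names(cpi)))
    stop("year(s) missing from the CPI index: ",
         paste(setdiff(key, names(cpi)), collapse = ", "))
  amount * unname(cpi[["2020"]] / cpi[key])
}

#' Convert euros to US dollars
#'
#' Uses the analysis's fixed exchange rate of 1 EUR = 1.0994 USD.
#'
#' @param amount Euros.
#' @param rate Dollars per euro, > 0.
#' @return US dollars.
#' @export
eur_to_usd <- function(amount, rate = 1.0994) {
  if (rate <= 0) stop("exchange rate must be > 0")
  amount * rate
}

#' Micro-costed unit cost of an e-visit
#'
#' The video-connection component of an e-visit is costed top-down by
#' dividing the yearly subscription cost by the system's full capacity
#' (11 patients per half-day, 110 per week, 50 outpatient weeks = 5500
#' e-visits per year) and applying a 22% overhead (reduced from the usual
#' 44% because an e-visit consumes no cleaning and less housing).
#'
#' @param annual_subscription Yearly subscription cost, euros.
#' @param capacity_per_year E-visits per year at full capacity, > 0.
#' @param overhead Overhead multiplier.
#' @return Euros per e-visit.
#' @export
unit_cost_evisit <- function(annual_subscription, capacity_per_year = 5500,
                             overhead = 1.22) {
  if (capacity_per_year <= 0) stop("capacity_per_year must be > 0")
  annual_subscription / capacity_per_year * overhead
}

#' Micro-costed unit cost of an in-office outpatient visit
#'
#' Direct hospital components (ECG, administrative and nurse-practitioner
#' time) are summed and multiplied by the standard 44% hospital overhead.
#'
#' @param component_costs Numeric vector of direct component costs, euros.
#' @param overhead Overhead multiplier.
#' @return Euros per visit.
#' @export
unit_cost_in_office <- function(component_costs, overhead = 1.44) {
  if (any(component_costs < 0)) stop("component costs must be >= 0")
  sum(component_costs) * overhead
}

#' Allocate a shared cost equally over patients
#'
#' Shared support costs (the 0.5-FTE in-hospital technical support plus
#' billed technical support) are spread equally over the patients who
#' used the system.
#'
#' @param total Total shared cost, euros.
#' @param n_patients Number of patients, > 0.
#' @return Euros per patient.
#' @export
allocate_shared_cost <- function(total, n_patients) {
  if (n_patients <= 0) stop("n_patients must be > 0")
  total / n_patients
}

#' Patient-related cost parameters
#'
#' Parameters of the sensitivity-analysis cost model for what a visit
#' costs the patient rather than the department: a 7 km trip each way at
#' the Dutch costing-manual rate of 0.19 EUR/km, 3.20 EUR parking, 4.5
#' hours lost to an in-office visit and half an hour to an e-visit valued
#' at a blended hourly wage (70% of the population economically
#' productive at 37.05 EUR/h, 30% at the non-productive tariff of 13.33
#' EUR/h), and 10 minutes per week of home measurements valued at the
#' non-productive tariff (measurements are taken outside office hours).
#'
#' @param travel_km_one_way Kilometres, one way.
#' @param km_rate Euros per kilometre.
#' @param round_trip Cost the trip both ways?
#' @param parking Euros per hospital visit.
#' @param hours_in_office Hours lost per in-office visit.
#' @param hours_e_visit Hours lost per e-visit.
#' @param productive_fraction Fraction of patients economically
#'   productive, in \[0, 1\].
#' @param wage_productive,wage_nonproductive Euros per hour.
#' @param box_minutes_per_week Minutes per week of home measurements.
#' @param weeks_per_year Weeks of use per year.
#' @return List of class `patient_cost_params`.
#' @export
patient_cost_params <- function(travel_km_one_way = 7, km_rate = 0.19,
                                round_trip = TRUE, parking = 3.20,
                                hours_in_office = 4.5, hours_e_visit = 0.5,
                                productive_fraction = 0.70,
                                wage_productive = 37.05,
                                wage_nonproductive = 13.33,
                                box_minutes_per_week = 10,
                                weeks_per_year = 52) {
  p <- structure(as.list(environment()), class = "patient_cost_params")
  nums <- unlist(p[names(p) != "round_trip"])
  if (any(nums < 0)) stop("patient cost parameters must be >= 0")
  if (productive_fraction > 1) stop("productive_fraction must be in [0, 1]")
  p
}

blended_wage <- function(params) {
  params$productive_fraction * params$wage_productive +
    (1 - params$productive_fraction) * params$wage_nonproductive
}

#' Patient-related cost of one visit
#'
#' In-office visits cost the patient travel (round trip by default),
#' parking, and 4.5 hours of lost time at the blended wage; e-visits cost
#' only half an hour of lost time (no travel, no parking).
#'
#' @param params A [patient_cost_params()].
#' @param visit_type `"in_office"` or `"e_visit"`.
#' @return Euros per visit.
#' @export
patient_related_visit_cost <- function(params = patient_cost_params(),
                                       visit_type = c("in_office", "e_visit")) {
  visit_type <- match.arg(visit_type)
  wage <- blended_wage(params)
  if (visit_type == "e_visit")
    return(params$hours_e_visit * wage)
  travel <- params$travel_km_one_way * params$km_rate *
    (if (params$round_trip) 2 else 1)
  travel + params$parking + params$hours_in_office * wage
}

#' Yearly patient time cost of using the home-monitoring devices
#'
#' @param params A [patient_cost_params()].
#' @return Euros per patient per year.
#' @export
patient_related_box_cost <- function(params = patient_cost_params()) {
  params$box_minutes_per_week / 60 * params$weeks_per_year *
    params$wage_nonproductive
}

#' Per-patient cost breakdown under a perspective
#'
#' Sums one patient's per-item department costs and, under the
#' `"combined"` perspective, adds the patient-related costs: the
#' patient's in-office and e-visit counts weighted by
#' [patient_related_visit_cost()], plus (intervention arm only) the
#' yearly device time cost.  Every item present on the record must exist
#' in the price table.
#'
#' @param record One-row trial data frame (or a list with the same
#'   fields).
#' @param prices A `price_table`.
#' @param params A [patient_cost_params()].
#' @param perspective `"department"` (base case) or `"combined"`
#'   (sensitivity analysis).
#' @param aliases Named character vector mapping composite record items
#'   onto the price-table entry that prices them (a hospitalization is
#'   priced per admission night; the allocated Box support share derives
#'   from the in-hospital support salary plus billed technical support).
#' @return List of class `cost_breakdown`: `per_item` (named euros),
#'   `total_department`, `total_patient_related`, `total_combined`.
#' @export
patient_cost_breakdown <- function(record, prices = default_price_table(),
                                   params = patient_cost_params(),
                                   perspective = c("department", "combined"),
                                   aliases = c(hospitalization = "admission_night",
                                               box_support = "inhospital_support")) {
  perspective <- match.arg(perspective)
  record <- as.list(record)
  cost_cols <- grep("^cost_", names(record), value = TRUE)
  items <- sub("^cost_", "", cost_cols)
  priced_as <- ifelse(items %in% names(aliases), aliases[items], items)
  unpriced <- items[!priced_as %in% prices$item_id]
  if (length(unpriced) > 0L)
    stop("no price table entry for item(s): ", paste(unpriced, collapse = ", "))
  per_item <- setNames(vapply(cost_cols, function(cc) as.numeric(record[[cc]]),
                              numeric(1)), items)
  total_dep <- sum(per_item)
  total_pat <- 0
  if (perspective == "combined") {
    n_io <- if (!is.null(record$count_in_office)) record$count_in_office else 0
    n_ev <- if (!is.null(record$count_e_visit)) record$count_e_visit else 0
    total_pat <- n_io * patient_related_visit_cost(params, "in_office") +
      n_ev * patient_related_visit_cost(params, "e_visit")
    if (identical(record$arm, "intervention"))
      total_pat <- total_pat + patient_related_box_cost(params)
  }
  structure(list(per_item = per_item,
                 total_department = total_dep,
                 total_patient_related = total_pat,
                 total_combined = total_dep + total_pat),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Cost breakdown (2020 euros)\n")
  for (nm in names(x$per_item))
    if (x$per_item[[nm]] != 0) cat(sprintf("  %-18s %10.2f\n", nm, x$per_item[[nm]]))
  cat(sprintf("  %-18s %10.2f\n", "department total", x$total_department))
  if (x$total_patient_related > 0) {
    cat(sprintf("  %-18s %10.2f\n", "patient-related", x$total_patient_related))
    cat(sprintf("  %-18s %10.2f\n", "combined total", x$total_combined))
  }
  invisible(x)
}

# Per-patient total department cost: sum of the cost_ columns.
department_totals <- function(records) {
  cost_cols <- grep("^cost_", names(records), value = TRUE)
  if (length(cost_cols) == 0L) return(rep(0, nrow(records)))
  rowSums(records[, cost_cols, drop = FALSE])
}

# Per-patient patient-related cost (visit-count weighted + device time).
patient_related_totals <- function(records, params = patient_cost_params()) {
  n_io <- if ("count_in_office" %in% names(records)) records$count_in_office else 0
  n_ev <- if ("count_e_visit" %in% names(records)) records$count_e_visit else 0
  n_io * patient_related_visit_cost(params, "in_office") +
    n_ev * patient_related_visit_cost(params, "e_visit") +
    ifelse(records$arm == "intervention", patient_related_box_cost(params), 0)
}

#' Per-patient total cost under a perspective
#'
#' @param records Trial data frame.
#' @param perspective `"department"` or `"combined"`.
#' @param params A [patient_cost_params()] (combined perspective only).
#' @return Numeric vector of per-patient totals, euros.
#' @export
total_costs <- function(records, perspective = c("department", "combined"),
                        params = patient_cost_params()) {
  perspective <- match.arg(perspective)
  tot <- department_totals(records)
  if (perspective == "combined")
    tot <- tot + patient_related_totals(records, params)
  tot
}

#' Arm-level cost summary (published-table layout)
#'
#' Arithmetic mean and sample SD of each item's per-patient cost over the
#' patients of one arm, plus the total row; per-item means sum to the
#' total mean by construction.
#'
#' @param records Trial data frame (post modified-ITT filter).
#' @param arm `"intervention"` or `"control"`.
#' @return Data frame with columns `item_id`, `n_events` (summed counts),
#'   `mean`, `sd`; the last row is the total (`item_id == "total"`).
#' @export
arm_cost_summary <- function(records, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  sub <- records[records$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no patients in arm '", arm, "'")
  cost_cols <- grep("^cost_", names(sub), value = TRUE)
  items <- sub("^cost_", "", cost_cols)
  n_events <- vapply(items, function(it) {
    cc <- paste0("count_", it)
    if (cc %in% names(sub)) sum(sub[[cc]]) else NA_real_
  }, numeric(1))
  means <- vapply(cost_cols, function(cc) mean(sub[[cc]]), numeric(1))
  sds <- vapply(cost_cols, function(cc) sd(sub[[cc]]), numeric(1))
  if (nrow(sub) == 1L) sds[] <- 0
  tot <- department_totals(sub)
  out <- data.frame(item_id = c(items, "total"),
                    n_events = c(n_events, NA_real_),
                    mean = c(unname(means), mean(tot)),
                    sd = c(unname(sds), if (nrow(sub) == 1L) 0 else sd(tot)))
  rownames(out) <- NULL
  out
}

#' Two-arm cost comparison table
#'
#' Per-item and total mean±SD for both arms with the between-arm mean
#' difference (control minus intervention), pooled-variance t confidence
#' interval and p-value, mirroring the published cost table.
#'
#' @param records Trial data frame (post modified-ITT filter).
#' @param perspective `"department"` or `"combined"`.
#' @param params A [patient_cost_params()] (combined perspective only).
#' @return Data frame with one row per item plus a `total` row.
#' @export
cost_comparison_table <- function(records,
                                  perspective = c("department", "combined"),
                                  params = patient_cost_params()) {
  perspective <- match.arg(perspective)
  int <- arm_cost_summary(records, "intervention")
  ctl <- arm_cost_summary(records, "control")
  sub_i <- records[records$arm == "intervention", , drop = FALSE]
  sub_c <- records[records$arm == "control", , drop = FALSE]
  cost_cols <- c(grep("^cost_", names(records), value = TRUE), "__total__")
  rows <- lapply(cost_cols, function(cc) {
    if (cc == "__total__") {
      a <- total_costs(sub_c, perspective, params)
      b <- total_costs(sub_i, perspective, params)
    } else {
      a <- sub_c[[cc]]
      b <- sub_i[[cc]]
    }
    tt <- mean_diff_ttest(a, b)
    data.frame(difference = tt$difference, ci_lower = tt$ci[1],
               ci_upper = tt$ci[2], p_value = tt$p_value)
  })
  diff <- do.call(rbind, rows)
  out <- data.frame(item_id = int$item_id,
                    int_n_events = int$n_events, int_mean = int$mean,
                    int_sd = int$sd,
                    ctl_n_events = ctl$n_events, ctl_mean = ctl$mean,
                    ctl_sd = ctl$sd)
  # the total row must reflect the requested perspective, not just the
  # department items arm_cost_summary() sums over
  ti <- total_costs(sub_i, perspective, params)
  tc <- total_costs(sub_c, perspective, params)
  last <- nrow(out)
  out$int_mean[last] <- mean(ti)
  out$int_sd[last] <- if (length(ti) > 1L) sd(ti) else 0
  out$ctl_mean[last] <- mean(tc)
  out$ctl_sd[last] <- if (length(tc) > 1L) sd(tc) else 0
  if (perspective == "combined") {
    pr_i <- patient_related_totals(sub_i, params)
    pr_c <- patient_related_totals(sub_c, params)
    pr_row <- data.frame(item_id = "patient_related",
                         int_n_events = NA_real_, int_mean = mean(pr_i),
                         int_sd = sd(pr_i),
                         ctl_n_events = NA_real_, ctl_mean = mean(pr_c),
                         ctl_sd = sd(pr_c))
    tt <- mean_diff_ttest(pr_c, pr_i)
    diff_pr <- data.frame(difference = tt$difference, ci_lower = tt$ci[1],
                          ci_upper = tt$ci[2], p_value = tt$p_value)
    n_items <- nrow(out) - 1L
    out <- rbind(out[seq_len(n_items), ], pr_row, out[nrow(out), ])
    diff <- rbind(diff[seq_len(n_items), ], diff_pr, diff[nrow(diff), ])
  }
  out <- cbind(out, diff)
  rownames(out) <- NULL
  out
}
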