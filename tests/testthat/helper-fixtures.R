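# Small configurations and hand-built records used across test files.

# Two-item trial, no missingness: fast to simulate, easy to reason about.
mini_config <- function(n = c(30L, 30L), dropouts = c(3L, 2L),
                        missing_prob = 0) {
  trial_config(
    n_enrolled = n, dropouts = dropouts,
    item_models = list(
      item_model("the_box", "fixed", rate = c(1, 0), unit_cost = c(318, 0)),
      item_model("in_office", "visit", rate = c(2, 4), unit_cost = c(96, 96)),
      item_model("hospitalization", "bernoulli", rate = c(0.1, 0.1),
                 unit_cost = c(2000, 2000), severity = "gamma",
                 severity_cv = 0.5)),
    utility_means = matrix(c(0.75, 0.74, 0.73, 0.71, 0.69, 0.68), 2, 3,
                           byrow = TRUE),
    utility_sd = 0.15, utility_correlation = 0.5,
    missing_prob = missing_prob)
}

# A degenerate configuration: nothing costs anything, identical utility
# means in both arms, nothing missing.
null_config <- function() {
  trial_config(
    n_enrolled = c(20L, 20L), dropouts = c(0L, 0L),
    item_models = list(
      item_model("in_office", "visit", rate = c(0, 0), unit_cost = c(96, 96))),
    utility_means = matrix(0.7, 2, 3),
    utility_sd = 0, utility_correlation = 0, missing_prob = 0)
}

# Hand-built completed records (costs and QALYs fixed) for bootstrap tests.
toy_completed <- function(int_cost, ctl_cost, int_qaly, ctl_qaly) {
  data.frame(
    patient_id = seq_len(length(int_cost) + length(ctl_cost)),
    arm = rep(c("intervention", "control"),
              c(length(int_cost), length(ctl_cost))),
    total_cost = c(int_cost, ctl_cost),
    qaly = c(int_qaly, ctl_qaly))
}

# A single price table shared by costing tests.
prices <- default_price_table()
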