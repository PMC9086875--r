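test_that("currency and price-level conversions follow the stated rates", {
  expect_equal(inflate_to_2020(100, 2020), 100)
  expect_equal(inflate_to_2020(100, 2016, cpi_index(c(2016, 2020), c(0.95, 1))),
               105.26, tolerance = 1e-4)
  expect_equal(inflate_to_2020(0, 2020), 0)
  expect_error(inflate_to_2020(100, 1999, cpi_index()), "1999")

  expect_equal(eur_to_usd(2417), 2657.3, tolerance = 0.05)
  expect_equal(round(eur_to_usd(471)), 518)
  expect_equal(eur_to_usd(0), 0)
  expect_error(eur_to_usd(1, rate = 0), "rate")
})

test_that("micro-costed unit costs reproduce the published visit prices", {
  expect_equal(unit_cost_evisit(55000, 5500, 1.22), 12.20)
  expect_equal(unit_cost_evisit(0), 0)
  # the subscription implied by the published 44 EUR e-visit price
  expect_equal(unit_cost_evisit(44 / 1.22 * 5500), 44)
  expect_error(unit_cost_evisit(1000, capacity_per_year = 0), "capacity")

  expect_equal(unit_cost_in_office(c(50, 16.67)), 96.0048)
  expect_equal(unit_cost_in_office(numeric(0)), 0)
  expect_equal(unit_cost_in_office(100, overhead = 1), 100)

  expect_equal(allocate_shared_cost(15367 + 1758, 88), 194.6, tolerance = 1e-3)
  expect_equal(round(allocate_shared_cost(15367 + 1758, 88)), 195)
  expect_equal(allocate_shared_cost(0, 88), 0)
  expect_equal(allocate_shared_cost(100, 1), 100)
  expect_error(allocate_shared_cost(100, 0), "n_patients")
})

test_that("patient-related visit and device-time costs match hand arithmetic", {
  p <- patient_cost_params()
  blended <- 0.70 * 37.05 + 0.30 * 13.33
  expect_equal(patient_related_visit_cost(p, "in_office"),
               2 * 7 * 0.19 + 3.20 + 4.5 * blended, tolerance = 1e-12)
  expect_equal(patient_related_visit_cost(p, "in_office"), 140.563,
               tolerance = 1e-3)
  expect_equal(patient_related_visit_cost(p, "e_visit"), 0.5 * blended,
               tolerance = 1e-12)
  expect_equal(patient_related_box_cost(p), 10 / 60 * 52 * 13.33,
               tolerance = 1e-12)
  expect_equal(patient_related_box_cost(
    patient_cost_params(box_minutes_per_week = 60)), 693.16)
  expect_equal(patient_related_box_cost(
    patient_cost_params(box_minutes_per_week = 0)), 0)

  zero <- patient_cost_params(travel_km_one_way = 0, km_rate = 0, parking = 0,
                              hours_in_office = 0, hours_e_visit = 0,
                              wage_productive = 0, wage_nonproductive = 0,
                              box_minutes_per_week = 0)
  expect_equal(patient_related_visit_cost(zero, "in_office"), 0)
  expect_equal(patient_related_visit_cost(zero, "e_visit"), 0)
})

test_that("the shipped price table carries the published unit costs", {
  published <- c(the_box = 318, stress_echo = 542, tte = 117, holter = 152,
                 e_visit = 44, in_office = 96, technical_support = 1758,
                 np_contact = 4, catheterization = 2037, pci_1v = 5999,
                 pci_mv = 6428, admission_night = 684,
                 inhospital_support = 15367)
  for (item in names(published))
    expect_equal(prices$unit_cost_eur[prices$item_id == item],
                 unname(published[item]), label = item)
  expect_true(all(prices$price_year == 2020))
})

test_that("cost breakdowns are additive and monotone across perspectives", {
  rec <- apply_mitt_filter(generate_trial(default_config(), seed = 21))
  params <- patient_cost_params()
  for (i in sample(nrow(rec), 25)) {
    dep <- patient_cost_breakdown(rec[i, ], prices, params, "department")
    com <- patient_cost_breakdown(rec[i, ], prices, params, "combined")
    expect_equal(dep$total_department, sum(dep$per_item), tolerance = 1e-9)
    expect_equal(com$total_combined,
                 com$total_department + com$total_patient_related,
                 tolerance = 1e-9)
    expect_gte(com$total_combined, dep$total_department)
    expect_equal(dep$total_patient_related, 0)
  }
  # single box-only intervention record: department total is the device price
  one <- data.frame(patient_id = "X", arm = "intervention", dropout = FALSE,
                    cost_the_box = 318)
  expect_equal(patient_cost_breakdown(one, prices)$total_department, 318)
  # unpriced items are refused by name
  bad <- data.frame(arm = "control", cost_helicopter = 5)
  expect_error(patient_cost_breakdown(bad, prices), "helicopter")
})

test_that("arm summaries use arithmetic means and sample SDs that sum coherently", {
  rec <- data.frame(patient_id = c("a", "b", "c"),
                    arm = c("intervention", "control", "control"),
                    dropout = FALSE,
                    count_in_office = c(2L, 4L, 4L),
                    cost_in_office = c(192, 384, 384),
                    count_tte = c(1L, 2L, 2L),
                    cost_tte = c(117, 234, 234))
  one <- arm_cost_summary(rec, "intervention")
  expect_equal(one$mean[one$item_id == "in_office"], 192)
  expect_equal(one$sd, rep(0, 3))
  expect_equal(one$mean[one$item_id == "total"], 192 + 117)

  two <- arm_cost_summary(rec, "control")
  expect_equal(two$sd, rep(0, 3))          # identical patients
  expect_equal(two$n_events[two$item_id == "in_office"], 8)

  big <- apply_mitt_filter(generate_trial(default_config(), seed = 4))
  summ <- arm_cost_summary(big, "control")
  expect_equal(summ$mean[summ$item_id == "total"],
               sum(summ$mean[summ$item_id != "total"]), tolerance = 1e-9)
  expect_error(arm_cost_summary(big[big$arm == "control", ], "intervention"),
               "no patients")
})
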