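test_that("cumulative transport reproduces the hand mass balance", {
  rec <- lymph_records(t_start = c(0, 1), t_end = c(1, 2),
                       volume = c(50, 60), concentration = c(1000, 500))
  curve <- cumulative_transport(rec, dose = 200)
  expect_equal(curve$cumulative_amount, c(0.05, 0.08))
  expect_equal(curve$cumulative_pct_dose[2], 0.04)

  zero <- lymph_records(0:11, 1:12, rep(70, 12), rep(0, 12))
  expect_equal(cumulative_transport(zero, 200)$cumulative_pct_dose,
               rep(0, 12))

  expect_error(lymph_records(c(0, 0.5), c(1, 1.5), c(50, 50), c(1, 1)),
               "overlap")
  expect_error(lymph_records(0, 1, -5, 10), "non-negative")
  expect_error(cumulative_transport(rec, dose = 0), "positive")
})

test_that("portal bioavailability is a dose-normalized AUC ratio", {
  expect_equal(absolute_bioavailability_portal(59.44, 200, 594.4, 20), 1)
  expect_equal(absolute_bioavailability_portal(100, 10, 100, 10), 100)
  base <- absolute_bioavailability_portal(59.44, 200, 594.4, 20)
  expect_equal(absolute_bioavailability_portal(2 * 59.44, 2 * 200, 594.4, 20),
               base)
  expect_error(absolute_bioavailability_portal(0, 200, 594.4, 20), "positive")
})

test_that("the partition identities behave at their edges", {
  expect_equal(total_bioavailability(0, 4.9), 4.9)
  expect_equal(relative_lymph_bioavailability(3.6, 3.6), 100)
  expect_equal(relative_lymph_bioavailability(0, 5), 0)
  expect_error(relative_lymph_bioavailability(1, 0), "inconsistent")
  expect_error(relative_lymph_bioavailability(5, 3), "at least")
})

test_that("lymph interval collections convert to an end-time concentration series", {
  rec <- lymph_records(0:11, 1:12, rep(70, 12), 100 * exp(-0.2 * (1:12)))
  prof <- lymph_profile_as_timeseries(rec, dose = 200)
  expect_equal(prof$times, 1:12)
  expect_equal(prof$fluid, "lymph")
  # definitional round-trip: profile AUC equals the trapezoid of the points
  expect_equal(auc_trapezoid(prof, 1, 12),
               ref_trapz(1:12, rec$conc_ng_ml))

  single <- lymph_records(0, 1, 70, 500)
  one <- lymph_profile_as_timeseries(single, dose = 200)
  expect_length(one$times, 1)
  expect_error(nca_extravascular(one), "at least 3|fewer than 2")
})

test_that("transport analysis handles the zero-lymph and missing-reference cases", {
  p <- make_params(phi_lymph = 0)
  rec <- simulate_oral_experiment(p, 200, flow = no_flow_noise())
  ivn <- nca_intravenous(
    handle_blq(simulate_iv_experiment(make_params(), 20)$serum, 1e-9))
  res <- transport_analysis(rec, ivn, lloq = 1)
  expect_equal(res$f_al, 0)
  expect_equal(res$f, res$f_ap)
  expect_equal(res$f_rl, 0)

  rec2 <- simulate_oral_experiment(make_params(), 200, flow = no_flow_noise())
  res2 <- transport_analysis(rec2, NULL, lloq = 1)
  expect_gt(res2$f_al, 0)
  expect_true(is.na(res2$f_ap) && is.na(res2$f) && is.na(res2$f_rl))
})

test_that("truncation never increases F_AL and the identities hold on results", {
  ivn <- nca_intravenous(
    handle_blq(simulate_iv_experiment(make_params(), 20)$serum, 1e-9))
  for (seed in 1:5) {
    rec <- apply_measurement_noise(
      simulate_oral_experiment(make_params(), 200,
                               flow = lymph_flow_model(70, 0.3),
                               seed = seed),
      noise_model(residual_cv = 0.15), seed = seed + 100)
    full <- transport_analysis(rec, ivn, lloq = 1)
    tr8 <- transport_analysis(rec, ivn, truncation_time = 8, lloq = 1)
    expect_lte(tr8$f_al, full$f_al + 1e-12)
    for (res in list(full, tr8)) {
      expect_equal(res$f, res$f_al + res$f_ap)
      expect_equal(res$f_rl, 100 * res$f_al / res$f)
    }
  }
})

test_that("the percentages are invariant to joint scaling of dose and amounts", {
  rec <- simulate_oral_experiment(make_params(), 200, flow = no_flow_noise())
  ivn <- nca_intravenous(
    handle_blq(simulate_iv_experiment(make_params(), 20)$serum, 1e-9))
  res <- transport_analysis(rec, ivn, lloq = 1e-9)

  k <- 3
  scaled <- rec
  scaled$dose <- rec$dose * k
  scaled$serum <- concentration_profile(rec$serum$times,
                                        rec$serum$concentrations * k,
                                        fluid = "serum", route = "oral",
                                        dose = rec$dose * k)
  scaled$lymph <- lymph_records(rec$lymph$t_start_h, rec$lymph$t_end_h,
                                rec$lymph$volume_ml,
                                rec$lymph$conc_ng_ml * k)
  res_k <- transport_analysis(scaled, ivn, lloq = 1e-9)
  for (f in c("f_al", "f_ap", "f", "f_rl"))
    expect_equal(res_k[[f]], res[[f]], tolerance = 1e-9)
})

test_that("a noise-free simulated period recovers its transport truth", {
  p <- make_params()
  rec <- simulate_oral_experiment(p, 200, flow = no_flow_noise())
  ivn <- nca_intravenous(
    handle_blq(simulate_iv_experiment(make_params(), 20)$serum, 1e-9))
  res <- transport_analysis(rec, ivn, lloq = 1)
  tr <- rec$truth
  expect_lt(abs(res$f_al - tr$f_al_true) / tr$f_al_true, 0.05)
  expect_lt(abs(res$f_rl - tr$f_rl_true), 2)
})
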