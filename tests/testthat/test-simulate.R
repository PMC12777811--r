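test_that("one-compartment simulation matches the closed-form solution", {
  p <- make_params(k12 = 0, k21 = 0)
  sched <- sampling_schedule(seq(0.5, 48, by = 0.5),
                             lymph_interval_bounds = 0:48)
  rec <- simulate_oral_experiment(p, 200, sched, no_flow_noise())
  expected <- oral_conc_1cpt(p, 200, rec$serum$times)
  expect_true(all(abs(rec$serum$concentrations - expected) <=
                    1e-6 * pmax(expected, max(expected) * 1e-9)))

  iv <- simulate_iv_experiment(p, 20, sampling_schedule(seq(0.25, 24, 0.25)))
  expected_iv <- iv_conc_1cpt(p, 20, iv$serum$times)
  expect_true(all(abs(iv$serum$concentrations - expected_iv) <=
                    1e-6 * expected_iv))
})

test_that("intravenous simulation is linear and mono-exponential in the one-compartment limit", {
  p <- make_params(k12 = 0, k21 = 0)
  sched <- sampling_schedule(c(0.5, 1, 2, 4, 8, 12, 24))
  a <- simulate_iv_experiment(p, 20, sched)
  b <- simulate_iv_experiment(p, 40, sched)
  expect_equal(b$serum$concentrations, 2 * a$serum$concentrations,
               tolerance = 1e-9)
  slopes <- diff(log(a$serum$concentrations)) / diff(a$serum$times)
  expect_equal(slopes, rep(-p$cl / p$vc, length(slopes)), tolerance = 1e-7)
})

test_that("dense trapezoidal AUC of the simulated profiles matches the analytic AUC", {
  p <- make_params(k12 = 0, k21 = 0)
  tgrid <- seq(0.05, 150, by = 0.05)
  rec <- simulate_oral_experiment(p, 200,
                                  sampling_schedule(tgrid, c(0, 150)),
                                  no_flow_noise())
  auc <- auc_trapezoid(prepend0(rec$serum))
  expect_lt(abs(auc - analytic_auc_oral(p, 200)) / analytic_auc_oral(p, 200),
            0.005)

  iv <- simulate_iv_experiment(make_params(k12 = 0, k21 = 0, vc = 50), 20,
                               sampling_schedule(seq(0.01, 30, by = 0.01)))
  ke <- 33.6 / 50
  c_last <- iv$serum$concentrations[length(iv$serum$times)]
  auc_iv <- auc_trapezoid(prepend0(iv$serum)) + c_last / ke
  # analytic identity AUC_inf = dose / CL: 20 mg / 33.6 l/h = 595.2 ng*h/ml
  expect_lt(abs(auc_iv - 595.2) / 595.2, 0.005)
})

test_that("mass is conserved and collected lymph converges to fa*phi*dose", {
  grid <- expand.grid(phi = c(0, 0.1, 0.5), eh = c(0, 0.7),
                      fa = c(0.2, 1), k2 = c(0, 1))
  sched <- sampling_schedule(c(1:12, 24, 100, 300),
                             lymph_interval_bounds = c(0:12, 24, 100, 300))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- make_params(fa = g$fa, phi_lymph = g$phi, eh = g$eh,
                     k12 = g$k2 * 1.5, k21 = g$k2 * 0.3)
    # the simulator itself hard-fails on any mass-balance violation
    rec <- simulate_oral_experiment(p, 200, sched, no_flow_noise())
    curve <- cumulative_transport(rec$lymph, 200)
    expect_true(all(diff(curve$cumulative_amount) >= 0))
    expect_equal(curve$cumulative_pct_dose[length(curve$times)],
                 rec$truth$f_al_true, tolerance = 1e-4)
  }
})

test_that("switching the lymph route off zeroes every lymph observation", {
  rec <- simulate_oral_experiment(make_params(phi_lymph = 0), 200,
                                  flow = no_flow_noise())
  expect_equal(rec$lymph$conc_ng_ml, rep(0, 13))
  expect_equal(rec$truth$f_al_true, 0)

  tr <- true_transport_fractions(make_params(fa = 1, phi_lymph = 0.5, eh = 0))
  expect_equal(unlist(tr, use.names = FALSE), c(50, 50, 100, 50))
})

test_that("measurement noise honours its contract", {
  rec <- simulate_oral_experiment(make_params(), 200, flow = no_flow_noise())
  clean <- apply_measurement_noise(rec, noise_model(residual_cv = 0,
                                                    lloq = 1), seed = 7)
  expect_equal(clean$serum$concentrations, rec$serum$concentrations)
  expect_equal(clean$lymph$conc_ng_ml, rec$lymph$conc_ng_ml)
  expect_equal(clean$serum$blq, rec$serum$concentrations < 1)

  n1 <- apply_measurement_noise(rec, noise_model(residual_cv = 0.2), seed = 11)
  n2 <- apply_measurement_noise(rec, noise_model(residual_cv = 0.2), seed = 11)
  expect_identical(n1, n2)
  n3 <- apply_measurement_noise(rec, noise_model(residual_cv = 0.2), seed = 12)
  expect_false(identical(n1$serum$concentrations, n3$serum$concentrations))
  expect_error(apply_measurement_noise(rec, noise_model()), "seed")
})

test_that("the log-normal error model reproduces its nominal CV", {
  flat <- structure(
    list(animal = "a", period = 1L, formulation = "x", route = "oral",
         dose = 200,
         serum = concentration_profile(seq_len(1e4), rep(100, 1e4),
                                       fluid = "serum", route = "oral",
                                       dose = 200),
         lymph = NULL, truth = NULL, params = NULL),
    class = "animal_record")
  noisy <- apply_measurement_noise(flat, noise_model(residual_cv = 0.2),
                                   seed = 5)
  cc <- noisy$serum$concentrations
  expect_lt(abs(sd(cc) / mean(cc) - 0.2), 0.02)
})

test_that("the cross-over generator reproduces the study design deterministically", {
  d1 <- generate_crossover_study(seed = 42)
  d2 <- generate_crossover_study(seed = 42)
  expect_identical(d1, d2)

  oral <- d1$serum[d1$serum$route == "oral", ]
  per_period <- table(oral$animal, oral$period)
  expect_true(all(per_period == 13))
  lym <- table(d1$lymph$animal, d1$lymph$period)
  expect_true(all(lym == 13))
  expect_equal(sort(unique(oral$time_h)), c(1:12, 24))
  # IV reference present, without lymph collection
  expect_true("iv" %in% d1$serum$route)
  expect_false(any(d1$lymph$animal %in%
                     d1$serum$animal[d1$serum$route == "iv"]))
  # each animal sees both formulations once
  forms <- table(oral$animal, oral$formulation) / 13
  expect_true(all(forms == 1))
})

test_that("with variability switched off all animals are identical within formulation", {
  d <- generate_crossover_study(
    n_animals = 3, noise = noise_model(residual_cv = 0, iiv_cv = 0),
    flow = no_flow_noise(), seed = 3)
  oral <- d$serum[d$serum$route == "oral", ]
  for (f in unique(oral$formulation)) {
    sub <- oral[oral$formulation == f, ]
    profiles <- split(sub$conc_ng_ml, sub$animal)
    for (pr in profiles[-1]) expect_equal(pr, profiles[[1]])
  }
  expect_warning(
    generate_crossover_study(n_animals = 1, seed = 9,
                             noise = noise_model(residual_cv = 0, iiv_cv = 0),
                             flow = no_flow_noise()),
    "paired")
})
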