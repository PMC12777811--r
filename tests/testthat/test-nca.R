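test_that("BLQ policy: zero before first quantifiable, drop embedded and trailing", {
  prof <- concentration_profile(c(0, 1, 2, 3), c(0, NA, 10, 20),
                                fluid = "serum", route = "oral", dose = 200,
                                blq = c(FALSE, TRUE, FALSE, FALSE))
  out <- handle_blq(prof, 1)
  expect_equal(out$times, c(0, 1, 2, 3))
  expect_equal(out$concentrations, c(0, 0, 10, 20))

  clean <- concentration_profile(1:4, c(5, 10, 8, 4), fluid = "serum",
                                 route = "oral", dose = 200)
  expect_equal(handle_blq(clean, 1)$concentrations, c(5, 10, 8, 4))

  # trailing BLQ at 24 h excluded from AUC and the terminal fit
  trail <- concentration_profile(c(0, 6, 12, 24), c(0, 10, 5, NA),
                                 fluid = "serum", route = "oral", dose = 200,
                                 blq = c(FALSE, FALSE, FALSE, TRUE))
  out <- handle_blq(trail, 1)
  expect_equal(out$times, c(0, 6, 12))
  # hand trapezoid on the surviving points: 6*(0+10)/2 + 6*(10+5)/2 = 75
  expect_equal(auc_trapezoid(out), 75)
  expect_match(paste(attr(out, "blq_log"), collapse = " "), "t=24")

  allblq <- concentration_profile(1:3, c(NA, NA, NA), fluid = "serum",
                                  route = "oral", dose = 200,
                                  blq = rep(TRUE, 3))
  expect_error(handle_blq(allblq, 1), "below the limit")
})

test_that("linear trapezoid reproduces hand-computed areas and is additive", {
  const <- concentration_profile(c(0, 4), c(10, 10), fluid = "serum",
                                 route = "oral", dose = 1)
  expect_equal(auc_trapezoid(const), 40)

  toy <- concentration_profile(0:2, c(0, 10, 5), fluid = "serum",
                               route = "oral", dose = 1)
  expect_equal(auc_trapezoid(toy), 12.5)

  set.seed(7)
  tt <- sort(c(8, sample(seq(0.5, 23.5, 0.5), 12)))
  prof <- concentration_profile(tt, runif(13, 1, 50), fluid = "serum",
                                route = "oral", dose = 1)
  expect_equal(auc_trapezoid(prof, min(tt), 8) + auc_trapezoid(prof, 8, max(tt)),
               auc_trapezoid(prof))
  # window edges between samples are linearly interpolated, so additivity
  # holds at arbitrary cut points too
  expect_equal(auc_trapezoid(prof, min(tt), 7.3) +
                 auc_trapezoid(prof, 7.3, max(tt)),
               auc_trapezoid(prof))
  expect_error(auc_trapezoid(prof, 0, 30), "outside")
})

test_that("terminal slope is exact on mono-exponentials and absent on flat tails", {
  tt <- c(2, 4, 6, 8, 10, 12)
  prof <- concentration_profile(tt, 100 * exp(-0.1 * tt), fluid = "serum",
                                route = "iv", dose = 20)
  fit <- estimate_lambda_z(prof)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-10)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-10)
  expect_equal(fit$n_points, 5)  # all post-Tmax points at the R2 tie

  flat <- concentration_profile(1:6, c(1, 5, 10, 10, 10, 10),
                                fluid = "serum", route = "oral", dose = 200)
  expect_null(estimate_lambda_z(flat))
  res <- nca_extravascular(flat)
  expect_true("no_terminal_phase" %in% res$flags)
  expect_true(is.na(res$auc_inf))
})

test_that("terminal slope recovers the slow phase of a bi-exponential at the study schedule", {
  tt <- c(1:12, 24)
  cc <- 50 * exp(-0.5 * tt) + 20 * exp(-0.08 * tt)
  prof <- concentration_profile(tt, cc, fluid = "serum", route = "oral",
                                dose = 200)
  fit <- estimate_lambda_z(prof)
  expect_lt(abs(fit$lambda_z - 0.08) / 0.08, 0.05)
})

test_that("extravascular NCA: tie rule, tail area, and simulator cross-check", {
  dup <- concentration_profile(c(1, 2, 4, 5, 8, 12), c(1, 5, 9, 9, 4, 2),
                               fluid = "serum", route = "oral", dose = 200)
  res <- nca_extravascular(dup)
  expect_equal(res$tmax, 4)
  expect_equal(res$cmax, 9)

  tt <- seq(2, 22, 2)
  tailp <- concentration_profile(tt, 10 * exp(-0.1 * (tt - 22)),
                                 fluid = "serum", route = "oral", dose = 200)
  res <- nca_extravascular(tailp)
  # closed-form tail area C_last / lambda_z = 10 / 0.1
  expect_equal(res$auc_inf - res$auc_last, 100, tolerance = 1e-6)

  p <- make_params()
  rec <- simulate_oral_experiment(p, 200, flow = no_flow_noise())
  res <- nca_extravascular(prepend0(rec$serum))
  expect_lt(abs(res$auc_inf - analytic_auc_oral(p, 200)) /
              analytic_auc_oral(p, 200), 0.03)
})

test_that("intravenous NCA recovers clearance and volume from dense noise-free data", {
  p <- make_params(k12 = 0, k21 = 0, cl = 2, vc = 10)
  sched <- sampling_schedule(seq(0.05, 60, by = 0.05))
  iv <- simulate_iv_experiment(p, 20, sched)
  res <- nca_intravenous(handle_blq(iv$serum, 1e-9), bodyweight = 64)
  expect_lt(abs(res$cl - 2) / 2, 0.01)
  expect_lt(abs(res$vss - 10) / 10, 0.02)
  expect_equal(res$vss, res$cl * res$mrt)
  expect_equal(res$cl_per_kg, res$cl / 64)
  # CL * AUC_inf returns the dose (unit conversion closes exactly)
  expect_equal(res$cl * res$auc_inf / 1000, 20, tolerance = 1e-12)
})

test_that("doubling the concentrations halves clearance exactly", {
  p <- make_params(k12 = 0, k21 = 0)
  iv <- simulate_iv_experiment(p, 20, iv_schedule())
  prof <- iv$serum
  doubled <- concentration_profile(prof$times, 2 * prof$concentrations,
                                   fluid = "serum", route = "iv", dose = 20)
  r1 <- nca_intravenous(prof)
  r2 <- nca_intravenous(doubled)
  expect_equal(r2$cl, r1$cl / 2, tolerance = 1e-12)
})

test_that("trapezoid error shrinks at second order under sampling refinement", {
  auc_true <- 100 / 0.2 * (1 - exp(-0.2 * 10))
  errs <- sapply(c(21, 41, 81), function(n) {
    tt <- seq(0, 10, length.out = n)
    prof <- concentration_profile(tt, 100 * exp(-0.2 * tt), fluid = "serum",
                                  route = "iv", dose = 1)
    abs(auc_trapezoid(prof) - auc_true)
  })
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})
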