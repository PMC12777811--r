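# Mechanistic simulator of a lymph-duct-cannulated animal study.
#
# Model: linear compartments. Only the absorbable fraction fa of the dose
# enters the gut depot; absorbed flux (ka * gut) splits phi_lymph to a lymph
# compartment and (1 - phi_lymph) to the portal route, of which the liver
# extracts eh before the remainder reaches the central compartment. The lymph
# compartment drains at klt into the cannula, i.e. drained mass is collected
# externally and permanently removed from the animal. Central eliminates at
# cl/vc with optional peripheral exchange (k12/k21). All amounts are tracked
# in ng internally (1 mg = 1e6 ng); volumes in ml (1 l = 1e3 ml); time in h.

MG_TO_NG <- 1e6
L_TO_ML <- 1e3

.state_names <- c("gut", "lymph", "central", "peripheral",
                  "collected", "eliminated", "extracted")

.cannula_rhs <- function(t, y, p) {
  absflux <- p$ka * y[1]
  dgut <- -absflux
  dlymph <- p$phi_lymph * absflux - p$klt * y[2]
  dcentral <- (1 - p$phi_lymph) * (1 - p$eh) * absflux -
    p$ke * y[3] - p$k12 * y[3] + p$k21 * y[4]
  dperiph <- p$k12 * y[3] - p$k21 * y[4]
  dcollected <- p$klt * y[2]
  delim <- p$ke * y[3]
  dextracted <- p$eh * (1 - p$phi_lymph) * absflux
  list(c(dgut, dlymph, dcentral, dperiph, dcollected, delim, dextracted))
}

# Integrate the cannulated-animal system and enforce the mass balance:
# sum(states) + (1 - fa) * dose == dose at every output time.
.solve_cannula <- function(params, dose_mg, times, route,
                           rtol = 1e-10, atol_rel = 1e-12) {
  dose_ng <- dose_mg * MG_TO_NG
  y0 <- stats::setNames(numeric(7L), .state_names)
  if (route == "oral") y0["gut"] <- params$fa * dose_ng else
    y0["central"] <- dose_ng
  p <- list(ka = params$ka, phi_lymph = params$phi_lymph, eh = params$eh,
            klt = params$klt, ke = params$cl / params$vc,
            k12 = params$k12, k21 = params$k21)
  times <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(y0, times, .cannula_rhs, p,
                        rtol = rtol, atol = atol_rel * max(dose_ng, 1))
  if (any(!is.finite(sol)))
    stop(sprintf("non-finite ODE solution for parameter set (ka=%g, klt=%g, cl=%g, vc=%g)",
                 params$ka, params$klt, params$cl, params$vc), call. = FALSE)
  m <- sol[, .state_names, drop = FALSE]
  tol <- 1e-6 * dose_ng
  if (any(m < -tol))
    stop(sprintf("negative compartment amounts beyond tolerance for parameter set (ka=%g, klt=%g, cl=%g, vc=%g)",
                 params$ka, params$klt, params$cl, params$vc), call. = FALSE)
  m[m < 0] <- 0
  unabsorbable <- if (route == "oral") (1 - params$fa) * dose_ng else 0
  total <- rowSums(m) + unabsorbable
  if (any(abs(total - dose_ng) > tol))
    stop(sprintf("mass balance violated (max rel err %.2e) for parameter set (ka=%g, klt=%g, cl=%g, vc=%g)",
                 max(abs(total - dose_ng)) / dose_ng,
                 params$ka, params$klt, params$cl, params$vc), call. = FALSE)
  list(times = sol[, "time"], states = m, dose_ng = dose_ng)
}

.lookup_state <- function(sol, at, state) {
  idx <- match(at, sol$times)
  stopifnot(!anyNA(idx))
  sol$states[idx, state]
}

# Interval volumes from the flow model; assumes the caller controls the RNG
# stream when cv_flow > 0.
.draw_interval_volumes <- function(flow, widths) {
  if (flow$cv_flow == 0) return(flow$mean_flow * widths)
  sdlog <- sqrt(log(1 + flow$cv_flow^2))
  rate <- stats::rlnorm(length(widths),
                        meanlog = log(flow$mean_flow) - sdlog^2 / 2,
                        sdlog = sdlog)
  rate * widths
}

.simulate_oral_core <- function(params, dose, schedule, flow,
                                animal = "pig1", period = 1L,
                                formulation = "oral") {
  bounds <- schedule$lymph_interval_bounds
  if (is.null(bounds) || length(bounds) < 2L)
    stop("oral simulation requires lymph collection intervals", call. = FALSE)
  out_times <- sort(unique(c(schedule$serum_times, bounds)))
  sol <- .solve_cannula(params, dose, out_times, route = "oral")
  serum_conc <- .lookup_state(sol, schedule$serum_times, "central") /
    (params$vc * L_TO_ML)
  cum_collected <- .lookup_state(sol, bounds, "collected")
  interval_mass <- pmax(diff(cum_collected), 0)
  widths <- diff(bounds)
  volumes <- .draw_interval_volumes(flow, widths)
  lymph_conc <- ifelse(volumes > 0, interval_mass / volumes, 0)
  truth <- true_transport_fractions(params)
  structure(
    list(animal = animal, period = as.integer(period),
         formulation = formulation, route = "oral", dose = dose,
         serum = concentration_profile(schedule$serum_times, serum_conc,
                                       fluid = "serum", route = "oral",
                                       dose = dose),
         lymph = lymph_records(bounds[-length(bounds)], bounds[-1],
                               volumes, lymph_conc),
         truth = truth, params = params),
    class = "animal_record")
}

#' Simulate one oral dosing period in a cannulated animal
#'
#' Integrates the linear gut/lymph/portal/central model for an orally dosed,
#' lymph-duct-cannulated animal and reports noise-free serum concentrations
#' at the scheduled sampling times together with interval lymph collections
#' (volume and flow-weighted mean concentration per interval). Measurement
#' noise is added separately by [apply_measurement_noise()].
#'
#' @param params A [pk_parameters()] object.
#' @param dose Oral dose (mg).
#' @param schedule A [sampling_schedule()] with lymph interval bounds.
#' @param flow A [lymph_flow_model()]; interval volumes are `flow * width`.
#' @param seed Integer seed, required when `flow$cv_flow > 0` (the flow draw
#'   is the only stochastic element here).
#' @param animal,period,formulation Labels carried into the record.
#' @return An `animal_record`: labels, dose, a serum
#'   [concentration_profile()], [lymph_records()], the closed-form
#'   [true_transport_fractions()] and the realized parameters.
#' @export
simulate_oral_experiment <- function(params, dose, schedule = oral_schedule(),
                                     flow = lymph_flow_model(), seed = NULL,
                                     animal = "pig1", period = 1L,
                                     formulation = "oral") {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(schedule, "sampling_schedule"),
            inherits(flow, "lymph_flow_model"))
  if (flow$cv_flow > 0) {
    if (is.null(seed))
      stop("'seed' is required when the lymph flow model is stochastic (cv_flow > 0)",
           call. = FALSE)
    with_seed(seed,
              .simulate_oral_core(params, dose, schedule, flow,
                                  animal, period, formulation))
  } else {
    .simulate_oral_core(params, dose, schedule, flow,
                        animal, period, formulation)
  }
}

#' Simulate the intravenous reference animal
#'
#' Bolus dose placed in the central compartment at time zero; serum profile
#' only (the lymph is not sampled in the intravenously dosed animal). For
#' this linear model the analytic `AUC_inf` equals `dose / cl` exactly.
#'
#' @inheritParams simulate_oral_experiment
#' @param dose Intravenous dose (mg).
#' @return An `animal_record` with a serum profile and no lymph records.
#' @export
simulate_iv_experiment <- function(params, dose, schedule = iv_schedule(),
                                   animal = "iv1", period = 1L,
                                   formulation = "iv_reference") {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(schedule, "sampling_schedule"))
  sol <- .solve_cannula(params, dose, schedule$serum_times, route = "iv")
  serum_conc <- .lookup_state(sol, schedule$serum_times, "central") /
    (params$vc * L_TO_ML)
  structure(
    list(animal = animal, period = as.integer(period),
         formulation = formulation, route = "iv", dose = dose,
         serum = concentration_profile(schedule$serum_times, serum_conc,
                                       fluid = "serum", route = "iv",
                                       dose = dose),
         lymph = NULL, truth = NULL, params = params),
    class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record> %s period %d, %s (%s), dose %g mg\n",
              x$animal, x$period, x$formulation, x$route, x$dose))
  if (!is.null(x$lymph))
    cat(sprintf("  %d serum samples, %d lymph intervals\n",
                length(x$serum$times), nrow(x$lymph)))
  else cat(sprintf("  %d serum samples, no lymph collection\n",
                   length(x$serum$times)))
  invisible(x)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.add_noise_core <- function(record, noise) {
  perturb <- function(x) {
    if (noise$residual_cv == 0) return(x)
    sdlog <- sqrt(log(1 + noise$residual_cv^2))
    x * exp(stats::rnorm(length(x), 0, sdlog))
  }
  s <- record$serum
  sc <- perturb(s$concentrations)
  record$serum <- concentration_profile(s$times, sc, fluid = s$fluid,
                                        route = s$route, dose = s$dose,
                                        blq = sc < noise$lloq)
  if (!is.null(record$lymph)) {
    lc <- perturb(record$lymph$conc_ng_ml)
    record$lymph <- lymph_records(record$lymph$t_start_h,
                                  record$lymph$t_end_h,
                                  record$lymph$volume_ml,
                                  lc, blq = lc < noise$lloq)
  }
  record
}

#' Apply proportional measurement noise and BLQ flagging
#'
#' Multiplies every serum and lymph concentration by `exp(e)` with
#' `e ~ Normal(0, sigma)`, `sigma = sqrt(log(1 + cv^2))`, then flags values
#' below the LLOQ. With `residual_cv = 0` the record is returned unchanged
#' apart from the BLQ flags. The same seed always yields an identical record.
#'
#' @param record An `animal_record`.
#' @param noise A [noise_model()].
#' @param seed Integer seed (required).
#' @return The perturbed `animal_record`.
#' @export
apply_measurement_noise <- function(record, noise, seed) {
  stopifnot(inherits(record, "animal_record"), inherits(noise, "noise_model"))
  if (missing(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  with_seed(seed, .add_noise_core(record, noise))
}

# Per-animal log-normal multipliers shared across the animal's two periods.
.draw_iiv <- function(iiv_cv, n_params) {
  if (iiv_cv == 0) return(rep(1, n_params))
  sdlog <- sqrt(log(1 + iiv_cv^2))
  stats::rlnorm(n_params, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.apply_iiv <- function(params, mult) {
  pk_parameters(fa = min(1, params$fa * mult[["fa"]]),
                phi_lymph = min(1, params$phi_lymph * mult[["phi_lymph"]]),
                eh = params$eh,
                ka = params$ka * mult[["ka"]],
                klt = params$klt * mult[["klt"]],
                cl = params$cl * mult[["cl"]],
                vc = params$vc * mult[["vc"]],
                k12 = params$k12, k21 = params$k21,
                bodyweight = params$bodyweight)
}

#' Simulate a two-period cross-over lymphatic transport study
#'
#' Emulates the full cannulated-pig design: every animal receives both
#' formulations in successive periods (alternating sequence across animals),
#' and one separate animal provides the intravenous reference profile.
#' Per-animal parameters are drawn log-normally around the formulation means
#' with the animal's multipliers shared across its two periods; residual
#' noise and BLQ flagging follow the [noise_model()].
#'
#' @param n_animals Number of orally dosed animals (default 3). Fewer than 2
#'   triggers a warning (paired analysis impossible) but the dataset is
#'   still produced.
#' @param params_by_formulation Named list of two [pk_parameters()] sets,
#'   one per formulation; defaults to [default_pig_parameters()] for the
#'   oil solution and nanoemulsion.
#' @param doses Named oral doses (mg) per formulation; default 200 mg each.
#' @param iv_params,iv_dose Parameter set and dose (mg) for the intravenous
#'   reference animal (defaults: nanoemulsion parameters, 20 mg).
#' @param schedule,iv_sched Sampling schedules (defaults [oral_schedule()],
#'   [iv_schedule()]: 13 serum samples and 13 lymph intervals per oral
#'   period).
#' @param noise A [noise_model()].
#' @param flow A [lymph_flow_model()].
#' @param seed Integer seed (required); the whole study is reproducible
#'   from it.
#' @return A `study_dataset`: list of data.frames `serum`, `lymph`, `truth`
#'   (per-animal, per-period realized transport truths).
#' @export
generate_crossover_study <- function(n_animals = 3,
                                     params_by_formulation = list(
                                       oil_solution = default_pig_parameters("oil_solution"),
                                       nanoemulsion = default_pig_parameters("nanoemulsion")),
                                     doses = NULL,
                                     iv_params = default_pig_parameters("nanoemulsion"),
                                     iv_dose = 20,
                                     schedule = oral_schedule(),
                                     iv_sched = iv_schedule(),
                                     noise = noise_model(),
                                     flow = lymph_flow_model(),
                                     seed) {
  if (missing(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  if (length(params_by_formulation) != 2L ||
      is.null(names(params_by_formulation)))
    stop("'params_by_formulation' must be a named list of two parameter sets",
         call. = FALSE)
  forms <- names(params_by_formulation)
  doses <- doses %||% stats::setNames(rep(200, 2L), forms)
  if (n_animals < 2)
    warning("fewer than 2 animals: paired formulation analysis will not be possible",
            call. = FALSE)
  iiv_names <- c("fa", "phi_lymph", "ka", "klt", "cl", "vc")
  with_seed(seed, {
    records <- list()
    for (i in seq_len(n_animals)) {
      mult <- stats::setNames(.draw_iiv(noise$iiv_cv, length(iiv_names)),
                              iiv_names)
      seq_forms <- if (i %% 2L == 1L) forms else rev(forms)
      for (per in 1:2) {
        f <- seq_forms[per]
        p_i <- .apply_iiv(params_by_formulation[[f]], mult)
        rec <- .simulate_oral_core(p_i, doses[[f]], schedule, flow,
                                   animal = sprintf("pig%d", i),
                                   period = per, formulation = f)
        records[[length(records) + 1L]] <- .add_noise_core(rec, noise)
      }
    }
    mult <- stats::setNames(.draw_iiv(noise$iiv_cv, length(iiv_names)),
                            iiv_names)
    ivp <- .apply_iiv(iv_params, mult)
    iv_rec <- simulate_iv_experiment(ivp, iv_dose, iv_sched, animal = "iv1")
    records[[length(records) + 1L]] <- .add_noise_core(iv_rec, noise)
    as_study_dataset(records)
  })
}

#' Assemble animal records into tabular study data
#'
#' @param records List of `animal_record` objects.
#' @return A `study_dataset` with data.frames `serum` (animal, period,
#'   formulation, route, dose_mg, time_h, conc_ng_ml, blq), `lymph` (animal,
#'   period, formulation, t_start_h, t_end_h, volume_ml, conc_ng_ml, blq)
#'   and `truth` (per oral record: f_al_true, f_ap_true, f_true, f_rl_true).
#' @export
as_study_dataset <- function(records) {
  serum <- do.call(rbind, lapply(records, function(r) {
    data.frame(animal = r$animal, period = r$period,
               formulation = r$formulation, route = r$route,
               dose_mg = r$dose, time_h = r$serum$times,
               conc_ng_ml = r$serum$concentrations, blq = r$serum$blq)
  }))
  lymph_list <- Filter(Negate(is.null), lapply(records, function(r) {
    if (is.null(r$lymph)) return(NULL)
    data.frame(animal = r$animal, period = r$period,
               formulation = r$formulation,
               t_start_h = r$lymph$t_start_h, t_end_h = r$lymph$t_end_h,
               volume_ml = r$lymph$volume_ml,
               conc_ng_ml = r$lymph$conc_ng_ml, blq = r$lymph$blq)
  }))
  lymph <- if (length(lymph_list)) do.call(rbind, lymph_list) else NULL
  truth_list <- Filter(Negate(is.null), lapply(records, function(r) {
    if (is.null(r$truth)) return(NULL)
    data.frame(animal = r$animal, period = r$period,
               formulation = r$formulation,
               f_al_true = r$truth$f_al_true, f_ap_true = r$truth$f_ap_true,
               f_true = r$truth$f_true, f_rl_true = r$truth$f_rl_true)
  }))
  truth <- if (length(truth_list)) do.call(rbind, truth_list) else NULL
  structure(list(serum = serum, lymph = lymph, truth = truth),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  oral <- unique(x$serum[x$serum$route == "oral", c("animal", "period")])
  cat(sprintf("<study_dataset> %d oral animal-periods, %d IV reference record(s)\n",
              nrow(oral), length(unique(x$serum$animal[x$serum$route == "iv"]))))
  cat(sprintf("  serum rows: %d; lymph rows: %d; truth rows: %d\n",
              nrow(x$serum), if (is.null(x$lymph)) 0L else nrow(x$lymph),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}
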