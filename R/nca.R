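# Non-compartmental analysis: linear trapezoidal AUC, terminal log-linear
# slope, extrapolation to infinity and IV disposition parameters.

#' Resolve below-LLOQ observations in a profile
#'
#' Applies the standard conservative policy: BLQ values before the first
#' quantifiable point are set to zero (pre-dose/pre-absorption convention);
#' BLQ values at or after the first quantifiable point — embedded between
#' quantifiable points or trailing after Tmax — are dropped from the profile.
#' Each edit is logged in the `"blq_log"` attribute of the result.
#'
#' @param profile A [concentration_profile()].
#' @param lloq Lower limit of quantification (ng/ml); concentrations below
#'   it are treated as BLQ even when not pre-flagged.
#' @return The edited [concentration_profile()] with no remaining BLQ flags.
#' @export
handle_blq <- function(profile, lloq = 1) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (!is.numeric(lloq) || lloq <= 0)
    stop("'lloq' must be positive", call. = FALSE)
  conc <- profile$concentrations
  blq <- profile$blq | (is.finite(conc) & conc < lloq)
  if (all(blq))
    stop("all observations are below the limit of quantification", call. = FALSE)
  log <- character()
  first_q <- which(!blq)[1]
  lead <- which(blq & seq_along(blq) < first_q)
  if (length(lead)) {
    conc[lead] <- 0
    blq[lead] <- FALSE
    log <- c(log, sprintf("BLQ at t=%g h before first quantifiable point set to 0",
                          profile$times[lead]))
  }
  drop <- which(blq)
  if (length(drop))
    log <- c(log, sprintf("BLQ at t=%g h dropped", profile$times[drop]))
  keep <- !blq
  out <- concentration_profile(profile$times[keep], conc[keep],
                               fluid = profile$fluid, route = profile$route,
                               dose = profile$dose)
  attr(out, "blq_log") <- log
  out
}

# Linear interpolation of the concentration at time t0 (t0 within span).
.interp_conc <- function(times, conc, t0) {
  stats::approx(times, conc, xout = t0, method = "linear", ties = "ordered")$y
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Linear trapezoidal AUC over a time window
#'
#' Area under the concentration-time curve by the linear trapezoidal rule
#' over successive quantifiable points, using the exact sampling times. When
#' a window edge falls between samples the concentration there is linearly
#' interpolated first, which makes the rule exactly additive over adjacent
#' sub-windows.
#'
#' @param profile A [concentration_profile()] (BLQ-handled; any remaining
#'   flagged points are excluded).
#' @param t_start,t_end Window bounds (h); default to the observed span.
#' @return AUC in ng*h/ml.
#' @export
auc_trapezoid <- function(profile, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  keep <- !profile$blq
  tt <- profile$times[keep]; cc <- profile$concentrations[keep]
  if (length(tt) < 2L)
    stop("fewer than 2 quantifiable points in the profile", call. = FALSE)
  t_start <- t_start %||% tt[1]
  t_end <- t_end %||% tt[length(tt)]
  if (t_start >= t_end)
    stop("'t_start' must be before 't_end'", call. = FALSE)
  eps <- 1e-9
  if (t_start < tt[1] - eps || t_end > tt[length(tt)] + eps)
    stop(sprintf("window [%g, %g] h lies outside the observed span [%g, %g] h",
                 t_start, t_end, tt[1], tt[length(tt)]), call. = FALSE)
  inside <- tt > t_start + eps & tt < t_end - eps
  x <- c(t_start, tt[inside], t_end)
  y <- c(.interp_conc(tt, cc, t_start), cc[inside], .interp_conc(tt, cc, t_end))
  if (length(x) < 2L)
    stop("fewer than 2 points in the requested window", call. = FALSE)
  .trapz(x, y)
}

# First moment (t * C) by the same linear trapezoid, full quantifiable span.
.aumc_trapezoid <- function(times, conc) .trapz(times, times * conc)

.tmax_index <- function(conc) which(conc == max(conc))[1]

#' Terminal slope estimation
#'
#' Ordinary least squares on log concentration versus time over candidate
#' tails: every suffix of at least 3 quantifiable points strictly after Tmax
#' (zero concentrations are excluded from the log fit). The tail maximizing
#' the adjusted R-squared is selected, with ties broken toward more points;
#' a negative slope is required.
#'
#' @param profile A BLQ-handled [concentration_profile()].
#' @return A `terminal_fit` (fields `lambda_z` (1/h), `t_half` (h),
#'   `n_points`, `r2_adj`, `time_span` (h)), or `NULL` when no admissible
#'   declining tail exists.
#' @export
estimate_lambda_z <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  keep <- !profile$blq
  tt <- profile$times[keep]; cc <- profile$concentrations[keep]
  imax <- .tmax_index(cc)
  tail_idx <- which(seq_along(tt) > imax & cc > 0)
  n_tail <- length(tail_idx)
  if (n_tail < 3L) return(NULL)
  x_all <- tt[tail_idx]; y_all <- log(cc[tail_idx])
  best <- NULL
  for (k in 3:n_tail) {
    x <- utils::tail(x_all, k); y <- utils::tail(y_all, k)
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (slope >= 0) next
    yhat <- mean(y) + slope * (x - mean(x))
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 1 else 1 - sum((y - yhat)^2) / sst
    r2_adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2_adj > best$r2_adj + 1e-10 ||
        (abs(r2_adj - best$r2_adj) <= 1e-10 && k > best$n_points)) {
      best <- list(lambda_z = -slope, t_half = log(2) / -slope,
                   n_points = k, r2_adj = r2_adj,
                   time_span = x[k] - x[1])
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "terminal_fit")
}

#' Convert an intravenous AUC to systemic clearance
#'
#' `CL = dose / AUC_inf`, with units converted so that a dose in mg and an
#' AUC in ng*h/ml yield clearance in l/h.
#'
#' @param dose_mg Intravenous dose (mg).
#' @param auc_inf AUC extrapolated to infinity (ng*h/ml).
#' @return Clearance in l/h.
#' @export
clearance_from_auc <- function(dose_mg, auc_inf) {
  if (!is.numeric(dose_mg) || dose_mg <= 0 || !is.numeric(auc_inf) ||
      auc_inf <= 0)
    stop("dose and AUC must be positive", call. = FALSE)
  dose_mg * 1000 / auc_inf
}

.new_nca_result <- function(...) {
  defaults <- list(cmax = NA_real_, tmax = NA_real_, auc_last = NA_real_,
                   auc_inf = NA_real_, aumc_inf = NA_real_,
                   pct_extrapolated = NA_real_, terminal = NULL,
                   cl = NA_real_, mrt = NA_real_, vss = NA_real_,
                   cl_per_kg = NA_real_, vss_per_kg = NA_real_,
                   route = NA_character_, fluid = NA_character_,
                   dose = NA_real_, flags = character())
  args <- list(...)
  defaults[names(args)] <- args
  structure(defaults, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s (%s), dose %g mg\n", x$fluid, x$route, x$dose))
  cat(sprintf("  Cmax %.4g ng/ml at Tmax %.3g h; AUC_last %.5g, AUC_inf %.5g ng*h/ml (%.1f%% extrapolated)\n",
              x$cmax, x$tmax, x$auc_last, x$auc_inf, x$pct_extrapolated))
  if (!is.null(x$terminal))
    cat(sprintf("  lambda_z %.4g /h (t1/2 %.3g h, %d points, adj R2 %.4f)\n",
                x$terminal$lambda_z, x$terminal$t_half,
                x$terminal$n_points, x$terminal$r2_adj))
  if (is.finite(x$cl))
    cat(sprintf("  CL %.4g l/h, MRT %.4g h, Vss %.4g l\n", x$cl, x$mrt, x$vss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Non-compartmental analysis of an extravascular profile
#'
#' Cmax and Tmax from the quantifiable points (ties broken to the earliest
#' time), AUC to the last quantifiable point by the linear trapezoid,
#' extrapolation `AUC_inf = AUC_last + C_last / lambda_z` using the observed
#' last concentration, and the percentage of AUC_inf obtained by
#' extrapolation (a warning flag is attached above 20 %).
#'
#' @param profile A BLQ-handled oral-route [concentration_profile()].
#' @return An `nca_result`; `auc_inf` is `NA` with flag
#'   `"no_terminal_phase"` when no terminal slope can be fitted.
#' @export
nca_extravascular <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  keep <- !profile$blq
  tt <- profile$times[keep]; cc <- profile$concentrations[keep]
  if (length(tt) < 3L)
    stop("at least 3 quantifiable points are required for NCA", call. = FALSE)
  imax <- .tmax_index(cc)
  auc_last <- auc_trapezoid(profile)
  term <- estimate_lambda_z(profile)
  flags <- character()
  if (is.null(term)) {
    auc_inf <- NA_real_; pct <- NA_real_
    flags <- c(flags, "no_terminal_phase")
  } else {
    c_last <- cc[length(cc)]
    auc_inf <- auc_last + c_last / term$lambda_z
    pct <- 100 * (auc_inf - auc_last) / auc_inf
    if (pct > 20) flags <- c(flags, "extrapolation_above_20pct")
  }
  .new_nca_result(cmax = cc[imax], tmax = tt[imax], auc_last = auc_last,
                  auc_inf = auc_inf, pct_extrapolated = pct, terminal = term,
                  route = profile$route, fluid = profile$fluid,
                  dose = profile$dose, flags = flags)
}

# Log-linear back-extrapolation of the bolus C0 from the first two observed
# points; carried back flat when the profile starts rising.
.iv_c0 <- function(times, conc) {
  if (length(conc) >= 2L && conc[1] > conc[2] && conc[2] > 0) {
    slope <- (log(conc[2]) - log(conc[1])) / (times[2] - times[1])
    exp(log(conc[1]) - slope * times[1])
  } else conc[1]
}

#' Non-compartmental analysis of an intravenous bolus profile
#'
#' As [nca_extravascular()], plus bolus disposition parameters:
#' `CL = dose / AUC_inf`, `MRT = AUMC_inf / AUC_inf` (no infusion
#' correction), `Vss = CL * MRT`. When the profile does not start at time
#' zero, C0 is back-extrapolated log-linearly from the first two samples and
#' the 0-to-first-sample segment is included in AUC and AUMC. AUMC is
#' extrapolated as `AUMC_last + C_last * t_last / lambda_z +
#' C_last / lambda_z^2`.
#'
#' @param profile A BLQ-handled iv-route [concentration_profile()] with a
#'   known dose.
#' @param bodyweight Optional bodyweight (kg) for per-kg clearance and
#'   volume.
#' @return An `nca_result` with `cl` (l/h), `mrt` (h), `vss` (l) and, when
#'   bodyweight is given, `cl_per_kg` (l/h/kg) and `vss_per_kg` (l/kg).
#' @export
nca_intravenous <- function(profile, bodyweight = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (profile$route != "iv")
    stop("'profile' must be an intravenous-route profile", call. = FALSE)
  keep <- !profile$blq
  tt <- profile$times[keep]; cc <- profile$concentrations[keep]
  if (length(tt) < 3L)
    stop("at least 3 quantifiable points are required for NCA", call. = FALSE)
  flags <- character()
  if (tt[1] > 0) {
    c0 <- .iv_c0(tt, cc)
    tt <- c(0, tt); cc <- c(c0, cc)
    flags <- c(flags, "c0_back_extrapolated")
  }
  imax_obs <- .tmax_index(profile$concentrations[keep])
  auc_last <- .trapz(tt, cc)
  aumc_last <- .aumc_trapezoid(tt, cc)
  term <- estimate_lambda_z(profile)
  if (is.null(term)) {
    return(.new_nca_result(cmax = profile$concentrations[keep][imax_obs],
                           tmax = profile$times[keep][imax_obs],
                           auc_last = auc_last, route = "iv",
                           fluid = profile$fluid, dose = profile$dose,
                           flags = c(flags, "no_terminal_phase")))
  }
  c_last <- cc[length(cc)]; t_last <- tt[length(tt)]
  auc_inf <- auc_last + c_last / term$lambda_z
  aumc_inf <- aumc_last + c_last * t_last / term$lambda_z +
    c_last / term$lambda_z^2
  pct <- 100 * (auc_inf - auc_last) / auc_inf
  if (pct > 20) flags <- c(flags, "extrapolation_above_20pct")
  cl <- clearance_from_auc(profile$dose, auc_inf)
  mrt <- aumc_inf / auc_inf
  vss <- cl * mrt
  .new_nca_result(cmax = profile$concentrations[keep][imax_obs],
                  tmax = profile$times[keep][imax_obs],
                  auc_last = auc_last, auc_inf = auc_inf,
                  aumc_inf = aumc_inf, pct_extrapolated = pct,
                  terminal = term, cl = cl, mrt = mrt, vss = vss,
                  cl_per_kg = if (is.null(bodyweight)) NA_real_ else cl / bodyweight,
                  vss_per_kg = if (is.null(bodyweight)) NA_real_ else vss / bodyweight,
                  route = "iv", fluid = profile$fluid, dose = profile$dose,
                  flags = flags)
}
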