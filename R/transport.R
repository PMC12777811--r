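# Lymphatic transport: cumulative mass balance from interval collections and
# the bioavailability partition F_AL / F_AP / F / F_RL.

#' Cumulative lymphatic transport curve
#'
#' Drug mass collected in each lymph interval is `concentration x volume`
#' (the aliquot concentration is taken as the flow-weighted mean over the
#' interval), accumulated in time order. The cumulative percentage of dose
#' is the direct mass-balance bioavailability via lymph, F_AL(t); its value
#' at the end of collection is F_AL. BLQ concentrations contribute zero
#' mass.
#'
#' @param records A [lymph_records()] table for one animal and period.
#' @param dose Administered dose (mg), > 0.
#' @return A `cumulative_transport_curve`: `times` (interval ends, h),
#'   `cumulative_amount` (mg), `cumulative_pct_dose` (%).
#' @export
cumulative_transport <- function(records, dose) {
  records <- .validate_records(records)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("'dose' must be a single positive number (mg)", call. = FALSE)
  conc <- ifelse(records$blq, 0, records$conc_ng_ml)
  amount_mg <- conc * records$volume_ml / MG_TO_NG
  cum <- cumsum(amount_mg)
  structure(list(times = records$t_end_h, cumulative_amount = cum,
                 cumulative_pct_dose = 100 * cum / dose, dose = dose),
            class = "cumulative_transport_curve")
}

.validate_records <- function(records) {
  if (inherits(records, "lymph_records")) return(records)
  req <- c("t_start_h", "t_end_h", "volume_ml", "conc_ng_ml")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("lymph records need columns t_start_h, t_end_h, volume_ml, conc_ng_ml",
         call. = FALSE)
  lymph_records(records$t_start_h, records$t_end_h, records$volume_ml,
                records$conc_ng_ml,
                blq = if ("blq" %in% names(records)) records$blq else NULL)
}

#' @export
print.cumulative_transport_curve <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<cumulative_transport_curve> %d intervals to %g h; F_AL(end) = %.3g%% of %g mg\n",
              n, x$times[n], x$cumulative_pct_dose[n], x$dose))
  invisible(x)
}

#' Absolute bioavailability via the portal vein
#'
#' The dose-normalized ratio of the oral (enteral) serum AUC in a
#' lymph-diverted animal to the intravenous reference AUC:
#' `100 * (AUC_ent / dose_ent) / (AUC_iv / dose_iv)` percent. With the
#' thoracic duct cannulated, lymph-routed drug never reaches the blood, so
#' this ratio isolates the portal route.
#'
#' @param auc_ent Oral serum AUC (ng*h/ml).
#' @param dose_ent Oral dose (mg).
#' @param auc_iv Intravenous reference AUC (ng*h/ml).
#' @param dose_iv Intravenous dose (mg).
#' @return F_AP in percent.
#' @export
absolute_bioavailability_portal <- function(auc_ent, dose_ent, auc_iv, dose_iv) {
  vals <- c(auc_ent = auc_ent, dose_ent = dose_ent,
            auc_iv = auc_iv, dose_iv = dose_iv)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad))
    stop(sprintf("'%s' must be positive", names(vals)[bad][1]), call. = FALSE)
  100 * (auc_ent / dose_ent) / (auc_iv / dose_iv)
}

#' Total absolute bioavailability
#'
#' In a lymph-duct-cannulated animal the lymph and portal routes are the two
#' disjoint gateways into the systemic circulation, so total bioavailability
#' is their sum: `F = F_AL + F_AP`.
#'
#' @param f_al Absolute bioavailability via lymph (%).
#' @param f_ap Absolute bioavailability via the portal vein (%).
#' @return F in percent.
#' @export
total_bioavailability <- function(f_al, f_ap) {
  if (!is.numeric(f_al) || !is.numeric(f_ap) || any(f_al < 0) || any(f_ap < 0))
    stop("'f_al' and 'f_ap' must be non-negative percentages", call. = FALSE)
  f_al + f_ap
}

#' Relative bioavailability via lymph
#'
#' The share of systemically available drug that traveled through the lymph:
#' `F_RL = 100 * F_AL / F` percent. Defined as 0 when `F_AL = 0` and
#' `F > 0`; an error when `F = 0` with `F_AL > 0` (inconsistent inputs).
#'
#' @param f_al Absolute bioavailability via lymph (%).
#' @param f Total absolute bioavailability (%).
#' @return F_RL in percent.
#' @export
relative_lymph_bioavailability <- function(f_al, f) {
  if (!is.numeric(f_al) || !is.numeric(f) || any(f_al < 0) || any(f < 0))
    stop("'f_al' and 'f' must be non-negative percentages", call. = FALSE)
  zero_f <- f == 0
  if (any(zero_f & f_al > 0))
    stop("inconsistent inputs: f = 0 with f_al > 0", call. = FALSE)
  if (any(f < f_al - 1e-12))
    stop("'f' must be at least 'f_al' (lymph route is part of the total)",
         call. = FALSE)
  out <- numeric(length(f_al))
  out[!zero_f] <- 100 * f_al[!zero_f] / f[!zero_f]
  out
}

#' Lymph interval collections as a concentration time series
#'
#' Assigns each interval's aliquot concentration to the interval end time
#' (matching the hourly sampling convention, so hourly intervals over
#' 0--12 h give points at 1..12 h alongside the serum samples). This enables
#' lymph Cmax/Tmax/AUC through the NCA engine. A single-interval record
#' yields a one-point profile, which the NCA functions reject as
#' insufficient.
#'
#' @param records A [lymph_records()] table.
#' @param dose Dose (mg) to tag the profile with.
#' @return A lymph-fluid [concentration_profile()].
#' @export
lymph_profile_as_timeseries <- function(records, dose) {
  records <- .validate_records(records)
  concentration_profile(records$t_end_h,
                        ifelse(records$blq, NA_real_, records$conc_ng_ml),
                        fluid = "lymph", route = "oral", dose = dose,
                        blq = records$blq)
}

#' Full transport analysis of one oral animal-period
#'
#' Assembles the bioavailability partition for one orally dosed,
#' lymph-duct-cannulated animal-period: F_AL by direct lymph mass balance,
#' F_AP from the dose-normalized oral/IV serum AUC ratio, `F = F_AL + F_AP`
#' and `F_RL = 100 * F_AL / F`, plus lymph/serum exposure ratios
#' (Cmax, Tmax, AUC_inf) from parallel NCA of the two fluids.
#'
#' With a truncation time `t*`, F_AL is restricted to intervals ending at or
#' before `t*` and the oral serum AUC is the windowed `AUC[0, t*]`; the IV
#' reference is always dose-normalized by its full `AUC_inf`. Without
#' truncation, F_AL uses the whole collection and the oral exposure is
#' `AUC_inf`. The exposure ratios are always computed from the full
#' (untruncated) profiles. A zero serum concentration at the dosing time is
#' prepended for the oral AUC. The two defining identities are asserted on
#' the result after construction.
#'
#' @param animal_record An oral `animal_record` (serum profile plus lymph
#'   records), e.g. from [simulate_oral_experiment()] or reconstructed from
#'   tables by [run_study_analysis()].
#' @param iv_reference_nca An `nca_result` from [nca_intravenous()], or
#'   `NULL` (then F_AP, F and F_RL are `NA` and F_AL is still reported).
#' @param truncation_time Truncation time `t*` (h), or `NULL` for the full
#'   analysis.
#' @param lloq LLOQ (ng/ml) used for BLQ handling of both fluids.
#' @return A `transport_result` with fields `f_al`, `f_ap`, `f`, `f_rl`
#'   (percent), `auc_serum`, `auc_lymph` (ng*h/ml), `cmax_serum`,
#'   `cmax_lymph`, `cmax_ratio`, `tmax_serum`, `tmax_lymph`, `tmax_ratio`,
#'   `auc_ratio`, `truncation_time`.
#' @export
transport_analysis <- function(animal_record, iv_reference_nca = NULL,
                               truncation_time = NULL, lloq = 1) {
  stopifnot(inherits(animal_record, "animal_record"))
  if (animal_record$route != "oral")
    stop("transport analysis applies to orally dosed records", call. = FALSE)
  if (is.null(animal_record$lymph))
    stop("oral record carries no lymph collection data", call. = FALSE)
  dose <- animal_record$dose

  records <- .validate_records(animal_record$lymph)
  curve <- cumulative_transport(records, dose)
  if (!is.null(truncation_time)) {
    sel <- curve$times <= truncation_time + 1e-9
    if (!any(sel))
      stop("no lymph interval ends at or before the truncation time",
           call. = FALSE)
    f_al <- curve$cumulative_pct_dose[max(which(sel))]
  } else {
    f_al <- curve$cumulative_pct_dose[length(curve$times)]
  }

  serum <- handle_blq(animal_record$serum, lloq)
  serum0 <- .prepend_zero(serum)
  serum_nca <- nca_extravascular(serum0)
  auc_ent <- if (!is.null(truncation_time))
    auc_trapezoid(serum0, 0, truncation_time) else serum_nca$auc_inf

  # lymph NCA is informative only; an all-BLQ or too-sparse lymph profile
  # leaves the ratio columns NA without failing the mass-balance analysis
  lymph_prof <- lymph_profile_as_timeseries(records, dose)
  lymph_nca <- tryCatch(
    nca_extravascular(.prepend_zero(handle_blq(lymph_prof, lloq))),
    error = function(e) NULL)

  if (!is.null(iv_reference_nca)) {
    stopifnot(inherits(iv_reference_nca, "nca_result"))
    auc_iv <- iv_reference_nca$auc_inf
    if (!is.finite(auc_iv))
      stop("IV reference NCA has no defined AUC_inf", call. = FALSE)
    f_ap <- if (is.finite(auc_ent))
      absolute_bioavailability_portal(auc_ent, dose, auc_iv,
                                      iv_reference_nca$dose) else NA_real_
  } else f_ap <- NA_real_

  if (is.finite(f_ap)) {
    f <- total_bioavailability(f_al, f_ap)
    f_rl <- relative_lymph_bioavailability(f_al, f)
  } else {
    f <- NA_real_; f_rl <- NA_real_
  }

  ratio <- function(a, b) if (!is.null(a) && !is.null(b) &&
                              is.finite(a) && is.finite(b) && b != 0)
    a / b else NA_real_
  res <- structure(
    list(animal = animal_record$animal, period = animal_record$period,
         formulation = animal_record$formulation, dose = dose,
         f_al = f_al, f_ap = f_ap, f = f, f_rl = f_rl,
         auc_serum = serum_nca$auc_inf,
         auc_lymph = if (is.null(lymph_nca)) NA_real_ else lymph_nca$auc_inf,
         cmax_serum = serum_nca$cmax,
         cmax_lymph = if (is.null(lymph_nca)) NA_real_ else lymph_nca$cmax,
         tmax_serum = serum_nca$tmax,
         tmax_lymph = if (is.null(lymph_nca)) NA_real_ else lymph_nca$tmax,
         cmax_ratio = ratio(if (is.null(lymph_nca)) NA_real_ else lymph_nca$cmax,
                            serum_nca$cmax),
         tmax_ratio = ratio(if (is.null(lymph_nca)) NA_real_ else lymph_nca$tmax,
                            serum_nca$tmax),
         auc_ratio = ratio(if (is.null(lymph_nca)) NA_real_ else lymph_nca$auc_inf,
                           serum_nca$auc_inf),
         truncation_time = truncation_time %||% NA_real_),
    class = "transport_result")
  .assert_partition_identities(res)
  res
}

.prepend_zero <- function(profile) {
  if (profile$times[1] == 0) return(profile)
  concentration_profile(c(0, profile$times), c(0, profile$concentrations),
                        fluid = profile$fluid, route = profile$route,
                        dose = profile$dose,
                        blq = c(FALSE, profile$blq))
}

.assert_partition_identities <- function(res) {
  if (is.finite(res$f)) {
    stopifnot(abs(res$f - (res$f_al + res$f_ap)) <= 1e-9 * max(1, res$f))
    if (res$f > 0)
      stopifnot(abs(res$f_rl - 100 * res$f_al / res$f) <= 1e-9 * max(1, res$f_rl))
  }
  invisible(res)
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("<transport_result> %s period %d, %s%s\n", x$animal, x$period,
              x$formulation,
              if (is.finite(x$truncation_time))
                sprintf(" (truncated at %g h)", x$truncation_time) else ""))
  cat(sprintf("  F_AL %.3g%%  F_AP %.3g%%  F %.3g%%  F_RL %.3g%%\n",
              x$f_al, x$f_ap, x$f, x$f_rl))
  cat(sprintf("  Cmax ratio %.3g  AUC ratio %.3g  Tmax ratio %.3g\n",
              x$cmax_ratio, x$auc_ratio, x$tmax_ratio))
  invisible(x)
}
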