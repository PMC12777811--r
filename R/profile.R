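#' Concentration-time profile
#'
#' A route- and dose-tagged concentration time series in one fluid.
#' Concentrations flagged BLQ (below the limit of quantification) keep a
#' placeholder value (possibly `NA`) and are interpreted by [handle_blq()].
#'
#' @param times Sampling times (h post-dose), strictly increasing, >= 0.
#' @param concentrations Concentrations (ng/ml); quantifiable values must be
#'   non-negative, BLQ entries may be `NA`.
#' @param fluid `"serum"` or `"lymph"`.
#' @param route `"oral"` or `"iv"`.
#' @param dose Administered dose (mg), > 0.
#' @param blq Logical vector flagging below-LLOQ observations.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(times, concentrations,
                                  fluid = c("serum", "lymph"),
                                  route = c("oral", "iv"),
                                  dose, blq = NULL) {
  fluid <- match.arg(fluid)
  route <- match.arg(route)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("'times' and 'concentrations' must have equal length", call. = FALSE)
  if (length(times) == 0L)
    stop("empty concentration profile", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("'times' must be finite, non-negative and strictly increasing",
         call. = FALSE)
  blq <- if (is.null(blq)) rep(FALSE, length(times)) else as.logical(blq)
  if (length(blq) != length(times))
    stop("'blq' must match the number of samples", call. = FALSE)
  bad <- !blq & (!is.finite(concentrations) | concentrations < 0)
  if (any(bad))
    stop(sprintf("negative or non-finite quantifiable concentration at t = %s h",
                 paste(times[bad], collapse = ", ")), call. = FALSE)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("'dose' must be a single positive number (mg)", call. = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 fluid = fluid, route = route, dose = dose, blq = blq),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> %s, %s route, dose %g mg, %d samples (%g-%g h)\n",
              x$fluid, x$route, x$dose, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Timed lymph-collection records
#'
#' Validates a set of lymph-collection intervals for one animal and period:
#' each interval has a start and end time, the total collected volume and the
#' aliquot concentration. Intervals must be non-overlapping and in time order.
#'
#' @param t_start,t_end Interval bounds (h post-dose).
#' @param volume Collected lymph volume per interval (ml), >= 0.
#' @param concentration Aliquot concentration (ng/ml); BLQ entries may be
#'   `NA` when flagged.
#' @param blq Logical BLQ flags (BLQ lymph concentrations contribute zero
#'   mass downstream).
#' @return A `data.frame` of class `lymph_records` with columns
#'   `t_start_h`, `t_end_h`, `volume_ml`, `conc_ng_ml`, `blq`.
#' @export
lymph_records <- function(t_start, t_end, volume, concentration, blq = NULL) {
  n <- length(t_start)
  if (length(t_end) != n || length(volume) != n || length(concentration) != n)
    stop("lymph record columns must have equal length", call. = FALSE)
  blq <- if (is.null(blq)) rep(FALSE, n) else as.logical(blq)
  if (n == 0L) stop("no lymph collection intervals given", call. = FALSE)
  o <- order(t_start)
  t_start <- as.numeric(t_start)[o]; t_end <- as.numeric(t_end)[o]
  volume <- as.numeric(volume)[o]
  concentration <- as.numeric(concentration)[o]; blq <- blq[o]
  if (any(!is.finite(t_start)) || any(!is.finite(t_end)) ||
      any(t_start < 0) || any(t_end <= t_start))
    stop("each lymph interval needs 0 <= t_start < t_end", call. = FALSE)
  if (n > 1L) {
    overlap <- which(t_start[-1] < t_end[-n] - 1e-9)
    if (length(overlap))
      stop(sprintf("overlapping lymph intervals: interval %d ends at %g h but interval %d starts at %g h",
                   overlap[1], t_end[overlap[1]],
                   overlap[1] + 1L, t_start[overlap[1] + 1L]), call. = FALSE)
  }
  if (any(volume < 0 | !is.finite(volume)))
    stop("lymph volumes must be finite and non-negative", call. = FALSE)
  bad <- !blq & (!is.finite(concentration) | concentration < 0)
  if (any(bad))
    stop("negative or non-finite quantifiable lymph concentration",
         call. = FALSE)
  structure(data.frame(t_start_h = t_start, t_end_h = t_end,
                       volume_ml = volume, conc_ng_ml = concentration,
                       blq = blq),
            class = c("lymph_records", "data.frame"))
}
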