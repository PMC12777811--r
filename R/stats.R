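# Cross-over and interspecies comparison statistics, summary tables in the
# publication layout, and the parameter-recovery report used for validation.

.new_comparison <- function(parameter, groups, n, means, sds, test,
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            note = NA_character_) {
  structure(list(parameter = parameter, groups = groups, n = n,
                 means = means, sds = sds, test = test,
                 t = t, df = df, p = p,
                 significant = is.finite(p) && p < 0.05, note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s vs %s (%s t-test)\n",
              x$parameter, x$groups[1], x$groups[2], x$test))
  cat(sprintf("  n = %s; means %.4g vs %.4g; t = %.3g (df %.3g), p = %.4g%s\n",
              paste(x$n, collapse = "/"), x$means[1], x$means[2],
              x$t, x$df, x$p, if (isTRUE(x$significant)) " *" else ""))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Paired formulation comparison within a cross-over study
#'
#' Two-sided paired t-test on per-animal values of one parameter between the
#' two formulations, with no period or sequence adjustment. Only animals
#' with both periods contribute. When the within-animal differences have
#' zero variance the test statistic is undefined; that degenerate case is
#' reported explicitly (`t = 0, p = 1` when all differences are zero, an
#' explanatory note otherwise) rather than as a spurious `p = 0`.
#'
#' @param results A data.frame with columns `animal`, `formulation` and the
#'   parameter to compare (one row per animal-period).
#' @param parameter Name of the parameter column.
#' @return A `comparison_result`.
#' @export
paired_formulation_comparison <- function(results, parameter) {
  if (!parameter %in% names(results))
    stop(sprintf("no column '%s' in the results table", parameter),
         call. = FALSE)
  forms <- sort(unique(results$formulation))
  if (length(forms) != 2L)
    stop("paired comparison needs exactly two formulations", call. = FALSE)
  wide <- merge(results[results$formulation == forms[1],
                        c("animal", parameter)],
                results[results$formulation == forms[2],
                        c("animal", parameter)],
                by = "animal", suffixes = c("_a", "_b"))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 2L)
    stop("fewer than 2 complete animal pairs", call. = FALSE)
  a <- wide[[paste0(parameter, "_a")]]
  b <- wide[[paste0(parameter, "_b")]]
  d <- a - b
  base <- list(parameter = parameter, groups = forms,
               n = c(length(a), length(b)),
               means = c(mean(a), mean(b)),
               sds = c(stats::sd(a), stats::sd(b)), test = "paired")
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(do.call(.new_comparison,
                     c(base, list(t = 0, df = length(d) - 1, p = 1,
                                  note = "identical values in both periods"))))
    return(do.call(.new_comparison,
                   c(base, list(note = sprintf(
                     "degenerate: constant non-zero difference %.4g with zero variance; t-test undefined",
                     d[1])))))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  do.call(.new_comparison,
          c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value)))
}

#' Unpaired two-group comparison (interspecies)
#'
#' Two-sided two-sample t-test between independent groups, equal-variance
#' (classical Student) by default; the variance assumption is recorded in
#' the result. Degenerate zero-variance inputs are reported explicitly.
#'
#' @param group_a,group_b Numeric value vectors (n >= 2 each).
#' @param parameter Parameter name for the report.
#' @param labels Group labels (length 2).
#' @param var_equal Use the pooled-variance Student test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return A `comparison_result`.
#' @export
unpaired_species_comparison <- function(group_a, group_b, parameter,
                                        labels = c("group_a", "group_b"),
                                        var_equal = TRUE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  base <- list(parameter = parameter, groups = labels,
               n = c(length(group_a), length(group_b)),
               means = c(mean(group_a), mean(group_b)),
               sds = c(stats::sd(group_a), stats::sd(group_b)),
               test = if (var_equal) "unpaired (Student)" else "unpaired (Welch)")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(do.call(.new_comparison,
                     c(base, list(t = 0,
                                  df = length(group_a) + length(group_b) - 2,
                                  p = 1, note = "identical constant groups"))))
    return(do.call(.new_comparison,
                   c(base, list(note = "degenerate: both groups constant with differing means; t-test undefined"))))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  do.call(.new_comparison,
          c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value)))
}

#' Group summary table (mean +/- SD)
#'
#' Summarizes each parameter per group as mean and sample SD (n - 1 in the
#' denominator; SD is reported as missing, not zero, for single-value
#' groups), with a formatted `mean +/- SD` label. When comparison results
#' are supplied, a significance marker (`*`, p < 0.05) is appended to the
#' second group's label for the compared parameters, following the usual
#' table convention.
#'
#' @param results Tidy results data.frame (one row per subject/period).
#' @param group_keys Character vector of grouping column names.
#' @param parameters Parameter columns to summarize; defaults to all numeric
#'   non-key columns.
#' @param comparisons Optional list of `comparison_result` objects.
#' @param digits Significant digits used in the formatted label.
#' @return A data.frame: `parameter`, the group keys, `n`, `mean`, `sd`,
#'   `label`, `significant`.
#' @export
summarize_parameters <- function(results, group_keys, parameters = NULL,
                                 comparisons = NULL, digits = 3) {
  stopifnot(is.data.frame(results), all(group_keys %in% names(results)))
  if (is.null(parameters)) {
    parameters <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                          c(group_keys, "period", "dose"))
  }
  sig_by_param <- list()
  for (cmp in comparisons %||% list())
    sig_by_param[[cmp$parameter]] <- isTRUE(cmp$significant)
  out <- list()
  groups <- unique(results[, group_keys, drop = FALSE])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  for (par in parameters) {
    for (g in seq_len(nrow(groups))) {
      sel <- rep(TRUE, nrow(results))
      for (k in group_keys) sel <- sel & results[[k]] == groups[[k]][g]
      v <- results[[par]][sel]
      v <- v[is.finite(v)]
      n <- length(v)
      m <- if (n) mean(v) else NA_real_
      s <- if (n > 1) stats::sd(v) else NA_real_
      sig <- isTRUE(sig_by_param[[par]]) && g == nrow(groups)
      label <- if (n == 0) NA_character_
      else if (is.na(s)) signif(m, digits)
      else sprintf("%s ± %s%s", signif(m, digits), signif(s, digits),
                   if (sig) "*" else "")
      row <- cbind(data.frame(parameter = par),
                   groups[g, , drop = FALSE],
                   data.frame(n = n, mean = m, sd = s, label = label,
                              significant = sig))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parameter-recovery report
#'
#' Compares estimated transport parameters against the simulator's truth
#' sidecar, matched by animal and period, and reports per-parameter bias,
#' relative bias and RMSE. This is the validation gate for the whole
#' simulate-estimate pipeline.
#'
#' @param truth Truth table (`animal`, `period`, `f_al_true`, `f_ap_true`,
#'   `f_true`, `f_rl_true`), e.g. the `truth` element of a `study_dataset`.
#' @param estimates Transport results table with columns `animal`, `period`,
#'   `f_al`, `f_ap`, `f`, `f_rl` (one row per animal-period).
#' @return A data.frame: `parameter`, `n`, `bias`, `rel_bias_pct`, `rmse`,
#'   `max_abs_error`.
#' @export
recovery_report <- function(truth, estimates) {
  stopifnot(is.data.frame(truth), is.data.frame(estimates))
  merged <- merge(truth, estimates, by = c("animal", "period"))
  if (nrow(merged) != nrow(truth) || nrow(merged) != nrow(estimates))
    stop("truth and estimates do not match one-to-one by animal and period",
         call. = FALSE)
  pars <- c("f_al", "f_ap", "f", "f_rl")
  rows <- lapply(pars, function(p) {
    est <- merged[[p]]
    tr <- merged[[paste0(p, "_true")]]
    ok <- is.finite(est) & is.finite(tr)
    err <- est[ok] - tr[ok]
    data.frame(parameter = p, n = sum(ok), bias = mean(err),
               rel_bias_pct = if (all(tr[ok] > 0))
                 100 * mean(err / tr[ok]) else NA_real_,
               rmse = sqrt(mean(err^2)),
               max_abs_error = max(abs(err)))
  })
  do.call(rbind, rows)
}
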