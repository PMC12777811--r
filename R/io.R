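# Readers and writers for the delimited study-table schemas, plus the YAML
# study configuration. All interchange is plain comma-separated text with
# dot decimals; times are hours post-dose (the dose event defines t = 0).

.required_serum_cols <- c("animal", "period", "formulation", "route",
                          "dose_mg", "time_h", "conc_ng_ml")
.required_lymph_cols <- c("animal", "period", "formulation", "t_start_h",
                          "t_end_h", "volume_ml", "conc_ng_ml")

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    hint <- ""
    if ("time_h" %in% missing && any(grepl("^time", names(df))))
      hint <- " (times must be hours post-dose in a column named 'time_h'; minute-based columns are not accepted)"
    if ("conc_ng_ml" %in% missing && any(grepl("^conc", names(df))))
      hint <- " (concentrations must be ng/ml in a column named 'conc_ng_ml')"
    stop(sprintf("%s: missing required column(s) %s%s", path,
                 paste(sQuote(missing), collapse = ", "), hint),
         call. = FALSE)
  }
}

.coerce_blq <- function(df) {
  if (!"blq" %in% names(df)) df$blq <- FALSE
  df$blq <- as.logical(df$blq)
  df
}

#' Read a serum concentration table
#'
#' Expects a comma-separated file with header columns `animal`, `period`,
#' `formulation`, `route`, `dose_mg`, `time_h`, `conc_ng_ml` and optionally
#' `blq`. Validates types, route labels, and strictly increasing sampling
#' times within each animal-period; violations are reported with the
#' offending file line number.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame.
#' @export
read_serum_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, .required_serum_cols, path)
  df <- .coerce_blq(df)
  if (!all(df$route %in% c("oral", "iv")))
    stop(sprintf("%s: 'route' must be 'oral' or 'iv' (line %d)", path,
                 which(!df$route %in% c("oral", "iv"))[1] + 1L),
         call. = FALSE)
  for (col in c("dose_mg", "time_h", "conc_ng_ml")) {
    bad <- which(!is.finite(df[[col]]) & !(col == "conc_ng_ml" & df$blq))
    if (length(bad))
      stop(sprintf("%s: non-numeric '%s' at line %d", path, col, bad[1] + 1L),
           call. = FALSE)
  }
  if (any(df$time_h < 0))
    stop(sprintf("%s: negative time at line %d", path,
                 which(df$time_h < 0)[1] + 1L), call. = FALSE)
  key <- paste(df$animal, df$period, df$route)
  for (k in unique(key)) {
    idx <- which(key == k)
    tt <- df$time_h[idx]
    if (is.unsorted(tt, strictly = TRUE)) {
      j <- idx[which(diff(tt) <= 0)[1] + 1L]
      stop(sprintf("%s: sampling times not strictly increasing for %s at line %d",
                   path, k, j + 1L), call. = FALSE)
    }
  }
  df
}

#' Read a lymph collection table
#'
#' Expects columns `animal`, `period`, `formulation`, `t_start_h`,
#' `t_end_h`, `volume_ml`, `conc_ng_ml` and optionally `blq`. Intervals
#' within each animal-period must be valid (`t_start < t_end`) and
#' non-overlapping; an overlap error names both offending file lines.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame.
#' @export
read_lymph_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, .required_lymph_cols, path)
  df <- .coerce_blq(df)
  for (col in c("t_start_h", "t_end_h", "volume_ml", "conc_ng_ml")) {
    bad <- which(!is.finite(df[[col]]) & !(col == "conc_ng_ml" & df$blq))
    if (length(bad))
      stop(sprintf("%s: non-numeric '%s' at line %d", path, col, bad[1] + 1L),
           call. = FALSE)
  }
  bad <- which(df$t_start_h < 0 | df$t_end_h <= df$t_start_h)
  if (length(bad))
    stop(sprintf("%s: invalid interval (need 0 <= t_start_h < t_end_h) at line %d",
                 path, bad[1] + 1L), call. = FALSE)
  key <- paste(df$animal, df$period)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(df$t_start_h[idx])]
    if (length(idx) > 1L) {
      starts <- df$t_start_h[idx]; ends <- df$t_end_h[idx]
      ov <- which(starts[-1] < ends[-length(ends)] - 1e-9)
      if (length(ov))
        stop(sprintf("%s: overlapping lymph intervals for %s at lines %d and %d",
                     path, k, idx[ov[1]] + 1L, idx[ov[1] + 1L] + 1L),
             call. = FALSE)
    }
  }
  df
}

#' Read a transport truth sidecar table
#'
#' @param path Path to the CSV file with columns `animal`, `period`,
#'   `formulation`, `f_al_true`, `f_ap_true`, `f_true`, `f_rl_true`.
#' @return A validated data.frame.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("animal", "period", "f_al_true", "f_ap_true",
                       "f_true", "f_rl_true"), path)
  df
}

#' Write a study dataset to delimited text tables
#'
#' Writes `serum.csv`, `lymph.csv` and the `truth.csv` sidecar into a
#' directory; the files round-trip through [read_study_dataset()].
#'
#' @param dataset A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(serum = file.path(dir, "serum.csv"),
             lymph = file.path(dir, "lymph.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(dataset$serum, paths[["serum"]], row.names = FALSE)
  if (!is.null(dataset$lymph))
    utils::write.csv(dataset$lymph, paths[["lymph"]], row.names = FALSE)
  if (!is.null(dataset$truth))
    utils::write.csv(dataset$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read a study dataset back from a directory of tables
#'
#' @param dir Directory containing `serum.csv` and optionally `lymph.csv`
#'   and `truth.csv`.
#' @return A `study_dataset`.
#' @export
read_study_dataset <- function(dir) {
  serum <- read_serum_table(file.path(dir, "serum.csv"))
  lymph_path <- file.path(dir, "lymph.csv")
  truth_path <- file.path(dir, "truth.csv")
  structure(list(serum = serum,
                 lymph = if (file.exists(lymph_path))
                   read_lymph_table(lymph_path) else NULL,
                 truth = if (file.exists(truth_path))
                   read_truth_table(truth_path) else NULL),
            class = "study_dataset")
}

#' Write named result tables to a directory
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

.config_defaults <- function() {
  list(n_animals = 3L,
       doses = list(oil_solution = 200, nanoemulsion = 200),
       iv_dose = 20, lloq = 1, truncation_time = 8,
       residual_cv = 0.15, iiv_cv = 0.3,
       mean_flow = 70, cv_flow = 0.25,
       seed = 1L, output_dir = "results",
       unpaired_var_equal = TRUE)
}

#' Read and validate a YAML study configuration
#'
#' Known keys (all optional, defaults in parentheses): `n_animals` (3),
#' `doses` (200 mg per formulation), `iv_dose` (20 mg), `lloq` (1 ng/ml),
#' `truncation_time` (8 h), `residual_cv` (0.15), `iiv_cv` (0.3),
#' `mean_flow` (70 ml/h), `cv_flow` (0.25), `seed` (1), `output_dir`
#' (`"results"`), `unpaired_var_equal` (`TRUE`). Unknown keys are rejected
#' by name.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A named list of class `study_config`.
#' @export
read_study_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop(sprintf("unknown configuration key(s): %s",
                   paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
    cfg[names(user)] <- user
  }
  if (cfg$lloq <= 0) stop("'lloq' must be positive", call. = FALSE)
  if (!is.null(cfg$truncation_time) && cfg$truncation_time <= 0)
    stop("'truncation_time' must be positive or null", call. = FALSE)
  structure(cfg, class = "study_config")
}
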