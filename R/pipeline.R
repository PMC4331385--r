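# Curve I/O, configuration and the end-to-end analysis pipeline.

.curve_cols <- c("time_s", "value", "region", "subject", "state")

#' Read perfusion curves from CSV
#'
#' Expects the dialect `time_s, value, region, subject, state` with a header
#' (state is `stress` or `rest`; region `aif`, `aif_pre` or a segment label).
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data frame of class `curve_table`.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.curve_cols, names(df))
  if (length(missing_cols))
    stop("curve file missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))) |
                 !is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad))
    stop("non-numeric time_s/value at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df$time_s <- as.numeric(df$time_s)
  df$value <- as.numeric(df$value)
  if (!all(df$state %in% c("stress", "rest")))
    stop("'state' must be 'stress' or 'rest'")
  class(df) <- c("curve_table", class(df))
  df
}

#' Write perfusion curves to CSV
#' @param df a curve table (columns `time_s, value, region, subject, state`)
#'   or a list of curves plus metadata.
#' @param path output CSV path.
#' @export
write_curves <- function(df, path) {
  missing_cols <- setdiff(.curve_cols, names(df))
  if (length(missing_cols))
    stop("curve table missing column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(df[, .curve_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten a synthetic cohort to a curve table
#' @param cohort a `perfusion_cohort` from [generate_cohort()].
#' @return data frame in the curve-CSV dialect (tissue curves plus one `aif`
#'   row group per subject-state).
#' @export
cohort_to_table <- function(cohort) {
  rows <- list()
  for (key in names(cohort$aifs)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    a <- cohort$aifs[[key]]
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = a$times, value = a$values, region = "aif",
      subject = as.integer(parts[1]), state = parts[2],
      stringsAsFactors = FALSE)
  }
  for (tc in cohort$tissue) {
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = tc$times, value = tc$values, region = tc$region,
      subject = attr(tc, "subject"), state = attr(tc, "state"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write an analysis report as JSON
#'
#' Serialises with unboxed scalars at 6 significant digits and a versioned
#' schema tag.
#'
#' @param path output path.
#' @param results named list.
#' @export
write_results <- function(path, results) {
  results$schema_version <- "1.0"
  results$package_version <- as.character(utils::packageVersion("cmrflow"))
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a pipeline configuration (YAML or JSON)
#' @param path file path ending in .yaml/.yml or .json.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
}

.table_curve <- function(df, region, subject, state, constructor) {
  sel <- df$region == region & df$subject == subject & df$state == state
  if (!any(sel)) return(NULL)
  sub <- df[sel, ]
  sub <- sub[order(sub$time_s), ]
  constructor(sub$time_s, sub$value, region = region)
}

#' Run the full quantification pipeline over a curve table
#'
#' Chains the analysis stages per subject and state: calibrate the scanner
#' constant from pre-contrast baseline frames, convert signal to
#' concentration, scale and align the pre-bolus AIF when `bolus = "dual"`,
#' truncate at the first-pass endpoint, fit the chosen model per segment,
#' aggregate to coronary territories, classify reduced flow and compute
#' summary statistics. Per-segment failures are recorded and do not abort the
#' remaining segments.
#'
#' @param curves a `curve_table` (from [read_curves()] or
#'   [cohort_to_table()]) of *signal* curves, or a path to such a CSV.
#' @param model `"fermi"` or `"dp"`.
#' @param bolus `"single"` uses the `aif` region; `"dual"` scales the
#'   `aif_pre` region onto the main bolus.
#' @param acq an [acquisition_params()] object.
#' @param native_t1 named list with `aif` and `tissue` native T1 (seconds).
#' @param config a [fit_config()].
#' @param threshold reduced-flow threshold, mL/min/mL.
#' @param mapping territory mapping (default [aha16_territories()]).
#' @param dose_ratio main:pre dose ratio for dual-bolus scaling.
#' @param n_baseline pre-contrast frames for calibration.
#' @param out optional path; when given the JSON report is written there.
#' @return report list (invisibly also written to `out`): `records`
#'   (per-segment fits), `territories`, `classification`, `stats`,
#'   `non_convergent`.
#' @export
run_pipeline <- function(curves, model = c("dp", "fermi"),
                         bolus = c("single", "dual"),
                         acq = acquisition_params(),
                         native_t1 = list(aif = 1.7, tissue = 1.2),
                         config = fit_config(), threshold = 2.5,
                         mapping = aha16_territories(), dose_ratio = 5,
                         n_baseline = 5L, out = NULL) {
  model <- match.arg(model)
  bolus <- match.arg(bolus)
  if (is.character(curves)) curves <- read_curves(curves)

  seg_regions <- sort(setdiff(unique(curves$region), c("aif", "aif_pre")))
  records <- list()
  failures <- list()
  for (subj in sort(unique(curves$subject))) {
    for (st in intersect(c("stress", "rest"), unique(curves$state[curves$subject == subj]))) {
      aif_sig <- .table_curve(curves, "aif", subj, st, signal_curve)
      if (is.null(aif_sig)) next
      cal_a <- calibrate_psi(aif_sig, native_t1$aif, acq, n_baseline)
      aif <- concentration_from_signal(aif_sig, cal_a, acq)
      if (bolus == "dual") {
        pre_sig <- .table_curve(curves, "aif_pre", subj, st, signal_curve)
        if (is.null(pre_sig))
          stop("dual-bolus analysis requested but region 'aif_pre' is absent")
        cal_p <- calibrate_psi(pre_sig, native_t1$aif, acq, n_baseline)
        pre <- concentration_from_signal(pre_sig, cal_p, acq)
        aif <- scale_prebolus_aif(pre, aif, dose_ratio)
      }
      for (reg in seg_regions) {
        tis_sig <- .table_curve(curves, reg, subj, st, signal_curve)
        if (is.null(tis_sig)) next
        seg_idx <- suppressWarnings(as.integer(gsub("\\D", "", reg)))
        res <- tryCatch({
          cal_t <- calibrate_psi(tis_sig, native_t1$tissue, acq, n_baseline)
          tis <- concentration_from_signal(tis_sig, cal_t, acq)
          fit <- mbf_fit(aif, tis, model = model, config = config)
          data.frame(subject = subj, segment = seg_idx, state = st,
                     model = model, bolus = bolus,
                     mbf = unname(coef(fit)["mbf"]), sse = fit$sse,
                     converged = fit$converged,
                     saturation_fraction = fit$saturation_fraction,
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(subject = subj, segment = seg_idx, state = st,
                     model = model, bolus = bolus, mbf = NA_real_,
                     sse = NA_real_, converged = FALSE,
                     saturation_fraction = NA_real_,
                     stringsAsFactors = FALSE)
        })
        records[[length(records) + 1L]] <- res
      }
    }
  }
  records <- do.call(rbind, records)
  if (is.null(records) || !nrow(records)) stop("no fittable curves found")

  terr <- territory_summary(records, mapping)
  terr$reduced_flow <- classify_reduced_flow(terr$mean_stress, threshold)

  stats_block <- list()
  st_mbf <- records$mbf[records$converged & records$state == "stress"]
  re_mbf <- records$mbf[records$converged & records$state == "rest"]
  if (length(st_mbf) > 1 && length(re_mbf) > 1)
    stats_block$stress_vs_rest <- welch_t(st_mbf, re_mbf)[c("test", "statistic", "p_value")]

  report <- list(
    model = model, bolus = bolus, threshold = threshold,
    n_segments_fitted = nrow(records),
    non_convergent = sum(!records$converged),
    records = records,
    territories = terr,
    classification = list(
      n_reduced = sum(terr$reduced_flow, na.rm = TRUE),
      territories_reduced = terr$territory[which(terr$reduced_flow)]),
    stats = stats_block)
  if (!is.null(out)) write_results(out, report)
  invisible(report)
}
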