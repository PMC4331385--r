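# Territory aggregation, reduced-flow classification at the 2.5 mL/min/mL
# threshold, perfusion reserve, and the comparison statistics.

#' Default AHA 16-segment to coronary-territory mapping
#'
#' Standard assignment of the 16-segment left-ventricular model to the three
#' main coronary arteries.
#'
#' @return named list with integer segment vectors for `LAD`, `LCX`, `RCA`.
#' @export
aha16_territories <- function() {
  list(LAD = c(1L, 2L, 7L, 8L, 13L, 14L),
       LCX = c(5L, 6L, 11L, 12L, 16L),
       RCA = c(3L, 4L, 9L, 10L, 15L))
}

#' Aggregate segment-level fits to vessel territories
#'
#' Averages converged segment MBF values per coronary territory and state.
#' Territories with no converged member segments are dropped with a warning.
#'
#' @param records data frame with columns `subject`, `segment`, `state`,
#'   `mbf`, `converged` (and optionally `model`, `bolus`).
#' @param mapping named list of segment indices per territory
#'   (default [aha16_territories()]).
#' @return data frame with one row per subject x territory: `mean_stress`,
#'   `sd_stress`, `mean_rest`, `sd_rest`, `n_stress`, `n_rest`, `mpr`
#'   (ratio of the means, NA when rest is absent).
#' @export
territory_summary <- function(records, mapping = aha16_territories()) {
  needed <- c("subject", "segment", "state", "mbf", "converged")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  recs <- records[records$converged, , drop = FALSE]
  out <- list()
  for (subj in unique(recs$subject)) {
    for (terr in names(mapping)) {
      segs <- mapping[[terr]]
      sel <- recs$subject == subj & recs$segment %in% segs
      st <- recs[sel & recs$state == "stress", "mbf"]
      re <- recs[sel & recs$state == "rest", "mbf"]
      if (!length(st) && !length(re)) {
        warning(sprintf("territory %s of subject %s has no converged segments; excluded",
                        terr, subj))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, territory = terr,
        mean_stress = if (length(st)) mean(st) else NA_real_,
        sd_stress = if (length(st) > 1) stats::sd(st) else if (length(st)) 0 else NA_real_,
        n_stress = length(st),
        mean_rest = if (length(re)) mean(re) else NA_real_,
        sd_rest = if (length(re) > 1) stats::sd(re) else if (length(re)) 0 else NA_real_,
        n_rest = length(re),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$mpr <- ifelse(!is.na(res$mean_rest) & res$mean_rest > 0,
                    res$mean_stress / res$mean_rest, NA_real_)
  res
}

#' Classify a territory as having reduced hyperaemic flow
#'
#' A vessel territory with mean stress MBF strictly below the threshold
#' (default 2.5 mL/min/mL of tissue) is considered a region of reduced
#' myocardial blood flow.
#'
#' @param mean_stress_mbf mean stress MBF, mL/min/mL (vectorised).
#' @param threshold decision threshold, mL/min/mL (default 2.5).
#' @return logical; `TRUE` means reduced flow. Strict `<`: exactly 2.5 is
#'   not reduced.
#' @export
classify_reduced_flow <- function(mean_stress_mbf, threshold = 2.5) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  mean_stress_mbf < threshold
}

#' Myocardial perfusion reserve
#' @param stress_mbf,rest_mbf MBF at stress and rest, mL/min/mL (vectorised).
#' @return stress/rest ratio.
#' @export
mpr <- function(stress_mbf, rest_mbf) {
  if (any(rest_mbf <= 0)) stop("'rest_mbf' must be > 0")
  stress_mbf / rest_mbf
}

#' Load the packaged patient vessel-territory table
#'
#' Per-territory mean (SD) stress MBF and perfusion-reserve values for the
#' five-patient coronary-artery-disease cohort, with the angiography/FFR
#' group of each vessel (1 = no/minor disease, 2 = non-obstructive,
#' 3 = obstructive). One row per patient x vessel (15 rows).
#'
#' @return data frame with columns `patient`, `vessel`, `group`,
#'   `dp_mbf_stress`, `dp_sd_stress`, `fermi_mbf_stress`, `fermi_sd_stress`,
#'   `dp_mpr`, `fermi_mpr`.
#' @export
load_table4 <- function() {
  path <- system.file("extdata", "table4.csv", package = "cmrflow")
  if (path == "") path <- file.path("inst", "extdata", "table4.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 15)
  df
}

#' Count reduced-flow detections per model and angiography group
#'
#' Applies [classify_reduced_flow()] to the per-vessel stress MBF means of
#' both models and tallies flagged vessels in Group 2 (non-obstructive),
#' Group 3 (obstructive) and their union (all stenotic vessels).
#'
#' @param territories data frame in the [load_table4()] layout (columns
#'   `group`, `dp_mbf_stress`, `fermi_mbf_stress`).
#' @param threshold decision threshold, mL/min/mL.
#' @return nested list: `$dp` and `$fermi`, each with `group1`, `group2`,
#'   `group3`, `stenotic` counts, plus `$n_group1/2/3` group sizes.
#' @export
detection_counts <- function(territories, threshold = 2.5) {
  g <- territories$group
  res <- lapply(c(dp = "dp_mbf_stress", fermi = "fermi_mbf_stress"),
                function(col) {
    flag <- classify_reduced_flow(territories[[col]], threshold)
    list(group1 = sum(flag[g == 1]),
         group2 = sum(flag[g == 2]),
         group3 = sum(flag[g == 3]),
         stenotic = sum(flag[g %in% c(2, 3)]))
  })
  res$n_group1 <- sum(g == 1)
  res$n_group2 <- sum(g == 2)
  res$n_group3 <- sum(g == 3)
  res
}

# ---- statistics --------------------------------------------------------

.stats_report <- function(test, statistic, p_value, ...) {
  structure(c(list(test = test, statistic = unname(statistic),
                   p_value = unname(p_value)), list(...)),
            class = "mbf_stats")
}

#' @export
print.mbf_stats <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  extra <- setdiff(names(x), c("test", "statistic", "p_value"))
  for (nm in extra) {
    v <- x[[nm]]
    if (is.numeric(v)) cat(sprintf("  %s: %s\n", nm,
                                   paste(signif(v, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Paired, Welch, variance-ratio and one-sample tests
#'
#' Thin wrappers around [stats::t.test()] / [stats::var.test()] returning a
#' uniform report structure (two-sided throughout).
#'
#' @param a,b numeric vectors (paired and equal length for `paired_t`).
#' @param mu0 null mean for `one_sample_t`.
#' @return object of class `mbf_stats` with `test`, `statistic`, `p_value`,
#'   `df`, `estimate`.
#' @name hypothesis_tests
NULL

#' @rdname hypothesis_tests
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  if (length(a) < 2) stop("need n >= 2")
  if (stats::sd(a - b) == 0 && all(a == b))
    return(.stats_report("paired t-test", 0, 1, df = length(a) - 1,
                         estimate = 0))
  tt <- stats::t.test(a, b, paired = TRUE)
  .stats_report("paired t-test", tt$statistic, tt$p.value,
                df = unname(tt$parameter), estimate = unname(tt$estimate))
}

#' @rdname hypothesis_tests
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each group")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  .stats_report("Welch two-sample t-test", tt$statistic, tt$p.value,
                df = unname(tt$parameter),
                estimate = unname(tt$estimate[1] - tt$estimate[2]))
}

#' @rdname hypothesis_tests
#' @export
f_variance <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each group")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: F statistic undefined")
  ft <- stats::var.test(a, b)
  .stats_report("F test of variances", ft$statistic, ft$p.value,
                df = unname(ft$parameter), estimate = unname(ft$estimate))
}

#' @rdname hypothesis_tests
#' @export
one_sample_t <- function(a, mu0) {
  if (length(a) < 2) stop("need n >= 2")
  if (stats::sd(a) == 0) stop("zero variance: t statistic undefined")
  tt <- stats::t.test(a, mu = mu0)
  .stats_report("one-sample t-test", tt$statistic, tt$p.value,
                df = unname(tt$parameter), estimate = unname(tt$estimate))
}

#' Bland–Altman agreement analysis
#'
#' Bias is `mean(a - b)`; 95% limits of agreement are bias +/- 1.96 SD of the
#' differences; the confidence interval of the bias uses the t distribution.
#'
#' @param a,b paired measurement vectors of equal length (n >= 2).
#' @return object of class `mbf_stats` with `bias`, `loa` (lower, upper),
#'   `bias_ci` (lower, upper), `sd_diff`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  n <- length(a)
  if (n < 2) stop("need n >= 2")
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sd_d
  ci <- bias + c(-1, 1) * stats::qt(0.975, n - 1) * sd_d / sqrt(n)
  .stats_report("Bland-Altman", bias, NA_real_, bias = bias, sd_diff = sd_d,
                loa = loa, bias_ci = ci, n = n)
}
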