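#' @title Agreement statistics and device grading
#' @description Bland-Altman comparison of invasive reference and estimated
#'   central pressures, cumulative error-distribution bins, and pass/fail
#'   grading against the ARTERY (2017), AAMI/ISO 81060-2 (2013),
#'   AAMI/ESH/ISO (2018) and BHS protocols. The difference sign convention
#'   throughout is invasive minus estimated.
#' @name agreement-grading
NULL

#' Build a paired-measurement table
#'
#' One row per patient with invasive and estimated central SBP/MAP/DBP.
#'
#' @param patient_id Character vector.
#' @param invasive,estimated Matrices or data.frames with columns `sbp`,
#'   `map`, `dbp` (mmHg).
#' @param site Optional site labels.
#' @param included Logical; defaults to all TRUE.
#' @param exclusion_reason Character; defaults to `""`.
#' @return Data.frame of class `paired_measurements` with columns
#'   `patient_id`, `site`, `included`, `exclusion_reason`, `inv_sbp`,
#'   `inv_map`, `inv_dbp`, `est_sbp`, `est_map`, `est_dbp`.
#' @export
paired_measurements <- function(patient_id, invasive, estimated,
                                site = "synthetic",
                                included = TRUE, exclusion_reason = "") {
  invasive <- as.data.frame(invasive)
  estimated <- as.data.frame(estimated)
  stopifnot(all(c("sbp", "map", "dbp") %in% names(invasive)),
            all(c("sbp", "map", "dbp") %in% names(estimated)))
  if (anyDuplicated(patient_id))
    stop("duplicate patient ids", call. = FALSE)
  out <- data.frame(patient_id = as.character(patient_id), site = site,
                    included = included,
                    exclusion_reason = exclusion_reason,
                    inv_sbp = invasive$sbp, inv_map = invasive$map,
                    inv_dbp = invasive$dbp,
                    est_sbp = estimated$sbp, est_map = estimated$map,
                    est_dbp = estimated$dbp)
  bad <- out$included &
    !(is.finite(out$inv_sbp) & is.finite(out$est_sbp) &
        out$inv_sbp > 0 & out$est_sbp > 0)
  if (any(bad))
    stop("included pairs must have positive, finite pressures", call. = FALSE)
  class(out) <- c("paired_measurements", "data.frame")
  out
}

#' Cumulative error-distribution bins
#'
#' Counts and percentages of absolute errors strictly below 5, 10 and
#' 15 mmHg (cumulative). Percentages are reported rounded to one decimal;
#' the unrounded values are retained for grading.
#'
#' @param diffs Numeric vector of errors (mmHg).
#' @param limits Bin limits (default `c(5, 10, 15)`).
#' @return Data.frame `limit`, `count`, `pct` (unrounded), `pct_rounded`.
#' @export
error_bins <- function(diffs, limits = c(5, 10, 15)) {
  n <- length(diffs)
  if (n < 1L) stop("need at least one error value", call. = FALSE)
  counts <- vapply(limits, function(L) sum(abs(diffs) < L), integer(1))
  pct <- 100 * counts / n
  data.frame(limit = limits, count = counts, pct = pct,
             pct_rounded = round(pct, 1))
}

#' Bland-Altman agreement for one pressure component
#'
#' Differences are invasive minus estimated. Reports mean difference, sample
#' SD (n-1), 95% limits of agreement (mean +/- 1.96 SD), Pearson r and r^2
#' of estimated vs invasive, the least-squares trend line of estimated on
#' invasive, the trend of difference on pair mean (the sloped line drawn on
#' Bland-Altman plots), and the cumulative error bins.
#'
#' @param pairs A `paired_measurements` table (only `included` rows are
#'   used).
#' @param component `"SBP"`, `"MAP"` or `"DBP"`.
#' @return An `agreement_result` list.
#' @export
bland_altman <- function(pairs, component = c("SBP", "MAP", "DBP")) {
  component <- match.arg(component)
  suff <- tolower(component)
  p <- pairs[pairs$included, , drop = FALSE]
  n <- nrow(p)
  if (n < 2L) stop("need at least 2 included pairs", call. = FALSE)
  inv <- p[[paste0("inv_", suff)]]
  est <- p[[paste0("est_", suff)]]
  d <- inv - est
  m <- mean(d); s <- stats::sd(d)
  degenerate <- stats::sd(inv) == 0 || stats::sd(est) == 0
  r <- if (degenerate) NA_real_ else stats::cor(inv, est)
  tr <- if (degenerate) c(NA_real_, NA_real_) else
    stats::coef(stats::lm(est ~ inv))
  ba_tr <- if (degenerate) c(NA_real_, NA_real_) else
    stats::coef(stats::lm(d ~ I((inv + est) / 2)))
  structure(list(
    component = component, n = n,
    mean_diff = m, sd_diff = s,
    loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
    r = r, r_squared = r^2,
    intercept = unname(tr[1]), slope = unname(tr[2]),
    ba_intercept = unname(ba_tr[1]), ba_slope = unname(ba_tr[2]),
    r_degenerate = degenerate,
    bins = error_bins(d)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s, n = %d\n", x$component, x$n))
  cat(sprintf("  mean diff %.2f mmHg, SD %.2f, LoA [%.2f, %.2f]\n",
              x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  if (!x$r_degenerate)
    cat(sprintf("  r = %.3f (r^2 = %.3f); trend est = %.2f + %.3f * inv\n",
                x$r, x$r_squared, x$intercept, x$slope))
  cat(sprintf("  |err| < 5/10/15 mmHg: %.1f%% / %.1f%% / %.1f%%\n",
              x$bins$pct_rounded[1], x$bins$pct_rounded[2],
              x$bins$pct_rounded[3]))
  invisible(x)
}

#' Probability of a tolerable error (2018 AAMI/ESH/ISO)
#'
#' Normal-model estimate of the probability that the device error lies
#' within `limit` mmHg: `100 * (Phi((limit - mean)/sd) -
#' Phi((-limit - mean)/sd))`. A zero SD is treated as a point mass.
#'
#' @param mean_diff,sd_diff Mean and SD of the differences, mmHg.
#' @param limit Tolerable-error limit, mmHg (default 10).
#' @return Probability in percent.
#' @export
iso2018_probability <- function(mean_diff, sd_diff, limit = 10) {
  if (sd_diff < 0) stop("sd_diff must be >= 0", call. = FALSE)
  if (sd_diff == 0) return(if (abs(mean_diff) <= limit) 100 else 0)
  100 * (stats::pnorm((limit - mean_diff) / sd_diff) -
           stats::pnorm((-limit - mean_diff) / sd_diff))
}

# BHS cumulative thresholds: percent of errors within 5/10/15 mmHg
.bhs_thresholds <- list(A = c(60, 85, 95), B = c(50, 75, 90),
                        C = c(40, 65, 85))

bhs_grade_from_pcts <- function(pcts) {
  for (g in names(.bhs_thresholds))
    if (all(pcts >= .bhs_thresholds[[g]])) return(g)
  "D"
}

#' Grade one pressure component against the validation protocols
#'
#' ARTERY 2017: mean difference strictly below 5 mmHg in magnitude and SD
#' strictly below 8 mmHg. AAMI 2013: the same limits, inclusively.
#' AAMI/ESH/ISO 2018: estimated probability of an error within 10 mmHg of
#' at least 85% (normal model; the empirical fraction is reported
#' alongside). BHS: cumulative bins against grade A/B/C thresholds
#' (60/85/95, 50/75/90, 40/65/85), graded on unrounded percentages, with
#' the grade from one-decimal rounded percentages reported too and a flag
#' when they disagree.
#'
#' @param result An `agreement_result`.
#' @return A `grading_result` list.
#' @export
grade_component <- function(result) {
  stopifnot(inherits(result, "agreement_result"))
  m <- result$mean_diff; s <- result$sd_diff
  prob <- iso2018_probability(m, s)
  pcts <- result$bins$pct
  g_unrounded <- bhs_grade_from_pcts(pcts)
  g_rounded <- bhs_grade_from_pcts(result$bins$pct_rounded)
  structure(list(
    component = result$component,
    artery_pass = abs(m) < 5 && s < 8,
    aami2013_pass = abs(m) <= 5 && s <= 8,
    iso2018_prob = prob,
    iso2018_empirical = result$bins$pct[result$bins$limit == 10],
    iso2018_pass = prob >= 85,
    bhs_grade = g_unrounded,
    bhs_grade_rounded = g_rounded,
    bhs_rounding_disagreement = g_unrounded != g_rounded
  ), class = "grading_result")
}

#' @export
print.grading_result <- function(x, ...) {
  cat(sprintf(
    "<grading_result> %s: ARTERY %s | AAMI2013 %s | ISO2018 %.1f%% (%s) | BHS %s\n",
    x$component,
    if (x$artery_pass) "pass" else "FAIL",
    if (x$aami2013_pass) "pass" else "FAIL",
    x$iso2018_prob, if (x$iso2018_pass) "pass" else "FAIL",
    x$bhs_grade))
  invisible(x)
}

#' Grade all components of a device comparison
#'
#' @param results List of `agreement_result` objects (one per component).
#' @return List of `grading_result` objects named by component, plus
#'   `overall`: list of per-protocol all-component pass flags (BHS pass
#'   means grade A).
#' @export
grade_device <- function(results) {
  g <- lapply(results, grade_component)
  names(g) <- vapply(g, `[[`, "", "component")
  g$overall <- list(
    artery_pass = all(vapply(g, `[[`, NA, "artery_pass")),
    aami2013_pass = all(vapply(g, `[[`, NA, "aami2013_pass")),
    iso2018_pass = all(vapply(g, `[[`, NA, "iso2018_pass")),
    bhs_all_grade_a = all(vapply(g, `[[`, "", "bhs_grade") == "A")
  )
  g
}

#' Reference-pressure range conformity
#'
#' Distribution of the invasive reference pressures over the ranges the
#' ARTERY consensus recommends for sample composition. The four rows
#' partition the sample: for systolic, at 100, 140 and 160 mmHg; for
#' diastolic, at 60, 85 and 100 mmHg (boundaries inclusive on the outer
#' rows, matching the `<=` / `>=` labels). Recommended shares (5%, -, 20%,
#' 5%) are attached, along with the recruitment ratio against the
#' 85-patient recommendation.
#'
#' @param values Numeric vector of invasive pressures, mmHg.
#' @param component `"SBP"` or `"DBP"`.
#' @return List `table` (data.frame `range`, `count`, `pct`, `goal_pct`),
#'   `n`, `recruitment_ratio_pct` (whole percent of the 85-patient goal).
#' @export
range_conformity <- function(values, component = c("SBP", "DBP")) {
  component <- match.arg(component)
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  cuts <- if (component == "SBP") c(100, 140, 160) else c(60, 85, 100)
  counts <- c(sum(values <= cuts[1]),
              sum(values > cuts[1] & values < cuts[2]),
              sum(values >= cuts[2] & values < cuts[3]),
              sum(values >= cuts[3]))
  labels <- c(sprintf("<=%g", cuts[1]),
              sprintf(">%g <%g", cuts[1], cuts[2]),
              sprintf(">=%g", cuts[2]),
              sprintf(">=%g", cuts[3]))
  list(table = data.frame(range = labels, count = counts,
                          pct = round(100 * counts / n, 1),
                          goal_pct = c(5, NA, 20, 5)),
       n = n,
       recruitment_ratio_pct = round(100 * n / 85))
}
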