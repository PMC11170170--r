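#' Validate staining records
#'
#' A staining record carries the per-sample distribution of tumor-cell staining
#' intensity (percent of tumor cells at 0, 1+, 2+ and 3+, columns `pct0`,
#' `pct1`, `pct2`, `pct3`) plus covariates. The four percentages must be
#' non-negative and sum to 100 within +/- 0.5; archival time must be
#' non-negative.
#'
#' @param records Data frame in the `ihc.csv` schema: `sample_id`,
#'   `patient_id`, `tumor_type`, `histology`, `tissue_location`, `patient_age`,
#'   `archival_years`, `pct0`, `pct1`, `pct2`, `pct3`.
#' @return `records`, invisibly, after validation.
#' @export
validate_staining <- function(records) {
  need <- c("sample_id", "patient_id", "pct0", "pct1", "pct2", "pct3")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("staining records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pct <- as.matrix(records[, c("pct0", "pct1", "pct2", "pct3")])
  if (any(is.na(pct)) || any(pct < 0))
    stop("staining percentages must be non-negative and non-missing",
         call. = FALSE)
  tot <- rowSums(pct)
  bad <- which(abs(tot - 100) > 0.5)
  if (length(bad) > 0L)
    stop("staining percentages must sum to 100 (+/- 0.5); offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if ("archival_years" %in% names(records) &&
      any(!is.na(records$archival_years) & records$archival_years < 0))
    stop("archival_years must be non-negative", call. = FALSE)
  invisible(records)
}

#' MAGE-A4 P score
#'
#' The P score is the percentage of tumor cells staining at intensity 2+ or
#' 3+; it is by construction invariant to how the remaining cells split
#' between 0 and 1+.
#'
#' @param records Validated staining records (data frame).
#' @return Numeric vector of P scores in `[0, 100]`, one per record.
#' @examples
#' p_score(data.frame(sample_id = "s", patient_id = "p",
#'                    pct0 = 0, pct1 = 3, pct2 = 60, pct3 = 37))  # 97
#' @export
p_score <- function(records) {
  validate_staining(records)
  records$pct2 + records$pct3
}

#' Positivity cutoffs
#'
#' The clinical-trial positivity rule is a P score of at least 30% at
#' intensity >= 2+. The original pre-amendment rule (>= 10% of cells at
#' >= 1+) ships as the `"legacy_1plus_10"` preset.
#'
#' @param min_pscore Minimum percent of cells at or above `min_intensity`.
#' @param min_intensity Minimum intensity rank counted into the score (ordinal
#'   0-3; the default 2 encodes ">= 2+").
#' @return An object of class `positivity_cutoff`.
#' @export
positivity_cutoff <- function(min_pscore = 30, min_intensity = 2) {
  stopifnot(min_pscore >= 0, min_pscore <= 100, min_intensity %in% 0:3)
  structure(list(min_pscore = min_pscore, min_intensity = min_intensity),
            class = "positivity_cutoff")
}

#' @rdname positivity_cutoff
#' @export
legacy_cutoff <- function() positivity_cutoff(min_pscore = 10, min_intensity = 1)

#' MAGE-A4 positivity call
#'
#' A sample is positive when the percentage of tumor cells at or above the
#' cutoff intensity meets the cutoff percentage (inclusive boundary: a P score
#' of exactly 30 is positive under the default rule).
#'
#' @param records Validated staining records.
#' @param cutoff A `positivity_cutoff` (default: the clinical rule, P score
#'   >= 30 at >= 2+).
#' @return Logical vector, one call per record.
#' @export
is_positive <- function(records, cutoff = positivity_cutoff()) {
  validate_staining(records)
  stopifnot(inherits(cutoff, "positivity_cutoff"))
  cols <- paste0("pct", seq(cutoff$min_intensity, 3L))
  score <- rowSums(as.matrix(records[, cols, drop = FALSE]))
  score >= cutoff$min_pscore
}

# Collapse records to one row per patient (optionally within extra keys):
# patient P score = maximum over the patient's samples, so any qualifying
# sample makes the patient positive.
.collapse_patients <- function(records, extra_keys = character()) {
  score <- p_score(records)
  key <- do.call(paste, c(lapply(c("patient_id", extra_keys),
                                 function(k) as.character(records[[k]])),
                          sep = "\r"))
  agg <- tapply(score, key, max)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  mx <- as.numeric(agg[key[first]])
  # rewrite the intensity columns so p_score(out) equals the patient maximum
  out$pct3 <- 0
  out$pct2 <- mx
  out$pct1 <- 0
  out$pct0 <- 100 - mx
  out
}

#' Positivity prevalence by a grouping covariate
#'
#' Per level of `key`: number evaluated, number positive, positivity rate
#' (full precision and display-rounded integer percent, half-up) and the
#' median P score. By default patients are the unit of analysis: a patient is
#' positive if any of their samples is, and the patient's P score is the
#' maximum over samples. Use `unit = "sample"` to count samples instead.
#'
#' @param records Validated staining records.
#' @param key Name of the grouping column (e.g. `"tumor_type"`).
#' @param cutoff A `positivity_cutoff`.
#' @param unit `"patient"` (default) or `"sample"`.
#' @return Data frame with columns `group`, `n`, `positive`, `rate`,
#'   `rate_pct`, `median_pscore`.
#' @export
prevalence_by <- function(records, key, cutoff = positivity_cutoff(),
                          unit = c("patient", "sample")) {
  unit <- match.arg(unit)
  validate_staining(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (!key %in% names(records))
    stop("records lack grouping column '", key, "'", call. = FALSE)
  if (unit == "patient") records <- .collapse_patients(records, extra_keys = key)
  grp <- as.character(records[[key]])
  grp[is.na(grp) | !nzchar(grp)] <- "Not recorded"
  score <- p_score(records)
  pos <- is_positive(records, cutoff)
  levels <- sort(unique(grp))
  out <- data.frame(
    group = levels,
    n = vapply(levels, function(g) sum(grp == g), 0L),
    positive = vapply(levels, function(g) sum(pos[grp == g]), 0L),
    stringsAsFactors = FALSE
  )
  out$rate <- out$positive / out$n
  out$rate_pct <- round_half_up(100 * out$rate, 0)
  out$median_pscore <- vapply(levels, function(g) stats::median(score[grp == g]), 0)
  rownames(out) <- NULL
  out
}

#' Primary/metastatic positivity agreement
#'
#' For patients with samples from both a primary and a metastatic site,
#' compares the per-location positivity calls (per-location maximum P score
#' when a location has several samples) and reports how many patients carry
#' the same MAGE-A4 diagnosis at both locations.
#'
#' @param records Validated staining records with a `tissue_location` column
#'   coded `"primary"` / `"metastatic"`.
#' @param cutoff A `positivity_cutoff`.
#' @return List with `n_dual` (patients with both locations), `agreeing`,
#'   `fraction`, `pct` (half-up integer percent) and `excluded` (patients
#'   lacking one of the locations).
#' @export
pairwise_location_agreement <- function(records, cutoff = positivity_cutoff()) {
  validate_staining(records)
  if (!"tissue_location" %in% names(records))
    stop("records lack 'tissue_location'", call. = FALSE)
  keep <- records$tissue_location %in% c("primary", "metastatic")
  records <- records[keep, , drop = FALSE]
  per_loc <- .collapse_patients(records, extra_keys = "tissue_location")
  pos <- is_positive(per_loc, cutoff)
  pid <- as.character(per_loc$patient_id)
  loc <- as.character(per_loc$tissue_location)
  dual <- intersect(pid[loc == "primary"], pid[loc == "metastatic"])
  agree <- vapply(dual, function(p) {
    pos[pid == p & loc == "primary"] == pos[pid == p & loc == "metastatic"]
  }, NA)
  n_dual <- length(dual)
  list(n_dual = n_dual,
       agreeing = sum(agree),
       fraction = if (n_dual > 0) sum(agree) / n_dual else NA_real_,
       pct = if (n_dual > 0) round_half_up(100 * sum(agree) / n_dual, 0) else NA_real_,
       excluded = length(unique(pid)) - n_dual)
}

#' Prevalence by archival-time stratum
#'
#' Bins records by years between tissue collection and testing into the
#' half-open intervals `[breaks[1], breaks[2]), ..., [breaks[k], Inf)` and
#' computes a prevalence row per bin. Antigen stability over archival time
#' shows up as similar rates across bins.
#'
#' @param records Validated staining records with `archival_years`.
#' @param breaks Strictly increasing lower bin boundaries (e.g. `c(0, 1, 5)`
#'   for `[0,1)`, `[1,5)`, `[5,Inf)`).
#' @param cutoff A `positivity_cutoff`.
#' @param unit Passed to [prevalence_by()].
#' @return Prevalence data frame with one row per bin (empty bins reported
#'   with `n = 0`).
#' @export
archival_strata <- function(records, breaks = c(0, 1, 5),
                            cutoff = positivity_cutoff(),
                            unit = c("patient", "sample")) {
  unit <- match.arg(unit)
  validate_staining(records)
  if (any(is.na(records$archival_years)))
    stop("archival_years must be non-missing", call. = FALSE)
  if (length(breaks) < 1L || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing", call. = FALSE)
  edges <- c(breaks, Inf)
  labels <- paste0("[", breaks, ",", c(breaks[-1L], "Inf"), ")")
  records$archival_bin <- cut(records$archival_years, breaks = edges,
                              labels = labels, right = FALSE)
  if (any(is.na(records$archival_bin)))
    stop("records fall below the first archival break", call. = FALSE)
  records$archival_bin <- as.character(records$archival_bin)
  out <- prevalence_by(records, "archival_bin", cutoff, unit = unit)
  # keep bin order, report empty bins explicitly
  full <- data.frame(group = labels, stringsAsFactors = FALSE)
  out <- merge(full, out, by = "group", all.x = TRUE, sort = FALSE)
  out$n[is.na(out$n)] <- 0L
  out$positive[is.na(out$positive)] <- 0L
  out[match(labels, out$group), , drop = FALSE]
}

#' Inter-reader / inter-run positivity concordance
#'
#' Percent agreement of the positivity call between each pair of readers (or
#' staining runs) over an aligned sample set, flagged against a configurable
#' acceptance floor.
#'
#' @param calls_by_reader Named list (>= 2 elements) of logical vectors of
#'   equal length, or a logical matrix with one column per reader; rows are
#'   samples.
#' @param floor Acceptance floor on percent agreement (default 80).
#' @return List with `pairs` (data frame: `reader_a`, `reader_b`,
#'   `agreement_pct`, `below_floor`) and `overall_pct` (mean pairwise
#'   agreement).
#' @export
reader_concordance <- function(calls_by_reader, floor = 80) {
  if (is.matrix(calls_by_reader))
    calls_by_reader <- as.list(as.data.frame(calls_by_reader))
  if (length(calls_by_reader) < 2L)
    stop("need calls from at least two readers", call. = FALSE)
  lens <- lengths(calls_by_reader)
  if (length(unique(lens)) != 1L)
    stop("readers scored mismatched sample sets", call. = FALSE)
  if (is.null(names(calls_by_reader)) || any(!nzchar(names(calls_by_reader))))
    names(calls_by_reader) <- paste0("reader", seq_along(calls_by_reader))
  nm <- names(calls_by_reader)
  combs <- utils::combn(length(nm), 2L)
  pairs <- data.frame(
    reader_a = nm[combs[1L, ]],
    reader_b = nm[combs[2L, ]],
    stringsAsFactors = FALSE
  )
  pairs$agreement_pct <- apply(combs, 2L, function(ij) {
    100 * mean(calls_by_reader[[ij[1L]]] == calls_by_reader[[ij[2L]]])
  })
  pairs$below_floor <- pairs$agreement_pct < floor
  list(pairs = pairs, overall_pct = mean(pairs$agreement_pct))
}
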