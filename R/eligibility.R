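#' Eligibility rule sets
#'
#' HLA eligibility for the MAGE-A4-directed TCR therapies requires at least one
#' inclusion HLA-A*02 allele and no exclusion allele. The defaults encode the
#' clinical criteria: inclusion P groups 02:01P, 02:02P, 02:03P and 02:06P
#' (comparable in vitro potency) and exclusion P group 02:05P (known TCR
#' alloreactivity; an annotation supplied here, never computed).
#'
#' Null alleles (expression suffix `N`) encode no surface protein, so by
#' default they confer neither inclusion nor exclusion; set
#' `count_null_alleles = TRUE` to treat them like expressed alleles.
#'
#' @param inclusion_groups Character vector of inclusion P-group ids.
#' @param exclusion_groups Character vector of exclusion P-group ids.
#' @param count_null_alleles Should suffix-N alleles count towards the rules?
#' @return An object of class `eligibility_rules`.
#' @examples
#' default_rules()
#' @export
default_rules <- function(inclusion_groups = c("02:01P", "02:02P", "02:03P", "02:06P"),
                          exclusion_groups = "02:05P",
                          count_null_alleles = FALSE) {
  if (length(intersect(inclusion_groups, exclusion_groups)) > 0L)
    stop("inclusion and exclusion P-group sets must be disjoint", call. = FALSE)
  if (!all(grepl("P$", c(inclusion_groups, exclusion_groups))))
    stop("P-group identifiers must end in 'P'", call. = FALSE)
  structure(
    list(inclusion_groups = inclusion_groups,
         exclusion_groups = exclusion_groups,
         count_null_alleles = isTRUE(count_null_alleles)),
    class = "eligibility_rules"
  )
}

#' @export
print.eligibility_rules <- function(x, ...) {
  cat("<eligibility_rules>\n",
      "  inclusion: ", paste(x$inclusion_groups, collapse = ", "), "\n",
      "  exclusion: ", paste(x$exclusion_groups, collapse = ", "), "\n",
      "  null alleles count: ", x$count_null_alleles, "\n", sep = "")
  invisible(x)
}

# P groups of the expressed alleles of a candidate pair (NULL-suffix filtered
# out unless the rules count them)
.pair_groups <- function(pair, rules, table) {
  expressed <- vapply(pair, function(a)
    rules$count_null_alleles || is.na(a$suffix) || a$suffix != "N", NA)
  vapply(pair[expressed], p_group, "", table = table)
}

#' Assess eligibility of one unambiguous allele pair
#'
#' A pair is eligible iff it carries at least one allele whose P group is in
#' the inclusion set (and which is expressed) and no allele whose P group is in
#' the exclusion set: exclusion dominates inclusion.
#'
#' @param pair A list of two `hla_allele` objects.
#' @param rules An `eligibility_rules` object.
#' @param table A `pgroup_table`.
#' @return `"eligible"` or `"ineligible"`.
#' @examples
#' tbl <- default_pgroup_table()
#' assess_candidate(list(parse_allele("A*02:01"), parse_allele("A*02:05")),
#'                  default_rules(), tbl)
#' @export
assess_candidate <- function(pair, rules, table) {
  stopifnot(length(pair) == 2L)
  groups <- .pair_groups(pair, rules, table)
  has_inclusion <- any(groups %in% rules$inclusion_groups)
  has_exclusion <- any(groups %in% rules$exclusion_groups)
  if (has_inclusion && !has_exclusion) "eligible" else "ineligible"
}

#' Contribution category of an eligible pair
#'
#' Classifies which inclusion alleles carry the eligibility, mirroring the
#' breakdown used in per-population eligibility figures: any 02:01P allele
#' (alone or combined with another inclusion allele) yields `A0201P`;
#' otherwise the exact set of inclusion groups present names the category
#' (`A0202_exclusive`, `A0203_exclusive`, `A0206_exclusive`,
#' `A0203_and_0206_exclusive`), with any other combination mapped to
#' `other_mixed`.
#'
#' @inheritParams assess_candidate
#' @return A category string.
#' @export
contribution_category <- function(pair, rules, table) {
  if (assess_candidate(pair, rules, table) != "eligible")
    stop("contribution_category() requires an eligible pair", call. = FALSE)
  groups <- .pair_groups(pair, rules, table)
  inc <- sort(unique(groups[groups %in% rules$inclusion_groups]))
  if ("02:01P" %in% inc) return("A0201P")
  if (identical(inc, "02:02P")) return("A0202_exclusive")
  if (identical(inc, "02:03P")) return("A0203_exclusive")
  if (identical(inc, "02:06P")) return("A0206_exclusive")
  if (identical(inc, c("02:03P", "02:06P"))) return("A0203_and_0206_exclusive")
  "other_mixed"
}

.category_levels <- c("A0201P", "A0202_exclusive", "A0203_exclusive",
                      "A0206_exclusive", "A0203_and_0206_exclusive",
                      "other_mixed", "none")

#' Assess eligibility of a (possibly ambiguous) genotype call
#'
#' Ambiguity is handled by unanimity: the call is decided only when every
#' candidate genotype agrees on the eligibility status, otherwise the result is
#' `indeterminate` (the laboratory resolution step that would disambiguate is
#' upstream of this package). The contribution category is reported only for
#' eligible results; if eligible candidates disagree on the category it falls
#' back to `other_mixed`.
#'
#' @param call An `hla_genotype` object.
#' @inheritParams assess_candidate
#' @return A list of class `eligibility_result` with `status`
#'   (`eligible`/`ineligible`/`indeterminate`), `reason` and
#'   `contribution_category` (`none` for non-eligible statuses).
#' @export
assess_genotype <- function(call, rules, table) {
  stopifnot(inherits(call, "hla_genotype"))
  statuses <- vapply(call$candidates, assess_candidate, "",
                     rules = rules, table = table)
  if (length(unique(statuses)) > 1L) {
    fmt <- vapply(call$candidates,
                  function(p) paste(vapply(p, format, ""), collapse = "+"), "")
    return(structure(
      list(status = "indeterminate",
           reason = paste0("candidates disagree: ",
                           paste(paste0(fmt, " [", statuses, "]"), collapse = "; ")),
           contribution_category = "none"),
      class = "eligibility_result"))
  }
  status <- statuses[[1L]]
  if (status != "eligible") {
    return(structure(
      list(status = status, reason = "no candidate satisfies the inclusion rule",
           contribution_category = "none"),
      class = "eligibility_result"))
  }
  cats <- vapply(call$candidates, contribution_category, "",
                 rules = rules, table = table)
  category <- if (length(unique(cats)) == 1L) cats[[1L]] else "other_mixed"
  structure(
    list(status = "eligible", reason = "at least one inclusion allele, no exclusion allele",
         contribution_category = category),
    class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat("<eligibility_result> ", x$status,
      if (x$status == "eligible") paste0(" (", x$contribution_category, ")"),
      "\n  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Summarise eligibility over a screening cohort
#'
#' Computes, per demographic group and overall, the screened and eligible
#' counts, the eligibility rate, the contribution-category breakdown, and the
#' share of eligible patients who qualify exclusively through non-02:01P
#' inclusion alleles (the statistic behind per-population gains from the
#' additional inclusion alleles).
#'
#' @param cohort A data frame with one row per patient, holding a genotype
#'   column of GL-subset strings plus demographic columns. Missing demographic
#'   values are grouped as `"Not recorded"`.
#' @param rules An `eligibility_rules` object.
#' @param table A `pgroup_table`.
#' @param group_keys Character vector of demographic column names to group by;
#'   `NULL` for the overall summary only.
#' @param genotype_col Name of the genotype column (default `"genotype"`).
#' @return A data frame of class `eligibility_summary` with one row per group
#'   plus an `"Overall"` row: `group`, `screened`, `eligible`, `indeterminate`,
#'   `rate` (full-precision fraction), `rate_pct` (half-up, one decimal),
#'   one count column per contribution category, and
#'   `exclusive_non0201_share` (fraction of eligible patients in the four
#'   exclusive non-02:01P categories).
#' @export
summarize_eligibility <- function(cohort, rules, table, group_keys = NULL,
                                  genotype_col = "genotype") {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data frame", call. = FALSE)
  if (!genotype_col %in% names(cohort))
    stop("cohort lacks genotype column '", genotype_col, "'", call. = FALSE)
  res <- lapply(cohort[[genotype_col]], function(g)
    assess_genotype(parse_genotype(g), rules, table))
  status <- vapply(res, `[[`, "", "status")
  category <- vapply(res, `[[`, "", "contribution_category")

  if (is.null(group_keys)) {
    grp <- rep("Overall", nrow(cohort))
  } else {
    missing_cols <- setdiff(group_keys, names(cohort))
    if (length(missing_cols) > 0L)
      stop("cohort lacks grouping column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    parts <- lapply(group_keys, function(k) {
      v <- as.character(cohort[[k]])
      v[is.na(v) | !nzchar(v)] <- "Not recorded"
      v
    })
    grp <- do.call(paste, c(parts, sep = " / "))
  }

  one_group <- function(idx, label) {
    n <- length(idx)
    elig <- sum(status[idx] == "eligible")
    indet <- sum(status[idx] == "indeterminate")
    cat_counts <- vapply(setdiff(.category_levels, "none"),
                         function(cl) sum(category[idx] == cl), 0L)
    exclusive <- sum(cat_counts[c("A0202_exclusive", "A0203_exclusive",
                                  "A0206_exclusive", "A0203_and_0206_exclusive")])
    rate <- elig / n
    c(list(group = label, screened = n, eligible = elig, indeterminate = indet,
           rate = rate, rate_pct = round_half_up(100 * rate, 1)),
      as.list(cat_counts),
      list(exclusive_non0201_share = if (elig > 0) exclusive / elig else NA_real_))
  }

  labels <- sort(unique(grp))
  rows <- lapply(labels, function(lb) one_group(which(grp == lb), lb))
  if (!identical(labels, "Overall"))
    rows <- c(rows, list(one_group(seq_along(grp), "Overall")))
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("eligibility_summary", "data.frame")
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (8.571 -> 9 at 0 digits, 44.75 -> 44.8
#' at 1 digit), the convention used for displayed percentages. Base R's
#' `round()` rounds half to even, which disagrees on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
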