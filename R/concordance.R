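#' Genotype concordance between assay and reference
#'
#' A typing result is concordant when the (unambiguous) reference genotype is
#' either identical to the assay genotype or included among the assay's
#' candidate genotypes when the assay call is ambiguous. Matching is unordered
#' and, by default, at two-field resolution — the resolution at which
#' eligibility is decided; set `resolution = "full"` to require all typed
#' fields (and suffix) to agree.
#'
#' @param reference An `hla_genotype` with exactly one candidate.
#' @param assay An `hla_genotype`, possibly ambiguous.
#' @param resolution `"two_field"` (default) or `"full"`.
#' @return Logical.
#' @examples
#' ref <- parse_genotype("A*02:01+A*68:01")
#' amb <- parse_genotype("A*02:01+A*68:01|A*02:135+A*69:02")
#' is_concordant(ref, amb)
#' @export
is_concordant <- function(reference, assay, resolution = c("two_field", "full")) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(reference, "hla_genotype"), inherits(assay, "hla_genotype"))
  if (reference$ambiguous)
    stop("reference genotype must be unambiguous", call. = FALSE)
  key <- function(a) {
    if (resolution == "two_field") two_field(a) else format(a)
  }
  pair_key <- function(pair) paste(sort(vapply(pair, key, "")), collapse = "+")
  ref_key <- pair_key(reference$candidates[[1L]])
  any(vapply(assay$candidates, pair_key, "") == ref_key)
}

#' One-sided Clopper-Pearson exact lower confidence bound
#'
#' Exact binomial lower bound at one-sided level `alpha`: the `alpha` quantile
#' of the Beta(x, n - x + 1) distribution, equal to `alpha^(1/n)` when all
#' trials succeed and 0 when none does.
#'
#' @param x Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param alpha One-sided significance level in (0, 1); default 0.05 gives a
#'   95% lower confidence bound.
#' @return Lower bound in `[0, 1]`.
#' @examples
#' clopper_pearson_lower(70, 70)  # 0.9581...
#' @export
clopper_pearson_lower <- function(x, n, alpha = 0.05) {
  .check_binom_args(x, n, alpha)
  if (x == 0) return(0)
  if (x == n) return(alpha^(1 / n))
  stats::qbeta(alpha, x, n - x + 1)
}

#' One-sided Wilson score lower confidence bound
#'
#' Lower root of the inverted normal-approximation score test, with
#' `z = qnorm(1 - alpha)`:
#' \deqn{(\hat p + z^2/2n - z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}) / (1 + z^2/n)}
#' floored at 0.
#'
#' @inheritParams clopper_pearson_lower
#' @return Lower bound in `[0, 1]`.
#' @examples
#' wilson_lower(70, 70)  # 0.9627...
#' @export
wilson_lower <- function(x, n, alpha = 0.05) {
  .check_binom_args(x, n, alpha)
  z <- stats::qnorm(1 - alpha)
  p_hat <- x / n
  lo <- (p_hat + z^2 / (2 * n) -
           z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  max(0, lo)
}

.check_binom_args <- function(x, n, alpha) {
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1L || length(n) != 1L ||
      is.na(x) || is.na(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n))
    stop("require integers 0 <= x <= n with n >= 1", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
}

#' Summarise typing concordance against an acceptance threshold
#'
#' Counts concordant records and computes both one-sided exact lower bounds
#' on the concordance proportion; the validation passes when both bounds
#' exceed the acceptance threshold (0.95 per the applicable regulatory
#' guidance).
#'
#' @param records A data frame with columns `sample_id`, `reference_genotype`
#'   and `assay_genotype` (GL-subset strings), e.g. as read from
#'   `concordance.csv`.
#' @param alpha One-sided level (default 0.05).
#' @param threshold Acceptance threshold on the lower bounds (default 0.95).
#' @param resolution Matching resolution passed to [is_concordant()].
#' @return An object of class `concordance_summary`: list with `n`,
#'   `concordant`, `proportion`, `cp_lower`, `wilson_lower`, `alpha`,
#'   `threshold`, `passes_threshold`.
#' @export
summarize_concordance <- function(records, alpha = 0.05, threshold = 0.95,
                                  resolution = c("two_field", "full")) {
  resolution <- match.arg(resolution)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame", call. = FALSE)
  need <- c("reference_genotype", "assay_genotype")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "), call. = FALSE)
  conc <- mapply(function(ref, asy) {
    is_concordant(parse_genotype(ref), parse_genotype(asy), resolution = resolution)
  }, records$reference_genotype, records$assay_genotype)
  n <- nrow(records)
  x <- sum(conc)
  cp <- clopper_pearson_lower(x, n, alpha)
  wl <- wilson_lower(x, n, alpha)
  structure(
    list(n = n, concordant = x, proportion = x / n,
         cp_lower = cp, wilson_lower = wl,
         alpha = alpha, threshold = threshold,
         passes_threshold = cp > threshold && wl > threshold),
    class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary>\n",
      sprintf("  concordant: %d / %d (%.2f%%)\n", x$concordant, x$n,
              round_half_up(100 * x$proportion, 2)),
      sprintf("  one-sided %g%% lower bounds: Clopper-Pearson %.2f%%, Wilson %.2f%%\n",
              100 * (1 - x$alpha),
              round_half_up(100 * x$cp_lower, 2),
              round_half_up(100 * x$wilson_lower, 2)),
      sprintf("  threshold %.0f%%: %s\n", 100 * x$threshold,
              if (x$passes_threshold) "PASS" else "FAIL"),
      sep = "")
  invisible(x)
}
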