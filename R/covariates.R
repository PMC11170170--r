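#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' Closed-form cross-product odds ratio for the table
#' `(a, b) / (c, d)` = (exposed positive, exposed negative) over (unexposed
#' positive, unexposed negative), with a Wald interval on the log scale,
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. If exactly one cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied with a
#' warning; two zero cells in the same row or column leave the odds ratio
#' undefined and raise an error.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row: `term`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @examples
#' odds_ratio_2x2(20, 10, 5, 20)$or  # 8
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  zero <- cells == 0
  if ((zero["a"] && zero["b"]) || (zero["c"] && zero["d"]) ||
      (zero["a"] && zero["c"]) || (zero["b"] && zero["d"]))
    stop("odds ratio undefined: two zero cells share a row or column",
         call. = FALSE)
  if (any(zero)) {
    warning("zero cell: applying Haldane-Anscombe +0.5 correction",
            call. = FALSE)
    cells <- cells + 0.5
  }
  log_or <- log(cells[["a"]]) + log(cells[["d"]]) -
    log(cells[["b"]]) - log(cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = "exposure",
    or = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    p_value = 2 * stats::pnorm(-abs(log_or / se)),
    n = sum(c(a, b, c, d)),
    stringsAsFactors = FALSE
  )
}

# Complete/quasi-separation check on a fitted binomial glm: a term whose
# coefficient walked to +-Inf shows up as a huge |estimate| with an even
# larger standard error.
.check_separation <- function(fit) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- which(!is.na(cf) & (abs(cf) > 15 | se > 1e3))
  bad <- setdiff(names(bad), "(Intercept)")
  if (length(bad) > 0L)
    stop("complete or quasi-complete separation detected for term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(cf))
    stop("rank-deficient model: coefficient(s) not estimable: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  invisible(fit)
}

#' Logistic-regression odds ratios with Wald confidence intervals
#'
#' Fits MAGE-A4 positivity (or any binary outcome) against covariates by
#' maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]). In `mode = "univariate"` each term is fitted
#' in its own model; in `mode = "multivariate"` all terms are fitted jointly
#' (adjusted odds ratios). Coefficients are reported exponentiated with Wald
#' intervals on the log-odds scale. The reference level of a categorical
#' covariate is its first factor level; declare factor levels explicitly for
#' reproducible ratios. Complete or quasi-complete separation raises an
#' error naming the separating term rather than silently correcting.
#'
#' @param table Data frame with the outcome and covariate columns; rows with
#'   missing values in the used columns are dropped per fit.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param terms Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per non-intercept coefficient: `mode`,
#'   `term`, `or`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
fit_logistic <- function(table, outcome = "positive", terms,
                         mode = c("univariate", "multivariate"),
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  if (!outcome %in% names(table))
    stop("table lacks outcome column '", outcome, "'", call. = FALSE)
  miss <- setdiff(terms, names(table))
  if (length(miss) > 0L)
    stop("table lacks covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(table[[outcome]]))
    stop("outcome must be non-missing", call. = FALSE)

  fit_one <- function(tms) {
    dat <- table[, c(outcome, tms), drop = FALSE]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    y <- dat[[outcome]]
    if (is.logical(y)) y <- as.integer(y)
    if (length(unique(y)) < 2L)
      stop("complete separation: outcome is constant in the analysis set",
           call. = FALSE)
    dat[[outcome]] <- y
    if (nrow(dat) <= length(tms) + 1L)
      stop("more parameters than observations", call. = FALSE)
    form <- stats::as.formula(paste(outcome, "~", paste(tms, collapse = " + ")))
    fit <- suppressWarnings(
      stats::glm(form, data = dat, family = stats::binomial(),
                 control = stats::glm.control(maxit = 100)))
    if (!fit$converged)
      stop("logistic regression failed to converge within 100 iterations",
           call. = FALSE)
    .check_separation(fit)
    cf <- summary(fit)$coefficients
    cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    data.frame(
      mode = mode,
      term = rownames(cf),
      or = exp(cf[, "Estimate"]),
      ci_low = exp(cf[, "Estimate"] - z * cf[, "Std. Error"]),
      ci_high = exp(cf[, "Estimate"] + z * cf[, "Std. Error"]),
      p_value = cf[, "Pr(>|z|)"],
      n = nrow(dat),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }

  out <- if (mode == "multivariate") fit_one(terms) else
    do.call(rbind, lapply(terms, fit_one))
  rownames(out) <- NULL
  out
}
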