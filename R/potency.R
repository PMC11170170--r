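#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of the LL.3 model with lower asymptote fixed at zero,
#' \deqn{y = d / (1 + \exp(b (\ln x - \ln e)))}
#' where `d` is the upper asymptote (response units), `e` the EC50 (molar) and
#' `b` the Hill slope (negative for a response that rises with concentration).
#' Estimation uses Levenberg-Marquardt least squares on the parameterisation
#' `(b, d, log10 e)` with a multi-start policy: the half-max-based start plus
#' `n_starts - 1` jittered copies, keeping the best residual sum of squares.
#'
#' @param concentrations Positive molar peptide concentrations, >= 4 distinct
#'   values.
#' @param responses Non-negative signal values, same length.
#' @param init Optional named starting values `c(b =, d =, log10_e =)`;
#'   by default `d0` is the maximum response, `e0` the concentration whose
#'   response is nearest half-max, and `b0 = -1`.
#' @param n_starts Number of starts (default 5).
#' @param allele Optional allele label stored on the fit.
#' @return An object of class `ll3_fit`: coefficients `b`, `d`, `log10_ec50`,
#'   plus `residual_ss`, `converged`, `extrapolated` (EC50 more than 2 log10
#'   units outside the tested concentration range) and the data.
#' @examples
#' x <- 10^seq(-10, -5, length.out = 8)
#' y <- 1 / (1 + exp(-1 * (log(x) - log(10^-7.8))))
#' coef(fit_ll3(x, y))
#' @export
fit_ll3 <- function(concentrations, responses, init = NULL, n_starts = 5,
                    allele = NA_character_) {
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    stop("concentrations and responses must be equal-length and non-missing",
         call. = FALSE)
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(y < 0)) stop("responses must be non-negative", call. = FALSE)
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (diff(range(y)) <= 1e-12 * max(1, max(abs(y))))
    stop("degenerate fit: responses are constant, no EC50 is identifiable",
         call. = FALSE)

  d0 <- max(y)
  e0 <- x[which.min(abs(y - d0 / 2))]
  start0 <- c(b = -1, d = d0, log10_e = log10(e0))
  if (!is.null(init)) {
    if (!all(c("b", "d", "log10_e") %in% names(init)))
      stop("init must name b, d and log10_e", call. = FALSE)
    start0 <- c(b = unname(init[["b"]]), d = unname(init[["d"]]),
                log10_e = unname(init[["log10_e"]]))
  }

  lx <- log(x)
  model <- function(b, d, log10_e) d / (1 + exp(b * (lx - log10_e * log(10))))
  dat <- data.frame(lx = lx, y = y)

  # deterministic jitter pattern so the fit is reproducible given the data
  jit <- cbind(b = c(0, -0.5, 0.5, -1, 1, rep(0, max(0, n_starts - 5))),
               d = c(0, 0.2, -0.2, 0.1, -0.1, rep(0, max(0, n_starts - 5))),
               e = c(0, 1, -1, 0.5, -0.5, rep(0, max(0, n_starts - 5))))[seq_len(n_starts), ,
                                                                         drop = FALSE]
  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- list(b = as.numeric(start0[["b"]] + jit[i, "b"]),
               d = as.numeric(start0[["d"]] * (1 + jit[i, "d"])),
               log10_e = as.numeric(start0[["log10_e"]] + jit[i, "e"]))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ d / (1 + exp(b * (lx - log10_e * log(10)))),
        data = dat, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                             ptol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    return(structure(
      list(allele = allele, coefficients = c(b = NA_real_, d = NA_real_,
                                             log10_ec50 = NA_real_),
           residual_ss = NA_real_, converged = FALSE, extrapolated = NA,
           data = data.frame(concentration = x, response = y)),
      class = "ll3_fit"))
  }
  cf <- stats::coef(best$fit)
  log10_ec50 <- cf[["log10_e"]]
  rng <- range(log10(x))
  extrapolated <- log10_ec50 < rng[1L] - 2 || log10_ec50 > rng[2L] + 2
  if (cf[["d"]] <= 0)
    stop("degenerate fit: non-positive upper asymptote", call. = FALSE)
  structure(
    list(allele = allele,
         coefficients = c(b = cf[["b"]], d = cf[["d"]], log10_ec50 = log10_ec50),
         residual_ss = best$rss, converged = TRUE, extrapolated = extrapolated,
         data = data.frame(concentration = x, response = y)),
    class = "ll3_fit")
}

#' @export
coef.ll3_fit <- function(object, ...) object$coefficients

#' @export
print.ll3_fit <- function(x, ...) {
  cat("<ll3_fit>", if (!is.na(x$allele)) paste0(" allele ", x$allele), "\n", sep = "")
  if (x$converged) {
    cat(sprintf("  b = %.4g, d = %.4g, log10(EC50) = %.4f  (RSS %.3g)%s\n",
                x$coefficients[["b"]], x$coefficients[["d"]],
                x$coefficients[["log10_ec50"]], x$residual_ss,
                if (isTRUE(x$extrapolated)) "  [EC50 extrapolated]" else ""))
  } else cat("  did not converge\n")
  invisible(x)
}

#' @export
predict.ll3_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else
    if (is.data.frame(newdata)) newdata$concentration else as.numeric(newdata)
  cf <- object$coefficients
  cf[["d"]] / (1 + exp(cf[["b"]] * (log(x) - cf[["log10_ec50"]] * log(10))))
}

#' @export
residuals.ll3_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' Average log10 EC50 over replicate fits
#'
#' Arithmetic mean of `log10_ec50` over the converged fits for one allele
#' (the summary reported per transduced HLA-A*02 subtype). Non-converged
#' fits are dropped with a warning.
#'
#' @param fits List of `ll3_fit` objects.
#' @return Mean log10 EC50 (molar).
#' @export
average_log_ec50 <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, NA, "ll3_fit")))
  conv <- vapply(fits, `[[`, NA, "converged")
  if (!any(conv)) stop("no converged fits", call. = FALSE)
  if (any(!conv))
    warning(sum(!conv), " non-converged fit(s) dropped from the average",
            call. = FALSE)
  mean(vapply(fits[conv], function(f) f$coefficients[["log10_ec50"]], 0))
}

#' Classify allele potency by EC50 fold change
#'
#' Compares an allele's mean log10 EC50 against the reference allele's
#' (A*02:01 in the clinical context). The shift `delta = allele - reference`
#' on the log10 scale is a fold change in EC50; potency is `"reduced"` iff
#' the fold change strictly exceeds `fold_threshold` (default 10), else
#' `"comparable"`.
#'
#' @param allele_mean Mean log10 EC50 of the allele of interest.
#' @param reference_mean Mean log10 EC50 of the reference allele.
#' @param fold_threshold Fold-change threshold (strict inequality).
#' @param allele,reference Optional labels.
#' @return List of class `potency_call`: `allele`, `reference`,
#'   `delta_log10_ec50`, `fold_change`, `classification`.
#' @examples
#' classify_allele_potency(-6.5, -7.8)$classification  # "reduced"
#' @export
classify_allele_potency <- function(allele_mean, reference_mean,
                                    fold_threshold = 10,
                                    allele = NA_character_,
                                    reference = NA_character_) {
  stopifnot(is.finite(allele_mean), is.finite(reference_mean), fold_threshold > 0)
  delta <- allele_mean - reference_mean
  structure(
    list(allele = allele, reference = reference,
         delta_log10_ec50 = delta, fold_change = 10^delta,
         classification = if (delta > log10(fold_threshold)) "reduced" else "comparable"),
    class = "potency_call")
}

#' @export
print.potency_call <- function(x, ...) {
  cat("<potency_call>",
      if (!is.na(x$allele)) paste0(" ", x$allele, " vs ", x$reference), "\n",
      sprintf("  delta log10(EC50) = %+.2f (%.1f-fold): %s\n",
              x$delta_log10_ec50, x$fold_change, x$classification),
      sep = "")
  invisible(x)
}

#' Per-allele potency analysis of a dose-response table
#'
#' Fits every (allele, replicate) curve in a `doseresponse.csv`-schema table,
#' averages log10 EC50 per allele and classifies each allele against the
#' named reference.
#'
#' @param data Data frame with columns `allele`, `replicate`,
#'   `concentration_M`, `response`.
#' @param reference Reference allele label (default `"A*02:01"`).
#' @param fold_threshold Fold-change threshold for "reduced" potency.
#' @return Data frame with one row per allele: `allele`, `n_curves`,
#'   `mean_log10_ec50`, `delta_log10_ec50`, `fold_change`, `classification`
#'   (`"reference"` for the reference row).
#' @export
potency_table <- function(data, reference = "A*02:01", fold_threshold = 10) {
  need <- c("allele", "replicate", "concentration_M", "response")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!reference %in% data$allele)
    stop("reference allele '", reference, "' absent from data", call. = FALSE)
  alleles <- unique(data$allele)
  means <- vapply(alleles, function(al) {
    sub <- data[data$allele == al, , drop = FALSE]
    fits <- lapply(split(sub, sub$replicate), function(rep_dat)
      fit_ll3(rep_dat$concentration_M, rep_dat$response, allele = al))
    average_log_ec50(fits)
  }, 0)
  n_curves <- vapply(alleles, function(al)
    length(unique(data$replicate[data$allele == al])), 0L)
  ref_mean <- means[[which(alleles == reference)]]
  out <- data.frame(allele = alleles, n_curves = n_curves,
                    mean_log10_ec50 = means, stringsAsFactors = FALSE)
  out$delta_log10_ec50 <- out$mean_log10_ec50 - ref_mean
  out$fold_change <- 10^out$delta_log10_ec50
  out$classification <- vapply(seq_len(nrow(out)), function(i) {
    if (out$allele[i] == reference) "reference" else
      classify_allele_potency(out$mean_log10_ec50[i], ref_mean,
                              fold_threshold)$classification
  }, "")
  rownames(out) <- NULL
  out
}
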