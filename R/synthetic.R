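#' Synthetic screening-cohort configuration
#'
#' Describes a diploid HLA-A cohort: a population mix, per-population allele
#' frequency vectors (each summing to 1, including a catch-all `"other"`
#' allele that never satisfies an eligibility rule), and the probability that
#' a genotype call carries a second, spurious candidate (typing ambiguity).
#'
#' The packaged default emulates a North American / European screening
#' population: five self-reported race/ethnicity groups with allele
#' frequencies in the range public frequency databases report for them
#' (A*02:01 common in European-ancestry groups, A*02:02 enriched in African-
#' ancestry, A*02:03/02:06 in Asian, A*02:06 also in Hispanic groups,
#' A*02:05 rare throughout).
#'
#' @param n_patients Cohort size.
#' @param populations Named list; each element has `proportion` and `freqs`
#'   (named allele-frequency vector summing to 1).
#' @param ambiguity_rate Probability a call gains a spurious extra candidate.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, populations, ambiguity_rate = 0.05,
                          seed = 1L) {
  stopifnot(n_patients >= 1, ambiguity_rate >= 0, ambiguity_rate <= 1)
  props <- vapply(populations, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("population proportions must sum to 1", call. = FALSE)
  for (nm in names(populations)) {
    f <- populations[[nm]]$freqs
    if (is.null(names(f)) || abs(sum(f) - 1) > 1e-9)
      stop("allele frequencies for population '", nm,
           "' must be named and sum to 1", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), populations = populations,
         ambiguity_rate = ambiguity_rate, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_config <- function(n_patients = 2000, ambiguity_rate = 0.05,
                                  seed = 1L) {
  mk <- function(...) {
    f <- c(...)
    c(f, other = 1 - sum(f))
  }
  populations <- list(
    "White, not Hispanic or Latino" = list(
      proportion = 0.795,
      freqs = mk("A*02:01" = 0.27, "A*02:02" = 0.002, "A*02:03" = 0.001,
                 "A*02:05" = 0.010, "A*02:06" = 0.005, "A*02:07" = 0.002,
                 "A*01:01" = 0.15, "A*03:01" = 0.13, "A*24:02" = 0.09)),
    "White, Hispanic or Latino" = list(
      proportion = 0.047,
      freqs = mk("A*02:01" = 0.20, "A*02:02" = 0.010, "A*02:03" = 0.005,
                 "A*02:05" = 0.020, "A*02:06" = 0.040, "A*02:07" = 0.005,
                 "A*01:01" = 0.06, "A*03:01" = 0.07, "A*24:02" = 0.12)),
    "Black or African American" = list(
      proportion = 0.048,
      freqs = mk("A*02:01" = 0.12, "A*02:02" = 0.040, "A*02:03" = 0.002,
                 "A*02:05" = 0.015, "A*02:06" = 0.005, "A*02:07" = 0.002,
                 "A*01:01" = 0.06, "A*03:01" = 0.08, "A*24:02" = 0.03)),
    "Asian" = list(
      proportion = 0.066,
      freqs = mk("A*02:01" = 0.08, "A*02:02" = 0.001, "A*02:03" = 0.050,
                 "A*02:05" = 0.002, "A*02:06" = 0.060, "A*02:07" = 0.060,
                 "A*01:01" = 0.04, "A*03:01" = 0.04, "A*24:02" = 0.18)),
    "Other" = list(
      proportion = 0.044,
      freqs = mk("A*02:01" = 0.20, "A*02:02" = 0.010, "A*02:03" = 0.010,
                 "A*02:05" = 0.010, "A*02:06" = 0.020, "A*02:07" = 0.010,
                 "A*01:01" = 0.08, "A*03:01" = 0.08, "A*24:02" = 0.10))
  )
  cohort_config(n_patients, populations, ambiguity_rate, seed)
}

# Split one seed into named sub-streams: the master seed seeds a draw of
# 32-bit sub-seeds, one per consumer, so adding a consumer never perturbs the
# streams before it.
.split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate diploid HLA-A genotype calls
#'
#' Each patient draws a population from the configured mix, then two alleles
#' independently from that population's frequency vector (Hardy-Weinberg
#' sampling); with probability `ambiguity_rate` the call gains a spurious
#' second candidate genotype, constructed to disagree with the true pair's
#' eligibility status with probability 0.5 so downstream indeterminate
#' handling is exercised.
#'
#' @param config A `cohort_config`.
#' @param rules,table Eligibility rules and P-group table used to steer the
#'   spurious candidates (defaults: [default_rules()], [default_pgroup_table()]).
#' @return Data frame in the `hla_typing.csv` schema: `patient_id`,
#'   `genotype` (GL-subset string), `population`.
#' @export
simulate_genotypes <- function(config, rules = default_rules(),
                               table = default_pgroup_table()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- .split_seed(config$seed, 4L)
  n <- config$n_patients
  pops <- names(config$populations)
  props <- vapply(config$populations, `[[`, 0, "proportion")

  set.seed(seeds[1L])
  pop <- sample(pops, n, replace = TRUE, prob = props)

  set.seed(seeds[2L])
  genotype <- character(n)
  true_status <- character(n)
  for (nm in pops) {
    idx <- which(pop == nm)
    if (length(idx) == 0L) next
    f <- config$populations[[nm]]$freqs
    a1 <- sample(names(f), length(idx), replace = TRUE, prob = f)
    a2 <- sample(names(f), length(idx), replace = TRUE, prob = f)
    genotype[idx] <- paste(.as_allele_name(a1), .as_allele_name(a2), sep = "+")
    true_status[idx] <- vapply(seq_along(idx), function(k) {
      assess_candidate(list(parse_allele(.as_allele_name(a1[k])),
                            parse_allele(.as_allele_name(a2[k]))),
                       rules, table)
    }, "")
  }

  set.seed(seeds[3L])
  ambiguous <- stats::runif(n) < config$ambiguity_rate
  discordant <- stats::runif(n) < 0.5
  spurious <- ifelse(
    (true_status == "eligible") == discordant,
    "A*03:01+A*68:01",   # ineligible candidate
    "A*02:01+A*24:02")   # eligible candidate
  genotype[ambiguous] <- paste(genotype[ambiguous], spurious[ambiguous],
                               sep = "|")

  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    genotype = genotype,
    population = pop,
    stringsAsFactors = FALSE
  )
}

# "other" stands for any allele with no eligibility role; give it a fixed
# neutral name so the GL strings stay parseable
.as_allele_name <- function(x) ifelse(x == "other", "A*11:01", x)

#' Closed-form expected eligibility rate of a cohort configuration
#'
#' Under Hardy-Weinberg sampling a patient is eligible iff they carry at least
#' one inclusion allele and no exclusion allele:
#' `(1 - x)^2 - (1 - x - i)^2` per population, where `i` and `x` are the
#' summed inclusion- and exclusion-allele frequencies. An eligible patient
#' whose call gains an eligibility-discordant spurious candidate (probability
#' `ambiguity_rate / 2`) is reported indeterminate, so the expected observed
#' eligible fraction is scaled by `1 - ambiguity_rate / 2`.
#'
#' @inheritParams simulate_genotypes
#' @return Expected fraction of patients reported eligible.
#' @export
expected_eligibility <- function(config, rules = default_rules(),
                                 table = default_pgroup_table()) {
  per_pop <- vapply(config$populations, function(p) {
    f <- p$freqs
    grp <- vapply(names(f), function(nm) {
      if (nm == "other") return("other")
      p_group(parse_allele(nm), table)
    }, "")
    i <- sum(f[grp %in% rules$inclusion_groups])
    x <- sum(f[grp %in% rules$exclusion_groups])
    (1 - x)^2 - (1 - x - i)^2
  }, 0)
  props <- vapply(config$populations, `[[`, 0, "proportion")
  sum(props * per_pop) * (1 - config$ambiguity_rate / 2)
}

#' IHC generative-model configuration
#'
#' Class-conditional model for synthetic staining records: a patient's tumor
#' type is drawn from `mix`; positivity is Bernoulli with
#' `logit(p) = intercept[tumor_type] + beta_age * (age - 60)/10 +
#' beta_scc * [SCC] + beta_metastatic * [metastatic] +
#' beta_archival * archival_years`. Positive samples draw a P score from
#' `30 + 70 * Beta(pos_shape1, pos_shape2)` (support `[30, 100]`); negative
#' samples are zero-inflated, scoring exactly 0 with probability
#' `neg_zero_prob` and otherwise `30 * Beta(neg_shape1, neg_shape2)`
#' (support `[0, 30)`), so the positivity call reproduces the Bernoulli draw.
#'
#' Default intercepts encode per-indication positivity rates ranging from 70%
#' (synovial sarcoma) down to 9% (gastric), with the tumor-type mix weighted
#' like a solid-tumor screening population; covariate coefficients default
#' to 0.
#'
#' @param intercepts Named logit-scale intercept per tumor type.
#' @param mix Named tumor-type probabilities (same names, sum to 1).
#' @param beta_age,beta_scc,beta_metastatic,beta_archival Covariate
#'   coefficients on the logit scale.
#' @param pos_shape1,pos_shape2,neg_shape1,neg_shape2 Beta shapes of the
#'   class-conditional P-score distributions.
#' @param neg_zero_prob Zero-inflation mass of the negative class.
#' @return An object of class `ihc_model_config`.
#' @export
ihc_model_config <- function(intercepts = NULL, mix = NULL,
                             beta_age = 0, beta_scc = 0, beta_metastatic = 0,
                             beta_archival = 0,
                             pos_shape1 = 1.2, pos_shape2 = 1.5,
                             neg_shape1 = 0.6, neg_shape2 = 2.5,
                             neg_zero_prob = 0.7) {
  if (is.null(intercepts)) {
    rates <- c(SyS = 0.70, MRCLS = 0.40, urothelial = 0.32, EGJ = 0.26,
               ovarian = 0.24, head_and_neck = 0.22, esophageal = 0.21,
               melanoma = 0.16, NSCLC = 0.14, gastric = 0.09)
    intercepts <- stats::qlogis(rates)
  }
  if (is.null(mix)) {
    counts <- c(SyS = 201, MRCLS = 67, urothelial = 93, EGJ = 93,
                ovarian = 226, head_and_neck = 200, esophageal = 100,
                melanoma = 243, NSCLC = 457, gastric = 70)
    mix <- counts[names(intercepts)] / sum(counts)
  }
  if (!setequal(names(intercepts), names(mix)))
    stop("intercepts and mix must name the same tumor types", call. = FALSE)
  if (abs(sum(mix) - 1) > 1e-9)
    stop("tumor-type mix must sum to 1", call. = FALSE)
  structure(
    list(intercepts = intercepts, mix = mix[names(intercepts)],
         beta_age = beta_age, beta_scc = beta_scc,
         beta_metastatic = beta_metastatic, beta_archival = beta_archival,
         pos_shape1 = pos_shape1, pos_shape2 = pos_shape2,
         neg_shape1 = neg_shape1, neg_shape2 = neg_shape2,
         neg_zero_prob = neg_zero_prob),
    class = "ihc_model_config")
}

# SCC is only a meaningful histology in some indications
.scc_prob <- c(NSCLC = 0.4, esophageal = 0.5, head_and_neck = 0.9, EGJ = 0.2)

#' Simulate IHC staining records for a cohort
#'
#' Draws tumor type, covariates, positivity and a class-conditional P score
#' per patient (see [ihc_model_config()]), then decomposes the P score into
#' the four intensity percentages: the positive mass splits 60/40 between 2+
#' and 3+, the remainder 70/30 between 0 and 1+ (the split is irrelevant to
#' the P score by construction).
#'
#' @param config An `ihc_model_config`.
#' @param cohort Data frame with a `patient_id` column (e.g. from
#'   [simulate_genotypes()]).
#' @param seed Integer seed.
#' @return Data frame in the `ihc.csv` schema.
#' @export
simulate_ihc <- function(config, cohort, seed = 1L) {
  stopifnot(inherits(config, "ihc_model_config"))
  n <- nrow(cohort)
  seeds <- .split_seed(seed, 2L)

  set.seed(seeds[1L])
  tumor_type <- sample(names(config$mix), n, replace = TRUE, prob = config$mix)
  patient_age <- pmin(75, pmax(18, round(stats::rnorm(n, 60, 10))))
  scc_p <- ifelse(tumor_type %in% names(.scc_prob), .scc_prob[tumor_type], NA)
  histology <- ifelse(is.na(scc_p), "other",
                      ifelse(stats::runif(n) < scc_p, "SCC", "AC"))
  tissue_location <- ifelse(stats::runif(n) < 0.3, "metastatic", "primary")
  archival_years <- pmin(20, stats::rexp(n, rate = 0.8))

  lp <- config$intercepts[tumor_type] +
    config$beta_age * (patient_age - 60) / 10 +
    config$beta_scc * (histology == "SCC") +
    config$beta_metastatic * (tissue_location == "metastatic") +
    config$beta_archival * archival_years

  set.seed(seeds[2L])
  positive <- stats::runif(n) < stats::plogis(lp)
  pscore <- numeric(n)
  npos <- sum(positive)
  pscore[positive] <- 30 + 70 * stats::rbeta(npos, config$pos_shape1,
                                             config$pos_shape2)
  nneg <- n - npos
  neg_zero <- stats::runif(nneg) < config$neg_zero_prob
  neg_scores <- 30 * stats::rbeta(nneg, config$neg_shape1, config$neg_shape2)
  neg_scores[neg_zero] <- 0
  pscore[!positive] <- neg_scores

  rest <- 100 - pscore
  data.frame(
    sample_id = paste0(cohort$patient_id, "-S1"),
    patient_id = cohort$patient_id,
    tumor_type = tumor_type,
    histology = histology,
    tissue_location = tissue_location,
    patient_age = patient_age,
    archival_years = archival_years,
    pct0 = 0.7 * rest,
    pct1 = 0.3 * rest,
    pct2 = 0.6 * pscore,
    pct3 = 0.4 * pscore,
    stringsAsFactors = FALSE
  )
}

#' Simulate dose-response curves from a known truth
#'
#' Generates replicate curves `response = LL3(b, d, log10_ec50) + noise`
#' with Gaussian noise truncated at zero, in the `doseresponse.csv` schema.
#'
#' @param truth Named vector `c(b =, d =, log10_e =)`.
#' @param concentrations Positive molar concentrations.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param replicates Number of replicate curves.
#' @param seed Integer seed.
#' @param allele Allele label for the output.
#' @return Data frame with columns `allele`, `replicate`, `concentration_M`,
#'   `response`.
#' @export
simulate_dose_response <- function(truth, concentrations, noise_sd = 0.05,
                                   replicates = 3, seed = 1L,
                                   allele = "A*02:01") {
  stopifnot(all(c("b", "d", "log10_e") %in% names(truth)))
  if (any(concentrations <= 0))
    stop("concentrations must be positive", call. = FALSE)
  mu <- truth[["d"]] / (1 + exp(truth[["b"]] *
                                  (log(concentrations) - truth[["log10_e"]] * log(10))))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(allele = allele, replicate = r,
               concentration_M = concentrations,
               response = pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
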