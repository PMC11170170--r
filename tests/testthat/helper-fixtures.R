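# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# staining records with prescribed P scores (split 60/40 between 2+ and 3+,
# remainder 70/30 between 0 and 1+, irrelevant to the P score)
make_staining <- function(pscore, patient_id = NULL, sample_id = NULL,
                          tumor_type = "SyS", histology = "other",
                          tissue_location = "primary", patient_age = 60,
                          archival_years = 1) {
  n <- length(pscore)
  if (is.null(patient_id)) patient_id <- sprintf("PT%04d", seq_len(n))
  if (is.null(sample_id)) sample_id <- paste0(patient_id, "-S1")
  rest <- 100 - pscore
  data.frame(
    sample_id = sample_id, patient_id = patient_id,
    tumor_type = rep_len(tumor_type, n), histology = rep_len(histology, n),
    tissue_location = rep_len(tissue_location, n),
    patient_age = rep_len(patient_age, n),
    archival_years = rep_len(archival_years, n),
    pct0 = 0.7 * rest, pct1 = 0.3 * rest,
    pct2 = 0.6 * pscore, pct3 = 0.4 * pscore,
    stringsAsFactors = FALSE
  )
}

# prevalence fixture: `positive` of `n` samples positive (P score 50 vs 0)
make_prevalence_group <- function(n, positive, tumor_type, id_prefix) {
  rec <- make_staining(c(rep(50, positive), rep(0, n - positive)),
                       patient_id = sprintf("%s%05d", id_prefix, seq_len(n)),
                       tumor_type = tumor_type)
  rec
}

# HLA typing cohort with a prescribed number of eligible patients per group
make_typing_cohort <- function(groups) {
  # groups: data.frame(group, screened, eligible)
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    data.frame(
      patient_id = sprintf("%s-%05d", gsub("[^A-Za-z]", "", g$group), seq_len(g$screened)),
      genotype = c(rep("A*02:01+A*01:01", g$eligible),
                   rep("A*01:01+A*03:01", g$screened - g$eligible)),
      population = g$group,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# independent numeric oracles for the binomial lower bounds
cp_lower_oracle <- function(x, n, alpha) {
  if (x == 0) return(0)
  f <- function(p) 1 - stats::pbinom(x - 1, n, p) - alpha
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-13)$root
}

wilson_lower_oracle <- function(x, n, alpha) {
  if (x == 0) return(0)
  z <- stats::qnorm(1 - alpha)
  p_hat <- x / n
  f <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  upper <- if (x == n) 1 - 1e-9 else p_hat - 1e-12
  stats::uniroot(f, c(0, upper), tol = 1e-13)$root
}

pair <- function(a, b) list(parse_allele(a), parse_allele(b))

# shared defaults (cheap to rebuild, but one copy keeps tests terse)
PG <- default_pgroup_table()
RULES <- default_rules()
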