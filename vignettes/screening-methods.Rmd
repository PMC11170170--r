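---
title: "Methods: HLA/MAGE-A4 biomarker screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA/MAGE-A4 biomarker screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magescreen)
```

# The screening problem

Engineered TCR T cell therapies against MAGE-A4 recognise a MAGE-A4 peptide
only when it is presented by a compatible HLA-A\*02 molecule. Screening for
such trials therefore proceeds through two gates. First, every candidate
patient is HLA-A typed at high resolution (two fields, i.e. the protein
level); a patient is HLA-eligible when they carry at least one *inclusion*
allele — A\*02:01, 02:02, 02:03 or 02:06, or any allele in the same P group —
and no *exclusion* allele (A\*02:05P, excluded because of known TCR
alloreactivity, an annotation this package takes as configuration and never
computes). Second, only HLA-eligible patients have tumor tissue tested for
MAGE-A4 by immunohistochemistry; combined eligibility requires both gates.
`run_screen()` reproduces exactly this gated flow.

This vignette documents the statistical procedures, the tunable parameters,
the synthetic-data generator and the design decisions behind the package.

# HLA eligibility

## Nomenclature, P groups, ambiguity

Alleles are parsed from WHO nomenclature (`A*02:01:01:02N`): locus, two to
four numeric fields, optional expression suffix (`N/L/S/C/A/Q`). Two fields
are the minimum because inclusion, exclusion and neutral A\*02 alleles only
separate at the protein level. P groups — sets of alleles with identical
α1/α2 peptide-binding domains — are read from the IMGT `hla_nom_p.txt`
dialect; a small curated subset covering the clinically relevant groups
ships with the package, and a full IMGT file loads through the same reader.
Alleles absent from the table map to a singleton group named by their
two-field projection: rare alleles occur in real screening data and should
be *neutral*, not an error.

Typing assays report ambiguity as alternative candidate genotypes
(GL-string `|`). Eligibility under ambiguity follows a unanimity rule:
decided only when every candidate agrees, otherwise `indeterminate`. This
mirrors practice — an ambiguous call that straddles the eligibility boundary
triggers laboratory re-resolution (group-specific sequencing primers), which
is upstream of this package. Null alleles (suffix `N`) encode no surface
protein, so by default they confer neither inclusion (no peptide
presentation) nor exclusion (no alloreactive target); the
`count_null_alleles` switch restores naive counting.

## Contribution categories

Eligible patients are classified by which inclusion alleles carry their
eligibility: any 02:01P allele puts the patient in `A0201P` (whether alone
or alongside another inclusion allele); otherwise the exact set of inclusion
groups present names the category (`A0202_exclusive`, `A0203_exclusive`,
`A0206_exclusive`, `A0203_and_0206_exclusive`). Combinations without a
defined label (e.g. 02:02 with 02:03 and no 02:01P) fall into
`other_mixed` rather than inventing a finer classification. The categories
partition the eligible patients; `summarize_eligibility()` additionally
reports the share of eligible patients in the exclusive non-02:01P
categories, the statistic that quantifies how much the additional inclusion
alleles broaden eligibility in non-European-ancestry populations.

Displayed eligibility rates are rounded half-up to one decimal
(`round_half_up()`); raw rates are kept at full precision, and rounding is
applied only at render time.

# Typing-concordance validation

A typing result is concordant when the unambiguous reference genotype
equals the assay genotype or is contained among the assay's candidates.
Matching defaults to two-field resolution — the resolution at which
eligibility is decided — with a `"full"` option.

Validation reports one-sided exact lower confidence bounds on the
concordance proportion at α = 0.05, compared to a 0.95 acceptance
threshold:

* **Clopper-Pearson**: the α quantile of Beta(x, n − x + 1); for x = n this
  is exactly α^(1/n), so 70/70 concordant samples give
  0.05^(1/70) = 0.9581.
* **Wilson**: the lower root of (p̂ − p)² = z² p(1 − p)/n with
  z = Φ⁻¹(1 − α) computed from the normal quantile, not a hard-coded 1.645;
  70/70 gives 1/(1 + z²/70) = 0.9628.

The two bounds are not ordered in general, so each is tested against its
own independent root-finding oracle rather than against each other.
Display rounding is half-up to two decimals.

# IHC scoring

The P score is the percentage of tumor cells staining at intensity ≥ 2+
(`pct2 + pct3`); it is invariant to how the remaining cells split between
0 and 1+. Positivity is P score ≥ 30 with an inclusive boundary; the
pre-amendment rule (≥ 10% at ≥ 1+) ships as `legacy_cutoff()`, not the
default. Intensities are ordinal ranks 0–3, "≥ 2+" means rank ≥ 2.

Patients with several samples are counted once: any positive sample makes
the patient positive, implemented as the per-patient maximum P score
(screening accepts any qualifying tissue regardless of origin). Denominators
therefore count patients by default; a `unit = "sample"` mode exists because
publications do not always state which unit a rate uses. The paired
primary/metastatic analysis takes the per-location maximum and compares the
two positivity calls per patient. Archival-time strata are half-open
intervals `[lo, hi)` with the last bin open-ended. Prevalence percentages
display as half-up integers (6/70 = 8.57 → 9%).

# Potency

Dose-response curves are fitted with a three-parameter log-logistic model
with the lower asymptote fixed at 0:

$$y = \frac{d}{1 + \exp\!\big(b(\ln x - \ln e)\big)}$$

where *d* is the upper asymptote (assay units), *e* the EC50 (molar) and
*b* the Hill slope — negative for a response rising with concentration, and
initialised at −1 accordingly. Fitting is Levenberg-Marquardt least squares
on (b, d, log10 e), with starts d₀ = max response, e₀ = concentration
nearest half-max, plus four deterministically jittered restarts (best
residual kept), tolerance 1e-10, at most 500 iterations. Constant-response
data raise a degenerate-fit error (no EC50 is identifiable); an EC50 more
than 2 log units outside the tested range is flagged extrapolated.
`fit_ll3()` returns a classed object with `coef`/`predict`/`residuals`
methods.

Per-allele potency is the arithmetic mean of log10 EC50 over converged
replicate fits. Classification against the reference allele (A\*02:01) is a
fold change on the EC50 scale: *reduced* potency iff
Δlog10 EC50 > log10(10), a strict inequality, so exactly 10-fold is still
*comparable*. Published mean log EC50 values (−7.8 for A\*02:01, −8.1 for
A\*02:02, −6.5 for A\*02:07, …) serve as simulation ground truths — raw
curves are not published — so tests check *recovery* of configured truths,
not reproduction of the table.

The simulation tests use a 13-point half-log titration spanning
10⁻¹¹–10⁻⁵ M, the standard cell-ELISA design; with Gaussian noise of
sd 0.05 on a unit-amplitude curve this design supports a median absolute
log10 EC50 recovery error below 0.05, and ten replicate curves recover the
mean within ±0.1.

# Covariate analysis

Positivity is regressed on clinical covariates by maximum-likelihood
logistic regression (IRLS via `stats::glm`), univariately (one term per
model) and multivariately (all terms jointly, i.e. adjusted). Results are
exponentiated coefficients with Wald 95% intervals on the log-odds scale —
Wald, not profile, to match the convention of reporting odds ratios with
symmetric CIs and to agree exactly with the closed-form 2×2 cross-product
estimator, which `odds_ratio_2x2()` provides as an independent check. The
reference level of a categorical covariate is its first factor level,
declared by the caller for reproducibility.

Zero cells: the 2×2 helper applies the Haldane-Anscombe +0.5 correction
with a warning; the regression instead *errors* on complete or
quasi-complete separation (detected as exploding coefficients/standard
errors, or a constant outcome) rather than silently correcting — at
screening sample sizes a separating covariate is a data problem the analyst
must see.

# The synthetic cohort generator

The generator exists so that every pipeline stage can be exercised, and its
statistical assumptions tested, without patient-level data (which is not
published). It emulates:

* **Genotypes** — each patient draws a population from a configured mix,
  then two alleles independently from that population's frequency vector
  (Hardy-Weinberg). The default five-population mix uses allele frequencies
  in the range public databases report (A\*02:01 ≈ 0.27 in European-ancestry
  populations, A\*02:02 enriched in African-ancestry, 02:03/02:06 in Asian,
  02:06 also in Hispanic populations, 02:05 rare everywhere), yielding an
  expected eligibility around 44%. Linkage and haplotype structure are
  deliberately not modelled — how specific alleles co-segregate is out of
  scope — so carrier rates follow the closed form 1 − (1 − f)², which
  `expected_eligibility()` exposes as the test oracle.
* **Ambiguity** — with configurable probability a call gains a spurious
  second candidate, constructed eligibility-discordant with probability
  0.5 so the indeterminate path is exercised; discordant spurious
  candidates turn eligible patients indeterminate, which the closed form
  accounts for with the factor 1 − ambiguity_rate/2.
* **IHC** — positivity is Bernoulli with a logistic link over tumor-type
  intercepts (defaults encode rates from 70% in synovial sarcoma down to
  9% in gastric cancer, mixed in proportions weighted like a solid-tumor
  screening population) and optional age/histology/location/archival
  coefficients (default 0). P scores are class-conditional: positives draw
  30 + 70·Beta(1.2, 1.5), negatives are zero-inflated (70% exact zeros)
  with the rest 30·Beta(0.6, 2.5) — supports chosen so the positivity call
  reproduces the Bernoulli draw exactly. The positive mass splits 60/40
  between 2+ and 3+ and the remainder 70/30 between 0 and 1+; the split is
  arbitrary, documented, and irrelevant to the P score by construction.
* **Dose-response** — LL3 mean curves plus Gaussian noise truncated at 0.

All randomness flows from one seed: the master seed seeds a draw of 32-bit
sub-seeds, one per consumer stream (population assignment, allele draws,
ambiguity, IHC covariates, IHC outcomes), so adding a stream never perturbs
the ones before it and every run is reproducible.

What passing tests do **not** show about real data: real genotype calls
have linkage, population substructure and allele-specific ambiguity
patterns; real P scores are not a two-component Beta mixture; real
covariates are correlated with indication. The generator validates the
*analysis machinery* — parsing, rules, estimators, gating — not the
epidemiology.

# Numerical and design choices

* **Rounding** is half-up (never banker's) and applied only at display:
  one decimal for eligibility percentages, two for concordance bounds,
  integers for prevalence.
* **Percent arithmetic** from published group counts (e.g. 2,959/6,606 =
  44.8%) is reproduced by building cohorts with those counts by
  construction and running the ordinary summary operations over them.
* **Patients carrying both an inclusion and an exclusion allele** are
  reported ineligible and are counted inside the ineligible pool; the
  published totals are consistent with this reading.
* **Ambiguity unanimity** (rather than best-candidate or
  frequency-weighted resolution) was chosen because the package cannot see
  the sequencing evidence that would justify anything sharper.
* **Problem sizes** used by the test-suite simulations: 10,000-patient
  cohorts for end-to-end rate checks (3-standard-error tolerance), 2,000–
  4,000 for generator calibration checks, 200 replicates of n = 500 for
  odds-ratio CI coverage, 100 curves for EC50 recovery — sizes at which
  Monte-Carlo error is small relative to the tolerances being asserted.

# Known limitations

* The P-group subset shipped covers the alleles the screening rules name
  plus common HLA-A alleles; analyses of unusual cohorts should load a full
  IMGT table.
* Eligibility is HLA-A-locus-only by design; the parser accepts other loci
  but the rules do not reason about them.
* The regression stage offers no model selection, interactions or survival
  endpoints; it reproduces the reported odds-ratio methodology only.
* Indeterminate genotypes are reported, not resolved; resolving them
  requires assay-level evidence outside the package's inputs.
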