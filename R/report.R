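#' Default screening configuration
#'
#' Assembles the configuration consumed by [run_screen()]: input CSV paths,
#' eligibility rules, P-group table path, positivity cutoff, grouping keys,
#' concordance settings and the reference allele for potency classification.
#' Any field may be overridden; `inputs$hla_typing` is the only mandatory
#' entry (`ihc`, `concordance` and `doseresponse` stages run only when their
#' input is present).
#'
#' @param ... Named overrides merged over the defaults (one level deep for
#'   nested lists).
#' @return A named list.
#' @export
screen_config <- function(...) {
  defaults <- list(
    inputs = list(hla_typing = NULL, ihc = NULL, concordance = NULL,
                  doseresponse = NULL),
    pgroup_table = NULL,
    rules = list(inclusion_groups = c("02:01P", "02:02P", "02:03P", "02:06P"),
                 exclusion_groups = "02:05P",
                 count_null_alleles = FALSE),
    cutoff = list(min_pscore = 30, min_intensity = 2),
    group_keys = "population",
    prevalence_keys = c("tumor_type", "histology", "tissue_location"),
    archival_breaks = c(0, 1, 5),
    covariate_terms = c("patient_age", "histology", "tissue_location"),
    alpha = 0.05,
    threshold = 0.95,
    reference_allele = "A*02:01",
    fold_threshold = 10,
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) defaults[[nm]][[k]] <- over[[nm]][[k]]
    } else defaults[[nm]] <- over[[nm]]
  }
  defaults
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    raw <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(screen_config, raw)
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  config
}

.read_csv_checked <- function(path, required, stage) {
  if (!file.exists(path))
    stop(stage, " input file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(dat))
  if (length(miss) > 0L)
    stop(stage, " input ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dat
}

#' Run the end-to-end screening pipeline
#'
#' Mirrors the gated clinical screening flow: HLA typing is assessed for every
#' patient; MAGE-A4 IHC is evaluated only in HLA-eligible patients; combined
#' eligibility requires both (HLA-eligible AND MAGE-A4-positive). Optional
#' typing-concordance and dose-response stages run when their inputs are
#' configured.
#'
#' @param config A configuration list from [screen_config()], or a path to a
#'   JSON/YAML file holding its fields.
#' @return An object of class `screening_report` with sections `eligibility`
#'   (summary table), `patients` (per-patient decisions), `ihc` (prevalence,
#'   archival and location-agreement tables), `concordance`, `potency`,
#'   `covariates`, `counts` (per-stage totals) and `provenance`.
#' @export
run_screen <- function(config) {
  config <- .load_config(config)
  if (is.null(config$inputs$hla_typing))
    stop("config$inputs$hla_typing is required", call. = FALSE)

  table <- if (is.null(config$pgroup_table)) default_pgroup_table() else
    read_pgroup_table(config$pgroup_table)
  rules <- default_rules(
    inclusion_groups = config$rules$inclusion_groups,
    exclusion_groups = config$rules$exclusion_groups,
    count_null_alleles = isTRUE(config$rules$count_null_alleles))
  cutoff <- positivity_cutoff(config$cutoff$min_pscore, config$cutoff$min_intensity)

  # --- HLA stage -----------------------------------------------------------
  typing <- .read_csv_checked(config$inputs$hla_typing,
                              c("patient_id", "genotype"), "HLA typing")
  group_keys <- intersect(config$group_keys, names(typing))
  elig_summary <- summarize_eligibility(typing, rules, table,
                                        group_keys = if (length(group_keys)) group_keys)
  res <- lapply(typing$genotype, function(g)
    assess_genotype(parse_genotype(g), rules, table))
  patients <- data.frame(
    patient_id = typing$patient_id,
    hla_status = vapply(res, `[[`, "", "status"),
    contribution_category = vapply(res, `[[`, "", "contribution_category"),
    stringsAsFactors = FALSE)
  eligible_ids <- patients$patient_id[patients$hla_status == "eligible"]
  message(sprintf("HLA stage: %d screened, %d eligible, %d indeterminate",
                  nrow(patients), length(eligible_ids),
                  sum(patients$hla_status == "indeterminate")))

  # --- IHC stage (HLA-eligible patients only) ------------------------------
  ihc_section <- NULL
  mage_positive_ids <- character()
  ihc_note <- NULL
  if (!is.null(config$inputs$ihc)) {
    ihc <- .read_csv_checked(config$inputs$ihc,
                             c("sample_id", "patient_id",
                               "pct0", "pct1", "pct2", "pct3"), "IHC")
    ihc <- ihc[ihc$patient_id %in% eligible_ids, , drop = FALSE]
    if (nrow(ihc) == 0L) {
      ihc_note <- "no HLA-eligible patients with IHC samples; IHC stage skipped"
      message("IHC stage: ", ihc_note)
    } else {
      validate_staining(ihc)
      per_patient <- .collapse_patients(ihc)
      mage_positive_ids <- per_patient$patient_id[is_positive(per_patient, cutoff)]
      prev_keys <- intersect(config$prevalence_keys, names(ihc))
      prevalence <- lapply(prev_keys, function(k) prevalence_by(ihc, k, cutoff))
      names(prevalence) <- prev_keys
      archival <- if ("archival_years" %in% names(ihc))
        archival_strata(ihc, config$archival_breaks, cutoff)
      agreement <- if ("tissue_location" %in% names(ihc))
        pairwise_location_agreement(ihc, cutoff)
      ihc_section <- list(prevalence = prevalence, archival = archival,
                          location_agreement = agreement)
      message(sprintf("IHC stage: %d evaluable patients, %d MAGE-A4 positive",
                      nrow(per_patient), length(mage_positive_ids)))
    }
  }

  # --- covariate stage -----------------------------------------------------
  covariates <- NULL
  if (!is.null(config$inputs$ihc) && is.null(ihc_note)) {
    terms <- intersect(config$covariate_terms, names(per_patient))
    if (length(terms) > 0L) {
      tab <- per_patient
      tab$positive <- is_positive(per_patient, cutoff)
      covariates <- tryCatch(
        rbind(fit_logistic(tab, "positive", terms, mode = "univariate"),
              fit_logistic(tab, "positive", terms, mode = "multivariate")),
        error = function(e) paste("covariate analysis not estimable:",
                                  conditionMessage(e)))
    }
  }

  # --- concordance stage ---------------------------------------------------
  concordance <- NULL
  if (!is.null(config$inputs$concordance)) {
    conc <- .read_csv_checked(config$inputs$concordance,
                              c("sample_id", "reference_genotype",
                                "assay_genotype"), "concordance")
    concordance <- summarize_concordance(conc, alpha = config$alpha,
                                         threshold = config$threshold)
  }

  # --- potency stage -------------------------------------------------------
  potency <- NULL
  if (!is.null(config$inputs$doseresponse)) {
    dr <- .read_csv_checked(config$inputs$doseresponse,
                            c("allele", "replicate", "concentration_M",
                              "response"), "dose-response")
    potency <- potency_table(dr, reference = config$reference_allele,
                             fold_threshold = config$fold_threshold)
  }

  combined <- intersect(eligible_ids, mage_positive_ids)
  patients$mage_a4_positive <- patients$patient_id %in% mage_positive_ids
  patients$combined_eligible <- patients$patient_id %in% combined

  input_files <- Filter(Negate(is.null), config$inputs)
  provenance <- list(
    inputs = lapply(input_files, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    pgroup_table = table$source,
    config_hash = .config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("magescreen")))

  structure(
    list(eligibility = elig_summary,
         patients = patients,
         ihc = ihc_section,
         ihc_note = ihc_note,
         concordance = concordance,
         potency = potency,
         covariates = covariates,
         counts = list(screened = nrow(patients),
                       hla_eligible = length(eligible_ids),
                       indeterminate = sum(patients$hla_status == "indeterminate"),
                       ihc_evaluable = if (is.null(ihc_section)) 0L else
                         nrow(per_patient),
                       mage_a4_positive = length(mage_positive_ids),
                       combined_eligible = length(combined)),
         provenance = provenance),
    class = "screening_report")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[sort(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat(sprintf("  HLA: %d screened, %d eligible (%.1f%%), %d indeterminate\n",
              x$counts$screened, x$counts$hla_eligible,
              round_half_up(100 * x$counts$hla_eligible / x$counts$screened, 1),
              x$counts$indeterminate))
  if (!is.null(x$ihc)) {
    cat(sprintf("  MAGE-A4: %d evaluable, %d positive; combined eligible %d\n",
                x$counts$ihc_evaluable, x$counts$mage_a4_positive,
                x$counts$combined_eligible))
  } else if (!is.null(x$ihc_note)) cat("  IHC: ", x$ihc_note, "\n", sep = "")
  if (!is.null(x$concordance))
    cat(sprintf("  concordance: %d/%d, CP %.2f%%, Wilson %.2f%%\n",
                x$concordance$concordant, x$concordance$n,
                100 * x$concordance$cp_lower, 100 * x$concordance$wilson_lower))
  if (!is.null(x$potency))
    cat("  potency: ", nrow(x$potency), " alleles classified\n", sep = "")
  invisible(x)
}

# fixed-order plain-list view of a report, so rendering is byte-stable
.report_as_list <- function(report) {
  df2l <- function(d) if (is.data.frame(d)) unclass(as.data.frame(d)) else d
  list(
    counts = report$counts,
    eligibility = df2l(report$eligibility),
    ihc = if (!is.null(report$ihc)) list(
      prevalence = lapply(report$ihc$prevalence, df2l),
      archival = df2l(report$ihc$archival),
      location_agreement = report$ihc$location_agreement),
    ihc_note = report$ihc_note,
    concordance = if (!is.null(report$concordance)) unclass(report$concordance),
    potency = df2l(report$potency),
    covariates = df2l(report$covariates),
    patients = df2l(report$patients),
    provenance = report$provenance)
}

#' Render a screening report to files
#'
#' Deterministic rendering: a fixed key order and render-time-only rounding
#' make repeated renderings of the same report byte-identical.
#'
#' @param report A `screening_report`.
#' @param format `"json"` (single file), `"csv"` (one CSV per tabular
#'   section plus a JSON remainder) or `"text"` (human-readable summary).
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(report, format = c("json", "csv", "text"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (format == "json") {
    path <- file.path(dir, "screening_report.json")
    jsonlite::write_json(.report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    written <- path
  } else if (format == "csv") {
    tabs <- list(eligibility = report$eligibility,
                 patients = report$patients)
    if (!is.null(report$ihc))
      for (k in names(report$ihc$prevalence))
        tabs[[paste0("prevalence_", k)]] <- report$ihc$prevalence[[k]]
    if (!is.null(report$ihc$archival)) tabs$archival <- report$ihc$archival
    if (is.data.frame(report$potency)) tabs$potency <- report$potency
    if (is.data.frame(report$covariates)) tabs$covariates <- report$covariates
    for (nm in names(tabs)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], path, row.names = FALSE)
      written <- c(written, path)
    }
    rest <- file.path(dir, "summary.json")
    jsonlite::write_json(list(counts = report$counts,
                              location_agreement = report$ihc$location_agreement,
                              concordance = if (!is.null(report$concordance))
                                unclass(report$concordance),
                              provenance = report$provenance),
                         rest, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    written <- c(written, rest)
  } else {
    path <- file.path(dir, "screening_report.txt")
    con <- file(path, open = "wt")
    sink(con)
    on.exit({ sink(); close(con) })
    print(report)
    cat("\nEligibility by group\n")
    el <- report$eligibility
    el$rate <- NULL
    print(el, row.names = FALSE)
    if (!is.null(report$ihc)) {
      for (k in names(report$ihc$prevalence)) {
        cat("\nMAGE-A4 prevalence by ", k, "\n", sep = "")
        pv <- report$ihc$prevalence[[k]]
        pv$rate <- NULL
        print(pv, row.names = FALSE)
      }
    }
    written <- path
  }
  invisible(written)
}
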