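#' Parse an HLA allele name
#'
#' Parses a WHO-nomenclature HLA allele string such as `"A*02:01"`,
#' `"HLA-A*02:135"` or `"A*02:01:01:02N"` into its components. High-resolution
#' (two-field) designation is the minimum accepted, since inclusion, exclusion
#' and neutral A*02 alleles are only distinguishable at the protein level.
#'
#' @param text Allele string of the form `LOCUS*F1:F2[:F3[:F4]][suffix]`, with
#'   an optional leading `"HLA-"`. The expression suffix, when present, is a
#'   single character among `N`, `L`, `S`, `C`, `A`, `Q` attached to the last
#'   field.
#' @return An object of class `hla_allele` with components `locus`, `fields`
#'   (character vector, 2-4 elements), `suffix` (`NA_character_` when absent)
#'   and `raw` (the input string).
#' @examples
#' a <- parse_allele("A*02:01:01:02N")
#' a$suffix
#' two_field(a)
#' @seealso [parse_genotype()], [two_field()], [format.hla_allele()]
#' @export
parse_allele <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("allele must be a single non-empty string", call. = FALSE)
  raw <- text
  s <- sub("^HLA-", "", trimws(text))
  m <- regexec("^([A-Za-z][A-Za-z0-9]*)\\*([0-9:]+)([NLSCAQ]?)$", s)
  parts <- regmatches(s, m)[[1L]]
  if (length(parts) == 0L)
    stop("malformed allele string: '", text, "'", call. = FALSE)
  locus <- parts[2L]
  fields <- strsplit(parts[3L], ":", fixed = TRUE)[[1L]]
  if (length(fields) < 2L)
    stop("allele '", text, "' has fewer than two fields; high-resolution ",
         "(two-field) typing is required", call. = FALSE)
  if (length(fields) > 4L)
    stop("allele '", text, "' has more than four fields", call. = FALSE)
  if (any(!nzchar(fields)) || any(!grepl("^[0-9]+$", fields)))
    stop("allele '", text, "' contains a non-numeric field token", call. = FALSE)
  suffix <- if (nzchar(parts[4L])) parts[4L] else NA_character_
  structure(
    list(locus = locus, fields = fields, suffix = suffix, raw = raw),
    class = "hla_allele"
  )
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$locus, "*", paste(x$fields, collapse = ":"),
         if (!is.na(x$suffix)) x$suffix else "")
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Two-field projection of an allele
#'
#' Truncates an allele to its first two fields (the protein-level designation),
#' dropping any expression suffix. This is the resolution at which P-group
#' membership and eligibility are decided.
#'
#' @param allele An `hla_allele` object.
#' @return A string such as `"A*02:01"`.
#' @export
two_field <- function(allele) {
  stopifnot(inherits(allele, "hla_allele"))
  paste0(allele$locus, "*", allele$fields[1L], ":", allele$fields[2L])
}

#' Parse a genotype-list string
#'
#' Parses a GL-string subset for one locus: `'+'` joins the two alleles of one
#' candidate genotype and `'|'` separates alternative candidate genotypes
#' (typing ambiguity). Phase operators are not part of the dialect.
#'
#' @param text Genotype string, e.g. `"A*02:01+A*68:01|A*02:135+A*69:02"`.
#' @param locus Expected locus; every allele must carry it. Default `"A"`.
#' @return An object of class `hla_genotype`: a list with `candidates` (a list
#'   of length-2 lists of `hla_allele`), `ambiguous` (`TRUE` iff more than one
#'   candidate) and `raw`.
#' @examples
#' g <- parse_genotype("A*02:01+A*68:01|A*02:135+A*69:02")
#' g$ambiguous
#' @export
parse_genotype <- function(text, locus = "A") {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("genotype string is empty", call. = FALSE)
  cand_strings <- strsplit(trimws(text), "|", fixed = TRUE)[[1L]]
  candidates <- lapply(cand_strings, function(cs) {
    toks <- strsplit(trimws(cs), "+", fixed = TRUE)[[1L]]
    if (length(toks) != 2L)
      stop("genotype candidate '", cs, "' must contain exactly two alleles",
           call. = FALSE)
    lapply(trimws(toks), parse_allele)
  })
  loci <- unlist(lapply(candidates, function(p) c(p[[1L]]$locus, p[[2L]]$locus)))
  if (any(loci != locus))
    stop("genotype '", text, "' mixes loci or is not at locus ", locus,
         call. = FALSE)
  structure(
    list(candidates = candidates, ambiguous = length(candidates) > 1L, raw = text),
    class = "hla_genotype"
  )
}

#' @export
format.hla_genotype <- function(x, ...) {
  paste(vapply(x$candidates,
               function(p) paste(vapply(p, format, ""), collapse = "+"), ""),
        collapse = "|")
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat("<hla_genotype> ", format(x),
      if (x$ambiguous) paste0("  [", length(x$candidates), " candidates]"),
      "\n", sep = "")
  invisible(x)
}
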