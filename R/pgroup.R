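#' P-group equivalence tables
#'
#' Alleles sharing an identical protein sequence over the peptide-binding
#' alpha-1/alpha-2 domains form a P group and are functionally interchangeable
#' for peptide presentation, so eligibility rules are expressed in P-group
#' identifiers (e.g. `"02:01P"`). A `pgroup_table` maps allele names to their
#' P group; alleles absent from the table fall back to a singleton group named
#' after their two-field projection.
#'
#' `read_pgroup_table()` reads the IMGT/HLA `hla_nom_p.txt` dialect:
#' semicolon-separated records `locus*;allele1/allele2/...;group`, with `#`
#' comment lines ignored. Records whose group field is empty describe alleles
#' outside any multi-allele P group; they map to their own two-field singleton.
#'
#' @param path Path to a file in the `hla_nom_p.txt` dialect.
#' @param source Short description stored with the table.
#' @return An object of class `pgroup_table`.
#' @examples
#' tbl <- default_pgroup_table()
#' p_group(parse_allele("A*02:09"), tbl)
#' @name pgroup_table
NULL

#' @rdname pgroup_table
#' @export
read_pgroup_table <- function(path, source = path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  map <- new.env(parent = emptyenv())
  for (ln in lines) {
    parts <- strsplit(ln, ";", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed P-group record: '", ln, "'", call. = FALSE)
    locus <- sub("\\*$", "", parts[1L])
    alleles <- strsplit(parts[2L], "/", fixed = TRUE)[[1L]]
    group <- if (length(parts) >= 3L) trimws(parts[3L]) else ""
    for (al in alleles) {
      al <- trimws(al)
      if (!nzchar(al)) next
      grp <- if (nzchar(group)) group else
        paste0(sub("^([0-9]+:[0-9]+).*$", "\\1", al), "P")
      key <- paste0(locus, "*", al)
      # full-name key always wins; two-field key only if unclaimed, so deep
      # listings of the same protein do not clobber one another
      assign(key, grp, envir = map)
      tf <- paste0(locus, "*", sub("^([0-9]+:[0-9]+).*$", "\\1", al))
      if (!exists(tf, envir = map, inherits = FALSE))
        assign(tf, grp, envir = map)
    }
  }
  structure(list(map = map, source = source), class = "pgroup_table")
}

#' @rdname pgroup_table
#' @export
default_pgroup_table <- function() {
  path <- system.file("extdata", "hla_nom_p_subset.txt", package = "magescreen",
                      mustWork = TRUE)
  read_pgroup_table(path, source = "packaged subset of the IMGT hla_nom_p dialect")
}

#' @export
print.pgroup_table <- function(x, ...) {
  cat("<pgroup_table> ", length(ls(x$map)), " allele keys (", x$source, ")\n",
      sep = "")
  invisible(x)
}

#' Resolve the P group of an allele
#'
#' Total function: listed alleles return their table group; unlisted alleles
#' return the singleton group named after their two-field projection (rare
#' alleles occur in screening data and are neutral unless the table says
#' otherwise).
#'
#' @param allele An `hla_allele` object.
#' @param table A `pgroup_table`.
#' @return A P-group identifier string ending in `"P"`, e.g. `"02:01P"`.
#' @export
p_group <- function(allele, table) {
  stopifnot(inherits(allele, "hla_allele"), inherits(table, "pgroup_table"))
  name <- paste0(allele$locus, "*", paste(allele$fields, collapse = ":"),
                 if (!is.na(allele$suffix)) allele$suffix else "")
  # most-specific first: full name, then truncations down to two fields
  keys <- name
  for (k in seq(length(allele$fields), 2L)) {
    keys <- c(keys, paste0(allele$locus, "*",
                           paste(allele$fields[seq_len(k)], collapse = ":")))
  }
  for (key in unique(keys)) {
    if (exists(key, envir = table$map, inherits = FALSE))
      return(get(key, envir = table$map, inherits = FALSE))
  }
  paste0(allele$fields[1L], ":", allele$fields[2L], "P")
}
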