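#' Per-read assignment tables
#'
#' A `read_assignments` object records, for one classifier applied to one
#' sample, the species-level taxid each read was assigned to. It is a data
#' frame with columns `read_id` (unique character) and `taxid` (species-rank
#' integer taxid, or `NA` for a read the classifier did not assign), plus
#' `sample_id` and `classifier_id` attributes.
#'
#' @param read_id character vector of unique read identifiers.
#' @param taxid integer vector (NA = not assigned), same length.
#' @param sample_id sample label.
#' @param classifier_id classifier label.
#' @return A `read_assignments` object.
#' @export
read_assignments <- function(read_id, taxid, sample_id = "sample",
                             classifier_id = "classifier") {
  read_id <- as.character(read_id)
  taxid <- as.integer(taxid)
  stopifnot(length(read_id) == length(taxid))
  dup <- read_id[duplicated(read_id)]
  if (length(dup) > 0) {
    stop("duplicate read id ", dup[1], call. = FALSE)
  }
  if (any(!is.na(taxid) & taxid <= 0L)) {
    stop("taxids must be positive integers or NA", call. = FALSE)
  }
  out <- data.frame(read_id = read_id, taxid = taxid,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "classifier_id") <- as.character(classifier_id)
  class(out) <- c("read_assignments", "data.frame")
  out
}

#' @export
print.read_assignments <- function(x, ...) {
  cat("<read_assignments> sample=", attr(x, "sample_id"),
      " classifier=", attr(x, "classifier_id"),
      ": ", nrow(x), " reads, ", sum(!is.na(x$taxid)), " assigned\n",
      sep = "")
  invisible(x)
}

#' Number of assigned reads in a table
#' @param x a [read_assignments] object.
#' @return Integer count of reads with a non-`NA` species.
#' @export
n_assigned <- function(x) {
  stopifnot(inherits(x, "read_assignments"))
  sum(!is.na(x$taxid))
}

# strsplit drops trailing empty fields, but e.g. unclassified Kraken2 lines
# legitimately end in a tab with an empty k-mer column; a sentinel appended
# before the split preserves them.
split_tsv_lines <- function(file, n_fields, what) {
  lines <- read_nonempty_lines(file)
  if (length(lines) == 0) return(list())
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  nf <- lengths(fields)
  bad <- nf != n_fields
  if (any(bad)) {
    stop(what, " line ", which(bad)[1], ": expected ", n_fields,
         " tab-separated fields, found ", nf[which(bad)[1]], call. = FALSE)
  }
  fields
}

parse_taxid_field <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) | v < 0L
  if (any(bad)) {
    stop(what, " line ", which(bad)[1], ": taxid field '", x[which(bad)[1]],
         "' is not a non-negative integer", call. = FALSE)
  }
  v
}

#' Parse Kraken2 standard per-read output
#'
#' The Kraken2 `--output` format has five tab-separated fields per read:
#' classification status (`C`/`U`), read id, taxid, sequence length and the
#' LCA k-mer string. `U` lines and taxids that do not resolve to species rank
#' become not-assigned; classified taxids are passed through
#' [resolve_to_species()], so strain-level hits are promoted and
#' above-species hits dropped.
#'
#' @param file path or connection to Kraken2 per-read output.
#' @param taxonomy a [taxonomy] object.
#' @param sample_id,classifier_id labels for the resulting table.
#' @return A [read_assignments] object with one entry per input line.
#' @export
read_kraken2_assignments <- function(file, taxonomy, sample_id = "sample",
                                     classifier_id = "kraken2") {
  fields <- split_tsv_lines(file, 5L, "kraken2 output")
  if (length(fields) == 0) {
    return(read_assignments(character(0), integer(0), sample_id, classifier_id))
  }
  status <- vapply(fields, `[[`, "", 1L)
  bad <- !status %in% c("C", "U")
  if (any(bad)) {
    stop("kraken2 output line ", which(bad)[1], ": status must be C or U",
         call. = FALSE)
  }
  read_id <- vapply(fields, `[[`, "", 2L)
  taxid <- parse_taxid_field(vapply(fields, `[[`, "", 3L), "kraken2 output")
  taxid[status == "U"] <- NA_integer_
  read_assignments(read_id, resolve_to_species(taxid, taxonomy),
                   sample_id, classifier_id)
}

#' Parse MEGAN6 rma2info read-to-class output
#'
#' `rma2info -r2c Taxonomy -n False` emits two tab-separated fields per
#' assigned read: read id and taxid. Reads MEGAN did not assign are absent
#' from the file and therefore absent from the returned table; downstream
#' merging treats absent reads as not-assigned.
#'
#' @inheritParams read_kraken2_assignments
#' @return A [read_assignments] object.
#' @export
read_megan_r2c <- function(file, taxonomy, sample_id = "sample",
                           classifier_id = "megan") {
  fields <- split_tsv_lines(file, 2L, "megan r2c")
  if (length(fields) == 0) {
    return(read_assignments(character(0), integer(0), sample_id, classifier_id))
  }
  read_id <- vapply(fields, `[[`, "", 1L)
  taxid <- parse_taxid_field(vapply(fields, `[[`, "", 2L), "megan r2c")
  read_assignments(read_id, resolve_to_species(taxid, taxonomy),
                   sample_id, classifier_id)
}

#' Read or write the canonical two-column assignment dialect
#'
#' The package's own on-disk dialect: a header line `read_id<TAB>taxid`, then
#' one line per read with the literal string `NA` for a not-assigned read.
#' [write_canonical_assignments()] and [read_canonical_assignments()] round
#' trip a [read_assignments] table exactly.
#'
#' @param file path or connection.
#' @param taxonomy optional [taxonomy]; when supplied, taxids are re-resolved
#'   to species rank on read.
#' @inheritParams read_kraken2_assignments
#' @return [read_canonical_assignments()] returns a [read_assignments].
#' @export
read_canonical_assignments <- function(file, taxonomy = NULL,
                                       sample_id = "sample",
                                       classifier_id = "classifier") {
  lines <- read_nonempty_lines(file)
  if (length(lines) == 0 || lines[1] != "read_id\ttaxid") {
    stop("canonical assignment file must start with header 'read_id\\ttaxid'",
         call. = FALSE)
  }
  lines <- lines[-1]
  if (length(lines) == 0) {
    return(read_assignments(character(0), integer(0), sample_id, classifier_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop("canonical assignment line ", which(nf != 2L)[1] + 1L,
         ": expected 2 tab-separated fields", call. = FALSE)
  }
  read_id <- vapply(fields, `[[`, "", 1L)
  raw <- vapply(fields, `[[`, "", 2L)
  taxid <- rep(NA_integer_, length(raw))
  has <- raw != "NA"
  taxid[has] <- parse_taxid_field(raw[has], "canonical assignment")
  if (!is.null(taxonomy)) taxid <- resolve_to_species(taxid, taxonomy)
  read_assignments(read_id, taxid, sample_id, classifier_id)
}

#' @rdname read_canonical_assignments
#' @param x a [read_assignments] object to write.
#' @export
write_canonical_assignments <- function(x, file) {
  stopifnot(inherits(x, "read_assignments"))
  taxid <- ifelse(is.na(x$taxid), "NA", as.character(x$taxid))
  writeLines(c("read_id\ttaxid", paste(x$read_id, taxid, sep = "\t")), file)
  invisible(x)
}

#' Parse species-count exports from MEGAN or Kraken2
#'
#' Two dialects are supported. `megan_c2c`: the two-column
#' `rma2info -c2c Taxonomy` export (taxid or scientific name, count); rows
#' whose taxon is not species rank in the taxonomy are dropped. For
#' rank filtering the taxonomy's rank column is authoritative, not any rank
#' flag the classifier printed. `kraken2_report`: the standard six-column
#' report (percent, clade count, direct count, rank code, taxid, name); rows
#' with rank code `S` are kept with their direct counts.
#'
#' @param file path or connection.
#' @param dialect `"megan_c2c"` or `"kraken2_report"`.
#' @param taxonomy a [taxonomy] object.
#' @param sample_id sample label.
#' @return A data frame (`species_counts`) with columns `taxid`, `count` and a
#'   `sample_id` attribute; species-level rows only.
#' @export
read_species_counts <- function(file, dialect = c("megan_c2c", "kraken2_report"),
                                taxonomy, sample_id = "sample") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(taxonomy, "taxonomy"))
  if (dialect == "megan_c2c") {
    fields <- split_tsv_lines(file, 2L, "megan c2c")
    if (length(fields) == 0) return(species_counts(integer(0), integer(0), sample_id))
    key <- vapply(fields, `[[`, "", 1L)
    count <- parse_taxid_field(vapply(fields, `[[`, "", 2L), "megan c2c")
    taxid <- suppressWarnings(as.integer(key))
    by_name <- is.na(taxid)
    taxid[by_name] <- taxonomy$taxid[match(key[by_name], taxonomy$name)]
    rank <- taxonomy$rank[match(taxid, taxonomy$taxid)]
    keep <- !is.na(rank) & rank == "species"
    return(species_counts(taxid[keep], count[keep], sample_id))
  }
  # kraken2_report: name column may itself contain indentation spaces but no
  # tabs, so a strict 6-field split applies.
  fields <- split_tsv_lines(file, 6L, "kraken2 report")
  if (length(fields) == 0) return(species_counts(integer(0), integer(0), sample_id))
  rank_code <- vapply(fields, `[[`, "", 4L)
  keep <- rank_code == "S"
  taxid <- parse_taxid_field(vapply(fields, `[[`, "", 5L), "kraken2 report")[keep]
  count <- parse_taxid_field(vapply(fields, `[[`, "", 3L), "kraken2 report")[keep]
  species_counts(taxid, count, sample_id)
}

species_counts <- function(taxid, count, sample_id = "sample") {
  out <- data.frame(taxid = as.integer(taxid), count = as.integer(count),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("species_counts", "data.frame")
  out
}

#' Write a species profile as a tab-delimited table
#'
#' Columns: species taxid, species name (taxid as string when no taxonomy is
#' given), read count, relative abundance printed with 6 significant digits.
#' Rows are ordered by descending count with ascending taxid as tie-break, so
#' output is deterministic and diffable.
#'
#' @param profile a [species_profile] object.
#' @param file path or connection.
#' @param taxonomy optional [taxonomy] for the name column.
#' @export
write_profile <- function(profile, file, taxonomy = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  ord <- order(-profile$count, profile$taxid)
  p <- profile[ord, , drop = FALSE]
  name <- if (is.null(taxonomy)) as.character(p$taxid) else {
    nm <- taxon_names(p$taxid, taxonomy)
    ifelse(is.na(nm), as.character(p$taxid), nm)
  }
  writeLines(c(
    "taxid\tname\tcount\tabundance",
    if (nrow(p) > 0) paste(p$taxid, name, p$count,
                           sprintf("%.6g", p$abundance),
                           sep = "\t")
  ), file)
  invisible(profile)
}
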