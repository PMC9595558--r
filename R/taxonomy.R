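#' Taxonomy tables and species-rank resolution
#'
#' A `taxonomy` object is a validated data frame of taxon nodes with columns
#' `taxid` (positive integer), `parent` (taxid of the parent node), `rank`
#' (free string; `"species"` is the rank that matters downstream) and `name`.
#' A node is a root when its parent is itself or taxid 1. Every other node's
#' parent must be present, parent chains must be acyclic, and taxids must be
#' unique.
#'
#' @name taxonomy
NULL

#' Construct and validate a taxonomy
#'
#' @param nodes data frame with columns `taxid`, `parent`, `rank`, `name`.
#' @return A `taxonomy` object (data frame with class `"taxonomy"`).
#' @export
taxonomy <- function(nodes) {
  required <- c("taxid", "parent", "rank", "name")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    stop("taxonomy requires columns taxid, parent, rank, name", call. = FALSE)
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$taxid <- as_taxid(nodes$taxid, "taxid")
  nodes$parent <- as_taxid(nodes$parent, "parent")
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)

  dup <- nodes$taxid[duplicated(nodes$taxid)]
  if (length(dup) > 0) {
    stop("duplicate taxid ", dup[1], call. = FALSE)
  }
  is_root <- nodes$parent == nodes$taxid | nodes$parent == 1L
  missing_parent <- !is_root & !(nodes$parent %in% nodes$taxid)
  if (any(missing_parent)) {
    bad <- nodes[missing_parent, ][1, ]
    stop("unknown parent ", bad$parent, " for taxid ", bad$taxid, call. = FALSE)
  }
  check_acyclic(nodes)

  rownames(nodes) <- NULL
  class(nodes) <- c("taxonomy", "data.frame")
  nodes
}

as_taxid <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v) || any(v < 0L)) {
    stop("column ", what, " must contain non-negative integer taxids",
         call. = FALSE)
  }
  v
}

# Walk every parent chain; a chain that revisits a node without reaching a
# root is a cycle. Tables are small, so the O(n * depth) walk is fine.
check_acyclic <- function(nodes) {
  parent_of <- nodes$parent
  names(parent_of) <- as.character(nodes$taxid)
  for (start in nodes$taxid) {
    seen <- character(0)
    cur <- start
    repeat {
      key <- as.character(cur)
      par <- parent_of[[key]]
      if (is.null(par) || par == cur || par == 1L) break
      if (key %in% seen) {
        stop("cycle in taxonomy involving taxid ", cur, call. = FALSE)
      }
      seen <- c(seen, key)
      cur <- par
    }
  }
  invisible(nodes)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x), " nodes, ",
      sum(x$rank == "species"), " species\n", sep = "")
  NextMethod()
}

#' Read a taxonomy from a tab-delimited table
#'
#' Expects four tab-separated columns: taxid, parent taxid, rank, name. A
#' header line is detected (first field not an integer) and skipped.
#'
#' @param file path or connection to a tab-delimited text source.
#' @return A validated [taxonomy] object.
#' @export
read_taxonomy <- function(file) {
  lines <- read_nonempty_lines(file)
  if (length(lines) > 0) {
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][1]
    if (is.na(suppressWarnings(as.integer(first)))) lines <- lines[-1]
  }
  if (length(lines) == 0) {
    return(taxonomy(data.frame(taxid = integer(0), parent = integer(0),
                               rank = character(0), name = character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("taxonomy line ", which(nf < 4L)[1], ": expected 4 tab-separated ",
         "columns (taxid, parent, rank, name)", call. = FALSE)
  }
  taxonomy(data.frame(
    taxid  = vapply(fields, `[[`, "", 1L),
    parent = vapply(fields, `[[`, "", 2L),
    rank   = vapply(fields, `[[`, "", 3L),
    name   = vapply(fields, `[[`, "", 4L),
    stringsAsFactors = FALSE
  ))
}

#' Read an NCBI-style nodes.dmp / names.dmp pair
#'
#' Convenience reader for the `"\t|\t"`-separated dump dialect used by the
#' NCBI taxonomy distribution. Only the taxid, parent and rank fields of
#' `nodes.dmp` and the `"scientific name"` rows of `names.dmp` are used.
#'
#' @param nodes_file path to a `nodes.dmp`-dialect file.
#' @param names_file optional path to a `names.dmp`-dialect file; when `NULL`
#'   node names default to the taxid as a string.
#' @return A validated [taxonomy] object.
#' @export
read_ncbi_taxonomy <- function(nodes_file, names_file = NULL) {
  split_dmp <- function(lines) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  nf <- split_dmp(read_nonempty_lines(nodes_file))
  nodes <- data.frame(
    taxid  = vapply(nf, `[[`, "", 1L),
    parent = vapply(nf, `[[`, "", 2L),
    rank   = vapply(nf, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  nodes$name <- nodes$taxid
  if (!is.null(names_file)) {
    mf <- split_dmp(read_nonempty_lines(names_file))
    cls <- vapply(mf, function(f) if (length(f) >= 4L) f[[4L]] else "", "")
    sci <- mf[cls == "scientific name"]
    nm <- vapply(sci, `[[`, "", 2L)
    names(nm) <- vapply(sci, `[[`, "", 1L)
    hit <- nodes$taxid %in% names(nm)
    nodes$name[hit] <- unname(nm[nodes$taxid[hit]])
  }
  taxonomy(nodes)
}

#' Resolve taxon identifiers to species rank
#'
#' Walks each taxon's ancestor chain (starting at the taxon itself) and
#' returns the first node whose rank is exactly `"species"`. Assignments at
#' ranks above species (genus, family, ...) therefore resolve to not-assigned,
#' mirroring the convention of ignoring assignments to superior taxa, while
#' sub-species and strain nodes are promoted to their species ancestor. Taxid
#' 0 (the unclassified sentinel), `NA` and taxids absent from the taxonomy all
#' resolve to not-assigned.
#'
#' @param taxids integer vector of taxon identifiers; `NA` and 0 allowed.
#' @param taxonomy a [taxonomy] object.
#' @return Integer vector of the same length: a species-rank taxid, or `NA`
#'   for not-assigned.
#' @export
resolve_to_species <- function(taxids, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  taxids <- as.integer(taxids)
  idx <- match(taxids, taxonomy$taxid)
  out <- rep(NA_integer_, length(taxids))
  todo <- unique(taxids[!is.na(idx)])
  if (length(todo) == 0) return(out)
  resolved <- vapply(todo, resolve_one, NA_integer_, taxonomy = taxonomy)
  out[!is.na(idx)] <- resolved[match(taxids[!is.na(idx)], todo)]
  out
}

resolve_one <- function(taxid, taxonomy) {
  i <- match(taxid, taxonomy$taxid)
  while (!is.na(i)) {
    if (taxonomy$rank[i] == "species") return(taxonomy$taxid[i])
    par <- taxonomy$parent[i]
    if (par == taxonomy$taxid[i] || par == 1L) return(NA_integer_)
    i <- match(par, taxonomy$taxid)
  }
  NA_integer_
}

#' Look up taxon names
#'
#' @param taxids integer vector.
#' @param taxonomy a [taxonomy] object.
#' @return Character vector of names; `NA` where the taxid is absent.
#' @export
taxon_names <- function(taxids, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  taxonomy$name[match(as.integer(taxids), taxonomy$taxid)]
}

read_nonempty_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines[nzchar(lines)]
}
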