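# Shared in-code fixtures: a small Drosophila-flavoured taxonomy, tempfile
# writers for classifier output dialects, random table generators and an
# independent per-read oracle for the pairwise merge rules.

fixture_taxonomy <- function() {
  taxonomy(data.frame(
    taxid  = c(1,      7147,    7214,     7215,    7227,      7240,      46245,     72271,        7366,    7370,      9998,    9999),
    parent = c(1,      1,       7147,     7214,    7215,      7215,      7215,      7227,         7214,    7366,      7214,    9998),
    rank   = c("no rank", "order", "family", "genus", "species", "species", "species", "subspecies", "genus", "species", "genus", "species"),
    name   = c("root", "Diptera", "Drosophilidae", "Drosophila", "Drosophila melanogaster",
               "Drosophila simulans", "Drosophila pseudoobscura", "D. melanogaster strain",
               "Musca", "Musca domestica", "OtherGenus", "Contaminant species")
  ))
}

tmp_lines <- function(...) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(...), f)
  f
}

# random species-resolved table over a given species set; a share of reads
# left not-assigned, a share of read ids dropped (MEGAN-style omission)
random_assignments <- function(n, species, p_na = 0.3, p_absent = 0.2,
                               sample_id = "s", classifier_id = "c") {
  read_id <- sprintf("r%04d", seq_len(n))
  taxid <- sample(species, n, replace = TRUE)
  taxid[stats::runif(n) < p_na] <- NA_integer_
  keep <- stats::runif(n) >= p_absent
  read_assignments(read_id[keep], taxid[keep], sample_id, classifier_id)
}

# brute-force re-implementation of the six pairwise merge cases, one read at
# a time; deliberately naive and structured unlike merge_assignments()
oracle_merge <- function(table_p, table_q, policy) {
  reads <- union(table_p$read_id, table_q$read_id)
  out <- integer(0)
  for (r in reads) {
    a <- if (r %in% table_p$read_id) table_p$taxid[table_p$read_id == r] else NA
    b <- if (r %in% table_q$read_id) table_q$taxid[table_q$read_id == r] else NA
    v <- if (is.na(a) && is.na(b)) NA_integer_
    else if (!is.na(a) && is.na(b)) { if (policy == "union") a else NA_integer_ }
    else if (is.na(a) && !is.na(b)) { if (policy == "union") b else NA_integer_ }
    else if (a != b) NA_integer_
    else a
    out[r] <- v
  }
  out
}
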