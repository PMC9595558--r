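#' Merge two classifiers' read assignments by union or intersection
#'
#' Implements the pairwise consensus rules for two classifiers *p* and *q*.
#' The read universe is the union of the two tables' read ids; a read missing
#' from one table counts as not-assigned for that classifier (MEGAN-style
#' exports omit unassigned reads). For a read with per-classifier assignments
#' (a_p, a_q):
#'
#' * both not-assigned: not-assigned under either policy;
#' * assigned by exactly one classifier: that species under `union`,
#'   not-assigned under `intersection`;
#' * assigned to different species: not-assigned under either policy
#'   (the read is discarded as conflicting);
#' * assigned to the same species by both: that species under either policy.
#'
#' Union therefore keeps every non-conflicting assignment, while intersection
#' keeps only reads on which the classifiers agree.
#'
#' @param table_p,table_q [read_assignments] tables for the same sample,
#'   already species-resolved.
#' @param policy `"union"` or `"intersection"`.
#' @return A [read_assignments] over the union of read ids; its
#'   `classifier_id` records the policy and both parent classifier ids.
#' @export
merge_assignments <- function(table_p, table_q,
                              policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table_p, "read_assignments"),
            inherits(table_q, "read_assignments"))
  sp <- attr(table_p, "sample_id")
  sq <- attr(table_q, "sample_id")
  if (!identical(sp, sq)) {
    stop("sample_id mismatch: '", sp, "' vs '", sq,
         "'; refusing to merge tables from different samples", call. = FALSE)
  }
  reads <- union(table_p$read_id, table_q$read_id)
  a_p <- table_p$taxid[match(reads, table_p$read_id)]
  a_q <- table_q$taxid[match(reads, table_q$read_id)]

  agree <- !is.na(a_p) & !is.na(a_q) & a_p == a_q
  merged <- rep(NA_integer_, length(reads))
  merged[agree] <- a_p[agree]
  if (policy == "union") {
    only_p <- !is.na(a_p) & is.na(a_q)
    only_q <- is.na(a_p) & !is.na(a_q)
    merged[only_p] <- a_p[only_p]
    merged[only_q] <- a_q[only_q]
  }

  # the merge can never invent a species absent from both inputs
  stopifnot(all(merged[!is.na(merged)] %in% c(a_p, a_q)))

  read_assignments(
    reads, merged, sample_id = sp,
    classifier_id = sprintf("%s(%s,%s)", policy,
                            attr(table_p, "classifier_id"),
                            attr(table_q, "classifier_id"))
  )
}
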