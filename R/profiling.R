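#' Per-sample species profiles
#'
#' A `species_profile` holds, for one sample, the number of reads assigned to
#' each species and the relative abundance of each species. The abundance
#' denominator is by default the total number of QC-passed reads in the
#' sample (`total_reads`), the same denominator used for the sample-level
#' proportion of informative reads; `denominator = "assigned"` divides by the
#' number of assigned reads instead. Zero-count species are not listed.
#'
#' @param counts named integer vector or two-column data frame
#'   (`taxid`, `count`) of assigned reads per species; zero counts dropped.
#' @param total_reads positive integer, QC-passed reads in the sample.
#' @param sample_id sample label.
#' @param denominator `"total"` (default) or `"assigned"`.
#' @return A `species_profile`: data frame with columns `taxid`, `count`,
#'   `abundance`, plus `sample_id`, `total_reads` and `denominator`
#'   attributes.
#' @export
species_profile <- function(counts, total_reads, sample_id = "sample",
                            denominator = c("total", "assigned")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(counts)) {
    taxid <- as.integer(counts$taxid)
    count <- as.integer(counts$count)
  } else {
    taxid <- as.integer(names(counts))
    count <- as.integer(counts)
  }
  total_reads <- as.integer(total_reads)
  stopifnot(length(total_reads) == 1L, !is.na(total_reads), total_reads >= 1L)
  if (anyNA(taxid) || anyNA(count) || any(count < 0L)) {
    stop("species counts must be non-negative integers keyed by taxid",
         call. = FALSE)
  }
  keep <- count > 0L
  taxid <- taxid[keep]
  count <- count[keep]
  if (anyDuplicated(taxid)) {
    stop("duplicate species taxid in profile", call. = FALSE)
  }
  if (sum(count) > total_reads) {
    stop("assigned reads (", sum(count), ") exceed total_reads (",
         total_reads, ")", call. = FALSE)
  }
  denom <- if (denominator == "total") total_reads else max(sum(count), 1L)
  ord <- order(-count, taxid)
  out <- data.frame(taxid = taxid[ord], count = count[ord],
                    abundance = count[ord] / denom)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "total_reads") <- total_reads
  attr(out, "denominator") <- denominator
  class(out) <- c("species_profile", "data.frame")
  out
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile> sample=", attr(x, "sample_id"),
      ": ", nrow(x), " species, ", sum(x$count), "/",
      attr(x, "total_reads"), " reads assigned (RPIR ",
      format(rpir(x), digits = 4), ")\n", sep = "")
  NextMethod()
}

#' Build a species profile from a read-assignment table
#'
#' Aggregates assigned reads per species. The sample-level relative
#' proportion of informative reads (RPIR) of the resulting profile is the
#' number of assigned reads divided by `total_reads`.
#'
#' @param assignments a [read_assignments] table (species-resolved).
#' @param total_reads positive integer; must be at least the number of
#'   assigned reads (it counts all QC-passed reads, assigned or not).
#' @inheritParams species_profile
#' @return A [species_profile].
#' @export
build_profile <- function(assignments, total_reads,
                          denominator = c("total", "assigned")) {
  stopifnot(inherits(assignments, "read_assignments"))
  assigned <- assignments$taxid[!is.na(assignments$taxid)]
  tab <- table(assigned)
  species_profile(
    data.frame(taxid = as.integer(names(tab)), count = as.integer(tab)),
    total_reads = total_reads,
    sample_id = attr(assignments, "sample_id"),
    denominator = denominator
  )
}

#' Sample-level relative proportion of informative reads
#'
#' @param profile a [species_profile].
#' @return Assigned reads divided by total QC-passed reads.
#' @export
rpir <- function(profile) {
  stopifnot(inherits(profile, "species_profile"))
  sum(profile$count) / attr(profile, "total_reads")
}

#' Apply an analytic detection limit to a species profile
#'
#' Retains exactly the species whose relative abundance is greater than or
#' equal to `epsilon`; counts and the total-read denominator are unchanged.
#' The comparison is inclusive, so a species sitting exactly at the threshold
#' survives. The operation is idempotent at fixed `epsilon` and monotone in
#' `epsilon`: raising the threshold can only shrink the species list.
#'
#' @param profile a [species_profile].
#' @param epsilon detection limit in `[0, 1]`; `0` retains everything.
#' @return The filtered [species_profile].
#' @export
apply_detection_limit <- function(profile, epsilon) {
  stopifnot(inherits(profile, "species_profile"),
            is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon <= 1)
  keep <- profile$abundance >= epsilon
  out <- profile[keep, , drop = FALSE]
  attr(out, "sample_id") <- attr(profile, "sample_id")
  attr(out, "total_reads") <- attr(profile, "total_reads")
  attr(out, "denominator") <- attr(profile, "denominator")
  class(out) <- class(profile)
  rownames(out) <- NULL
  out
}
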