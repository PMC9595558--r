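#' Benchmarking contexts for single-species libraries
#'
#' In a single-species benchmark library every read is assumed to originate
#' from one known *focal species*, so read-level truth labels are available:
#' a read assigned to the focal species is a true positive (TP), a read
#' assigned to any other species is a false positive (FP), and a read left
#' unassigned by the assessed method but assigned to the focal species by at
#' least one of the two base classifiers is a false negative (FN). True
#' negatives are not counted: unassigned reads are dominated by nuclear DNA
#' that cannot map to a mitogenome reference and cannot be separated from
#' artefacts.
#'
#' @param focal_species species-rank taxid of the library's focal species.
#' @param total_reads positive integer, QC-passed reads in the library.
#' @param base_tables list of the two individual classifiers'
#'   [read_assignments] tables (used for the FN denominator).
#' @param contaminants integer vector of known contaminant species taxids;
#'   must not include the focal species.
#' @param taxonomy optional [taxonomy]; when given, the focal species must be
#'   present at species rank.
#' @return A `benchmark_context` list.
#' @export
benchmark_context <- function(focal_species, total_reads, base_tables,
                              contaminants = integer(0), taxonomy = NULL) {
  focal_species <- as.integer(focal_species)
  contaminants <- as.integer(contaminants)
  stopifnot(length(focal_species) == 1L, !is.na(focal_species),
            focal_species > 0L,
            is.list(base_tables), length(base_tables) == 2L)
  lapply(base_tables, function(x) stopifnot(inherits(x, "read_assignments")))
  if (focal_species %in% contaminants) {
    stop("focal species ", focal_species,
         " cannot be listed as a contaminant", call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    r <- taxonomy$rank[match(focal_species, taxonomy$taxid)]
    if (is.na(r) || r != "species") {
      stop("focal species ", focal_species,
         " is absent from the taxonomy or not species rank", call. = FALSE)
    }
  }
  structure(
    list(focal_species = focal_species,
         total_reads = as.integer(total_reads),
         base_tables = base_tables,
         contaminants = contaminants),
    class = "benchmark_context"
  )
}

#' Remove known contaminant species from an assignment table
#'
#' Reads assigned to a contaminant species are removed from the table
#' entirely (they are not down-graded to not-assigned: contamination is real
#' DNA of a known other species and is excluded from the benchmark), and the
#' removed reads are tallied per contaminant species.
#'
#' @param assignments a [read_assignments] table.
#' @param contaminants integer vector of contaminant species taxids.
#' @return A list with elements `clean` (the filtered [read_assignments]) and
#'   `removed` (a `species_counts` data frame of removed reads per
#'   contaminant).
#' @export
exclude_contaminants <- function(assignments, contaminants) {
  stopifnot(inherits(assignments, "read_assignments"))
  contaminants <- as.integer(contaminants)
  hit <- !is.na(assignments$taxid) & assignments$taxid %in% contaminants
  removed_tab <- table(assignments$taxid[hit])
  clean <- read_assignments(
    assignments$read_id[!hit], assignments$taxid[!hit],
    sample_id = attr(assignments, "sample_id"),
    classifier_id = attr(assignments, "classifier_id")
  )
  list(
    clean = clean,
    removed = species_counts(as.integer(names(removed_tab)),
                             as.integer(removed_tab),
                             sample_id = attr(assignments, "sample_id"))
  )
}

#' Evaluate one classification method on a single-species library
#'
#' Pipeline: (1) build the method's species profile and apply the detection
#' limit `epsilon`; (2) count TP as reads assigned to the focal species when
#' it survives the filter, and FP as reads assigned to any other surviving
#' species (reads of filtered-out species count neither way); (3) the FN
#' denominator follows "true positive reads by any tool": with `U` the set of
#' reads assigned to the focal species by at least one base classifier,
#' FN = max(|U| - TP, 0); (4) richness is the number of surviving species
#' (the focal species included when present), RPIR = (TP + FP) / total_reads,
#' precision = TP / (TP + FP) and recall = TP / (TP + FN), each `NA` when its
#' denominator is zero.
#'
#' Contaminants are expected to have been excluded (via
#' [exclude_contaminants()]) from the method table and both base tables
#' before calling.
#'
#' @param method_assignments species-resolved [read_assignments] of the
#'   method under evaluation (a base classifier or a merged table).
#' @param context a [benchmark_context].
#' @param epsilon detection limit in `[0, 1]`.
#' @param method_id label stored in the result; defaults to the table's
#'   `classifier_id`.
#' @return A one-row data frame of class `benchmark_result` with columns
#'   `method_id`, `tp`, `fp`, `fn`, `richness`, `rpir`, `precision`,
#'   `recall`.
#' @export
evaluate_method <- function(method_assignments, context, epsilon = 0,
                            method_id = NULL) {
  stopifnot(inherits(method_assignments, "read_assignments"),
            inherits(context, "benchmark_context"))
  if (is.null(method_id)) method_id <- attr(method_assignments, "classifier_id")

  profile <- build_profile(method_assignments, context$total_reads)
  profile <- apply_detection_limit(profile, epsilon)
  surviving <- profile$taxid

  tp <- if (context$focal_species %in% surviving) {
    profile$count[match(context$focal_species, profile$taxid)]
  } else 0L
  fp <- sum(profile$count) - tp

  focal_by_any <- unique(unlist(lapply(context$base_tables, function(tab) {
    tab$read_id[!is.na(tab$taxid) & tab$taxid == context$focal_species]
  })))
  fn <- max(length(focal_by_any) - tp, 0L)

  res <- data.frame(
    method_id = method_id,
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    richness = length(surviving),
    rpir = (tp + fp) / context$total_reads,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(res) <- c("benchmark_result", "data.frame")
  res
}

#' Aggregate benchmark results over samples
#'
#' Computes the per-metric mean and sample standard deviation (n - 1
#' denominator) over a collection of per-library results. Undefined metric
#' values (`NA` precision or recall from a zero denominator) are excluded
#' metric-wise with a warning.
#'
#' @param results list of `benchmark_result` rows from [evaluate_method()],
#'   or a data frame of row-bound results; at least 2 results.
#' @return A data frame with columns `metric`, `mean`, `sd`, `n` covering
#'   richness, rpir, precision and recall.
#' @export
aggregate_benchmarks <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (length(results) == 0) stop("no results to aggregate", call. = FALSE)
  combined <- do.call(rbind, lapply(results, as.data.frame))
  if (nrow(combined) < 2L) {
    stop("need at least 2 results to aggregate", call. = FALSE)
  }
  metrics <- c("richness", "rpir", "precision", "recall")
  rows <- lapply(metrics, function(m) {
    v <- combined[[m]]
    if (anyNA(v)) {
      warning(sum(is.na(v)), " undefined ", m,
              " value(s) excluded from aggregation", call. = FALSE)
      v <- v[!is.na(v)]
    }
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  do.call(rbind, rows)
}

#' Format a benchmark summary at the conventional display precision
#'
#' Richness is shown to 1 decimal, precision and recall to 3 decimals and
#' RPIR to 4 decimals, as `mean +/- sd` strings; the underlying aggregate
#' keeps full precision.
#'
#' @param summary output of [aggregate_benchmarks()].
#' @return The summary with an added `display` character column.
#' @export
format_benchmark_summary <- function(summary) {
  digits <- c(richness = 1L, rpir = 4L, precision = 3L, recall = 3L)
  d <- digits[summary$metric]
  d[is.na(d)] <- 3L
  summary$display <- vapply(seq_len(nrow(summary)), function(i) {
    sprintf("%.*f \u00b1 %.*f", d[i], summary$mean[i], d[i], summary$sd[i])
  }, character(1))
  summary
}
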