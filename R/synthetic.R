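#' Configure a two-classifier single-species simulation
#'
#' The simulator emulates the error structure observed when two independent
#' read classifiers are run on a library containing DNA of a single (focal)
#' species: each classifier assigns only a small fraction of reads at species
#' level (most reads are nuclear and cannot hit a mitogenome reference), and
#' an assigned read occasionally goes to a wrong species, preferentially a
#' congener of the focal species. An error-correlation knob controls how
#' often the two classifiers make the *same* wrong call on the same read —
#' the quantity that determines how many false-positive species survive an
#' intersection merge.
#'
#' @param n_reads number of reads in the sample (all truly focal).
#' @param focal_species focal species taxid.
#' @param species_pool integer vector of wrong-target species taxids
#'   (excluding the focal species).
#' @param congener logical vector along `species_pool`: is the species a
#'   congener of the focal species?
#' @param assign_prob length-2 numeric: per-classifier probability that a
#'   read is assigned at species level at all.
#' @param error_prob length-2 numeric: per-classifier probability that an
#'   assigned read goes to a wrong species.
#' @param congener_weight length-2 numeric: per-classifier relative sampling
#'   weight of a congeneric wrong target over a non-congeneric one
#'   (default 10 for both).
#' @param error_correlation probability in `[0, 1]` that, given both
#'   classifiers err on the same read, they err to the same wrong species.
#' @param seed integer seed; identical configs reproduce identical samples.
#' @param classifier_ids labels for the two simulated classifiers.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_reads, focal_species, species_pool,
                              congener = rep(FALSE, length(species_pool)),
                              assign_prob = c(0.007, 0.007),
                              error_prob = c(0.01, 0.24),
                              congener_weight = c(10, 10),
                              error_correlation = 0,
                              seed = 1L,
                              classifier_ids = c("sim_p", "sim_q")) {
  n_reads <- as.integer(n_reads)
  focal_species <- as.integer(focal_species)
  species_pool <- as.integer(species_pool)
  stopifnot(
    n_reads >= 1L, length(focal_species) == 1L, focal_species > 0L,
    length(congener) == length(species_pool),
    is.logical(congener),
    length(assign_prob) == 2L, all(assign_prob >= 0), all(assign_prob <= 1),
    length(error_prob) == 2L, all(error_prob >= 0), all(error_prob <= 1),
    length(congener_weight) %in% c(1L, 2L), all(congener_weight > 0),
    length(error_correlation) == 1L,
    error_correlation >= 0, error_correlation <= 1,
    length(classifier_ids) == 2L
  )
  if (focal_species %in% species_pool) {
    stop("species_pool must not contain the focal species", call. = FALSE)
  }
  if (anyDuplicated(species_pool)) {
    stop("species_pool taxids must be unique", call. = FALSE)
  }
  if (length(species_pool) == 0 && any(error_prob > 0)) {
    stop("species_pool is empty but error_prob > 0: ",
         "there is no wrong species to assign to", call. = FALSE)
  }
  structure(
    list(n_reads = n_reads, focal_species = focal_species,
         species_pool = species_pool, congener = congener,
         assign_prob = as.numeric(assign_prob),
         error_prob = as.numeric(error_prob),
         congener_weight = rep(as.numeric(congener_weight), length.out = 2L),
         error_correlation = as.numeric(error_correlation),
         seed = as.integer(seed),
         classifier_ids = as.character(classifier_ids)),
    class = "simulation_config"
  )
}

#' Normalized wrong-target weights for one classifier
#'
#' Congeners of the focal species get `congener_weight` times the weight of
#' non-congeners, reflecting that misassignments fall predominantly on
#' species of the same genus.
#'
#' @param config a [simulation_config].
#' @param classifier 1 or 2.
#' @return Numeric vector along `config$species_pool`, summing to 1 (empty
#'   pool gives an empty vector).
#' @export
wrong_target_weights <- function(config, classifier = 1L) {
  stopifnot(inherits(config, "simulation_config"), classifier %in% c(1L, 2L))
  if (length(config$species_pool) == 0) return(numeric(0))
  w <- ifelse(config$congener, config$congener_weight[classifier], 1)
  w / sum(w)
}

#' Simulate a single-species sample classified by two error-prone classifiers
#'
#' Per read and classifier: with `assign_prob` the read is assigned at
#' species level; an assigned read is correct (focal species) with
#' probability `1 - error_prob`, otherwise a wrong species is drawn from the
#' pool with congener weighting. For reads on which *both* classifiers err,
#' with probability `error_correlation` the two classifiers take one shared
#' wrong species (drawn from the elementwise mean of the two classifiers'
#' weight vectors, a choice symmetric in p and q), otherwise their wrong
#' draws are independent. All randomness
#' derives from `config$seed` through per-classifier substreams, so the
#' output is reproducible byte for byte and adding draws for one classifier
#' does not perturb the other's.
#'
#' @param config a [simulation_config].
#' @return A `synthetic_sample` list: `truth` (data frame read_id,
#'   taxid = focal), `table_p` and `table_q` ([read_assignments]),
#'   `total_reads` and the echoed `config`.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_reads
  read_id <- sprintf("read%07d", seq_len(n))
  w_each <- list(wrong_target_weights(config, 1L), wrong_target_weights(config, 2L))

  # substream seeds, then independent draws per classifier
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)

  draw_classifier <- function(k) {
    set.seed(sub[k])
    assigned <- stats::runif(n) < config$assign_prob[k]
    wrong <- stats::runif(n) < config$error_prob[k]
    target <- if (length(config$species_pool) > 0) {
      # index-based draw: sample(x, ...) would misbehave for a length-1 pool
      config$species_pool[sample.int(length(config$species_pool), n,
                                     replace = TRUE, prob = w_each[[k]])]
    } else rep(NA_integer_, n)
    taxid <- rep(NA_integer_, n)
    taxid[assigned & !wrong] <- config$focal_species
    taxid[assigned & wrong] <- target[assigned & wrong]
    list(assigned = assigned, wrong = wrong, taxid = taxid)
  }
  p <- draw_classifier(1L)
  q <- draw_classifier(2L)

  # correlation coupling: only reads where both classifiers erred
  set.seed(sub[3L])
  couple <- stats::runif(n) < config$error_correlation
  shared <- if (length(config$species_pool) > 0) {
    config$species_pool[sample.int(length(config$species_pool), n,
                                   replace = TRUE,
                                   prob = (w_each[[1L]] + w_each[[2L]]) / 2)]
  } else rep(NA_integer_, n)
  both_wrong <- p$assigned & p$wrong & q$assigned & q$wrong
  tie <- both_wrong & couple
  p$taxid[tie] <- shared[tie]
  q$taxid[tie] <- shared[tie]

  structure(
    list(
      truth = data.frame(read_id = read_id,
                         taxid = rep(config$focal_species, n)),
      table_p = read_assignments(read_id, p$taxid, sample_id = "synthetic",
                                 classifier_id = config$classifier_ids[1]),
      table_q = read_assignments(read_id, q$taxid, sample_id = "synthetic",
                                 classifier_id = config$classifier_ids[2]),
      total_reads = n,
      config = config
    ),
    class = "synthetic_sample"
  )
}

#' Closed-form expected intersection false-positive read count
#'
#' With uncorrelated errors, a read becomes an intersection false positive
#' only when both classifiers assign it, both err, and both independently
#' draw the same wrong species:
#' `n * a_p * a_q * e_p * e_q * sum_s w_p(s) * w_q(s)`.
#'
#' @param config a [simulation_config] (with `error_correlation = 0`).
#' @return Expected number of intersection-assigned wrong reads.
#' @export
expected_intersection_fp_reads <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  w_p <- wrong_target_weights(config, 1L)
  w_q <- wrong_target_weights(config, 2L)
  config$n_reads * prod(config$assign_prob) * prod(config$error_prob) *
    sum(w_p * w_q)
}
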