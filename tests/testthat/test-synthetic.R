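pool <- 100L + seq_len(20)

test_that("identical configs reproduce identical samples byte for byte", {
  cfg <- simulation_config(5000, 7227L, pool,
                           assign_prob = c(0.3, 0.3),
                           error_prob = c(0.1, 0.2),
                           error_correlation = 0.3, seed = 11L)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_canonical_assignments(s1$table_p, f1)
  write_canonical_assignments(s2$table_p, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$table_q$taxid, s2$table_q$taxid)

  s3 <- simulate_sample(simulation_config(5000, 7227L, pool,
                                          assign_prob = c(0.3, 0.3),
                                          error_prob = c(0.1, 0.2),
                                          error_correlation = 0.3,
                                          seed = 12L))
  expect_false(identical(s1$table_p$taxid, s3$table_p$taxid))
})

test_that("degenerate configurations behave as stated", {
  # no errors: intersection precision 1 and no false-positive species
  cfg <- simulation_config(2000, 7227L, pool,
                           assign_prob = c(0.5, 0.5),
                           error_prob = c(0, 0), seed = 3L)
  s <- simulate_sample(cfg)
  m <- merge_assignments(s$table_p, s$table_q, "intersection")
  ctx <- benchmark_context(7227L, s$total_reads,
                           list(s$table_p, s$table_q))
  res <- evaluate_method(m, ctx)
  expect_equal(res$fp, 0L)
  expect_equal(res$precision, 1)

  # classifier q never assigns: intersection empty, union equals p
  cfg0 <- simulation_config(2000, 7227L, pool,
                            assign_prob = c(0.4, 0),
                            error_prob = c(0.1, 0.1), seed = 4L)
  s0 <- simulate_sample(cfg0)
  i0 <- merge_assignments(s0$table_p, s0$table_q, "intersection")
  u0 <- merge_assignments(s0$table_p, s0$table_q, "union")
  expect_equal(n_assigned(i0), 0L)
  expect_equal(u0$taxid[match(s0$table_p$read_id, u0$read_id)],
               s0$table_p$taxid)

  # empty pool is only valid when no errors can occur
  expect_error(simulation_config(10, 7227L, integer(0),
                                 error_prob = c(0.1, 0)),
               "species_pool is empty")
  expect_s3_class(simulation_config(10, 7227L, integer(0),
                                    error_prob = c(0, 0)),
                  "simulation_config")
})

test_that("richness ordering union >= base >= intersection on replicates", {
  # sparse assignment keeps the two classifiers' read sets nearly disjoint,
  # the regime the ordering claim describes; a conflicting read (assigned to
  # different species by both) is dropped from the union and can remove a
  # singleton species, so replicates with conflicts are checked only for the
  # always-true directions
  for (seed in 1:15) {
    cfg <- simulation_config(5000, 7227L, pool,
                             assign_prob = c(0.02, 0.02),
                             error_prob = c(0.1, 0.25), seed = seed)
    s <- simulate_sample(cfg)
    rich <- function(tab) nrow(build_profile(tab, s$total_reads))
    u <- merge_assignments(s$table_p, s$table_q, "union")
    i <- merge_assignments(s$table_p, s$table_q, "intersection")
    r_p <- rich(s$table_p); r_q <- rich(s$table_q)

    expect_lte(rich(i), min(r_p, r_q))
    expect_true(all(u$taxid[!is.na(u$taxid)] %in%
                      c(s$table_p$taxid, s$table_q$taxid)))

    a_p <- s$table_p$taxid[match(u$read_id, s$table_p$read_id)]
    a_q <- s$table_q$taxid[match(u$read_id, s$table_q$read_id)]
    conflicts <- sum(!is.na(a_p) & !is.na(a_q) & a_p != a_q)
    if (conflicts == 0) expect_gte(rich(u), max(r_p, r_q))
  }
})

test_that("intersection suppresses false-positive species on average", {
  fp_species <- function(tab, total) {
    prof <- build_profile(tab, total)
    sum(prof$taxid != 7227L)
  }
  counts <- t(vapply(1:50, function(seed) {
    cfg <- simulation_config(2000, 7227L, 100L + seq_len(12),
                             assign_prob = c(0.4, 0.4),
                             error_prob = c(0.15, 0.3),
                             congener_weight = 1,
                             error_correlation = 0, seed = seed)
    s <- simulate_sample(cfg)
    i <- merge_assignments(s$table_p, s$table_q, "intersection")
    c(p = fp_species(s$table_p, s$total_reads),
      q = fp_species(s$table_q, s$total_reads),
      i = fp_species(i, s$total_reads))
  }, c(p = 0, q = 0, i = 0)))
  expect_lt(mean(counts[, "i"]), mean(counts[, "p"]))
  expect_lt(mean(counts[, "i"]), mean(counts[, "q"]))
})

test_that("intersection FP reads match the closed-form expectation", {
  cfg <- simulation_config(50000, 7227L, pool,
                           assign_prob = c(0.6, 0.5),
                           error_prob = c(0.2, 0.3),
                           congener_weight = 1,
                           error_correlation = 0, seed = 21L)
  expected <- expected_intersection_fp_reads(cfg)
  # per-read FP probability is tiny, so the count is near-Poisson
  sigma <- sqrt(expected)
  observed <- vapply(1:8, function(k) {
    cfg_k <- simulation_config(50000, 7227L, pool,
                               assign_prob = c(0.6, 0.5),
                               error_prob = c(0.2, 0.3),
                               congener_weight = 1,
                               error_correlation = 0, seed = 100L + k)
    s <- simulate_sample(cfg_k)
    m <- merge_assignments(s$table_p, s$table_q, "intersection")
    sum(!is.na(m$taxid) & m$taxid != 7227L)
  }, integer(1))
  expect_lt(abs(mean(observed) - expected), 3 * sigma / sqrt(length(observed)))
})

test_that("base precision converges to 1 - error_prob", {
  cfg <- simulation_config(20000, 7227L, pool,
                           assign_prob = c(0.5, 0.5),
                           error_prob = c(0.2, 0.05), seed = 31L)
  s <- simulate_sample(cfg)
  ctx <- benchmark_context(7227L, s$total_reads,
                           list(s$table_p, s$table_q))
  res_p <- evaluate_method(s$table_p, ctx)
  m <- res_p$tp + res_p$fp
  expect_lt(abs(res_p$precision - 0.8), 4 * sqrt(0.2 * 0.8 / m))
})

test_that("error correlation raises shared wrong calls", {
  shared_wrong <- function(rho, seed) {
    cfg <- simulation_config(20000, 7227L, pool,
                             assign_prob = c(0.8, 0.8),
                             error_prob = c(0.3, 0.3),
                             congener_weight = 1,
                             error_correlation = rho, seed = seed)
    s <- simulate_sample(cfg)
    m <- merge_assignments(s$table_p, s$table_q, "intersection")
    sum(!is.na(m$taxid) & m$taxid != 7227L)
  }
  expect_gt(mean(vapply(1:5, function(k) shared_wrong(0.9, k), integer(1))),
            mean(vapply(1:5, function(k) shared_wrong(0, k), integer(1))))
})
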