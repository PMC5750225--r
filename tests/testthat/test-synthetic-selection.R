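test_that("initial library has the configured size, structure and composition", {
  cfg <- selection_config(random_region_len = 8L, pool_size = 2000L, seed = 3L)
  pool <- generate_initial_library(cfg)
  expect_s3_class(pool, "seq_pool")
  expect_equal(sum(pool$count), 2000L)
  expect_true(all(nchar(pool$region) == 8L))
  reads <- pool_reads(pool, with_primers = TRUE)
  expect_true(all(nchar(reads) == 8L + nchar(cfg$primer_5) + nchar(cfg$primer_3)))
  ## i.i.d. uniform base usage
  freq <- oracle_mono_counts(paste0(pool_reads(pool), collapse = ""))
  freq <- freq / sum(freq)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("library generation is deterministic under seed and config is validated", {
  cfg <- selection_config(pool_size = 500L, seed = 7L)
  expect_identical(generate_initial_library(cfg), generate_initial_library(cfg))
  cfg2 <- selection_config(pool_size = 500L, seed = 8L)
  expect_false(identical(generate_initial_library(cfg)$region,
                         generate_initial_library(cfg2)$region))
  expect_error(selection_config(pool_size = 0), "pool_size")
  expect_error(selection_config(nonspecific_fraction = 1.2), "nonspecific_fraction")
})

test_that("pure nonspecific rounds preserve pool frequencies", {
  ## beta = 1 resampling is abundance-proportional: composition is unchanged
  ## in expectation; chi-square across seeds should rarely reject
  cfg <- selection_config(random_region_len = 6L, pool_size = 5000L, seed = 1L)
  pool <- generate_initial_library(cfg)
  model <- poly_a_affinity(k = 4L)
  n_sig <- 0L
  for (s in 1:10) {
    nxt <- simulate_selection_round(pool, model, nonspecific_fraction = 1,
                                    reads_out = 5000L, seed = 100L + s)
    m <- merge(pool, nxt, by = "region", all = TRUE)
    m[is.na(m)] <- 0
    keep <- m$count.x > 0
    p <- suppressWarnings(
      stats::chisq.test(m$count.y[keep], p = m$count.x[keep] / sum(m$count.x[keep]))$p.value)
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 3L)
})

test_that("degenerate selection fixes the only high-affinity sequence", {
  pool <- structure(data.frame(region = c(strrep("A", 20), strrep("C", 20)),
                               count = c(500L, 500L)),
                    class = c("seq_pool", "data.frame"),
                    primer_5 = "GG", primer_3 = "CC")
  model <- affinity_model(10L, weights = c(AAAAAAAAAA = 1), background = 0)
  nxt <- simulate_selection_round(pool, model, nonspecific_fraction = 0,
                                  reads_out = 1000L, seed = 1L)
  expect_equal(nxt$region, strrep("A", 20))
  expect_equal(nxt$count, 1000L)
})

test_that("all-zero affinity is rejected with advice about the background weight", {
  pool <- structure(data.frame(region = strrep("C", 20), count = 10L),
                    class = c("seq_pool", "data.frame"))
  model <- affinity_model(10L, weights = c(AAAAAAAAAA = 1), background = 0)
  expect_error(simulate_selection_round(pool, model, 0, 10L, seed = 1L),
               "background")
})

test_that("adenosine-preferring selection enriches the A homopolymer across rounds", {
  ## expected frequency of the A homopolymer word is nondecreasing round
  ## over round; pool sized so that homopolymer-bearing molecules exist
  freq_a6 <- function(pool) {
    tb <- count_kmers(pool, 6)
    n <- tb$counts[strrep("A", 6)]
    (if (is.na(n)) 0 else n) / tb$total_windows
  }
  traj <- matrix(NA_real_, nrow = 8, ncol = 6)
  for (s in 1:8) {
    cfg <- selection_config(random_region_len = 12L, pool_size = 3e4,
                            reads_per_round = 1e4,
                            nonspecific_fraction = 0.2, seed = 200L + s)
    sim <- simulate_seqrs(cfg, poly_a_affinity(k = 6L, fold_per_a = 2))
    traj[s, ] <- vapply(sim$pools, freq_a6, numeric(1))
  }
  mean_traj <- colMeans(traj)
  expect_true(all(diff(mean_traj) > -0.1 * mean_traj[-6]))
  expect_gt(mean_traj[6], 5 * mean_traj[1])
})

test_that("sequence affinity aggregates windows by max or sum", {
  m_max <- affinity_model(2L, weights = c(AA = 10), background = 1)
  m_sum <- affinity_model(2L, weights = c(AA = 10), background = 1,
                          aggregation = "sum_windows")
  expect_equal(sequence_affinity(m_max, "AACG"), 10)
  expect_equal(sequence_affinity(m_sum, "AACG"), 12)  # AA + AC + CG
  ## analytic adenosine model agrees with an explicit weight table
  poly <- poly_a_affinity(k = 2L, fold_per_a = 3, background = 2)
  tab <- affinity_model(2L, weights = sapply(
    all_kmers <- c(outer(c("A","C","G","U"), c("A","C","G","U"), paste0)),
    function(m) 2 * 3^lengths(regmatches(m, gregexpr("A", m)))), background = 2)
  seqs <- random_rna(20, 7, prob = c(0.4, 0.2, 0.2, 0.2))
  expect_equal(sequence_affinity(poly, seqs), sequence_affinity(tab, seqs))
})

test_that("a full simulated experiment writes one FASTQ per round plus a manifest", {
  out <- tempfile("seqrs_")
  cfg <- selection_config(random_region_len = 12L, n_rounds = 3L,
                          pool_size = 2000L, reads_per_round = 500L, seed = 5L)
  sim <- simulate_seqrs(cfg, poly_a_affinity(k = 6L), out_dir = out)
  expect_length(sim$files, 4L)           # rounds 0..3
  expect_true(all(file.exists(sim$files)))
  expect_equal(max(sim$manifest$round), cfg$n_rounds)
  ## FASTQ round trip: depth, read length, and recoverable random regions
  reads <- read_reads(sim$files[1], "fastq")
  expect_length(reads, 500L)
  regions <- trim_constant_regions(reads, cfg$primer_5, cfg$primer_3)
  expect_equal(attr(regions, "n_discarded"), 0L)
  expect_true(all(nchar(regions) == 12L))
  ## byte-identical output under the same seed
  out2 <- tempfile("seqrs_")
  simulate_seqrs(cfg, poly_a_affinity(k = 6L), out_dir = out2)
  expect_identical(readLines(sim$files[4]),
                   readLines(file.path(out2, basename(sim$files[4]))))
})

test_that("the unselected library is uniform at the k-mer level", {
  cfg <- selection_config(pool_size = 5e4, reads_per_round = 5e4, seed = 9L)
  pool <- generate_initial_library(cfg)
  tb <- count_kmers(pool, 6)
  f <- tb$counts / tb$total_windows
  ## all 4^6 k-mers observed, frequencies near 4^-6
  expect_length(f, 4^6)
  expect_lt(max(f) / min(f), 2.5)
  ## at k = 10 the depth is far below the universe: counts stay tiny
  tb10 <- count_kmers(pool, 10)
  expect_lt(max(tb10$counts), 10)
})
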