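test_that("the U statistic uses midranks and is symmetric in its group sizes", {
  r <- suppressWarnings(mann_whitney(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$u_statistic, 4.5)          # n1*n2/2 under exchangeability
  x <- c(0.1, 3, 5); y <- c(2, 4, 6, 8)
  u1 <- mann_whitney(x, y)$u_statistic
  u2 <- mann_whitney(y, x)$u_statistic
  expect_equal(u1 + u2, length(x) * length(y))
})

test_that("small tie-free comparisons use the exact distribution", {
  r <- mann_whitney(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 6)            # 1 of C(4,2) arrangements
  expect_equal(r$p_value, oracle_mw_exact(c(1, 2), c(3, 4), "less"))
  ## random tie-free cases, every alternative
  set.seed(23)
  for (i in 1:5) {
    x <- sample(seq(0, 1, by = 0.001), 5); y <- sample(seq(2, 3, by = 0.001), 7)
    for (alt in c("two_sided", "greater", "less"))
      expect_equal(mann_whitney(x, y, alt)$p_value, oracle_mw_exact(x, y, alt))
  }
})

test_that("ties and large samples fall back to the corrected normal approximation", {
  x <- c(rep(1, 5), 2, 3); y <- c(rep(1, 3), 4, 5, 6)
  r <- mann_whitney(x, y)
  expect_equal(r$method, "normal_tie_corrected")
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_warning(r2 <- mann_whitney(rep(2, 4), rep(2, 6)), "identical")
  expect_equal(r2$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("fold partitions are disjoint, exhaustive and balanced", {
  f <- kfold_partition(20L, n_folds = 10L, seed = 1L)
  expect_equal(as.vector(table(f)), rep(2L, 10))
  labels <- c(rep(1, 30), rep(0, 70))
  fs <- kfold_partition(labels, 10L, stratified = TRUE, seed = 2L)
  expect_equal(length(fs), 100L)
  for (k in 1:10) {
    expect_equal(sum(labels[fs == k] == 1), 3L)
    expect_equal(sum(labels[fs == k] == 0), 7L)
  }
  ## uneven sizes differ by at most one overall and per class
  labels2 <- c(rep(1, 23), rep(0, 41))
  f2 <- kfold_partition(labels2, 10L, seed = 3L)
  sizes <- tabulate(f2, 10)
  expect_lte(diff(range(sizes)), 1L)
  pos_sizes <- vapply(1:10, function(k) sum(labels2[f2 == k] == 1), integer(1))
  expect_lte(diff(range(pos_sizes)), 1L)
  expect_error(kfold_partition(20L, n_folds = 1L), "n_folds")
  expect_error(kfold_partition(5L, n_folds = 10L), "at least")
})

test_that("ROC curves start at (0,0), end at (1,1) and integrate correctly", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  cv <- roc_curve(scores, labels)
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_false(is.unsorted(cv$fpr))
  expect_equal(trapezoid_auc(cv), 1)
  expect_error(roc_curve(scores, rep(1, 6)), "both classes")
})

test_that("trapezoidal AUC equals exhaustive pair counting, with ties diagonal", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(1:8, n, replace = TRUE)   # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    auc <- trapezoid_auc(roc_curve(scores, labels))
    expect_equal(auc, oracle_pair_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC respects score negation and monotone transforms", {
  set.seed(34)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  auc <- trapezoid_auc(roc_curve(scores, labels))
  expect_equal(trapezoid_auc(roc_curve(-scores, labels)), 1 - auc)
  expect_equal(trapezoid_auc(roc_curve(exp(2 * scores), labels)), auc)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  ours <- trapezoid_auc(roc_curve(scores, labels))
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("cross-validated AUC detects a strongly planted motif", {
  x <- simulate_occupancy_sites(occupancy_config(n_positive = 60L, n_negative = 0L,
                                                 window_len = 30L,
                                                 motif = strrep("A", 12L), seed = 41L))
  ## mononucleotide-matched negatives: same base counts, scattered A's
  neg <- make_matched_negatives(x$seq, order = 0L, seed = 42L)
  lab <- labeled_sequences(c(x$seq, neg), c(rep(1L, 60), rep(0L, 60)))
  res <- cross_validated_auc(lab, trainer = llr_trainer(k = 5L), n_folds = 10L,
                             seed = 7L)
  expect_gt(res$auc, 0.9)
  ## the mean curve lies between the fold envelope at every grid point
  expect_true(all(res$mean_tpr >= apply(res$tpr_by_fold, 1, min) - 1e-12))
  expect_true(all(res$mean_tpr <= apply(res$tpr_by_fold, 1, max) + 1e-12))
  ## reproducible under seed
  res2 <- cross_validated_auc(lab, trainer = llr_trainer(k = 5L), n_folds = 10L,
                              seed = 7L)
  expect_equal(res$auc, res2$auc)
})

test_that("cross-validation is stable in the number of folds", {
  x <- simulate_occupancy_sites(occupancy_config(n_positive = 100L, n_negative = 0L,
                                                 window_len = 40L, seed = 43L))
  neg <- make_matched_negatives(x$seq, order = 0L, seed = 44L)
  lab <- labeled_sequences(c(x$seq, neg), c(rep(1L, 100), rep(0L, 100)))
  a2 <- cross_validated_auc(lab, trainer = llr_trainer(k = 5L), n_folds = 2L, seed = 1L)
  a10 <- cross_validated_auc(lab, trainer = llr_trainer(k = 5L), n_folds = 10L, seed = 1L)
  expect_lt(abs(a2$auc - a10$auc), 0.05)
})

test_that("a fixed motif model can be evaluated without training", {
  x <- simulate_occupancy_sites(occupancy_config(n_positive = 40L, n_negative = 40L,
                                                 window_len = 30L, seed = 45L))
  model <- build_pfm(strrep("A", 8))
  res <- cross_validated_auc(x, trainer = model_scorer(model), n_folds = 5L, seed = 2L)
  expect_gt(res$auc, 0.9)
})

test_that("positional density is a delta at the center for jitter-free planting", {
  x <- simulate_occupancy_sites(occupancy_config(n_positive = 80L, n_negative = 80L,
                                                 window_len = 51L,
                                                 motif = "AAGGCUAUGCAC",
                                                 seed = 46L))
  dens <- kmer_positional_density(x, "AAGGCUAU", flank = 10L, label_filter = 1L)
  start_offset <- (25L - 6L) - 25L           # planted start relative to center
  expect_equal(dens$density[dens$offsets == start_offset], 1)
  expect_equal(sum(dens$density > 0), 1L)
  expect_equal(dens$cumulative[length(dens$cumulative)], 1)
  expect_false(is.unsorted(dens$cumulative))
  expect_error(kmer_positional_density(x, character(0), 10L), "nonempty")
  expect_error(kmer_positional_density(x, "ACGUACGU", flank = 40L), "flank")
})

test_that("null labels produce chance-level cross-validated AUC", {
  set.seed(47)
  seqs <- random_rna(100, 25)
  labels <- rep(c(0L, 1L), 50)
  res <- cross_validated_auc(seqs, labels, trainer = llr_trainer(k = 4L),
                             n_folds = 5L, seed = 3L)
  expect_gt(res$auc, 0.3)
  expect_lt(res$auc, 0.7)
})
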