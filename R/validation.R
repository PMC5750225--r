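#' Mann-Whitney (Wilcoxon rank-sum) comparison of two score groups
#'
#' The U statistic is computed from midrank sums (ties receive midranks).
#' The p-value is exact — full enumeration of arrangements — whenever both
#' groups have at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric score vectors (both nonempty); `x` is group 1.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (group 1
#'   relative to group 2).
#' @param exact_max size threshold for the exact method.
#' @return an object of class `mw_test`: list with `u_statistic` (for
#'   group 1), `n1`, `n2`, `p_value`, `method`, `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "greater", "less"),
                         exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1")
    p <- 1
    method <- "normal_tie_corrected"
  } else if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- stats::wilcox.test(x, y, alternative = alt, exact = TRUE,
                            correct = FALSE)$p.value
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alt, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal_tie_corrected"
  }
  structure(list(u_statistic = u1, n1 = n1, n2 = n2,
                 p_value = p, method = method, alternative = alternative),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ", ", x$alternative, ")\n",
      "U = ", x$u_statistic, ", n1 = ", x$n1, ", n2 = ", x$n2,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Partition items into cross-validation folds
#'
#' Folds are disjoint, exhaustive, and of sizes differing by at most one.
#' Stratified partitioning (the default when labels are supplied)
#' additionally preserves the class ratio within each fold to one item.
#'
#' @param labels class label vector (one entry per item), or a single
#'   integer giving the number of items for unstratified partitioning.
#' @param n_folds number of folds (>= 2, <= number of items).
#' @param stratified balance class counts across folds?
#' @param seed optional integer seed.
#' @return integer vector of fold assignments in `1:n_folds`.
#' @export
kfold_partition <- function(labels, n_folds = 10L, stratified = TRUE,
                            seed = NULL) {
  if (length(labels) == 1L && is.numeric(labels)) {
    labels <- rep(0L, labels)
    stratified <- FALSE
  }
  n <- length(labels)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need at least n_folds items")
  with_seed(seed, {
    fold <- integer(n)
    if (!stratified) {
      fold <- sample(rep_len(seq_len(n_folds), n))
    } else {
      load <- integer(n_folds)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        nc <- length(idx)
        base <- nc %/% n_folds
        rem <- nc %% n_folds
        ## spill the remainder into the currently lightest folds
        extras <- order(load, sample.int(n_folds))[seq_len(rem)]
        assign_folds <- c(rep(seq_len(n_folds), base), extras)
        fold[idx] <- assign_folds
        load <- load + tabulate(assign_folds, n_folds)
      }
    }
    fold
  })
}

#' Empirical ROC curve
#'
#' Thresholds sweep the unique scores in descending order; tied scores are
#' grouped, so ties contribute diagonal segments. The curve starts at
#' (0, 0) and ends at (1, 1).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (logical or 0/1) with both classes present.
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) stop("labels must contain both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  keep <- !duplicated(s, fromLast = TRUE)
  data.frame(fpr = c(0, cumsum(!l)[keep] / N),
             tpr = c(0, cumsum(l)[keep] / P))
}

#' Trapezoidal area under a ROC curve
#'
#' @param fpr,tpr coordinates of the curve (fpr nondecreasing), or a data
#'   frame from [roc_curve()] as the first argument.
#' @return area in `[0, 1]`.
#' @export
trapezoid_auc <- function(fpr, tpr = NULL) {
  if (is.data.frame(fpr)) { tpr <- fpr$tpr; fpr <- fpr$fpr }
  stopifnot(length(fpr) == length(tpr), !is.unsorted(fpr))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

## Vertical interpolation of a ROC curve onto an FPR grid. The empirical
## curve is a staircase: at a duplicated FPR (vertical jump) the upper
## envelope applies, and between breakpoints the TPR is constant at the
## last breakpoint's value. Linear interpolation of the jump tops would
## bias small-sample curves upward (~+0.03 AUC at 20/20 test folds).
interp_roc <- function(curve, grid) {
  tpr_max <- tapply(curve$tpr, curve$fpr, max)
  f <- as.numeric(names(tpr_max))
  stats::approx(f, as.numeric(tpr_max), xout = grid, method = "constant",
                f = 0, rule = 2, ties = "ordered")$y
}

#' Cross-validated ROC with fold-averaged curve and trapezoidal AUC
#'
#' Splits the labeled set into `n_folds` folds (stratified by default),
#' trains the scorer on each training split, scores the held-out fold,
#' forms the per-fold ROC, vertically interpolates each fold curve onto a
#' fixed FPR grid, averages the curves, and integrates the mean curve by
#' trapezoids.
#'
#' @param x a [labeled_sequences()] object, or a character vector of
#'   sequences with `labels` supplied.
#' @param labels binary labels (ignored when `x` is a labeled set).
#' @param trainer a function `(train_seqs, train_labels) -> function(test_seqs) -> scores`;
#'   see [llr_trainer()] and [model_scorer()].
#' @param n_folds number of folds.
#' @param fpr_grid FPR grid for vertical averaging (default 101 points).
#' @param stratified stratify folds by class? If `FALSE` and a fold ends
#'   up missing a class, the partition falls back to stratified with a
#'   warning.
#' @param seed integer seed controlling the partition.
#' @return an object of class `roc_cv`: list with `fold_curves`,
#'   `fpr_grid`, `mean_tpr`, `auc`, `fold_aucs`, `n_folds`, `seed`.
#' @export
cross_validated_auc <- function(x, labels = NULL, trainer = llr_trainer(),
                                n_folds = 10L, fpr_grid = seq(0, 1, length.out = 101L),
                                stratified = TRUE, seed = 1L) {
  if (inherits(x, "labeled_sequences")) {
    labels <- x$label
    x <- x$seq
  }
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(x), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L) stop("labeled set must contain both classes")
  fold <- kfold_partition(labels, n_folds, stratified = stratified, seed = seed)
  if (!stratified) {
    bad <- vapply(seq_len(n_folds),
                  function(f) length(unique(labels[fold == f])) < 2L, logical(1))
    if (any(bad)) {
      warning("a fold is missing a class; falling back to stratified partition")
      fold <- kfold_partition(labels, n_folds, stratified = TRUE, seed = seed)
    }
  }
  fold_curves <- vector("list", n_folds)
  fold_aucs <- numeric(n_folds)
  tpr_mat <- matrix(NA_real_, length(fpr_grid), n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    score_fun <- trainer(x[!test], labels[!test])
    sc <- score_fun(x[test])
    fold_curves[[f]] <- roc_curve(sc, labels[test])
    fold_aucs[f] <- trapezoid_auc(fold_curves[[f]])
    tpr_mat[, f] <- interp_roc(fold_curves[[f]], fpr_grid)
  }
  mean_tpr <- rowMeans(tpr_mat)
  structure(list(fold_curves = fold_curves, fpr_grid = fpr_grid,
                 mean_tpr = mean_tpr, tpr_by_fold = tpr_mat,
                 auc = trapezoid_auc(fpr_grid, mean_tpr),
                 fold_aucs = fold_aucs, n_folds = as.integer(n_folds),
                 seed = seed),
            class = "roc_cv")
}

#' Likelihood-classifier trainer for cross-validation
#'
#' @param k,pseudocount passed to [train_likelihood()].
#' @return a trainer function for [cross_validated_auc()].
#' @export
llr_trainer <- function(k = 6L, pseudocount = 0.5) {
  function(train_seqs, train_labels) {
    clf <- train_likelihood(train_seqs[train_labels == 1L],
                            train_seqs[train_labels == 0L],
                            k = k, pseudocount = pseudocount)
    function(test_seqs) score_llr(clf, test_seqs)
  }
}

#' Fixed-model scorer for cross-validation
#'
#' Wraps a pre-built [build_pfm()] model so that folds differ only in
#' their test points (no training).
#'
#' @param model a `motif_model`.
#' @param ... passed to [score_sequence()].
#' @return a trainer function for [cross_validated_auc()].
#' @export
model_scorer <- function(model, ...) {
  force(model)
  function(train_seqs, train_labels) {
    function(test_seqs) score_sequence(model, test_seqs, ...)
  }
}

#' @export
print.roc_cv <- function(x, ...) {
  cat("Cross-validated ROC: ", x$n_folds, " folds, mean AUC = ",
      round(x$auc, 4), " (fold range ",
      round(min(x$fold_aucs), 3), "-", round(max(x$fold_aucs), 3), ")\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.roc_cv <- function(x, ...) {
  graphics::plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  for (cv in x$fold_curves)
    graphics::lines(cv$fpr, cv$tpr, col = "grey70")
  graphics::lines(x$fpr_grid, x$mean_tpr, lwd = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Positional density of k-mer hits around crosslink centers
#'
#' For each offset in `[-flank, flank]` relative to the recorded center
#' (offset 0 = crosslink site), the fraction of sequences with a hit from
#' `kmer_set` starting at that offset, together with the cumulative
#' distribution of hit positions.
#'
#' @param x a [labeled_sequences()] object (one class at a time, or use
#'   `label_filter`).
#' @param kmer_set nonempty character vector of k-mers (equal length).
#' @param flank maximal offset; must not exceed the distance from any
#'   center to its sequence edge (allowing a full k-mer at `+flank`).
#' @param label_filter optionally restrict to one label (0 or 1).
#' @return an object of class `positional_density`: list with `offsets`,
#'   `density`, `cumulative`, `n_sequences`, `n_hits`.
#' @export
kmer_positional_density <- function(x, kmer_set, flank, label_filter = NULL) {
  stopifnot(inherits(x, "labeled_sequences"))
  if (length(kmer_set) == 0L) stop("kmer_set must be nonempty")
  kmer_set <- as_rna(kmer_set)
  k <- unique(nchar(kmer_set))
  if (length(k) != 1L) stop("kmer_set has mixed lengths")
  if (!is.null(label_filter)) x <- x[x$label == label_filter, ]
  if (nrow(x) == 0L) stop("no sequences after filtering")
  L <- nchar(x$seq)
  if (any(x$center - flank < 0) || any(x$center + flank + k > L))
    stop("flank exceeds the distance from a center to its sequence edge")
  offsets <- seq(-flank, flank)
  hit_count <- integer(length(offsets))
  for (i in seq_along(offsets)) {
    start0 <- x$center + offsets[i]           # 0-based start
    w <- substring(x$seq, start0 + 1L, start0 + k)
    hit_count[i] <- sum(w %in% kmer_set)
  }
  total <- sum(hit_count)
  structure(list(offsets = offsets,
                 density = hit_count / nrow(x),
                 cumulative = if (total > 0) cumsum(hit_count) / total
                              else rep(0, length(offsets)),
                 n_sequences = nrow(x), n_hits = total),
            class = "positional_density")
}

#' @export
print.positional_density <- function(x, ...) {
  cat("Positional k-mer density over offsets ", min(x$offsets), "..",
      max(x$offsets), " (", x$n_hits, " hits in ", x$n_sequences,
      " sequences)\n", sep = "")
  invisible(x)
}
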