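## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths.

## Naive per-read dictionary k-mer counter.
oracle_count_kmers <- function(reads, k) {
  env <- new.env(parent = emptyenv())
  total <- 0L
  for (r in reads) {
    L <- nchar(r)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      w <- substr(r, i, i + k - 1L)
      env[[w]] <- (if (is.null(env[[w]])) 0L else env[[w]]) + 1L
      total <- total + 1L
    }
  }
  counts <- unlist(as.list(env))
  list(counts = counts[order(names(counts), method = "radix")], total = total)
}

## Base and dinucleotide count vectors of a single sequence.
oracle_mono_counts <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "U")))
}
oracle_dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  table(factor(di, levels = lv))
}

## AUC by exhaustive concordant/tied pair counting.
oracle_pair_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Exact Mann-Whitney p-value by full enumeration of rank arrangements.
oracle_mw_exact <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_null <- apply(idx, 2, function(i) sum(rank(pooled)[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_less <- mean(u_null <= u_obs)
  p_greater <- mean(u_null >= u_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

## Random RNA sequences with given composition.
random_rna <- function(n, len, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = prob),
           collapse = ""), character(1))
}
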