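#' Build a motif model from top-ranked k-mers
#'
#' The specificity model has a dual representation: a weighted position
#' frequency matrix (PFM) with its log-odds transform for continuous
#' scoring, and the raw top-k-mer set for hit-count (occurrence) scoring.
#' `pfm[j, b]` is the weight-averaged frequency of base `b` at position
#' `j`; log-odds are `log2(pfm / background)` with zero entries floored at
#' `pseudofreq` before the ratio (so fully conserved positions keep their
#' exact 2-bit log-odds against a uniform background).
#'
#' @param kmers character vector of equal-length k-mers (e.g. the top 50
#'   8-mers of an enrichment landscape).
#' @param weights nonnegative weights, not all zero; default equal.
#' @param background base composition (A, C, G, U), summing to 1.
#' @param pseudofreq floor applied to zero PFM entries in the log-odds
#'   transform.
#' @param scoring_mode default scoring mode for [score_sequence()].
#' @return an object of class `motif_model`.
#' @export
build_pfm <- function(kmers, weights = NULL,
                      background = rep(0.25, 4), pseudofreq = 1e-3,
                      scoring_mode = c("max_window_logodds", "hit_count")) {
  scoring_mode <- match.arg(scoring_mode)
  kmers <- as_rna(kmers)
  if (length(kmers) == 0L) stop("empty k-mer set")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers have mixed lengths")
  if (is.null(weights)) weights <- rep(1, length(kmers))
  stopifnot(length(weights) == length(kmers), all(weights >= 0))
  if (sum(weights) == 0) stop("weights must not all be zero")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-9)
  mat <- matrix(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE),
                nrow = length(kmers), ncol = k, byrow = TRUE)
  pfm <- t(vapply(seq_len(k), function(j) {
    vapply(RNA_BASES, function(b) sum(weights[mat[, j] == b]), numeric(1))
  }, numeric(4))) / sum(weights)
  colnames(pfm) <- RNA_BASES
  lo <- log2(pmax(pfm, pseudofreq) /
               matrix(background, nrow = k, ncol = 4, byrow = TRUE))
  colnames(lo) <- RNA_BASES
  structure(list(k = as.integer(k),
                 top_kmers = data.frame(kmer = kmers, weight = weights,
                                        stringsAsFactors = FALSE),
                 pfm = pfm, log_odds = lo,
                 background = background, pseudofreq = pseudofreq,
                 scoring_mode = scoring_mode),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif model: k =", x$k, "built from", nrow(x$top_kmers),
      "k-mers; scoring mode", x$scoring_mode, "\n")
  cat("Consensus:", paste0(colnames(x$pfm)[max.col(x$pfm)], collapse = ""), "\n")
  invisible(x)
}

#' Information-content matrix for a sequence logo
#'
#' Per-position information content in bits for a 4-letter alphabet:
#' `IC_pos = 2 - H_pos` with `H` the Shannon entropy of the position's
#' base frequencies, apportioned to bases as `IC_pos * f(pos, b)` (the
#' letter heights of a conventional sequence logo). Equal weighting by
#' default; no small-sample correction.
#'
#' @param kmers equal-length sequences (e.g. the top 300 10-mers).
#' @param weights optional nonnegative weights.
#' @return an object of class `logo_matrix`: list with `length`,
#'   `freq` (length x 4), `info_content` (length x 4, bits) and
#'   `total_ic_per_pos`.
#' @export
build_logo <- function(kmers, weights = NULL) {
  m <- build_pfm(kmers, weights)
  f <- m$pfm
  h <- -rowSums(ifelse(f > 0, f * log2(f), 0))
  ic_total <- 2 - h
  structure(list(length = m$k, freq = f,
                 info_content = f * ic_total,
                 total_ic_per_pos = ic_total),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("Sequence logo matrix, length", x$length, "\n")
  cat("Dominant base per position:",
      paste0(colnames(x$freq)[max.col(x$info_content)], collapse = ""), "\n")
  cat("Total IC (bits):", format(round(x$total_ic_per_pos, 2)), "\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.logo_matrix <- function(x, ...) {
  graphics::barplot(t(x$info_content), beside = FALSE,
                    names.arg = seq_len(x$length),
                    legend.text = colnames(x$info_content),
                    xlab = "position", ylab = "information (bits)",
                    ylim = c(0, 2), ...)
  invisible(x)
}

## Map equal-length sequences to a per-window score matrix or hit matrix.
sequence_windows_by_length <- function(seqs, k) {
  L <- nchar(seqs)
  split(seq_along(seqs), L)
}

#' Score sequences with a motif model
#'
#' `max_window_logodds`: the maximum over sliding windows of the summed
#' per-position log-odds (best-site score). `hit_count`: the number of
#' windows whose k-mer belongs to the model's top-k-mer set (optionally
#' summing the k-mers' weights instead of counting).
#'
#' @param model a [build_pfm()] model.
#' @param seqs character vector, each of length >= `k`.
#' @param mode scoring mode; defaults to the model's.
#' @param weighted_hits in `hit_count` mode, sum k-mer weights rather than
#'   counting hits.
#' @return numeric vector of scores.
#' @export
score_sequence <- function(model, seqs, mode = model$scoring_mode,
                           weighted_hits = FALSE) {
  mode <- match.arg(mode, c("max_window_logodds", "hit_count"))
  seqs <- as_rna(seqs)
  if (any(nchar(seqs) < model$k))
    stop("all sequences must be at least as long as the model's k")
  out <- numeric(length(seqs))
  for (idx in sequence_windows_by_length(seqs, model$k)) {
    len <- nchar(seqs[idx[1L]])
    n_win <- len - model$k + 1L
    if (mode == "max_window_logodds") {
      bases <- matrix(match(unlist(strsplit(seqs[idx], "", fixed = TRUE),
                                   use.names = FALSE), RNA_BASES),
                      nrow = length(idx), ncol = len, byrow = TRUE)
      sc <- matrix(0, nrow = length(idx), ncol = n_win)
      for (j in seq_len(model$k))
        sc <- sc + matrix(model$log_odds[j, ][bases[, j:(j + n_win - 1L), drop = FALSE]],
                          nrow = length(idx))
      out[idx] <- do.call(pmax, as.data.frame(sc))
    } else {
      wm <- matrix(window_matrix(seqs[idx], model$k), nrow = length(idx))
      if (weighted_hits) {
        w <- stats::setNames(model$top_kmers$weight, model$top_kmers$kmer)
        hits <- matrix(w[wm], nrow = length(idx))
        hits[is.na(hits)] <- 0
        out[idx] <- rowSums(hits)
      } else {
        out[idx] <- rowSums(matrix(wm %in% model$top_kmers$kmer,
                                   nrow = length(idx)))
      }
    }
  }
  out
}

#' @export
predict.motif_model <- function(object, newdata, ...) {
  score_sequence(object, newdata, ...)
}

#' Train a class-conditional k-mer likelihood classifier
#'
#' Learns pseudocounted k-mer frequency models for bound (positive) and
#' unbound (negative) training sequences; [score_llr()] then scores a
#' sequence by its average per-window log-likelihood ratio. This is the
#' "learned data likelihood" used to evaluate how well an in vitro
#' specificity landscape predicts in vivo occupancy.
#'
#' @param pos,neg character vectors of training sequences (both nonempty).
#' @param k word length; must not exceed the shortest training sequence.
#' @param pseudocount pseudocount for the class frequency models.
#' @return an object of class `llr_classifier`.
#' @export
train_likelihood <- function(pos, neg, k = 6L, pseudocount = 0.5) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be nonempty")
  pos <- as_rna(pos); neg <- as_rna(neg)
  if (k > min(nchar(c(pos, neg))))
    stop("k exceeds the shortest training sequence")
  tab_pos <- count_kmers(pos, k, "positive")
  tab_neg <- count_kmers(neg, k, "negative")
  lf <- function(tab) {
    f <- kmer_frequencies(tab, names(tab$counts), pseudocount)
    list(log_freq = log(f),
         log_baseline = log(pseudocount /
                              (tab$total_windows + pseudocount * 4^k)))
  }
  structure(c(list(k = as.integer(k), pseudocount = pseudocount),
              stats::setNames(lf(tab_pos), c("log_freq_pos", "log_baseline_pos")),
              stats::setNames(lf(tab_neg), c("log_freq_neg", "log_baseline_neg"))),
            class = "llr_classifier")
}

#' Average per-window log-likelihood ratio of sequences
#'
#' `score = mean over windows of [log f_pos(m) - log f_neg(m)]`; positive
#' scores favour the bound class.
#'
#' @param classifier a [train_likelihood()] model.
#' @param seqs character vector, each of length >= `k`.
#' @return numeric vector of scores.
#' @export
score_llr <- function(classifier, seqs) {
  seqs <- as_rna(seqs)
  k <- classifier$k
  if (any(nchar(seqs) < k))
    stop("all sequences must be at least as long as the classifier's k")
  lookup <- function(lf, base, kmers) {
    v <- unname(lf[kmers])
    v[is.na(v)] <- base
    v
  }
  out <- numeric(length(seqs))
  for (idx in sequence_windows_by_length(seqs, k)) {
    wm <- matrix(window_matrix(seqs[idx], k), nrow = length(idx))
    lp <- matrix(lookup(classifier$log_freq_pos, classifier$log_baseline_pos, wm),
                 nrow = length(idx))
    ln <- matrix(lookup(classifier$log_freq_neg, classifier$log_baseline_neg, wm),
                 nrow = length(idx))
    out[idx] <- rowMeans(lp - ln)
  }
  out
}

#' @export
predict.llr_classifier <- function(object, newdata, ...) {
  score_llr(object, newdata)
}

#' @export
print.llr_classifier <- function(x, ...) {
  cat("Class-conditional k-mer likelihood classifier (k = ", x$k,
      ", pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}
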