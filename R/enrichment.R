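#' Trim constant primer regions from reads
#'
#' Returns the subsequence strictly between the first exact match of the
#' 5' primer and the first exact match of the 3' primer downstream of it.
#' Reads lacking either primer are discarded (`NA`), and the discard count
#' is attached as an attribute.
#'
#' @param reads character vector of reads.
#' @param primer_5,primer_3 constant flank sequences (nonempty).
#' @return character vector of random regions with `NA` for discarded
#'   reads; attribute `n_discarded` counts them.
#' @export
trim_constant_regions <- function(reads, primer_5, primer_3) {
  primer_5 <- as_rna(primer_5); primer_3 <- as_rna(primer_3)
  if (nchar(primer_5) == 0 || nchar(primer_3) == 0)
    stop("primers must be nonempty")
  reads <- as_rna(reads)
  p5 <- regexpr(primer_5, reads, fixed = TRUE)
  start <- ifelse(p5 > 0, p5 + nchar(primer_5), NA_integer_)
  tail_part <- ifelse(is.na(start), NA_character_, substring(reads, start))
  p3 <- regexpr(primer_3, tail_part, fixed = TRUE)
  region <- ifelse(!is.na(start) & p3 > 0, substring(tail_part, 1L, p3 - 1L),
                   NA_character_)
  structure(region, n_discarded = sum(is.na(region)))
}

#' Count all overlapping k-mers in a set of reads
#'
#' Every read of length `L >= k` contributes its `L - k + 1` overlapping
#' windows; shorter reads contribute nothing.
#'
#' @param reads character vector of (already trimmed) RNA sequences, or a
#'   `seq_pool` from the selection simulator.
#' @param k word length (>= 1).
#' @param sample_id label stored with the table (e.g. round/replicate).
#' @return an object of class `kmer_counts`: list with `k`, `counts`
#'   (named integer vector), `total_windows`, `sample_id`.
#' @export
count_kmers <- function(reads, k, sample_id = "") {
  stopifnot(k >= 1)
  if (inherits(reads, "seq_pool")) {
    ## count windows on unique regions, then scale by molecule count
    if (nrow(reads) == 0L || nchar(reads$region[1L]) < k) {
      counts <- stats::setNames(integer(0), character(0))
    } else {
      km <- window_matrix(reads$region, k)
      km <- matrix(km, nrow = nrow(reads))
      tab <- rowsum(rep(reads$count, ncol(km)), as.vector(km))
      counts <- stats::setNames(as.integer(tab), rownames(tab))
    }
  } else {
    reads <- as_rna(reads[!is.na(reads)])
    wins <- extract_windows(reads, k)
    if (length(wins) == 0L) {
      counts <- stats::setNames(integer(0), character(0))
    } else {
      tab <- table(wins)
      counts <- stats::setNames(as.integer(tab), names(tab))
    }
  }
  counts <- counts[order(names(counts), method = "radix")]
  structure(list(k = as.integer(k), counts = counts,
                 total_windows = sum(counts), sample_id = sample_id),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer count table (k = ", x$k, "): ", length(x$counts),
      " distinct k-mers, ", x$total_windows, " windows",
      if (nzchar(x$sample_id)) paste0(" [", x$sample_id, "]"), "\n", sep = "")
  invisible(x)
}

#' Pseudocounted k-mer frequencies
#'
#' `(c(m) + p) / (T + p * 4^k)`; sums to 1 over all `4^k` k-mers.
#'
#' @param table a [count_kmers()] table.
#' @param kmers k-mers to evaluate (default: observed ones).
#' @param pseudocount pseudocount `p` (> 0 unless fully observed).
#' @return named numeric vector of frequencies.
#' @export
kmer_frequencies <- function(table, kmers = names(table$counts),
                             pseudocount = 0.5) {
  c_m <- table$counts[kmers]
  c_m[is.na(c_m)] <- 0L
  stats::setNames(as.numeric(c_m + pseudocount) /
                    (table$total_windows + pseudocount * 4^table$k), kmers)
}

#' k-mer enrichment of a selected sample over a reference
#'
#' `enrichment(m)` is the ratio of pseudocounted frequencies,
#' `[(c_sel(m)+p)/(T_sel+p*4^k)] / [(c_ref(m)+p)/(T_ref+p*4^k)]`. Values
#' are stored for the union of observed k-mers; k-mers unobserved in both
#' samples share the constant `baseline` ratio.
#'
#' With `reference = NULL` the enrichment is taken against the uniform
#' expectation `4^-k`, i.e. `enrichment(m) = f_sel(m) * 4^k`. This is the
#' appropriate reference when the input library is uniform by design and
#' the sequencing depth is small relative to the `4^k` universe, where a
#' sampled round-0 table would contribute more sampling noise than signal
#' (mean reference count per k-mer below ~5); [compute_enrichment()] warns
#' in that situation.
#'
#' @param selected,reference [count_kmers()] tables with equal `k`;
#'   `reference = NULL` uses the uniform expectation.
#' @param pseudocount pseudocount `p` (> 0).
#' @return an object of class `enrichment_table`: list with `k`,
#'   `enrichment` (named numeric), `baseline`, sample ids and `pseudocount`.
#' @export
compute_enrichment <- function(selected, reference = NULL, pseudocount = 0.5) {
  stopifnot(inherits(selected, "kmer_counts"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(reference)) {
    kmers <- names(selected$counts)
    f_sel <- kmer_frequencies(selected, kmers, pseudocount)
    enr <- f_sel * 4^selected$k
    baseline <- as.numeric(pseudocount /
      (selected$total_windows + pseudocount * 4^selected$k) * 4^selected$k)
    ref_id <- "uniform"
  } else {
    stopifnot(inherits(reference, "kmer_counts"))
    if (selected$k != reference$k)
      stop("selected and reference tables have different k")
    if (reference$total_windows < 5 * 4^selected$k)
      warning("reference table is shallow relative to the 4^k universe; ",
              "consider the uniform reference (reference = NULL)")
    kmers <- sort(union(names(selected$counts), names(reference$counts)),
                  method = "radix")
    f_sel <- kmer_frequencies(selected, kmers, pseudocount)
    f_ref <- kmer_frequencies(reference, kmers, pseudocount)
    enr <- f_sel / f_ref
    baseline <- (pseudocount / (selected$total_windows + pseudocount * 4^selected$k)) /
      (pseudocount / (reference$total_windows + pseudocount * 4^selected$k))
    ref_id <- reference$sample_id
  }
  structure(list(k = selected$k,
                 enrichment = enr,
                 baseline = baseline,
                 selected_sample = selected$sample_id,
                 reference_sample = ref_id,
                 pseudocount = pseudocount),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  top <- rank_kmers(x, min(5L, length(x$enrichment)))
  cat("k-mer enrichment table (k = ", x$k, "), ",
      length(x$enrichment), " k-mers; top:\n", sep = "")
  print(top)
  invisible(x)
}

#' Rank k-mers by enrichment
#'
#' Descending by score; ties broken by ascending lexicographic (C
#' collation) order, so the ranking is total and platform independent.
#'
#' @param table an [compute_enrichment()] table (or any named numeric
#'   vector of scores).
#' @param n number of top k-mers to return (`<= 4^k`).
#' @return data frame with columns `kmer`, `score`, `rank`.
#' @export
rank_kmers <- function(table, n) {
  scores <- if (inherits(table, "enrichment_table")) table$enrichment else table
  stopifnot(!is.null(names(scores)))
  if (inherits(table, "enrichment_table") && n > 4^table$k)
    stop("n exceeds the k-mer universe size")
  o <- order_desc_lex(scores, names(scores))
  o <- o[seq_len(min(n, length(o)))]
  data.frame(kmer = names(scores)[o], score = unname(scores[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Reproducibility of two replicate landscapes
#'
#' Pearson correlation across k-mers between two replicate samples,
#' computed on the union of each table's `top_n` most abundant k-mers.
#' By default the correlated quantity is log10 enrichment over the
#' replicate's own reference (input library); log10 counts or raw counts
#' are available when no reference exists.
#'
#' @param a,b [count_kmers()] tables for the two replicates (same `k`).
#' @param top_n per-table number of most abundant k-mers defining the
#'   compared universe (>= 2); capped at the observed universe.
#' @param value `"log10_enrichment"`, `"log10_count"` or `"count"`.
#' @param reference_a,reference_b round-0 tables for the enrichment
#'   space; `NULL` uses the uniform reference (see
#'   [compute_enrichment()]).
#' @param pseudocount pseudocount for frequencies/enrichment and for
#'   log counts.
#' @return Pearson correlation coefficient (single number).
#' @export
replicate_correlation <- function(a, b, top_n = 120000L,
                                  value = c("log10_enrichment", "log10_count",
                                            "count"),
                                  reference_a = NULL, reference_b = NULL,
                                  pseudocount = 0.5) {
  value <- match.arg(value)
  stopifnot(inherits(a, "kmer_counts"), inherits(b, "kmer_counts"))
  if (a$k != b$k) stop("tables have different k")
  if (top_n < 2) stop("top_n must be >= 2")
  top_of <- function(tb) {
    o <- order_desc_lex(tb$counts, names(tb$counts))
    names(tb$counts)[o[seq_len(min(top_n, length(o)))]]
  }
  kmers <- union(top_of(a), top_of(b))
  if (value == "log10_enrichment") {
    ea <- compute_enrichment(a, reference_a, pseudocount)
    eb <- compute_enrichment(b, reference_b, pseudocount)
    look <- function(e) {
      v <- e$enrichment[kmers]
      v[is.na(v)] <- e$baseline
      log10(v)
    }
    va <- look(ea); vb <- look(eb)
  } else {
    look <- function(tb) {
      v <- as.numeric(tb$counts[kmers])
      v[is.na(v)] <- 0
      if (value == "log10_count") log10(v + pseudocount) else v
    }
    va <- look(a); vb <- look(b)
  }
  if (length(kmers) < 2L || stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("degenerate (zero-variance) landscape; correlation undefined")
  stats::cor(va, vb)
}
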