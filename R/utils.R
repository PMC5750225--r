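#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Normalise sequences to the RNA alphabet
#'
#' Upper-cases input and maps T to U. Any residual character outside
#' A/C/G/U is an error: the package works on single-stranded RNA and never
#' reverse-complements.
#'
#' @param x character vector of sequences.
#' @return character vector over the alphabet A, C, G, U.
#' @export
as_rna <- function(x) {
  x <- chartr("T", "U", toupper(as.character(x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("sequences contain characters outside the RNA alphabet (A/C/G/U): ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  x
}

## All 4^k RNA k-mers in lexicographic order (small k only).
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 12)
  g <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  sort(do.call(paste0, g))
}

## Flat vector of all overlapping k-windows, read by read.
## Reads shorter than k contribute nothing.
extract_windows <- function(seqs, k) {
  L <- nchar(seqs)
  out <- vector("list", length(unique(L)))
  i <- 0L
  for (len in unique(L)) {
    if (len < k) next
    i <- i + 1L
    rs <- seqs[L == len]
    n <- len - k + 1L
    out[[i]] <- unlist(lapply(seq_len(n), function(j) substring(rs, j, j + k - 1L)),
                       use.names = FALSE)
  }
  unlist(out[seq_len(i)], use.names = FALSE)
}

## Per-sequence window matrix for equal-length sequences (n x n_windows).
window_matrix <- function(seqs, k) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L, L >= k)
  n <- L - k + 1L
  vapply(seq_len(n), function(j) substring(seqs, j, j + k - 1L),
         character(length(seqs)))
}

## Deterministic descending order by score, ascending lexicographic ties
## (C collation, platform independent).
order_desc_lex <- function(score, name) {
  order(-score, name, method = "radix")
}
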