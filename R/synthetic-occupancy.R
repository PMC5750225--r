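#' Configuration for simulated protein-occupancy sites
#'
#' Emulates short sequence windows centered on a crosslink site, as obtained
#' from CLIP-style profiling of an RNA-binding protein: positives carry a
#' planted recognition motif near the window center, negatives are drawn
#' from a background base composition.
#'
#' @param n_positive,n_negative numbers of labeled windows.
#' @param window_len window length in bases.
#' @param motif RNA motif planted in positives (length <= `window_len`).
#' @param plant_offset_jitter maximal shift (bases) of the motif start
#'   around the centered position, uniform on the integer range.
#' @param background_composition base probabilities for A, C, G, U; must
#'   sum to 1.
#' @param seed integer seed.
#' @return an object of class `occupancy_config`.
#' @export
occupancy_config <- function(n_positive = 200L, n_negative = 200L,
                             window_len = 50L,
                             motif = strrep("A", 12L),
                             plant_offset_jitter = 0L,
                             background_composition = rep(0.25, 4),
                             seed = 1L) {
  motif <- as_rna(motif)
  stopifnot(n_positive >= 0, n_negative >= 0, plant_offset_jitter >= 0)
  if (window_len < nchar(motif))
    stop("motif is longer than the window")
  if (length(background_composition) != 4 ||
      abs(sum(background_composition) - 1) > 1e-9 ||
      any(background_composition < 0))
    stop("background_composition must be 4 nonnegative probabilities summing to 1")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 window_len = as.integer(window_len),
                 motif = motif,
                 plant_offset_jitter = as.integer(plant_offset_jitter),
                 background_composition = background_composition,
                 seed = as.integer(seed)),
            class = "occupancy_config")
}

random_background <- function(n, len, composition) {
  if (n == 0L) return(character(0))
  mat <- matrix(sample(RNA_BASES, n * len, replace = TRUE, prob = composition),
                nrow = n, ncol = len)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Bundle sequences, binary occupancy labels and crosslink centers
#'
#' @param seq character vector of RNA sequences.
#' @param label integer/logical vector, 1 = bound (positive).
#' @param center optional 0-based center coordinates; defaults to
#'   `floor(length / 2)`.
#' @return an object of class `labeled_sequences` (a data frame with
#'   columns `id`, `seq`, `label`, `center`).
#' @export
labeled_sequences <- function(seq, label, center = NULL) {
  seq <- as_rna(seq)
  label <- as.integer(label)
  stopifnot(length(label) == length(seq), all(label %in% c(0L, 1L)))
  if (is.null(center)) center <- as.integer(nchar(seq) %/% 2L)
  stopifnot(length(center) == length(seq),
            all(center >= 0), all(center < nchar(seq)))
  structure(data.frame(id = sprintf("site_%05d", seq_along(seq)),
                       seq = seq, label = label, center = as.integer(center),
                       stringsAsFactors = FALSE),
            class = c("labeled_sequences", "data.frame"))
}

#' Simulate labeled occupancy windows
#'
#' Positives are background windows with the motif overwritten so that its
#' own center lands on the window center (0-based index `floor(L/2)`) plus
#' a uniform jitter; negatives are pure background. All coordinates are
#' 0-based.
#'
#' @param config an [occupancy_config()].
#' @return a [labeled_sequences()] object with an attribute
#'   `motif_start` giving the 0-based planted start per positive.
#' @export
simulate_occupancy_sites <- function(config) {
  stopifnot(inherits(config, "occupancy_config"))
  with_seed(config$seed, {
    L <- config$window_len
    m <- nchar(config$motif)
    center <- L %/% 2L
    centered_start <- center - m %/% 2L
    jit <- config$plant_offset_jitter
    pos <- random_background(config$n_positive, L, config$background_composition)
    starts <- integer(config$n_positive)
    if (config$n_positive > 0) {
      offs <- if (jit > 0) sample(seq(-jit, jit), config$n_positive, replace = TRUE)
              else rep(0L, config$n_positive)
      starts <- pmin(pmax(centered_start + offs, 0L), L - m)
      pos <- paste0(substr(pos, 1L, starts),
                    config$motif,
                    substr(pos, starts + m + 1L, L))
    }
    neg <- random_background(config$n_negative, L, config$background_composition)
    out <- labeled_sequences(c(pos, neg),
                             c(rep(1L, config$n_positive), rep(0L, config$n_negative)),
                             rep(center, config$n_positive + config$n_negative))
    attr(out, "motif_start") <- starts
    attr(out, "motif") <- config$motif
    out
  })
}

#' Write a labeled set as FASTA plus a label/center TSV
#'
#' @param x a [labeled_sequences()] object.
#' @param fasta,tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_labeled_sequences <- function(x, fasta, tsv) {
  s <- Biostrings::BStringSet(x$seq)
  names(s) <- x$id
  Biostrings::writeXStringSet(s, fasta, format = "fasta")
  utils::write.table(x[, c("id", "label", "center")], tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read a labeled set from FASTA plus a label/center TSV
#'
#' @param fasta,tsv paths written by [write_labeled_sequences()].
#' @return a [labeled_sequences()] object.
#' @export
read_labeled_sequences <- function(fasta, tsv) {
  s <- Biostrings::readBStringSet(fasta, format = "fasta")
  meta <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  meta <- meta[match(names(s), meta$id), ]
  labeled_sequences(as.character(s), meta$label, meta$center)
}

#' Composition-matched shuffled negatives
#'
#' Order 0 permutes each sequence's bases (exact mononucleotide
#' preservation). Order 1 performs a dinucleotide-preserving shuffle by the
#' Eulerian-path construction (Altschul-Erickson style): the sequence is a
#' walk on the base graph whose edges are its dinucleotides; a random
#' edge arrangement whose per-vertex last edges form a tree into the
#' terminal base yields a new walk with exactly the same dinucleotide
#' multiset. This is the standard control for base-content bias in motif
#' scoring.
#'
#' @param seqs character vector of RNA sequences.
#' @param order 0 (mononucleotide) or 1 (dinucleotide-preserving).
#' @param seed optional integer seed.
#' @return character vector of shuffled sequences. Sequences shorter than
#'   `order + 1` are returned unchanged with a warning.
#' @export
make_matched_negatives <- function(seqs, order = 1L, seed = NULL) {
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  seqs <- as_rna(seqs)
  with_seed(seed, {
    short <- nchar(seqs) < order + 1L
    if (any(short))
      warning(sum(short), " sequence(s) shorter than order + 1 returned unchanged")
    out <- seqs
    idx <- which(!short)
    if (order == 0L) {
      out[idx] <- vapply(seqs[idx], function(s) {
        paste0(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    } else {
      out[idx] <- vapply(seqs[idx], dinuc_shuffle_one, character(1),
                         USE.NAMES = FALSE)
    }
    out
  })
}

## One dinucleotide-preserving shuffle via a random Eulerian walk.
dinuc_shuffle_one <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) return(s)
  verts <- unique(ch)
  first <- ch[1L]
  last <- ch[n]
  edges <- split(ch[-1L], factor(ch[-n], levels = verts))
  inner <- setdiff(verts, last)
  ## pick per-vertex last edges until they form a tree rooted at `last`
  repeat {
    last_edge <- vapply(inner, function(v) {
      tg <- edges[[v]]
      tg[sample.int(length(tg), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in inner) {
      cur <- v
      for (step in seq_len(length(verts) + 1L)) {
        if (cur == last) break
        cur <- last_edge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  arranged <- lapply(verts, function(v) {
    tg <- edges[[v]]
    if (v %in% inner) {
      i <- match(last_edge[[v]], tg)
      rest <- tg[-i]
      c(if (length(rest)) rest[sample.int(length(rest))], tg[i])
    } else {
      if (length(tg) > 1L) tg[sample.int(length(tg))] else tg
    }
  })
  names(arranged) <- verts
  res <- character(n)
  res[1L] <- first
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2:n) {
    nxt <- arranged[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste0(res, collapse = "")
}
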