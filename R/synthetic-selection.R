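#' Configuration for a simulated SEQRS selection experiment
#'
#' The simulated experiment mirrors the bench protocol: an RNA library with a
#' randomized region between two constant primer-derived flanks is carried
#' through iterative rounds of affinity selection against an immobilized
#' protein, and every round (including the unselected input, round 0) is
#' sequenced.
#'
#' @param random_region_len length of the randomized region in bases.
#' @param n_rounds number of selection rounds (>= 1).
#' @param pool_size number of molecules carried in the selection pool. This
#'   is deliberately much larger than the sequencing depth: in the bench
#'   protocol the bound RNA is re-amplified between rounds, so the carried
#'   pool is never bottlenecked down to the number of sequenced reads.
#' @param reads_per_round sequencing depth: reads drawn from each round's
#'   pool for the per-round FASTQ.
#' @param nonspecific_fraction probability in `[0, 1]` that a molecule is
#'   carried through a round by background (abundance-proportional) capture
#'   rather than by affinity.
#' @param primer_5,primer_3 constant flank sequences (RNA).
#' @param seed integer seed; identical seeds reproduce identical pools.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(random_region_len = 20L,
                             n_rounds = 5L,
                             pool_size = 1e6,
                             reads_per_round = 1e5,
                             nonspecific_fraction = 0.2,
                             primer_5 = "GGGAAUGGAUCCACAUCUACG",
                             primer_3 = "UUCACUGCAGACUUGACGAAG",
                             seed = 1L) {
  stopifnot(random_region_len >= 1, n_rounds >= 1,
            reads_per_round >= 1, nchar(primer_5) > 0, nchar(primer_3) > 0)
  if (pool_size <= 0) stop("pool_size must be positive")
  if (nonspecific_fraction < 0 || nonspecific_fraction > 1)
    stop("nonspecific_fraction must lie in [0, 1]")
  structure(list(random_region_len = as.integer(random_region_len),
                 n_rounds = as.integer(n_rounds),
                 pool_size = as.integer(pool_size),
                 reads_per_round = as.integer(reads_per_round),
                 nonspecific_fraction = nonspecific_fraction,
                 primer_5 = as_rna(primer_5),
                 primer_3 = as_rna(primer_3),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Ground-truth affinity model over k-mers
#'
#' Relative affinity of the protein for each length-`k` RNA word. Listed
#' k-mers carry explicit weights; every unlisted k-mer falls back to the
#' `background` weight, so the lookup is defined for all `4^k` words. A
#' sequence's affinity aggregates its sliding windows either by the best
#' site (`max_window`, occupancy dominated by the strongest contact) or by
#' the sum over sites (`sum_windows`, multi-site binding).
#'
#' @param k word length.
#' @param weights named nonnegative numeric vector of explicit k-mer weights
#'   (may be empty).
#' @param background weight for unlisted k-mers (>= 0).
#' @param aggregation `"max_window"` or `"sum_windows"`.
#' @return an object of class `affinity_model`.
#' @seealso [poly_a_affinity()] for the adenosine-preferring default.
#' @export
affinity_model <- function(k, weights = numeric(0), background = 1,
                           aggregation = c("max_window", "sum_windows")) {
  aggregation <- match.arg(aggregation)
  stopifnot(k >= 1, background >= 0)
  if (length(weights)) {
    if (is.null(names(weights)) || any(nchar(names(weights)) != k))
      stop("weights must be named by length-", k, " k-mers")
    names(weights) <- as_rna(names(weights))
    if (any(weights < 0)) stop("affinity weights must be nonnegative")
  }
  if (background == 0 && (!length(weights) || all(weights == 0)))
    stop("at least one weight must be positive")
  structure(list(k = as.integer(k), weights = weights,
                 background = background, aggregation = aggregation),
            class = "affinity_model")
}

#' Adenosine-preferring affinity model
#'
#' Energy-additive model of a Poly(A)-binding domain: every adenosine in the
#' binding window contributes an equal free-energy increment, so relative
#' affinity is `background * fold_per_a^(number of A in the window)`. The
#' default fold change of 1.4 per adenosine (about 0.2 kcal/mol per contact
#' at 22 degrees C) is calibrated so that a default-sized simulated
#' selection reproduces the two signatures of the bench assay at once: the
#' adenosine homopolymer tops the round-5 enrichment landscape, and
#' independent replicate selections give strongly correlated landscapes.
#' See the methods vignette for the calibration rationale.
#'
#' @param k binding-window length (default 10, the word size over which the
#'   specificity landscape is read out).
#' @param fold_per_a multiplicative affinity gain per adenosine.
#' @param background affinity of an A-free window (> 0).
#' @param aggregation see [affinity_model()].
#' @return an `affinity_model` whose weights are computed analytically from
#'   adenosine content rather than stored as an explicit table.
#' @export
poly_a_affinity <- function(k = 10L, fold_per_a = 1.4, background = 1,
                            aggregation = "max_window") {
  stopifnot(fold_per_a > 0, background > 0)
  m <- affinity_model(k, numeric(0), background, aggregation)
  m$fold_per_a <- fold_per_a
  m
}

## Vectorized weight lookup for a vector of k-mers.
kmer_weight <- function(model, kmers) {
  if (!is.null(model$fold_per_a)) {
    n_a <- nchar(kmers) - nchar(gsub("A", "", kmers, fixed = TRUE))
    return(model$background * model$fold_per_a^n_a)
  }
  w <- unname(model$weights[kmers])
  w[is.na(w)] <- model$background
  w
}

#' Aggregate affinity of sequences under a model
#'
#' Slides the model's k-window over each sequence and aggregates window
#' weights by the model's aggregation rule. Sequences shorter than `k`
#' get weight 0.
#'
#' @param model an [affinity_model()].
#' @param seqs character vector of RNA sequences (the randomized regions).
#' @return numeric vector of per-sequence affinities.
#' @export
sequence_affinity <- function(model, seqs) {
  seqs <- as_rna(seqs)
  L <- nchar(seqs)
  out <- numeric(length(seqs))
  for (len in unique(L)) {
    idx <- which(L == len)
    if (len < model$k) next
    if (!is.null(model$fold_per_a)) {
      ## running adenosine count per window, computed on a logical matrix
      ch <- matrix(unlist(strsplit(seqs[idx], "", fixed = TRUE), use.names = FALSE) == "A",
                   nrow = length(idx), ncol = len, byrow = TRUE)
      cs <- ch * 1L
      for (j in 2:len) cs[, j] <- cs[, j] + cs[, j - 1L]
      n_win <- len - model$k + 1L
      wins <- vapply(seq_len(n_win), function(s) {
        hi <- cs[, s + model$k - 1L]
        if (s == 1L) hi else hi - cs[, s - 1L]
      }, numeric(length(idx)))
      wins <- matrix(wins, nrow = length(idx))
      w <- model$background * model$fold_per_a^wins
    } else {
      wm <- window_matrix(seqs[idx], model$k)
      w <- matrix(kmer_weight(model, wm), nrow = length(idx))
    }
    out[idx] <- if (model$aggregation == "max_window")
      do.call(pmax, as.data.frame(w)) else rowSums(w)
  }
  out
}

#' Generate the unselected (round-0) library
#'
#' Draws `pool_size` molecules whose randomized regions are i.i.d. uniform
#' over A/C/G/U, with the constant flanks attached.
#'
#' @param config a [selection_config()].
#' @return an object of class `seq_pool`: a data frame with columns `region`
#'   and `count`, plus the flanks as attributes.
#' @export
generate_initial_library <- function(config) {
  stopifnot(inherits(config, "selection_config"))
  with_seed(config$seed, {
    L <- config$random_region_len
    n <- config$pool_size
    mat <- matrix(sample(RNA_BASES, n * L, replace = TRUE), nrow = n, ncol = L)
    regions <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    tab <- table(regions)
    pool <- data.frame(region = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
    structure(pool, class = c("seq_pool", "data.frame"),
              primer_5 = config$primer_5, primer_3 = config$primer_3)
  })
}

#' Simulate one round of affinity selection
#'
#' RNA-protein complexes surviving the wash steps are modeled as a
#' multinomial resample of the pool: sequence `s` with count `c(s)` and
#' aggregate affinity `w(s)` is drawn with probability proportional to
#' `(1 - beta) * c(s) w(s) / sum(c w) + beta * c(s) / sum(c)`, where `beta`
#' is the nonspecific (background carry-over) fraction.
#'
#' @param pool a `seq_pool`.
#' @param model an [affinity_model()].
#' @param nonspecific_fraction `beta` in `[0, 1]`.
#' @param reads_out total molecules drawn into the next round.
#' @param seed optional integer seed.
#' @return the next-round `seq_pool`.
#' @export
simulate_selection_round <- function(pool, model, nonspecific_fraction,
                                     reads_out, seed = NULL) {
  stopifnot(inherits(pool, "seq_pool"), nrow(pool) > 0, reads_out >= 1)
  beta <- nonspecific_fraction
  if (beta < 0 || beta > 1) stop("nonspecific_fraction must lie in [0, 1]")
  cnt <- pool$count
  p <- beta * cnt / sum(cnt)
  if (beta < 1) {
    w <- sequence_affinity(model, pool$region)
    cw <- cnt * w
    if (sum(cw) == 0)
      stop("all sequence affinities are zero; give the affinity model a ",
           "nonzero background weight")
    p <- p + (1 - beta) * cw / sum(cw)
  }
  with_seed(seed, {
    new_cnt <- as.integer(stats::rmultinom(1L, size = as.integer(reads_out), prob = p))
    keep <- new_cnt > 0L
    structure(data.frame(region = pool$region[keep], count = new_cnt[keep],
                         stringsAsFactors = FALSE),
              class = c("seq_pool", "data.frame"),
              primer_5 = attr(pool, "primer_5"), primer_3 = attr(pool, "primer_3"))
  })
}

#' Expand a pool into individual reads
#'
#' @param pool a `seq_pool`.
#' @param with_primers attach the constant flanks?
#' @return character vector with one element per molecule.
#' @export
pool_reads <- function(pool, with_primers = FALSE) {
  reads <- rep(pool$region, pool$count)
  if (with_primers)
    reads <- paste0(attr(pool, "primer_5"), reads, attr(pool, "primer_3"))
  reads
}

#' Draw a sequencing sample from a pool
#'
#' Multinomial subsample of `depth` molecules in proportion to their pool
#' abundances — sequencing observes a sample of the pool, not the pool
#' itself.
#'
#' @param pool a `seq_pool`.
#' @param depth number of reads.
#' @param seed optional integer seed.
#' @return a `seq_pool` of `depth` molecules.
#' @export
sample_reads <- function(pool, depth, seed = NULL) {
  stopifnot(inherits(pool, "seq_pool"), depth >= 1)
  with_seed(seed, {
    cnt <- as.integer(stats::rmultinom(1L, as.integer(depth),
                                       prob = pool$count))
    keep <- cnt > 0L
    structure(data.frame(region = pool$region[keep], count = cnt[keep],
                         stringsAsFactors = FALSE),
              class = c("seq_pool", "data.frame"),
              primer_5 = attr(pool, "primer_5"),
              primer_3 = attr(pool, "primer_3"))
  })
}

#' Simulate a full SEQRS experiment
#'
#' Runs `n_rounds` of selection from a fresh random library. Each round
#' carries `pool_size` molecules (re-amplification keeps the pool large),
#' and `reads_per_round` molecules are sequenced from every round,
#' including the unselected input (round 0). One FASTQ file is written per
#' round, plus a TSV manifest recording the simulation parameters.
#' Qualities are a constant 'I' (Phred+33 score 40); they are never used
#' downstream.
#'
#' @param config a [selection_config()].
#' @param model an [affinity_model()].
#' @param out_dir output directory; created if missing. `NULL` keeps the
#'   simulation in memory only.
#' @return invisibly, a list with `pools` (carried pools, rounds 0..n),
#'   `reads` (sequenced samples as `seq_pool`s, rounds 0..n), `files`
#'   (FASTQ paths or `NULL`), and `manifest` (data frame).
#' @export
simulate_seqrs <- function(config, model, out_dir = NULL) {
  stopifnot(inherits(config, "selection_config"), inherits(model, "affinity_model"))
  pools <- vector("list", config$n_rounds + 1L)
  pools[[1L]] <- generate_initial_library(config)
  for (r in seq_len(config$n_rounds)) {
    pools[[r + 1L]] <- simulate_selection_round(
      pools[[r]], model, config$nonspecific_fraction,
      reads_out = config$pool_size,
      seed = config$seed + 1000L * r)
  }
  names(pools) <- paste0("round_", 0:config$n_rounds)
  reads <- lapply(seq_along(pools), function(i)
    sample_reads(pools[[i]], config$reads_per_round,
                 seed = config$seed + 1000L * (i - 1L) + 500L))
  names(reads) <- names(pools)
  manifest <- data.frame(
    round = 0:config$n_rounds,
    file = paste0("round_", 0:config$n_rounds, ".fastq"),
    pool_molecules = vapply(pools, function(p) sum(p$count), numeric(1)),
    pool_unique = vapply(pools, nrow, integer(1)),
    reads = vapply(reads, function(p) sum(p$count), numeric(1)),
    nonspecific_fraction = config$nonspecific_fraction,
    seed = config$seed,
    model_k = model$k,
    model_aggregation = model$aggregation,
    stringsAsFactors = FALSE)
  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
    files <- file.path(out_dir, manifest$file)
    for (i in seq_along(files))
      write_pool_fastq(reads[[i]], files[i])
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(pools = pools, reads = reads, files = files,
                 manifest = manifest))
}

#' Write a pool as FASTQ
#'
#' One record per molecule, constant flanks attached, constant quality 'I'.
#'
#' @param pool a `seq_pool`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pool_fastq <- function(pool, path) {
  reads <- pool_reads(pool, with_primers = TRUE)
  x <- Biostrings::BStringSet(reads)
  names(x) <- sprintf("mol_%06d", seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' Reads are normalised to the RNA alphabet (T is mapped to U).
#'
#' @param path input file.
#' @param format `"fastq"` or `"fasta"`.
#' @return character vector of sequences.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  as_rna(as.character(Biostrings::readBStringSet(path, format = format)))
}

#' @export
print.seq_pool <- function(x, ...) {
  cat("SEQRS sequence pool:", sum(x$count), "molecules,",
      nrow(x), "unique regions of length",
      unique(nchar(x$region))[1L], "nt\n")
  invisible(x)
}
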