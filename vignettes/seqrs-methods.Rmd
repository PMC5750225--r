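---
title: "Models and methods behind seqrstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seqrstools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqrstools)
```

# Scope

`seqrstools` implements the computational side of a SEQRS experiment —
iterative in vitro selection of a randomized RNA library against an
immobilized RNA-binding protein, read out by high-throughput sequencing of
every round — together with the downstream analyses such an experiment
feeds: k-mer enrichment landscapes, replicate reproducibility, position
frequency matrices and sequence logos, likelihood classifiers validated by
cross-validated ROC against protein-occupancy windows, equilibrium binding
and RNA-decay curve fits, and a small set of two-channel imaging
quantifications. Because real selections and occupancy datasets are rarely
redistributable, the package ships a first-class synthetic-data layer with
known ground truth; every analysis can be exercised end to end without any
external file.

The running example throughout is a Poly(A)-binding protein (PABP): a
protein whose specificity is dominated by adenosine content, whose
highest-affinity site is an adenosine homopolymer, and which needs on the
order of a dozen consecutive bases for a full-affinity contact.

# The selection simulator

## Library and rounds

The simulated library is a randomized region (default 20 nt, i.i.d.
uniform over A/C/G/U) between two constant primer flanks. One selection
round is modeled as multinomial resampling of the carried pool: a sequence
$s$ with count $c(s)$ and aggregate affinity $w(s)$ is drawn with
probability

$$P(s) \propto (1-\beta)\,\frac{c(s)\,w(s)}{\sum_{s'} c(s')w(s')}
       + \beta\,\frac{c(s)}{\sum_{s'} c(s')},$$

where $\beta$ (`nonspecific_fraction`, default 0.2) is the fraction of
molecules carried through by background capture rather than by binding.
This is the simplest update that produces round-over-round enrichment; PCR
amplification bias and sequencing error are deliberately not modeled, as
they are not needed to exercise the downstream analyses.

Two sizes are distinct on purpose. The **carried pool** (`pool_size`,
default $10^6$) is resampled at its own size every round: on the bench the
bound RNA is re-amplified between rounds, so the pool is never
bottlenecked down to the sequenced sample. The **sequencing depth**
(`reads_per_round`, default $10^5$) is a multinomial subsample of each
round's pool, written as FASTQ (constant quality, since qualities carry no
information here). Collapsing these two — carrying only as many molecules
as are sequenced — makes selection winner-take-all within two or three
rounds and destroys the replicate reproducibility that the real assay
shows; decoupling them is the single most consequential design choice in
the simulator.

## The ground-truth affinity model

No quantitative specificity model for PABP exists to copy, so the package
defines one. `poly_a_affinity()` is energy-additive:
each adenosine in a binding window of width $k$ (default 10) contributes
an equal free-energy increment, giving relative affinity

$$w(m) = \mathrm{background} \times f^{\,n_A(m)},$$

with $f$ = `fold_per_a` and a sequence's affinity the maximum over its
sliding windows (occupancy dominated by the best site; `sum_windows` is
available for multi-site binding). The default $f = 1.4$ (about
0.2 kcal/mol per adenosine contact at 22 °C) was calibrated once so that
the simulator reproduces, at its default sizes, the two qualitative
behaviours the real experiment shows simultaneously: the most enriched
10-mer after five rounds is the adenosine homopolymer, and independent
replicate selections give strongly correlated k-mer landscapes (Pearson r
around 0.8 at the package's replicate-study scale, comparable to the
reproducibility reported for the bench assay). Much stronger per-base
energies concentrate the final pool onto a handful of founder molecules —
enrichment still finds the homopolymer, but replicates stop agreeing
because each replicate's winners are private; much weaker energies spread
the signal so thin that the homopolymer no longer tops the landscape.
Arbitrary tabulated models (`affinity_model()`) are supported for other
specificities.

Everything in the alphabet is RNA (T maps to U on input) and no
reverse-complement scanning happens anywhere: binding is to
single-stranded RNA. RNA secondary structure is not simulated. Coordinates
are 0-based; window centers sit at `floor(L/2)`.

# Enrichment landscapes

`count_kmers()` tallies every overlapping window of the retained random
regions; `compute_enrichment()` forms pseudocounted frequency ratios

$$E(m) = \frac{(c_{\mathrm{sel}}(m)+p)/(T_{\mathrm{sel}}+p\,4^k)}
              {(c_{\mathrm{ref}}(m)+p)/(T_{\mathrm{ref}}+p\,4^k)},$$

with a Jeffreys-style default $p = 0.5$. The reference is normally the
round-0 (input) sample. One numerical caveat matters at $k = 10$: a
$10^5$-read sample spreads roughly $10^6$ windows over $4^{10} \approx
10^6$ possible words, so a *sampled* round-0 table has mean count ~1 per
k-mer and its sampling noise dominates the ratio. For a library that is
uniform by construction the package therefore also offers the uniform
expectation as reference (`reference = NULL`, $E(m) = f_{\mathrm{sel}}(m)
\cdot 4^k$), and warns when a supplied reference is shallow relative to
the universe (mean count below ~5). The bundled analyses use the exactly
known input-pool composition as the round-0 reference at $k = 10$.

Ranking (`rank_kmers()`) is descending by score with ascending
lexicographic tie-break in C collation — a total, platform-independent
order. Replicate reproducibility (`replicate_correlation()`) is a Pearson
correlation of log10 enrichment (or log10/raw counts) over the union of
each replicate's `top_n` most abundant k-mers; `top_n` defaults to
120,000, capped at the observed universe. The replicate study bundled with
the package runs at pool $2\times10^5$, depth $5\times10^4$, $k = 6$:
at that granularity each informative k-mer is carried by hundreds of
independent molecules, so the correlation measures the landscape rather
than founder noise.

# Motif models, logos, and the likelihood classifier

`build_pfm()` converts a ranked k-mer set (e.g. the top 50 8-mers) into a
weighted position frequency matrix with log-odds
$\log_2(\mathrm{PFM}/\mathrm{background})$; zero entries are floored at
`pseudofreq` ($10^{-3}$) rather than smoothing the whole matrix, so fully
conserved positions keep their exact 2-bit log-odds. The same object keeps
the raw k-mer set, because two scoring semantics are genuinely needed:
continuous best-site scores (`max_window_logodds`) for ROC analysis, and
occurrence counts (`hit_count`) for positional-density contrasts.

`build_logo()` computes per-position information content
$(2 - H_{\mathrm{pos}})$ bits apportioned to bases by frequency, with
equal weighting of the input k-mers (an enrichment-weighted variant is a
parameter away) and no small-sample correction — with hundreds of input
k-mers the correction is negligible.

`train_likelihood()` is the "learned data likelihood": class-conditional
pseudocounted k-mer frequency models for bound and unbound training
sequences, scored by the average per-window log-likelihood ratio
(`score_llr()`). The word size defaults to $k = 6$ — long enough to see
run structure, short enough that a few hundred 50-nt windows estimate the
class frequencies. Swapping the classes negates every score exactly, a
property the tests assert.

# Occupancy validation

`mann_whitney()` computes U from midrank sums; p-values are exact by full
enumeration whenever both groups have at most 8 observations and no ties
(at most $\binom{16}{8} = 12{,}870$ arrangements — instant), otherwise
the normal approximation with tie and continuity corrections is used.
The two-sided alternative is the default.

`roc_curve()` sweeps thresholds over unique scores in descending order, so
tied scores contribute diagonal segments — exactly the convention under
which the trapezoidal area equals the normalized Mann–Whitney U statistic
(concordant pairs plus half the ties). That identity is enforced in the
tests against an exhaustive pair-counting oracle.

`cross_validated_auc()` partitions the labeled set into stratified folds
(stratification is on by default; small minority classes otherwise break
folds, and a non-stratified run that loses a class in some fold falls back
to stratified with a warning), trains on each 9/10, scores the held-out
1/10, and vertically averages the fold ROCs on a fixed 101-point
false-positive-rate grid before integrating by trapezoids. Vertical
averaging on a fixed grid was chosen over threshold averaging because it
is deterministic and standard. At vertical jumps the upper envelope is
interpolated.

`kmer_positional_density()` profiles where a k-mer set lands relative to
recorded crosslink centers (offset 0 = center), with the cumulative
distribution normalized over hits.

## Composition-matched controls

`make_matched_negatives()` produces shuffled controls preserving each
sequence's base multiset (order 0) or dinucleotide multiset (order 1, by
the Eulerian-path construction: per-vertex last edges are drawn until they
form a tree into the terminal base, remaining edges are permuted, and the
new walk is read off — preservation is exact, and the first and last base
are fixed by construction). One subtlety worth knowing: a
dinucleotide-preserving shuffle of a sequence containing a long A-run
keeps all its AA dinucleotides, which re-chain into substantial A-runs in
the control. For a homopolymer motif the order-1 control is therefore a
deliberately hard negative; the bundled classifier benchmarks use order-0
(mononucleotide) controls, which match base content while scattering the
run.

# Curve fitting

`fit_kd()` fits the hyperbolic saturation form
$y = A_{\mathrm{free}} + (A_{\mathrm{bound}} - A_{\mathrm{free}})\,
P/(K_d + P)$ — the standard anisotropy model when the labeled probe (0.5
nM in the motivating experiments) is far below $K_d$, so depletion is
negligible. Fitting is Levenberg–Marquardt with multi-start over a
geometric grid of $K_d$ candidates spanning the concentration range;
standard errors come from the fit curvature, with a residual bootstrap as
an option. A quadratic ligand-depletion variant (using the probe
concentration) sits behind `model = "quadratic"`. The concentration unit
throughout is nM; the motivating literature prints the same values in nM
in the text and μM in a figure caption, and nM is the reading consistent
with a 0.5 nM probe and sub-micromolar affinity.

`fit_half_life()` fits $y = y_0\,2^{-t/t_{1/2}}$ under one of two error
models. The default absolute model is raw-scale least squares, seeded by
the log-linear regression of $\log y$ on $t$ and never returning a worse
raw-scale residual sum than that seed. The relative model
(`error_model = "relative"`) minimises squared error of $\log y$ — the
maximum-likelihood estimator when measurement error scales with the
signal, which is how densitometry readouts behave, and the model under
which the bundled recovery study runs. The distinction matters
quantitatively: on the experimental time grid {0, 0.5, 1, 2, 3, 6, 24} h
with an 18 h half-life, only 2.5 half-life units are observed, and a
Cramér–Rao calculation shows a single curve with 5% *additive* noise
cannot determine the half-life to better than ~9% median error by any
estimator, while 5% constant-CV noise on a triplicate series (the bench
design) is recoverable to ~3%. If no observation falls below 90% of the
initial intensity, the decay is not identifiable within the observation
window and the function reports a censored lower bound (the window span)
instead of a point estimate — the honest summary for chemically
stabilized RNAs whose decay is too slow to measure, which real
experiments report as "half-life greater than the observation window".

# Imaging quantification

Three formulas, each a direct matrix computation: Manders M1 (fraction of
above-threshold channel-A intensity in pixels where channel B is also
above threshold), corrected total cell fluorescence (integrated ROI
density minus ROI area times the mean of background-ROI means; "readings"
is plural, so multiple background regions are averaged), and intensity
correlation analysis (sum of mean-centered intensity products over an
ROI). Thresholds are explicit arguments, with `otsu_threshold()` as a
logged automatic option, rather than hidden auto-thresholds. The summary
"percentage of intensity correlation" is ambiguous in its source; the
package reads it as the share of ROIs with a positive ICA score
(`ica_percentage()`) and documents that as one interpretation.
`normalize_to_control()` expresses measurements as percent of a control
group's mean.

# What the synthetic data does and does not show

The generators emulate: graded, composition-driven selection with a
background carry-over fraction; occupancy windows with a planted motif at
a jittered center and composition-matched controls; saturation and decay
curves with additive Gaussian noise; and two-channel images with an exact,
constructed overlap fraction. They do not emulate PCR jackpots, sequencing
error, RNA secondary structure (the bench protocol's EDTA note suggests
structured RNAs are depleted, but no structure model is described to
copy), CLIP-specific biases such as crosslink sequence preference, or
optical blur and shot noise. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well-calibrated on data matching its
assumptions — not that any particular biological dataset will reach the
same numbers.

Problem sizes used by the bundled checks were chosen as the smallest at
which each behaviour is stable: the landscape study runs the full default
experiment (pool $10^6$, depth $10^5$, 5 rounds); the replicate study runs
pool $2\times10^5$, depth $5\times10^4$ with $k=6$ landscapes (pairs of
independent selections, plus no-selection null pairs at half that
size); the
classifier benchmark uses 200 positives and 200 matched controls of 50 nt;
curve recovery uses 100 repeated fits (12-point binding curves at 2%
additive noise; triplicate 7-point decay series at 5% constant-CV noise
on the experimental time grid {0, 0.5, 1, 2, 3, 6, 24} h).

# Reproducibility

Every generator is a pure function of its configuration including the
seed, and restores the caller's RNG state. File outputs are byte-stable
under a fixed seed. The acceptance script (`scripts/acceptance.R`) derives
all of its sub-seeds from a single `--seed` argument.
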