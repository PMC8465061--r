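---
title: "Methods: selection simulation, dyad motif discovery, genome scanning and binding kinetics in selexscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection simulation, dyad motif discovery, genome scanning and binding kinetics in selexscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexscan)
```

# Scope

`selexscan` implements the computational side of a reverse-genetic workflow
for defining a transcription factor's DNA-binding consensus by iterative
restriction-protection selection (REPSA, a SELEX variant in which
protein-bound templates escape type IIS restriction cleavage and survive PCR
amplification). The package covers six analysis layers — selection
simulation, read refinement, ZOOPS EM motif discovery, letter-probability
matrix tools, genome scanning with exact p-values, and binding
quantification (biosensor kinetics and cleavage-protection titrations) —
plus a pipeline orchestrator. This vignette documents the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic data can show.

# Selection simulation

## Template and library model

A selection template is a 73-bp duplex: a 24-bp randomized core between
defined flanks that carry the FokI and BpmI recognition sites
(`selection_template()`). A library (`selection_library`) is a weighted
multiset of core sequences; `generate_library()` draws cores i.i.d. uniform
over `{A,C,G,T}^24`.

## Sequence-to-affinity map

No experiment reports the true mapping from an arbitrary 24-mer to a
dissociation constant, so the simulator uses a standard energetic model
(`affinity_model()`): cores are scored with a planted motif's log2-odds
matrix (best window, either strand — a homodimer binds one site per
template), and

$$K_D(\mathrm{seq}) = K_D^{\min}\,e^{\beta\,(s_{\max} - s(\mathrm{seq}))},$$

monotone non-increasing in score. Defaults used throughout: the planted
motif is built from the dyad consensus `AWTGTRA(N)6TYACAWT` with
`mismatch_prob = 0.02` (each column gives 98% of the probability to the
allowed bases), `kd_min = 3` nM and `beta = 1` per log2-odds unit. With
these values one point mutation at a fixed consensus position multiplies
`K_D` by `exp(log2(0.98 / 0.0067)) ≈ 1.4e3`, which reproduces the
experimentally observed scale of single-point-mutation penalties for this
regulator (roughly 7-fold to >290-fold, with several mutants pushed past
the 1000-nM measurement limit).

## Selection round

One round (`simulate_repsa_round()`) applies, per template,

* occupancy `theta = C / (C + K_D(core))` at protein concentration `C`
  (34 nM dimer by default, the concentration used in the selections);
* survival probability `theta + (1 - theta) (1 - e)` with cleavage
  efficiency `e` (default 0.9) — an occupied template is protected, an
  unoccupied one survives only if the enzyme misses it;
* binomial survival per core, then multinomial resampling with replacement
  back to `pcr_resampling_depth`, keeping library size constant the way PCR
  amplification does. Per-round template counts and cycle numbers are not
  reported for the original selections, so depth is a free configuration
  parameter.

Enzyme identity (FokI in rounds 1–2, BpmI after — the switch made in the
bench protocol to avoid intrinsically cleavage-resistant artifacts) carries
no sequence specificity here; it is expressed only as a per-round cleavage
efficiency.

## What desk-scale selection can and cannot reproduce

The real selection starts from ~6×10^10 molecules; the default simulated
depth is 10^5. A zero-mismatch match to the 20-bp dyad consensus occurs in a
random 24-mer with probability ≈ 6×10^-7 (10 windows × (1/4)^10 × (1/2)^4),
so the full-scale pool contains thousands of perfect sites while a
10^5-molecule pool contains none in ~94% of draws — and selection with
multinomial resampling reweights existing sequences, it never creates new
ones. The bench observation that cleavage-resistant material reaches a
majority of the pool by Round 5 therefore cannot be reproduced by a
uniform-start simulation at desk scale; even a single perfect founder can
reach only ~40% in five rounds, because the per-round enrichment ratio is
capped at `(theta_max + (1 - theta_max) (1 - e)) / (1 - e) ≈ 9.3`. What the
simulation *does* validate is the selection dynamics themselves: with a
doped starting pool (e.g. `plant_consensus_sites()` at 1% prevalence) the
consensus-bearing fraction rises monotonically and exceeds 50% within a few
rounds, and the library's mean motif score is non-decreasing across rounds.
The package's tests assert exactly these properties; the uniform-start
majority criterion is reported as computed (≈0%) rather than adjusted.

## Reads, genomes, sensorgrams, band intensities

`reads_from_library()` emits `flank + core + flank` reads with i.i.d.
substitution errors, optional 5'-truncated flanks, and constant per-base
Phred qualities — refinement needs a thresholdable quality signal, not a
platform error model (homopolymer indels and other platform specifics are
out of scope). `generate_genome()` produces an i.i.d. background genome at a
stated GC content with planted sites and a non-overlapping ORF table
including a divergent gene pair, for scanner and annotation tests.
`simulate_sensorgram()` and `simulate_repa_bands()` are direct evaluations
of the closed-form models described below, plus optional Gaussian noise.

# Read refinement

`refine_reads()` accepts a read when its mean Phred quality is at least 20
(the read-level quality statistic reported for the original data; a
per-base trimming rule is deliberately not used), both flank anchors are
found (first-leftmost match) in the given or reverse-complement
orientation, and the intervening segment is exactly the expected core
length. Anchor matching tolerates one substitution per 10 anchor bases by
default — enough for sequencing error, tight enough to reject chimeras.
Every read lands in exactly one counter (quality/flank/length/passed), so
the statistics always sum to the input count. `deduplicate()` removes exact
forward-strand repeats only; reverse-complement pairs are kept because
collapsing them would erase the strand information that palindrome analysis
uses.

# Motif discovery

`discover_motif()` fits a ZOOPS (zero-or-one occurrence per sequence) motif
model by EM — appropriate because a 24-nt core holds at most one 20-bp
site. All windows on both strands compete within a sequence; the background
is the 0-order composition of the input; every M-step adds a pseudocount of
0.1 per base per column. With `palindromic = TRUE` the count matrix is
averaged with its reverse complement after each M-step; because column
totals are equal, this is the exact maximizer of the expected
complete-data log likelihood under the self-reverse-complementarity
constraint, so the EM objective still increases monotonically. The trace
exposed in the `"ll_trace"` attribute is the EM objective (data log
likelihood plus the Dirichlet-smoothing term corresponding to the
pseudocount); the plain likelihood alone can wiggle by tiny amounts under
MAP smoothing, the objective cannot.

EM is restarted from `n_starts` seedings, each initialized from a randomly
chosen data window (0.55 on the observed base, 0.15 elsewhere); the best
final objective wins. The loss surface has shifted-alignment local optima,
so 10–20 starts are recommended for 20-bp motifs. Inputs larger than 1000
sequences are subsampled (seeded) to a set of 1000, mirroring the practice
of submitting fixed-size refined sets to motif discovery. A
log-likelihood-ratio against the background-only model is reported as
`score_significance`; it is a relative measure for comparing runs on the
same input and deliberately **not** a MEME E-value, whose calibration is
out of scope.

`consensus_from_pwm()` converts columns to IUPAC codes: a single base at
probability ≥ 0.7, a two-base code when the top two sum to ≥ 0.8, else `N`;
the dyad decomposition is read off the longest internal all-N run. With
~400 true sites these thresholds cleanly separate fixed positions (p ≈
0.97), two-base positions (p ≈ 0.5/0.5) and spacer positions (top two ≈
0.55), while being insensitive to sampling noise of a few percent.

# PWM tools

`extend_palindromic()` implements the construction of an extended dyad
matrix from a well-determined block of an asymmetric discovered motif:
columns `block_start..block_end` (length L) are concatenated with their own
reverse complement, giving an exactly self-reverse-complementary width-2L
matrix. Concatenation-with-mirror, not overlay-averaging, is the default
because doubling an 11-column block into 22 columns is only consistent with
non-overlapping concatenation; an `overlap` argument provides the averaged
alternative. Block bounds are explicit arguments (1-based, matching
position numbering in motif tables) since the exact block choice is an
analyst decision.

`iupac_mismatches()` counts positions outside the pattern's allowed sets
(`N` allows all); `spacer_variants()` rebuilds a dyad pattern with a
shorter/longer N spacer, reproducing the 19- and 21-nt spacer-mutant probe
designs. `write_meme_minimal()`/`read_meme_minimal()` round-trip the MEME
minimal motif format (version, alphabet, strands, background, one
letter-probability matrix block) to within 1e-6 per cell; parse errors name
the missing section or offending line.

# Genome scanning

`scan_genome()` scores every window on both strands with
`log2((p + 0.001) / bg)` log-odds (background = 0-order composition of the
scanned sequences, overridable). Exact p-values come from
`score_pvalue_distribution()`: scores are discretized to integers on a
common step (the widest column range spans `granularity = 1000` bins — at
motif width ~22 the discretization error is orders of magnitude below the
10^-4 and 5×10^-6 thresholds in use) and the null distribution of a random
background word is computed by position-wise convolution; the survival
function is exact for the discretized matrix, and tests verify it equals
brute-force enumeration over all 4^w words for widths ≤ 6. q-values are
Benjamini–Hochberg over **all** `2 Σ (len - w + 1)` tested windows, not
just reported ones. Internally coordinates are 0-based half-open; every
emitted coordinate is 1-based inclusive.

`annotate_hits()` keeps hits with `p ≤ 5e-6` and classifies them against a
feature table: a hit within `[-200, +20]` of a gene start (on that gene's
strand) is a promoter-window call; a hit inside both windows of a divergent
gene pair yields two calls flagged bidirectional; otherwise hits are
intragenic or intergenic-far. The annotated gene start (translation start)
is the transcription start proxy, because the organism's transcription
starts are not annotated; offsets against predicted core-promoter +1 sites
from external promoter-prediction tools are therefore **not** reproduced.
Opposite-strand overlapping hits of a palindromic motif at one locus are
reported separately, never merged.

# Binding kinetics

`model_response()` is the closed-form 1:1 Langmuir
association-then-dissociation model (association
`R_eq (1 - e^{-k_obs t})`, `k_obs = k_on C + k_off`,
`R_eq = R_max C / (C + k_off/k_on)`; dissociation
`R(t_s) e^{-k_off (t - t_s)}`), with analyte concentrations in nM (dimeric
protein) converted to M internally. `fit_global()` fits one `(k_on, k_off,
R_max)` across all concentrations by Levenberg–Marquardt least squares in
log-parameter space, from a grid of ≥9 starts log-spaced over `k_on ∈
[10^4, 10^7]`, `k_off ∈ [10^-4, 10^-1]` (lowest SSE wins — the loss is
multimodal at low signal). A single shared `R_max` reflects one sensor
load; `per_trace_rmax = TRUE` relaxes that. `KD = k_off/k_on × 10^9` nM and
pooled `R² = 1 - SSE/SST` are reported. Because the published account of
indeterminate fits says only that parameters "could not be determined
conclusively" with an estimated `K_D > 1000` nM, the ambiguity rule is
operationalized explicitly: `status = "ambiguous"` when fitted KD > 1000
nM, when the optimizer ends on the parameter box boundary, or when R² <
0.5 (including flat, no-signal data). Association/dissociation durations
and `R_max` values are not printed for the original experiments, so
real-trace refits are not attempted; synthetic refits anchored to the
printed rate constants are used instead (a noiseless five-concentration
refit recovers the printed wild-type KD of 3.447 nM exactly to 4
significant figures).

# Cleavage-protection titration

`protection_fraction()` is `uncleaved / (uncleaved + cleaved)` per lane;
`protection_curve()` subtracts the control probe's fraction from the
binding-probe's fraction (clipped to [0, 1]). Subtraction, not a ratio: the
control shares the reaction but carries no binding site, so its cleaved
fraction estimates per-lane enzyme activity. `fit_protection_kd()`
optionally summarizes a curve by fitting `a·C/(C + K)`; `K` is an apparent
half-maximal concentration under the assay's cleavage conditions, not a
calibrated KD, and is not claimed to reproduce any printed value (the
original band intensities are not tabulated, so only property-based checks
apply).

# Pipeline

`run_pipeline()` chains simulate → refine → discover → extend → scan →
annotate with every stage artifact on disk (FASTQ/FASTA/MEME/GFF3/TSV/JSON)
so each CLI subcommand is independently usable; sub-seeds are derived from
the global seed and recorded, and the manifest holds MD5 hashes so reruns
are verifiably byte-identical. The demonstration configuration uses a doped
starting library (5% planted sites) for the reason explained above: it is
the desk-scale stand-in for a full-scale pool in which consensus sites are
present by chance. A missing configuration block fails fast with the block
named. The packaged problem sizes (600–2000 templates, 2–3 rounds, 20–50 kb
genomes, 500–1000 discovery sequences, 10–20 EM starts) were chosen so the
full test suite and the demonstration pipeline each run in well under a
minute to a few minutes on a single CPU while keeping every statistical
check far from its noise floor.

# Known limitations

* The sequence-to-affinity map is a single-site occupancy model with an
  exponential score-energy relation; no partition function over multiple
  sites, no cooperative or flanking-sequence effects.
* Sequencing noise is i.i.d. substitutions plus flank truncation; no
  platform-specific indel model.
* Motif discovery reports the best motif per run; there is no multi-motif
  erasure, no variable-spacer model, and the significance statistic is not
  an E-value.
* Scanning uses a 0-order background; no higher-order Markov background,
  no operon inference, no core-promoter element prediction.
* Passing tests on synthetic data demonstrate correctness of the
  implemented models, not that real selections are free of artifacts
  (enzyme-resistant sequences, amplification bias) — the bench protocol
  controls for those upstream.
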