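---
title: "Calling DNA base modifications from single-molecule sequencing kinetics"
author: "smrtcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling DNA base modifications from single-molecule sequencing kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrtcall)
```

## The measurement and the model

Single-molecule real-time (SMRT) sequencing watches one polymerase copy a
circular template and records, for every incorporated base, the inter-pulse
duration (IPD, the waiting time before the incorporation) and the pulse
width (PW, the duration of the incorporation event). Base modifications on
the template — 5-methylcytosine (5mC), 5-hydroxymethylcytosine (5hmC),
N6-methyladenine (6mA) — slow the polymerase at and around the modified
position, leaving a multiplicative footprint on the kinetics. Because the
circular template is traversed many times, each strand of a molecule
yields several subreads whose kinetics can be aggregated onto consensus
coordinates; the number of passes per strand is the *subread depth*, and
aggregation accuracy grows with it.

`smrtcall` turns this signal into per-site modification calls. For a
candidate site (the C of a CpG, or an adenine) it assembles a *measurement
window*: 10 nt of context on either side of the target (21 rows by
default), with one row per position carrying the normalized kinetics, a
one-hot base identity, an adapter flag and the relative position. A
compact convolutional + transformer network maps the window to a
*modification score* in [0, 1] (the softmax probability of the modified
class); scores above a cutoff (default 0.5) become `modified` labels.

All positions in the API are 0-based; BED output is 0-based half-open.

## Windows and normalization

Two normalization schemes make windows comparable across molecules and
instruments; both are scale-invariant (multiplying a molecule's raw
kinetics by any constant leaves normalized windows unchanged):

* **median50** (cytosine modifications): each kinetic channel is divided
  by its median over a 50-nt span centred on the target, truncated at
  molecule + adapter boundaries. The span, rather than the whole molecule,
  avoids biases from molecule-length-dependent kinetics.
* **thymine-median** (6mA): every kinetic value in the window is divided
  by the median kinetic value of *thymines of the same strand* within the
  span, with separate divisors for IPD and PW. Unmodified adenine and
  thymine kinetics are essentially exchangeable, so unmodified adenines
  normalize to a distribution centred at 1. Afterwards, all kinetic values
  at declared *confounder positions* — known or provisionally called
  neighboring 6mA sites — are set to exactly 1, so a window containing
  several modifications resembles a window containing only its target.

Numerical guards: the divisor is floored at `epsilon` (default 1e-3), and
normalized values are clamped to [0, 10] to bound outliers; an all-zero
channel normalizes to zeros with a warning; a span without thymines falls
back to the molecule-wide thymine median. Dividing by a median of the
~10–20 thymines in a span carries a small upward convexity bias (of order
half a percent) in the mean normalized value; the acceptance script
measures it directly (target `t3`).

Windows that would run past a fragment end are completed from the adapter
flank kinetics when available (`adapter = 1` on those rows); otherwise
the site is a *no-call*. With adapter padding every candidate site is
callable — the no-call region within 10 nt of fragment ends disappears.
Window widths 5–41 are supported; 21 is the default used throughout.

The channel layouts are versioned (`duplex-v1`, `single-v1`); a trained
scorer records its layout id and refuses windows built under another.
Duplex windows store Crick kinetics base-pair aligned in Watson
coordinates; single-strand windows are built in the called strand's
5'→3' orientation.

## The scoring network

`scorer_config()` describes the architecture: four 1-d convolutional
layers (64 filters, kernel 5, same-padding, ReLU) with batch
normalization between successive convolutions; sinusoidal positional
embeddings (standard base-10000 form) added to the convolutional output;
three transformer encoder layers (4-head scaled dot-product attention,
GELU feed-forward of width 128, post-layer-norm, dropout 0.1); then
flatten, a 128-unit ReLU layer, and a 2-unit softmax whose modified-class
probability is the score. The attention uses query/key/value projections
with d_model equal to the filter count, so positional embeddings are
added rather than concatenated. A relative-position input channel is kept
in the feature matrix as well; the redundancy with the sinusoidal
embeddings is harmless.

The forward and backward passes are implemented directly in matrix
algebra (one small compiled kernel performs the per-sample attention
products), with Adam optimisation, stratified validation splits, minority
upsampling for class balance, per-epoch validation AUC, early stopping,
and best-checkpoint selection. Analytic gradients are verified against
finite differences in the test suite. GELU uses the sigmoid approximation
`x * sigmoid(1.702 x)`. Training is deterministic for a fixed seed on one
machine; checkpoints reload to identical predictions.

Unspecified hyperparameters (optimizer, learning rate 1e-3, batch size
256, epochs, patience) are `train_config()` defaults, configurable and
recorded in the model metadata. One binary model is trained per task
(uC/5mC, uC/5xC, 5mC/5hmC, uA/6mA), matching the two-unit output;
multiclass scoring is future work.

## The synthetic kinetics generator

Controlled-access instrument data cannot ship with a package, so every
stage is exercised against a simulator whose phenomenology mirrors what
the calling stack relies on:

* per-position kinetic baselines drawn per base identity from a
  log-normal family (defaults: IPD medians A/T 0.22 — the unmodified
  adenine scale — C 0.26, G 0.24; site-to-site sdlog 0.25), with
  unmodified adenine and thymine identical by construction;
* multiplicative per-pass noise (sdlog 0.6; SMRT per-pass kinetics are
  very noisy), aggregated over the drawn subread depth per strand, so
  accuracy grows with depth;
* Gaussian-decay multiplicative footprints over ±5 nt around each
  modified base (central IPD factors: 6mA 4.1 — anchored to the ~4-fold
  modified/unmodified adenine median IPD ratio — 5mC 1.6, 5hmC 1.3;
  PW 1.3/1.2/1.1; decay sd 1.5 nt). The footprint shape and flank
  magnitudes are free simulator parameters, not measured claims;
* adapter flanks with unmodified baseline kinetics;
* placement rules per application: symmetric per-CpG Bernoulli
  methylation (optionally with uC/5mC/5hmC class draws), WGA-style
  all-adenine 6mA, Dam-style GATC 6mA on both strands plus background,
  jagged-end fill-in 6mA (every adenine of the filled-in 3' segment
  opposite a 5' overhang), and accessibility-driven 6mA whose probability
  follows a raised cosine of the distance to the nearest anchor site.

Identical configurations (the seed is part of the configuration) give
byte-identical fixtures. The simulator does *not* model sequencing
errors, polymerase pausing artifacts, context-specific (k-mer) kinetic
baselines, or real genome composition, so green tests demonstrate that
the machinery recovers planted structure under the stated noise — not
that any particular accuracy will be achieved on real instrument data.

## Calling workflows

* `call_5mC()` scores every callable CpG cytosine (median50-normalized,
  duplex by default) and labels by the cutoff; uncallable sites are
  emitted as `no_call`. A duplex molecule with a zero-depth strand
  degrades to single-strand calling when a fallback single-strand model
  is supplied, otherwise its sites are `no_call` with a notice.
* `call_5hmC_two_stage()` first separates uC from modified cytosine
  (5xC) and then resolves the modified sites into 5mC versus 5hmC with a
  second model; both stage scores are retained. The same cutoff is used
  for both stages by default.
* `call_6mA_iterative()` handles the confounding of a target by
  neighboring 6mA: round one scores all adenines with no confounders;
  later rounds rebuild windows declaring the previous round's
  above-cutoff sites (never the target itself) as confounders, until the
  label set is stable or `max_6mA_iterations` (default 3) is reached.
  How confounders are identified at inference is not prescribed by the
  training procedure, which masks known truth; the iterative
  provisional-call scheme is this package's resolution of that gap.
  6mA calling is strand-specific; call each strand separately.
* `region_level()` and `molecule_profiles()` aggregate calls to regions
  (`modified / (modified + unmodified)`, no-calls excluded, empty regions
  missing rather than 0) and to per-molecule binary CpG profiles.

The 6mA training design matters: a model fit only on a pure
fully-modified library versus a pure unmodified library learns that *any*
kinetic elevation marks a modification and transfers poorly to
mixed-density molecules, where unmodified adenines sit inside the
footprints of true 6mA. `simulate_6mA_windows()` therefore trains on one
mixed-density library: positives are true 6mA sites and negatives the
remaining adenines of the same molecules — including footprint-confounded
ones — with known neighbors masked in both classes. At matched
sensitivity this model achieves a lower false-positive rate than a
single-site normalized-IPD threshold, which is the property the
acceptance suite checks.

## Downstream applications

* `jagged_end_profile()` bins labelled adenine calls by distance from
  each strand's 3' end; end repair of 5' overhangs in the presence of
  N6-methyl-dATP elevates the 6mA level inside the filled-in segment.
* `anchor_periodicity()` bins 6mA levels by signed offset to the nearest
  anchor and estimates the dominant period as the first
  above-noise local maximum of the mean-subtracted autocorrelation
  (periodogram peak as an alternative). The noise floor is the normal
  quantile at a 1% Bonferroni level over tested lags scaled by
  `1/sqrt(n_bins)`; profiles without a peak above it report a missing
  period rather than a number.
* `motif_enrichment()` scores every short word (contiguous 4–6-mers and
  gapped 3-mer pairs) containing an adenine at a fixed index by the 6mA
  level of that adenine across occurrences versus the background level.
  Words are *ranked by the upper-tail exact binomial p-value* rather than
  by the raw enrichment ratio: at fixed occurrence counts the ratio is
  noise-dominated for rare words, whereas the binomial tail orders words
  by evidence; the enrichment ratio is still reported per word.
  Single-mismatch neighbours with enrichment within 10% merge into an
  IUPAC consensus. Full PWM/EM motif discovery is out of scope.
* `molecule_origin_score()` compares each molecule's binary CpG profile
  with per-site methylation probabilities of two reference classes: the
  per-molecule score is the logistic of the mean per-CpG Bernoulli
  log-likelihood ratio, and the per-sample score is the mean over
  molecules. The exact published tumor-scoring formula lives outside this
  package's sources; this Bernoulli log-likelihood-ratio score is a
  documented stand-in implementing the same comparison principle, and its
  logistic normalization, per-CpG averaging and mean-over-molecules
  aggregation are this package's choices. Molecules below `min_cpg`
  scorable sites are excluded, supporting stratified analyses (few vs
  many CpGs per molecule).

## Experiment scales and acceptance quantities

The packaged experiments run at desk scale on one CPU:

* the headline 5mC experiment trains the default architecture on 20,000
  simulated windows (10,000 per class, depth 20) for two epochs and
  evaluates ROC/PR AUC on 5,000 held-out windows;
* the depth-stratification, 6mA-baseline and two-stage experiments use a
  reduced architecture (3 conv layers of 32 filters, 2 transformer
  layers) and 6,000–9,000 windows each — enough to demonstrate the
  qualitative properties without hour-long runs;
* the two-stage experiment uses a deliberately widened 5hmC footprint
  (IPD 4.5/PW 1.8 vs 5mC 1.8/1.25): with the conservative default
  footprints the 5mC/5hmC Bayes separation under realistic site-to-site
  kinetic variability caps three-class accuracy below the near-separable
  regime this workflow validation is meant to exercise. Package defaults
  are unchanged;
* application-level recoveries (GATC motif, 180-bp periodicity,
  jagged-end profile) convert simulator ground truth into calls through a
  fixed synthetic operating point (sensitivity 0.96, false-positive rate
  0.01, `truth_to_calls()`) so they test the simulator and application
  layers in seconds rather than minutes.

`scripts/acceptance.R` recomputes, from a fresh simulation under a
caller-supplied seed: the value stored at a confounder position after
6mA normalization (`t1`), the percentage of CpG sites callable with
adapter padding over a library with CpGs at every end distance 0–20
(`t2`), and the mean thymine-median-normalized value over 100,000
unmodified adenines drawn, together with thymines, from one symmetric
truncated-normal distribution with no per-pass noise (`t3` — the
condition is per-position i.i.d. values, so pass noise is switched off
and depth is immaterial).

## Known limitations

* Kinetic units are dimensionless: frame counts and seconds are both
  accepted because every downstream computation is scale-invariant under
  the normalizations.
* The simulator's kinetic baselines depend on base identity only, not on
  wider sequence context; real polymerase kinetics have strong k-mer
  structure that a model trained on simulation has never seen.
* No trained weights ship with the package; scorers are trained on the
  user's (or simulated) labelled windows.
* Subread-to-consensus alignment is upstream: both input formats carry
  kinetics already in consensus coordinates.
* The origin score's mean-over-molecules sample aggregation is a
  placeholder for cohort-calibrated scoring.
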