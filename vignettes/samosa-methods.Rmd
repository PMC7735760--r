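---
title: "Models and methods behind samosa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind samosa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters, the
numerical choices, and the limits of the `samosa` pipeline. The package
analyses single-molecule chromatin footprinting data in which accessible
adenines carry an exogenous m6dA mark that raises the interpulse duration
(IPD) during single-molecule real-time sequencing.

## The methylation-calling model

**Signal model.** IPDs are modelled as log-normal within each methylation
class: `log(IPD)` is Gaussian with a higher mean at methylated A/T template
positions. This is the standard working model for polymerase kinetics and
is also how the bundled simulator emits data. All inference happens on the
scale `log2(IPD + pseudocount)` with `pseudocount = 0.01`: log-scale
modelling keeps the two classes near-Gaussian, and the small offset only
guards genuinely zero IPDs. A large offset (for example `+1`) would
compress the lower class much more than the upper, skewing both components
and visibly mis-calibrating the mixture posterior, which is why the small
pseudocount is the default; the offset is an exposed argument of
`normalize_ipd()`.

**Per-molecule normalization.** Each molecule is normalized by a robust
z-score, `(log2(IPD + c) - centre) / scale`, to remove per-molecule
polymerase-speed differences. The centre and scale (median and scaled MAD)
are estimated from the molecule's **G/C positions** by default
(`reference_bases = "GC"`): G/C bases cannot carry m6dA, so they track
polymerase speed without tracking methylation. Centring on the A/T
positions themselves (available as `reference_bases = "AT"`) would cancel
genuine between-molecule and between-sample methylation-level differences —
a fully methylated and a fully unmethylated molecule would become
indistinguishable — so the G/C baseline is the default. If a molecule has
fewer than `min_obs = 20` observed reference positions the scored positions
are used instead; molecules with fewer than 20 observed A/T IPDs, or with
no usable spread, are flagged low-information and excluded from fitting and
calling. When the MAD degenerates to zero the standard deviation is used;
if that is also zero the molecule is flagged.

Both A and T template positions are scored by default (`bases_scored =
"AT"`), since consensus reads interleave the adenine signal of both
strands; `"T"` restricts scoring to template thymines.

**Mixture fit.** `fit_mixture()` pools normalized values across unflagged
molecules and fits a two-component Gaussian mixture by EM. One global fit
per sample is the default: it is far more stable than per-molecule fits,
and per-molecule polymerase effects are already removed by the
normalization. A per-molecule refit is available (`call_sample(...,
per_molecule = TRUE)`) for samples where within-molecule heterogeneity of
the signal distribution is suspected.

Numerical choices:

* deterministic initialization from the lower and upper quartiles of the
  pooled values (no random restarts — the 1-d two-component problem at
  these sample sizes is not multimodal in practice, and determinism under
  a fixed input is worth more);
* convergence when the **mean** log-likelihood changes by less than
  `tol = 1e-6` per observation (a per-observation tolerance behaves the
  same at n = 10^3 and n = 10^6), capped at `max_iter = 200`;
* a variance floor of `1e-3` against collapse onto duplicated values, with
  a warning;
* a minimum component weight of 0.02 below which the fit is flagged as
  effectively single-component (the posterior then approximates the
  marginal class prior and should not be over-interpreted);
* components are relabeled after fitting so that component 1 is always the
  higher-mean (methylated) one;
* `subsample` optionally caps the number of pooled values (seeded,
  default in the pipeline: 2 × 10^5), which bounds fitting cost with no
  visible effect on the estimates at these scales.

Posteriors are computed on the log scale
(`1 / (1 + exp(l0 - l1))`), so extreme values cannot underflow; a
nearest-mean fallback exists for the pathological all-underflow case.

## Footprinting

**Smoothing.** All smoothing is a centred, missing-aware rolling mean
(`rolling_mean_nan()`): the mean of the observed values in the window,
missing where fewer than `min_count = 1` values are observed. Non-A/T
positions and masked IPDs are missing by construction. In vitro analyses
use a 5-bp window (dyad calling benefits from minimal smoothing); in vivo
analyses — autocorrelograms, averaged profiles, state clustering — use
33 bp, which bridges local A/T deserts without erasing nucleosome-scale
structure.

**Dyad calling.** `call_dyads()` takes a 133-bp rolling mean of the track
and calls nucleosome dyads at local minima, greedily accepted deepest-first
(leftmost on exact ties) under a 147-bp minimum separation — one nucleosome
footprint. Three additions make the textbook recipe robust:

* *Edge margin* (`edge_margin = 73`, half a footprint): minima closer than
  this to a molecule end are partial-nucleosome artifacts and are excluded.
* *Valley filters*: a candidate valley must be at least `min_depth = 0.05`
  below the lower of its two local barriers, and its bottom must sit below
  `max_level = 0.5`. The level filter follows from geometry: the 133-bp
  window at a true dyad lies inside the 147-bp footprint, so its mean
  posterior must be below one-half, while noise dips in long accessible
  stretches sit far above it. The level filter intentionally uses the
  absolute posterior scale; the detector itself is invariant to adding a
  constant (tested with the filter disabled).
* *Half-depth centring* (`refine = TRUE`): because the window is narrower
  than the footprint, the smoothed valley has a flat, noisy bottom
  (~14 bp) on which the raw argmin wanders. The reported dyad is instead
  the midpoint of the interval in which the smoothed track stays below
  `bottom + depth/2`, with the local barriers found by climbing outward
  from the valley bottom (bounded at 147 bp, so a shallower neighbouring
  valley cannot contribute its far wall). On simulated arrays this roughly
  halves the dyad error relative to the argmin.

Plateaus in the smoothed track are collapsed to their leftmost index before
tie-breaking, and the smoothed values are quantized at 1e-9 so that exact
plateaus survive the cumulative-sum arithmetic of the rolling mean.

**NRL summaries.** Pairwise NRLs are successive differences of adjacent
dyads; the averaged single-molecule NRL is `(last - first) / (n - 1)`.
Both are missing with fewer than two dyads — an empty call set is a valid
result, not an error.

**Autocorrelograms.** For lag `k = 0 .. floor(L/2) - 1`, the Pearson
correlation of the smoothed track with its `k`-shifted copy over positions
where both are observed. Restricting to equal-length comparisons makes the
output exactly half the input length. Lags with fewer than `min_n = 10`
overlapping observations, or zero variance in either segment, are missing
rather than extrapolated. The inner loop is a small C++ kernel; a
brute-force R implementation serves as its oracle in the tests (agreement
to 1e-10). Tracks used for clustering are truncated to their first
1000 bp before the autocorrelogram.

**NRL peak calling.** `find_nrl_peak()` reports the first (smallest-lag)
local maximum of the autocorrelogram within `lag_range = c(120, 350)` bp
whose prominence (height above the higher of the two flanking key minima)
exceeds `prominence = 0.03`; failure to find one sets `peak_found = FALSE`
and is never an error — the fraction of peak-missing molecules is itself a
readout (irregular fibres miss more often). The search range spans
sub-chromatosome to very long repeats; the prominence default was chosen so
that averaged autocorrelograms of in-vivo-like simulations yield robust
peaks in the 180–190 bp band while flat autocorrelograms yield none. Both
knobs are exposed; raising the prominence (to ~0.2) makes the
regular/irregular missing-rate contrast sharper at the cost of more missing
estimates overall.

## Fibre clustering

Molecules at least 500 bp long enter a molecules × lags matrix
(`build_matrix()`), truncated to the 250 lags guaranteed to exist for every
included molecule — a fixed-width representation avoids padding artifacts
from ragged autocorrelograms. Residual missing lags are imputed by the row
mean; fewer than 50 eligible molecules is an error (graph clustering below
that is noise).

`leiden_cluster()` builds a Euclidean k-nearest-neighbour graph
(`k_neighbors = 15`) and partitions it with Leiden under the modularity
objective. The partition is seeded and reproducible; labels are contiguous
and ordered by decreasing cluster size; clusters smaller than 100 molecules
are flagged rather than merged. The resolution default is 1.0, but the
meaningful value is data-dependent: the tuning criterion used throughout
the package's own analyses is *the largest resolution at which no cluster
falls below 100 molecules*, automated in `tune_resolution()`. On the
planted two-pattern mixtures used in the tests this criterion selects 0.25,
at which the planted partition is recovered essentially exactly; the
four-pattern recovery is insensitive to resolution across 0.15–0.6.
All-identical rows are a single cluster by definition (the kNN graph is
arbitrary there, so the case is short-circuited).

`summarize_clusters()` reports per cluster: size and fraction, median and
MAD of single-molecule NRLs, the fraction of molecules without an
autocorrelogram peak, the missing-aware mean modification profile over the
5' 1000 bp, and the mean autocorrelogram. All summaries are invariant to
relabeling.

## Feature-centric analyses

* `assign_molecules()`: a molecule hits a feature when its alignment
  interval overlaps the feature expanded by `max_dist = 1000` bp on both
  sides, **closed** at the boundary (a gap of exactly 1 kb counts; this is
  the `maxgap` convention of IRanges, and a brute-force all-pairs oracle
  checks it in the tests). Multi-feature hits are all kept.
* `motif_windows()`: 500-bp windows centred on the motif midpoint
  (`floor((start + end)/2)`; window `[mid - 250, mid + 250)`), only from
  molecules fully covering the window. Rows are put in reference
  orientation (minus-strand molecules reversed) and then flipped for
  minus-strand motifs, so column 1 is always the motif's 5' side; applying
  the extraction with toggled strands yields mirrored matrices.
* `cut_profile()`: both alignment ends of every hitting molecule
  contribute one count at their (strand-flipped) offset from the motif
  midpoint; counts are also normalized per molecule supplied.
* `state_cluster()`: Leiden on the 33-bp-smoothed 500-wide window rows,
  reusing the fibre-clustering machinery, with per-cluster mean window
  profiles.
* `fisher_test()`: two-sided conditional p by the probability-mass rule
  (sum of hypergeometric probabilities not exceeding the observed table's,
  with the conventional `1 + 1e-7` tie tolerance), vectorized over tables
  via `dhyper`; the odds ratio is the sample odds ratio `ad/bc` (infinite
  when `bc = 0` and `ad > 0`, undefined on an empty margin, where p is 1).
  The tests verify exhaustive agreement with direct enumeration for every
  table of total at most 40 and spot-check `stats::fisher.test`.
* `storey_qvalues()`: pi0 estimated on the lambda grid 0.05–0.95 (step
  0.05) with a df-3 cubic-spline smoother evaluated at the largest lambda,
  clipped to (0, 1]; `q_i = min over p_j >= p_i of pi0 * m * p_j /
  rank(p_j)`. With fewer than 20 p-values pi0 is fixed at 1, which reduces
  the procedure exactly to Benjamini–Hochberg (verified against
  `p.adjust`).
* `matched_controls()`: control regions sampled without replacement so the
  control GC histogram matches the target histogram in 2.5%-GC bins,
  seeded; under-populated bins borrow from the nearest bins with a
  message. This is a transparent stand-in for model-based matched-region
  selection: repeat content is **not** matched, and externally supplied
  control BEDs can be used instead wherever a feature set is accepted.
* `enrichment_scan()`: one Fisher test per (cluster, category) against the
  background of all labeled molecules, Storey q across the whole scan,
  significance at q < 0.1. Molecules carrying several category labels are
  counted once per category (the alternative — deduplication — would make
  the background depend on the category set; the chosen convention keeps
  each 2×2 table self-consistent).

## The simulator: what it emulates, and what it does not

`fibre_spec()` + `simulate_sample()` generate molecules with known
nucleosome positions: regular arrays (dyads at `flank5 + footprint/2 +
k·NRL` with Gaussian jitter, clamped to one footprint of separation) and
irregular fibres (linkers drawn as `5 bp + Geometric` with mean 40 bp,
truncated at 250 bp — a broad, right-skewed spread with no dominant
periodicity). `spec_601_array()` reproduces the in vitro benchmark design:
nine nucleosomes at a 193-bp repeat (147-bp core + 46-bp linker) behind
~450 bp of free DNA, with a tiled repeat-unit base sequence.
`simulate_mnase_fragments()` cuts linkers (midpoint + jitter, clamped
outside footprints, each linker cut with probability 0.5) to produce
oligonucleosome ladders.

IPDs are emitted log-normally: unmethylated `logmean 0`, methylated
`logmean 1.1` (≈3× median fold-change), both `logsd 0.5`, chosen to make
the mixture identifiable yet overlapping; the true m6dA fold-change on
current instruments is not published, so this default is a tunable
stand-in, not a calibration. Methylation is Bernoulli per A/T position:
probability 0.9 in linkers, 0.05 inside footprints, and 5% of A/T
observations are masked as missing — defaults meant to represent an
efficient but imperfect methyltransferase reaction and real coverage
gaps. An optional zero-mean per-k-mer offset (2 bp 5', 5 bp 3') on the
log scale exercises the context profiler; it is off by default.

What the simulator does **not** emulate: polymerase pulse-width physics and
pass-count effects, consensus-calling errors, mapping artifacts,
sequence-driven nucleosome positioning, linker-histone/chromatosome
structure, and real genomic base composition (bases are uniform-random or
tiled repeats). Passing tests therefore demonstrate that the pipeline's
inference is correct *under its stated signal model* — they do not
guarantee the same accuracy on real kinetics, where class separation,
context effects, and missingness are less benign.

A note on the context-profile test: with 8-mer contexts there are 65,536
bins, so at the ~10^5-position scale of a desk-sized simulation each bin
holds only one or two observations and per-context means are dominated by
noise. The recovery test therefore runs the identical machinery at 4-mer
resolution, where bins hold dozens of observations; the 8-mer default is
exercised for its binning and sorting semantics.

## Problem sizes and runtime

The test-suite simulations are sized for a single CPU: 1000 molecules for
each of the two recovery benchmarks (the nonanucleosomal-array experiment
and the 172-bp regular-fibre experiment), 500 and 800 molecules for the
two- and four-pattern planted clustering mixtures, 200 null replicates of
1000 molecules for the empirical-FDR check, and exhaustive Fisher
enumeration up to table total 40. The full suite runs in a few minutes;
`scripts/acceptance.R` recomputes the two benchmark experiments from
scratch in about a minute.

## Known limitations

* The mixture is two-component by design; hemi-methylation, other base
  modifications, or multimodal kinetics would need more components.
* Posterior calibration holds under the log-normal signal model; strong
  unmodelled context effects will mis-calibrate posteriors unless the
  context offset is included in the normalization (the context profiler
  quantifies, but does not correct, such effects).
* Dyad calling assumes mono-nucleosome footprints (~147 bp); chromatosomes
  and larger non-histone footprints shift dyads and NRLs accordingly.
* GC-binned control matching ignores repeat content.
* The Leiden resolution is a genuine degree of freedom: cluster counts are
  a function of it, and only the tuning criterion, not a specific count,
  is part of the method.
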