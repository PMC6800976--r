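---
title: "Tracking gradual brain-state transitions: model, design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking gradual brain-state transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `dfctrack`, the design
decisions that were genuinely open, the numerical choices, and what the
validation suite does and does not establish.

## The model

Resting-state BOLD recordings are summarized as a `T × N` matrix of
region-averaged signals. The working model is that the brain's functional
connectivity passes through a small number of quasi-stationary *states*,
and that the handoff from one state to the next is not instantaneous: it
plays out over a *transition interval* of several sampling points. The
pipeline estimates where those intervals lie, how conversion progresses
inside them, and how the network topology of steady and transition periods
compares.

### Windowed connectivity

A sliding window of `n = 20` time points advanced in steps of `l = 1`
yields `g = floor((T − n)/l) + 1` windows (157 for `T = 176`). Windowing is
1-based and inclusive: window `k` covers time points
`[1 + (k−1)l, n + (k−1)l]`, matching the `M_1..M_g` labeling used in all
reports. Within each window, pairwise Pearson correlations are computed,
absolute values taken, and entries below the threshold `th = 0.5` removed;
an edge exactly at the threshold is retained. The default keeps `|r|` as
the edge weight (`weighted_abs`); a `binary` mode records only edge
presence, since the thresholding step can equally be read as defining edge
existence. Both are first-class and every output records the mode used.
The `g` thresholded matrices vectorize (row-major upper triangle,
`d = N(N−1)/2` entries) into the state observation matrix `G`; a
`features = "raw"` switch vectorizes the unthresholded `|r|` matrices
instead, because the choice of feeding thresholded versus raw coefficients
to the embedding is not dictated by anything upstream.

### Embedding, clustering, segmentation

`G` is embedded into two dimensions with an exact t-SNE implemented in
C++: per-row affinities tuned to perplexity 30 by bisection, 1000 gradient
iterations with early exaggeration (factor 12 for the first 100
iterations), momentum 0.5 → 0.8 at iteration 250, learning rate 200, and
adaptive per-coordinate gains. With `g` of a few hundred windows the exact
O(g²) kernel costs milliseconds per iteration, so no tree approximation is
used. The initialization is drawn from N(0, 10⁻⁴) under the configured
seed, and the result is a deterministic function of `(G, config)`.

The embedded windows are clustered by k-means with `k = m` (default
`m = 5`) and 10 restarts. Raw cluster labels need not be temporally
contiguous, so a segmentation step enforces contiguity: a width-5 sliding
mode filter removes isolated flips (ties keep the current label when it
participates, otherwise the smallest label wins), then any run shorter
than `min_run = 3` windows is merged into its longer neighbor until
exactly `m` runs remain. If the merge loop cannot reach `m` runs of
length ≥ `min_run` — as with temporally structureless labelings — the
repetition fails and is counted rather than silently dropped. Runs are
relabeled `1..m` in temporal order, which makes the result invariant to
permutations of the raw cluster ids. The *critical point* `D_q` is the
last window of run `q`.

### Repetition statistics

The embedding is stochastic, so the embed→cluster→segment step is repeated
`R` times (default 1000; the scaled validation suites use 50) with seeds
`base_seed .. base_seed + R − 1`, giving each repetition an independent and
reproducible random stream. The per-transition histogram `N_k` counts how
often `D_q` lands on window `k` across successful repetitions; row sums
equal the number of successes by construction, and failures are reported
alongside.

The transition interval `P_q = (t1, t2)` is the *shortest contiguous
window range holding at least `alpha = 0.9` of the histogram mass*, ties
broken toward the smaller `t1`. This estimator is deterministic,
scale-free, and stable under count rescaling; the mass fraction trades
interval tightness against tail coverage.

Two summary statistics are computed from the intervals:

* **Interval coincidence degree.** For subject `y`,
  `Q_y = Σ_x overlap(P_x, P_{x+1}) / g_y` over adjacent interval pairs,
  where overlap counts shared integer window indices inclusively; the
  group value `Q̄` is the arithmetic mean. `Q̄ = 0` exactly when all
  adjacent intervals are disjoint.
* **Instantaneous conversion rate.** The default (cumulative) form is
  `λ(k) = Σ_{τ=t1..k} N_τ / Σ_{τ=t1..t2} N_τ`, the fraction of the
  interval's transition mass accrued by window `k`; it is non-decreasing
  with `λ(t2) = 1` and is invariant to scaling all counts. A labeled
  `density` variant divides by the interval length. Both are
  operationalizations of the same trend statistic — the defining
  expression admits more than one reading, so the package exposes both and
  tags every output with the form used.

### State networks and topology overlap

Given the `m − 1` estimated intervals, the timeline splits into
`s = 2m − 1` alternating steady/transition sets (9 for `m = 5`). A window
on an interval boundary belongs to the transition set, and every window
belongs to exactly one set; empty steady gaps (overlapping or touching
transition intervals) are an error prompting a smaller mass fraction or
fewer states. A fixed reference layout for 157-window recordings ships as
`partition_hc9()`.

Window networks are averaged element-wise within each set per subject
(`S̄`) and across subjects (`Z̄`). Similarity between two state networks
uses the neighbor topology overlap coefficient; per node

    C_i = Σ_j (1 − |a_ij − b_ij|) a_ij b_ij / sqrt(Σ_j a_ij · Σ_j b_ij)

with `C_i := 0` for a node of zero strength in either network (included,
not excluded, from the node average — deterministic and conservative).
The `(1 − |Δ|)` weight penalizes weight disagreement on shared edges; the
absolute value is required for the coefficient to stay within `[0, 1]`
(the bound follows from `a² ≤ a` on `[0, 1]` plus Cauchy–Schwarz, and is
property-tested). A `classic` mode drops that factor, recovering the
standard temporal topological overlap. Note that for *weighted* networks
the self-overlap of a network with edge weights `w` is `Σw²/Σw < 1`, so
magnitudes depend on the edge-weight mode; comparisons should fix one
mode throughout.

### Group comparison

Two groups are compared with one-way ANOVA (via `stats::lm`), once on
per-subject coincidence degrees and once on the off-diagonal
upper-triangle entries of each group's overlap matrix (36 values for
`s = 9`, giving degrees of freedom 1/70/71 for two groups). No
multiple-testing correction is applied: the two ANOVAs are standalone.

## The synthetic-data generator

`synthetic_spec()` describes a piecewise-stationary multivariate Gaussian
process: each latent state is a block correlation matrix (unit variances,
`r_in = 0.7` within a connectivity module, `r_out = 0.1` across), states
follow each other at evenly spaced boundaries, and every covariance is
validated positive semi-definite at construction. Defaults mirror a
typical acquisition: 90 regions, 176 time points, 5 states, 20 subjects.
Consecutive states share a common two-block backbone and relocate ~10 % of
regions between modules, so state networks are variations on a shared
connectome rather than unrelated topologies — resting-state networks
differ in a minority of connections, and this keeps cross-state overlap
coefficients in a realistic high range rather than near zero.

Two knobs control transition sharpness:

* `ramp_length ρ`: around each boundary, the covariance is the convex
  mixture `(1 − w)Σ_p + wΣ_{p+1}` with `w` rising linearly across the ramp
  (`w = i/(ρ+1)` strictly inside, so the pure states are the limits).
  Mixing the *covariance* rather than the samples keeps every time point's
  marginal distribution well defined. Ramps are truncated at the midpoints
  between neighboring boundaries so they remain pairwise disjoint.
* `boundary_jitter`: each subject's boundaries shift by an integer drawn
  uniformly in `[−jitter, +jitter]`, clamped to preserve ordering. Jitter
  offsets are drawn unconditionally (as scaled uniforms) so cohorts
  generated from the same seed share all random draws — a paired design
  that lets group contrasts be evaluated with common random numbers.

The generator emulates: regime-switching correlation structure, gradual
transitions, and between-subject timing variability. It does **not**
emulate hemodynamic convolution, scanner noise, motion, topological
heterogeneity across subjects, or the breakdown of clusterability seen in
clinical populations. Consequences for interpretation are discussed below.

## Validation suites and problem sizes

The suites run on scaled problems chosen to exercise every code path with
planted ground truth: 20 regions × 200 time points × 3 states for recovery
and contrast experiments, 50 embedding repetitions per histogram, 500
t-SNE iterations, and 10 generator seeds (or paired seed sets) per
experiment; oracle-equivalence checks use ≥ 100 random small instances per
operation at tolerance 10⁻¹⁰.

* **Structural constants** (window count 157, feature dimension 4005,
  9-interval layout, 90 × 90 window networks) are exact and instant.
* **Recovery**: with sharp boundaries, the modal critical point of every
  transition falls within `±(n − 1)` windows of the window centered on the
  true boundary in 10/10 seeds — the window length bounds the achievable
  localization, since any window containing the boundary mixes both
  states.
* **Directional group contrast**: two cohorts differing only in timing
  regularity (jitter 0/ramp 5 versus jitter 15/ramp 25) are compared on
  `Q̄` and on the mean off-diagonal overlap coefficient across paired seed
  sets. This suite documents a *negative* result, kept deliberately: see
  below.

## What the timing-only contrast can and cannot show

The validation experiments show that per-subject critical-point histograms
are narrow (1–10 windows) whenever the latent states are separable enough
to segment at all: across repetitions only the embedding initialization
varies, and the temporal mode filter plus run merging absorb small
cut-point fluctuations. Adjacent transitions, by contrast, sit tens of
windows apart in any geometry whose segments can host a sliding window.
Two consequences follow:

* `Q̄` is exactly zero for *both* cohorts — adjacent per-subject intervals
  never collide. Between-subject jitter cannot widen a within-subject
  histogram, and covariance ramps widen it only by a few windows.
* Blurring a cohort's state networks by timing irregularity makes them
  slightly *more* similar to one another (mixtures of shared-backbone
  states lie closer together than the crisp states do), so the mean
  cross-state overlap does not reliably decrease for the irregular cohort.

In empirical recordings, cohorts with irregular dynamics differ not merely
in transition *timing* but in the clusterability of their connectivity
patterns — repeated embeddings of such data scatter critical points over
wide ranges, producing overlapping intervals and weakened state networks.
A Gaussian regime generator whose groups differ only in jitter and ramp
length does not reproduce that regime, and the corresponding directional
checks fail by construction. They are retained, unweakened, as an honest
record of the generator's scope: passing recovery and invariant suites
validates the estimators; they do not by themselves establish that the
coincidence/overlap contrast separates clinical groups.

## Numerical choices and degenerate inputs

* Zero-variance regions within a window get zero correlations (with a
  warning naming them) rather than failing the whole sequence.
* `estimate_interval` ties: shortest length first, then smallest `t1`.
* k-means empty-cluster failures retry with a fresh initialization up to
  5 times before the repetition is declared failed.
* t-SNE requires `perplexity < g`; degenerate inputs (fewer than 5
  windows, non-finite features) are rejected up front.
* The indefinite-covariance check at spec construction names the
  offending state; correlation targets that break positive
  semi-definiteness (e.g. strongly negative `r_out` with several blocks)
  are caught before any sampling.
* All window and time indices in interfaces and reports are 1-based.

## Known limitations

* Temporal contiguity is enforced post hoc; a latent state that recurs
  later in the recording is split into separate runs by design.
* The interval estimator assumes unimodal-ish histograms; strongly
  multimodal critical-point distributions yield wide intervals rather
  than multiple candidates.
* Overlap-coefficient magnitudes are not comparable across edge-weight
  modes (see above).
* The simulator's Gaussian, zero-mean, unit-variance model omits
  hemodynamics and noise structure; results on it bound what the
  estimators can do, not what real cohorts will show.
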