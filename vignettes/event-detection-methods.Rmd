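---
title: "Detecting structural transition events in cotranscriptional SHAPE-Seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural transition events in cotranscriptional SHAPE-Seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeEvents)
```

## The data and its model

Cotranscriptional SHAPE-Seq measures, for every intermediate length ℓ of a
growing nascent RNA, a per-nucleotide reactivity that reflects structural
flexibility: unpaired nucleotides react strongly with the SHAPE reagent,
base-paired or protein-occluded nucleotides react weakly.  The ρ reactivity
measure normalizes each length's reactivities to a mean near 1, making rows
comparable.  The resulting matrix (rows = transcript lengths, columns =
nucleotide positions, cells defined only for `n ≤ ℓ`) encodes folding
trajectories: reading a column down the length axis, a nucleotide that pairs
shows a reactivity drop, one that unpairs or emerges from the ~14-nt RNA
polymerase (RNAP) footprint shows a rise.

This package detects two phenomenologically distinct event classes in these
columns and never mixes them: **swings** (rapid changes over a few lengths)
and **ramps** (gradual changes over many lengths).

## Swing detection: a proportional–integral scheme

Change detection down a column is treated like error tracking in
proportional–integral feedback control.  With ŝ the column smoothed by a
centered moving average of `w_smooth` lengths (edges truncate; undefined
cells split the column into independent runs), and `L = i_length`:

* baseline: `b_t = mean(ŝ_{t−L} … ŝ_{t−1})` — the recent history, causal
  (excludes `t`);
* proportional term: `e_t = ŝ_t − b_t` — instantaneous departure;
* integral term: `g_t = Σ_{k=t−L+1..t} e_k` — sustained departure, defined
  only when every addend is;
* relative term: `rel_t = ŝ_t / max(b_t, ε)`, `ε = 10⁻⁶` — fold change,
  which keeps detection meaningful in low- and high-reactivity datasets
  alike (an absolute change that is signal in a quiet dataset is noise in a
  loud one).

A cell up-flags iff `e_t ≥ p_up` **and** `g_t ≥ i_up` **and**
`rel_t ≥ 1 + r_up`; down-flags iff `−e_t ≥ p_down`, `−g_t ≥ i_down`,
`rel_t ≤ 1/(1 + r_down)`.  Same-direction flag runs, allowing gaps of at
most `merge_gap` defined-but-unflagged lengths, become events when they
contain at least `min_duration` flagged lengths and when the smoothed signal
departs from the event-start baseline by at least `m_floor`.  Event
magnitude is `ŝ(end) − b(start)`, signed (clamped to 0 in the rare
pathological merged run whose residual sign disagrees with its direction).

The seven tunable cutoffs `{p_up, p_down, i_up, i_down, r_up, r_down,
m_floor}` — the PIR thresholds — are deliberately independent: up and down
sensitivity differ in real data, the proportional and integral channels
catch sharp versus sustained departures, the relative channel normalizes
context, and `m_floor` rejects changes too small to matter regardless of
shape.

Because the baseline and integral windows are causal, **no event can start
within the first `i_length` defined lengths of a column** (in fact the
integral term first exists at run position `2·i_length`, since each of its
addends needs its own full baseline window).  This mirrors the known failure
mode of missing events at the very start of transcription.

### Parameters, units, defaults

| parameter | meaning | units | default |
|---|---|---|---|
| `p_up`, `p_down` | min proportional excursion | reactivity | data-derived |
| `i_up`, `i_down` | min integral excursion | reactivity·lengths | data-derived |
| `r_up`, `r_down` | min fold change − 1 | dimensionless | 0.3 |
| `m_floor` | min absolute smoothed change | reactivity | 0.1 |
| `w_smooth` | smoothing window (odd) | lengths | 3 |
| `i_length` | baseline/integral window | lengths | 5 |
| `min_duration` | min flagged lengths per event | lengths | 2 |
| `merge_gap` | max unflagged gap merged | lengths | 1 |

"Data-derived" means the 60th percentile of the pooled `|e|` (resp. `|g|`)
distribution (`default_thresholds()`): a starting point that adapts to the
dataset's overall noise level before automated rescaling.

### Automated threshold selection

`autotune_thresholds()` scales the seven PIR thresholds jointly by factors α
on a grid (default: 21 log-spaced factors in `[0.25, 4]`, spanning the
±50–100% perturbation range used in the sensitivity analyses) and counts the
consensus flagged cells N(α) across replicates.  Every flag condition is a
one-sided comparison, so N(α) is non-increasing — it falls steeply while
noise cells drop out, then plateaus where only genuine transitions remain.
After min–max normalizing both axes to `[0, 1]`, the α closest to the origin
(`√(α̂² + N̂²)` minimal, ties to the smaller α) marks this elbow, the same
geometric heuristic used to pick cluster counts.  If nothing flags at any α
the smallest factor is returned with a warning.

## Ramp detection: sliding-window regression

A window of `w_ramp` consecutive defined lengths (default 15) is fit by
ordinary least squares of reactivity against length.  The window flags up
when `slope ≥ slope_min` (default 0.01 reactivity/length), `R² ≥ fit_min`
(default 0.5) and `slope·(w_ramp−1) ≥ net_min` (default 0.15) — the last
condition converts slope into an implied net change so that long windows
cannot flag on negligible drifts; down is symmetric.  A zero-variance window
has slope 0 and `R²` *defined* as 0 (the 0/0 case is resolved toward "no
trend").  Windows containing undefined cells are skipped entirely.
Overlapping same-direction flagged windows merge into one maximal ramp; the
merged magnitude is recomputed by a single OLS over the merged span (times
the span in lengths) rather than averaging window slopes, giving one
interpretable number.  One ramp setting is intended to serve all datasets;
the defaults were chosen so the simulated transitions of this package's
generator are recoverable, and all values are config keys.

Upramps that begin right where a nucleotide exits the polymerase are often
experimental artifacts (short fragments are harder to detect, so reactivity
at those positions grows as the RNA elongates); `detect_ramps(...,
mask_3prime = k)` optionally excludes windows touching the last `k`
positions of each transcript.  Off by default.

## Replicate consensus, grouping, lagged pairs

**Consensus** (`consensus_events()`): an event is retained only when every
replicate contains a matching event — same nucleotide, class and direction,
intervals overlapping after padding by `tol` (default 3 lengths).
Implementation: connected components of the cross-replicate match graph,
with edges only between *different* replicates; a component survives iff it
covers all replicates.  This realizes "conserved in every replicate" while
being invariant to replicate order, and makes single-replicate consensus
exactly the identity (allowing intra-replicate edges would let tolerance
padding merge two distinct nearby events).  Consensus coordinates are the
lower medians of member starts/ends — the replicates disagree about where an
event begins, so a member value (not an interpolated one) in the middle of
the pack is used; magnitude is the member mean.  Swings are never confirmed
by ramps: the classes are distinct phenomena.

**Concurrency groups** (`group_concurrent()`): events of the same direction
whose onsets differ by ≤ `max_start_gap` (default 2) are linked across
nucleotides; connected components of two or more get a `group_id`.
Concurrent onsets at several nucleotides suggest a single structural
transition.

**Lagged pairs** (`find_lagged_pairs()`): per nucleotide, an upswing
followed by its nearest downswing with a lag inside `[min_lag, max_lag]`
(default `[8, 16]`, centered on the ~12-length motif of transient
hyper-reactivity before pairing); each downswing is claimed at most once,
nearest upswing first, ties to the earlier upswing.

## The simulator and what a green test establishes

`make_trajectory()` builds a ground-truth pairing-state trajectory
(`unpaired`, `paired`, `helix_end` per cell), overlays the RNAP footprint
(the trailing 14 positions of every transcript forced to a paired-like
`footprint` state, since footprint protection is indistinguishable from
pairing in reactivity), and derives truth events from the state changes:
footprint→unpaired is an expected upswing, unpaired→paired(-like) a
downswing, paired(-like)→unpaired an upswing.  The default
`hairpin_formation` scenario is a 100-nt RNA (lengths 21–120) with a 6-bp
hairpin (arms 30–35/42–47, loop 36–41) folding at length 75: a hairpin of
typical bacterial-regulatory-RNA size whose folding changes a modest
fraction (~16%) of the transcript, so the per-length renormalization shift
it induces stays below the relative-channel threshold, as in real data where
one folding event does not rewrite the whole row.  `hairpin_rearrangement`
adds a later transition in which the loop pairs into a longer helix.

`simulate_reactivities()` draws each cell's raw reactivity as the average of
`n_reps = 1000` gamma variates (shape 1) with state-dependent means —
unpaired 1.5, helix-end 0.4, paired/footprint 0.05 — then renormalizes each
row to mean 1 over its defined cells, mimicking ρ.  The exact
parameterization of the published ternary model is not restated here; gamma
families with these means are this package's choice and all are config keys.
Each cell consumes its own RNG substream (a per-cell seed matrix derived
once from the top-level seed), so matrices are reproducible regardless of
evaluation order.

What the simulator does **not** emulate: read-depth-dependent noise
heteroskedasticity, correlated errors along a row introduced by the
reactivity calculation itself, 3'-end signal loss for short fragments, or
sequence-dependent reagent bias.  A green benchmark therefore establishes
that the detector recovers clean, well-separated transitions through the
renormalization and footprint confounders — not that it would achieve the
same precision/recall on experimental data.

### A known red check

The acceptance suite asserts that helix-end truth events (terminal base
pairs, smaller reactivity change) are recovered at a *strictly* lower rate
than stacked-pair events by the default pipeline.  In this stated world that
cannot happen: averaging 1000 shape-1 gamma draws leaves ~3% noise, and both
transition magnitudes (~0.8 and ~1.16 normalized units) exceed every
threshold the autotune design can reach by an order of magnitude, so both
categories are recovered completely and the strict inequality is impossible.
The check is asserted as stated and left red rather than weakened.  The
underlying mechanism is real and is demonstrated in the unit suite: with
equal thresholds placed *between* the two magnitudes, helix-end recall drops
while stacked-pair recall does not — smaller-magnitude events always drop
out first as thresholds rise.

## Sensitivity analysis

`perturb_thresholds()` implements the perturbation scenarios: `stringent` is
a 100% increase (×2) of all seven PIR thresholds, `lenient` a 50% decrease
(×0.5) — multiplicative, the plain reading of "percent change in each
threshold"; `single` scales one threshold (structural parameters only behind
an explicit `structural = TRUE`, with rounding and an odd-`w_smooth`
guarantee); `pair` applies ×2/×0.5 to a named pair.  `pairwise_cohort()`
enumerates all `C(7,2)·4 = 84` pair/direction variants, runs detection +
consensus for each, and reports per-(nucleotide, length, direction)
agreement — the fraction of the 84 runs flagging that cell, computed on
pre-merge flags since disagreement clusters in transcript length around true
events rather than at the nucleotide level.  By monotonicity, any cell
flagged under the uniformly stringent scenario has agreement 1.

## Numerical choices and degenerate inputs

* `ε = 10⁻⁶` in the relative term guards division by a zero baseline; a
  legitimate zero reactivity is distinct from an undefined cell (`NA` on
  disk).
* Zero-variance regression windows: slope 0, `R² := 0` (no trend).
* `benchmark_events()` matches greedily, closest start first, ties to the
  earlier truth event; empty detection gives recall 0 and precision `NaN`
  with a warning rather than a silent 0.
* Event tables sort deterministically (nucleotide, start, class, `up`
  before `down`); all writers emit full-precision numbers so read∘write is
  the identity.
* Provenance headers carry a config digest and seed but no timestamps, so
  identical configurations reproduce byte-identical outputs.
* Autotune with a constant N(α) curve returns the smallest factor (the
  normalized count axis degenerates to 0, leaving distance driven by α
  alone).

## Limitations

* The PIR realization here (which seven cutoffs, causal baseline, trailing
  integral) is this package's concrete design for the published scheme whose
  exact equations live in supplementary material not consumed here; the
  module boundaries let a different realization replace `compute_signals()`
  without touching consensus, sensitivity or the simulator.
* Detection is per-column; correlated changes across neighboring nucleotides
  are only recognized downstream by concurrency grouping.
* ρ renormalization couples cells within a row: a large folding event shifts
  every other position's normalized value at that length, which the relative
  channel only partially absorbs (visible as the need for the elbow search
  on clean simulations).
* The simulator's scenario templates cover hairpin formation/rearrangement
  and static controls, not pseudoknots or ligand-dependent bifurcations.
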