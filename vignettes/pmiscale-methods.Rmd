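---
title: "Sliding-window TM topography prediction and scale learning with pmiscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window TM topography prediction and scale learning with pmiscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmiscale)
```

## The model

Proteins entering the secretory pathway carry either a cleavable N-terminal
signal peptide (SP) or, for many membrane proteins, a signal anchor — the
first transmembrane (TM) helix, which targets the protein to the endoplasmic
reticulum and stays inserted in the membrane. Both the hydrophobic h-region
of a signal peptide and a TM helix are built from mostly hydrophobic side
chains, yet the translocon reliably sorts them. `pmiscale` exploits the
compositional difference between the two with a deliberately minimal model:
a 20-value per-residue scale `h(r)` and a fixed sliding window.

The score of the window starting at position `i` of a sequence is the mean
scale value of its `n` residues,

    H_i = (1/n) * sum_{j = i}^{i + n - 1} h(r_j),

and the *PMI value* of a sequence is `max_i H_i`. A sequence whose PMI value
strictly exceeds a threshold `tau_first` is classified as a TM segment
(signal anchor); otherwise as a signal peptide. The built-in `PMIscale`
(`builtin_scale("PMIscale")`) is the published translocon-insertion
propensity scale; `builtin_scale("KD")` is the standard Kyte–Doolittle
(1982) hydropathy index, which also serves as the optimizer's starting
point. Other published scales are not hard-coded because their exact source
values vary between transcriptions; they can be loaded from a two-column
text file with `read_scale()`.

The whole predictor has 22 parameters: the 20 scale values and two
thresholds. That austerity is the point — what the model can and cannot
predict is directly informative about how much of membrane-protein
topography is decided by local residue composition at the translocon.

## Topography: the two-threshold greedy scan

`locate_tm_segments()` slides the window along the full protein. The first
window whose score strictly exceeds `tau_first` (default 2.7) becomes the
first TM segment, occupying exactly `n = 23` residues. Scanning resumes
`gap + 1` residues after the segment end (default `gap = 2`, i.e. at least
two residues separate consecutive TM helices), and every subsequent segment
only needs to exceed the laxer `tau_next` (default 2.1). The asymmetry
encodes the observation that the first TM segment of a protein must insert
on its own, while downstream segments get help from the already-anchored
chain.

The membrane/non-membrane call (`predict_membrane()`) additionally requires
the first segment to start within `nterm_limit` residues of the N-terminus
(default 140, the upper end of the 110–140 residue range over which signal
recognition particle binding to the nascent chain declines). The limit
applies only to the membrane call, not to pure localization; setting
`limit_localization = TRUE` in `topography_params()` extends it to the scan
itself, since the published description is ambiguous on that point.

Numerical conventions, chosen once and tested:

* **Strict thresholds.** "Exceeds" is implemented as `>`; a window scoring
  exactly `tau` does not qualify. Ties are therefore conservative (SP / no
  segment).
* **Fixed segment length.** Predicted segments are always exactly `n`
  residues; there is no extension or trimming step. The method localizes by
  windows only.
* **Coordinates.** All user-facing coordinates are 1-based inclusive.
* **Short sequences.** A sequence shorter than `n` is scored as a single
  whole-sequence window, with a warning, rather than dropped.
* **Ambiguous residues.** Lowercase letters are upper-cased; non-canonical
  letters (B, J, O, U, X, Z) score 0.0 — near the neutral region of both
  built-in scales — with a warning. How the original training data handled
  ambiguity codes is not documented anywhere we know of; this is this
  package's choice.
* **Running sums.** Profiles are computed with a cumulative sum (O(L) per
  sequence) and are required by the test suite to match a naive
  re-averaging oracle to 1e-9.

## Segment-level evaluation

`match_segments()` pairs predicted and observed segments one-to-one,
greedily in sequence order, counting a pair as matched when it overlaps by
at least `min_overlap` residues (default 5; benchmark papers in this area
rarely state their criterion, so it is a visible, configurable parameter).
`benchmark_topography()` aggregates: sensitivity = TP / (TP + FN) over
segments, "specificity" = TP / (TP + FP) — note this is segment-level
*precision*, the convention of TM-helix benchmark servers, not a
true-negative rate — and the percentage of proteins predicted with no
segment errors at all. Degenerate zero-denominator ratios report 100% with
a warning so that aggregate counts remain usable.

## Learning a scale by grouped steepest ascent

`optimize_scale()` treats the 20 scale values as the solution vector of a
combinatorial local search. A candidate neighbor keeps, raises, or lowers
each value of the *current group* by `delta`; all `3^|G| - 1` combinations
(the all-unchanged identity is excluded — it is the current solution, and
keeping it would mask termination) are scored by the training-set ROC AUC
of the resulting max-window classifier, and the best strictly-improving
neighbor is accepted (steepest ascent). Ties are broken by a deterministic
enumeration order (residues alphabetical, move order unchanged < -delta <
+delta), so the whole procedure is reproducible without any random state.

Searching all 20 residues at once (3^20 neighbors) is infeasible, so the
residues are partitioned into three groups processed in order — G1 =
{F,L,I,V,Y,W}, G2 = {A,T,D,E,R,G,H}, G3 = {C,K,S,M,N,P,Q}, the published
grouping — each capped at 3^7 - 1 = 2186 neighbor evaluations per step.
User-supplied groups larger than 7 fall back to single-coordinate moves
with a warning. Within a group the step size walks down `delta_schedule`
(default `c(3, 2, 1, 0.5, 0.25, 0.1)`): the published account starts at
[+3, -3] — large enough to let the maximum-scoring window *move* along the
sequence, which matters because database TM annotations are only
approximately positioned — and "gradually decreases", without stating the
exact schedule; the default here is a reasonable geometric-ish refinement
and is fully configurable. Phases run G1 -> G2 -> G3 once by default;
`recycle = TRUE` repeats the full pass until no move is accepted, which can
squeeze out a little more training AUC at the cost of more evaluations.

The AUC itself is computed as the Mann–Whitney concordance probability via
midranks (`auc()`), which handles ties exactly; the test suite pins it to a
brute-force double loop over all (positive, negative) pairs at 1e-12.

Because every accepted move strictly increases a statistic bounded by 1 and
taking finitely many values on a fixed dataset, the search terminates; a
`max_steps_per_phase` cap (default 1000) guards against configuration
errors and raises an error carrying the trace collected so far.

**What is deliberately out of scope:** re-deriving the published PMIscale
values by re-running the search. The result of a local search is path- and
schedule-dependent, and the original delta schedule is unstated; the
published values are therefore shipped as constants and the optimizer is
validated by its behavioral properties (monotone improvement, determinism,
exhaustive-search agreement on single-residue groups, full separation of an
inverted-hydrophobicity training set, and held-out recovery on synthetic
data) rather than by value reproduction.

### Implementation note

Scoring thousands of candidate scales is the hot loop. Each window's score
is the inner product of its residue-frequency vector with the scale, so the
package precomputes one window-frequency matrix per training set, pads each
sequence's window block to a common height by repeating its first window (a
duplicate can never change a maximum), and evaluates a whole batch of
neighbors as a single matrix product followed by a vectorized per-sequence
running maximum. A full steepest step over a 7-residue group on a
1005-example training set takes a few seconds in plain R.

## The synthetic-data generator

The package must be testable end-to-end without downloading the original
benchmark files, so `generate_dataset()` emulates the *structure* of the
training data: TM examples are a hydrophobic core of 19–25 residues plus 10
flanking residues on each side (as the signal-anchor training segments were
built); SP examples are protein N-termini truncated to at most 60 residues
with the canonical three-part architecture — a 1–5 residue n-region
containing at least one lysine/arginine, a 6–12 residue hydrophobic
h-region, and polar c-region/mature-sequence filler.

Residues are drawn i.i.d. from three configurable composition vectors. The
defaults concentrate TM mass on I/L/F/V/A/G/W/Y (0.18/0.22 on I/L, the large
hydrophobics dominating), h-region mass on L/A/V/C (0.35 L, 0.25 A — the
h-region is hydrophobic but biased toward small side chains), and background
mass on polar residues. No published generative model exists for these data;
the defaults were set once to mimic the compositional bias the method
exploits, and they are study conditions, not tuning knobs. All randomness
flows through an explicit seeded stream object (`rng_stream()`), never the
ambient `.Random.seed`, so every example is reproducible and generation
never perturbs a caller's RNG.

What the generator does *not* emulate: positional composition gradients
within helices, cleavage-site motifs, sequence redundancy/homology
structure, polytopic cooperativity between neighboring helices, and the
marginally hydrophobic TM segments that make real benchmarks hard. Passing
tests on synthetic data therefore demonstrate correctness of the machinery
and recoverability under the model's own assumptions — not real-data
accuracy, which is what the published benchmark numbers (and the
supplementary-data hooks in the test suite) are for. On the default
synthetic compositions even the Kyte–Doolittle scale separates the classes
almost perfectly; the inverted-hydrophobicity configuration used in the
optimizer tests is the stress case, forcing the search to climb from AUC
near 0 to 1.

Problem sizes used throughout the examples and tests mirror the published
dataset shapes: 305 TM + 700 SP for training, 130 TM + 300 SP for held-out
evaluation, and batches of 100–200 synthetic proteins with 0–4 TM segments
for the topography benchmark.

## Worked example

```{r example}
pmi <- builtin_scale("PMIscale")

# discriminate SP from signal anchors on a synthetic test set
test <- generate_dataset(130, 300, generator_config(seed = 7))
evaluate_discrimination(test, pmi)$auc

# localize TM segments in a two-helix protein
s <- paste0(strrep("G", 5), strrep("L", 23), strrep("G", 5),
            strrep("I", 23), strrep("G", 5))
locate_tm_segments(s, pmi)$segments

# learn a scale from scratch on a small training set
train <- generate_dataset(50, 100, generator_config(seed = 42))
fit <- optimize_scale(train, optimizer_config(delta_schedule = c(3, 1)))
fit
```

## Known limitations

* Topography only: the package predicts where TM segments are, not their
  in/out orientation (no positive-inside rule, no re-entrant helices).
* Families whose helices are atypically hydrophilic (e.g. GPCRs) are poorly
  served by any purely compositional, window-local method, this one
  included.
* The published "specificity" of segment benchmarks is precision-like; if a
  true-negative rate on per-residue labels is needed, it must be computed
  from the exported segment tables.
* The optimizer finds a local optimum of a piecewise-constant objective;
  different groupings, schedules, or starting scales can end at different
  (similarly performing) scales.
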