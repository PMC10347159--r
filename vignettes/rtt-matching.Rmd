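---
title: "Retention time trajectory matching: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention time trajectory matching: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(rttmatch)
```

## The model

A chromatogram run under one set of experimental conditions assigns every
compound a retention time. Pairing each compound's time under a reference
condition with its time under the current condition yields a monotone 2D
curve — the retention time trajectory — that characterizes the condition as
a whole. The method's central assumption is that run-to-run drift comes from
*minor* perturbations of the physical state (temperature program, flow
rate): drifts are smooth and non-linear in retention time, but elution order
is preserved. Under that assumption, identifying the peaks of a sample that
contains an unknown subset of the target list reduces to a combinatorial
question: which injective, order-preserving assignment of peaks to targets
places the sample's trajectory closest to some characterized trajectory?

Closeness is the mean squared residual (MSR): the sum of squared
retention-time differences over all paired coordinates — labeled internal
standards plus assigned peaks — divided by the number of contributing pairs,
`N_std + N_sample − N_interf`. Normalizing by the pair count is what lets
hypotheses with different numbers of interferent labels compete on one
scale. Internal standards, whose identity is known in every sample, serve
twice: their residuals alone (`SSR_std`, identical for every candidate)
screen the library before any target pairing is scored, and their anchor
coordinates partition the assignment space, since a peak eluting between two
standards can only be a compound eluting between them.

## Tunable parameters

* `delta_t` (seconds, default **30**): the cutoff half-window. A (peak,
  compound) pair is admissible only if some retained trajectory puts the
  compound within `delta_t` of the peak. Choose it above the library's
  worst-case drift (here: tens of seconds at the end of a 600 s
  chromatogram); the identification is insensitive to the exact value, which
  only controls how aggressively the candidate space is pruned.
* `screen_rule` / `screen_value` / `screen_floor` (defaults
  `keep_fraction`, 0.5, 20): after sorting by `SSR_std`, keep the best
  fraction (or top-k), but never fewer than `min(n_lib, screen_floor)`
  trajectories. The floor means a six-condition library is not screened at
  all by default; screening pays off only for large (e.g. hybridized)
  libraries.
* `interferent_factor` (default **2**): a peak is relabeled interferent when
  its squared residual exceeds this multiple of the current MSR. The value
  is a convention ("much larger, e.g. twice"), exposed rather than resolved;
  sensitivity to it is bounded by the distance gate below.
* `min_interferent_distance` (seconds, default **1.5**): a peak may carry a
  *voluntary* interferent label against a given trajectory — whether during
  candidate scoring or post-hoc relabeling — only if it lies farther than
  this from every retention time of that trajectory. The default is the
  scale of within-envelope drift mismatch: a peak sitting on the trajectory
  it is scored against is a target, however its residual compares to the
  mean. Peaks with no admissible compound at all are forced interferents and
  exempt.
* `max_results` (default 4): length of the ranked result list.

## Why the interferent rules are gated

Ranking results with and without interferent labels by MSR alone is
degenerate: removing any residual above the mean lowers the MSR, so with
unrestricted labeling the top result would always shed its largest residuals
— under ordinary measurement noise the largest of a dozen squared residuals
exceeds twice their mean ~15% of the time, so genuine targets would be
flagged constantly. Two guards keep the ranking meaningful, both derived
from the method's own premises:

1. **Distance gate, per trajectory.** Interferent evidence is distance from
   the library (that is the first interferent criterion); we therefore
   require every voluntarily labeled peak to be at least
   `min_interferent_distance` from the trajectory the candidate is scored
   against. Enforcing this per trajectory (inside the search, not against
   the pooled library) matters in both directions: a peak near *some other*
   condition's trajectory can still be hypothesized an interferent under the
   achieving condition, and a candidate cannot quietly drop a peak that the
   achieving trajectory explains well.
2. **Majority guard.** Candidates labeling more than half the unlabeled
   peaks as interferents are demoted below all majority-target results (and
   greedy relabeling stops at the same point, with a warning). A sample
   dominated by interferents is outside the method's stated domain.

Relabeling itself is greedy — largest qualifying residual first, MSR
recomputed with the reduced denominator after each step — because the
threshold depends on the MSR, which changes after each removal; the greedy
order is deterministic and each step strictly decreases the MSR, so
refinement terminates and is idempotent.

## The synthetic world

The generator emulates the validation design of a small-molecule GC study:
20 target compounds plus 2 internal standards over a ~600 s chromatogram,
minimum apex spacing 5 s, standards placed mid-gap in the two widest
low-density sections. Drift conditions are smooth order-preserving warps

    RT' = s·RT + c·RT²/span + w(RT),

with linear scale `s`, curvature `c`, and `w` a seeded 4-sinusoid
low-frequency wobble bounded by its amplitude. The characterized library
uses six conditions with scales 0.98–1.02, alternating curvature up to
±0.008 and 1 s wobble — retention-time deviations from a few seconds early
in the run to tens of seconds at the end, the regime the method targets.

*Within-envelope* sample conditions are drawn as a characterized condition
with bounded parameter jitter (|Δs| ≤ 10⁻³, |Δc| ≤ 5·10⁻⁴, same wobble
realization) plus ±0.15 s uniform apex jitter: a run that approximately
reproduces a characterized state, as in a library built densely enough for
its purpose. The resulting trajectory mismatch to the nearest library entry
is bounded by ~1 s — matching the sub-second-RMS residuals that real
within-envelope validation chromatograms exhibit — and is what makes 100%
recovery a *provable* property of the stated world: a wrong assignment must
shift some peak by at least the 5 s minimum gap, costing far more than any
admissible mismatch. Interferent peaks are placed uniformly with ≥ 3 s
clearance from every drifted compound; with ≤ 1 s trajectory mismatch they
are always beyond the 1.5 s distance gate of the achieving trajectory while
genuine targets never are, so flagging is likewise deterministic in-world.

*Out-of-envelope* conditions are built as the two-trajectory extrapolation
`2·lib_f − lib_c` of two characterized conditions (scale ≈ 1.044, beyond the
measured 0.98–1.02) plus fresh 0.3 s wobble — precisely the premise of
library hybridization: drift states beyond the measured envelope remain
linear combinations of measured ones. Experimental-only matching
misidentifies a substantial fraction of subset samples under this drift
(the smooth ~10–20 s mismatch lets single-step assignment shifts cancel
residuals); expanding the library with the midpoint and the two
extrapolation formulas for every experimental pair restores 100%.

What a green test does **not** establish: robustness to elution-order
switches (excluded by assumption — a new library is required), co-elution
closer than the apex detector's separation, interferents closer to a target
than the drift scale (the method's stated limit), peak-shape or
concentration effects (apexes only), or performance under drifts that are
neither within the envelope nor affine combinations of measured conditions.

## Numerical choices

* Retention times are seconds as doubles; duplicate apex times are refused
  at 10⁻⁹ s rather than silently collapsed.
* Candidate search is a depth-first walk over peaks in elution order,
  assigning compounds in increasing id order; prefix residual sums are kept
  per retained trajectory, and a subtree is cut when its best achievable
  MSR (smallest prefix numerator over the largest possible denominator)
  already exceeds the current k-th best — exact, since residuals are
  non-negative. The unconstrained `C(N_tgt, N_sample)` set is never
  materialized.
* Ties in the ranking break deterministically: fewer interferents, then
  lexicographically smaller compound sequence, then library label; library
  screening ties keep input order (stable sort).
* Hybridization coefficients must sum to 1 (all standard formulas do), so a
  compound with equal retention times in both parents keeps that time
  exactly; order-violating or non-positive hybrids are rejected, duplicate
  hybrids (max per-compound difference < 0.05 s, below reporting precision)
  are dropped, and hybrids are never re-hybridized, which bounds the
  expansion and makes it idempotent.
* Degenerate inputs: an assignment with no residual pairs (no standards,
  all peaks interferent) is refused as vacuous; an empty candidate stream
  reports whether `delta_t` or an order conflict emptied it; plateau maxima
  in traces take their leftmost sample as apex.

## Design choices that were genuinely open

* **Standard recognition.** How standard peaks are recognized upstream is
  unspecified in the underlying method; this package takes labeled standards
  as input and offers `auto_label_standards()` (nearest peak within
  `delta_t`, erroring on ambiguity) as an explicit convention.
* **Window semantics.** A pair is admissible when *any* retained trajectory
  explains it — the permissive reading; the alternative (all trajectories)
  would eliminate correct pairs whenever the library spans a wide envelope.
  Screening is applied before admissibility is computed, so enumeration and
  scoring see the same retained set.
* **Interferent hypothesis generation.** Free interferent labeling would
  make the all-interferent candidate always admissible; hypotheses are
  therefore generated only where the distance gate allows them (see above),
  with forced labels where no compound is admissible. This replaces a
  coarser pooled-library gate that both blocked legitimate hypotheses (when
  *another* condition's trajectory passed near the interferent while every
  neighboring compound was present, the candidate space collapsed to empty)
  and admitted the shed-the-worst-half degeneracy under severe drift.
* **Refinement scope.** Post-hoc relabeling is applied to each reported
  result against its achieving trajectory, and the report is re-ranked;
  results below the reporting cutoff are not revisited.

## Known limitations

Identification quality is only as good as the library's coverage of the
drift space; the hybridization formulas extend it linearly, not
physically. The candidate space, though heavily pruned, is exponential in
the worst case (no standards, huge `delta_t`, many peaks); `enumerate_candidates`
exposes a count-only mode and a collection cap for that reason. The apex
detector performs no deconvolution: co-eluting peaks closer than the
sampling/separation limits merge. All statistics assume residuals measured
at the apex; peak asymmetry that moves apexes (overload, tailing) is drift
the library did not see.
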