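---
title: "Energy-landscape analysis of binarized brain activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of binarized brain activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elascape)
```

## The model

`elascape` treats a multichannel recording — in the motivating application,
resting-state fMRI time series from `N` regions of interest of a functional
network, with `N` between roughly 6 and 15 — as a trajectory through the
finite space of binary activity patterns `V = (σ₁, …, σ_N)`, `σᵢ ∈ {−1, +1}`.
Each channel is binarized at its own temporal mean (strictly above the mean
= active), so channels are active about half the time and the pattern
statistics are centred.

The pattern distribution is modeled by the pairwise maximum-entropy (MEM)
distribution: the unique distribution matching the empirical first moments
`⟨σᵢ⟩` and second moments `⟨σᵢσⱼ⟩` with no further structure. It is the
Boltzmann distribution `P(V) ∝ exp(−E(V))` of the Ising energy

$$E(V) = -\sum_i h_i \sigma_i - \tfrac{1}{2}\sum_i \sum_{j \neq i} J_{ij}\sigma_i\sigma_j ,$$

where `hᵢ` is the tendency of channel *i* to be active in isolation and
`Jᵢⱼ` the interaction between channels *i* and *j*. Low-energy patterns
are frequent patterns; the *energy landscape* over all `2^N` patterns,
with single-flip (Hamming-1) adjacency, is the object of analysis.

Model fitting is exact-enumeration moment matching: starting at
`h = 0, J = 0`, iterate

$$h_i \leftarrow h_i + \alpha(\langle\sigma_i\rangle - \langle\sigma_i\rangle_m),
\qquad
J_{ij} \leftarrow J_{ij} + \alpha(\langle\sigma_i\sigma_j\rangle - \langle\sigma_i\sigma_j\rangle_m),$$

where `⟨·⟩_m` are expectations under the current model, computed exactly by
summing over all `2^N` states. This is gradient descent on the KL
divergence from data to model, which is convex in `(h, J)`, so the fixed
point is unique and the start affects only the iteration count. Fit
quality is reported as the base-2 KL divergence `D2` between the empirical
pattern distribution and the fitted Boltzmann law.

Sample-size economics drive the design: at `N = 8` there are 256 patterns,
so a single subject's recording (a few hundred time points) cannot
estimate the distribution, while pooled group data can. The package
therefore fits one model per group and computes dynamics per subject on
that group landscape — the split that makes per-subject indices available
for clinical-score correlations.

### Tunable fitting parameters

| parameter | default | meaning |
|---|---|---|
| `step_alpha` | 0.2 | learning rate of the moment updates (dimensionless) |
| `tol` | 1e-5 | convergence threshold on the largest absolute moment mismatch |
| `max_iter` | 500,000 | iteration cap; exceeding it returns `converged = FALSE`, never an error |

The defaults converge in well under a second for `N ≤ 9` with empirical
moments from thousands of samples. `tol` is measured on moments (not on
`D2`) because the update is moment-space gradient descent; at convergence
the model reproduces the target moments to `tol` by construction.

## Landscape topography

* **Local minima** are patterns strictly lower in energy than all `N`
  single-flip neighbors — candidate stable brain states. Strictness
  matters: plateau ties are not minima, and a perfectly flat landscape is
  reported as degenerate rather than silently producing nonsense.
* **Basins** are computed by iterated steepest descent: from any pattern,
  repeatedly step to the lowest-energy neighbor while it is strictly
  lower. Ties among equally lowest neighbors go to the smallest state
  index — an arbitrary but deterministic rule; with parameters fitted from
  continuous data, exact ties have measure zero.
* **Barriers**: the barrier between two minima is the lowest energy
  threshold at which they fall into separate connected components when all
  patterns above the threshold are deleted. This equals the minimax path
  energy, and the package computes it with a union-find sweep over states
  in increasing energy order; the test suite verifies the equivalence
  against both a literal threshold-deletion implementation and brute-force
  minimax search. Barrier matrices are symmetric and ultrametric by
  construction of the merge process.
* **Classification**: among the four lowest minima, the two disjoint
  pairs minimizing the total mutual barrier are formed (with an
  ultrametric barrier matrix this coincides with greedy smallest-barrier
  pairing, which the tests assert); the pair containing the global
  minimum is *major state 1*, the other *major state 2*, all remaining
  minima *minor*. Degenerate cases (fewer than four minima) fall back to
  labeling the lowest one or two minima as the majors and are flagged.
  Labels extend to every pattern through its basin.

When two independently fitted landscapes are compared (the two groups of
a cohort), the near-mirror symmetry typical of resting-state landscapes
makes "which pair contains the global minimum" a coin flip on fitting
noise. The pipeline therefore renames the majors by a fit-independent
convention — the more-active pair (higher mean `σ` over the pair's minima
patterns) is MAJOR1 — via `align_major_labels()`. The energy-based rule
remains the primitive; the alignment only stabilizes cross-group
comparisons of per-major metrics.

## Dynamics

Each time point inherits its basin's label, giving a three-letter
sequence over {MAJOR1, MAJOR2, MINOR}. Three families of indicators are
computed per subject:

* **Appearance frequency** of each label (fractions of time, summing to 1).
* **Transition structure**: the 3×3 matrix of consecutive-step transitions
  (counts summing to `T − 1`), and, after run-length compression, *direct*
  transitions (adjacent runs of the two different majors) versus
  *indirect* transitions (two different majors bridged only by minor
  runs). An excursion from a major to minor and back to the same major is
  neither. Because published transition percentages do not pin down the
  denominator, both normalizations are emitted: per time step
  (`/(T − 1)`) and per run boundary.
* **Mean duration**: the mean length of maximal runs of each label, in
  sampling steps (TR units). A label that never occurs has duration 0,
  which downstream comparisons treat as a legitimate value (a subject who
  never visits minor states has zero minor dwell).

Subject boundaries are respected throughout: pooled matrices carry their
seam positions, and temporal statistics are only ever computed on single
subject sequences.

## Random-walk simulation

`simulate_walk()` runs single-spin-flip Metropolis dynamics: propose one
of the `N` neighbors uniformly, accept with probability
`min(1, exp(−ΔE))`, and count rejected proposals as repeats of the
current pattern. This rule was chosen because its stationary distribution
is exactly the fitted Boltzmann law, making the simulation self-consistent
with the model — the long-run occupancy check (total-variation distance
below 0.02 after 10⁶ steps for `N ≤ 7`) is part of the acceptance tests.
The default simulation length is 10⁵ steps, with the step count, burn-in
and initial state configurable. Rejected-step repeats count toward dwell
times, matching the discrete-time occupancy statistics of the empirical
sequences.

## Group statistics

Group contrasts use Welch's unequal-variance t-test (the robust default
when group variances differ, as planted cohorts do); score relations use
Pearson correlation with two-sided p-values, consistent with linear
scatter summaries. No multiple-testing correction is applied by default;
a Benjamini–Hochberg option exists behind the `adjust` argument of
`compare_groups()`. Zero-variance degeneracies yield `NA` statistics with
the offending metric still reported.

## The synthetic cohort

Clinical resting-state data with patient/control contrasts are access
restricted, so the package ships a generator that plants the structure
the analysis is designed to detect. Its defaults are the package's study
conditions:

* `N = 8` channels, `T = 190` time points per subject at TR = 3 s — a
  typical single-run resting-state length at the channel count of a
  mid-sized functional network.
* Two groups of 20 subjects. Every subject follows the same base model
  `(h, J)` with couplings scaled by a subject depth factor
  `β_s ~ Normal(group depth, 0.05)`: 1.0 for the control-like group, 0.6
  for the patient-like group. Flattening the landscape (smaller β) is the
  planted mechanism of patient-like instability: it provably raises
  minor-state occupancy and shortens major-state dwell times.
* Binary sequences are generated by the Metropolis walk under the
  subject's own scaled parameters (temporally correlated, like real
  recordings), then observed as `σ + Normal(0, 0.5)` continuous signals so
  the binarization step is exercised end to end.
* Clinical scores follow `14 + 15·β_s + Normal(0, 1.5)`, clipped to
  [0, 30] — an MMSE-like scale on which the patient-like group lands near
  23 and the control-like group near 29, with minor-state occupancy
  negatively related to the score through the shared dependence on β.

The base `(h, J)` (see `default_cohort_params()`) is a frozen,
hand-designed coupling set with an exact block-swap/sign-flip symmetry
(`h_{i+4} = −h_i`, `J` block-circulant), chosen so the landscape matches
the qualitative geometry reported for resting-state networks: the two
major states are mirror-image mostly-active/mostly-inactive pattern
pairs, minima occur in complementary pairs, control-like minor occupancy
sits at a few percent, and major dwell times are a few TR. The symmetry
shares every group contrast evenly between the two majors instead of
concentrating it in one.

What the generator does **not** emulate: hemodynamic filtering and
autocorrelated scanner noise, subject-level deviations from the group
coupling *pattern* (only the overall depth varies), and site or
demographic covariates. Passing tests on this cohort demonstrate that
the pipeline detects the planted landscape-depth mechanism at realistic
sample sizes — not that real patient data follow that mechanism.

## Numerical choices and edge cases

* Exhaustive enumeration is capped at `N = 15` (32,768 states); larger
  inputs are refused with a capability error rather than approximated.
* Boltzmann probabilities are normalized in log space (subtract the
  maximum before exponentiating), so strongly coupled landscapes cannot
  overflow.
* `D2` terms with empirical probability 0 contribute nothing; a pattern
  observed in data but impossible under the model yields `Inf` (which
  cannot occur for a fitted MEM, whose probabilities are strictly
  positive).
* Energy ties are broken by state index wherever an order is needed
  (basin descent, merge order in the barrier sweep, global-minimum
  choice). Fitted parameters make exact ties measure-zero; the
  deterministic rule keeps reruns byte-identical.
* Non-convergence of the fit is a reported state (`converged = FALSE`),
  not an exception; NaN divergence (pathological step size) is an error
  suggesting a smaller `step_alpha`.
* All randomness flows through explicit seeds: the cohort generator is a
  deterministic function of its master seed, and the walk takes its own
  seed, so the whole pipeline reruns identically.

## Problem sizes used in the tests

Unit tests run oracles on `N ≤ 6` landscapes (exhaustive checks over all
instances and pairs), parameter recovery uses 20,000 exact samples at
`N = 7`, walk-convergence checks use 10⁶ steps at `N ≤ 7`, and the
cohort-level checks run the default 20 + 20 subject cohort across ten
generator seeds, with 50 replicate null cohorts for type-I calibration.
These sizes were chosen as the smallest at which each property is
sharply testable.

## Known limitations

* The pairwise model ignores third- and higher-order interactions; `D2`
  quantifies, but does not remove, that approximation.
* One model per group assumes group homogeneity of the coupling pattern;
  subjects influence the fit only through their pooled samples.
* The major/minor classification presumes the "two low pairs" geometry.
  Landscapes without it (fewer than four minima) are handled by the
  documented fallbacks but are flagged as degenerate, and metrics that
  reference a class absent from a landscape (e.g. minor frequency when no
  minor minima exist) are legitimately zero for every subject of that
  group.
* Dwell times are bounded below by the sampling interval; fast state
  changes within one TR are invisible at the modeled timescale.
* Landscape topography is sensitive to fitting noise at realistic sample
  sizes. A group of 20 subjects at 190 time points pools 3,800 samples
  over 256 patterns; coupling standard errors are then comparable to the
  depth of shallow minima, so the fitted minima count can differ from the
  generating landscape's and fluctuates between cohorts. Energies, D2 and
  occupancy-weighted quantities are much more stable than the discrete
  minima set. Conclusions that hinge on the exact number of minima, or on
  contrasts mediated by shallow minima, need substantially more pooled
  data than contrasts of occupancy or dwell times.
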