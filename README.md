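# elascape

Energy-landscape analysis of binarized multichannel brain activity in R.

Resting-state fMRI recordings switch between a small set of recurring
activity patterns. `elascape` implements the statistical-mechanics view of
that process: the binarized activity of `N` regions of interest (ROIs) is
modeled with a pairwise maximum-entropy (Ising) model, whose Boltzmann
distribution assigns every activity pattern `V ∈ {−1,+1}^N` an energy

```
E(V) = − Σᵢ hᵢ σᵢ − ½ Σᵢ Σ_{j≠i} Jᵢⱼ σᵢ σⱼ,     P(V) ∝ exp(−E(V))
```

with channel biases `h` and pairwise couplings `J` fitted by exact
moment matching. The resulting energy landscape over all `2^N` patterns is
then analysed topographically — local minima (stable brain states), basins
of attraction, and the disconnectivity graph whose energy barriers say how
hard it is to move between states. The lowest minima group into two
*major states* (typically a mostly-active pattern pair and its mirror);
everything else is a *minor state*. Per-subject dynamics are summarized by
three indicators: appearance frequency of each state, direct vs indirect
transitions between the major states (an indirect transition is bridged by
minor-state visits), and mean dwell time in TR units. A Metropolis
random walk on the fitted landscape — whose stationary law is exactly the
fitted Boltzmann distribution — provides matching simulated dynamics, and
Welch t-tests / Pearson correlations relate the per-subject indices to
group membership and a clinical score.

The package is aimed at researchers analysing small networks of brain
regions (roughly 6–15 channels, where exact enumeration is feasible) and
ships a synthetic-cohort generator that plants the qualitative structure
reported for patient/control resting-state comparisons — a flattened,
less stable landscape in the patient-like group and clinical scores tied
to landscape depth — so the full pipeline can be exercised and validated
without access-restricted clinical data.

## Test suite

```r
testthat::test_dir("tests/testthat", package = "elascape",
                   load_package = "installed")
```

## Worked example

```r
library(elascape)

cohort <- generate_cohort(cohort_spec(), seed = 1)   # 20 + 20 subjects
res    <- run_landscape_pipeline(cohort)
res
#> Energy-landscape pipeline: 2 group(s), 40 subjects
#>   patient: 7 minima, D2 = 0.0502 bits, converged = TRUE
#>   control: 4 minima, D2 = 0.0477 bits, converged = TRUE
```

The patient-like group's flatter landscape supports more local minima and
its fit quality `D2` (base-2 KL divergence between the empirical pattern
distribution and the model) stays small, i.e. the pairwise model captures
the pattern statistics well. Group contrasts of the dynamic indices:

```r
dplyr::select(res$comparisons, metric, mean1, mean2, t, p_value, stars)
#>   metric         mean1(control) mean2(patient)      t   p_value stars
#> 1 freq_major1            0.543          0.344  12.9   5.0e-15   ***
#> 3 freq_minor             0.000          0.371 -26.4   2.0e-16   ***
#> 4 direct_freq            0.208          0.119   6.8   6.3e-08   ***
#> 5 indirect_freq          0.000          0.041 -15.3   4.0e-12   ***
#> 6 dur_major1             5.36           2.90    7.3   1.7e-07   ***
```

(Group landscapes are refitted from each generated cohort, so minima
counts and the sharpness of these contrasts vary with the seed; the signs
shown are the planted structure.) The patient-like group occupies major states
less, visits minor states more, switches between the majors indirectly
through minor states more often, and dwells in the majors for fewer TR
steps — and minor-state occupancy correlates negatively with the clinical
score (`res$correlations`).

Individual stages are ordinary functions on matrices and tibbles:

```r
b      <- binarize(cohort$series[[1]])        # T x N matrix of ±1
fit    <- fit_mem(pool_group(lapply(cohort$series, binarize)))
glance(fit)                                   # D2, iterations, convergence
land   <- energy_landscape(fit)
minima <- find_local_minima(land)
disc   <- build_disconnectivity(land, minima)
autoplot(disc)                                # disconnectivity tree
```

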