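# sanstates

Discover discrete conformational states of a protein from a
structure-prediction ensemble, and quantify their populations — and the
population *shift* between experimental conditions — against small-angle
neutron scattering (SANS) data.

The package targets a common situation in integrative structural biology:
AlphaFold-style sampling (e.g. via MSA subsampling) produces hundreds of
candidate conformations of a flexible protein such as a pentameric
ligand-gated ion channel, with per-model confidence scores (mean pLDDT)
stored in the B-factor column, while solution SANS provides low-resolution
but condition-resolved experimental curves. `sanstates` connects the two:

1. **Forward model.** For every conformation the theoretical SANS curve is
   computed with an implicit-solvent Debye sum,
   `I(q) = Σⱼ Σₖ bⱼ bₖ sin(q rⱼₖ)/(q rⱼₖ)`, using tabulated coherent neutron
   scattering lengths, excluded-volume contrast
   `b_eff = b_coh − ρ_solv V_excl` (with ρ_solv linear in the buffer D₂O
   fraction), H/D exchange of N/O/S-bound hydrogens, and an optional
   hydration-shell bead layer (contrast 5.50898% of the solvent SLD by
   default). Curves are normalized to `I(0) = 1`.
2. **State discovery.** Models are filtered by mean confidence; the curves
   are mean-centred and projected onto the principal components carrying
   >95% of the variance; Ward agglomerative clustering (k = 2) labels the
   models; and a sweep over confidence cutoffs picks the threshold that
   maximizes the mean silhouette score `s = (b − a)/max(a, b)`. The
   highest-confidence model in each cluster becomes that state's
   representative.
3. **Population fitting.** Experimental curves are fitted with scaled
   two-state mixtures,
   `χ² = Σᵢ [f (w₁I₁(qᵢ) + w₂I₂(qᵢ)) − I_exp(qᵢ)]² / (N_q σ²(qᵢ))`,
   with the scale `f` minimized in closed form and `w₁` scanned on a grid.
   The between-condition difference curve is fitted with
   `f̄ δw (I₁ − I₂)` to estimate the population shift δw, where `f̄` is the
   mean of the per-condition best-fit scales and the denominator propagates
   both conditions' errors.

Structural descriptors for labelling the discovered states are included:
superposition RMSD (Kabsch), RMSD to the ensemble average, per-residue RMSF,
a probe-sphere pore-radius profile, and centre-of-mass spread metrics
(e.g. the "M2 spread" gating descriptor for ion channels). A synthetic
fixture generator plants two bead-model states, low-confidence
intermediates and noisy mixture "experimental" curves with known ground
truth.

## Worked example

Generate a synthetic two-state study (stacked-ring bead models at radii
5 Å and 6.5 Å — "closed-like" and "expanded" — plus 6 low-confidence
intermediates; a resting condition that is 100% state 1 and an activating
condition with 30% state 2) and run the full pipeline:

```r
library(sanstates)

dir <- tempfile()
write_fixture(fixture_spec(seed = 1), dir,
              opts = forward_options(shell_enabled = FALSE))
run <- run_pipeline(file.path(dir, "models"),
                    file.path(dir, "activating.dat"),
                    file.path(dir, "resting.dat"),
                    opts = forward_options(shell_enabled = FALSE))
run
#> <sans_run>
#> <cluster_sweep> 44 thresholds; best 89.2 (silhouette 0.986, 7 models, 2 clusters)
#> representatives: [0] model_034, [1] model_015
#> <population_fit>
#>   condition A: <two_state_fit> w1 = 0.72, w2 = 0.28, f = 0.9974, chi2 = 1.228
#>   condition B: <two_state_fit> w1 = 1.00, w2 = 0.00, f = 1.009, chi2 = 2.229
#>   f_bar = 1.003
#>   difference: <difference_fit> delta_w = -0.31, f_bar = 1.003, chi2_delta = 1.124
```

Reading the output: the silhouette-maximizing confidence cutoff (89.2)
excludes every planted intermediate; the two cluster representatives are
one model per true state; the activating condition fits as a 72/28 mixture
(planted: 70/30) while the resting condition is pure state 1 (planted:
100/0); and the difference-curve fit recovers a population shift of 0.31
toward the expanded state (planted: 0.30) with `χ²_ΔI ≈ 1.1`, i.e.
residuals at the noise level. Here `w1` refers to the higher-PC1 cluster's
curve, which for this seed is the *compact* state, hence the negative sign
of `delta_w`.

Tabular summaries and plots follow broom/ggplot2 conventions:

```r
glance(run$popfit)
#> # A tibble: 1 × 7
#>    w1_a chi2_a  w1_b chi2_b f_bar delta_w chi2_delta
#>   <dbl>  <dbl> <dbl>  <dbl> <dbl>   <dbl>      <dbl>
#> 1  0.72   1.23     1   2.23  1.00   -0.31       1.12
tidy(run$sweep)            # threshold / n_retained / silhouette table
autoplot(run$sweep)        # silhouette vs cutoff
autoplot(run$popfit$diff)  # chi2 profile over the population shift
```

A thin command-line wrapper with `synth`, `curves`, `states` and `fit`
subcommands is installed at `inst/cli/sanstates.R`.

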