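---
title: "Discovering conformational states and fitting their populations from SANS curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conformational states and fitting their populations from SANS curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanstates)
```

## The problem

Deep-learning structure predictors run with subsampled alignments produce
ensembles that may contain several functional conformations of a flexible
protein — for an ion channel, closed-like and open-like pores — mixed with
partially formed or misfolded models. Solution SANS measures a single
orientationally averaged curve $I(q)$ per condition, too low-resolution to
invert for structures, but sensitive enough at intermediate $q$
(roughly $q \in [0.1, 0.2]\,\text{Å}^{-1}$ for a pentameric channel) to
distinguish conformational states and their relative populations.
`sanstates` implements the connecting pipeline: a forward model from
coordinates to curves, curve-space state discovery, and population fitting
against per-condition experimental data.

## Forward model

The theoretical curve is the Debye double sum over sites $j,k$ with
effective scattering lengths $b_j$,

$$I(q) = \sum_j \sum_k b_j b_k \,\frac{\sin(q r_{jk})}{q r_{jk}},$$

with $\operatorname{sinc}(0) = 1$. Effective lengths follow the standard
neutron contrast model $b_\text{eff} = b_\text{coh} - \rho_s V$, with
tabulated coherent lengths (H $-3.7406$, D $6.671$, C $6.6511$, N $9.37$,
O $5.803$, S $2.847$ fm), tabulated displaced volumes scaled by
$(r_0/r_m)^3$ (default ratio 1), and a solvent scattering-length density
linear in the buffer D$_2$O fraction ($-0.56\times10^{-6}\,\text{Å}^{-2}$
at 0% to $6.36\times10^{-6}\,\text{Å}^{-2}$ at 100%). Hydrogens bound to
N, O or S (identified by a 1.25 Å heavy-atom search) exchange with the
buffer, mixing the H and D lengths by the D$_2$O fraction;
non-exchangeable hydrogens mix by the protein deuteration fraction.
Defaults mirror a typical deuterated-buffer SANS measurement: 100% D$_2$O,
no protein deuteration, hydration-shell contrast 5.50898% of the solvent
density, and curves normalized to $I(0) = 1$.

Assumptions and simplifications:

* **Flat form factors.** Sites scatter as points; there is no $q$-dependent
  atomic form factor. This is the usual neutron small-angle approximation
  and restricts X-ray use to a qualitative mode.
* **Hydration shell.** A single layer of dummy beads on a grid-based
  surface (probe and spacing 3 Å), each carrying the shell contrast times
  the solvent density times the bead volume. The shell is a coarse stand-in
  for boundary-layer scattering; every analytic test therefore runs with
  `shell_enabled = FALSE`, and conclusions that depend on the exact shell
  construction should not be drawn.
* **q grid.** Default 201 uniform points on $[0, 0.45]\,\text{Å}^{-1}$,
  matching the range over which experimental curves for a mid-size protein
  are typically usable; the embedding and fits are stable under grid
  refinement (doubling the grid does not change cluster labels in the
  packaged fixtures).
* **Cost.** The pair sum is exact ($O(N^2)$ pairs) up to 2000 sites, and
  switches to 0.05 Å distance binning above that, using the
  weight-averaged distance per bin, which keeps the binned sum within
  $10^{-4}$ relative of the exact sum on the packaged fixtures.
  Residue-bead mode (per-residue sums placed at the Cα) is available for
  large ensembles.

The same site weights drive the contrast-weighted radius of gyration and
the pair-distance distribution $P(r)$; the latter is stored as a density
so that $\sum_\text{bins} P(r)\operatorname{sinc}(qr)\,\Delta r$ plus the
self-term reproduces $I(q)$ up to binning error — a property used as a
cross-check in the tests.

## State discovery

Given per-model curves and mean per-model confidence scores (pLDDT
convention: per-residue values in the B-factor column, averaged over
residues using each residue's first atom):

1. retain models with confidence at or above a cutoff (inclusive);
2. mean-centre the curves — no per-$q$ rescaling, so intensity differences
   keep their physical meaning — and project onto the smallest number of
   principal components (at least 2) explaining >95% of the variance;
3. cluster with Ward-linkage agglomerative clustering, $k = 2$;
4. score with the mean silhouette and repeat over every distinct
   confidence value from the base cutoff (default 75) upward;
5. choose the cutoff maximizing the silhouette and, per cluster, the
   highest-confidence model as representative.

Decisions taken where the procedure is genuinely open:

* **Linkage.** Ward on Euclidean distances in PC space — the standard
  compact-cluster default; configurable.
* **Sign conventions.** Each PC is flipped so its largest-magnitude loading
  is positive; cluster label 0 is the lower-mean-PC1 cluster. Both make
  runs deterministic and order-independent.
* **Ties.** Equal maximal silhouettes across a plateau of cutoffs resolve
  to the smallest cutoff (retaining the most models); the plateau is
  reported.
* **Degenerate thresholds.** Cutoffs leaving fewer than 3 models, or
  identical curves, are recorded with `NA` silhouette and skipped for the
  argmax rather than erroring.

A caveat the tests surfaced: when only a handful of models survive a high
cutoff, the silhouette of an arbitrary 2-split is upward-biased (a
two-point cluster is always "tight"), and in an embedding dominated by a
single variation mode even a featureless cloud scores ≈0.6. The sweep's
argmax is therefore meaningful only when the winning threshold retains a
reasonable number of models; `run_state_discovery` warns below a
configurable silhouette floor (default 0.5), and the sweep table should be
inspected rather than trusting the single best number. The confidence
metric is pluggable precisely because its usefulness is system-specific.

## Population fitting

For one condition with intensities $I_\text{exp}(q_i)$ and errors
$\sigma(q_i)$ over $N_q$ points, a weighted two-state mixture is scored by

$$\chi^2 = \sum_{i=1}^{N_q}
\frac{\left[f\,(w_1 I_1(q_i) + w_2 I_2(q_i)) - I_\text{exp}(q_i)\right]^2}
     {N_q\,\sigma^2(q_i)},$$

with $w_1 + w_2 = 1$, $w_1$ scanned on a 0.01 grid (the profile is itself
an output), and $f$ given in closed form at each weight. No constant
background term is fitted. Flat-profile ties resolve toward larger $w_1$.

For two conditions, the experimental difference curve is fitted by
$\bar f\,\delta w\,(I_1 - I_2)$ with
$$\chi^2_{\Delta I} = \sum_i
\frac{[\bar f \delta w (I_1(q_i) - I_2(q_i)) -
       (I^a_\text{exp}(q_i) - I^b_\text{exp}(q_i))]^2}
     {N_q(\sigma_a^2(q_i) + \sigma_b^2(q_i))},$$
$\delta w$ scanned over $[-1, 1]$ so the data can contradict the assumed
direction of the shift; ties resolve to the smallest $|\delta w|$. The
scale $\bar f$ is the arithmetic mean of the two conditions' best-mixture
scales — the wording "the scale that minimized the per-condition fit" also
admits single-state fits, but tying $\bar f$ to each condition's own best
mixture is the self-consistent reading and is what `compute_f_bar`
implements. Condition grids that differ slightly are reconciled by linear
interpolation with error propagation
$\sigma' = \sqrt{(1-t)^2\sigma_l^2 + t^2\sigma_r^2}$; interpolation-induced
error correlation is ignored (the intended use is sub-$10^{-4}$ Å$^{-1}$
grid offsets), and a warning flags larger gaps.

## The synthetic study

The fixture generator plants everything the pipeline is asked to recover:
two states built from five stacked rings of twelve beads (ring spacing
3 Å) at radii 5 and 6.5 Å — a compact and an expanded "pore" — with
0.15 Å coordinate jitter; 20 models per state with confidence uniform on
85–90; 6 geometric intermediates (interpolated radius) with confidence
uniform on 76–80, emulating the empirical pattern that partially formed
conformations score lower; and per-condition "experimental" curves
$I_\text{exp} = f \sum_s w_s I_s + \varepsilon$ at 1% relative Gaussian
noise with the generating SD reported as $\sigma$. The default conditions
are $(1, 0)$ and $(0.7, 0.3)$: a planted population shift of 0.30. The
noise SD is floored at 5% of the curve maximum so that error weights stay
bounded near intensity minima — real SANS errors likewise do not vanish.

What the fixtures do *not* emulate: real predictor output statistics
(confidence pathologies, misfolding modes), instrument resolution
smearing, buffer-subtraction systematics, or concentration effects.
Passing the planted-recovery tests demonstrates the pipeline's internal
consistency — filtering, embedding, clustering, and fitting recover a known
truth at realistic noise — not that any particular real ensemble contains
its functional states.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run at desk scale by choice:
60-bead models, 46-model ensembles, 201-point curves, 100-seed recovery
loops, and 100-replicate noise studies; these sizes make every check a
few-minute computation while leaving the estimators' behaviour unchanged.
Degenerate inputs error early and descriptively: empty ensembles, zero
shared atoms, all-zero contrast, identical curves in PCA, identical state
curves in the difference fit. All randomness in fixture generation flows
from a single integer seed, and generation restores the caller's RNG
state.

## Geometry descriptors

Superposition uses the SVD form of the Kabsch algorithm (proper rotations
only); RMSD-to-average superposes all models on the first, averages, and
re-superposes on the mean; RMSF is computed about the post-fit mean with
optional per-subunit averaging. The pore profile is a simplified
probe-sphere: at each point of an axis the radius is the minimal
centre-distance minus van der Waals radius, clamped to $[0, 10]$ Å. The
default axis is the first principal axis of the Cα coordinates — adequate
for an elongated channel, overridable by two explicit points (all analytic
tests pass an explicit axis). This is an approximation to pathway-following
tools (HOLE/CHAP): it cannot follow a curved pore and reports a capped
radius where the axis exits the protein. Selections use a compact
`"chain:residues:atom"` syntax; system-specific residue ranges (e.g. which
helix counts as "pore-lining") are configuration, not code.

## Known limitations

* The forward model is a reduced implicit-solvent calculator: agreement
  with specific external programs is not a goal, and absolute-scale
  intensities are not modelled (all fits include a free scale).
* Two states only; the cluster count is fixed at $k = 2$ by design, with a
  configurable escape hatch but no automatic model selection.
* The silhouette argmax can favour very small surviving subsets (see
  above); inspect `tidy(sweep)`.
* Difference-curve errors assume independent conditions and ignore
  interpolation correlation.
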