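---
title: "Benchmarking transcriptome-integration methods for flux prediction"
author: "fluxbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking transcriptome-integration methods for flux prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxbench)
```

## The problem

Constraint-based models describe the steady-state flux space of a
metabolic network: all flux vectors $v$ with $S v = 0$ inside the bound
box $lb \le v \le ub$. Flux balance analysis (FBA) selects a point from
that space by maximizing an objective, typically biomass production; its
parsimonious variant (pFBA) additionally minimizes the total absolute
flux $\sum_r |v_r|$ at the fixed optimum, reflecting economical enzyme
usage. A long line of methods instead tries to pick the point using
transcript abundances, on the premise that a reaction's expression hints
at its flux. `fluxbench` implements six such formulations — GIMME, iMAT,
E-Flux, pairwise MADE, Lee-12 and GX-FBA — together with the evaluation
harness needed to compare them fairly against pFBA on data with known
or measured fluxes: expression-to-reaction mapping through GPR rules,
projection of measured fluxes onto the model's feasible space,
futile-cycle removal, a normalized error metric, scenario-based
benchmarking, parameter-sensitivity sweeps, and a shuffle-noise
robustness protocol.

All linear and mixed-binary programs are solved by a small dense
two-phase simplex (Dantzig pricing with a Bland anti-cycling fallback)
with depth-first branch and bound for the binary formulations. The
networks this package targets are deliberately small — tens of
reactions — so a dense exact solver is simpler and more transparent
than an external dependency. The measured-flux projection is a quadratic
program solved with `quadprog`.

## Expression-to-reaction mapping

Gene-protein-reaction (GPR) rules are boolean formulas in which *and*
encodes enzyme complexes and *or* encodes isozymes. Continuous levels
map through a rule with AND $\to$ min (a complex is limited by its
scarcest subunit) and OR $\to$ max or sum (interchangeable isozymes).
Genes without a measurement are removed from the formula rather than
imputed; a fully unmeasured rule leaves the reaction unscored. Discrete
classes (low / intermediate / high) come from linear-interpolation
percentiles of the gene-level values — 25th and 75th by default — and
propagate through the rule with tri-valued AND $\to$ min, OR $\to$ max.
Ties fall to `intermediate` (comparisons are strict), so a constant
vector classifies everything intermediate rather than arbitrarily.

Per-method isozyme defaults follow each method's original formulation:
`sum` for E-Flux and Lee-12, `max` for GX-FBA and (continuous) GIMME,
and gene-level discretization mapped through the boolean rule for iMAT
and MADE. Each default can be overridden via `method_config(or_mode =
...)`. Percentile thresholds are computed over gene-level values by
default (`threshold_level = "reaction"` switches to mapped scores); the
estimator choice matters little for well-spread data but is documented
because it is not standardized across the literature.

## The six formulations

* **GIMME** minimizes $\sum_r w_r |v_r|$ with $w_r = \max(t - x_r, 0)$,
  the deficit of a reaction's expression below the cutoff threshold
  $t$ (25th percentile), subject to the growth rate reaching 90% of its
  maximum (`objective_fraction`). When the growth rate is already fixed
  by a measurement the growth requirement is dropped — it would have no
  effect.
* **iMAT** classifies reactions high/low and maximizes the count of
  satisfied predictions: a high reaction carrying at least the
  activation threshold (1 flux unit, in either direction for reversible
  reactions) or a low reaction carrying none. It imposes no biomass
  objective.
* **E-Flux** turns expression into "pipe capacities": each scored
  reaction's bounds shrink to its expression level normalized by the
  maximum gene expression; biomass is then maximized on the unit-scaled
  network, and the resulting adimensional distribution is rescaled so
  glucose uptake matches the measured rate. Exchange-rate constraints
  are deliberately not applied (they are incommensurable with the
  unit-scaled bounds); positive lower bounds such as ATP maintenance
  are likewise released in the adimensional network.
* **Pairwise MADE** compares each condition against a reference: the
  desired transition of every gene is the sign of its expression
  change, and a MILP over binary gene states for both conditions
  maximizes agreement with those transitions (unit weights) while both
  states must support 90% of their respective maximum growth. Gene
  states gate reactions through the GPR rules inside the MILP. The
  reported flux is the test-condition pFBA solution in the
  state-constrained model.
* **Lee-12** minimizes the distance between normalized fluxes and
  normalized expression, $\sum_r \big| |v_r|/u_{glc} - \hat x_r \big|$
  over the scored reactions, with the flux vector normalized by the
  glucose uptake rate and the expression vector by the glucose
  transporter expression. No biomass objective is used. For reversible
  reactions the absolute flux is linearized by forward/reverse
  splitting, which can overstate $|v_r|$ when the two halves are
  simultaneously active; the parsimonious tie-break below suppresses
  that artifact, and the bundled networks are irreversible so the tests
  are unaffected.
* **GX-FBA** uses differential expression against a reference state: the
  reference flux is the midpoint of each reaction's FVA range under the
  reference constraints (precomputed once, since FVA dominates the
  cost); reactions with $|\log_2 F_r| \ge 0.5$ (with
  $F_r = x^{test}_r / x^{ref}_r$) form the active set; the perturbed LP
  maximizes $\sum (\log_2 F_r / v^{ref}_r)\, v_r$ with each active
  reaction capped at $F_r\, v^{ref}_r$. Reactions with zero reference
  expression or negligible reference flux are excluded (and logged);
  an empty active set is a failure, as is an infeasible cap set —
  GX-FBA is the most failure-prone method under heavily constrained
  scenarios, and those failures are recorded rather than patched. When
  a cap contradicts a hard measurement band the measurement wins and
  the cap is skipped for that reaction.

**Alternative optima.** Several of these objectives ignore most of the
flux vector, so their optima are highly degenerate; which vertex a
solver reports is arbitrary. `fluxbench` makes the reported distribution
unique and interpretable by a uniform secondary selection: the primary
objective is pinned at its optimum (binaries fixed) and the total
absolute flux is minimized among the remaining optima. This is the same
enzyme-economy argument that motivates pFBA and the flux-sum tie-breaks
used by later GIMME derivatives. A visible consequence: methods without
any biomass term (iMAT, Lee-12, GX-FBA) report zero or near-zero growth
unless a growth constraint is supplied, because growing costs synthesis
flux that their objectives never reward.

## Evaluation pipeline

Measured fluxes (13C-derived intracellular rates, uptake, secretion and
growth) rarely lie exactly in a model's feasible space. Before any
method runs, each condition's measurements are projected onto the
feasible space by minimizing the squared distance over the measured
reactions subject to $S v = 0$ and bounds (`fit_fluxes_to_model`; a
$10^{-10}$ ridge keeps the quadratic form positive definite and
perturbs the projection far below every comparison tolerance).

Three constraint scenarios are benchmarked. `uptake_only` fixes the
measured uptake rates; `full_physiology` fixes the complete set of
uptake, growth and secretion rates; `min_growth_90` fixes uptakes and
adds a growth floor of 90% of the maximum theoretical growth rate.
Intracellular measurements are never constraints — they are the
prediction target. Fixing uses a symmetric band
$\delta = \max(10^{-6}, 10^{-3}|m|)$ so floating-point measurements
cannot render the model infeasible; the band contributes a baseline
error of order $10^{-3}$, which is why even a self-consistent
prediction does not score exactly zero. Whether uptakes are fixed
values or upper bounds is configurable (`uptake_as`), defaulting to
fixed bands.

Predictions pass through futile-cycle removal before scoring: the
cycle-capable set is found structurally (close every exchange, run FVA;
anything that can still carry flux lives on an internal cycle) and the
absolute flux over that set is minimized with all other fluxes fixed.
Exchange fluxes, the objective flux, and the total flux can only stay
or shrink.

The error of a prediction $u$ against measurements $v$ over the
compared set is the normalized Euclidean distance
$\|u - v\|_2 / \|v\|_2$: 0 for a perfect prediction, 1 for an all-zero
one, scale-invariant across conditions. The compared set is every
measured entry, including those fixed as constraints — under
`full_physiology` the constrained entries contribute essentially
nothing, which is precisely the expected error drop when physiology is
given. An alternative normalization by $\|v\|_2^2$ is available behind
`normalization = "norm_sq"`. Failed computations yield records without
an error value and are excluded from averages but counted.

## Synthetic fixtures

Real multi-omics datasets with matched transcriptomes and 13C fluxes
are scarce and large; the bundled generator builds a toy study with
known ground truth instead. The canonical network is hardcoded (21
reactions, 21 genes) so worked examples cite stable numbers: glucose
and oxygen uptake, lumped glycolysis with a lower-yield alternative
route and a gluconeogenic back-reaction, fermentation exits (lactate,
ethanol, acetate), pyruvate oxidation and a lumped TCA cycle, oxidative
phosphorylation, ATP maintenance, a two-reaction shuttle that can carry
futile-cycle flux, and a biomass reaction fed by precursors and a
lumped polymerization step. The polymerization step matters: it makes
growth cost substantial synthesis flux, as it does in genome-scale
reconstructions where biomass drains hundreds of biosynthetic
reactions. Without it, biomass would be the flux-cheapest carbon sink
of a small network and even objective-free formulations would "grow".
The network reproduces the three canonical regimes: fully respiratory
growth under ample oxygen, overflow metabolism (fermentation-product
secretion) under oxygen limitation, and fermentative growth under
anaerobiosis.

Conditions cycle through three archetypes mirroring published study
designs: a chemostat-like glucose series, an oxygenation series from
anaerobic to fully aerobic, and single-gene perturbation mutants under
moderate oxygen limitation. Each condition's truth is the pFBA flux of
the (possibly perturbed) model under its uptakes; measurements are the
truth values at the uptake, secretion, growth and central intracellular
reactions (emulating 13C coverage); expression is generated by
inverting the GPR mapping from the target score $|v_r| + 1$ (the offset
keeps zero-flux genes measurable and gives the percentile thresholds
spread at zero flux) with optional multiplicative log-normal noise.
Generation is bit-reproducible from `(n_conditions, seed)`.

What passing tests on these fixtures do **not** show: real transcript
levels are far from proportional to fluxes (central metabolism is
heavily post-transcriptionally regulated), platform noise is not
log-normal, and on a 21-reaction network the full-physiology scenario
nearly determines the interior fluxes, so scenario-(b) errors collapse
toward the measurement-band floor in a way genome-scale models would
not. The fixtures validate the machinery and the mechanism story, not
field performance.

## Sensitivity and robustness protocols

One parameter is varied at a time over 20 grid points, the others held
at defaults: objective fraction linearly in $[0,1]$ (GIMME, MADE), the
GIMME cutoff over the 0th–100th percentile, the iMAT activation
threshold log-spaced in $[0.1, 10]$, and the iMAT low/high thresholds
over the 0th–75th / 25th–100th percentiles. Per grid point the error is
averaged over all conditions; infeasible points are excluded and
counted.

Noise robustness shuffles the expression vector ($r$) and evaluates the
convex combination $y = (1-\lambda) x + \lambda r$, which preserves the
value distribution exactly and interpolates from original data
($\lambda = 0$) to fully random data ($\lambda = 1$). Ten equally
spaced $\lambda$ levels spanning $[0, 1]$ inclusive are used (both
endpoints are meaningful states), with 100 evaluations per level, each
with a fresh shuffle from its own derived child seed so partial reruns
reproduce. At $\lambda = 0$ all replicates are identical, so the
variance is exactly zero — a useful determinism check.

## Numerical choices

Solver feasibility and integrality tolerances are $10^{-6}$ with an
absolute floor of $10^{-9}$; equality pinning of a primary objective
uses a relative band of $10^{-7}$. iMAT's zero-flux reward closes the
reaction's bounds exactly; its activation constraints use the bound
magnitudes as big-M values (bounds are $\pm 1000$, so no scaling issues
arise at toy scale). Branch and bound prunes with a unit gap for the
integral consistency/agreement objectives and seeds its incumbent with
a root rounding heuristic. Degenerate isozyme splits (flux shared
between parallel identical reactions) are not individually
reproducible across solvers; tests compare objectives and totals, never
individual split fluxes.

## Problem sizes used in checks

The bundled checks run the full benchmark (7 methods × 6 conditions ×
2 scenarios), the 10 × 100 shuffle-robustness protocol for one method,
100-seed shuffled-control comparisons over 3 conditions, and 20-point
sweeps — a few minutes end to end on one core, chosen so the whole
evaluation remains convenient to rerun while still exercising every
protocol constant at its stated value.
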