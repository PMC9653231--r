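---
title: "Methods: a branching protometabolism simulator for dividing protocells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a branching protometabolism simulator for dividing protocells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`protoflux` simulates an autotrophic protocell: a fatty-acid vesicle whose
contents grow by fixing CO2 (with H2 as the reductant, implicit) at
iron–sulfur clusters chelated by amino acids and associated with the
membrane. Fixation produces an activated two-carbon unit (C2, an acetyl-CoA
equivalent) that feeds a branching protometabolism producing six tracked
molecular species:

* `fa` — fatty acids, the membrane; the cell's size proxy,
* `aa1` — FeS-chelating amino acids, which catalyse CO2 fixation,
* `aa2` — a second amino-acid pool, a nucleotide precursor,
* `s` — sugars, a nucleotide precursor,
* `e` — an energy currency (acetyl-phosphate-like), a consumed substrate of
  nucleotide synthesis,
* `n` — nucleotides, the catalytic cofactors under study.

State is a vector of molecule counts. Cell volume is proportional to the
fatty-acid count (`vol_per_fa * fa`), so the concentration of species $X$ is
$[X] = X / (v_\mathrm{fa}\, \mathrm{FA})$; no surface-to-volume geometry is
modelled beyond this proportionality.

Between divisions the counts obey mass-action ODEs. Total fixation flux
(C2 units per day for the whole cell) is

$$\Phi = k_\mathrm{fix}\, c_{\mathrm{CO_2}}\, [\mathrm{AA_1}]\,
  (1 + K_{CN}^{\mathrm{eff}} [N])\, V,$$

proportional to the *number* of FeS-bearing amino acids (Fe and S ions are
assumed non-limiting) and boosted linearly by nucleotide catalysis of
fixation ($K_{CN}$). Fixed carbon is finite, so the branches compete: branch
$i \in \{FA, AA_1, AA_2, S, E\}$ carries weight

$$w_i = \lambda_i \left(1 + K_{iN}\,\frac{[N]}{K_\mathrm{sat} + [N]}\right),$$

and receives the renormalized fraction $w_i / \sum_j w_j$ of the flux,
divided by its carbon stoichiometry $n_{C2,i}$ (all 1 by default). With no
pathway catalysis the fractions are exactly the baseline split
$\lambda = (0.376, 0.282, 0.282, 0.05, 0.01)$, the thermodynamically
assigned proportions of the standard preset. Nucleotide synthesis is
trimolecular with a linear autocatalytic boost,

$$R_N = K_{NE}\, [\mathrm{AA_2}][S][E]\, (1 + K_{NN} [N])\, V,$$

consuming one AA2, one S and one E per nucleotide. Carbon is conserved by
construction: production rates weighted by $n_{C2}$ sum to $\Phi$ at every
state, and the whole right-hand side is homogeneous of degree one in the
counts (doubling a cell doubles its rates).

The cell divides when `fa` reaches `fa_div`; the tracked daughter inherits
half of every count, either exactly (deterministic) or as independent
`Binomial(count, 1/2)` draws (stochastic segregation). One daughter is
followed per division — under binomial partitioning the two are
exchangeable, and rates here are per-cell quantities, so population
bookkeeping would add nothing.

## Calibration and parameter choices

The branch fractions and catalysis constants ($K_{CN} = 10^3$,
$K_{NE} = K_{NN} = 2$, $K_\mathrm{sat} = 1$) are the standard preset. Three
constants are calibration choices of this package:

* **`k_fix`** $= \log 2 / \lambda_{AA_1} \approx 2.458$/day. In the null
  model (all nucleotide feedbacks off) the AA1 pool grows exponentially at
  $\mu = \lambda_{AA_1} k_\mathrm{fix}$ and the converged division cycle is
  a doubling, so the asymptotic division rate is $\mu / \log 2$ — exactly
  1.0 division/day by this choice. This closed form pins the time axis; it
  is verified numerically rather than assumed in the tests.
* **`fa_div`** $= 10\times$ the initial fatty-acid count. Because the
  deterministic dynamics are degree-one homogeneous, the threshold sets only
  the absolute count scale, not the steady-state rate or concentrations.
  The default ($10^4$ fatty acids at division) corresponds to a small
  vesicle's worth of membrane molecules, so that binomial partitioning acts
  on molecular populations rather than a handful of molecules.
* **`vol_per_fa`** $= 0.1$. The count-to-concentration scale decides how
  strongly the nucleotide feedbacks engage. It is set so that nucleotide
  synthesis runs substrate-limited: at the null steady state about 97% of
  the energy-currency supply is consumed by nucleotide synthesis. In this
  regime the energy currency genuinely limits nucleotide production — which
  is what makes catalysis of the E pathway feed through near-linearly to
  nucleotide concentration, and what gives the costly-sugar variant its
  qualitative flip (below). With a tenfold larger scale the same network
  sits in a weak-consumption regime where every feedback degenerates into a
  sub-percent perturbation and no substrate is ever limiting.

The catalysis cost $\alpha$ discounts fixation catalysis in proportion to
the strength of each *distinct* pathway-catalysis activity:
$K_{CN}^{\mathrm{eff}} = K_{CN}\max(0,\, 1 - \alpha\, C)$ with
$C = K_{FA,N} + \max(K_{AA_1N}, K_{AA_2N}) + K_{SN} + K_{EN}$. The
amino-acid pair driven at a shared strength is one catalytic activity on
amino-acid synthesis and counts once; summing it twice would clip the cost
to zero already at strength 0.5 and make moderate and strong catalysis
indistinguishable. The clip at zero is the one documented clip in the
model; everywhere else out-of-range inputs are rejected, never adjusted.

The default initial state sits on the balanced-growth ray
($\mathrm{AA_1}/\mathrm{FA} = \lambda_{AA_1}/\lambda_{FA}$), purely to
shorten transients; the initial-condition scan demonstrates that steady
state does not depend on it.

## Numerical choices

Integration uses `deSolve::lsodar`, which switches between stiff and
non-stiff methods (strong autocatalysis makes the energy-currency dynamics
stiff) and locates the division threshold by root finding; at the located
event $|\mathrm{FA} - \mathrm{fa_{div}}|/\mathrm{fa_{div}} < 10^{-6}$.
Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; the experiment layer
tightens these to `1e-10`/`1e-12` and demands a steady-state criterion of
`rel_tol = 1e-7`, because several pathway-catalysis effects are fractions of
a percent and must be resolved far above solver noise. Integrators probe
marginally negative states near absorbing boundaries; these are clamped to
zero for rate evaluation, while genuinely negative states raise an error.

Steady state is declared when the last five inter-division intervals have a
relative spread below `rel_tol` (deterministic), or when the running mean of
the last twenty intervals agrees with the previous twenty within two
standard errors (stochastic). The division rate is the reciprocal of the
trailing-interval mean; equilibrium concentrations are trapezoid-weighted
time averages over the final cycle, re-integrated densely at 401 points.
Collapsed cells — those that never reach the threshold within the time
budget (500 days by default) — report rate zero; a cell with no FeS amino
acids or no substrates is a legal, stalled state, not an error. In
stochastic mode counts are rounded half-to-even before sampling; the
`noise` knob is a variance multiplier interpolating between exact halving
(0) and full binomial variance (1), and at 0 the deterministic rule is used
verbatim so the no-noise limit is exact.

## What the experiments emulate

Each experiment regenerates its own inputs; there is no external data.

* `sweep_kcn()`: division rate along a fixation-catalysis grid — a pure
  positive feedback, monotone by construction of the flux law.
* `sweep_pathway()`: pathway catalysis under the slow ($10^{0.9}$) and fast
  ($10^4$) fixation-catalysis presets, with the catalysis-free reference.
  The slow/fast values follow the conventional log-scale presentation of
  the fixation-catalysis axis.
* `heatmap_autocatalysis()`: autocatalysis x fixation catalysis grids
  (13 log-spaced points per axis by default, $10^{-2}..10^4$ and
  $10^0..10^4$).
* `initial_condition_scan()`, `stochastic_segregation()`,
  `sugar_cost_variant()`, `co2_scan()`: steady-state invariance to initial
  conditions, robustness to partitioning noise, the sugar-stoichiometry
  variant (8 C2 per sugar moves the limiting substrate from energy to
  sugars, since $\lambda_S/8 < \lambda_E$), and growth versus CO2
  availability.

The acceptance checks assert relative orderings against in-run baselines,
never absolute divisions-per-day: the absolute scale depends on the
calibration constants above and is implementation-defined.

## A structural property worth knowing

In this formulation, catalysis of amino-acid synthesis cannot collapse
growth, however strong. The argument is short: the converged division cycle
is a doubling of every count, so the division rate equals
$\mu / \log 2$, where $\mu$ is the balanced growth rate; because fixation is
driven by the AA1 count, $\mu = f_{AA_1} k_\mathrm{fix}
(1 + K_{CN}^{\mathrm{eff}}[N^*])$, and the AA1 allocation fraction
$f_{AA_1}$ is monotone *increasing* in the amino-acid weight boost. Strong
amino-acid catalysis therefore speeds division slightly rather than
starving the membrane: diverting flux away from fatty acids changes the
cell's composition (its steady-state ray), not its doubling time, as long
as the fatty-acid fraction stays positive — which the saturating, bounded
weights guarantee. A genuine membrane-starvation collapse would require
unbounded flux diversion or a fixation law that saturates in AA1; both are
outside this model's forms. The acceptance suite states the collapse
expectation for strong amino-acid catalysis anyway, and that single check
fails by design of the model — the suite documents the divergence instead
of hiding it. Growth does collapse in this model for other reasons: zero
CO2, no FeS amino acids, or a competitive catalysis cost that wipes out
fixation catalysis.

## Problem sizes and runtime

The shipped checks use desk-scale sizes chosen as the package's own
defaults: 1000 random states for the conservation properties, 6-point
fixation-catalysis grids, 4-point pathway grids under two presets, a 5x5
heat map, a 2x2 initial-condition design, and 20 stochastic seeds. A full
lineage converges in 20–60 cycles and fractions of a second; the complete
acceptance layer runs in well under ten minutes on one CPU.

## Limitations

* No spatial structure, membrane biophysics, osmotic pressure, explicit
  Fe/S pools, or CO2/H2 depletion; the division rule uses the fatty-acid
  count alone.
* Nucleotide synthesis stoichiometry is fixed at 1:1:1 (AA2:S:E) per
  nucleotide; only the carbon stoichiometry of the branches is tunable.
* The stochastic-robustness property presumes molecular-population counts.
  At very small cells (tens of nucleotide molecules), partitioning noise
  couples to the nonlinear fixation feedback and the measured mean rate
  drifts off the deterministic value — a real small-number effect, not an
  estimator bug.
* The synthetic experiments probe the network's topology, not prebiotic
  chemistry: rate constants are relative, so passing checks support
  qualitative claims about feedback architecture, never quantitative rates
  for any real protocell system.
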