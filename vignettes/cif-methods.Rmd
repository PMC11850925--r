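---
title: "Models and methods behind cifsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cifsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifsim)
```

cifsim models microfluidic leukapheresis by controlled incremental
filtration (CIF): a central retentate channel flanked by two filtrate
channels, connected by hundreds of ~20 µm gaps, each of which bleeds off a
tiny fraction (~10⁻³) of the retentate flow. The width $w_l$ of the
wall-adjacent fluid lamina extracted at each gap sets a cell-size cutoff:
cells small enough to ride inside the lamina leave with the fluid, larger
cells stay in the central channel and are progressively concentrated. This
vignette records the models, the defaults and the reasoning behind the
choices that the interface does not make obvious.

## Element design

At gap $i$ a per-side fraction $f_{gap}(i)$ of the retentate flow
$Q_r(i)$ leaves through each of the two symmetric gap arrays, so

$$Q_{gap}(i) = f_{gap}(i)\,Q_r(i), \qquad
  Q_r(i+1) = Q_r(i)\,(1 - 2 f_{gap}(i)).$$

The link between the flow fraction and the lamina width is the cumulative
flux fraction of the velocity profile across the channel width. The default
is the depth-averaged plane-Poiseuille profile, for which a lamina of
normalised width $x = w_l/w_r$ carries the flow fraction
$F(x) = 3x^2 - 2x^3$. With a 150 µm channel depth comparable to the lamina
and width scales, a depth-averaged two-dimensional treatment is the natural
resolution; a plug profile is available as a degenerate reference through
the `profile` argument. `lamina_width_from_fraction()` inverts $F$ by
bisection; the forward map is closed-form, so round trips are exact to
solver tolerance (tested at $10^{-8}$).

`design_element()` fixes $w_l$ from the initial pair
$(f_{gap}^{*}, w_r^{*})$ and then recomputes $f_{gap}(i)$ gap by gap so the
realised lamina width never drifts (the design-loop invariant is a relative
deviation below $10^{-6}$; in practice it is at rounding error because each
$f_{gap}(i)$ is obtained from the exact inverse).

Two width rules are provided:

* **constant-velocity** (default): $w_r(i) \propto Q_r(i)$, keeping the mean
  retentate velocity constant as flow is lost. Widths cannot shrink
  indefinitely — posts must stay separable — so a floor (`min_width`,
  default twice the gap width) stops the contraction. From the floor
  onwards the width is held fixed and $f_{gap}$ becomes constant
  (`on_floor = "clamp"`); with `on_floor = "error"` the design is instead
  declared infeasible, naming the failing gap. A floor-then-fixed-width
  phase is unavoidable for realistic flow ratios: reaching FR = 20 with a
  purely proportional rule would contract the channel 21-fold, far below
  anything manufacturable.
* **fixed-width**: $w_r$ stays at $w_r^{*}$, which makes the whole schedule
  constant-$f$ — the classical reference geometry with the closed-form
  retentate fraction $(1 - 2f)^{N}$.

Filtrate widths grow with the per-side cumulative filtrate flow under the
same constant-velocity logic, floored at the gap width.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `f_gap_star` | `1e-3` | the reference element family spans 0.72–1.70 × 10⁻³ |
| `w_r_star` | 230 µm | puts the size cutoff $2 w_l \approx 8.5$ µm of the `1e-3` element between lymphocyte (7.5 µm) and monocyte (9.5 µm) diameters, which is what a leukapheresis element must do. At 100 µm the cutoff would sit below the RBC diameter and every cell type would be retained — no size selectivity at all. |
| `gap_width` | 20 µm | nominal gap opening; also the filtrate-width floor |
| `depth` | 150 µm | carried as metadata; the lamina model is depth-averaged |
| `target_fr` | 20 | caps small-cell loss at $1/(1+FR) \approx 4.8\%$ and concentration at 21-fold |
| `q_in` | 150 µL/min | 1.2 mL/min shared by eight parallel elements |
| `min_width` | `2 * gap_width` | post separability |

The initial retentate width and the gap count of the physical elements are
not public; the values here are this package's own operating points, chosen
once from the size-cutoff argument above, and everything downstream treats
them as configuration, not truth.

## Single-pass separation

A cell of radius $r$ can only be captured if its centre fits inside the
lamina, i.e. $r < w_l$. Between the point-particle limit
($p = f_{gap}$) and steric exclusion ($p = 0$) three models interpolate:

* **flux** (default): $p = f_{gap}\,F\!\big((w_l - r)/w_r\big) / F(w_l/w_r)$ —
  the fraction of the lamina flux accessible to the cell centre. Smooth,
  and exactly the quadratic small-$x$ limit $p \approx f_{gap}(1 - r/w_l)^2$
  for thin laminae.
* **hard**: $p = f_{gap}$ for $r < w_l$, else 0.
* **power**: $p = f_{gap}\,((w_l - r)/w_l)^q$.

Retention over the element under the well-mixed assumption (radial position
resampled from the flux-weighted distribution between gaps) is
$\prod_i (1 - 2 p_i(d))$, and a type's collection efficiency (CE) is that
product integrated over the type's log-normal diameter distribution on a
201-point midpoint-quantile grid. Volumes split by the realised flow ratio
and concentrations follow from exact conservation, which gives the identity
$CR = (CE/100)(1 + FR)$ tested to $10^{-9}$.

The Monte-Carlo path draws individual cells and walks them gap by gap with
independent capture draws; it is the stochastic oracle for the closed-form
product (agreement within 3 binomial standard errors at $10^5$ cells is an
acceptance property). An optional `remix = FALSE` mode gives each cell a
persistent flux coordinate renormalised after every extraction, retaining
wall depletion — useful for exploring how far the well-mixed assumption
matters, not a calibrated physical model.

**Which steric model to use.** The flux model is the default because it is
the smoothest minimal interpolation. It does, however, over-capture
intermediate cells: an RBC with $r \approx 0.6\,w_l$ still sees ~12% of the
point-particle capture per gap, which compounds over an FR-20 element to a
~60–70% RBC collection efficiency — an order of magnitude above the
observed fluid-share loss (~5%). The hard cutoff, smoothed only by the
diameter spread of each population, reproduces the observed whole-blood
pattern much better (RBC and platelets at the fluid share, eosinophils and
monocytes at 75–95%, lymphocytes lowest among leukocytes), and is what the
acceptance script and the CLI `recirculate` command use for whole-blood
predictions. Cell deformability is the likely physical reason the hard
model works better: a red cell that partially overlaps the lamina is not
carried out proportionally to overlap — it squeezes back into the faster
core flow. Margination, cell–cell interactions and hematocrit-dependent
rheology are not modelled at all, so neither model should be read as a
quantitative prediction of experimental CE; the package asserts orderings
and conservation laws, not percentages.

## Hydraulics

Multiplexed arrays and pumpless arteriovenous operation reduce to linear
lumped networks: rectangular-duct resistances from the classical odd-term
series (five terms, converging as $n^{-5}$), Kirchhoff balance solved as a
linear system in the unknown node pressures, fixed-flow edges (the
retentate withdrawal pump) entering as source terms. Blood is treated as a
constant-viscosity Newtonian fluid at 4 mPa·s — shear thinning is out of
scope for a lumped model. Pressures are in mmHg at physiologic boundaries
and resistances in mmHg/(µL/min); `rect_channel_resistance()` converts
from SI internally. The in-vivo template (`invivo_circuit()`) encodes the
arterial source, device, return line and fixed-flow withdrawal branch; the
sham arm's resistance bridge is a single equivalent resistance matched to
its target flow, since its internal geometry is not public.

Capture is modelled as flow-rate independent (creeping flow), so
parallelization changes throughput and dead volume but not CE/CR —
deterministically exact in the model, and to sampling error in Monte-Carlo
(both are acceptance properties). Dead volumes add: 87 µL per device, with
the eight-device interconnect tubing taking the combined device+tubing
total to 4.2 mL.

## Recirculation

The in-vivo procedure is a single well-mixed compartment of volume $V(t)$
drained through the circuit at flow $Q$ (the measured filtrate return):

$$\frac{dC_k}{dt} = -\frac{Q\,(CE_k/100)}{V}\,C_k + \frac{I_k}{V},$$

with per-type influx $I_k$ (default 0; a zero-order term is the minimal
structure able to represent stress demargination in sham animals).
Discrete events perturb the state: CBC draws remove whole blood
(cells and volume; by default the volume is considered replaced, so draws
dilute counts — the mechanism behind the sham arm's RBC decline), and
fluid boluses add volume without cells. The continuously withdrawn
retentate volume ($5\%$ of $Q$ by default, FR ≈ 20) is replaced 1:1 by
saline by default, which is what "fluid removed and given" implies; both
replacement policies are configurable. The circuit's extracorporeal volume
is subtracted from the compartment at connection. Integration uses
`deSolve::lsoda` with events at every draw and bolus, relative tolerance
$10^{-8}$; with constant coefficients the solution matches
$C_0 e^{-(CE/100)\,V_{proc}/\mathrm{eTBV}}$ to $10^{-6}$ relative
(an acceptance property). A run aborts with a diagnostic if $V(t)$ ever
reaches zero. Randomness enters only through optional log-normal CBC
measurement noise, which requires a seed.

Kinetics are referenced to the filtrate-return flow as the circuit flow.
One visible consequence: at $CE = 100\%$ and a withdrawal fraction of 0.05
the retentate-to-blood concentration ratio evaluates to
$1/0.05 = 20$ rather than $1 + FR = 21$; the ~5% difference is exactly the
retentate share of the processed flow, and the epoch-level estimators
inherit it.

Two estimator subtleties are worth knowing:

* **CR denominator.** The per-epoch concentration ratio divides the
  retentate aliquot concentration by the mean *filtrate* concentration
  (`denominator = "filtrate"`, the default) or by the contemporaneous
  *circulating* concentration (`"blood"`). The filtrate denominator is
  undefined when a type is captured completely (its filtrate concentration
  is zero); the blood denominator is the robust choice for near-complete
  capture.
* **Aliquot CE bias.** The serial-aliquot collection-efficiency estimator
  divides collected cells by $\tfrac{1}{2}(C_{pre}+C_{post}) V_{proc}$.
  Under exponential depletion the arithmetic mean overstates the true
  time-average of $C(t)$, so the estimator under-recovers the injected CE
  by the factor $\tanh(x/2)/(x/2)$ with
  $x = (CE/100) \cdot \mathrm{eTBV\ processed}$ — about 3% low at
  $x = 0.6$, 22% low at $x = 1.9$. The estimator is implemented exactly as
  written, without debiasing; parameter-recovery tests therefore use
  moderate efficiencies ($x \lesssim 0.8$), where recovery is within 5%.

## Synthetic fixtures

`make_blood()` produces CBC-style panels for humans and rats with
log-normal concentration noise (CV 10% by default) and log-normal diameter
distributions. The concentration means (human: RBC 5×10⁶, PLT 2.5×10⁵,
WBC 7×10³ per µL with a 60/30/7/3 PMN/LYM/MON/EOS differential; rat:
lymphocyte-rich differential, higher RBC and PLT) and the effective
diameters (human RBC 5.5, PLT 2.5, LYM 7.5, PMN 8.5, MON 9.5, EOS 9.0,
blasts 10.5 µm; rat sizes shifted so EOS and PMN are the two largest
subtypes) are literature-informed fixture defaults, not measurements from
any specific dataset. A hyperleukocytosis preset raises the WBC count above
the 100,000/µL clinical threshold, and a blast spike models a leukemic
cell-line addition. Validation bounds are deliberately generous — they
catch unit mistakes, not unusual biology.

The rat protocol template draws 0.3 mL of whole blood every 15 minutes for
3 hours from a 0.375 kg subject (eTBV 26.25 mL, circuit ECV 736 µL). That
sampling burden alone dilutes RBC by ~13% over the procedure — the size of
decline observed in sham-operated animals — which is why the template uses
it; it was chosen from the volume arithmetic, not fitted.

What passing tests do **not** show about real blood: the fixtures have no
margination or cell-deformability physics, no hematocrit-dependent
viscosity, no platelet activation, and diameter spreads are idealised
log-normals. Conservation laws, monotonicity in size, flow-ratio limits and
estimator behaviour transfer to real data; absolute CE percentages do not.

## Numerical choices and problem sizes

Bisection and round-trips at $10^{-8}$; design-loop lamina constancy at
$10^{-6}$ (achieved at rounding error); flow conservation checked at
$10^{-10}$; ODE tolerance $10^{-8}$ with the ledger checked at $10^{-6}$;
deterministic CE on 201 quantiles; Monte-Carlo oracle comparisons at
$10^5$ cells (3-SE bands); all random draws behind explicit seeds via
`withr::with_seed()`. The test suite exercises full-scale elements (the
1521-gap constant-$f$ reference and the ~266-gap default element) and
complete 180-minute recirculation runs; these sizes run in seconds, so
nothing is scaled down below the scientifically meaningful size.

## Known limitations

* The steric capture models bracket, but do not resolve, deformability —
  absolute CE values are model-dependent (see above).
* The recirculation compartment has no marginated or splenic pool;
  demargination is a constant influx, not a feedback.
* The hydraulic model is steady and rigid: no pulsatility, compliance or
  progressive occlusion.
* The sham bridge and the multiplex tubing split are modelled from their
  totals, not from internal geometry.
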