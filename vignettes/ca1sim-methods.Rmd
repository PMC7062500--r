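---
title: "Methods: a reduced CA1 model for exchanger and K[Ca] manipulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced CA1 model for exchanger and K[Ca] manipulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1sim)
```

## What the package models

`ca1sim` simulates a CA1 pyramidal neuron as a branched electrical cable
with voltage- and calcium-gated membrane mechanisms, and uses that model to
ask how two calcium-handling mechanisms — the electrogenic Na+/Ca2+
exchanger (NCX) and the Ca2+-activated K+ conductance (K[Ca]) — shape
three phenomena: orthodromic firing under gamma-frequency synaptic drive,
backpropagating action potentials (bAPs), and the pairing of bAPs with
EPSPs that induces spike-timing-dependent plasticity (STDP).

The membrane potential of each compartment obeys the cable equation

$$C_m \frac{\partial V}{\partial t} =
  -\sum_k g_k(V, \mathrm{Ca}) (V - E_k) - I_\mathrm{NCX}(V, \mathrm{Ca})
  + I_\mathrm{axial} + I_\mathrm{stim},$$

with a submembrane calcium pool per compartment driven by the calcium
currents and cleared by a first-order pump plus the exchanger itself.

## The exchanger: electrochemical times allosteric

The exchanger current is the product of two factors,

$$I_\mathrm{NCX} = \mathrm{Allo} \cdot \Delta E, \qquad
  \mathrm{Allo} = \frac{1}{1 + (K_{m,\mathrm{Ca(act)}}/[\mathrm{Ca}]_i)^{n}},$$

$$\Delta E = V_\mathrm{max}\,
  \frac{[\mathrm{Na}]_i^3 [\mathrm{Ca}]_o e^{\gamma V F / RT}
        - [\mathrm{Na}]_o^3 [\mathrm{Ca}]_i e^{(\gamma - 1) V F / RT}}
       {(k_{m,\mathrm{Na}}^3 + [\mathrm{Na}]_o^3)(k_{m,\mathrm{Ca}} + [\mathrm{Ca}]_o)
        (1 + k_\mathrm{sat} e^{(\gamma-1) V F / RT})}.$$

The cycle moves 3 Na+ per 1 Ca2+, so the net current reverses at
$V_\mathrm{rev} = (RT/F)\ln([\mathrm{Na}]_o^3 [\mathrm{Ca}]_i /
([\mathrm{Na}]_i^3 [\mathrm{Ca}]_o))$ — about $-71$ mV at the default ion
concentrations (Ca$_i$ 50 nM, Na$_i$ 10 mM, Ca$_o$ 2 mM, Na$_o$ 140 mM,
307.15 K). Below $V_\mathrm{rev}$ the exchanger runs forward (Ca2+
extrusion, net inward current); above it, in reverse (Ca2+ entry, net
outward current). Component currents are $i_{Na} = 3\phi$ and
$i_{Ca} = -2\phi$ for net current $\phi$, so their ratio is exactly
$-3/2$ at every instant — a property the test suite checks on recorded
traces. Density manipulations scale $V_\mathrm{max}$; allosteric
manipulations scale the output of Allo (clamped at 1). A
$K_{m,\mathrm{Ca(act)}}$ shift would be an alternative reading of an
"allosteric" manipulation; output scaling was chosen because the gradient
experiments depict a spatial scale factor, and both routes remain available
through the parameter record.

## K[Ca] and the calcium pool

The K[Ca] conductance is $\bar g\, m^2 (V - E_K)$ with Hill-type calcium
activation: $m_\infty = \alpha \mathrm{Ca}^n / (\alpha \mathrm{Ca}^n +
\beta)$ and $\tau_m = 1/(\alpha \mathrm{Ca}^n + \beta)$ with $n = 2$, so
$m_\infty / \tau_m = \alpha\,\mathrm{Ca}^n$ identically — a second exact
algebraic invariant under test. A floor of 0.1 ms on $\tau_m$ avoids
stiffness at high calcium. The rate coefficients keep the cited functional
form but use an SK-like affinity (half-activation near 250 nM,
$\alpha = 4.8\times 10^5\ \mathrm{ms}^{-1}\mathrm{mM}^{-2}$,
$\beta = 0.03\ \mathrm{ms}^{-1}$): the thalamic parameterization the form
comes from half-activates near 25 µM, far above the submembrane transients
this model produces (~0.3–1 µM), and would leave the conductance
permanently shut. Voltage dependence of the rates is structurally
supported; with only calcium dependence configured the voltage factor is 1.

The calcium pool is a single submembrane shell per compartment:

$$\frac{d[\mathrm{Ca}]_i}{dt} = -\frac{i_\mathrm{Ca}}{2 F d}
  - \frac{[\mathrm{Ca}]_i - \mathrm{Ca}_\mathrm{rest}}{\tau_\mathrm{decay}},$$

with shell depth $d = 0.1$ µm and pump time constant 80 ms, floored at
1 nM. Sodium is held at 10 mM: the exchanger's Na+ flux is reported but
not fed back into a sodium pool, matching common practice and avoiding an
unconstrained accumulation model.

## Channel complement and its calibration

The paper-scale model carries fourteen mechanisms whose densities are not
published; this package uses a reduced, configurable complement — transient
Na (m³h; soma/dendrite and axon densities), delayed-rectifier K (n⁴),
A-type K (a·b, density increasing linearly with path distance), one L-type
Ca channel (m², fixed +120 mV reversal so channel stiffness is decoupled
from pool dynamics), leak, the calcium pool, NCX, and K[Ca]. R/T/N-type
Ca, persistent Na, and KM are expressible with `hh_channel_spec()` but off
by default. Kinetics are classic HH-style rate functions resting near
−65 mV, used as effective rates at model temperature.

All constants live in `inst/extdata/config/mechanisms.yaml`. The free
densities were calibrated once against four qualitative anchors and then
frozen:

* resting potential near −74 mV, stable over seconds;
* gamma drive (10 synapses, 40 Hz, Poisson) fires at 14–17 spikes/s
  across seeds with the 0.006 µS synaptic weight;
* a 2 nA × 2 ms somatic pulse elicits exactly one spike that actively
  invades the apical tree (trunk peaks from ~42 to ~24 mV);
* the distal-trunk EPSP (0.0008 µS, double-exponential 0.5/5 ms) is
  ~4 mV locally.

The exchanger scale $V_\mathrm{max} = 0.1$ mA/cm² deserves a note. At this
density the exchanger's dominant effect on the synapse-site calcium
transient is forward-mode clearance, so removing it *raises* the
potentiation readout. At several-fold higher densities the reverse-mode
calcium entry during the bAP overtakes clearance and the direction flips.
The model therefore takes the forward-dominated regime as its operating
point; the knockout-raises-potentiation result should be read as
calibration-contingent, which is also how the experiment tables flag it.

## Discretization and integration

Sections are split into an odd number of compartments by the d_lambda rule
(fraction 0.1 of the 100 Hz AC length constant); compartment areas are
frustum sums over the 3D geometry, and axial conductances come from the
closed-form integral of $R_a / (\pi r^2)$ over half-compartments with
linear taper. The voltage step is Crank–Nicolson with the tree system
solved exactly in $O(n)$ by a Hines elimination (parent-before-child
ordering); gating states relax exponentially at the midpoint voltage
(staggered update), and the pool uses an implicit-decay update. Observed
temporal order on the passive step response is ≥ 1.8 (measured 2.0);
spatial refinement from d_lambda 0.1 to 0.02 moves somatic input
resistance by < 1%. Default dt is 0.025 ms. The nonlinear exchanger
current is treated as a constant source within each step; its conductance
is orders of magnitude below the channel conductances, so this does not
affect the observed convergence order. Synaptic events snap to the step
containing them (error ≤ dt/2). Divergence (any non-finite state) aborts
with the compartment and time.

## Morphology and regions

SWC trees are split into sections at branch points and structure-type
changes; a multi-point soma collapses to one equivalent cylinder (arc
length and membrane area preserved). The apical partition is: the trunk
follows, from the apical root, the child with the greatest distal subtree
length, and ends at the first node where the two largest child subtrees
each exceed 30% of the remaining apical length (the terminal bifurcation);
distal sections are tuft, shed side branches are oblique. The 30% rule is
a package choice — the source analysis names the partition but not a rule —
and it is deterministic and validated against generator ground truth.

## The synthetic morphology

`generate_reduced_ca1()` emulates the regional structure the analysis
needs at desk scale (~100 compartments): a 20×20 µm soma, a 400 µm trunk
tapering 2.5→1 µm, three 150 µm obliques attached near 120/200/280 µm
(jittered per seed), a terminal bifurcation into two stems and four
terminal tuft branches of 150 µm, two 200 µm basal dendrites, and a 300 µm
axon. It reproduces what matters for these experiments — a trunk with
≥ 300 µm of synapse-eligible cable, oblique side branches, a distal tuft —
and *not* the statistics of real reconstructions (branch-order and
diameter distributions, spines, 3D tortuosity). Tests passing on it
validate the machinery and the qualitative mechanism effects, not
quantitative agreement with any particular real cell.

Simulated "cells" are seeds: one seed fixes the jittered morphology and
the synapse placement/event draws, which is how the seven-cell raster and
the 10-cell condition tables are produced.

## Experiments and readouts

* **E1** — seven seeds of 1 s gamma drive; raster, per-cell mean firing
  rate, and the SPIKE-synchronization matrix (adaptive coincidence window:
  half the minimum of the four neighbouring inter-spike intervals; a train
  with fewer than two spikes contributes no window and the partner's
  rules).
* **E2** — spike half-width (the above-threshold duration $t_2 - t_1$ at
  the 10 mV detection threshold, *not* width at half-maximum) and peak
  amplitude across exchanger localizations, 10 seeds per condition, with
  Mann–Whitney U and Tukey HSD tables exactly as the source analysis used
  them (no extra multiplicity layer).
* **E3** — single-bAP peak-voltage and depolarization-time maps over all
  apical compartments for localization and linear-gradient models.
  Depolarization time is stimulus onset to the absolute voltage peak (a
  threshold-crossing alternative is available behind a flag). Gradients
  run from 0.5 at the proximal anchor to 1.5 at the distal tip so the mean
  factor is ~1 and spatial redistribution is separated from dosage; the
  normalization is recorded in the run manifest.
* **E4** — single bAP/EPSP pairings (EPSP at the distal trunk compartment,
  bAP 10 ms later, paired when ≤ 35 ms) across the knockout / localization
  / gradient taxonomy, 10 morphology seeds per condition. The potentiation
  index is deliberately defined (the source never states one): peak
  synaptic calcium in the paired condition over peak calcium in the
  EPSP-alone condition, measured in a 60 ms window after EPSP onset so a
  bAP outside the pairing window cannot enter the index (this gives the
  expected index → 1 separation limit at Δt = 500 ms). A voltage-coupled
  alternative (paired peak over the linear sum of the alone peaks) is
  computed side by side, and the K[Ca] manipulations are read out on it;
  both appear in the tables because the original figure units are
  unspecified.

Each pairing condition runs EPSP-alone, bAP-alone, and paired from a fresh
solver state with an identical 50 ms settling period, so conditions are
state-isolated by construction.

## Numerical and degenerate-input choices

* Ion concentrations are clamped except submembrane calcium; calcium is
  floored at 1 nM.
* `hines_solve` raises on a singular diagonal; the assembled
  Crank–Nicolson matrix is strictly diagonally dominant for dt > 0.
* Region classification requires at least one apical section; an apical
  root that runs to a tip without a qualifying bifurcation yields an empty
  tuft (ball-and-stick is all primary).
* Gradient manipulations reject a degenerate distance span; localization
  to an empty region set is the knockout.
* Group comparisons with all-identical samples report p = 1 rather than
  erroring; groups need n ≥ 3.

## Known limitations

* The channel complement is reduced and its densities are this package's
  calibration; absolute half-widths, peak voltages, and potentiation
  magnitudes are not comparable to the source figures, only the
  directions and null results are.
* One submembrane shell per compartment — no radial diffusion, buffers,
  stores, or spines.
* Effect sizes of the exchanger/K[Ca] manipulations on the potentiation
  indices are small (fractions of a percent to a few percent) and
  direction-stable across seeds; they should be read as mechanistic
  demonstrations, not effect-size predictions.
* The ISI string-similarity percentages and the per-pulse outward-current
  reduction percentages reported alongside the original experiments
  depend on unpublished densities and are out of scope.
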