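---
title: "A multi-scale model of hepatic calcium signaling and glycogenolysis under autonomic control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of hepatic calcium signaling and glycogenolysis under autonomic control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

`hepacal` simulates how a liver lobule mobilizes its glycogen stores when
the body demands glucose, for example during intense exercise, and how
that mobilization is coordinated by the autonomic nervous system. The
model couples three scales:

* **Hepatocytes.** Each of the `N = 15` hepatic layers along the
  porto-central axis contains a hepatocyte described by an
  IP3-calcium cross-coupling oscillator (four states: the free
  alpha-1 adrenergic receptor fraction `r`, cytosolic IP3, cytosolic
  calcium `CaI`, and the free IP3-receptor fraction `g` on the ER) plus a
  glycogen store and an intracellular free-glucose pool. Calcium
  potentiates glycogen breakdown through glycogen phosphorylase kinase.
  Adjacent cells exchange IP3 through gap junctions with a uniform
  mass-transfer coefficient `G_ij`; calcium itself does not cross
  junctions, and chain ends are no-flux.
* **Sinusoidal blood.** Five species (glucose, insulin, glucagon,
  epinephrine, norepinephrine) advect from the periportal compartment
  (index 1) to the pericentral compartment (index `N`) at
  `bf = 0.15 N` per second and drain into a body compartment whose
  volume is `s = 5 N` hepatic compartments. Hormones and catecholamines
  are cleared only in the liver, by first-order kinetics per
  compartment; this clearance creates the porto-central catecholamine
  gradient that biases where calcium waves start.
* **Body organs.** The CNS senses systemic glucose `GB` and activates
  below `G_symp = 4500` uM with saturation constant 500 uM. CNS drive
  stimulates adrenal catecholamine synthesis (factors 6 and 14 on
  epinephrine and norepinephrine) and, in innervated hepatic layers,
  adds a synaptic norepinephrine stimulus `K_NEpn_stim * CNSAct` with
  `K_NEpn_stim = 2` nM. The pancreas secretes glucagon below and insulin
  above a glucose reference (`G_ref = 2` a.u., one a.u. = 2500 uM), each
  as a Hill function of the log-deviation. Peripheral tissues consume
  glucose at a basal rate that is multiplied by 3.5 during the exercise
  window (1 h starting at `t = 500` s).

Innervation patterns encode species differences: all 15 layers
(human-like), the first four periportal layers (rodent-like), or none
(denervated). An alternative model variant decouples the adrenal gland
from CNS feedback and instead gives the CNS an additive effect on
glucagon secretion, with steeper 1-to-2 zonation gradients and coupling
levels `G_ij` of 1 and 2.

## Zonation

Two kinds of zonation oppose each other. The cell-intrinsic calcium
parameters `k_r` (receptor recycling, 0.5 to 1.0 /s) and `k_IP3`
(saturating IP3 synthesis, 0.5 to 0.6 /s) increase linearly from the
periportal to the pericentral end, making pericentral cells the more
excitable. The glycogenolytic capacity, in contrast, is
periportal-favored: a linear weight from 1.0 (PP) to 0.5 (PC) multiplies
the breakdown flux, standing in for the oxygen-dependent enzyme
gradients of the full hepatic metabolic network, which is outside this
package's scope. Circulating catecholamines add a third, dynamic
gradient: hepatic clearance makes the stimulus strongest periportally.
Which gradient wins determines the wave direction (below).

## The glycogen-to-glucose backbone

The full hepatic carbon network is deliberately collapsed to a
glycogen -> free glucose -> sinusoid chain. Breakdown flux per cell is

```
w_i * v_brk * KPhosmax * Glyc^4/(Glyc^4 + Km^4) * Phos/(Km_Phos + Phos)
    * (1 + v_CaI_max * vGPK(CaI))
```

with `KPhosmax = (Glu + 45 pM)/(Ins + 26.66 pM)` read from the local
sinusoidal hormones (stored in nM, converted at this interface), the
phosphate factor held at one half (`Phos = Km_Phos = 4000` uM; phosphate
dynamics belong to the out-of-scope network), and `vGPK` the thresholded
GPK activity: basal `v0 = 0.05` below a calcium amplitude of 0.44 uM and
`CaI/(Km_CaI + CaI)` above it. Two Michaelis constants coexist in the
source material for this term, 3 uM (printed inside the activity
equation) and 0.6 uM (stated as the Michaelis constant of the
calcium-induced increase). The package defaults to 0.6 uM
(`use_Km_CaI = TRUE`): at realistic spike amplitudes of 0.5-1.1 uM the
3 uM constant caps the calcium contribution to glycogenolysis at a few
percent, which cannot support a double-digit calcium share of glucose
output, whereas 0.6 uM places it near ten percent. The printed constant
remains selectable.

Free intracellular glucose exchanges with the local sinusoid at
`k_export = 0.1` /s, fast relative to `bf` so transport, not export,
limits delivery. Glycogen starts at 300 mM glucosyl units everywhere,
large enough not to deplete within the protocol; there is no
glycogenesis term, so stores decrease monotonically (this is an
exercise-state model).

## Unit bridges and clearance constants

Several constants required by a closed multi-organ loop are not fixed by
the printed rate laws; they are the package's calibrated design choices:

* **Body-side dilution.** All body-compartment source terms (pancreatic
  and adrenal secretion) are expressed in sinusoidal concentration units
  and diluted by `s` in the body balance, mirroring the dilution of the
  return-flow term.
* **Catecholamine volume bridge** (`catechol_scale = 0.45`). The printed
  adrenal synthesis rates, taken literally against `bf` and `s`, would
  put systemic catecholamines far above the nanomolar range in which the
  receptor binding constant (1 /nM/s) and the 2 nM synaptic stimulus
  operate; every scenario would then saturate identically. The bridge
  places resting sinusoidal stimulus near 1 nM and exercise stimulus in
  the low nanomolar range, where innervation differences matter.
* **Clearances.** Catecholamines clear at 0.15 /s per compartment,
  giving a roughly two-fold porto-central stimulus gradient at normal
  flow. Insulin clears at 0.005 /s; hepatic first-pass extraction of
  insulin is much larger than that of glucagon, whose clearance is set
  to zero so that the resting glucagon level (0.8 nM) is a stable
  baseline and the exercise response is a slow accumulation sized by the
  hypoglycemic deviation.
* **Basal uptake.** The basal body consumption balances the resting
  hepatic glucose export, which is measured by a short burn-in
  simulation (the static estimate misses the calcium activity that
  resting catecholamines already elicit in the most excitable cells) and
  scaled by `u_basal_factor = 0.5875`. This factor, together with the
  constants above, was calibrated once so that the paired
  exercise/no-exercise comparison at `t = 4000` s shows the intended
  roughly two-fold rises in systemic catecholamines and glucagon; it is
  not a per-scenario dial.

With these choices the exercise run dips into hypoglycemia as demand
jumps, is braked by insulin washout, glucagon accumulation and the
calcium arm, and recovers through the CNS activation band so that the
4000 s readout sits near `CNSAct ~ 0.1`.

## Calcium waves and their analysis

A calcium wave is an ordered front of spike maxima crossing the chain.
`detect_spikes()` finds local maxima above 0.44 uM (the glycogenolysis
threshold, so detected spikes are the metabolically relevant ones) with
a prominence of at least 0.1 uM and a 20 s refractory interval.
`wave_metrics()` then traces fronts cell by cell: the pericentral cell's
spikes define reference waves and median period `P`; each cell
contributes its spike nearest to its neighbor's matched spike, within
`P/2` per step. This chain-tracing replaces naive matching of the k-th
spike of every cell, which mis-pairs trains as soon as a slower cell
skips a beat, and keeps fronts wider than half a period correctly
oriented. The signed lag between the extreme cells (positive = wave
travels PC to PP) averages over complete waves; runs are classified as
direction `"none"` when fewer than six complete waves exist, when
whole-chain fronts are sporadic coincidences (completeness below 35% of
reference spikes, the uncoupled signature), when the lag dispersion
exceeds a quarter period, or when the mean lag is below 1 s
(synchronous firing). Velocity is `(N-1)/|lag|` cells per second; a
hepatocyte diameter (conventionally ~25 um) converts it to um/s if
supplied.

Under extensive innervation the uniform synaptic drive lets the
intrinsic pericentral excitability win: waves run PC to PP. With minimal
or no innervation the clearance-generated periportal stimulus advantage
wins: waves run PP to PC. Amplifying adrenal secretion (1.2-fold for the
rodent-like pattern, 1.4-fold for the denervated liver) raises the
whole-lobule stimulus into the regime where the intrinsic gradient again
dominates and restores PC-to-PP propagation. With `G_ij = 0` the cells
drift at their intrinsic frequencies and no coherent front exists. These
contrasts live in a narrow stimulus window (roughly 3-7 nM at the
periportal end); the calibration above places the exercise transient in
that window deliberately.

## What a closed demand loop can and cannot reproduce

Because the body compartment closes the loop, cumulative glucose output
over the protocol is largely demand-determined: with a fixed uptake
schedule, the difference between two scenarios' cumulative outputs
equals the volume-weighted difference of their final systemic glucose
(plus small store differences). Feedback therefore equalizes totals
across scenarios to within about 0.1%. Orderings that rest on large,
robust mechanism differences (normotensive above hypertensive output;
weak coupling beating strong coupling under hypertension with extensive
innervation, and the reverse with minimal innervation; periportal-favored
zonal profiles; strong coupling at least matching weak coupling) hold in
the simulations. Orderings whose underlying capacity differences are of
the same order as the feedback equalization (weak versus uncoupled
junctions; human versus rodent innervation at matched coupling) are not
resolvable in this closed-loop backbone, and the corresponding checks in
the test suite document that honestly rather than being weakened. The
same mass-balance argument caps the measurable two-run calcium
contribution to cumulative glycogenolysis at a few percent: when the
calcium-mobilizing stimulus is disabled, the deeper hypoglycemia recruits
enough extra glucagon to replace most of the missing flux within the
hour. The potentiation-side decomposition along a single run's own
trajectory (`glycogenolysis_fluxes()` evaluated with basal GPK activity)
isolates the calcium share without that confound and is the quantity to
inspect when studying the calcium arm mechanistically.

## Numerical choices

The coupled system (170 states for `N = 15`) is stiff during spikes. It
is integrated with `lsoda` at `rtol = 1e-6`, `atol = 1e-9`, dense output
every 1 s, through a compiled right-hand side; a pure-R reference
implementation of the same derivatives (`engine = "R"`) exists for
verification and agrees to machine precision. The exercise step is a
genuine discontinuity, so integration restarts at the window edges with
the uptake constant switched. The IP3-receptor fraction `g` is clamped
to `[0, 1]` by zeroing its derivative at the bounds; the raw rate law
would drive it negative at low calcium. Halving the tolerances changes
cumulative glucose output by far less than 0.1%. There is no randomness
anywhere in the model; identical configurations produce bit-identical
trajectories.

Problem sizes used in the shipped analyses: 15 layers, 4100 s horizon
(500 s baseline plus a 1 h exercise window), 1 s output resolution. A
full scenario integrates in well under a second of CPU time, so the
whole scenario battery (innervation x coupling x flow x amplification)
runs in seconds.

## Worked example

```{r example}
library(hepacal)

ex  <- run_scenario(preset("human", G_ij = 5))
ctl <- run_scenario(preset("no_exercise", G_ij = 5))

summary(ex)
plot(ex, species = "CaI", cells = c(1, 8, 15))

## wave characterization over the exercise window
wave_metrics(spike_trains(ex, window = c(500, 4100)))

## zonal glucose output
glucose_outputs(ex, c(500, 4100))$per_layer
```

## Limitations

The metabolic backbone is minimal: no gluconeogenesis, glycolysis,
lipid, FFA or ATP pathways, no insulin-receptor cascade, no glycogen
resynthesis, and constant intracellular phosphate. The lobule is a
one-dimensional chain, so each cell has at most two neighbors; island
patterns of partial synchronization can appear at weak coupling but are
not formally detected. Hemodynamic feedback of CNS activation on liver
blood flow is not modeled; portal hypertension enters only as a
proportional flow increase. The pseudo-steady readout at 4000 s sits on
a slowly drifting trajectory, not a fixed point, so snapshot quantities
(hormone folds, CNS activation) are calibration-sensitive in a way that
window-integrated quantities are not. Passing the shipped scenario tests
shows internal consistency of this model under its stated conditions; it
does not by itself validate the model against real livers.
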