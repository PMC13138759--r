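---
title: "Modeling cerebral arteriolar vasomotion and neurovascular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cerebral arteriolar vasomotion and neurovascular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vasodyn)
```

`vasodyn` simulates the vasodynamics of mouse cortical penetrating
arterioles (PAs) embedded in a segmented cerebrovascular network. This
vignette explains the models, the choices behind their parameters, what the
synthetic inputs do and do not emulate, and the numerical decisions a user
or reviewer should know about.

## The cerebrovascular network

The vasculature is a graph of cylindrical segments between one artery
boundary node (ABN) and one vein boundary node (VBN): a pial arterial tree
(169 segments), thirty PAs of twenty-eight 30-um segments each (so each PA
spans 840 um of cortex), and a fixed chain of microvessels per PA — a
precapillary sphincter, three transition-zone orders and three capillary
orders. Pial and PA segments are *arteriolar*: they carry the active wall
models and are electrically coupled wherever two arteriolar segments share
a node. Microvessels are passive fixed conduits; their tuning to a specific
arterial pressure is taken as given here.

PA maximal active diameters taper linearly with depth from 18 um at the
surface to 12.6 um at 840 um, which puts 16.4 um at 250 um depth; that
segment (the ninth of the first PA, `PA01_09`) is the package's reference
segment for single-segment experiments and summary metrics. Wall thickness
is fixed at one tenth of the maximal active diameter. A relative
contractility index declines linearly from 1 at the surface to 0.8 at full
depth; steeper declines make the superficial myogenic rebound dominate the
depth structure of stimulus-evoked responses (see *Limitations*).

**Free geometry.** The pial tree topology and the microvessel diameters are
not constrained by published data, but the intravascular pressure (IP)
distribution they produce is: within the 40-130 mmHg autoregulation range
of arterial boundary pressure (ABNP), IP inside PAs should span roughly
30-65 mmHg, and the 250-um segment should sit at 30-35 mmHg when
ABNP = 40 mmHg. A conventional wide pial tree (40 to 20 um) is far too
conductive to produce any of this: nearly the whole pressure drop would
then occur in the microvessels, and — because the gain of the network-wide
myogenic feedback loop is proportional to the product of the fixed
(downstream) and active (upstream) resistance fractions — the synchronized
network could not sustain oscillations at all. The default geometry
(pial taper 26 to 16 um, 400-um pial segments, capillaries 5.5-6.2 um) was
therefore chosen against the stated IP anchors only: it gives
IP = 32.6 mmHg at 250 um depth at ABNP = 40, IP about 47 mmHg at the PA
midpoint at ABNP = 60, and ~11 nl/min of flow per PA, all physiological.
Everything is configurable through `network_config()`.

## Hemodynamics

At every vasodynamic step the package solves the steady-state Kirchhoff
system with Poiseuille conductances `G = pi D^4 / (128 mu L)` and Dirichlet
pressures at ABN and VBN (sparse Cholesky via Matrix). From the nodal
pressures it derives per-segment flow `Q` (nl/min), intravascular pressure
`IP` (mean of the end-node pressures, mmHg), circumferential wall stress
`WS = IP D / h` (Laplace, mmHg) and wall shear stress
`WSS = 32 mu |Q| / (pi D^3)` (dyn/cm2). Viscosity defaults to a constant
3 mPa s; a smooth diameter-dependent in-vitro law is available behind
`viscosity_model()` but is not used in the headline simulations, since no
published law accompanies the model being reproduced. Flow conservation at
interior nodes holds to 1e-9 relative and the sparse solve is tested
against a dense textbook solver.

`record_max_stresses()` sweeps ABNP from 40 to 130 mmHg while arteriolar
diameters follow a linear autoregulation schedule (maximally dilated at 40,
77% of that at 130) and records each segment's maximum WS and WSS. These
maxima normalise all mechanosensitive transfer functions.

## The macro-scale vasomotion model

Each arteriolar segment carries two diameter components.

* **Myogenic response (MR).** The membrane potential follows the wall
  stress from `MR_D = 5` s earlier:
  `V_init = -45 + MR_F (WS_delayed - WS_avg)` with
  `MR_F = 19e-3` mV/mmHg. Potentials of adjacent segments then equilibrate
  through a resistive-capacitive inner loop
  (`V <- V + (dt2/RC) sum(V_nb - V)`, `dt2 = 0.1` ms, `RC = 1` ms, run for
  one outer step `dt1 = 0.2` s). The myogenic diameter contribution is
  `D_MR = (-45 - V_final)` um: depolarisation above baseline constricts.
* **Passive distension (PD).**
  `D_PD = 0.9 d_max (1 + 0.5 (1 - exp(-0.003 WS)))`, a saturating
  distension of the unpressurised diameter, evaluated at the real-time WS.
  This term is the amplifier: dilation raises WS, which distends further,
  and the delayed MR corrects the deviation a few seconds later.

The committed diameter is `D_PD + D_MR`, rate-limited per step to 15%/s
upward (dilation) and 7.5%/s downward (constriction) by default. `WS_avg`
is frozen from the initial state — the maximal-active-diameter network at
ABNP = 60 mmHg, where `WS_avg = 10 IP` because `h = 0.1 d_max` — and is
never re-baselined. Since the passive equilibrium lies above the initial
diameter, the first steps dilate the network and the delayed feedback takes
it from there; the run is fully deterministic.

Behaviour, as measured by the package's own tests and acceptance script on
600-s runs (3000 steps, 1009 coupled segments): sustained synchronized
triangular oscillations near 0.1 Hz; steady peak-to-trough amplitude
~28% of mean diameter at the reference segment with 15/7.5%/s limits,
~43% with symmetric 15%/s limits, ~29% with symmetric limits and
`MR_D = 3` s; passive distension carries ~17% of the oscillation amplitude
(myogenic ~85%). The realized slope never exceeds the smaller rate limit —
the constriction limit paces both phases, because WS can only recover as
fast as the vessel moves. Restricting the active model to a single PA, or
freezing `D_PD` mid-run, produces monotonically decaying oscillations:
synchronization and passive distension are both required to sustain
vasomotion.

For functional-hyperemia runs a single global gamma-band envelope `GB`
(range-normalised) inhibits the myogenic component
(`D_MR - 10 GB`, lagged 1.9 s) and its one-sided smoothed version `GB_S`
damps it (`x (1 - GB_S)`), standing for fast neurogenic inhibition and the
slowly decaying NO/cGMP pathway respectively. The smoothing time constant
is tied to the 5-s NO decay. An optional astrocytic rule
(`astro_params()`) injects a transient extra inhibition pulse whenever a
segment's smoothed constriction rate crosses a threshold (default 2%/s,
10-s refractory); threshold and refractory are free parameters — no
quantitative values exist for them — and `astro_sensitivity_scan()`
explores their effect.

## The cellular PA segment model

The cellular layer replaces the two-line macro wall with a reduced SMC/EC
pair per segment. It is a deliberate phenomenological reduction — not a
transcription of any published ODE system — whose target is the
input-output behaviour of a PA segment:

* **Mechanotransduction.** Normalised wall stress drives second messengers
  (IP3/DAG) through a quasi-linear sigmoid (steepness 8) and *down*-regulates
  SMC Kir open probability through the mirror sigmoid, both with a
  first-order lag `tau_mct = 5` s (1-20 s physiological; NPY-receptor
  activation lowers it).
* **Membrane.** The SMC potential relaxes (`tau_vm = 0.3` s) toward a
  conductance-weighted balance of a lumped depolarising current
  (TRPM4/TMEM16A, reversal 0 mV), Kir, Kv and BK currents (potassium
  Nernst reversal), the myoendothelial junction (MGJ) to the EC, and
  homocellular gap junctions to neighbouring segments. Kir carries a
  rectification-block factor with its own kinetics (`tau_rect = 0.8` s) and
  a residual unblocked fraction (0.15): the residual keeps Kir relevant at
  resting potentials (50% Kir inhibition visibly constricts the vessel),
  and the block kinetics produce the transient hyperpolarisation overshoot
  when a 60 mM potassium bath is washed out — the abrupt negative shift of
  the reversal potential meets a still-unblocked channel. The EC potential
  follows its WSS-gated Kir current and the MGJ; without flow EC Kir is
  deactivated.
* **Calcium and crossbridges.** Cytosolic calcium relaxes toward a
  sigmoidal function of voltage (VOCC activation) with a fast rise
  (0.6 s, constriction) and slower fall (1.6 s, dilation). A four-state
  crossbridge model (free/phosphorylated x attached/detached) converts
  calcium into tone: the phosphorylation rate is a Hill function of
  calcium (n = 2) and the dephosphorylation rate is raised by NO/cGMP
  (`k2 (1 + 0.6 NO)`), so NO both relaxes the muscle and *desensitises*
  tone to calcium. Tone is the attached-bridge fraction, normalised to 1
  at full activation.
* **Wall.** `D = D_pd(WS) - c ci tone d_max`, with the passive curve
  saturating at 130% of the maximal active diameter and `c` fixed so full
  tone at saturated distension yields the ~42% maximal myogenic tone of
  the reference segment.

**Per-segment calibration.** `calibrate_cellular()` anchors every segment
at the autoregulated baseline (ABNP = 60 mmHg, diameters at maximal
active): the sigmoid midpoints sit at the segment's baseline normalised
stress, the depolarising conductance is solved so the membrane balances at
-40 mV, the VOCC midpoint so calcium balances at 140 nM, and the Hill
midpoint so the crossbridge steady state returns exactly the baseline
diameter. Two global constants — the mechanosensitivity
exponent (`mech_gain = 2.5`) and the calcium fall time (1.6 s) — were then
calibrated once so that a single in-network segment, nudged off balance at simulation onset, shows a
weakly damped oscillation with a 9.4 +/- 0.5 s period, dilation-phase
component lags of roughly 2.3 s (WS to potential), 1.6 s (potential to
calcium) and 1.4 s (calcium to diameter), a shorter constriction phase
(fast calcium rise), and full damping of the oscillation within two to
three minutes when the surrounding network is held fixed.
`calibrate_delay_chain()` measures all of this from a fresh run.

Virtual protocols: `myography_mt()` (pressure myography with tone clamped
to zero for the passive curve; the ex-vivo pressure axis is the in-silico
pressure minus a constant 25 mmHg tissue-load offset), `run_voltage_clamp()`
(steady-state I-V curves, resting membrane potential as the zero crossing,
resting resistance as the reciprocal slope), `run_mediator_challenge()`
(bath application of potassium, glutamate or NO at fixed pressure) and
`simulate_cellular_pa()` (a full 28-segment PA in the network, with
impulse/step neurogenic stimuli whose NO rise propagates upward at
400 um/s above 600 um depth and decays with a 5-s time constant).

## What the synthetic gamma-band generator emulates

`synthetic_gamma()` produces a positive, band-limited (0.01-0.3 Hz)
envelope with occasional step-like transitions, binned at 0.4 s — the
shape of integrated gamma-band power records used to drive neurovascular
coupling experiments. It does not emulate cross-frequency structure,
state transitions tied to behaviour, or any coupling between the envelope
and the simulated vasculature; passing tests with it therefore show that
the NVC pipeline transforms a realistic *class* of drive correctly, not
that it predicts any particular animal's recording. Real recordings can be
supplied as two-column CSVs via `read_gamma_csv()`.

## Numerical choices

* Outer (hemodynamic) step `dt1 = 0.2` s; inner coupling step
  `dt2 = 0.1` ms with `RC = 1` ms (stable while
  `dt2/RC x max degree < 1`; the default network's maximum coupling degree
  is 3). The engine applies the inner loop as a precomputed dense matrix
  power, bit-for-bit equivalent to the explicit iteration when the
  1e-6 mV early-exit never triggers (on the full network it never does;
  `couple_potentials()` retains the explicit loop and the two are tested
  against each other).
* The cellular integrator is fixed-step explicit Euler at `dt = 1e-3` s.
  All cellular time constants are >= 0.2 s, so the stiffness ratio is
  mild; halving or tenthing the step moves the calibrated oscillation
  period by far less than the 0.5-s acceptance band. The step is a
  parameter (`cellular_params(dt = )`).
* Steady-state protocol solvers use damped fixed-point iteration; where
  the quasi-static map is multivalued (strong WS feedback), dynamic
  settling (`settle` in `run_mediator_challenge()`) is used instead so
  challenges start from the attractor the dynamics actually select.
* Metrics: amplitudes are `(max - min)/mean x 100` over a steady window
  (the final 200 s of a 600-s run); peak detection uses local extrema with
  prominence >= 1% of the mean; dilation onsets come from 4-parameter
  logistic fits with the onset at 5% of the maximum fitted slope
  (the threshold is configurable).

Problem sizes used throughout the test-suite and acceptance script — a
1009-segment network for 600-s macro runs, single segments or one
28-segment PA for cellular runs of 35-120 s — are the package's reference
conditions for these models.

## Known limitations

* The pial geometry is a calibrated stand-in. Quantities that depend on
  its unpublished details (absolute amplitudes, exact IP profiles) carry
  a few percentage points of geometric uncertainty; the package's
  acceptance tolerances reflect that.
* In potassium challenges the peak dilation grows monotonically up to
  16 mM; the reduced Kir model does not reproduce a maximum at 8 mM. The
  60 mM depolarisation-constriction and the Kir-dependent washout
  overshoot do reproduce.
* The active myography curve peaks near an in-silico pressure of 40 mmHg,
  slightly above the 30-35 mmHg anchor range.
* In impulse-response runs the model reproduces the delayed superficial
  dilation, the deeper post-stimulus undershoot and the dependence of both
  on gap-junctional coupling, but not the *attenuation* of the dilation
  peak toward the surface; the corresponding acceptance expectation is
  left failing by design rather than weakened.
* Rate limits, delays and time constants are deterministic; in vivo they
  are stochastic and continuously modulated, which broadens the vasomotion
  spectrum in ways this package does not attempt to capture.
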