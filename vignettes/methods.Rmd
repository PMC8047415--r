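---
title: "Models and methods behind atriavuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atriavuln}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atriavuln` is a desk-scale workbench for studying how the choice of an
arrhythmia induction protocol affects the assessment of atrial
fibrillation vulnerability *in silico*. It trades anatomical realism (no
patient geometry, no fiber architecture, no wall thickness) for full
reproducibility: every component — tissue, membrane kinetics, protocols,
phase analysis — is generated and controlled in code. This vignette
documents the models it implements, the parameters that matter, and the
design decisions taken where the problem was genuinely open.

## Tissue model

Tissue is a regular grid of nodes (1D strands, 2D sheets) with spacing
`h` in mm; electrical properties live on the elements between nodes. The
transmembrane voltage obeys the monodomain reaction–diffusion equation

$$\beta C_m \frac{\partial V_m}{\partial t} =
  \nabla\!\cdot\!(\sigma \nabla V_m) - \beta I_{\rm ion} + I_{\rm stim},$$

discretized with an explicit operator-split scheme: a 5-point (3-point in
1D) diffusion stencil with harmonic-mean face conductivities and no-flux
boundaries, followed by one ionic step per node. The default time step is
0.02 ms and a stability guard enforces `dt <= h^2 / (2 d D_max)` in `d`
dimensions. The surface-to-volume ratio (`beta = 140` 1/mm) and specific
capacitance (`cm = 1` uF/cm^2) are not independently identifiable from
conduction velocity alone; they are exposed in the configuration and
their defaults are the values commonly used with the human atrial
membrane model. Stimuli are transmembrane current densities over a 2 x 2
mm footprint, 30 uA/cm^2 for 2 ms by default, entered as `dV/dt` in
mV/ms (identical numbers for a 1 uF/cm^2 membrane).

Non-conductive ("percolation") elements stay in the diffusion operator
with a conductivity of exactly `1e-7` S/m — passive barriers rather than
holes — matching how electrical decoupling by fibrotic infiltration is
modeled at tissue scale. The geodesic machinery (pacing rings, rotor
distances, the eikonal solve) uses an 8-neighbour grid graph in which an
edge is passable only if an element it touches conducts, so a
one-element-thick barrier blocks paths exactly as it blocks diffusion.

## Membrane models

Two kinetics are available:

* **`courtemanche`** — the Courtemanche–Ramirez–Nattel human atrial
  ionic model (21 states), integrated with Rush–Larsen for the gates and
  forward Euler for voltage and concentrations. At rest it sits at
  −81.2 mV and drifts by less than 0.01 mV over 10 s; the paced action
  potential at 1 Hz has APD94 ≈ 313 ms.
* **`fast_test`** — a 3-variable phenomenological model (fast inward,
  slow inward, outward current surrogates and two recovery gates) for
  tests and demonstrations where full ionic detail is unnecessary. Its
  defaults are a shortened-action-potential variant of the classic
  3-current formulation: `tau_r = 20`, `tau_si = 18`, `tau_wp = 600`
  (ms), giving APD94 ≈ 130 ms, a cell ERP near 110 ms, and compact
  spiral waves that fit on sheets a few centimetres across. These values
  were chosen once, when the model preset was designed, so that
  desk-scale domains can host re-entry; they are not tuned per test.

Remodeling presets act through a named conductance-scale map. The
`cytokine_fibrotic` preset is fixed to −50% g_K1, −40% g_Na, −50% g_CaL
and is applied automatically to nodes adjacent to `fibrotic_remodeled`
elements. The chronic-`AF` preset is representative (IK1 up, Ito, ICaL
and IKur down, IKs up) and deliberately configurable, since published AF
variants of the atrial model differ in their exact factor sets. For the
fast model the scales map onto the corresponding current surrogates
(g_Na → fast inward, g_CaL → slow inward, g_K1 → outward). One caution
follows from the 3-variable structure: reducing the outward surrogate
*alone* (g_K1 well below ~0.8) can leave the plateau without any
restoring current and diverge — the cytokine preset remains stable
because it reduces the slow inward current by the same factor.

## Induction protocols

All protocols run against a *simulation context* that supports a small
verb set (deliver beat, wait, checkpoint/restore, probe a coupling,
induction check), so the protocol logic is testable against scripted
backends.

**Rapid pacing (RP).** A priming beat followed by a train of stimuli
whose coupling interval decrements from `s` to `l` in steps of 10 ms,
with `N` beats per coupling interval. Arrhythmia checking runs either
after every beat (mode B) or once at the end (mode E). Defaults are
`s/l = 300/200` ms for the control phenotype and `200/130` ms for the
AF-remodeled one.

**PEERP.** Pacing at the end of the effective refractory period: after
each beat the local ERP is found by a run-time binary search (resolution
1 ms by default) and the next stimulus is delivered exactly then, up to
`max_beats = 4` stimuli. The first ERP guess is the APD94 of the paced
single cell; "sinus rhythm" for that guess is rendered as steady pacing
at 1,000 ms cycle length, since no rate is prescribed for it. The
capture predicate is the local propagation criterion: the transmembrane
potential must cross −50 mV upward at at least one node in a geodesic
ring 4–6 mm around the site, within a check window after the stimulus.
The window defaults to 80 ms, which covers 6 mm at conduction velocities
down to 0.1 m/s with margin. Two bracketing rules are deliberate: the
search bracket `[guess/2, guess]` expands only upward (far below the
refractory period the *previous* activation is still crossing the ring
and would alias as capture), and if the evaluated probes ever violate
monotonicity the search falls back to an exhaustive linear scan with a
warning. ERP probe beats run from a checkpointed state and are rolled
back, so probing never perturbs the protocol history.

**PSD.** Phase-singularity-distribution initialization: an
activation-time map with exactly one phase singularity is built as
`T(x) = mod(s·CL·θ(x)/2π + D(x)/v, CL)`, where `θ` is the angle around
the seeded core, `D` the eikonal distance from it (computed on the
conductive grid graph), `v` the conduction speed and `s = ±1` the
chirality. The map is converted to a tissue state by sampling a paced
limit-cycle template (20 pre-pacing beats by default) at phase
`mod(−T, CL)` per node, and the monodomain model is continued from that
state. Whether the original construction warps the angle by the eikonal
solution or adds the two terms is not fixed by our sources; the additive
form is this package's declared choice, and it demonstrably yields a
single singularity of the requested chirality. The cycle length follows
the rule `CL = round(1.05 × ERP)` — 315 ms for the control phenotype
(ERP 300 ms) and 168 ms for the AF variant (ERP 160 ms). On a 2D sheet
the clinical viewing convention (endo-to-epi) has no meaning, so
*anticlockwise* is defined as positive winding in the standard planar
orientation, and corresponds to detected topological charge +1.

**Induction criterion.** A site is *inducing* when the episode is
sustained for at least 1.5 s after the end of the protocol. Since
"sustained" must be decided frame-by-frame, it is operationalized as:
in every output frame of the continuation window at least one conductive
node is at or above −50 mV, *and* a new activation (upward crossing of
−50 mV) occurs somewhere in every rolling 500 ms — the second clause
distinguishes re-entrant propagation from a hung depolarized plateau.
The whole domain is checked, not a neighbourhood of the pacing site,
because induced rotors often stabilize far from it. In mode-B rapid
pacing the same continuation runs after every beat and is rolled back
when negative; the continuation length equals the final criterion window
(1.5 s) unless configured otherwise.

## Phase analysis and episode classification

Phase is computed per node by time-delay embedding,
`φ(t) = atan2(V(t) − V*, V(t−τ) − V*)`, with `τ = 10` ms and `V*` the
per-node temporal mean of the analysis window; resting nodes (peak-to-
peak below 1 mV) are masked. Phase singularities are plaquette
topological charges: the winding of wrapped phase differences around
each elementary grid cell, reported where it equals ±2π, with boundary
plaquettes excluded. Detections are tracked by greedy nearest-neighbour
association among same-charge detections, gated at 1 m/s, with
distance-then-index tie-breaking; one-frame gap bridging exists but is
off by default.

A trajectory is a long-living phase singularity (llPS) at lifetime ≥
500 ms; an llPS is *stable* when it is present throughout the final
1.5 s and its positions in that window fit an axis-aligned square of
5 cm edge. Episodes are classified as `stable_llPS`, `nonstable_llPS`,
`Fl` (flutter) or `Multi`. The flutter-vs-multi decision, done by visual
inspection in the study this workbench emulates, is automated for
reproducibility: flutter requires periodic activation (coefficient of
variation of per-node cycle lengths < 0.1) with at most 2 simultaneous
wavefronts (8-connected components of depolarizing suprathreshold
tissue); the thresholds are configurable and logged.

## Vulnerability maps and sensitivity analyses

`run_vulnerability_map()` runs one protocol from every pacing site
independently, each from the same rested state, and aggregates
inducibility and maintenance per spatial segment (rectangular `k × k`
blocks on synthetic domains, standing in for anatomical parcellations).
Pacing sites form a regular grid with 1 cm inter-point distance by
default, snapped to conductive tissue within `d/2` or dropped.
`spacing_sensitivity()` reports the percentage of
stable-llPS-maintaining segments recovered when only the sites on
coarser subgrids (1.5–3 cm) are used; subsets are selected from the
*original candidate positions*, so they are nested and the recovery
percentage is non-increasing in the spacing. `erp_tolerance_sweep()`
re-runs the PEERP map at ERP resolutions of 1–8 ms; the stability of the
inducing-point count is the readout.

## What the synthetic domains do and do not show

The built-in geometries (strands, homogeneous sheets, two-region
"LAW/RAW" sheets with percolated fibrosis) reproduce the *mechanisms*
the protocols rely on — refractoriness and its dispersion, percolation
barriers, functional re-entry, rotor anchoring and drift — at a scale
where a full vulnerability map runs on one CPU in minutes. They do not
reproduce anatomical re-entry circuits, fiber anisotropy fields,
transmural heterogeneity, or the absolute inducibility counts of
whole-atria studies, all of which are geometry-bound. Passing tests on
these domains validate the protocol logic and the analysis chain, not
clinical predictions. Domain sizes in the test-suite are chosen so each
end-to-end scenario exercises its mechanism at the smallest size where
it is physically possible: spiral re-entry, for instance, needs the
domain edge to exceed roughly one wavelength (conduction velocity times
refractory period), which with the fast membrane model at reduced
conductivity is 3–6 cm.

## Numerical choices and degenerate inputs

* Conductivity tuning brackets on σ and bisects geometrically (CV scales
  as √σ on cables) to `|CV − target| ≤ 0.01` m/s; unstable or
  non-propagating evaluations count as "too slow". Targets outside the
  bracketable range raise an error that reports the achieved range.
* Activation times are first upward crossings of −40 mV at full time-step
  resolution; conduction velocity is the slope of a position-on-time
  regression over a central window, rejecting non-monotone activation.
* `apd94` measures from the maximum-upstroke-velocity sample of the last
  complete action potential to 94% repolarization toward the
  pre-stimulus diastolic level, with linear interpolation between
  samples; traces without a depolarization or without repolarization are
  errors, not NA.
* Exact-count sampling everywhere in the fibrosis generator:
  `round(fraction × N)` elements, sampled without replacement under a
  mandatory seed; identical seeds give identical label arrays.
* Sites whose 4–6 mm ring is empty (too close to a boundary) are
  protocol errors; per-site failures are recorded in vulnerability
  reports rather than aborting the map.
* The limit-cycle template flags beat-to-beat APD94 alternans above 5 ms
  with a warning and uses the last beat.

## Known limitations

Episodes are classified on the retained frame history (1 ms output
interval by default); phenomena faster than the output interval are
invisible to the phase analysis even though the solver resolves them.
The 3-variable test model has no rate-dependent concentration dynamics,
so very long pacing trains do not accumulate the slow APD adaptation the
full atrial model shows. Anisotropy is a single longitudinal:transverse
ratio rather than a fiber field. The monodomain formulation is retained
throughout; bidomain effects are out of scope.
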