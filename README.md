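# atriavuln

Arrhythmia-vulnerability assessment on synthetic atrial tissue.

In both clinics and simulation studies, whether an atrium counts as
"inducible" depends strongly on the electrical stimulation protocol used
to provoke the arrhythmia — decremental trains, burst pacing and
singularity seeding can disagree on the same substrate. `atriavuln` is a
desk-scale workbench for studying exactly that: it implements a
monodomain reaction–diffusion solver on synthetic 1D/2D tissue, the
Courtemanche–Ramirez–Nattel human atrial membrane model (plus a fast
3-variable test model), percolation-type fibrosis, and three induction
protocols —

* **RP** — rapid pacing with a decrementing coupling-interval train
  `RP(s,l,N)`, checking for arrhythmia after every beat (mode B) or at
  the end (mode E);
* **PEERP** — pacing at the end of the effective refractory period: each
  extra stimulus is delivered at the smallest propagating coupling,
  found by a run-time binary search with 1 ms resolution against the
  local propagation criterion (Vm ≥ −50 mV in a 4–6 mm ring around the
  site);
* **PSD** — phase-singularity-distribution initialization: an eikonal
  activation map `T(x) = mod(CL·θ/2π + D/v, CL)` seeds a single rotor of
  chosen chirality, with `CL = round(1.05 × ERP)`.

Induced episodes are analysed through phase (time-delay embedding),
phase-singularity detection (plaquette topological charge), trajectory
tracking, and classified as multiple wavefronts, flutter, non-stable or
stable long-living phase singularity (llPS: lifetime ≥ 500 ms; stable:
final 1.5 s inside a 5 cm bounding box). Per-site results aggregate into
vulnerability maps with spacing- and ERP-tolerance sensitivity analyses.

A site is *inducing* when its protocol initiates an episode that remains
active for at least 1.5 s after the protocol ends.

## Worked example

Tune a strand to the physiological conduction velocity, then seed and
classify a rotor on a sheet:

```r
library(atriavuln)

# conduction-velocity calibration on a 5 cm strand (full atrial model)
model <- membrane_model("courtemanche")
tuned <- tune_conductivity(0.7, model, geom = make_strand(201, 0.25))
tuned$cv
#> [1] 0.6925242        # m/s, within 0.01 of the 0.7 m/s target
tuned$sigma
#> [1] 0.288809         # S/m

# PSD cycle lengths from the 5%-above-ERP rule
psd_cycle_length(c(300, 160))
#> [1] 315 168          # ms, control and AF-remodeled phenotypes

# seed an anticlockwise rotor on a 6 cm sheet (fast test model)
fast <- membrane_model("fast_test")
sheet <- make_sheet(121, 121, 0.5, sigma = 0.045)
res <- run_psd(sheet, fast, c(30, 30), cl = 130, speed = 0.2,
               t_end = 1650, dt = 0.05)
check_induction(res, t_protocol_end = 50, geom = sheet)
#> [1] TRUE             # still active 1.5 s later

ph <- compute_phase(res, tau = 10)
detect_ps(ph, frame = 30)
#>       x     y charge
#>   33.75 32.25      1  # exactly the seeded singularity, charge +1
```

The printed numbers are what the code produces on this machine; the
tuned conductivity and the detected singularity position vary at the
stated tolerances with solver settings.

A thin command-line interface over the same functions ships in
`inst/cli/atriavuln.R` (subcommands `simulate`, `erp`, `peerp`, `rp`,
`psd`, `analyze-ps`, `vulnmap`, `make-fixture`), driven by a YAML
configuration with units embedded in the key names.

See `vignettes/methods.Rmd` for the models, parameter defaults, the
operationalized induction/classification criteria, and the package's
design decisions.

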