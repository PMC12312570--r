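---
title: "Measuring the mechanics of cell aggregates with a micropipette force sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the mechanics of cell aggregates with a micropipette force sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfstretch)
```

## The measurement

A micropipette force sensor (MFS) experiment stretches a small multicellular
aggregate — here, T-cell aggregates that form upon in vitro activation —
between two glass micropipettes held by gentle suction. A straight pipette on
a linear motor moves at constant speed $v$ (20 µm s⁻¹, after a 1 mm s⁻²
acceleration phase lasting ~20 ms); an L-shaped pipette of calibrated spring
constant $k_p$ stays nominally fixed and bends by $x(t)$, reporting the force
$F = k_p x$. Recording at 30 frames s⁻¹ gives, per frame,

- engineering stress $\sigma = F / (\pi R_0^2)$,
- engineering strain $\varepsilon = \Delta L / L_0$ with
  $\Delta L = x_s - x$ and $x_s = v t$,

where $R_0$, $L_0$ are the initial radius and length of the (approximately
cylindrical) aggregate. Engineering, not true, stress and strain are used
throughout — the cross-section is never updated during stretch — which keeps
results directly comparable with the aggregate-stretching literature that
uses the same convention. The Young's modulus $E$ is the slope of the initial
linear regime, fitted on the first 10–30 points; the ultimate tensile
strength $\sigma_{UTS}$ is the maximum stress sustained before rupture.

This package implements that pipeline end to end — calibration, tip
tracking, geometry measurement, stress–strain conversion with error
propagation, fitting, quality control, and group statistics — together with
a synthetic-experiment generator so every stage is testable without any
laboratory data.

## The spring-chain model

The mechanistic model treats the aggregate as randomly packed cells of
radius $r_c$, each responding along the stretch axis as a Hookean spring of
effective stiffness $k_c$ (cell body and its cell–cell adhesion bonds in
series, lumped into one spring). Springs in a line along the stretch axis
form a force chain of $n_x \sim L_0 / 2 r_c$ springs; the cross-section
carries $n_A \sim R_0^2 / r_c^2$ such chains in parallel. Series and
parallel composition give

$$E \sim \frac{k_c}{r_c},$$

independent of aggregate size — the package's `predict_modulus()` /
`infer_cell_stiffness()` pair. The scaling leaves a geometric prefactor of
order one undetermined. We use prefactor 1 for inference, which is the
convention behind the headline estimate $k_c \approx r_c E \approx 8 \times
10^{-4}$ N m⁻¹ for $E = 248$ Pa and $r_c = 3.3$ µm. The prefactor realised
by a concrete simple-cubic lattice is computed separately by
`lattice_scaling_constant()` (about 0.55, varying by ~12% across geometries
from lattice discreteness) and is never silently substituted for 1.

Two open choices were resolved as follows. The chain count $n_A$ carries no
π/4 disc-packing factor: the lattice realisation already answers the
question empirically, and the inference convention is fixed at prefactor 1
anyway. The cell spring is kept lumped rather than split into cell-body and
adhesion-bond springs, as the available data cannot separate the two.

```{r}
infer_cell_stiffness(E = 248, r_c = 3.3e-6)   # N/m
lsc <- lattice_scaling_constant()
mean(lsc$c); sd(lsc$c) / mean(lsc$c)
```

## The simulator: a stated world

`build_lattice_aggregate()` places cells on a simple-cubic lattice with
spacing $2 r_c$, keeping sites inside the cylinder; axial nearest-neighbour
bonds get stiffness $k_c$. Lateral bonds are off by default — under axial
load with one axial degree of freedom per node they carry no force in a full
cylinder, which is the model's own justification for neglecting them — but
can be enabled for stiffness computations.

`simulate_stretch()` couples this network to the cantilever quasi-statically:
inertia and viscosity are dropped (at 20 µm s⁻¹ the loading timescale is
seconds; nothing in the measured data resolves a faster relaxation), and per
frame the deflection solves $k_p x = F_{agg}(x_s - x)$ by bisection. The
aggregate is ductile through a two-threshold bond law, the simplest
constitutive choice that reproduces the observed curve shape (linear rise,
plastic roll-off, maximum, rupture):

- elastic up to a yield strain (default 0.25),
- tangent stiffness reduced by `plastic_factor` (default 0.5) beyond yield,
- bond failure at a rupture strain (default 1.0, matching the strain scale
  at which real aggregates break).

Per-bond thresholds are jittered log-normally (10% default) so chains fail
gradually rather than all at once; chain failures within a frame cascade
until equilibrium. Because the default network is a disjoint union of
identical-length chains, the chain tension law is piecewise linear and is
solved exactly and vectorised; `network_stiffness()` provides the
independent linear-equilibrium oracle (sparse axial solve) that the
simulator's initial stiffness is tested against.

Defaults are the study's stated operating point: $v = 20$ µm s⁻¹,
acceleration 1 mm s⁻² (modelled, though it lasts under one frame), 30
frames s⁻¹, $k_p = 20$ nN µm⁻¹ (mid-range of the 10–40 nN µm⁻¹ cantilevers),
$r_c = 3.3$ µm, $k_c = 8 \times 10^{-4}$ N m⁻¹.

With these defaults the simulated $\sigma_{UTS}/E$ ratio is about 0.5,
somewhat below the measured cohort ratio (~1.6); reproducing the latter
would require strain-hardening beyond the bilinear law and is out of scope —
recovery tests therefore compare the pipeline against the simulator's own
ground truth, not against cohort values.

`render_frames()` draws the two pipettes and the aggregate as anti-aliased
dark silhouettes (the aggregate's drawn area is conserved as it lengthens),
applies a mild Gaussian blur and additive pixel noise. It deliberately does
not model phase-contrast optics, cell-scale texture dynamics, active
motility, or aggregate "shivering": the render exists so that tracking and
geometry measurement can be validated against known motions, not for
optical realism. A green render-and-track test therefore establishes
sub-pixel tracking on clean, high-contrast silhouettes — it does not
establish robustness to debris, illumination drift, or focus changes in real
video.

## Measurement modules

`track_tip()` uses normalised cross-correlation of a frame-0 template with
parabolic sub-pixel refinement, searching a small window around the previous
position (expanded automatically when the peak hits the window edge, e.g. at
the rupture snap-back). The horizontal axis is the stretch axis; vertical
motion is reported as a QC drift metric, not subtracted.

`measure_geometry()` emulates the repeat-based manual measurement: $L_0$ is
the horizontal span between the pipette openings, re-detected five times
with jittered thresholds; $R_0$ is the silhouette half-height at five axial
stations, each refined to sub-pixel by interpolating the intensity profile
at the threshold crossing. Means and SDs over the five repeats feed the
error propagation:

$$\frac{\delta\sigma}{\sigma} =
  \sqrt{\left(\frac{\delta k_p}{k_p}\right)^2 +
        \left(\frac{2\,\delta R_0}{R_0}\right)^2},
\qquad
\frac{\delta\varepsilon}{\varepsilon} = \frac{\delta L_0}{L_0}.$$

Deflection noise is intentionally excluded from the propagated errors,
matching the convention of propagating only $k_p$, $R_0$, $L_0$. The
propagation is first order and distribution-free; when validating it against
Monte Carlo, the input perturbations are drawn log-normally, the natural
noise model for strictly positive measurands. (With Gaussian perturbations
the quadratically-propagated $1/R_0^2$ term picks up ~8% extra spread from
the small-$R_0$ tail once the relative SD reaches 10%; below ~5% the two
noise models agree with the formula and each other.)

`estimate_spring_constant()` implements the water-droplet calibration: drop
volume from the spheroid $V = \tfrac43 \pi a b^2$ (side-view semi-axes; the
orientation convention matters only for aspherical drops), weight
$W = \rho g V$, and $k_p = W / \Delta x$ per drop, with mean and SD over
repeats. Buoyancy in air and evaporation during measurement are not
corrected — both are negligible at these drop sizes and timescales.

## Fitting and quality control

`fit_young_modulus()` scans the window $w \in [10, 30]$ and keeps the
highest-$R^2$ window, ties going to the largest $w$; on a noise-free
piecewise-linear curve this stops exactly at the kink. A fixed-window policy
(default 20) is available for reproducibility. An intercept is fitted and
discarded, since the time origin (first frame of motor motion, acceleration
phase included) can offset the curve by a fraction of a frame.

`qc_validate()` encodes the exclusion rules: `jump` when any stress
increment in the loading portion (up to the stress maximum — the collapse
after the peak is rupture, not an artefact) exceeds 10× the median absolute
increment; `no_stretch` when rupture occurs below 2% strain;
`vertical_drift` beyond 2 µm; `rotation` and `slip` as operator
annotations. A slip only withholds $\sigma_{UTS}$ (the peak force is
unreliable when the aggregate moves in a pipette) while $E$ — fitted from the
early frames — is kept. The numeric thresholds are configuration, not
measured truth: real studies excluded such curves by eye, and no quantitative
criterion is available to calibrate against.

`double_stretch_analysis()` handles pre-stretch protocols. The simulator
summarises the (unmodelled) relaxation during the ~9 s wait between
stretches by a single softening factor, default 0.7, the scale observed
experimentally; no relaxation dynamics are invented.

## Group-level statistics

`generate_group_dataset()` emulates a multi-mouse study: per-mouse log-normal
baselines tuned so the pooled reference group has mean 248 Pa and SD 234 Pa
(an SD comparable to the mean rules out a tight symmetric law), with the
total log-variance split evenly between mouse and within-mouse levels (the
even split is a judgement call; the data constrain only the total), 8
aggregates per mouse and condition (within the 5–25 range of real samples),
and per-mouse condition ratios of 2.8 ± 0.7 (W-7 addition) and 0.30 ± 0.02
(anti-CD3) times the reference. The ± values are treated as across-mice SDs;
the reports label their own spread explicitly. `welch_test()` (with the
star coding of the field), `box_summary()` (type-7 quantiles, 1.5 IQR
whiskers; the plotting convention is switchable), `paired_ratio()`
(aggregating by mean within mouse) and `covariate_null_check()` (OLS slope
with 95% CI) mirror the reporting style of such studies. No
multiple-testing correction is applied, matching pairwise reporting
practice.

```{r}
d <- generate_group_dataset(n_mice = 10, seed = 1)
paired_ratio(d, "PMA+I+W7", "PMA+I")[c("mean_ratio", "sd_ratio")]
welch_test(d$E[d$group == "anti-CD3"], d$E[d$group == "PMA+I"])
```

## Numerical choices and limitations

- Bisection tolerances: the deflection root is bisected 60 times (machine
  precision on metre-scale brackets); chain tensions are piecewise-linear
  and solved exactly, so the only model error is the quasi-static
  assumption itself.
- Rounding: chain counts round half-up with a floor of one, keeping a
  single-cell aggregate representable.
- Degenerate inputs: disconnected networks report zero stiffness with a
  flag instead of raising, so rupture sweeps terminate cleanly; single
  droplet observations calibrate with SD 0 plus a low-replication warning;
  QC-invalid experiments surface as `valid = FALSE` rows, never as silent
  omissions.
- The plastic bond law is nonlinear-elastic under unloading (no residual
  strain); only monotone loading and the softening-factor double-stretch
  protocol are within its remit.
- Rate dependence is absent by construction: the study stretched at one
  speed, and a viscoelastic extension would not be testable against it.
- The simulator's stretching path requires the default axial-chain
  topology; general networks (lateral bonds on) are supported only by the
  linear stiffness oracle.
- Cohort-level numbers (248 ± 234 Pa, 390 ± 334 Pa, the condition ratios)
  come from real animals and are generator parameters here, not
  reproducible results; tests recover generator truths, and the one
  externally anchored acceptance value is the desk-scale inference
  $k_c = r_c E$.
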