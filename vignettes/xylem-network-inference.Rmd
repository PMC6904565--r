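---
title: "Inferring heterogeneous pressure gradients in xylem networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring heterogeneous pressure gradients in xylem networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemflow)
```

## The model

Xylem is modelled as a resistance graph. Each vessel is an axial chain of
cylindrical lumen segments; each segment of radius $r$ and length $L$
carries the Hagen-Poiseuille resistance

$$R_{\mathrm{lumen}} = \frac{8 \eta L}{\pi r^4},$$

converted to mass-flow units through the fluid density $\rho$. Vessels
exchange water laterally through inter-vessel pit fields, modelled as
$R_{\mathrm{pit}} = r_{\mathrm{pit}} / A_{\mathrm{pit}}$ with
$A_{\mathrm{pit}}$ the membrane area and $r_{\mathrm{pit}} = 168$ the
area-specific pit resistance for grapevine. (The unit that constant is
conventionally quoted with, MPa m$^{-1}$ s$^{-1}$, does not reduce to an
area-specific resistance; the package treats it as MPa s m$^{-1}$, which
makes $r_{\mathrm{pit}}/A$ a volumetric resistance, and keeps the number
verbatim.) Vessel relays - short narrow bridges between vessels - are
decomposed into two relay pit fields in series with a relay lumen whose
resistance follows Hagen-Poiseuille from the relay diameter.

Steady flow obeys Kirchhoff node balance: with conductances $g_{ij} =
1/R_{ij}$ on edges and Dirichlet pressures on the top and bottom
boundaries, interior pressures solve the reduced graph-Laplacian system,
assembled sparsely (`Matrix`) and solved directly. Flows are
$Q_{ij} = (P_i - P_j) g_{ij}$, positive upward.

Working units are kPa for pressure, ug s$^{-1}$ for mass flow and um for
length, because every quantity of interest (pixel flows, fitted drops,
axial gradients) is then of order one; conversions live in one file and
nowhere else. Fluid defaults are water at 20 degrees C
($\eta = 1.002 \times 10^{-9}$ MPa s, $\rho = 998$ kg m$^{-3}$); the
source measurements do not state a temperature, so the constants are
explicit arguments everywhere.

## The inverse problem

The data are a 2-D raster of per-pixel mass flow (flow MRI, 78 um pixels)
observed at the top of the sample. The forward model downsamples a
network solution to that raster by summing the top-slice flows of all
vessels whose top centroid falls in a pixel. The objective averages
residuals (model minus observation) over a 5-by-5 pixel window before
summing their squares; the averaging absorbs the small registration
mismatch expected between the imaging modalities. The window is mask
aware: each included pixel is averaged over the included pixels of its
neighbourhood, divided by their count, so borders and mask edges are
unbiased. Whether pixels containing no modelled vessel contribute
residuals is configurable through the `include` matrix; by default they
do (model value zero).

Three scenarios share one exploit: flows are linear in the imposed
boundary pressures.

* **Uniform**: a single top pressure drop. The model map is
  $\Delta P \cdot M_1$ with $M_1$ the unit-drop map, so the minimizer is
  closed-form, $\Delta P^\ast = \langle S M_1, S O\rangle / \|S M_1\|^2$
  with $S$ the (linear) windowed-averaging operator. A masked variant
  restricts the objective to a domain of interest.
* **Total flow**: $\Delta P = Q_{\mathrm{obs}} / Q_{\mathrm{unit}}$,
  exact, no iteration.
* **Per group**: vessels partition into connected groups (components of
  the vessel/connection graph), and each group gets its own top pressure.
  One unit-drop solve per group - a single factorization with one
  right-hand side per group - yields the sensitivity matrix, and the
  objective becomes bound-constrained linear least squares in the
  per-group drops. With the default sign constraint (drop $\ge 0$) this
  is solved by active-set non-negative least squares on the raw design
  matrix, warm-started from the full passive set; with finite upper
  bounds, by L-BFGS-B on the exact quadratic followed by active-set
  polishing. Convergence of the polish loop is declared at a relative
  step below $10^{-12}$.

Numerical choices that matter:

* Least-squares subproblems use a rank-revealing SVD with singular values
  below $10^{-12}$ of the largest treated as zero. Groups whose pixel
  footprints coincide exactly are unidentifiable as individuals; the
  pseudoinverse gives such clusters their minimum-norm split instead of
  letting ill-conditioning contaminate the identifiable groups. Groups
  with no footprint on any included pixel are clamped to zero drop and
  reported (`clamped_groups`); clamping is the conservative choice for
  conduits the observation cannot see.
* The initial iterate for the bounded solver is the uniform-scenario
  best fit broadcast to all groups.
* Components of a network that contain no pressure-assigned node make the
  system singular; they are rejected with the component named rather than
  silently zeroed.
* Registration is a configured rigid in-plane offset applied to vessel
  centroids; no automatic registration is attempted (an overlap search is
  easy to add as a diagnostic but is not part of any fit).

A practical caveat the recovery experiments make visible: groups whose
flow sensitivity is near zero (narrow, weakly connected vessels) absorb
observation noise with arbitrarily large fitted drops. The package
default keeps the spec's one-sided bound; the analysis drivers pass a
finite `upper` (2 kPa, about 2.5 times the largest drop the generator
imposes) as a plausibility bound when fitting noisy maps.

## Statistics

Reported summaries are flow-weighted: mean $\sum w x / \sum w$ with
flows as weights, and the weighted variance in its reliability-weights
form $\sum w (x-\mu)^2 / (\sum w - \sum w^2/\sum w)$, which reduces to
the ordinary sample variance under equal weights and is invariant to
rescaling the weights. Model fit is quantified by Nash-Sutcliffe
efficiency, $1 - \sum(o-m)^2/\sum(o-\bar o)^2$. Axial gradients are
per-vessel imposed drops over the sample length (MPa m$^{-1}$);
transverse gradients are absolute pressure differences between 4-adjacent
non-empty pixels of the flow-weighted pixel pressure map, each unordered
pair counted once (diagonal neighbours excluded - pixel adjacency is a
documented convention, not a measured one). Specific conductivity is
total flow over the flow-weighted gradient times domain area.

Deviations from the idealized flow-radius curve
$Q(r) = \rho \pi r^4 g / (8\eta)$ are tested with a two-tailed one-sample
t-test of zero-mean residuals in a sliding 6-um radius window, evaluated
at 1-um steps (the step is a package choice; windows with fewer than two
vessels are skipped with a warning), with a utility sweeping widths up to
12 um. Domain contrasts (inner/outer by dorsal-ventral/lateral) use a
fixed-effects two-way ANOVA; the layout is unbalanced, so Type II sums of
squares are used (`car::Anova`), a choice the source analysis leaves
unstated. Flow redirection between two fits of the same network ledgers
per-vessel flow changes: the redirected share is the summed positive
changes over total flow, and the wide-vessel loss is the summed losses of
above-mean-radius vessels over their reference-scenario flow.

## The analogue network

A five-vessel normalized resistor network (two upstream files, a central
vessel, two downstream files; lumen elements 0.25 units, walls 1 unit,
unit end-to-end pressure) illustrates how connection heterogeneity alone
creates transverse pressure differences and redirects flow toward
narrower conduits. The wiring is stored as a packaged fixture, and six
frozen reference values - three element flows in the most heterogeneous
variant and the three observed:theoretical conductance ratios - act as
the fixture's acceptance gate in the tests: they over-determine the wall
placement, so if any of them drifts past two-decimal rounding it is the
fixture, not the solver, that must be revisited. Electrically equivalent
re-labelings of the wiring exist (sliding a wall tap one element along
the central vessel); one representative is frozen. In this wiring the
central vessel's downstream element ends blind, as real vessels do
beyond their last functional connection.

The theoretical conductance of a variant sums the lumen conductances of a
quarter-length segment (half the lumina of the central and the two
downstream vessels) and divides by four; the observed conductance is
total flow over the end-to-end pressure difference. Their ratio falls
from 0.41 (homogeneous) to 0.31 (most heterogeneous) - computed, not
asserted, in `analysis/04_analogue.R` and the acceptance script.

## The synthetic generator

`synthetic_spec()` defaults follow the anatomical census of a first-year
grapevine internode: 491 vessels in a 10.4 mm$^2$ annular
cross-section (outer radius 2000 um, pith 830 um) of a 3300-um sample;
lognormal diameters moment-matched to 44 +/- 34 um in the dorsal/ventral
wedges and 30 +/- 20 um in the lateral ones (truncated below 5 um);
pit-field areas lognormal 0.015 +/- 0.012 mm$^2$; relay diameters
lognormal 10 +/- 11 um; per-group pressure drops uniform on the 0-0.78
kPa range such stems exhibit in vivo; 78-um pixels. Where the census
gives no value the choice is documented here and fixed: vessels are
placed by Poisson-disc
dart-throwing with a 5-um wall clearance (wedge and diameter are drawn
first and kept, so packing rejection cannot bias the diameter
distribution); connection formation follows distance kernels
$p_0 e^{-g/\lambda}$ in the perimeter gap $g$, with amplitudes, decay
lengths and a Poisson pit multiplicity chosen once so the realized
census approximates the reference one (about 400 pit fields, 83 relays,
290 groups with 200 solitary vessels); connection heights are uniform
along the sample; observation noise is zero-mean Gaussian per nonzero
pixel with SD 0.5 ug s$^{-1}$ (the imaging noise law is not
characterized in the source; 0.5 is of order 1% of a typical synthetic
pixel flow).

Besides iid per-group drops the generator offers a `serial_feeder`
pressure model: each group's drop is the share of a system-level drop
(default 0.78 kPa) that falls across the sampled segment when the group
drains through a narrow feeder conduit (radius 15 um) representing the
unimaged network above the sample. Wide, conductive groups then receive
systematically smaller drops - the physical mechanism by which serial
resistance redirects flow toward narrow vessels - and the recovery
experiments check that per-group fitting reproduces the resulting
reduced wide-vessel flow share while a uniform-gradient fit cannot.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: the functional asymmetry between inner and
outer xylem (drops are iid across groups unless `serial_feeder` is used,
so no domain carries systematically more flow); MRI physics (partial
volume, signal decay, the real noise law); vessel endings and 3-D
tortuosity (every synthetic vessel runs the full sample, as all vessels
in the measured segment did); and the spatial clustering of real vessel
groups beyond what the distance kernels induce. Quantities that depend on
a real dataset - in-vivo NSE values, fitted drops, conductivities,
redirection percentages - are out of reach of a synthetic harness by
construction and are not asserted anywhere in the test suite.

## Problem sizes and runtimes

The test suite exercises 80-vessel networks for most fitting tests and
the full 491-vessel default for the exact-recovery and pipeline checks;
the recovery-versus-noise sweep uses 6 seeds per noise level and the
null-calibration check 1000 simulated windows. These sizes keep the
whole suite around half a minute while leaving every code path covered.
The analysis scripts under `analysis/` use the full default spec and run
in about a minute end to end.

## Known limitations

* Vessel-to-pixel assignment is by top-slice centroid; area-weighted
  splitting is a documented alternative not implemented as a default.
* Per-interval lumen radius equals the vessel radius in the generator;
  sub-vessel radius variation is supported by the data model (per-segment
  radii) but no published convention exists for it.
* The TIFF raster dialect stores samples rescaled to [0, 1] with the
  affine range in a text sidecar, because the underlying TIFF writer only
  stores that interval; the CSV dialect is bit-faithful and is the
  reference format.
* Identifiability of per-group pressures is data-limited: groups sharing
  every pixel with others are reported clamped or recovered only as a
  cluster (minimum-norm). `observable_groups()` implements the private-
  pixel criterion used by the recovery experiments.
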