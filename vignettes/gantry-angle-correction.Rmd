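---
title: "Gantry-angle-corrected dose prediction QA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gantry-angle-corrected dose prediction QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gacqa)
```

## The problem

In step-and-shoot IMRT each beam is delivered as a sequence of static MLC
segments. Where two segments meet, opposing or sequential leaf ends form an
*abutment*: a millimetre-scale mismatch in leaf stop position produces a
visible over- or underdose line. Leaf stop positions are not gantry-angle
invariant — gravity sags the leaf bank — yet per-beam QA (diode arrays,
films) is almost always measured at gantry 0. `gacqa` implements an
empirical correction for this: abutment dose deltas are measured per gantry
angle with a portal imager (EPID), converted to dose through a film-anchored
linear calibration, and injected into the per-beam QA error maps before
back-projecting them onto the 3D dose grids.

## The non-gap test and its analysis

A 20 cm × 20 cm open field is emulated by ten abutting 2 cm × 20 cm strips
delivered with zero leaf gap; the per-pixel **sum** of the ten EPID
exposures is the composite image (summation assumes a linear detector
response, appropriate for equal-MU strips). At each of the 171 abutment
nodes (9 junctions × 19 leaf pairs, 2 cm apart laterally, 1 cm leaf width)
the ratio

$$R = \frac{A}{B} \times 100$$

is computed, where $A$ is the mean pixel value in a 10 mm × 5 mm region of
interest centred on the abutment at the leaf centre and $B$ is the mean of
the two flanking open-field (strip-centre) ROI means. Flanking on both
sides removes beam-profile and output variations. $R > 100$ marks an
overdose line, $R < 100$ an underdose. The ROI is 10 mm along leaf travel ×
5 mm along leaf width, specified at isocenter scale and converted to
detector pixels by the SID/SAD magnification (1.5 for the 150 cm/100 cm
geometry); the image axes the 10 × 5 sizes attach to are configurable
because the acquisition convention does not fix them unambiguously.

Reproducibility is summarized as the per-node coefficient of variation
(sample SD / mean × 100) over repeat acquisitions.

Field sizes are verified per leaf pair by FWHM: the crossplane profile at
the leaf centre (averaged over the central 5 mm of the leaf width) is
referenced to a plateau estimated over the central 50 % of the *nominal*
field — robust against abutment lines, unlike a global maximum — and each
edge is the 50 % crossing found by linear sub-pixel interpolation scanning
from outside inward. Positions are reported at isocenter scale (× SAD/SID),
the clinical convention; a positive per-side error means an opening larger
than nominal.

## Pixel-ratio to dose-ratio calibration

Film-derived relative dose ratios $y$ (abutment dose over neighbouring
open-field dose, dimensionless near 1) are regressed on EPID pixel ratios
$x$ (near 100) by ordinary least squares, $y = a x + b$, with Pearson's
$r$ reported. Only the slope $a$ is used downstream: the gantry-angle
correction works with *differences* of pixel ratios between angles, in
which the intercept cancels. The film densitometry chain itself (scanner,
red channel, self-development) is out of scope; film data enter as
already-converted dose ratios.

## The GAC lookup table

For measured gantry angles $\theta$ (defaults include the cardinal and the
clinical treatment angles), each node's delta is

$$\Delta(\theta, \ell, x) = a \, \bigl( R(\theta, \ell, x) - R(0°, \ell, x) \bigr),$$

a *fraction* of local dose (× 100 gives percent), identically zero at the
0° reference. This difference-through-the-slope reading is the only one
consistent with a slope quoted per pixel-ratio *unit*; a quotient of ratios
was considered and rejected. Queries interpolate linearly between the two
neighbouring 20 mm nodes of the same leaf (constant extrapolation beyond
the outermost nodes, no interpolation across physically independent
leaves) and linearly on the circle between the two adjacent measured angles
(wrapping 315° → 0° across 360°). Angular interpolation is a convenience,
not a validated physical model: where accuracy matters the table should be
built at the actual treatment angles, which the builder accepts directly.

## Error maps, abutment detection, back-projection

Per beam, the fractional error map on the planned 1 mm grid is

$$e(u, v) = \frac{D_\mathrm{meas}(u,v) - D_\mathrm{plan}(u,v)}{D_\mathrm{plan}(u,v)}$$

with the sparse diode measurement interpolated bilinearly, masked where the
planned dose falls below 10 % of its maximum (e is 0 off-mask). Abutments
are detected on the segmented intensity map by scanning each leaf row at
the 1 mm map resolution: adjacent-sample differences of at least 1 % of the
beam maximum mark a step at its midpoint; steps within 1 mm are merged
(magnitude-weighted) and each detection is matched to the segment whose
leaf end lies within 1.5 mm.

The GAC delta, weighted by the matched segment's MU fraction, is **added**
to $e$ over a 2 mm band (configurable) centred on the abutment within the
leaf's row span. Additive combination of fractional errors differs from
multiplicative only at second order for the ~2–7 % magnitudes involved.
The MU weighting reflects that an abutment formed by a segment carrying
10 % of the beam's MU cannot perturb the whole-beam dose by the
full-exposure delta. The physical width of an abutment line is not sharply
defined; 2 mm is a deliberate, configurable default.

Back-projection fixes a divergent-projection, multiplicative model: every
voxel centre is rotated into the beam frame (IEC 61217 gantry rotation
about the isocenter) and projected from the source (SAD 1000 mm) onto the
isocenter plane, $u = x_b \cdot \mathrm{SAD}/(\mathrm{SAD} - z_b)$, and the
corrected dose is $D' = D \times (1 + e(u, v))$ with bilinear lookup
($e = 0$ outside the map). The single measurement plane (10 cm depth) is
applied along the whole ray: depth dependence of the error is deliberately
ignored, matching the QA geometry in which the map is acquired. The
predicted total is the voxelwise sum over beams; with zero error and zero
correction it reproduces the planned composite exactly, a closure property
the tests assert at machine precision.

## Evaluation metrics

*Gamma* uses global normalization (dose criterion as a percentage of the
reference maximum — the prevailing convention for film-vs-plan
comparisons), a search lattice of step DTA/10 out to a radius of 3 × DTA,
and excludes reference points below the low-dose threshold from the pass
rate. The implementation visits offsets in order of increasing distance
and retires a point once no remaining offset can improve its gamma; this
is exactly equivalent to the exhaustive search over the same lattice, and
the test suite proves the equivalence against an independent brute-force
oracle on randomized planes. Gamma is asymmetric in its arguments, and the
reference always supplies the normalization and the evaluation points.

*DTA* finds, per reference point, the nearest search-lattice location
where the evaluated dose equals the point's dose — either within a small
tolerance (0.1 % of the reference maximum) or by bracketing between
adjacent lattice samples — capped at the search radius; its accuracy is one
lattice step.

*DVH indices* follow the "dose received by at least x % of the volume"
convention (ICRU 83 reading of D98/D2), computed by linear interpolation
of the order statistics (`stats::quantile`, type 7); VxGy is the
percentage of structure voxels at or above x Gy. Structures are rasterized
by voxel-centre-in-polygon with the even-odd rule; partial-volume
weighting was rejected for testability.

Group comparisons use the paired two-tailed Student's t test; constant
differences are handled as the analytic limit (t = 0, p = 1 when the mean
difference is zero).

## What the synthetic generators emulate

The generators encode the study conditions as defaults rather than tunable
knobs: 1024 × 1024 panel at 0.40 mm/px and SID 150 cm; ten 2 cm × 20 cm
strips; 19 leaves of 10 mm; five treatment beams at 45°, 105°, 180°, 255°
and 315° with three abutting segments each; 2 mm planning grid; 7 mm diode
pitch; 78 Gy over 39 fractions prescribed to the PTV mean.

Strip fields use an error-function penumbra whose half-maximum falls
exactly on the nominal edge; rising and falling edges of abutting strips
cancel, so the unperturbed composite equals the open field to rounding
error and the null pipeline yields ratios of exactly 100. The penumbra
sigma defaults to 1.5 mm at isocenter (a sharp but realistic MLC edge);
larger values leak field-edge penumbra into the outermost open-field ROIs
and bias the edge abutment ratios — a real effect the default deliberately
keeps below the 0.05 ratio-unit level. Junction perturbations multiply a
10 mm band around the junction per leaf, so a configured ΔR is recovered
exactly by the ROI analysis.

Noise has two components: per-pixel multiplicative Gaussian noise (quantum
noise; largely averaged away by the ~700-pixel ROIs) and a per-junction
multiplicative fluctuation per acquisition that models delivery and
leaf-position reproducibility — the component that actually dominates the
observed ratio variability. The calibration generator's default noise
(σ = 0.075 on the dose ratio, x uniform on [90, 110]) is chosen by
variance algebra so the fitted correlation lands near 0.84, the strength
observed for film/EPID pairings.

The plan fixture's forward model is *not* a dose engine: dose is fluence ×
an exponential depth factor (attenuation 0.004/mm, a 10 MV-like value),
normalized so the PTV mean equals the prescription. It guarantees exactly
the relationships the pipeline consumes — per-beam planes consistent with
per-beam grids, abutments consistent with segment boundaries and MU
fractions, diode measurements equal to the planned plane times (1 + a known
smooth error field) — and nothing more. Passing tests therefore demonstrate
the correctness of the analysis chain, not the realism of scatter,
heterogeneity, tongue-and-groove or leaf transmission, all of which are out
of scope. Segment-step columns are genuinely undersampled by a 7 mm diode
lattice, so error maps near steps carry large interpolation artefacts, as
they do with real diode arrays; the end-to-end checks compare against an
oracle that composes the same maps rather than against the injected truth
at those columns.

## Numerical choices and degenerate inputs

* Text dose planes use a fixed two-line header (origin; spacing) — the
  native TPS export dialect is not standardized, so the package defines
  one and round-trips it losslessly at 17 significant digits.
* RT Dose files are written explicit-VR little-endian with 32-bit unsigned
  pixels; the scaling defaults to max/(2³¹−1), so quantization error is at
  most one scaling quantum. The reader rejects non-uniform frame offsets
  and missing dose-grid scaling.
* Reticle offset correction resamples bilinearly; trigonometry uses
  `sinpi`/`cospi` so right-angle rotations are exact and the 180°
  correction is an involution. Offsets above 50 px warn but are applied.
* Problem sizes in the test suite — 61³ voxel grids, 1024² panels, planes
  up to 40 × 40 for gamma-oracle equivalence, 200 calibration replicates —
  were chosen so the full suite completes in about a minute while still
  exercising the default study geometry end to end.
* Degenerate inputs error early with messages naming the failed
  precondition: empty grids, negative doses, ragged text matrices, missing
  0° reference, mismatched replicate grids, empty structure masks,
  length-mismatched paired samples.

## Known limitations

* The GAC table is purely empirical; it does not model the physical cause
  (gravity-induced leaf sag) and cannot extrapolate to collimator or couch
  rotations.
* Angular interpolation between measured angles is linear on the circle
  and unvalidated between distant nodes; measure at the treatment angles
  when possible.
* The error map is single-plane; depth dependence and beam hardening are
  ignored by design.
* Whether the correction should be confined to the abutment columns or
  smeared over a wider region is not settled by the available evidence;
  the band width is exposed as a parameter.
* The DICOM support is deliberately minimal (RT Dose, standard tags,
  explicit VR little endian): it is sufficient for this pipeline's round
  trips and for interoperability checks with general-purpose DICOM tools,
  not a general DICOM library.
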