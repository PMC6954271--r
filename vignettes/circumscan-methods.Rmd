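---
title: "Coverage geometry and optical sectioning for circumferential organ surface microscopy"
author: "circumscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage geometry and optical sectioning for circumferential organ surface microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circumscan)
```

## The problem

When a solid organ such as a radical prostatectomy specimen is excised,
the clinically decisive question is whether tumor cells reach the inked
resection surface. Conventional slide-based pathology samples a vanishing
fraction of that surface — one 4 µm section per ~3 mm gross block, about
0.13 % — so an attractive alternative is to image the intact surface
directly with an optical-sectioning fluorescence microscope while the
fresh specimen rests against a glass slide. `circumscan` implements the
computational side of such a workflow: how much surface *can* be imaged,
how to plan the acquisition, how to reconstruct, stitch and register the
images, and how to quantify the coverage actually achieved.

## Coverage geometry of a compressible sphere

The organ is modeled as a sphere of radius $r$ that flattens under its
own weight by a depth $h = rc$, where $c \in [0, 1)$ is the
dimensionless *compressibility coefficient*. The flattened face in
contact with the slide is the base disc of a spherical cap,

$$a = \sqrt{2rh - h^2} = r\sqrt{2c - c^2}, \qquad A = \pi a^2 .$$

**Four-aspect imaging.** Rotating the specimen by 90° between four
acquisitions images four such discs, covering the fraction

$$S_I = \frac{4 \pi a^2}{4 \pi r^2} = 2c - c^2,$$

independent of size. At $c = 0.2$ (typical for dense glandular tissue)
this is 36 %. The model is only meaningful until the four discs touch,
which happens at $a = r/\sqrt{2}$, i.e. $c = 1 - 1/\sqrt{2} \approx
0.29$, where coverage is exactly 50 %. Beyond that bound
`four_aspect_coverage()` raises an error rather than clipping — the
bound is an upper limit of the model's validity, not a saturation value.

**n-rotation (polygonal) imaging.** Mounting the organ on an axial rod
and imaging $n$ narrow strips (the cross-section is a circle inscribed
in a regular $n$-gon; $n = 10$ in the canonical protocol) covers, per
face, the contact disc clipped to the face's azimuthal half-width
$w = r(1-c)\tan(\pi/n)$:

$$A_{\text{clip}} = \begin{cases} \pi a^2 & w \ge a\\
2\left[w\sqrt{a^2-w^2} + a^2 \arcsin(w/a)\right] & w < a \end{cases}
\qquad S_n = \frac{n A_{\text{clip}}}{4\pi r^2}.$$

As $n \to \infty$ this converges to the *band limit*
$(1-c)\sqrt{2c-c^2}$ — a contact band of compressed circumference
$2\pi r(1-c)$ and axial extent $2a$. Both constructions give 48 % at
$c = 0.2$, $n = 10$ (0.48044 and 0.48000). The package exposes both
(`polygonal_coverage()`, modes `clipped_disc` and `band_limit`) because
the printed whole-percent figure does not distinguish them; clipped-disc
is the default as the geometrically explicit model, and
`coverage_numeric_oracle()` provides an independent quadrature check
that never touches the closed form.

```{r coverage}
four_aspect_coverage(0.2)
polygonal_coverage(0.2, n = 10)
polygonal_coverage(0.2, mode = "band_limit")$coverage_fraction
coverage_numeric_oracle(0.2, n = 10)
```

**Acquisition planning.** `plan_acquisition()` rounds the ruler-measured
diameter and length *up* to whole millimetres (the measurement policy of
the protocol), computes the panel width $\pi d / n$ — the arc of a
$360/n$° central angle — and tiles each panel with frames stepped by
`fov * (1 - overlap)`, with ceiling counts so nothing is missed. The
default overlap of 10 % is an implementation choice; the protocol states
only that frames overlap.

## Square-law optical sectioning

The microscope projects a sinusoidal pattern, phase-stepped by one third
of its period across three frames $x_1, x_2, x_3$. In-focus structure is
modulated; defocused background is not. `square_law_reconstruct()`
computes

$$I = \sqrt{(x_1-x_2)^2 + (x_1-x_3)^2 + (x_2-x_3)^2},$$

which cancels any signal common to the three frames exactly and maps a
sinusoid of amplitude $M$ to $\sqrt{9/2}\,M$ regardless of local phase
(the identity $\sum_{i<j}(s_i - s_j)^2 = \tfrac{9}{2}$ for unit
three-phase sinusoids). Flat-field correction divides each raw frame by
a mean-normalized reference of a uniform fluorescent slide; the package
applies it to the raw frames *before* reconstruction (the order is
configurable — applying it to the reconstructed section instead is
algebraically identical for a static illumination profile, since the
square law is homogeneous of degree one in a pixelwise scaling).
Floating-point math is used throughout; quantization to 16-bit
(`rescale_to_16bit()`) happens only at export, with a constant image
mapping to zeros (warned) so batch pipelines keep running.

`optical_calibration()` carries the resolution bookkeeping: USAF group
$g$ element $e$ has $2^{g + (e-1)/6}$ line pairs/mm, so group 9 element
1 is 512 lp/mm (1.95 µm pitch); at 0.645 µm pixels a 2048 px sensor
spans 1.32 mm and the three-pixel lateral resolution is 1.94 µm.

## The synthetic phantom

No public image data exist for this kind of acquisition, so the
`generate_surface()` / `simulate_acquisition()` pair creates fully
synthetic ground truth. The canonical frame is the *unrolled cylinder*:
x is circumferential (width $\pi d$), y axial, rotation starting at the
posterior centre. The surface texture emulates an acridine-orange-
stained specimen with three feature classes — bright curvilinear nerve
tracts (~130 µm wide), dark circular adipose voids (~0.5 mm), punctate
bright nuclei (~10 µm) — at Poisson-drawn counts over correlated
background texture. `apply_fiducials()` paints the stencil pattern used
for registration: a dark central line around the circumference and hash
marks every 10 mm, applied multiplicatively so ink is strictly darker
than the tissue it covers.

The forward model in `simulate_acquisition()` gives pixels inside the
geometric contact patch (the clipped disc of the coverage model, drawn
in unrolled coordinates about each panel centre) the modulated signal
$x_i = B + \text{truth}\cdot(1 + m\sin(\phi + 2\pi i/3))$, and
out-of-contact pixels only blurred, unmodulated background — which the
square law rejects exactly, so reconstructed out-of-contact pixels are
zero and Otsu masking is honestly exercised. Rod slippage is modeled by
shifting a panel's source window circumferentially (rotational, degrees)
or axially (mm). All randomness flows through one seed; identical
configurations are bit-identical.

Deliberate simplifications, and what they imply for the tests: the
contact patch is drawn directly in unrolled coordinates, ignoring the
arc-versus-chord distortion of flattening a face (this makes the
measured phantom coverage agree with the closed-form model by
construction, which is exactly what the end-to-end invariant should
check); there is no point-spread function, no autofocus error, no
staining variability, and photon noise is off by default (Poisson at a
configurable photon budget when on). Passing the phantom tests therefore
demonstrates the correctness of the *pipeline algebra* — reconstruction,
stitching, registration, quantification — not robustness to real-tissue
optics.

Test problem sizes: the standard phantom is a 40 mm × 30 mm organ at
$c = 0.2$, rendered at 0.05 mm/px (600 × 2513 px), imaged in 10 panels
of 3 × 6 tiles with 10 % overlap. At that pitch a 10 µm nucleus is
sub-pixel, so the test phantoms scale the nucleus diameter up to 0.2 mm;
the generator refuses any feature smaller than 2 px rather than
silently dropping it.

## Mosaicking and registration

Tiles are acquired in serpentine (boustrophedon) order
(`serpentine_coords()`), refined by translation-only correlation on
their overlap strips (`refine_offsets()`; degenerate or featureless
overlaps keep the nominal stage offset with a warning), and stitched by
feather (linear distance-to-edge ramp) or overwrite blending. No
rotation or scale is ever introduced. Panels are trimmed to their
nominal width and concatenated into the rolled-out panorama
(`assemble_rollout()`), with anatomical labels assigned by azimuth
(posterior → left → anterior → right → posterior for $n = 10$).

`detect_fiducials()` finds ink markers as dips of intensity profiles
below a running-median baseline, ignoring columns whose baseline carries
no signal (out-of-contact gaps). `measure_hash_spacing()` divides each
adjacent gap by its rounded multiple of the smallest gap before
averaging, because hashes that fall between contact patches are
invisible and would otherwise bias the mean upward; for fully visible
marker sets this is exactly the mean adjacent spacing.
`align_panels()` makes the central line collinear (axial offsets) and
the hash sequence periodic across seams (circumferential shifts).

Duplicate-panel detection (`detect_duplicate_overlap()`) handles rod
slippage: one panel is slid over the other and correlated over the
*intersection of tissue supports*, after removing per-row and per-column
means so that frame-fixed structure — the contact outline, the ink line,
the hash marks — cannot masquerade as shared tissue. The repeat
threshold (0.5) and the seam-continuity criterion (NCC > 0.95) are
package defaults; the protocol literature offers only anecdotes of ~90 %
and ~10 % duplicated panels, both of which the phantom reproduces. A
flagged repeat is either trimmed to its novel span or dropped,
per `apply_alignment(policy=)`.

## Coverage quantification

`otsu_tissue_mask()` thresholds at the 256-bin between-class-variance
maximizer (implemented directly so its tie-breaks and degenerate policy
are part of the contract: a constant image yields an all-background mask
with a warning). Tissue area is pixel count × pixel pitch²
(`area_from_mask()`, cm²); the reference surface area comes from a
triangulated mesh via the half-cross-product rule
(`mesh_surface_area()`, with minimal ascii PLY/OBJ/STL readers and an
icosphere generator for analytic checks). Coverage is their ratio
(`coverage_percent()`).

`summarize_cases()` reproduces printed per-case summary tables: mean and
**population** standard deviation (divisor $N$) per column — the
convention that reproduces the published spreads exactly, where the
sample SD (divisor $N-1$) does not — with half-up rounding to two
decimals (whole minutes for times). Cases lacking their own surface scan
are covered against the mean surface area of the scanned cases.
Throughput is mean imaged area over mean elapsed time; the ratio of
throughputs is taken before rounding.

```{r table1}
tab <- read_case_table(system.file("extdata", "table1.csv",
                                   package = "circumscan"))
summarize_cases(tab)
```

## Known limitations

* The sphere/rigid-plane abstraction ignores ellipsoidal organ shapes
  and any contact mechanics beyond uniform flattening.
* Registration is rigid (translation only); deformable tissue motion
  between rotations is out of scope.
* The fiducial detector assumes dark ink on bright tissue; polarity is
  a parameter but inverted-contrast stains are untested.
* The phantom's optics are idealized (no PSF, perfect phase steps);
  quantitative claims about real-tissue image quality cannot be made
  from it.
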