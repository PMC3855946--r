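---
title: "Simulating B-mode ultrasound from CT: model and design notes"
author: "ctus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating B-mode ultrasound from CT: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctus` turns a CT volume and a probe pose into an 8-bit B-mode sector image.
This vignette records the model each stage implements, the assumptions it
rests on, and the choices made where the design was genuinely open.

## 1. Multiscale vascular enhancement

**Model.** Vessels in non-contrast CT are nearly isointense with the tissue
around them, so they are located geometrically rather than by intensity. At
each analysis scale $s$ (mm) the volume is convolved with derivatives of a
Gaussian; the second-derivative responses are multiplied by $s^{2\gamma}$ so
responses are comparable across scales. The Hessian eigenvalues, sorted by
magnitude $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$, enter the line-filter
response

$$\nu_0 = \left(1-e^{-\mathcal{R}_A^2/2\alpha^2}\right)
           e^{-\mathcal{R}_B^2/2\beta^2}
           \left(1-e^{-S^2/2c^2}\right),$$

set to $0$ whenever $\lambda_2>0$ or $\lambda_3>0$. The ratios are the
standard ones for this family of filters:
$\mathcal{R}_A=|\lambda_2|/|\lambda_3|$ (plate vs. line),
$\mathcal{R}_B=|\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blob), and
$S$ the Frobenius norm of the Hessian (structure vs. noise). In the 2D
variant we use $\mathcal{R}_B = |\lambda_1|/|\lambda_2|$; the signed ratio
would flip sign with polarity, and the filter's gate already carries the
polarity information, so the magnitude is the self-consistent choice.

**Parameters.** `scales` (mm): match the vessel radii of interest; the
pipeline default `c(1.5, 2.5, 4)` covers 2–5 mm abdominal vasculature.
`gamma = 1` is the scale-invariance exponent. `alpha = beta = 0.5` are the
literature defaults for the ratio terms. The structure threshold `c` accepts
a number or `"auto"` (half the maximum Frobenius norm at the current scale).

**Calibration of `c`.** The auto rule keys on the *global* response maximum.
In body CT that maximum sits at bone and air interfaces (intensity steps of
1000+ HU), three orders of magnitude above the response of near-isointense
vessels, so auto-`c` drives vessel scores to numerical zero. The pipeline
default is therefore an absolute `c = 1`: vessels with a few HU of contrast
produce γ-normalised Hessian norms of about 2 under the default phantom
conditions, and half the typical target response is the same heuristic the
auto rule applies, aimed at the structures of interest instead of the
strongest edge in the volume. Users simulating contrast-enhanced CT (bright
vessels) should raise `c` toward the response their vessels actually
produce.

**A caveat on scale selection.** With auto-`c`, each scale's structure term
is normalised by that scale's own maximum, which flattens the comparison
across scales: the multiscale maximum is then decided by the ratio terms
alone. With a fixed absolute `c` the matched scale wins on an ideal tube, as
scale-space reasoning predicts; the tests assert the argmax property in that
setting.

**From response to rendering.** `multiscaleEnhance` returns the raw
per-voxel map. The pipeline does not modulate with it directly: the
eigenvalue ratios are noise-sensitive, and an unregularised weight
measurably *adds* texture to homogeneous tissue instead of darkening
lumina. The pipeline therefore (i) smooths the map with a Gaussian at the
smallest analysis scale and (ii) maps it to a vascular membership — 0 below
10% of the map's maximum, 1 above 30%, linear in between. Lumen interiors
then sit on the plateau and are replaced *uniformly* by the configured
lumen intensity (`vesselIntensityShift`, default −100 HU, blended with
weight `blendWeight`, default 0.5), which is what makes them echo-free
downstream; the membership gradient is confined to the rim, and
sub-threshold responses in tissue do not modulate at all. The blend itself
is `blended = source − w·v·(source − shift)`, i.e. the weighted integration
of the source with the vessel-replaced image.

**Boundary handling.** Gaussian convolution uses whole-sample reflection to
avoid edge ringing; the derivative kernels are sampled analytically,
truncated at $4\sigma$, and DC-corrected so constant and linear volumes give
exactly zero second derivatives in the interior. Scales are interpreted in
mm and converted to a per-axis voxel sigma, so anisotropic CT is handled. A
response at floating-point round-off level (an exactly homogeneous volume)
is treated as no structure.

## 2. Thin-plate-spline scan conversion

The sector grid (field of view $\varphi$, radii $r_s \ldots r_l$, $m$ radial
× $n$ tangential samples) is paired with the rectangle grid node-by-node:
rectangle node (row $i$, col $j$) ↔ sector point at radius
$r_s + i\,\Delta r$ and angle $-\varphi/2 + j\,\varphi/(n-1)$ from the apex.
The spline minimises the classical bending-energy objective; with the kernel
$U(r)=r^2\log r$ the solution splits into an affine part and a warp with no
affine content, computed through the QR separation of $[1\,|\,q]$. With
$\lambda = 0$ (the default) landmarks are interpolated exactly; $\lambda$ is
exposed for users who want smoothing.

Fitting on all $m\times n$ nodes would cost $O((mn)^3)$; the default is a
10×10 control sub-lattice with dense evaluation, which preserves the smooth
mapping at interactive cost. The forward and inverse transforms are fitted
independently (landmarks swapped). The sector raster derives only from the
geometry and the pixel pitch; the scanline content is determined by
$m \times n$.

Degenerate inputs: fewer than 3 landmarks, collinear landmarks, and
mismatched pair counts are rejected; $U(0)=0$ handles coincident points
(e.g. the apex row of an $r_s=0$ sector).

## 3. Adjacent-region acoustic model

Acoustic impedance is roughly proportional to CT intensity, so the
reflection weight of the interface between consecutive samples is the
intensity analogue of the impedance formula,
$\alpha_{ref} = \left((I_2-I_1)/(I_2+I_1)\right)^2$. Intensities are
shifted by `huShift` (default 1024, clamped to ≥ 1) because the formula is
ill-defined at non-positive values. Three rules sit on top:

- below a relative difference of 0.1% no reflection is emitted
  (`reflectThreshold`); the discontinuity this introduces is at most
  threshold², i.e. $10^{-6}$, hence negligible;
- interfaces where exactly one side is bone (≥ 300 HU) reflect 43%;
- interfaces where exactly one side is air (≤ −500 HU) reflect 99%
  (air wins when both rules fire).

The 300/−500 HU class boundaries are standard Hounsfield ranges, exposed in
the config. Per depth sample the echo is
$\alpha_{ref}\,U_{in}\,|\hat r\cdot\hat n|\,e^{-2A}$: the obliquity factor
uses Sobel gradients of the rectangular grid (the beam is the depth axis
after scan conversion; a zero gradient means normal incidence), and $A$ is
the running attenuation integral $\sum_j \alpha_j\,\Delta d$, which reduces
to the textbook $\alpha d$ product in a homogeneous medium and generalises
it to piecewise media. The same $\alpha_{ref}$ plays both the reflection
and attenuation roles, which is why bone (0.43 per interface crossing)
shadows everything distal to it.

Speckle has no closed form in this model family; the choice here is a
scattering term proportional to the local deviation of the shifted
intensity from its 5-sample neighbourhood mean (CT noise and tissue
inhomogeneity thus become speckle, and smooth gradients do not), attenuated
like any echo, multiplied by $(1-\text{vesselSuppress}\cdot\nu_0)$ so lumina
stay dark, and finally modulated by seeded multiplicative Gaussian speckle
$\max(0, 1+\sigma\xi)$. Echo amplitudes are clamped to $U_{in}$ (receiver
saturation), keeping the energy book-keeping honest. Every column's speckle
seed derives deterministically from the master seed.

## 4. Transducer integration and display

Adjacent scanlines are summed with a normalised Kaiser window
($I_0$-based taps, shape `kaiserAlpha = 2`, aperture `nElements = 7`,
truncate-and-renormalise at the edges — no wraparound and no zero padding
that would darken the borders), a 3-sample box blur runs along depth, the
rectangle is mapped back into the sector through the inverse spline, and
the in-sector range is stretched linearly to 0…255 with half-up rounding
(a constant image maps to all zeros). The per-element physical weight
$\cos\theta_i\, e^{-2\alpha_{ref} d_0/\cos\theta_i}$ with
$\theta_i=\arctan(|i|\,d/d_0)$ is exposed as `physicalWeight`; the Kaiser
window is the stated approximation of that weighting on already-propagated
scanlines, and the package follows it rather than re-propagating per
element.

## The synthetic phantoms

`makeAbdominalPhantom` builds the canonical test volume: 128³ voxels at
1.5 mm — soft tissue 50 HU with σ = 8 Gaussian noise, a liver-like
ellipsoid at 60 HU, a branching vessel tree at 55 HU (deliberately within
a few HU of the liver, as in real non-contrast CT), a 1000 HU bone
ellipsoid and a −1000 HU air pocket, with ground-truth masks returned
alongside. Radii (2.2–4.5 mm) are in the range of hepatic vasculature. The
default probe pose looks through the liver with the bone inside the
field of view.

What the phantoms emulate: HU contrasts, CT noise, tube geometry at
clinically plausible radii, bone/air occluders. What they do not: organ
shape realism, partial-volume blur of a real scanner reconstruction,
directional CT noise, breathing/probe-pressure deformation, flow. Passing
tests on these phantoms therefore demonstrates the model's *mechanisms*
(enhancement, shadowing, anechoic rendering, determinism), not clinical
image fidelity, which would require paired CT/ultrasound data.

Test problem sizes are chosen to keep the full suite under a minute of
filter work: 64³ fixtures for structure-discrimination properties, the
128³ phantom for the end-to-end checks.

## Numerical choices and degenerate inputs

- Eigenvalues of the symmetric 3×3 Hessian use the closed-form
  trigonometric solution, vectorised over the volume; ties in the magnitude
  sort break by ascending signed value.
- $\lambda_3 = 0$ (with $\lambda_2 \le 0$) means all eigenvalues vanish at
  sorted order, and the response is 0; $\mathcal{R}_B$'s $0/0$ at
  $\lambda_1 = 0$ resolves to the line-like limit 0.
- Trilinear/bilinear samplers return a configurable background
  (default −1000 HU, air) outside their domain, so a sector that exits the
  volume behaves like leaving the body.
- The raw+sidecar reader validates byte counts against dims × dtype;
  volumes containing NaN are rejected at load.
- All randomness (phantom noise, speckle) flows from explicit integer
  seeds; one master seed derives every module seed, making the whole
  pipeline byte-reproducible.

## Known limitations

- No refraction or ray bending: rays are straight; refraction is listed
  among the phenomena but not computed.
- Attenuation is frequency-independent; the transducer frequency is
  recorded in the config but drives no equation.
- The Kaiser aperture approximates multi-element integration laterally; it
  is not delay-and-sum beamforming.
- The anechoic-vessel mechanism depends on the vesselness filter finding
  the vessels: at very low contrast-to-noise the membership map misses
  small branches, which then render with tissue texture.
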