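---
title: "Affine image transformations and affine Gaussian derivative receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affine image transformations and affine Gaussian derivative receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affrf)
```

## The problem

When a smooth surface patch in the world is viewed from different
distances and directions — monocularly, binocularly, or over time — its
projection to the image plane changes. To first order those changes are
local 2-D affine transformations $x' = \mathcal{A}x$ (translations are
removed by fixating a common surface point). A visual front end whose
receptive fields are *covariant* under this family can match filter
responses across views: if the filter parameters are transformed along
with the image, the responses are identical. This package provides the
two halves of that story and the machinery to verify it numerically:

1. a closed-form canonical decomposition of $\mathcal{A}$ that exposes
   its four degrees of freedom geometrically, and
2. the affine Gaussian derivative model of (simple-cell-like) receptive
   fields, whose three (or, extended, four) shape parameters map onto
   those degrees of freedom.

## The canonical decomposition

From the entries of $\mathcal{A}$ define
$T = (a_{11}+a_{22})/2$, $A = (a_{21}-a_{12})/2$,
$C = (a_{11}-a_{22})/2$, $S = (a_{12}+a_{21})/2$, and the radii
$P = \sqrt{T^2+A^2}$, $Q = \sqrt{C^2+S^2}$. For maps reasonably close
to a positive multiple of the identity (operationally: $P > 0$ and
$\rho_2 = P - Q > 0$),

$$\mathcal{A} \;=\; \mathcal{R}_{\psi/2}\, \mathcal{R}_{\varphi/2}\,
  \operatorname{diag}(\rho_1, \rho_2)\,
  \mathcal{R}_{\varphi/2}\, \mathcal{R}_{-\psi/2},$$

with $\rho_1 = P + Q$, $\rho_2 = P - Q$ the singular values,
$\varphi = \operatorname{atan2}(A, T)$ the total rotation, and
$\psi = \operatorname{atan2}(S, C)$ twice the orientation of the
symmetry axis of the non-isotropic stretch. Equivalently this is an SVD
$\mathcal{R}_\alpha \operatorname{diag}(\rho_1,\rho_2)
\mathcal{R}_\beta^T$ with $\alpha = (\psi+\varphi)/2$,
$\beta = (\psi-\varphi)/2$, and with both outer factors guaranteed to
be rotations. The geometric reading: uniform scale
$S = \sqrt{\rho_1\rho_2}$, total rotation $\varphi$, stretch
$\lambda = \rho_1/\rho_2$ about a preferred axis at angle $\psi/2$.

```{r decompose}
A <- affine_map(1.5, 0.5, 0.5, 1.5)
affine_decompose(A)
```

### Numerical choices

* **Angles** are extracted with the two-argument arctangent, not the
  ratio forms $\tan\varphi = A/T$, $\tan\psi = S/C$, so the
  $T \le 0$ and $C \le 0$ quadrants are handled; branches are
  $\varphi, \psi \in (-\pi, \pi]$, hence symmetry-axis orientation
  $\psi/2 \in (-\pi/2, \pi/2]$.
* **Similarity transforms** ($Q = 0$) leave $\psi$ undefined — any
  value reproduces $\mathcal{A}$. The canonical choice $\psi = 0$ is
  used and flagged in the result; the guard $Q < 10^{-14} P$ prevents
  round-off noise from manufacturing an arbitrary axis.
* **Out-of-regime maps** ($\rho_2 \le 0$, e.g. reflections) raise an
  error by default; `permissive = TRUE` returns factors flagged
  `valid = FALSE` instead. $P = 0$ (symmetric traceless maps) is
  reported as degenerate.
* With `verify = TRUE` the reconstruction is checked against the input
  at a tolerance of $10^{-10}$ relative to the max-norm.

## Viewing geometry

Two standard projection models supply affine maps with physical
parameters. Monocular: a patch at distance $\Lambda$ and slant $\nu$
(tilt along the second axis) maps by
$\mathcal{A} = \Lambda^{-1}\operatorname{diag}(1, \cos\nu)$, so the
decomposition yields stretch $1/\cos\nu$ and scale
$\sqrt{\cos\nu}/\Lambda$ for every valid $(\Lambda,\nu)$. Binocular: a
cyclopean observer with half-vergence $\mu$, gaze $\gamma$ and depth
gradient $(Z_X, Z_Y)$ induces an upper-triangular disparity-gradient
map whose lower-left entry is structurally zero. The package only
enforces non-vanishing denominators ($\cos(\gamma+\mu)$,
$\cos\mu - Z_X\sin\mu$); physically meaningful configurations keep
both positive. Deformation fields $(\mathcal{A}-\mathcal{I})x$ over a
unit square are available for visualization (CSV and quiver PNG).

## The receptive-field model

The affine Gaussian kernel $g(x;\Sigma)$ has covariance
$\Sigma = \Sigma(\sigma_1, \sigma_2, \varphi)$ with eigenvalues
$\sigma_1^2, \sigma_2^2$ and first eigendirection at angle $\varphi$.
Receptive fields are scale-normalized directional derivatives,

$$T(x) \;=\; \sigma_1^{m_1}\sigma_2^{m_2}\,
  \partial_\theta^{m_1}\, \partial_{\perp\theta}^{m_2}\, g(x;\Sigma),$$

evaluated by expanding the directional operators binomially into
Cartesian partials, each of which is a Hermite-type polynomial times
the Gaussian (computed by an exact polynomial recursion, so no
symbolic algebra and no finite differencing is involved). The aligned
first- and second-order cases ($\theta = \varphi$, $m_2 = 0$) also
have hand-written closed forms, `simple_cell_value()`, cross-checked
against the general path and against high-order finite differences in
the tests. One normalization note: the per-order factor is
$\sigma_1^{m_1}\sigma_2^{m_2}$ — one scale power per derivative order
along each axis — which reduces to the conventional $\sigma_1^m$ when
all derivatives are taken along the kernel orientation.

Shape descriptors: size $\bar\sigma = \sqrt{\sigma_1\sigma_2}$ and
eccentricity $\epsilon = \sigma_2/\sigma_1$. These correspond
one-to-one to the uniform scale $\sqrt{\rho_1\rho_2}$, the (inverse)
stretch $\rho_1/\rho_2$, and the rotation $\varphi$ of the affine
decomposition. The fourth affine degree of freedom has no counterpart
in the aligned three-parameter model; the package therefore also
implements the two published extensions: free differentiation
directions ($\theta \ne \varphi$, `general_directional_value()`), and
steering (below).

## Covariance verification

`verify_affine_covariance()` tests
$L'(\mathcal{A}x;\ \mathcal{A}\Sigma\mathcal{A}^T) = L(x;\Sigma)$ on
synthetic imagery: smooth the source, warp the image, smooth the warp
at the transformed covariance, interpolate at mapped positions,
compare over the interior. Design choices that matter for the numbers:

* **Stimuli** are seeded periodic band-limited Gaussian noise (Fourier
  cutoff at wavelength $\ge 4$ px, typically 8 px) and drifting
  gratings — smooth enough that discretization, not aliasing,
  dominates. They are pure functions of their spec, seed included.
* **Warping and sampling** use separable Catmull-Rom cubic
  interpolation with reflective boundaries; on the centred pixel grid,
  90-degree rotations are exact pixel permutations, giving a
  zero-interpolation-error reference case.
* **Convolution** is truncated-kernel spatial accumulation by default
  (truncation behaviour explicit); an FFT path gives identical results
  to round-off and is used where kernels are large.
* **Truncation**: sampled kernels default to $4\sigma$ (discrete mass
  deficit $\approx 10^{-4}$). The verification driver uses $6\sigma$,
  because the $4\sigma$ mass deficit is resolution-independent and
  would floor the error, masking the first-order convergence property
  (halving the pixel spacing must at least halve the interior RMS
  error; measured ratios are near 0.1, interpolation being the
  dominant, higher-order term).
* **Interior margin**: a band of kernel-truncation width plus the
  interpolation stencil (plus velocity displacement in space-time) is
  excluded; the identity is exact only in the continuum and away from
  boundary effects.

For spatio-temporal data the separable model
$T(x,t) = g(x - vt;\Sigma)h(t;\tau)$ is used, with $h$ a unit-mass
Gaussian of variance $\tau$ — the temporal kernel's shape is not
constrained by the covariance results used here, only its variance, so
the non-causal choice is the simplest adequate one. Under a pure
spatial affine transform ($t' = t$) the covariance identity holds with
$\Sigma' = \mathcal{A}\Sigma\mathcal{A}^T$ and $\tau' = \tau$. For the
velocity parameter the package exposes two rules: `"equal"`
($v' = v$), which is exact when $v = 0$ (the separable case used in
the acceptance tests), and `"map"` ($v' = \mathcal{A}v$), which the
convolution algebra shows to be the exact rule for velocity-adapted
kernels — the test suite demonstrates that `"map"` beats `"equal"`
whenever $v \ne 0$. Both are provided because published statements of
the result are ambiguous on this point.

## Steering and response matching

For a fixed $\Sigma$, the order-$m$ directional derivative at any
angle lies in the $(m{+}1)$-dimensional span of Cartesian partials
$\partial_{x_1}^i\partial_{x_2}^{m-i} g$, so $M \ge m+1$ responses at
sufficiently different angles suffice to synthesize any other:
`steer_coefficients()` solves the linear system in that
monomial-coefficient space (least squares when $M > m+1$) and reports
an independent pointwise kernel residual. "Sufficiently different" is
operationalized as a condition estimate below $10^6$; repeated angles
(mod $\pi$) are rejected. `match_responses()` does the corresponding
job across an affine transformation — least-squares fit of warped
source responses against a basis of transformed-domain responses —
since no closed-form construction of those coefficients exists for
general maps and $m \ge 2$; for $m = 1$ the closed-form route
(gradient transformation $\mathcal{A}^{-T}$ composed with steering)
agrees with the fit, which the tests check. For $m \ge 2$ the
eigendirection pair alone is an insufficient basis; the implementation
enforces $M \ge m+1$ and conditioning rather than a formula for the
number of extra directions.

## Semigroup cascade

Gaussian convolution adds covariances:
$g(\cdot;\Sigma_1) * g(\cdot;\Sigma_2) = g(\cdot;\Sigma_1+\Sigma_2)$.
`cascade_smooth()` carries any already-computed response (including
derivative responses) from $\Sigma_1$ to $\Sigma_2$ by convolving with
$g(\cdot;\Delta\Sigma)$, $\Delta\Sigma = \Sigma_2 - \Sigma_1$,
provided $\Delta\Sigma$ is symmetric positive definite; a zero
increment is the identity and an indefinite increment is rejected
naming the offending eigenvalue. This is the computational basis for
obtaining coarser-scale receptive fields from a single finest-scale
layer.

## What a green test establishes — and what it does not

The synthetic stimuli are periodic, band-limited, and noise-free; real
imagery is none of these. The covariance checks therefore establish
correctness of the discrete implementation of a continuum identity (to
interpolation/discretization accuracy, with measured convergence), not
robustness to sensor noise, aliasing, or boundary content. Geometry
maps are first-order linearizations: nothing here models full
perspective nonlinearity, camera calibration, or estimation of
$\mathcal{A}$ from image data (shape-from-texture/disparity inference
is out of scope). The decomposition applies to maps near a positive
scalar multiple of the identity ($\rho_2 > 0$); reflections and
half-turn-dominated maps are outside the regime by design. Interpolation
error in warping scales roughly like $(\text{spacing}/\text{wavelength})^4$,
so round-trip figures quoted for band-limited noise assume content
wavelengths of 12 px and above at unit spacing.

## Defaults worth knowing

| Parameter | Default | Why |
|---|---|---|
| kernel truncation (`sample_kernel`, `smooth_field`) | $4\sigma$ | mass deficit $\sim 10^{-4}$, standard display/convolution radius |
| truncation in `verify_affine_covariance` | $6\sigma$ | keeps truncated mass below discretization error (convergence check) |
| similarity threshold `q_tol` | $10^{-14}$ | round-off guard for the $\psi = 0$ convention |
| steering condition limit | $10^6$ | operational reading of "sufficiently different directions" |
| noise cutoff | 8 px | discretization-dominated regime at unit spacing |
| stretch limit in verification | 4 | keeps warped kernels within frame |
| eccentricity gallery endpoint | 1/4 | published range end is unspecified; one octave beyond half |
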