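---
title: "Derivatives and inverses of cascaded L+NL vision models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivatives and inverses of cascaded L+NL vision models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnlcascade)
```

## The model

`lnlcascade` implements feed-forward cascades of linear+nonlinear (L+NL)
modules, the standard skeleton of models of the visual pathway: the response
to a vectorized stimulus $x^0 \in \mathbb{R}^{d_0}$ is
$S = S^{(n)} \circ \dots \circ S^{(1)}$ with each layer
$S^{(i)}(x) = N^{(i)}(L^i x)$, a filter bank followed by a saturating
(possibly interacting) nonlinearity.  The package's point is everything
*beyond* the forward transform:

* **the Jacobian w.r.t. the stimulus**, $\nabla_{x^0} S = \prod_{i=n}^{1}
  \nabla_{y^i} N^{(i)} L^i$, which carries the adaptive receptive fields,
  the perceptual metric $M(x) = J^\top J$, the sensitivity
  ($\det M$ is inversely proportional to the volume of the discrimination
  region) and the multi-information reduction of the code;
* **the Jacobian w.r.t. the parameters**, assembled per layer from
  $\nabla_\theta N$ and, for the linear weights, $\nabla_y N \cdot
  B({x^{i-1}}^\top)$ (a block replication of the layer input), which drives
  gradient-based fitting;
* **the analytic inverse**, $S^{-1} = {S^{(1)}}^{-1} \circ \dots \circ
  {S^{(n)}}^{-1}$ with ${S^{(i)}}^{-1}(x) = {L^i}^\dagger N^{-1}(x)$, which
  turns model-based decoding into a sequence of matrix solves.

Three nonlinearity families are provided.

**Divisive normalization** (canonical): $x = D_{\mathrm{sign}(y)}
D^{-1}_{b + He}\, e$ with energies $e = |y|^\gamma$.  Its stimulus Jacobian
is the subtraction of a diagonal term and an $H$-coupled term; its inverse
reduces to solving $(I - D_{|x|} H)\, e = b \odot |x|$, which exists while
the spectral radius of $D_{|x|} H$ stays below 1 —
`dn_invertibility_margin()` reports that radius, and the packaged example
model is sized so it stays near 0.3 on the synthetic fixture grid.  The
interaction kernel can be parameterized as intra-subband Gaussians
(amplitude $c_k$ = total interaction pool, width $\sigma_k$ in deg), with
optional binary structure matrices sharing one value per subband;
derivatives w.r.t. $\sigma$ and $c$ are analytic.  A note on the
$\sigma$/$c$ derivatives: since $\sigma_k$ enters only row $k$ of $H$, the
per-sensor derivative is the row contraction $(F e)_k$ of the
derivative kernel; the finite-difference oracle in the test suite is the
arbiter of this form.

**Wilson–Cowan steady state**: $x$ solves $0 = -\alpha x + \mu W f(x) +
\lambda y$.  The inverse is closed form; the forward map is computed by a
damped fixed-point iteration (damping 0.8, tolerance $10^{-10}$, cap
10\,000) followed by a Newton polish to near machine precision, so that
finite differences of the forward map are clean.  A sufficient contraction
condition $\alpha > |\mu|\, \lVert W \rVert_\infty \sup |f'|$ is enforced at
construction (it is sufficient, not necessary; configurations violating it
are rejected rather than risked).  The sigmoid is a named, swappable spec;
`tanh` with unit slope is the default since no canonical choice exists.

**Two-gamma tone mapping**: $x = \mathrm{sign}(y) |y|^{\gamma(|y|)}$ with
the exponent easing from $\gamma_L$ (low inputs) to $\gamma_H$ around the
transition point $\mu_1$ with sharpness $m$.  The derivative involves
$\log|y|$ and $1/|y|$, so below a patch radius $\varepsilon$ (default
$10^{-3}$ in normalized input units) the curve is replaced by the quadratic
$a_1 |y|^2 + a_2 |y|$ whose coefficients make value and slope continuous at
$\varepsilon$; a unit test verifies the $C^1$ property numerically.  The
inverse has no closed form (the exponent depends on the input); each
component is bracketed and root-found to $10^{-13}$, and non-monotone
parameter combinations are rejected at construction after a grid check.

Two conventions are fixed package-wide: stimuli are vectorized
last-dimension-first (bands fastest, then columns, then rows), and matrix
parameters are vectorized **row-wise** wherever a parameter Jacobian is
involved (`jacobian_params()`, `pack_params()`), so a perturbation
$\Delta L$ is applied as $\mathrm{vect}(\Delta L^\top)$.
$\mathrm{sign}(0) = 0$ everywhere; consequently the divisive-normalization
Jacobian is null at exactly zero drives, and for $\gamma < 1$ the
$|y|^{\gamma-1}$ factor is clamped at $|y| = 10^{-6}$ (stimulus units)
inside the Jacobian only.

## Worked models

`build_cartoon_model()` is the three-pixel, two-layer system used for every
closed-form cross-check: brightness $x^1 = (y^1)^{\gamma_1}$ followed by
printed DC/low/high frequency analyzers $F$ (orthonormal to their printed
3-decimal precision, $|\det F| = 0.99945$), band-pass gains
$G = \mathrm{diag}(0.8, 1, 0.2)$ and a saturating contrast response with
identity interaction kernel.  $\gamma_1$ defaults to 0.65 (the one
experimentally anchored exponent) and $b$ to 1, chosen so the layer-2 drives
are $O(1)$; neither value is canonical and all numeric checks involving them
are equalities between the closed forms and the generic machinery, valid for
any admissible values.  Because the closed-form sensitivity is an exact
equality test here, it includes the $\det(F)^2$ factor that an exactly
orthonormal analyzer would make 1.

`build_reduced_fourlayer()` is a desk-scale analog of the full
brightness / contrast / CSF-masking / wavelet-masking program on
`size x size` luminance images.  Design choices, made once:

* the image subtends 1 degree (`samples_per_deg = size`), the natural
  reduction of a foveal patch; all interaction scales are tied to the pixel
  grid so behavior is resolution-independent;
* the contrast stage uses $L = I - 0.9 B$ (local-mean kernel $B$): the pure
  deviation operator annihilates constant images and would destroy
  invertibility, so 10% of the mean is let through;
* the CSF stage is a high-frequency-emphasis filter $1.5 I - 0.5 B$,
  a band-pass-like gain with spectrum in $[1, 1.5]$ (invertible by
  construction) rather than a calibrated human CSF;
* the wavelet stage is an exactly orthonormal two-scale separable Haar
  transform built in code, with intra-subband Gaussian kernels of one
  coefficient-spacing width;
* semisaturations at the wavelet stage (0.25 in detail subbands, 1.5 in the
  approximation) are sized so responses reach $O(1)$–$O(4)$: response noise
  with a fixed Fano factor has relative size $\sqrt{F/|r|}$, so a model with
  $O(0.1)$ responses would drown in 30–100% relative noise while a
  calibrated model sits at a few percent;
* interaction pools $c$ are small enough that $|x| \cdot c$, an upper bound
  on the invertibility radius, stays well below 1 on the fixture grid
  (`invertibility_sweep()` measures ~0.3).

The exact psychophysically calibrated parameters of the full-scale model are
intentionally out of scope; none of the package's checks depend on them.

## Applications

**MAD synthesis** (`mad_run()`, `eigen_mad()`): on the sphere of fixed RMSE
around a reference, gradient steps on the perceptual distance are projected
back by removing the component parallel to the Euclidean-distance gradient
and solving the projection constant $\nu$ analytically (of the quadratic's
two real roots we take the one nearest the pre-projection point, which
reduces to a radial rescale).  The step is $0.1 \times$ radius by default,
halved on failure, so the distance trace is monotone by construction.  The
initial point is seeded white noise scaled to the sphere.  The second-order
solution takes the extremal eigenvectors of $M(x_A)$; in patch mode the
metric is block-diagonal and the global extremal eigenvector is a per-patch
eigenvector embedded at the winning patch (ties broken at the lowest index
and flagged).

**Fitting** (`fit_cascade()`): quadratic response-matching, Pearson
alignment with mean opinion scores (including the centering matrix and the
per-item response-difference rows; items with numerically zero response
difference are dropped with a warning, as their normalization is undefined),
and an inverse-consistency cost built from
$\nabla_\Theta S^{-1} = -(\nabla_{x^0} S)^{-1} \nabla_\Theta S$.
Positivity of $\gamma, b, \sigma, c$ is maintained by optimizing logs.  Two
drivers: a backtracking gradient method (monotone accepted steps,
mini-batches, early stopping on a held-out split with patience 20) and an
L-BFGS refinement via `stats::optim()` with the analytic gradients, the tool
of choice for noiseless parameter recovery (it recovers a small
divisive-normalization layer's $\gamma$, $b$ and kernel $\sigma$ from 500
samples to well under 1%).

**Decoding** (`cascade_inverse()`, `simulate_measurement()`,
`evaluate_decoding_grid()`): measurements are simulated as the forward
response to an input corrupted by Gaussian noise, blurred per subband
(width in degrees, converted through each subband's own sampling density)
and distorted by additive Gaussian noise of variance $F |r|$ per
coefficient — responses can be negative, so a literal Poisson draw is
undefined and the Fano variance-to-mean-magnitude ratio is the property
kept.  Baselines are multivariate ridge regression and RBF kernel ridge
regression with the closed-form leave-one-out selector for the ridge
strength (no pre-installed package offers multi-output kernel ridge, so the
ten-line standard construction is done here).  The grid evaluation trains
the baselines on pairs from the central luminance/contrast cell only and
averages the mean absolute error over several test draws per cell
(`n_test = 8` in the acceptance suite), because at $16 \times 16$ pixels a
single draw's MAE is dominated by one noise realization, whereas large
images self-average.  Rectangular linear stages are pseudo-inverted with an
optional ridge on the squared singular values; what a fat stage discards
(metamerism) is unrecoverable by construction and the round trip returns the
row-space projection.

## Synthetic data

All test inputs are generated, seeded, and self-audited:

* `generate_image_grid()` draws $1/f$ Gaussian fields and rescales them
  affinely to each cell's mean luminance and RMS contrast
  (`sd/mean`; the paper-style contrast definition is not fixed anywhere, so
  RMS is assumed and isolated in this one generator).  A Gaussian field
  cannot reach contrast 0.9 inside a bounded positive display range, so the
  standardized field is iteratively clamped to the per-cell feasible bound
  and re-standardized; the targets are then met exactly, at the price of an
  increasingly bimodal pixel distribution at high contrast — the same
  regime real high-contrast scenes occupy.  Cells whose bound is infeasible
  would be flagged; none are on the default grid (luminances 25–80 cd/m² on
  a 0–160 cd/m² display, contrasts 0.1–0.9, 7×9 cells).
* `generate_three_pixel_ensemble()` draws AR(1)-correlated triplets
  (neighbor correlation 0.9) standardized per sample, so every sample has
  exactly the requested mean and RMS contrast.
* `generate_mos_dataset()` builds quality-rating data from a known cascade:
  random white-noise / smoothing / contrast distortions, scored through a
  saturating monotone link of the true perceptual distance plus observer
  noise.  Ground truth is retained.  Note the link's curvature means the
  Pearson-optimal semisaturation need not equal the generating one —
  exactly as with real opinion scores.

What these generators do *not* emulate: phase structure, edges and
occlusions of natural images, spatial nonstationarity, and any
observer-specific rating biases.  Tests passing on them certify the
calculus (Jacobians, inverses, gradients and their consistency), not
ecological validity of the worked models.

## Numerical choices

* Finite-difference oracle: central differences, step
  $10^{-6} \max(1, |x_j|)$ per coordinate; for Jacobians w.r.t. the full
  parameter vector of a multi-layer cascade the tests use $10^{-5}$, which
  balances truncation against roundoff accumulated through the layers.
* Divisive-normalization series inverse: truncated Neumann expansion,
  default order 10, with an a-posteriori residual check against
  $10^{-8}$ (warning, not silent acceptance).
* Entropy estimator for the multi-information reduction: equal-width
  histograms with $\lceil n^{1/3} \rceil$ bins, Miller–Madow bias
  correction, plus the $\log_2$ bin-width differential term.  The Jacobian
  term $E[\log_2 |\det \nabla S|]$ may be computed on a seeded subsample,
  since the entropies are vectorized but the per-sample Jacobians are not.
* Pseudoinverse ridge: added to the squared singular values; condition
  numbers above $10^8$ raise a warning.

## Known limitations

* The identity `delta_MI = delta_h + jac_term` holds by construction; the
  *flatness* of the marginal-entropy term across the luminance/contrast
  plane, reported for the full calibrated model, does **not** hold for the
  cartoon model at any parameterization we examined: the input marginal
  entropies scale as $3\log_2(\mathrm{lum} \cdot \mathrm{con})$ while the
  saturated responses only partially track that scale, so the
  marginal-entropy term varies by the same order as the multi-information
  reduction itself.  The corresponding assertion in the acceptance suite is
  kept at its stated threshold and fails honestly.
* Only feed-forward cascades and steady states: no temporal dynamics, no
  feedback, no video stimuli.
* The Wilson–Cowan contraction check is sufficient, not necessary; valid
  but non-contracting regimes are rejected.
* Parameter Jacobians are implemented for divisive normalization (the
  canonical case); Wilson–Cowan and two-gamma layers contribute only their
  linear weights to the parameter vector.
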