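---
title: "Methods: segmentation, normalization, wavelet-PCA features and SVM verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, normalization, wavelet-PCA features and SVM verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irispipe)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter and their defaults, the conventions
that had to be pinned for results to be reproducible, and what the
synthetic cohorts do and do not demonstrate.

## The verification problem

Iris verification asks: given an eye image and a claimed identity, should
the claim be accepted? The iris — the textured annulus between the dark
pupil and the white sclera — carries enough stable, person-specific
structure to answer this reliably, provided the annulus can be (i) located,
(ii) brought to a canonical geometry so captures of the same eye are
comparable, and (iii) summarized by features compact enough for fast,
robust matching. The pipeline implements those three steps plus the
decision stage.

## Segmentation: edge map and circular Hough voting

The pupil and limbic boundaries are modeled as circles
$(x-x_c)^2 + (y-y_c)^2 = r^2$. The image is smoothed with a 3×3 box filter
(to keep single-pixel noise out of the gradient), differentiated by
centered finite differences, and the gradient magnitude thresholded at a
quantile of its nonzero values (`edge_thresh_quantile`, default 0.985).
Each surviving edge pixel votes in a 3-D accumulator over integer centers
and radii; the peak cell gives the circle.

Numerical conventions are pinned because they are observable in results:

* an edge pixel votes for center $(y_c, x_c)$ at radius $r$ iff the
  *rounded* euclidean distance between them equals $r$ (the synthetic
  circle masks in the test suite use the same membership rule, which makes
  exact-recovery assertions well-posed);
* peak ties break to the smallest radius, then row-major center order, so
  the output is deterministic;
* coordinates are 0-based, row = y downward, column = x rightward.

Two passes are made. The pupil pass uses unweighted gradients and the
pupil radius window (default 15–35 px). The limbic pass multiplies the
x-derivative — the detector of *vertically oriented* edges — by
`vertical_weight` (default 4) before thresholding. Eyelids run
horizontally, so their edges excite the y-derivative only; after weighting
they fall below the quantile threshold while the left and right arcs of
the limbic boundary survive. The limbic center is constrained to within
15 px of the pupil center, the radius window defaults to 55–90 px, and
pupil-inside-iris is enforced; on violation the segmentation retries once
with the magnitude threshold halved before raising an error that carries
both candidate circles.

Two parameter choices deserve a note. The radius windows are not
universal constants; they are matched to the geometry the synthetic
generator produces and must be reconfigured for other optics. The edge
threshold default of 0.985 was chosen because the iris texture's internal
gradients reach roughly half the boundary contrast: a looser threshold
admits enough texture edges that, for small pupils (whose boundary has few
perimeter pixels, with votes further split across neighboring accumulator
cells by the integer grid), a texture-fed circle can out-vote the true
boundary. Keeping only the top 1.5% of gradient magnitudes isolates the
boundary arcs while leaving enough pixels for robust voting.

The voting loop is implemented in C++ (Rcpp): the accumulator update is a
per-pixel, per-radius scatter that dominates the pipeline's cost. The test
suite checks it cell-for-cell against a brute-force R voter on small
inputs, together with translation equivariance and radius-window
monotonicity of the peak.

## Normalization: the rubber-sheet model

The annulus between the two circles is mapped to a fixed
`radial_res × angular_res` rectangle, $I[x(r,\theta), y(r,\theta)] \to
I(r,\theta)$. Column $j$ samples $\theta_j = 2\pi j/\texttt{angular\_res}$
(half-open grid; $\theta = 0$ on the positive x-axis, increasing toward
positive y). Row $i$ samples $t_i = i/(\texttt{radial\_res}-1)$,
inclusive at both ends, and the sample point is the per-angle blend
$(1-t_i)\,P(\theta_j) + t_i\,L(\theta_j)$ of the pupil-boundary point into
the limbic-boundary point. The blend handles non-concentric circles
without a common-center approximation. Intensities are bilinear
interpolated; the rare sample outside the image is clamped to the border
and counted in the template metadata rather than raised as an error, which
keeps slightly off segmentations usable while remaining visible.

Defaults are 60 radial × 300 angular samples, giving the 60 × 300 template
whose one-level wavelet decomposition is 30 × 150. Endpoint inclusivity of
the radial grid is a convention of this implementation, not a fact forced
by the model. A `rotate_template()` utility applies circular column
shifts (one column = $2\pi/300$ of in-plane rotation); the test suite
verifies that rotating a concentric source pattern by $2\pi k/300$ shifts
template columns by exactly $k$ up to interpolation error.

## Feature extraction: one-level DWT, LL selection, PCA

A separable one-level discrete wavelet transform splits the template into
four half-resolution sub-bands LL, LH, HL, HH; only the LL approximation
is retained for matching, halving each template dimension before any
statistics are estimated. The filters are orthonormal (Haar default; db2
and db4 available) with periodized convolution, so energy is conserved and
the inverse transform reconstructs exactly — both asserted in tests, the
Haar case against an explicit 2×2 block-sum oracle. Odd input dimensions
are extended by replicating the last row/column (templates are even-sized
by default, so this is a robustness path, flagged in metadata).

PCA is then fitted on the flattened (row-major) enrollment LL vectors:

1. mean $x_m = \frac{1}{N}\sum_k x_k$;
2. centering $x_z = x_i - x_m$;
3. scatter matrix $c = X_z^{\mathsf T} X_z$ — deliberately without a
   $1/N$ normalizer: eigenvectors are unaffected by the scaling and the
   eigenvalues are documented as unnormalized scatter eigenvalues;
4. eigenpairs $(\gamma_i, e_i)$ of $c$, sorted by $\gamma$ descending.
   When the dimension $d$ (4500 for the default template) exceeds the
   sample count $N$, the $N \times N$ Gram matrix $X_z X_z^{\mathsf T}$ is
   diagonalized instead and its eigenvectors mapped back through
   $X_z^{\mathsf T}$ and renormalized — the eigen-iris identity. The test
   suite checks the two routes agree to $10^{-8}$ at $N = 10$, $d = 50$;
5. projection $f = E_k^{\mathsf T}(x - x_m)$.

Eigenvector signs are fixed by making each vector's largest-magnitude
entry positive; without a pinned sign, serialized models and frozen test
expectations would be ambiguous. The retained dimension `k` defaults to
the smallest number of components covering 95% of $\sum\gamma$, capped at
$N-1$ (the centered scatter's maximal rank); it may also be set to a fixed
integer. Degenerate training sets (all vectors identical) produce a valid
model with all $\gamma = 0$ and an empty projection rather than an error.

The compression argument of this design is dimensional: whatever the image
resolution, the matcher operates on at most $N-1$ numbers per template,
and the DWT quarters the pixel count before the PCA is even fitted, which
is what makes enrollment-time eigendecomposition and test-time projection
cheap.

## Matching: per-subject linear SVMs

Verification is framed as one binary decision per enrolled subject: a
maximum-margin hyperplane $w \cdot x + b = 0$ with
$y_i(w \cdot x_i + b) \ge 1$ on separable data, trained one-vs-rest
(subject's enrollment features against everyone else's). Training is
delegated to libsvm (via e1071) with a linear kernel, soft-margin penalty
`svm_c` (default 1.0), and a tight optimizer tolerance so the recovered
$(w, b)$ is reproducible to about $10^{-6}$; the hyperplane is then stored
explicitly and oriented so the enrolled subject scores positive. The
two-point-per-class toy with classes at $(\pm2, 0), (\pm3, 0)$ has the
hand-derivable solution $w = (0.5, 0)$, $b = 0$ (support vectors at
$\pm2$, margin $2/\lVert w \rVert = 4$), which the test suite asserts.

A claim of subject $s$ with feature vector $f$ is accepted iff
$w_s \cdot f + b_s$ strictly exceeds the decision threshold (default 0; a
score exactly on the hyperplane is rejected). The threshold is exposed to
move along the FAR/FRR trade-off.

Evaluation runs, for every test vector, one genuine claim and one impostor
claim against a wrong identity drawn per true subject from the other
enrolled subjects under `protocol_seed`. Drawing the wrong identity per
subject (not per vector) makes the report invariant to test-order
permutation, which is asserted as a property. The metrics are

$$\mathrm{FAR} = \frac{IA}{IA+IR}\cdot 100,\qquad
\mathrm{FRR} = \frac{GR}{GA+GR}\cdot 100,\qquad
\mathrm{accuracy} = \frac{GA+IR}{GA+GR+IA+IR}\cdot 100,$$

with FAR reported as `NA` when no impostor trials exist. These formulas
are declared conventions of this package; published FAR/FRR figures are
not always accompanied by their trial designs, so cross-paper comparisons
need care.

## The synthetic generator: what it emulates and what it does not

`render_eye()` draws a dark pupil disc (≈30), a textured iris annulus
(base 120), and bright sclera (220) on an 8-bit canvas, adds Gaussian
noise, clips and rounds. The iris texture is a sum of five radial/angular
sinusoids — amplitudes 15–35, angular harmonics 3–16, up to five radial
half-waves, with phases drawn from a generator seeded by
`(subject_id, texture_seed)` — evaluated in the annulus coordinates the
rubber-sheet model uses. That gives band-limited, per-subject-distinctive,
bit-reproducible texture with no external assets, and it makes
same-subject captures map to nearly identical templates even under capture
jitter. Optional occlusion covers a fraction of the iris top and bottom
with bright horizontal bands, emulating eyelids only in their alignment.

`make_cohort()` renders repeated captures per subject sharing the texture
identity but differing in noise realization, a ≤3 px center jitter and a
≤1 px relative pupil offset. Defaults — 280×320 px images, pupil radii
15–35 px, iris radii 55–90 px, noise sd 8 — were chosen once as a
realistic small-image regime: boundary contrasts are tens of intensity
units against single-digit noise, and the pupil/iris radius ratio spans
roughly 0.2–0.6 as in near-infrared captures.

What the cohorts do **not** contain: real iris microtexture (crypts,
furrows — the synthetic texture is far smoother and more periodic),
specular highlights, eyelashes, off-axis gaze, pupil dilation between
captures, sensor vignetting, or contoured eyelids. Passing the end-to-end
cohort criteria therefore demonstrates that the pipeline's stages compose
correctly and recover known ground truth under noise and jitter — it does
not predict accuracy on real gated-database imagery, and the package makes
no such claim.

## Numerical choices and degenerate inputs

* Constant images yield an empty edge map (not an error); fewer than 8
  edge pixels is a segmentation failure.
* The segmentation retry relaxes the *magnitude* threshold (halved), not
  the quantile, so the retry is monotone: it can only add edge pixels.
* Out-of-bounds rubber-sheet samples clamp to the border and increment a
  metadata counter.
* Serialization of templates and PCA models uses a JSON header plus raw
  little-endian float64 payload, so round trips are bit-exact; SVM
  hyperplanes are stored as full-precision JSON.
* Color inputs are converted by ITU-R BT.601 luminance weights; images are
  handled as 0-based (row, col) matrices on the 0–255 scale throughout.
* All stochastic steps (texture, noise, jitter, impostor draws) run under
  locally scoped seeds derived from user-supplied integers; the caller's
  RNG state is never disturbed.

## Problem sizes used by the checks

The property suites run on deliberately small instances chosen to make
brute-force oracles exact and fast: Hough equivalence on ≤64×64 masks,
DWT oracles on matrices up to 60×300, PCA cross-checks at $N=10$, $d=50$.
The cohort-scale checks use 100 images (20 subjects × 5 captures, noise
sd 8) for segmentation recovery and 20 subjects × (5 enroll + 5 test) for
the end-to-end verification report. These sizes give stable pass/fail
behavior across seeds while keeping a full run in the low minutes on one
core.

## Known limitations

* No eyelid/eyelash masking: occluded template rows enter the feature
  vector; heavy occlusion degrades matching.
* Circle-only boundary model; strongly elliptical boundaries (off-axis
  gaze) will segment poorly.
* The Hough accumulator is integer-grid; sub-pixel boundary localization
  is out of scope (errors of ±1 px are expected and tolerated downstream).
* One-vs-rest training cost grows with the enrolled population; at very
  large galleries a shared multi-class formulation would be preferable.
* The PCA basis is fixed at enrollment; adding subjects requires refitting
  (no incremental update).
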