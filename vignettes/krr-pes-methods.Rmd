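---
title: "Kernel ridge regression potentials: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel ridge regression potentials: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krrpes)
```

This vignette is the package's account of the science it implements: the
regression model and its assumptions, the parameters that matter, what the
synthetic data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## The regression model

A scalar molecular property (we will say "energy", but the library is
unit-agnostic) is modeled as a kernel expansion over training geometries:
$$\hat f(\mathbf{x}) = \sum_{j=1}^{N_{tr}} \alpha_j\, k(\mathbf{x}, \mathbf{x}_j),
\qquad (\mathbf{K} + \lambda \mathbf{I})\,\boldsymbol\alpha = \mathbf{y}.$$
The model is nonparametric: the training descriptors are part of the model,
and after hyperparameter selection the final model is retrained on the
*whole* training set (sub-training plus validation), because discarding the
validation points would waste reference data.

Assumptions worth keeping in mind:

* the property is a smooth function of the descriptor — kernel length
  scales are meaningful only if the descriptor resolves the physics;
* training labels are either exact (interpolation, small $\lambda$) or
  carry roughly homoscedastic noise (regression, larger $\lambda$);
* a single molecule: all geometries share one element sequence (the
  Coulomb matrix can pad across sizes, but every workflow here is
  single-molecule).

### Descriptors and their derivatives

The RE descriptor ($x_d = r^{\mathrm{ref}}_d / r_d$ over all atom pairs in
lexicographic order $(a,b), a<b$ — the canonical order used everywhere, as
no standard fixes one) is rotation- and translation-invariant and complete,
but not invariant under permutations of same-element atoms.  Three
treatments are provided, in increasing fidelity and cost:

1. *unsorted* — ignore the problem;
2. *sorted* — reorder homonuclear atoms by descending nuclear-repulsion
   sum (CM: by descending row norm).  Sorting restores invariance at the
   price of discontinuities in the interpolant; ties are broken by the
   original atom index so the map is deterministic.  For sorted RE the
   reference and the query are each sorted by their own repulsion sums;
   sorting one against the other's order would make the descriptor depend
   on which geometry is called "reference", which we judged less
   defensible.  Sorted variants expose no analytic Jacobian;
3. *permuted* — the normalized symmetrized kernel
   $$\bar k(M, M_j) = \frac{\sum_P k(x(M), x(PM_j))}
   {\sqrt{\sum_P k(x(M), x(PM))\sum_P k(x(M_j), x(PM_j))}},$$
   which is exactly invariant and satisfies $\bar k(M, M)=1$.  Its
   Cartesian gradient includes the self-terms from the normalization: both
   arguments of the self-sums depend on the query coordinates.  We
   implement those terms as the generic two-argument chain rule through
   the descriptor Jacobian with the permutation-induced column mapping,
   which is algebraically identical to the usual per-dimension shortcut
   but holds for any differentiable kernel, and we verify the whole path
   against central finite differences.  Permutations are enumerated as the
   full product of within-group permutations, groups left to right, each
   group in lexicographic order; the product is capped at $10!$ with an
   explicit error because cost is linear in $N_{perm}$ per kernel entry.

The Coulomb matrix uses distances in Bohr (1 Å = 1/0.52917721067 Bohr, the
only unit conversion in the package); its vectorization keeps both
symmetric halves of the padded matrix — redundant, but it matches the
matrix display practitioners expect, and the kernel is indifferent to the
duplication beyond a factor $\sqrt 2$ absorbed by $\sigma$.

### Solvers and conditioning

The regularized system is solved by Cholesky factorization, falling back
to Bunch–Kaufman (`Matrix::BunchKaufman`) and then LU with a warning; a
solution with non-finite coefficients counts as a failure so genuinely
singular systems (duplicate geometries at $\lambda = 0$) error out rather
than silently averaging.  The max-norm solve residual is stored in the
model and a warning is emitted above $10^{-6}$ — RBF kernel matrices on
densely sampled 1-D coordinates reach condition numbers of $10^{15}$
quickly, and users should know when they are in that regime.  The default
$\lambda = 2^{-35}$ is small enough not to bias interpolation visibly and
large enough to keep Cholesky stable on typical problems; every function
accepts an explicit value.

Model files are a versioned JSON container with doubles stored as
`%.17g` strings, the shortest text encoding that round-trips IEEE doubles
bit-exactly, so a reloaded model reproduces predictions identically.

## Hyperparameter selection

$\sigma$ and $\lambda$ are searched on a nested logarithmic grid: 11
points per axis in $\log_2$ space ($\sigma$ exponents 2…9, $\lambda$
exponents −35…−6 by default — brackets that cover RE-descriptor scales
from tight interpolation to heavy smoothing), three passes, each pass
re-centered one current grid step to either side of the incumbent in log
space.  Validation loss ties prefer smaller $\lambda$, then smaller
$\sigma$ — a smoothness bias that makes the search deterministic.  Losses
over multiple properties combine either as $L_{val} + w\,L_{gr}$ or as
the parameter-free geometric mean $\sqrt{L_{val} L_{gr}}$.

## Multi-step workflows

**Δ-learning** trains the correction model on `target − baseline` and adds
the user-supplied baseline back at prediction time; no hidden scaling.
The benefit is largest when the correction is smoother than the target,
which is what the test fixture constructs (a rough baseline shared by
both levels plus a long-wavelength correction).

**Self-correction** stacks layers, each fitting the residual of the sum of
its predecessors.  With interpolating layers the second layer's targets
are numerically zero; with regularized layers the in-sample residual is
provably nonincreasing because the smoother $K(K+\lambda I)^{-1}$ has
spectrum in $(0, 1]$.

**Learning curves** run fresh seeded samplings per size and repeat
(5 repeats by default).  The default keeps one fixed held-out test set
across all sizes and repeats so comparisons are paired; resampling the
test set per repeat is available and flagged in the output.  Wall-clock
columns are recorded for information only.  The decay is fit as
$\varepsilon = \varepsilon_a + a N^{-b}$ with $\varepsilon_a, a \ge 0$,
$b > 0$ by Levenberg–Marquardt with box constraints, seeded from the
log–log linear fit and multi-started from deterministic perturbations of
that seed; an optional log-residual objective is the likelihood-matched
choice when errors carry multiplicative noise, which is the usual
situation for RMSEs spanning orders of magnitude.  $a$ is the
noise-amplified parameter of the three: reliable recovery needs sizes
reaching the asymptote-dominated regime and relative-noise-aware fitting,
which is exactly how the tests operationalize their recovery check.

## The ML nuclear-ensemble spectrum pipeline

The ensemble starts with `n_batch` (default 50) points in farthest-point
order over the descriptors — FPS because the labeled set should cover the
ensemble's spread as fast as possible; random acquisition is available.
Each iteration labels `n_batch` more points, trains one model per
excitation energy and one per oscillator strength, and summarizes their
accuracy as the geometric mean of the per-model validation RMSEs.  The
per-model RMSE is estimated by 5-fold cross-validation with pooled
out-of-fold residuals rather than a single 80:20 split: at
$N_{tr} \approx 100$ a single 20 % split estimates an RMSE with ~15 %
sampling noise, which would make the relative-change criterion (threshold
0.1) fire or stall essentially at random; pooling every labeled point
keeps the 80:20 training proportion per fold while cutting the estimator
noise several-fold.  Convergence uses $|\mathrm{rRMSE}| < 0.1$: the signed
definition $(\mathrm{RMSE}_{now}-\mathrm{RMSE}_{prev})/\mathrm{RMSE}_{now}$
is negative whenever the model improves, so a literal signed reading would
declare victory on any improvement however large; the absolute-value
reading is the defensible one, and the literal signed mode is provided as
an option.  After convergence, labeled points keep their reference labels
and only the remainder is predicted; negative predicted oscillator
strengths are clipped to zero before the cross section
$$\sigma(E) = \frac{\pi e^2 \hbar}{2 m c \varepsilon_0 E}
\sum_n \frac{1}{N_p} \sum_i \Delta E_{0n} f_{0n}\,
\mathcal N(E;\, \Delta E_{0n},\, \delta/2)$$
is accumulated (CODATA constants; Å²/molecule vs photon energy in eV;
$\delta = 0.01$ eV default broadening).  The $1/E$ prefactor is evaluated
at the grid energy, as printed in the standard formulation — evaluating it
at the transition energy instead would change the band shape by
$O(\delta/\Delta E)$, negligible at the default broadening.  The default
grid spans the labeled transition-energy range padded by $10\delta$ with
step $\delta/5$.

## Synthetic data: what it does and does not show

Three PES generators (Morse diatomic with $D = 0.17$, $a = 2$ Å$^{-1}$,
$r_{eq} = 1$ Å sampled on $[0.7, 2.5]$ Å — covalent-bond scales; a
water-like harmonic triatomic; a CH$_3$-like XH$_3$ fragment whose energy
is built from permutation-symmetric polynomials of the X–H and H–H
distances) return exact analytic gradients, with optional Gaussian noise
applied to energies only, never to geometries, so descriptor tests stay
exact.  The XH$_3$ equilibrium is constructed from exact trigonometry so
its three X–H and three H–H distances agree to machine precision — an
only-approximately symmetric reference breaks permuted-kernel invariance
at the $10^{-6}$ level, far above the $10^{-10}$ the end-to-end tests
demand.

The labeled nuclear-ensemble generator displaces a water-like equilibrium
by isotropic Gaussians (width 0.05 Å by default, a stand-in for a Wigner
distribution, which it does not reproduce in width anisotropy or
mode structure), and labels each point with smooth functions of the pair
distances plus label noise (0.02 eV on energies, 0.002 on strengths —
the scale of typical TDDFT reproducibility).  A few percent of strengths
dip below zero by construction so the clipping rule is exercised.  The
"easy" convergence fixture used in the tests shrinks the displacement
width to 0.02 Å: the learnable signal is then small against the label
noise floor, the surrogate models reach that floor within the first one
or two batches, and the convergence loop terminates in two or three
iterations — it verifies the loop's logic and bookkeeping, not learning
capacity.  Passing these tests therefore demonstrates correctness of the
machinery on smooth, low-dimensional, noise-controlled surfaces; it says
nothing about accuracy on real ab initio data, conformationally flexible
molecules, or descriptors outside the implemented families.

## Numerical choices and problem sizes

* Matérn factorial terms are computed in log space and the order capped at
  20 to keep coefficients finite.
* Kernel matrices are assembled from one triangular half and mirrored, so
  symmetry is exact despite floating-point non-associativity; diagonals
  are set to 1 exactly.
* FPS breaks min-distance ties by lowest index; the first two points are
  the globally most distant pair.  SBS slices the deformation-sorted
  ensemble into 5 near-equal regions by default and interleaves slices
  proportionally to their sizes (equal-count drawing is an option) —
  whether the original platform samples slices proportionally or equally
  is not documented, and proportional keeps every prefix representative
  of the deformation distribution.
* Indices are 1-based everywhere, matching both R convention and the
  index-file format.
* Test and acceptance workloads use 30–400 point datasets and ensembles
  of a few hundred to 2000 points — sizes at which every pipeline,
  including the nested grid search and the ML-NEA loop, completes in
  seconds while leaving all scaling behavior visible on the learning
  curves.

## Known limitations

* Training on gradient labels (force matching) is not implemented — the
  kernel-Hessian machinery it needs is out of scope here.
* No predictive variance (this is ridge regression, not Gaussian-process
  inference).
* The permutationally invariant kernel enumerates permutations
  exhaustively; molecules with many equivalent groups hit the $10!$ cap.
* User-supplied descriptors carry no Jacobian, so gradient prediction is
  refused for them, as it is for sorted descriptor variants.
* The learning-curve amplitude $a$ is intrinsically hard to pin down from
  noisy curves; treat fitted amplitudes with error bars in mind even when
  $\varepsilon_a$ and $b$ are stable.
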