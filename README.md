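# krrpes

Machine-learned potential energy surfaces (PESs) for single molecules with
kernel ridge regression, plus the surrounding machinery a PES study needs:
molecular descriptors with analytic derivatives, data sampling and
model selection, Δ-learning and self-correction workflows, automatic
learning curves, and absorption-spectrum simulation by the
machine-learning nuclear-ensemble approach (ML-NEA).

The package is aimed at computational chemists who want an inspectable,
pure-R implementation of these methods that runs end to end on synthetic
molecular data — every workflow here is exercised without any external
dataset or electronic-structure code.

## The model

A property *y* (typically an energy in Hartree) of a molecular geometry
**M** is predicted as a kernel expansion over training geometries,

```
f(x) = Σ_j α_j k(x, x_j),        (K + λI) α = y,
```

where **x** = x(**M**) is a molecular descriptor, **K** the kernel matrix
over the training descriptors and λ ≥ 0 a regularization hyperparameter.
The linear system is solved by Cholesky factorization (with Bunch–Kaufman
and LU fallbacks), never by explicit inversion.

Descriptors:

* **RE** — inverse internuclear distances normalized by a reference
  structure, `x_d = r_ref_d / r_d` over all atom pairs.  RE + Gaussian
  kernel is the *KREG* model.
* **CM** — the Coulomb matrix, `0.5 Z_a^2.4` on the diagonal and
  `Z_a Z_b / r_ab` (Bohr) off it, zero-padded and vectorized; unsorted and
  row-norm-sorted variants.
* **ID** — plain inverse distances `1/r_ab`.
* user-supplied descriptor vectors read from text files.

Kernels: Gaussian, Laplacian, exponential, and Matérn with integer order
*n* (n = 0 reduces exactly to the exponential kernel).  Gaussian and
Matérn (n > 0) have analytic gradients, so Cartesian energy gradients
(forces) follow by the chain rule through the descriptor Jacobian.  For
molecules with equivalent nuclei (e.g. methyl hydrogens) a normalized
permutationally invariant kernel sums the base kernel over all allowed
atom permutations; predictions are then exactly invariant under hydrogen
exchange, which plain descriptors are not.

Around the regression core:

* sampling: random splits, farthest-point sampling (FPS), structure-based
  sampling (SBS) with deformation slicing, k-fold cross-validation;
* hyperparameter selection of (σ, λ) on a nested logarithmic grid against
  a validation split, with value/gradient losses combined as a weighted
  sum or geometric mean;
* Δ-learning (`target = baseline + learned correction`) and
  self-correction (stacked layers fitting successive residuals);
* learning curves `ε(N) = ε_a + a N^(-b)` with constrained power-law fits;
* ML-NEA: iterative training-set growth over a nuclear ensemble with a
  geometric-mean-RMSE convergence criterion, then Gaussian-broadened
  absorption cross sections
  `σ(E) = πe²ħ/(2mcε₀E) Σ_n N_p⁻¹ Σ_i ΔE f · N(E; ΔE, δ/2)`
  in Å²/molecule.

## Worked example

Train a KREG model on 50 points of a synthetic Morse diatomic
(well depth D = 0.17, r_eq = 1 Å) and evaluate it on 200 held-out points:

```r
library(krrpes)
spec  <- synthetic_pes_spec("morse_diatomic")
train <- generate_pes_dataset(spec, 50, seed = 1)
test  <- generate_pes_dataset(spec, 200, seed = 2)
dsp   <- descriptor_spec("RE", reference_geometry = train$metadata$equilibrium)
model <- krr_train(train, kernel_spec("gaussian", sigma = 0.3), dsp, lambda = 2^-35)
ev    <- evaluate_model(model, test)
ev$values
#> Statistical analysis (N = 200)
#>   MAE                  1.2212436e-07
#>   MSE (mean signed)    -4.8551365e-08
#>   RMSE                 4.306464e-07
#>   mean(y_hat)          -0.093957054
#>   mean(y)              -0.093957006
#>   largest + outlier   5.9192367e-07 (index 159)
#>   largest - outlier   -5.15629e-06 (index 51)
#>   regression y_hat = a + b*y:
#>     a      -6.1814468e-08    SE(a)  5.9842317e-08
#>     b      0.99999986    SE(b)  5.4857767e-07
#>     R      1    R^2    1
```

The test RMSE of 4.3e-7 is about 0.0003% of the 0.17 well depth: the
surface is learned to interpolation accuracy.  `ev$gradient_rmse`
(≈ 3.9e-5 per Å here) compares the chain-rule force predictions against
the generator's exact analytic gradients.  `tidy(model)`, `glance(model)`
and `autoplot()` methods expose coefficients, model summaries, learning
curves and spectra in tidyverse form.

A keyword-file front end (`run_input_file()`, wrapped by
`inst/cli/krrpes.R`) drives the same functionality from the shell:

```
task=createMLmodel
XYZfile=geoms.xyz
Yfile=energies.dat
sigma=0.3
MLmodelOut=model.krr
```

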