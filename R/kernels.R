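#' Kernel specification
#'
#' @param family One of `"gaussian"`, `"laplacian"`, `"exponential"`,
#'   `"matern"`.  All share the length-scale `sigma`; Matern has the extra
#'   integer order `matern_n` (`n = 0` reduces exactly to the exponential
#'   kernel).  Laplacian, exponential and Matern with `n = 0` are not
#'   differentiable.
#' @param sigma Positive length scale (descriptor units).
#' @param matern_n Nonnegative integer Matern order (capped at 20).
#' @param permutation_groups Optional [permutation_groups()]; when present
#'   the symmetrized, normalized permutationally invariant kernel is used.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(family = c("gaussian", "laplacian", "exponential", "matern"),
                        sigma = 1, matern_n = 2L, permutation_groups = NULL) {
  family <- match.arg(family)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  matern_n <- as.integer(matern_n)
  if (family == "matern") {
    if (matern_n < 0L) stop("matern_n must be >= 0", call. = FALSE)
    if (matern_n > 20L) {
      stop("matern_n capped at 20 (factorial terms overflow beyond that)",
           call. = FALSE)
    }
  }
  structure(
    list(family = family, sigma = sigma, matern_n = matern_n,
         permutation_groups = permutation_groups),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> ", x$family,
      if (x$family == "matern") paste0(" (n=", x$matern_n, ")"),
      ", sigma=", format(x$sigma),
      if (!is.null(x$permutation_groups)) ", permutationally invariant",
      "\n", sep = "")
  invisible(x)
}

kernel_is_differentiable <- function(spec) {
  spec$family == "gaussian" || (spec$family == "matern" && spec$matern_n > 0L)
}

## log of (n+k)!/(2n)! * choose(n,k); computed in log space so large n stay
## finite
.matern_log_coef <- function(n, k) {
  lgamma(n + k + 1) - lgamma(2 * n + 1) + lchoose(n, k)
}

## Matern polynomial sum_{k=0}^{n} (n+k)!/(2n)! C(n,k) (2d/sigma)^(n-k)
.matern_poly <- function(d, sigma, n) {
  s <- 0
  for (k in 0:n) {
    s <- s + exp(.matern_log_coef(n, k)) * (2 * d / sigma)^(n - k)
  }
  s
}

#' Evaluate a kernel function
#'
#' Gaussian `exp(-||x - xj||^2 / (2 sigma^2))`; Laplacian
#' `exp(-||x - xj||_1 / sigma)`; exponential `exp(-||x - xj||_2 / sigma)`;
#' Matern `exp(-d/sigma) * sum_{k=0}^{n} (n+k)!/(2n)! C(n,k) (2d/sigma)^(n-k)`
#' with `d` the Euclidean distance.  All values lie in (0, 1] and equal 1
#' exactly when the inputs coincide.
#'
#' @param spec A [kernel_spec()].
#' @param x,xj Numeric descriptor vectors of equal length.
#' @return Scalar kernel value.
#' @export
kernel_value <- function(spec, x, xj) {
  if (length(x) != length(xj)) stop("descriptor dimension mismatch", call. = FALSE)
  dx <- x - xj
  switch(spec$family,
    gaussian = exp(-sum(dx^2) / (2 * spec$sigma^2)),
    laplacian = exp(-sum(abs(dx)) / spec$sigma),
    exponential = exp(-sqrt(sum(dx^2)) / spec$sigma),
    matern = {
      d <- sqrt(sum(dx^2))
      exp(-d / spec$sigma) * .matern_poly(d, spec$sigma, spec$matern_n)
    }
  )
}

#' Analytic kernel gradient with respect to the first argument
#'
#' Gaussian: `dk/dx_d = (x_{j,d} - x_d) k / sigma^2`.  Matern (`n > 0`):
#' `dk/dx_d = exp(-d/sigma) * sum_{k=0}^{n-1} (n+k-1)!/(2n)! C(n,k) (n-k)
#' (2/sigma^2) (2d/sigma)^(n-k-1) * (x_{j,d} - x_d)`.  The Laplacian,
#' exponential and Matern `n = 0` kernels are not differentiable and raise
#' an error.
#'
#' @inheritParams kernel_value
#' @return Numeric vector `dk/dx` of the same length as `x`.
#' @export
kernel_gradient <- function(spec, x, xj) {
  if (length(x) != length(xj)) stop("descriptor dimension mismatch", call. = FALSE)
  if (!kernel_is_differentiable(spec)) {
    stop("kernel family '", spec$family,
         if (spec$family == "matern") " (n=0)",
         "' is not differentiable", call. = FALSE)
  }
  dx <- x - xj
  if (spec$family == "gaussian") {
    return(-dx / spec$sigma^2 * exp(-sum(dx^2) / (2 * spec$sigma^2)))
  }
  # matern, n > 0
  n <- spec$matern_n
  d <- sqrt(sum(dx^2))
  s <- 0
  for (k in 0:(n - 1)) {
    s <- s + exp(lgamma(n + k) - lgamma(2 * n + 1) + lchoose(n, k)) *
      (n - k) * (2 / spec$sigma^2) * (2 * d / spec$sigma)^(n - k - 1)
  }
  -dx * s * exp(-d / spec$sigma)
}

## -- permutationally invariant kernel ---------------------------------------

## Descriptors of all permuted images of a geometry (rows = permutations)
permuted_descriptors <- function(spec_d, geom, perms) {
  do.call(rbind, lapply(perms, function(p) {
    eval_descriptor(spec_d, apply_permutation(geom, p))$x
  }))
}

## S(A, B) = sum_P k(x(A), x(P B)) given descriptor of A and permuted
## descriptors of B
.perm_sum <- function(spec, xA, XB_perm) {
  sum(apply(XB_perm, 1, function(xb) kernel_value(spec, xA, xb)))
}

#' Normalized permutationally invariant kernel value
#'
#' Symmetrizes the base kernel over all permutations of equivalent atoms and
#' normalizes so that the self-kernel is exactly 1:
#' `kbar(M, Mj) = sum_P k(x(M), x(P Mj)) / sqrt(sum_P k(x(M), x(P M)) *
#' sum_P k(x(Mj), x(P Mj)))`.
#'
#' @param spec A [kernel_spec()] carrying `permutation_groups`.
#' @param geom_i,geom_j [mol_geometry()] objects.
#' @param dspec A [descriptor_spec()] (family RE or CM; the unsorted
#'   descriptor is evaluated on each permuted image).
#' @return Scalar symmetrized kernel value.
#' @export
perm_kernel_value <- function(spec, geom_i, geom_j, dspec) {
  groups <- spec$permutation_groups
  if (is.null(groups)) {
    stop("kernel_spec has no permutation_groups; use kernel_value()", call. = FALSE)
  }
  perms <- enumerate_permutations(groups, n_atoms(geom_i))
  xi <- eval_descriptor(dspec, geom_i)$x
  xj <- eval_descriptor(dspec, geom_j)$x
  Xi_p <- permuted_descriptors(dspec, geom_i, perms)
  Xj_p <- permuted_descriptors(dspec, geom_j, perms)
  s_cross <- .perm_sum(spec, xi, Xj_p)
  s_ii <- .perm_sum(spec, xi, Xi_p)
  s_jj <- .perm_sum(spec, xj, Xj_p)
  s_cross / sqrt(s_ii * s_jj)
}

## d/dM of sum_P k(x(M), x(P Mj)) where only the first argument depends on M.
## J is the descriptor Jacobian at M (N_x x 3N_at).  Returns length-3N_at
## vector.
.grad_cross <- function(spec, xi, Xj_p, J) {
  g <- numeric(ncol(J))
  for (p in seq_len(nrow(Xj_p))) {
    g <- g + as.vector(crossprod(J, kernel_gradient(spec, xi, Xj_p[p, ])))
  }
  g
}

## d/dM of sum_P k(x(M), x(P M)): M enters both arguments.  For each
## permutation P, chain through the Jacobian of x(M) (first argument) and
## the Jacobian of x(P M) (second argument; equals the Jacobian evaluated at
## the permuted geometry with its atom-columns mapped back to the original
## atom order).  For distance-based kernels dk/d(second arg) = -dk/d(first
## arg evaluated with the arguments swapped)... we use the exact identity
## dk/dv = -dk/du for k depending on u - v only.
.grad_self <- function(spec, dspec, geom, perms, xi, Xi_p, J1) {
  n_at <- n_atoms(geom)
  g <- numeric(3L * n_at)
  for (p in seq_along(perms)) {
    perm <- perms[[p]]
    xp <- Xi_p[p, ]
    gk <- kernel_gradient(spec, xi, xp)      # dk/du at (u, v) = (xi, xp)
    # first-argument contribution
    g <- g + as.vector(crossprod(J1, gk))
    # second-argument contribution: dk/dv = -gk; chain through d x(P M)/d M.
    gp <- apply_permutation(geom, perm)
    J2 <- eval_descriptor(dspec, gp, with_jacobian = TRUE)$jacobian
    # column block for atom 'a' of gp is atom perm[a] of the original M
    J2m <- matrix(0, nrow(J2), ncol(J2))
    for (a in seq_len(n_at)) {
      src <- (3 * (a - 1) + 1):(3 * a)
      dst <- (3 * (perm[a] - 1) + 1):(3 * perm[a])
      J2m[, dst] <- J2[, src]
    }
    g <- g - as.vector(crossprod(J2m, gk))
  }
  g
}

#' Gradient of the permutationally invariant kernel
#'
#' Cartesian gradient of the normalized symmetrized kernel with respect to
#' the coordinates of `geom_i`, including the self-permutation correction
#' terms arising from the normalization (both arguments of the self sums
#' depend on the query coordinates).
#'
#' @inheritParams perm_kernel_value
#' @return `N_at x 3` matrix `d kbar / d M` of `geom_i`.
#' @export
perm_kernel_gradient <- function(spec, geom_i, geom_j, dspec) {
  groups <- spec$permutation_groups
  if (is.null(groups)) {
    stop("kernel_spec has no permutation_groups; use kernel_gradient()",
         call. = FALSE)
  }
  if (!kernel_is_differentiable(spec)) {
    stop("base kernel is not differentiable", call. = FALSE)
  }
  n_at <- n_atoms(geom_i)
  perms <- enumerate_permutations(groups, n_at)
  di <- eval_descriptor(dspec, geom_i, with_jacobian = TRUE)
  xi <- di$x
  xj <- eval_descriptor(dspec, geom_j)$x
  Xi_p <- permuted_descriptors(dspec, geom_i, perms)
  Xj_p <- permuted_descriptors(dspec, geom_j, perms)
  s_cross <- .perm_sum(spec, xi, Xj_p)
  s_ii <- .perm_sum(spec, xi, Xi_p)
  s_jj <- .perm_sum(spec, xj, Xj_p)

  g_cross <- .grad_cross(spec, xi, Xj_p, di$jacobian)
  g_self <- .grad_self(spec, dspec, geom_i, perms, xi, Xi_p, di$jacobian)

  g <- (s_ii * s_jj)^(-0.5) * (g_cross - 0.5 * g_self * (s_cross / s_ii))
  matrix(g, n_at, 3, byrow = TRUE)
}

## -- kernel matrices --------------------------------------------------------

#' Kernel matrix over a set of geometries
#'
#' `K[i, j]` is the (plain or permutationally invariant) kernel of pair
#' `(i, j)`.  Assembled from one triangular half and mirrored, so the result
#' is exactly symmetric; the diagonal is exactly 1.
#'
#' @param spec A [kernel_spec()].
#' @param dspec A [descriptor_spec()].
#' @param geometries List of [mol_geometry()] objects.
#' @return Symmetric `N x N` matrix with unit diagonal.
#' @export
kernel_matrix <- function(spec, dspec, geometries) {
  n <- length(geometries)
  if (n < 1L) stop("need at least one geometry", call. = FALSE)
  if (!is.null(spec$permutation_groups)) {
    K <- diag(1, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        K[i, j] <- K[j, i] <- perm_kernel_value(spec, geometries[[i]],
                                                geometries[[j]], dspec)
      }
    }
    return(K)
  }
  X <- descriptor_matrix(dspec, geometries)
  kernel_matrix_from_x(spec, X, X, symmetric = TRUE)
}

## Vectorized kernel matrix from descriptor matrices (rows = points).
## symmetric = TRUE forces exact symmetry and unit diagonal.
kernel_matrix_from_x <- function(spec, X, Xj, symmetric = FALSE) {
  if (spec$family == "laplacian") {
    D1 <- l1_cross_dist(X, Xj)
    K <- exp(-D1 / spec$sigma)
  } else {
    D2 <- sq_cross_dist(X, Xj)
    K <- switch(spec$family,
      gaussian = exp(-D2 / (2 * spec$sigma^2)),
      exponential = exp(-sqrt(D2) / spec$sigma),
      matern = {
        d <- sqrt(D2)
        exp(-d / spec$sigma) * .matern_poly(d, spec$sigma, spec$matern_n)
      }
    )
  }
  if (symmetric) {
    K[lower.tri(K)] <- t(K)[lower.tri(K)]
    diag(K) <- 1
  }
  K
}

## squared Euclidean cross-distances, clipped at 0 against rounding
sq_cross_dist <- function(X, Y) {
  D <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  D[D < 0] <- 0
  D
}

l1_cross_dist <- function(X, Y) {
  n <- nrow(X); m <- nrow(Y)
  D <- matrix(0, n, m)
  for (s in seq_len(ncol(X))) {
    D <- D + abs(outer(X[, s], Y[, s], "-"))
  }
  D
}
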