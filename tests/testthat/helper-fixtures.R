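# Shared fixtures and independent numerical oracles.

# random geometry with given elements, coordinates in a ~4 Angstrom box
rand_geom <- function(elements, seed = NULL) {
  n <- length(elements)
  coords <- matrix(stats::runif(n * 3, -2, 2), n, 3)
  mol_geometry(elements, coords)
}

# central finite differences of a scalar function of a geometry -> N_at x 3
fd_geom_grad <- function(f, geom, h = 1e-5) {
  n <- n_atoms(geom)
  G <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    for (t in 1:3) {
      cp <- geom$coordinates; cp[a, t] <- cp[a, t] + h
      cm <- geom$coordinates; cm[a, t] <- cm[a, t] - h
      G[a, t] <- (f(mol_geometry(geom$elements, cp)) -
                    f(mol_geometry(geom$elements, cm))) / (2 * h)
    }
  }
  G
}

# central finite differences of a scalar function of a vector
fd_vec_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# finite-difference Jacobian of a descriptor evaluation (rows follow x)
fd_descriptor_jacobian <- function(eval_x, geom, h = 1e-5) {
  x0 <- eval_x(geom)
  J <- matrix(0, length(x0), 3 * n_atoms(geom))
  for (a in seq_len(n_atoms(geom))) {
    for (t in 1:3) {
      cp <- geom$coordinates; cp[a, t] <- cp[a, t] + h
      cm <- geom$coordinates; cm[a, t] <- cm[a, t] - h
      col <- 3 * (a - 1) + t
      J[, col] <- (eval_x(mol_geometry(geom$elements, cp)) -
                     eval_x(mol_geometry(geom$elements, cm))) / (2 * h)
    }
  }
  J
}

# brute-force greedy farthest-point oracle (quadratic, tiny n only)
fps_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  pair <- which(D == max(D), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- sort(as.integer(pair))
  while (length(sel) < n) {
    rem <- setdiff(seq_len(n), sel)
    mind <- vapply(rem, function(i) min(D[i, sel]), 0)
    sel <- c(sel, rem[which.max(mind)])
  }
  sel
}

# rigid rotation + translation of a geometry
transform_geom <- function(geom, angle = 0.7, axis = c(0, 0, 1), shift = c(1, -2, 0.5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  mol_geometry(geom$elements,
               sweep(geom$coordinates %*% t(R), 2, -shift))
}

# default XH3 fixture pieces used across files
xh3_fixture <- function(n = 30, seed = 1, noise_sd = 0) {
  ds <- generate_perm_symmetric_dataset(
    synthetic_pes_spec("perm_symmetric_xh3", noise_sd = noise_sd), n, seed = seed)
  list(
    dataset = ds,
    groups = permutation_groups(2:4),
    ref = ds$metadata$equilibrium,
    h_perms = list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4),
                   c(1, 3, 4, 2), c(1, 4, 2, 3), c(1, 4, 3, 2))
  )
}

morse_fixture <- function(n = 50, seed = 1) {
  ds <- generate_pes_dataset(synthetic_pes_spec("morse_diatomic"), n, seed = seed)
  list(dataset = ds,
       descriptor = descriptor_spec("RE", reference_geometry = ds$metadata$equilibrium))
}
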