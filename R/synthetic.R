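#' Specification of a synthetic potential energy surface
#'
#' Three analytic families with exact gradients:
#' * `morse_diatomic` — a Morse oscillator
#'   `E(r) = D (1 - exp(-a (r - r_eq)))^2 - D` on a two-atom molecule; the
#'   defaults (`D = 0.17` Hartree, `a = 2.0` 1/Angstrom, `r_eq = 1.0`
#'   Angstrom, sampled on `r` in `[0.7, 2.5]` Angstrom) are in the range of
#'   a covalent single bond.
#' * `harmonic_polyatomic` — a water-like triatomic with harmonic pair
#'   terms `E = sum_pairs k/2 (r - r0)^2`.
#' * `perm_symmetric_xh3` — a CH3-like XH3 fragment whose energy is built
#'   from symmetric polynomials of the three X-H distances and of the three
#'   H-H distances, hence exactly invariant under all 6 H permutations.
#'
#' @param form One of the three family names.
#' @param D,a,r_eq Morse well depth (value units), width (1/Angstrom) and
#'   equilibrium distance (Angstrom).
#' @param k Harmonic force constant (value units per Angstrom^2).
#' @param range Sampling range of the stretched coordinate(s), Angstrom.
#' @param noise_sd Additive Gaussian noise applied to energies only
#'   (default 0: geometries and gradients stay exact).
#' @return A `synthetic_pes_spec` object.
#' @export
synthetic_pes_spec <- function(form = c("morse_diatomic", "harmonic_polyatomic",
                                        "perm_symmetric_xh3"),
                               D = 0.17, a = 2.0, r_eq = 1.0, k = 0.5,
                               range = c(0.7, 2.5), noise_sd = 0) {
  form <- match.arg(form)
  if (D <= 0) stop("well depth D must be > 0", call. = FALSE)
  if (range[1] <= 0 || range[1] >= range[2]) {
    stop("invalid sampling range (must exclude r = 0)", call. = FALSE)
  }
  structure(list(form = form, D = D, a = a, r_eq = r_eq, k = k,
                 range = range, noise_sd = noise_sd),
            class = "synthetic_pes_spec")
}

## Morse energy and derivative wrt r
.morse_e <- function(r, D, a, r_eq) D * (1 - exp(-a * (r - r_eq)))^2 - D
.morse_de <- function(r, D, a, r_eq) {
  u <- exp(-a * (r - r_eq))
  2 * D * (1 - u) * a * u
}

#' Generate a synthetic PES dataset with exact analytic gradients
#'
#' Geometries are sampled uniformly (seeded) over the spec's coordinate
#' range; energies come from the closed form and gradients from its exact
#' derivative.  Optional Gaussian noise is added to the energies only.
#'
#' @param spec A [synthetic_pes_spec()].
#' @param n_points Number of geometries (>= 1).
#' @param seed Integer seed; recorded in the dataset metadata.
#' @return A [mol_dataset()] with values and gradients.  The metadata
#'   carries `equilibrium`, the analytic minimum-energy geometry, handy as
#'   an RE reference.
#' @export
generate_pes_dataset <- function(spec, n_points, seed = 1) {
  if (n_points < 1L) stop("n_points must be >= 1", call. = FALSE)
  switch(spec$form,
    morse_diatomic = generate_morse(spec, n_points, seed),
    harmonic_polyatomic = generate_harmonic(spec, n_points, seed),
    perm_symmetric_xh3 = generate_perm_symmetric_dataset(spec, n_points, seed)
  )
}

generate_morse <- function(spec, n, seed) {
  rs <- with_seed(seed, stats::runif(n, spec$range[1], spec$range[2]))
  noise <- if (spec$noise_sd > 0) {
    with_seed(seed + 1L, stats::rnorm(n, 0, spec$noise_sd))
  } else rep(0, n)
  geoms <- lapply(rs, function(r) {
    mol_geometry(c("H", "H"), rbind(c(0, 0, 0), c(r, 0, 0)))
  })
  values <- .morse_e(rs, spec$D, spec$a, spec$r_eq) + noise
  grads <- lapply(rs, function(r) {
    de <- .morse_de(r, spec$D, spec$a, spec$r_eq)
    rbind(c(-de, 0, 0), c(de, 0, 0))   # dE/dM along the bond axis
  })
  eq <- mol_geometry(c("H", "H"), rbind(c(0, 0, 0), c(spec$r_eq, 0, 0)))
  mol_dataset(geoms, values, grads,
              metadata = list(seed = seed, spec = spec, equilibrium = eq))
}

## energy from pairwise harmonic terms: E = sum_d k/2 (r_d - r0_d)^2 over
## the canonical pair order; exact gradient by the pair-distance chain rule
.pairwise_energy <- function(geom, r0, kvec) {
  pd <- pair_distances(geom)
  dr <- pd$r - r0
  e <- sum(kvec / 2 * dr^2)
  n_at <- n_atoms(geom)
  g <- matrix(0, n_at, 3)
  for (d in seq_along(dr)) {
    a <- pd$pairs[d, 1]; b <- pd$pairs[d, 2]
    dir <- pd$diff[d, ] / pd$r[d]        # unit vector from b to a
    g[a, ] <- g[a, ] + kvec[d] * dr[d] * dir
    g[b, ] <- g[b, ] - kvec[d] * dr[d] * dir
  }
  list(energy = e, gradient = g)
}

generate_harmonic <- function(spec, n, seed) {
  # water-like O-H-H skeleton; displace all atoms around equilibrium
  eq_coords <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  eq <- mol_geometry(c("O", "H", "H"), eq_coords)
  r0 <- pair_distances(eq)$r
  kvec <- c(spec$k, spec$k, spec$k / 4)  # softer H..H "bend" surrogate
  amp <- 0.15
  disp <- with_seed(seed, matrix(stats::runif(n * 9, -amp, amp), ncol = 9))
  noise <- if (spec$noise_sd > 0) {
    with_seed(seed + 1L, stats::rnorm(n, 0, spec$noise_sd))
  } else rep(0, n)
  geoms <- lapply(seq_len(n), function(i) {
    mol_geometry(eq$elements, eq_coords + matrix(disp[i, ], 3, 3, byrow = TRUE))
  })
  ev <- lapply(geoms, .pairwise_energy, r0 = r0, kvec = kvec)
  mol_dataset(geoms,
              values = vapply(ev, `[[`, 0, "energy") + noise,
              gradients = lapply(ev, `[[`, "gradient"),
              metadata = list(seed = seed, spec = spec, equilibrium = eq))
}

#' Generate a permutation-symmetric XH3 dataset
#'
#' A carbon-like center with three hydrogens; the energy is a function of
#' the symmetric polynomials of the three X-H distances plus a harmonic
#' term in the three H-H distances, so it is exactly invariant under all 6
#' permutations of the hydrogens.  Gradients are exact.
#'
#' @param spec A [synthetic_pes_spec()] (form `perm_symmetric_xh3`; other
#'   forms are rejected).
#' @param n_points Number of geometries.
#' @param seed Integer seed.
#' @return A [mol_dataset()] with values and gradients; metadata carries
#'   the equilibrium geometry and `h_indices = 2:4`.
#' @export
generate_perm_symmetric_dataset <- function(spec, n_points, seed = 1) {
  if (spec$form != "perm_symmetric_xh3") {
    stop("spec form must be perm_symmetric_xh3", call. = FALSE)
  }
  # trigonal-pyramidal CH3-like fragment, C at origin; directions built from
  # exact trigonometry so the three X-H (and three H-H) reference distances
  # coincide to machine precision -- the permuted-kernel invariance tests
  # rely on a symmetric reference
  d0 <- spec$r_eq * 1.09
  beta <- 1.91           # X-H polar angle from the +z axis, rad
  phi <- 2 * pi * (0:2) / 3
  eq_coords <- rbind(
    c(0, 0, 0),
    t(vapply(phi, function(p) {
      d0 * c(sin(beta) * cos(p), sin(beta) * sin(p), cos(beta))
    }, numeric(3)))
  )
  eq <- mol_geometry(c("C", "H", "H", "H"), eq_coords)
  r0 <- pair_distances(eq)$r
  # pairs in canonical order for 4 atoms: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  # X-H terms get k, H-H terms k/4: symmetric under any H permutation
  kvec <- c(spec$k, spec$k, spec$k, spec$k / 4, spec$k / 4, spec$k / 4)
  amp <- 0.12
  disp <- with_seed(seed, matrix(stats::runif(n_points * 12, -amp, amp), ncol = 12))
  noise <- if (spec$noise_sd > 0) {
    with_seed(seed + 1L, stats::rnorm(n_points, 0, spec$noise_sd))
  } else rep(0, n_points)
  geoms <- lapply(seq_len(n_points), function(i) {
    mol_geometry(eq$elements, eq_coords + matrix(disp[i, ], 4, 3, byrow = TRUE))
  })
  ev <- lapply(geoms, .pairwise_energy, r0 = r0, kvec = kvec)
  mol_dataset(geoms,
              values = vapply(ev, `[[`, 0, "energy") + noise,
              gradients = lapply(ev, `[[`, "gradient"),
              metadata = list(seed = seed, spec = spec, equilibrium = eq,
                              h_indices = 2:4))
}

#' Generate a labeled synthetic nuclear ensemble
#'
#' Ensemble points are the equilibrium water-like geometry plus seeded
#' Gaussian displacements (a stand-in for a Wigner-distribution sample).
#' Per state `n`, the excitation energy is a smooth function of the pair
#' distances around a base energy `3 + n` eV, and the oscillator strength
#' is a smooth positive function with a deliberate small negative tail
#' (roughly a few percent of points for the later states) so the
#' negative-strength clipping rule is exercised.  Optional Gaussian label
#' noise emulates the finite precision of the reference electronic-
#' structure labels.
#'
#' @param n_points Ensemble size `N_p`.
#' @param n_states Number of excited states `N_fs`.
#' @param seed Integer seed.
#' @param displacement_sd Gaussian displacement width, Angstrom
#'   (default 0.05; 0 collapses all points onto the equilibrium).
#' @param noise_sd_energy,noise_sd_strength Label noise standard deviations
#'   (defaults 0.02 eV and 0.002).
#' @return A fully labeled [spectrum_ensemble()].
#' @export
generate_labeled_ensemble <- function(n_points, n_states = 1, seed = 1,
                                      displacement_sd = 0.05,
                                      noise_sd_energy = 0.02,
                                      noise_sd_strength = 0.002) {
  if (n_points < 1L || n_states < 1L) {
    stop("n_points and n_states must be >= 1", call. = FALSE)
  }
  eq_coords <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  eq <- mol_geometry(c("O", "H", "H"), eq_coords)
  r0 <- pair_distances(eq)$r
  disp <- with_seed(seed, matrix(stats::rnorm(n_points * 9, 0, displacement_sd),
                                 ncol = 9))
  geoms <- lapply(seq_len(n_points), function(i) {
    mol_geometry(eq$elements, eq_coords + matrix(disp[i, ], 3, 3, byrow = TRUE))
  })
  dr <- t(vapply(geoms, function(g) pair_distances(g)$r - r0, numeric(3)))
  en <- with_seed(seed + 1L,
                  matrix(stats::rnorm(n_points * n_states, 0, noise_sd_energy),
                         ncol = n_states))
  sn <- with_seed(seed + 2L,
                  matrix(stats::rnorm(n_points * n_states, 0, noise_sd_strength),
                         ncol = n_states))
  energies <- matrix(0, n_points, n_states)
  strengths <- matrix(0, n_points, n_states)
  for (s in seq_len(n_states)) {
    # smooth state-dependent response to the bond-length deformations
    ce <- c(1.5, -1.0, 0.5) * s / 2
    energies[, s] <- 3 + s + dr %*% ce + 0.5 * rowSums(dr^2) + en[, s]
    cf <- c(-0.4, 0.3, -0.2) / 2
    strengths[, s] <- 0.05 / s + dr %*% cf + sn[, s]
  }
  if (any(energies <= 0)) {
    energies[energies <= 0] <- .Machine$double.eps
  }
  spectrum_ensemble(geoms, energies, strengths)
}
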