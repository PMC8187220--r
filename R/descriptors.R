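#' Descriptor specification
#'
#' Describes how a molecular geometry is turned into an ML input vector.
#'
#' @param family One of `"RE"` (inverse distances relative to a reference
#'   structure), `"CM"` (Coulomb matrix), `"ID"` (plain inverse distances) or
#'   `"user"` (precomputed vectors supplied by file).
#' @param variant `"unsorted"` (default), `"sorted"`, or `"permuted"`.
#'   Sorting means homonuclear repulsion sorting for RE and row-norm sorting
#'   for CM; `"permuted"` activates the permutationally invariant kernel and
#'   requires `permutation_groups`.
#' @param reference_geometry Reference [mol_geometry()]; required for RE.
#' @param permutation_groups A [permutation_groups()] object; required for
#'   the permuted variant.
#' @param max_atoms Padding dimension for CM (default: atoms of the first
#'   geometry seen).
#' @return A `descriptor_spec` object.
#' @export
descriptor_spec <- function(family = c("RE", "CM", "ID", "user"),
                            variant = c("unsorted", "sorted", "permuted"),
                            reference_geometry = NULL,
                            permutation_groups = NULL,
                            max_atoms = NULL) {
  family <- match.arg(family)
  variant <- match.arg(variant)
  if (family == "RE" && is.null(reference_geometry)) {
    stop("the RE descriptor requires a reference_geometry", call. = FALSE)
  }
  if (variant == "permuted" && is.null(permutation_groups)) {
    stop("the permuted variant requires permutation_groups", call. = FALSE)
  }
  structure(
    list(family = family, variant = variant,
         reference_geometry = reference_geometry,
         permutation_groups = permutation_groups,
         max_atoms = max_atoms),
    class = "descriptor_spec"
  )
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("<descriptor_spec> ", x$family, " (", x$variant, ")\n", sep = "")
  invisible(x)
}

#' Permutation groups of equivalent atoms
#'
#' Groups of 1-based atom indices whose members share an element and may be
#' permuted freely (e.g. the three H of a methyl group).  The symmetrized
#' kernel sums over the full product of all within-group permutations,
#' `N_perm = prod(factorial(group sizes))`.
#'
#' @param ... Integer vectors, one per group (each of length >= 2), or a
#'   single list of such vectors.
#' @return A `perm_groups` object.
#' @export
permutation_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  groups <- lapply(groups, as.integer)
  if (any(lengths(groups) < 2L)) {
    stop("every permutation group needs at least 2 atoms", call. = FALSE)
  }
  if (anyDuplicated(unlist(groups))) {
    stop("permutation groups must be disjoint", call. = FALSE)
  }
  structure(groups, class = "perm_groups")
}

#' Number of permutations generated by a group set
#' @param groups A [permutation_groups()] object.
#' @return `prod(factorial(group sizes))`.
#' @export
n_permutations <- function(groups) prod(factorial(lengths(groups)))

## Enumerate all atom permutations (full-length index vectors) induced by
## the groups: groups processed left to right, permutations of each group in
## lexicographic order.  N_perm capped at 10!.
enumerate_permutations <- function(groups, n_at) {
  np <- n_permutations(groups)
  if (np > factorial(10)) {
    stop("permutation group product too large (N_perm > 10!)", call. = FALSE)
  }
  perms <- list(seq_len(n_at))
  for (g in groups) {
    gperms <- all_perms(length(g))
    perms <- unlist(lapply(perms, function(p) {
      lapply(gperms, function(gp) {
        q <- p
        q[g] <- p[g][gp]
        q
      })
    }), recursive = FALSE)
  }
  perms
}

## all permutations of 1:k in lexicographic order
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_perms(k - 1L)
    out <- c(out, lapply(rest, function(r) c(i, setdiff(seq_len(k), i)[r])))
  }
  out
}

#' Reorder a geometry's atoms by a permutation
#'
#' @param geom A [mol_geometry()].
#' @param perm Integer permutation of `1:n_atoms(geom)`; row `i` of the
#'   result is atom `perm[i]` of the input.  Each atom must map to a
#'   same-element position.
#' @return The permuted geometry.
#' @export
apply_permutation <- function(geom, perm) {
  perm <- as.integer(perm)
  n <- n_atoms(geom)
  if (!identical(sort(perm), seq_len(n))) {
    stop("perm must be a permutation of 1:", n, call. = FALSE)
  }
  if (!identical(geom$elements[perm], geom$elements)) {
    stop("permutation maps atoms across different elements", call. = FALSE)
  }
  mol_geometry(geom$elements, geom$coordinates[perm, , drop = FALSE])
}

## canonical pair order: lexicographic (a, b), a < b.  Returns 2-column
## integer matrix of pair indices.
pair_index <- function(n_at) {
  a <- rep(seq_len(n_at - 1L), times = (n_at - 1L):1L)
  b <- unlist(lapply(seq_len(n_at - 1L), function(i) (i + 1L):n_at))
  cbind(a = a, b = b)
}

pair_distances <- function(geom) {
  pr <- pair_index(n_atoms(geom))
  d <- geom$coordinates[pr[, 1], , drop = FALSE] -
       geom$coordinates[pr[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r <= 0)) stop("singular geometry: coincident atoms", call. = FALSE)
  list(pairs = pr, diff = d, r = r)
}

## Jacobian of the inverse-distance family: x_d = c_d / r_d with c_d constant
## per pair.  d x_d / d M_at = x_d (M_bt - M_at) / r^2 (and the negative for
## atom b).  Returns an N_x x (3 N_at) matrix, columns grouped per atom
## (x1 y1 z1 x2 y2 z2 ...).
inverse_distance_jacobian <- function(pd, x, n_at) {
  nx <- length(x)
  J <- matrix(0, nx, 3L * n_at)
  fac <- x / pd$r^2
  for (d in seq_len(nx)) {
    a <- pd$pairs[d, 1]; b <- pd$pairs[d, 2]
    g <- fac[d] * pd$diff[d, ]           # d x_d / d M_b = +x_d (M_a-M_b)/r^2
    J[d, (3 * (b - 1) + 1):(3 * b)] <- g
    J[d, (3 * (a - 1) + 1):(3 * a)] <- -g
  }
  J
}

#' RE descriptor: reference-relative inverse distances
#'
#' `x_d = r_ref_d / r_d` over all unordered atom pairs in canonical
#' lexicographic order `(a, b), a < b`.  At the reference geometry every
#' component is 1.
#'
#' @param geom Query [mol_geometry()].
#' @param ref Reference [mol_geometry()] with the identical element sequence.
#' @param with_jacobian If `TRUE`, also return the analytic Jacobian
#'   `d x / d M` (`N_x x 3 N_at`, columns per atom in x,y,z order).
#' @return List with `x` and (optionally) `jacobian`.
#' @export
re_descriptor <- function(geom, ref, with_jacobian = FALSE) {
  if (!same_elements(geom, ref)) {
    stop("geometry and reference have different element sequences", call. = FALSE)
  }
  pd <- pair_distances(geom)
  pr <- pair_distances(ref)
  x <- pr$r / pd$r
  out <- list(x = x)
  if (with_jacobian) out$jacobian <- inverse_distance_jacobian(pd, x, n_atoms(geom))
  out
}

#' ID descriptor: unnormalized inverse distances
#'
#' `x_d = 1 / r_d` (Angstrom^-1) over the canonical pair order; equals the
#' RE descriptor with all reference distances set to 1.
#'
#' @inheritParams re_descriptor
#' @return List with `x` and (optionally) `jacobian`.
#' @export
id_descriptor <- function(geom, with_jacobian = FALSE) {
  pd <- pair_distances(geom)
  x <- 1 / pd$r
  out <- list(x = x)
  if (with_jacobian) out$jacobian <- inverse_distance_jacobian(pd, x, n_atoms(geom))
  out
}

#' Coulomb-matrix descriptor
#'
#' Diagonal `0.5 * Z^2.4`, off-diagonal `Z_a Z_b / r_ab` with distances in
#' Bohr, zero-padded to `max_atoms` rows/columns, vectorized row-major
#' (both symmetric halves kept).  The sorted variant reorders atoms by
#' descending Euclidean row norm (ties: original atom order) before
#' vectorization; it has no analytic Jacobian.
#'
#' @param geom A [mol_geometry()].
#' @param max_atoms Padding dimension (>= `n_atoms(geom)`).
#' @param variant `"unsorted"` or `"sorted"`.
#' @param with_jacobian If `TRUE` (unsorted only), return the analytic
#'   Jacobian with respect to Angstrom coordinates.
#' @return List with `x` and (optionally) `jacobian`.
#' @export
cm_descriptor <- function(geom, max_atoms = n_atoms(geom),
                          variant = c("unsorted", "sorted"),
                          with_jacobian = FALSE) {
  variant <- match.arg(variant)
  n <- n_atoms(geom)
  if (max_atoms < n) stop("max_atoms must be >= n_atoms(geom)", call. = FALSE)
  if (with_jacobian && variant == "sorted") {
    stop("analytic Jacobian is unsupported for the sorted Coulomb matrix",
         call. = FALSE)
  }
  r_ang <- dist_matrix(geom)
  if (any(r_ang[upper.tri(r_ang)] <= 0)) {
    stop("singular geometry: coincident atoms", call. = FALSE)
  }
  r_bohr <- r_ang * .ang2bohr
  z <- geom$charges
  M <- outer(z, z) / r_bohr
  diag(M) <- 0.5 * z^2.4

  ord <- seq_len(n)
  if (variant == "sorted") {
    norms <- sqrt(rowSums(M^2))
    ord <- order(-norms, seq_len(n))    # stable: ties by original index
    M <- M[ord, ord, drop = FALSE]
  }
  P <- matrix(0, max_atoms, max_atoms)
  P[seq_len(n), seq_len(n)] <- M
  out <- list(x = as.vector(t(P)))      # row-major vectorization

  if (with_jacobian) {
    nx <- max_atoms^2
    J <- matrix(0, nx, 3L * n)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        d <- (a - 1L) * max_atoms + b   # row-major position of entry (a, b)
        # x = Za Zb / (r_ang * ang2bohr); derivative wrt Angstrom coordinates
        g <- -(z[a] * z[b] / (.ang2bohr * r_ang[a, b]^3)) *
          (geom$coordinates[a, ] - geom$coordinates[b, ])
        J[d, (3 * (a - 1) + 1):(3 * a)] <- g
        J[d, (3 * (b - 1) + 1):(3 * b)] <- -g
      }
    }
    out$jacobian <- J
  }
  out
}

#' Sort homonuclear atoms by descending nuclear-repulsion sum
#'
#' Within each maximal set of same-element atoms, atoms are reordered by
#' descending `sum_b Z_a Z_b / r_ab` (Angstrom distances; the ordering is
#' unit-independent).  Positions occupied by each element are preserved, so
#' the element sequence of the output equals the input's.  Ties are broken
#' by original atom index (stable).  Idempotent.
#'
#' @param geom A [mol_geometry()].
#' @return List with `geometry` (the reordered [mol_geometry()]) and `order`
#'   (integer vector: row `i` of the output is atom `order[i]` of the input).
#' @export
sort_homonuclear <- function(geom) {
  n <- n_atoms(geom)
  r <- dist_matrix(geom)
  if (any(r[upper.tri(r)] <= 0)) stop("singular geometry: coincident atoms", call. = FALSE)
  z <- geom$charges
  rep_sum <- vapply(seq_len(n), function(a) {
    sum(z[a] * z[-a] / r[a, -a])
  }, 0)
  ord <- seq_len(n)
  for (el in unique(geom$elements)) {
    pos <- which(geom$elements == el)
    if (length(pos) > 1L) {
      ord[pos] <- pos[order(-rep_sum[pos], pos)]
    }
  }
  list(geometry = apply_permutation(geom, ord), order = ord)
}

#' Evaluate a descriptor spec on one geometry
#'
#' Dispatches on the spec's family and variant.  The permuted variant
#' returns the plain unsorted descriptor; permutation handling lives in the
#' symmetrized kernel.
#'
#' @param spec A [descriptor_spec()].
#' @param geom A [mol_geometry()].
#' @param with_jacobian Return the analytic Jacobian too?
#' @return List with `x` and optionally `jacobian`.
#' @export
eval_descriptor <- function(spec, geom, with_jacobian = FALSE) {
  if (spec$family == "user") {
    stop("user-supplied descriptors are precomputed; pass vectors directly",
         call. = FALSE)
  }
  sorted <- spec$variant == "sorted"
  if (sorted && with_jacobian) {
    stop("analytic Jacobian is unsupported for sorted descriptor variants",
         call. = FALSE)
  }
  switch(spec$family,
    RE = {
      ref <- spec$reference_geometry
      if (sorted) {
        geom <- sort_homonuclear(geom)$geometry
        ref <- sort_homonuclear(ref)$geometry
      }
      re_descriptor(geom, ref, with_jacobian)
    },
    ID = {
      if (sorted) geom <- sort_homonuclear(geom)$geometry
      id_descriptor(geom, with_jacobian)
    },
    CM = {
      ma <- if (is.null(spec$max_atoms)) n_atoms(geom) else spec$max_atoms
      cm_descriptor(geom, ma, variant = if (sorted) "sorted" else "unsorted",
                    with_jacobian = with_jacobian)
    }
  )
}

## Descriptor matrix for a list of geometries (rows = geometries)
descriptor_matrix <- function(spec, geometries) {
  rows <- lapply(geometries, function(g) eval_descriptor(spec, g)$x)
  do.call(rbind, rows)
}
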