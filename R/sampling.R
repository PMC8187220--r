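#' Random training/test split
#'
#' Uniform sampling without replacement; the platform default is an 80:20
#' training:test split.  Reproducible under `seed` (R's Mersenne-Twister,
#' recorded in the result's attributes).
#'
#' @param n Number of records.
#' @param fraction_train Training fraction (default 0.8); the training count
#'   is `round(fraction_train * n)`.  Ignored when `n_train` is given.
#' @param n_train Optional explicit training count.
#' @param seed Integer seed.
#' @return A [split_indices()] with groups `training` and `test`.
#' @export
random_split <- function(n, fraction_train = 0.8, n_train = NULL, seed = 1) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(n_train)) n_train <- round(fraction_train * n)
  if (n_train > n) stop("requested training size exceeds n", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_train))
  out <- split_indices(training = sort(idx),
                       test = setdiff(seq_len(n), idx), n = n)
  attr(out, "rng") <- list(kind = RNGkind()[1], seed = seed)
  out
}

## run expr under a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Farthest-point sampling order
#'
#' Greedy max-min ordering over descriptor vectors: the first two points are
#' the globally most distant pair; each next point maximizes its minimum
#' Euclidean distance to all points already selected.  Ties are broken by
#' the lowest index, so the ordering is deterministic.  Any prefix of the
#' returned ordering is itself an FPS sample.
#'
#' @param x Numeric matrix of descriptor vectors (rows = points), >= 2 rows.
#' @return Integer vector: all row indices in selection order.
#' @export
fps_order <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("farthest-point sampling needs at least 2 points", call. = FALSE)
  D <- as.matrix(stats::dist(x))
  # globally most distant pair, ties by lowest (row, col)
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  sel <- sort(as.integer(best))
  min_d <- pmin(D[, sel[1]], D[, sel[2]])
  remaining <- setdiff(seq_len(n), sel)
  while (length(remaining)) {
    nxt <- remaining[which.max(min_d[remaining])]   # which.max: lowest index wins
    sel <- c(sel, nxt)
    remaining <- setdiff(remaining, nxt)
    min_d <- pmin(min_d, D[, nxt])
  }
  sel
}

#' Structure-based sampling order
#'
#' Points are sorted by Euclidean descriptor distance to the equilibrium
#' point, partitioned into `n_slices` contiguous near-equal regions
#' (degrees of deformation), and a greedy farthest-point ordering is built
#' within each slice — the slice containing the equilibrium point is seeded
#' with it.  The full returned ordering interleaves the slices
#' proportionally to their sizes (option `proportional = FALSE` draws
#' equally), so any prefix is a balanced sample across deformation regions.
#' Deterministic: no randomness is involved.
#'
#' @param x Numeric matrix of descriptor vectors (rows = points).
#' @param eq_index Row index of the (near-)equilibrium point.
#' @param n_slices Number of deformation slices (default 5).
#' @param proportional Draw from slices proportionally to slice size
#'   (default) or in equal counts.
#' @return Integer vector: all row indices in selection order; the first
#'   entry is always `eq_index`.
#' @export
sbs_order <- function(x, eq_index, n_slices = 5, proportional = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  eq_index <- as.integer(eq_index)
  if (eq_index < 1L || eq_index > n) stop("eq_index out of bounds", call. = FALSE)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  if (n_slices > n) stop("n_slices exceeds the number of points", call. = FALSE)
  d_eq <- sqrt(colSums((t(x) - x[eq_index, ])^2))
  by_dist <- order(d_eq, seq_len(n))            # eq point lands first
  # near-equal contiguous slices
  slice_id <- integer(n)
  bounds <- round(seq(0, n, length.out = n_slices + 1))
  for (s in seq_len(n_slices)) {
    slice_id[by_dist[(bounds[s] + 1):bounds[s + 1]]] <- s
  }
  slice_orders <- lapply(seq_len(n_slices), function(s) {
    members <- which(slice_id == s)
    if (length(members) == 1L) return(members)
    if (s == 1L) {
      # greedy max-min seeded at the equilibrium point
      sel <- eq_index
      rem <- setdiff(members, sel)
      Dsub <- as.matrix(stats::dist(x[members, , drop = FALSE]))
      rownames(Dsub) <- colnames(Dsub) <- members
      min_d <- Dsub[as.character(members), as.character(eq_index)]
      names(min_d) <- members
      while (length(rem)) {
        nxt <- rem[which.max(min_d[as.character(rem)])]
        sel <- c(sel, nxt)
        rem <- setdiff(rem, nxt)
        min_d <- pmin(min_d, Dsub[, as.character(nxt)])
      }
      sel
    } else {
      members[fps_order(x[members, , drop = FALSE])]
    }
  })
  # proportional (or equal) interleave: repeatedly take from the slice whose
  # consumed fraction is lowest; ties -> lower slice number
  taken <- integer(n_slices)
  sizes <- lengths(slice_orders)
  quota <- if (proportional) sizes else rep(max(sizes), n_slices)
  out <- integer(0)
  while (length(out) < n) {
    frac <- ifelse(taken < sizes, taken / quota, Inf)
    s <- which.min(frac)
    taken[s] <- taken[s] + 1L
    out <- c(out, slice_orders[[s]][taken[s]])
  }
  out
}

#' k-fold cross-validation splits
#'
#' Shuffles the indices once (seeded) and deals them into `k` folds whose
#' sizes differ by at most one; each index appears in exactly one validation
#' fold.  `k = n` gives leave-one-out.
#'
#' @param n Number of records.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return List of `k` [split_indices()] objects with groups `training` and
#'   `validation`.
#' @export
kfold_splits <- function(n, k, seed = 1) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  shuffled <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)    # sizes differ by <= 1
  lapply(seq_len(k), function(f) {
    val <- sort(shuffled[fold_of == f])
    split_indices(training = setdiff(seq_len(n), val), validation = val, n = n)
  })
}

#' Split a dataset with a named sampling scheme
#'
#' Front end over [random_split()], [fps_order()], [sbs_order()] and
#' user-supplied indices, returning training/test groups.
#'
#' @param dataset A [mol_dataset()].
#' @param scheme `"random"`, `"fps"`, `"sbs"` or `"user"`.
#' @param fraction_train Training fraction (default 0.8).
#' @param n_train Optional explicit training count.
#' @param descriptor [descriptor_spec()] used for fps/sbs distances.
#' @param eq_index Equilibrium index for sbs (default 1).
#' @param n_slices Slices for sbs (default 5).
#' @param seed Seed for the random scheme.
#' @param user_split A [split_indices()] for `scheme = "user"`.
#' @return A [split_indices()] with groups `training` and `test`.
#' @export
sample_dataset <- function(dataset, scheme = c("random", "fps", "sbs", "user"),
                           fraction_train = 0.8, n_train = NULL,
                           descriptor = NULL, eq_index = 1L, n_slices = 5,
                           seed = 1, user_split = NULL) {
  scheme <- match.arg(scheme)
  n <- length(dataset)
  if (scheme == "random") return(random_split(n, fraction_train, n_train, seed))
  if (scheme == "user") {
    if (is.null(user_split)) stop("user scheme requires user_split", call. = FALSE)
    return(user_split)
  }
  if (is.null(descriptor)) {
    stop("fps/sbs sampling needs a descriptor_spec for distances", call. = FALSE)
  }
  X <- descriptor_matrix(descriptor, dataset$geometries)
  ord <- if (scheme == "fps") fps_order(X) else sbs_order(X, eq_index, n_slices)
  if (is.null(n_train)) n_train <- round(fraction_train * n)
  split_indices(training = sort(ord[seq_len(n_train)]),
                test = sort(ord[-seq_len(n_train)]), n = n)
}
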