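#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

## Nuclear charges for the elements a single-molecule PES study is likely to
## meet.  Symbols are stored capitalized ("Cl", not "CL").
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, I = 53, Xe = 54
)

## 1 Angstrom in Bohr; used only inside the Coulomb-matrix descriptor.
.ang2bohr <- 1 / 0.52917721067

normalize_symbol <- function(sym) {
  s <- tolower(trimws(sym))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

symbol_to_z <- function(symbols) {
  sym <- normalize_symbol(symbols)
  z <- .element_z[sym]
  bad <- is.na(z)
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(symbols[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(z)
}

#' Construct a molecular geometry
#'
#' A geometry is an ordered set of atoms: chemical symbols plus Cartesian
#' coordinates in Angstrom.  Nuclear charges are derived from the symbols.
#'
#' @param elements Character vector of chemical symbols (one per atom).
#' @param coordinates Numeric matrix with one row per atom and exactly three
#'   columns (x, y, z in Angstrom).
#' @return An object of class `mol_geometry` with fields `elements`,
#'   `coordinates` and `charges`.
#' @examples
#' water <- mol_geometry(
#'   c("O", "H", "H"),
#'   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
#' )
#' water
#' @export
mol_geometry <- function(elements, coordinates) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (ncol(coordinates) != 3L) {
    stop("coordinates must have exactly 3 columns", call. = FALSE)
  }
  if (length(elements) != nrow(coordinates)) {
    stop("length(elements) must equal nrow(coordinates)", call. = FALSE)
  }
  if (length(elements) < 1L) stop("a geometry needs at least one atom", call. = FALSE)
  elements <- normalize_symbol(elements)
  structure(
    list(
      elements = elements,
      coordinates = unname(coordinates),
      charges = symbol_to_z(elements)
    ),
    class = "mol_geometry"
  )
}

#' @export
print.mol_geometry <- function(x, ...) {
  cat("<mol_geometry> ", n_atoms(x), " atoms: ",
      paste(x$elements, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom A `mol_geometry`.
#' @return Integer atom count.
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Construct a molecular dataset
#'
#' Bundles a list of geometries with optional per-geometry reference values
#' (e.g. energies; units are the user's and are never converted) and optional
#' Cartesian gradients (value units per Angstrom).
#'
#' @param geometries List of [mol_geometry()] objects.
#' @param values Optional numeric vector, one value per geometry.
#' @param gradients Optional list of per-geometry `N_at x 3` matrices.
#' @param metadata Optional named list carried along verbatim.
#' @return An object of class `mol_dataset`.
#' @export
mol_dataset <- function(geometries, values = NULL, gradients = NULL,
                        metadata = list()) {
  if (!is.list(geometries) || !all(vapply(geometries, inherits, TRUE, "mol_geometry"))) {
    stop("geometries must be a list of mol_geometry objects", call. = FALSE)
  }
  n <- length(geometries)
  if (!is.null(values)) {
    values <- as.double(values)
    if (length(values) != n) stop("values length must match geometry count", call. = FALSE)
  }
  if (!is.null(gradients)) {
    if (!is.list(gradients) || length(gradients) != n) {
      stop("gradients must be a list with one matrix per geometry", call. = FALSE)
    }
    gradients <- lapply(seq_len(n), function(i) {
      g <- as.matrix(gradients[[i]])
      if (!all(dim(g) == c(n_atoms(geometries[[i]]), 3L))) {
        stop("gradient ", i, " has wrong shape", call. = FALSE)
      }
      storage.mode(g) <- "double"
      unname(g)
    })
  }
  structure(
    list(geometries = geometries, values = values, gradients = gradients,
         metadata = metadata),
    class = "mol_dataset"
  )
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat("<mol_dataset> ", length(x$geometries), " geometries",
      if (!is.null(x$values)) " + values",
      if (!is.null(x$gradients)) " + gradients", "\n", sep = "")
  invisible(x)
}

#' @export
length.mol_dataset <- function(x) length(x$geometries)

#' Subset a dataset by geometry indices
#'
#' Keeps per-index association between geometries, values and gradients.
#'
#' @param dataset A [mol_dataset()].
#' @param idx Integer vector of 1-based geometry indices.
#' @return A new `mol_dataset` with the selected records, in `idx` order.
#' @export
dataset_subset <- function(dataset, idx) {
  idx <- as.integer(idx)
  n <- length(dataset$geometries)
  if (any(idx < 1L | idx > n)) stop("subset indices out of bounds", call. = FALSE)
  mol_dataset(
    geometries = dataset$geometries[idx],
    values = if (!is.null(dataset$values)) dataset$values[idx],
    gradients = if (!is.null(dataset$gradients)) dataset$gradients[idx],
    metadata = dataset$metadata
  )
}

#' Named index groups describing a dataset split
#'
#' @param ... Named integer vectors (e.g. `training =`, `test =`,
#'   `subtraining =`, `validation =`).  Groups must be disjoint.
#' @param n Total number of records the indices refer to (bounds check).
#' @return An object of class `split_indices` (a named list).
#' @export
split_indices <- function(..., n = NULL) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) && is.null(names(groups))) {
    groups <- groups[[1]]
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("all split groups must be named", call. = FALSE)
  }
  groups <- lapply(groups, as.integer)
  all_idx <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("split groups must be disjoint", call. = FALSE)
  if (!is.null(n) && length(all_idx) && any(all_idx < 1L | all_idx > n)) {
    stop("split indices out of bounds", call. = FALSE)
  }
  structure(groups, class = "split_indices", n = n)
}

#' @export
print.split_indices <- function(x, ...) {
  sizes <- vapply(x, length, 1L)
  cat("<split_indices> ", paste(names(x), sizes, sep = ":", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## interatomic distance matrix in Angstrom
dist_matrix <- function(geom) {
  as.matrix(stats::dist(geom$coordinates))
}

same_elements <- function(a, b) identical(a$elements, b$elements)
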