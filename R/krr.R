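#' Train a kernel ridge regression model
#'
#' Solves the regularized linear system `(K + lambda I) alpha = y` by matrix
#' factorization (never explicit inversion).  Cholesky is the default; if it
#' fails the solver falls back, with a warning, to Bunch-Kaufman and then LU.
#' The max-norm residual of the solve is stored in the model metadata, with
#' a warning above 1e-6.
#'
#' @param dataset A [mol_dataset()] with values, **or** a numeric matrix of
#'   precomputed descriptor vectors (rows = points; user descriptors).
#' @param kernel A [kernel_spec()].
#' @param descriptor A [descriptor_spec()] (ignored when `dataset` is a
#'   descriptor matrix).
#' @param lambda Nonnegative regularization (default `2^-35`).
#' @param solver `"cholesky"` (default), `"bunch_kaufman"` or `"lu"`.
#' @param values Reference values when `dataset` is a descriptor matrix.
#' @return A `krr_model` object.
#' @examples
#' ds <- generate_pes_dataset(synthetic_pes_spec("morse_diatomic"), 30, seed = 1)
#' spec <- descriptor_spec("RE", reference_geometry = ds$geometries[[1]])
#' m <- krr_train(ds, kernel_spec("gaussian", sigma = 0.5), spec)
#' predict(m, ds$geometries[1:3])
#' @export
krr_train <- function(dataset, kernel, descriptor = NULL,
                      lambda = 2^-35,
                      solver = c("cholesky", "bunch_kaufman", "lu"),
                      values = NULL) {
  solver <- match.arg(solver)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)

  if (is.matrix(dataset)) {
    if (is.null(values)) stop("values must be supplied with a descriptor matrix",
                              call. = FALSE)
    X <- dataset
    y <- as.double(values)
    geometries <- NULL
    descriptor <- descriptor %||% descriptor_spec("user")
    K <- kernel_matrix_from_x(kernel, X, X, symmetric = TRUE)
  } else {
    if (is.null(dataset$values)) stop("dataset has no reference values", call. = FALSE)
    if (is.null(descriptor)) stop("a descriptor_spec is required", call. = FALSE)
    y <- dataset$values
    geometries <- dataset$geometries
    K <- kernel_matrix(kernel, descriptor, geometries)
    X <- if (is.null(kernel$permutation_groups)) {
      descriptor_matrix(descriptor, geometries)
    }
  }
  n <- length(y)
  A <- K + diag(lambda, n)
  sol <- solve_regularized(A, y, solver)
  residual <- max(abs(A %*% sol$alpha - y))
  if (residual > 1e-6) {
    warning("ill-conditioned kernel system: solve residual ", format(residual),
            call. = FALSE)
  }
  structure(
    list(
      kernel = kernel, descriptor = descriptor, lambda = lambda,
      alpha = as.vector(sol$alpha), training_x = X,
      training_geometries = geometries, training_y = y,
      solver_used = sol$solver, residual = residual,
      format_version = "krrpes-model-1"
    ),
    class = "krr_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finite_or_null <- function(sol) {
  if (all(is.finite(sol$alpha))) sol else NULL
}

## factorized solve with documented fallback chain
solve_regularized <- function(A, y, solver) {
  try_one <- function(s) {
    switch(s,
      cholesky = tryCatch({
        R <- chol(A)
        finite_or_null(list(alpha = backsolve(R, forwardsolve(t(R), y)),
                            solver = "cholesky"))
      }, error = function(e) NULL),
      bunch_kaufman = tryCatch({
        bk <- Matrix::BunchKaufman(Matrix::Matrix(A, sparse = FALSE))
        finite_or_null(list(alpha = as.vector(Matrix::solve(bk, y)),
                            solver = "bunch_kaufman"))
      }, error = function(e) NULL),
      lu = tryCatch(finite_or_null(list(alpha = solve(A, y), solver = "lu")),
                    error = function(e) NULL)
    )
  }
  chain <- switch(solver,
    cholesky = c("cholesky", "bunch_kaufman", "lu"),
    bunch_kaufman = c("bunch_kaufman", "lu"),
    lu = "lu"
  )
  for (i in seq_along(chain)) {
    sol <- try_one(chain[i])
    if (!is.null(sol)) {
      if (i > 1L) {
        warning("solver '", chain[1], "' failed; fell back to '", chain[i], "'",
                call. = FALSE)
      }
      return(sol)
    }
  }
  stop("singular system: all factorizations failed (duplicate training ",
       "points with lambda = 0?)", call. = FALSE)
}

#' @export
print.krr_model <- function(x, ...) {
  cat("<krr_model> ", length(x$alpha), " training points, ",
      x$kernel$family, " kernel (sigma=", format(x$kernel$sigma),
      "), lambda=", format(x$lambda), ", solver=", x$solver_used, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the regression coefficients of a KRR model
#' @param x A `krr_model`.
#' @param ... Unused.
#' @return Tibble with one row per training point (`index`, `alpha`, `y`).
#' @export
tidy.krr_model <- function(x, ...) {
  tibble::tibble(index = seq_along(x$alpha), alpha = x$alpha, y = x$training_y)
}

#' One-row model summary
#' @param x A `krr_model`.
#' @param ... Unused.
#' @return Tibble with kernel family, sigma, lambda, training size, solver
#'   and solve residual.
#' @export
glance.krr_model <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel$family, sigma = x$kernel$sigma, lambda = x$lambda,
    n_train = length(x$alpha), solver = x$solver_used, residual = x$residual
  )
}

#' Predict values with a KRR model
#'
#' `f(x) = sum_j alpha_j k(x, x_j)`.
#'
#' @param object A `krr_model`.
#' @param newdata List of [mol_geometry()], a [mol_dataset()], or a numeric
#'   matrix of descriptor vectors (user-descriptor models).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.krr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "mol_dataset")) newdata <- newdata$geometries
  if (inherits(newdata, "mol_geometry")) newdata <- list(newdata)
  if (is.matrix(newdata)) {
    Kq <- kernel_matrix_from_x(object$kernel, newdata, object$training_x)
    return(as.vector(Kq %*% object$alpha))
  }
  if (!is.null(object$kernel$permutation_groups)) {
    check_query_elements(object, newdata)
    return(vapply(newdata, function(g) {
      ks <- vapply(object$training_geometries, function(tg) {
        perm_kernel_value(object$kernel, g, tg, object$descriptor)
      }, 0)
      sum(object$alpha * ks)
    }, 0))
  }
  if (is.null(object$training_x)) {
    stop("model stores no training descriptors", call. = FALSE)
  }
  check_query_elements(object, newdata)
  Xq <- descriptor_matrix(object$descriptor, newdata)
  Kq <- kernel_matrix_from_x(object$kernel, Xq, object$training_x)
  as.vector(Kq %*% object$alpha)
}

check_query_elements <- function(object, geometries) {
  ref <- object$descriptor$reference_geometry %||% object$training_geometries[[1]]
  if (is.null(ref)) return(invisible())
  ok <- vapply(geometries, function(g) identical(g$elements, ref$elements), TRUE)
  if (!all(ok)) {
    stop("query geometry element sequence does not match the model's", call. = FALSE)
  }
  invisible()
}

#' Predict Cartesian gradients with a KRR model
#'
#' Chain rule through the descriptor Jacobian:
#' `df/dM_at = sum_j alpha_j sum_d dk(x, x_j)/dx_d * dx_d/dM_at`; for the
#' permuted variant the symmetrized-kernel gradient is used instead.
#' Requires a differentiable kernel and a descriptor with an analytic
#' Jacobian (unsorted/permuted RE, unsorted CM, ID).
#'
#' @param model A `krr_model`.
#' @param geometries List of [mol_geometry()] or a [mol_dataset()].
#' @return List of `N_at x 3` gradient matrices (value units per Angstrom).
#' @export
predict_xyz_gradients <- function(model, geometries) {
  if (inherits(geometries, "mol_dataset")) geometries <- geometries$geometries
  if (inherits(geometries, "mol_geometry")) geometries <- list(geometries)
  if (!kernel_is_differentiable(model$kernel)) {
    stop("kernel family is not differentiable; cannot predict gradients",
         call. = FALSE)
  }
  if (model$descriptor$family == "user") {
    stop("user-supplied descriptors carry no Jacobian; gradient prediction ",
         "is unsupported", call. = FALSE)
  }
  if (model$descriptor$variant == "sorted") {
    stop("sorted descriptor variants have no analytic Jacobian", call. = FALSE)
  }
  check_query_elements(model, geometries)
  if (!is.null(model$kernel$permutation_groups)) {
    return(lapply(geometries, function(g) {
      G <- 0
      for (j in seq_along(model$alpha)) {
        G <- G + model$alpha[j] *
          perm_kernel_gradient(model$kernel, g, model$training_geometries[[j]],
                               model$descriptor)
      }
      G
    }))
  }
  lapply(geometries, function(g) {
    dd <- eval_descriptor(model$descriptor, g, with_jacobian = TRUE)
    gx <- numeric(length(dd$x))
    for (j in seq_along(model$alpha)) {
      gx <- gx + model$alpha[j] *
        kernel_gradient(model$kernel, dd$x, model$training_x[j, ])
    }
    matrix(as.vector(crossprod(dd$jacobian, gx)), n_atoms(g), 3, byrow = TRUE)
  })
}

## -- model persistence ------------------------------------------------------

#' Save a KRR model to a versioned JSON container
#'
#' The container stores the kernel and descriptor specs, lambda, training
#' descriptors/geometries, regression coefficients and a format-version
#' string at full double precision, so a reloaded model reproduces
#' predictions bit-identically.
#'
#' @param model A `krr_model`.
#' @param path Output path (conventional extension `.krr`).
#' @return `path`, invisibly.
#' @export
save_krr <- function(model, path) {
  # doubles are stored as %.17g strings: shortest representation that
  # round-trips bit-exactly through text
  num <- function(x) if (is.null(x)) NULL else sprintf("%.17g", as.double(x))
  mat <- function(m) if (is.null(m)) NULL else
    list(dim = dim(m), data = num(as.vector(m)))
  ser_geom <- function(g) list(elements = g$elements,
                               coordinates = mat(g$coordinates))
  payload <- list(
    format_version = model$format_version,
    kernel = list(family = model$kernel$family, sigma = num(model$kernel$sigma),
                  matern_n = model$kernel$matern_n,
                  permutation_groups = unclass(model$kernel$permutation_groups)),
    descriptor = list(
      family = model$descriptor$family, variant = model$descriptor$variant,
      max_atoms = model$descriptor$max_atoms,
      reference_geometry = if (!is.null(model$descriptor$reference_geometry))
        ser_geom(model$descriptor$reference_geometry)
    ),
    lambda = num(model$lambda),
    alpha = num(model$alpha),
    training_y = num(model$training_y),
    training_x = mat(model$training_x),
    training_geometries = if (!is.null(model$training_geometries))
      lapply(model$training_geometries, ser_geom),
    solver_used = model$solver_used,
    residual = num(model$residual)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a KRR model saved by [save_krr()]
#'
#' @param path Path to the model file.
#' @return A `krr_model`.
#' @export
load_krr <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
                        stop("corrupt or truncated model file: ", path,
                             call. = FALSE)
                      })
  if (!identical(payload$format_version, "krrpes-model-1")) {
    stop("incompatible model format version: ",
         payload$format_version %||% "<missing>", call. = FALSE)
  }
  num <- function(x) if (is.null(x)) NULL else as.double(unlist(x))
  de_mat <- function(m) if (is.null(m)) NULL else
    matrix(as.double(unlist(m$data)), unlist(m$dim)[1], unlist(m$dim)[2])
  de_geom <- function(g) mol_geometry(unlist(g$elements), de_mat(g$coordinates))
  pg <- payload$kernel$permutation_groups
  kern <- kernel_spec(payload$kernel$family, num(payload$kernel$sigma),
                      payload$kernel$matern_n,
                      permutation_groups = if (length(pg))
                        permutation_groups(as_group_list(pg)))
  ref <- payload$descriptor$reference_geometry
  dsp <- descriptor_spec(payload$descriptor$family, payload$descriptor$variant,
                         reference_geometry = if (!is.null(ref)) de_geom(ref),
                         permutation_groups = kern$permutation_groups,
                         max_atoms = payload$descriptor$max_atoms)
  tg <- payload$training_geometries
  if (!is.null(tg) && length(tg)) tg <- lapply(tg, de_geom) else tg <- NULL
  structure(
    list(kernel = kern, descriptor = dsp, lambda = num(payload$lambda),
         alpha = num(payload$alpha), training_x = de_mat(payload$training_x),
         training_geometries = tg, training_y = num(payload$training_y),
         solver_used = payload$solver_used, residual = num(payload$residual),
         format_version = payload$format_version),
    class = "krr_model"
  )
}

as_group_list <- function(pg) {
  if (is.list(pg)) lapply(pg, function(g) as.integer(unlist(g)))
  else list(as.integer(pg))
}
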