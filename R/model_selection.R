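#' Loss specification for model selection
#'
#' Three ways to turn per-property errors into one scalar: values only,
#' the weighted sum `L = L_val + w_grxyz * L_grxyz`, or the parameter-free
#' geometric mean `L = sqrt(L_val * L_grxyz)`.
#'
#' @param mode `"values_only"` (default), `"sum_weighted"` or
#'   `"geometric_mean"`.
#' @param w_grxyz Nonnegative gradient weight; required for `sum_weighted`.
#' @param base_metric `"RMSE"` (default) or `"MAE"`.
#' @return A `loss_spec` object.
#' @export
loss_spec <- function(mode = c("values_only", "sum_weighted", "geometric_mean"),
                      w_grxyz = NULL, base_metric = c("RMSE", "MAE")) {
  mode <- match.arg(mode)
  base_metric <- match.arg(base_metric)
  if (mode == "sum_weighted") {
    if (is.null(w_grxyz) || w_grxyz < 0) {
      stop("sum_weighted requires a nonnegative w_grxyz", call. = FALSE)
    }
  }
  structure(list(mode = mode, w_grxyz = w_grxyz, base_metric = base_metric),
            class = "loss_spec")
}

#' Combine value and gradient losses
#'
#' @param spec A [loss_spec()].
#' @param l_val Nonnegative value loss.
#' @param l_grxyz Nonnegative gradient loss (required unless
#'   `mode = "values_only"`).
#' @return Scalar combined loss.
#' @export
combined_loss <- function(spec, l_val, l_grxyz = NULL) {
  if (l_val < 0 || (!is.null(l_grxyz) && l_grxyz < 0)) {
    stop("losses must be nonnegative", call. = FALSE)
  }
  switch(spec$mode,
    values_only = l_val,
    sum_weighted = {
      if (is.null(l_grxyz)) stop("gradient loss missing for sum_weighted", call. = FALSE)
      l_val + spec$w_grxyz * l_grxyz
    },
    geometric_mean = {
      if (is.null(l_grxyz)) stop("gradient loss missing for geometric_mean", call. = FALSE)
      sqrt(l_val * l_grxyz)
    }
  )
}

#' Grid specification for nested hyperparameter search
#'
#' Both hyperparameters are searched on a logarithmic grid: `points` values
#' evenly spaced in `log_base` exponents between `min_exp` and `max_exp`,
#' for `n_passes` passes.  After each pass the grid re-centers (in log
#' space) on the best point, one current grid step to each side.
#'
#' @param sigma_exp Range of sigma exponents (default `c(2, 9)`, base 2).
#' @param lambda_exp Range of lambda exponents (default `c(-35, -6)`).
#' @param points Grid points per hyperparameter per pass (default 11).
#' @param n_passes Refinement passes (default 3).
#' @param log_base Logarithm base (default 2).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(sigma_exp = c(2, 9), lambda_exp = c(-35, -6),
                      points = 11, n_passes = 3, log_base = 2) {
  stopifnot(sigma_exp[1] < sigma_exp[2], lambda_exp[1] < lambda_exp[2],
            points >= 2, n_passes >= 1)
  structure(list(sigma_exp = sigma_exp, lambda_exp = lambda_exp,
                 points = as.integer(points), n_passes = as.integer(n_passes),
                 log_base = log_base),
            class = "grid_spec")
}

## validation loss of one (sigma, lambda) candidate using precomputed
## descriptor blocks; returns list(loss, l_val, l_grxyz) or NULL on failure
.candidate_loss <- function(sigma, lambda, env) {
  kern <- kernel_spec(env$kernel_family, sigma, env$matern_n,
                      permutation_groups = env$perm_groups)
  model <- tryCatch(
    suppressWarnings(
      if (is.null(env$perm_groups)) {
        krr_train(env$X_sub, kern, env$descriptor, lambda, values = env$y_sub)
      } else {
        krr_train(env$sub_dataset, kern, env$descriptor, lambda)
      }
    ),
    error = function(e) NULL
  )
  if (is.null(model)) return(NULL)
  pred <- if (is.null(env$perm_groups)) {
    as.vector(kernel_matrix_from_x(kern, env$X_val, env$X_sub) %*% model$alpha)
  } else {
    predict(model, env$val_geoms)
  }
  metric <- function(e) if (env$loss$base_metric == "MAE") mean(abs(e)) else sqrt(mean(e^2))
  l_val <- metric(pred - env$y_val)
  l_gr <- NULL
  if (env$loss$mode != "values_only") {
    gp <- predict_xyz_gradients(model, env$val_geoms)
    comp_err <- unlist(Map(function(a, b) as.vector(a - b), gp, env$g_val))
    l_gr <- metric(comp_err)
  }
  list(loss = combined_loss(env$loss, l_val, l_gr), l_val = l_val,
       l_grxyz = l_gr, model = model)
}

#' Nested logarithmic grid search for sigma and lambda
#'
#' Exhaustively evaluates each grid pass by training on the sub-training
#' set and scoring on the validation set; the next pass brackets the best
#' point one grid step to each side in log space.  Ties prefer smaller
#' lambda, then smaller sigma (smoothness bias).  After the final pass the
#' model is retrained on the whole training set (sub-training plus
#' validation) with the best hyperparameters.
#'
#' @param dataset A [mol_dataset()] with values (and gradients when the loss
#'   needs them).
#' @param kernel_family Kernel family name (see [kernel_spec()]).
#' @param descriptor A [descriptor_spec()].
#' @param grid A [grid_spec()].
#' @param loss A [loss_spec()].
#' @param fraction_sub Sub-training fraction of the training set (default
#'   0.8, mirroring the platform's 80:20 default).
#' @param seed Seed for the sub-training/validation split.
#' @param matern_n Matern order when `kernel_family = "matern"`.
#' @param permutation_groups Optional [permutation_groups()] for the
#'   symmetrized kernel.
#' @return List with `sigma`, `lambda`, `model` (retrained on the full
#'   training set), `best_loss`, and `log` — a tibble with one row per
#'   evaluated candidate (pass, sigma, lambda, L_val, L_grxyz, L).
#' @export
grid_search <- function(dataset, kernel_family = "gaussian", descriptor,
                        grid = grid_spec(), loss = loss_spec(),
                        fraction_sub = 0.8, seed = 1, matern_n = 2L,
                        permutation_groups = NULL) {
  if (is.null(dataset$values)) stop("dataset has no values", call. = FALSE)
  if (loss$mode != "values_only" && is.null(dataset$gradients)) {
    stop("loss mode needs gradients but the dataset has none", call. = FALSE)
  }
  n <- length(dataset)
  split <- random_split(n, fraction_train = fraction_sub, seed = seed)
  sub_i <- split$training
  val_i <- split$test

  env <- new.env(parent = emptyenv())
  env$kernel_family <- kernel_family
  env$matern_n <- matern_n
  env$perm_groups <- permutation_groups
  env$descriptor <- descriptor
  env$loss <- loss
  env$sub_dataset <- dataset_subset(dataset, sub_i)
  env$val_geoms <- dataset$geometries[val_i]
  env$y_sub <- dataset$values[sub_i]
  env$y_val <- dataset$values[val_i]
  env$g_val <- if (!is.null(dataset$gradients)) dataset$gradients[val_i]
  if (is.null(permutation_groups)) {
    X <- descriptor_matrix(descriptor, dataset$geometries)
    env$X_sub <- X[sub_i, , drop = FALSE]
    env$X_val <- X[val_i, , drop = FALSE]
  }

  lb <- grid$log_base
  s_lo <- grid$sigma_exp[1]; s_hi <- grid$sigma_exp[2]
  l_lo <- grid$lambda_exp[1]; l_hi <- grid$lambda_exp[2]
  log_rows <- list()
  best <- NULL
  for (pass in seq_len(grid$n_passes)) {
    s_grid <- seq(s_lo, s_hi, length.out = grid$points)
    l_grid <- seq(l_lo, l_hi, length.out = grid$points)
    pass_best <- NULL
    for (le in l_grid) {
      for (se in s_grid) {
        cand <- .candidate_loss(lb^se, lb^le, env)
        if (is.null(cand)) next
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          pass = pass, sigma = lb^se, lambda = lb^le,
          L_val = cand$l_val,
          L_grxyz = if (is.null(cand$l_grxyz)) NA_real_ else cand$l_grxyz,
          L = cand$loss
        )
        better <- is.null(pass_best) || cand$loss < pass_best$loss ||
          (cand$loss == pass_best$loss &&
             (le < pass_best$le || (le == pass_best$le && se < pass_best$se)))
        if (better) pass_best <- list(loss = cand$loss, se = se, le = le)
      }
    }
    if (is.null(pass_best)) stop("all grid candidates failed to train", call. = FALSE)
    if (is.null(best) || pass_best$loss <= best$loss) best <- pass_best
    # re-center one current grid step to each side of the pass best
    s_step <- (s_hi - s_lo) / (grid$points - 1)
    l_step <- (l_hi - l_lo) / (grid$points - 1)
    s_lo <- pass_best$se - s_step; s_hi <- pass_best$se + s_step
    l_lo <- pass_best$le - l_step; l_hi <- pass_best$le + l_step
  }
  sigma <- lb^best$se
  lambda <- lb^best$le
  final_kernel <- kernel_spec(kernel_family, sigma, matern_n,
                              permutation_groups = permutation_groups)
  final <- krr_train(dataset, final_kernel, descriptor, lambda)
  list(sigma = sigma, lambda = lambda, model = final, best_loss = best$loss,
       log = dplyr::bind_rows(log_rows))
}

#' Evaluate a trained model on a test set
#'
#' Runs the full statistics suite on value predictions (and gradient RMSE
#' when the test set carries gradients).  If training indices are known and
#' overlap the test indices a warning flags the overlap.
#'
#' @param model A `krr_model`.
#' @param test_dataset A nonempty [mol_dataset()] with values.
#' @param train_indices,test_indices Optional index vectors used only for
#'   the disjointness check.
#' @return List with `values` (an [error_report()]) and optionally
#'   `gradient_rmse`.
#' @export
evaluate_model <- function(model, test_dataset, train_indices = NULL,
                           test_indices = NULL) {
  if (!length(test_dataset)) stop("empty test set", call. = FALSE)
  if (is.null(test_dataset$values)) stop("test set has no values", call. = FALSE)
  if (!is.null(train_indices) && !is.null(test_indices) &&
      length(intersect(train_indices, test_indices))) {
    warning("test set overlaps the training set; statistics are optimistic",
            call. = FALSE)
  }
  pred <- predict(model, test_dataset)
  out <- list(values = error_report(pred, test_dataset$values))
  if (!is.null(test_dataset$gradients) && model$descriptor$family != "user" &&
      model$descriptor$variant != "sorted" && kernel_is_differentiable(model$kernel)) {
    gp <- predict_xyz_gradients(model, test_dataset)
    out$gradient_rmse <- gradient_rmse(gp, test_dataset$gradients)
  }
  out
}
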