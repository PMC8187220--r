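#' Train a delta-learning correction model
#'
#' Learns the difference between an expensive target method and a cheap
#' baseline method: the correction model is an ordinary KRR model trained on
#' `target - baseline`, and predictions add the user-supplied baseline back
#' (`prediction = baseline + correction`).
#'
#' @param dataset A [mol_dataset()]; its `values` are the **target** values.
#' @param baseline Numeric vector of baseline values, one per geometry.
#' @param kernel A [kernel_spec()].
#' @param descriptor A [descriptor_spec()].
#' @param lambda Regularization (default `2^-35`).
#' @return A `delta_model` wrapping the correction `krr_model`.
#' @export
train_delta <- function(dataset, baseline, kernel, descriptor, lambda = 2^-35) {
  if (is.null(dataset$values)) stop("dataset has no target values", call. = FALSE)
  if (is.null(baseline) || length(baseline) != length(dataset)) {
    stop("baseline values missing or of wrong length", call. = FALSE)
  }
  diff_ds <- mol_dataset(dataset$geometries,
                         values = dataset$values - as.double(baseline))
  corr <- krr_train(diff_ds, kernel, descriptor, lambda)
  structure(list(correction = corr), class = "delta_model")
}

#' Predict with a delta-learning model
#'
#' Element-wise `baseline + correction` — the baseline must be supplied for
#' every query geometry (it comes from the cheap reference method, not from
#' ML).
#'
#' @param model A `delta_model`.
#' @param geometries List of [mol_geometry()] or a [mol_dataset()].
#' @param baseline Numeric baseline values, one per query.
#' @return Numeric vector of target-level predictions.
#' @export
predict_delta <- function(model, geometries, baseline) {
  if (inherits(geometries, "mol_dataset")) geometries <- geometries$geometries
  if (length(baseline) != length(geometries)) {
    stop("a baseline value is required for every query geometry", call. = FALSE)
  }
  if (!length(geometries)) return(numeric(0))
  as.double(baseline) + predict(model$correction, geometries)
}

#' @export
print.delta_model <- function(x, ...) {
  cat("<delta_model> correction: ")
  print(x$correction)
  invisible(x)
}

#' Train a self-correcting model stack
#'
#' Layer 1 is trained on the values; every further layer is trained on the
#' residual of the running sum of the previous layers.  Prediction is the
#' sum of all layers.
#'
#' @param dataset A [mol_dataset()] with values.
#' @param kernel A [kernel_spec()].
#' @param descriptor A [descriptor_spec()].
#' @param n_layers Number of layers (>= 1).
#' @param lambda Regularization, recycled across layers.
#' @return A `self_correction_model` with fields `layers` and
#'   `layer_targets` (the training targets each layer saw).
#' @export
train_self_correction <- function(dataset, kernel, descriptor, n_layers = 2,
                                  lambda = 2^-35) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("n_layers must be >= 1", call. = FALSE)
  if (is.null(dataset$values)) stop("dataset has no values", call. = FALSE)
  lambda <- rep_len(lambda, n_layers)
  residual <- dataset$values
  layers <- vector("list", n_layers)
  targets <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    targets[[i]] <- residual
    layer_ds <- mol_dataset(dataset$geometries, values = residual)
    layers[[i]] <- tryCatch(
      krr_train(layer_ds, kernel, descriptor, lambda[i]),
      error = function(e) stop("training failed in layer ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    residual <- residual - predict(layers[[i]], dataset$geometries)
  }
  structure(list(layers = layers, layer_targets = targets,
                 final_residual = residual),
            class = "self_correction_model")
}

#' Predict with a self-correcting model stack
#' @param object A `self_correction_model`.
#' @param newdata Geometries (list or [mol_dataset()]).
#' @param ... Unused.
#' @return Numeric vector: the sum of all layers' predictions.
#' @export
predict.self_correction_model <- function(object, newdata, ...) {
  preds <- lapply(object$layers, predict, newdata)
  Reduce(`+`, preds)
}

#' @export
print.self_correction_model <- function(x, ...) {
  cat("<self_correction_model> ", length(x$layers), " layers\n", sep = "")
  invisible(x)
}

#' Automatic learning-curve generation
#'
#' For every training size and repeat: sample a fresh (seeded) training set
#' from the pool, optionally optimize hyperparameters, train, and evaluate
#' the test RMSE/MAE.  By default one fixed held-out test set is shared by
#' all sizes and repeats (paired comparisons); `fixed_test = FALSE` samples
#' the test set per repeat instead.  Wall-clock training/prediction times
#' are recorded for information only.
#'
#' @param dataset A [mol_dataset()] with values.
#' @param kernel A [kernel_spec()]; its sigma/lambda are used when
#'   `optimize = FALSE`.
#' @param descriptor A [descriptor_spec()].
#' @param sizes Integer vector of training-set sizes.
#' @param repeats Repeats per size (default 5).
#' @param n_test Test-set size (default: all points not used for training at
#'   the largest size).
#' @param seed Master seed; each size/repeat derives its own sub-seed.
#' @param optimize Optimize sigma/lambda per repeat via [grid_search()]?
#' @param grid,loss Passed to [grid_search()] when optimizing.
#' @param lambda Regularization when not optimizing.
#' @param fixed_test Share one held-out test set (default) or resample per
#'   repeat.
#' @return A `learning_curve` object: tibble `table` with columns `Ntrain`,
#'   `repeat_id`, `seed`, `RMSE_test`, `MAE_test`, `t_train_s`,
#'   `t_predict_s`, `fixed_test`, plus the power-law `fit` on the mean
#'   RMSEs (see [fit_power_law()]).
#' @export
learning_curve <- function(dataset, kernel, descriptor, sizes, repeats = 5,
                           n_test = NULL, seed = 1, optimize = FALSE,
                           grid = grid_spec(), loss = loss_spec(),
                           lambda = 2^-35, fixed_test = TRUE) {
  if (is.null(dataset$values)) stop("dataset has no values", call. = FALSE)
  n <- length(dataset)
  sizes <- as.integer(sizes)
  if (is.null(n_test)) n_test <- n - max(sizes)
  if (n_test < 1L) stop("no points left for the test set", call. = FALSE)

  test_fixed <- if (fixed_test) {
    with_seed(seed, sample.int(n, n_test))
  }
  rows <- list()
  for (si in seq_along(sizes)) {
    ntr <- sizes[si]
    pool_max <- n - n_test
    if (ntr > pool_max) {
      warning("size ", ntr, " skipped: only ", pool_max,
              " points available for training", call. = FALSE)
      next
    }
    for (rep_i in seq_len(repeats)) {
      sub_seed <- (seed * 10000L + si * 100L + rep_i) %% .Machine$integer.max
      test_i <- if (fixed_test) test_fixed else {
        with_seed(sub_seed + 1L, sample.int(n, n_test))
      }
      pool <- setdiff(seq_len(n), test_i)
      train_i <- with_seed(sub_seed, sample(pool, ntr))
      train_ds <- dataset_subset(dataset, train_i)
      test_ds <- dataset_subset(dataset, test_i)
      t0 <- proc.time()[["elapsed"]]
      model <- if (optimize) {
        grid_search(train_ds, kernel$family, descriptor, grid, loss,
                    seed = sub_seed, matern_n = kernel$matern_n,
                    permutation_groups = kernel$permutation_groups)$model
      } else {
        krr_train(train_ds, kernel, descriptor, lambda)
      }
      t1 <- proc.time()[["elapsed"]]
      pred <- predict(model, test_ds)
      t2 <- proc.time()[["elapsed"]]
      err <- pred - test_ds$values
      rows[[length(rows) + 1L]] <- tibble::tibble(
        Ntrain = ntr, repeat_id = rep_i, seed = sub_seed,
        RMSE_test = sqrt(mean(err^2)), MAE_test = mean(abs(err)),
        t_train_s = t1 - t0, t_predict_s = t2 - t1, fixed_test = fixed_test
      )
    }
  }
  table <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(dplyr::group_by(table, .data$Ntrain),
                            rmse = mean(.data$RMSE_test), .groups = "drop")
  fit <- if (nrow(means) >= 3) {
    tryCatch(fit_power_law(means$Ntrain, means$rmse), error = function(e) NULL)
  }
  structure(list(table = table, fit = fit), class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve> ", nrow(x$table), " runs over ",
      length(unique(x$table$Ntrain)), " sizes\n", sep = "")
  if (!is.null(x$fit)) {
    cat("  power law: eps_a=", format(x$fit$eps_a, digits = 4),
        ", a=", format(x$fit$a, digits = 4),
        ", b=", format(x$fit$b, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a learning curve
#' @param x A `learning_curve`.
#' @param ... Unused.
#' @return The per-run tibble.
#' @export
tidy.learning_curve <- function(x, ...) x$table

#' One-row learning-curve summary (power-law parameters)
#' @param x A `learning_curve`.
#' @param ... Unused.
#' @return Tibble with `eps_a`, `a`, `b` (NA when the fit failed).
#' @export
glance.learning_curve <- function(x, ...) {
  if (is.null(x$fit)) {
    tibble::tibble(eps_a = NA_real_, a = NA_real_, b = NA_real_)
  } else {
    tibble::tibble(eps_a = x$fit$eps_a, a = x$fit$a, b = x$fit$b)
  }
}

#' Write a learning-curve table to CSV
#' @param lc A `learning_curve` (or its tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_learning_curve <- function(lc, path) {
  tb <- if (inherits(lc, "learning_curve")) lc$table else lc
  utils::write.csv(as.data.frame(tb), path, row.names = FALSE)
  invisible(path)
}

#' Read a learning-curve CSV written by [write_learning_curve()]
#' @param path CSV path.
#' @return Tibble with the recorded columns.
#' @export
read_learning_curve <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Fit the power-law decay of a learning curve
#'
#' Nonlinear least squares of `eps = eps_a + a / N^b` with constraints
#' `eps_a >= 0`, `a >= 0`, `b > 0` (Levenberg-Marquardt with box bounds).
#' The initial guess comes from the log-log linear fit
#' `log(eps) ~ log(a) - b log(N)` (which assumes `eps_a = 0`); ten
#' deterministic multi-starts perturb that seed and the lowest-residual
#' solution wins.  If no start converges, the log-log fallback is reported
#' with a warning.  Constant errors yield `eps_a = const`, `a -> 0` and an
#' unidentifiable-exponent flag.
#'
#' @param sizes Training-set sizes (>= 3 distinct values).
#' @param errors Positive errors, one per size.
#' @param log_residuals Minimize squared residuals of `log(eps)` instead of
#'   `eps` (default `FALSE`).  The log objective is the maximum-likelihood
#'   choice when the errors carry multiplicative (relative) noise, which is
#'   the usual situation for RMSEs spanning orders of magnitude.
#' @return List with `eps_a`, `a`, `b`, `converged`, and
#'   `b_identifiable`.
#' @export
fit_power_law <- function(sizes, errors, log_residuals = FALSE) {
  sizes <- as.double(sizes); errors <- as.double(errors)
  if (length(unique(sizes)) < 3L) stop("need >= 3 distinct sizes", call. = FALSE)
  if (any(errors <= 0)) stop("errors must be positive", call. = FALSE)
  if (max(errors) - min(errors) < 1e-14 * max(errors)) {
    return(list(eps_a = mean(errors), a = 0, b = NA_real_, converged = TRUE,
                b_identifiable = FALSE))
  }
  ll <- stats::lm(log(errors) ~ log(sizes))
  a0 <- exp(stats::coef(ll)[[1]])
  b0 <- max(-stats::coef(ll)[[2]], 1e-3)
  df <- data.frame(N = sizes, eps = errors)
  starts <- list(c(0, a0, b0))
  mults <- c(0.25, 0.5, 1, 2, 4)
  for (m in mults) {
    starts[[length(starts) + 1L]] <- c(min(errors) / 2, a0 * m, b0)
    starts[[length(starts) + 1L]] <- c(0, a0, min(max(b0 * m, 1e-3), 10))
  }
  starts <- starts[seq_len(min(10L, length(starts)))]
  df$leps <- log(df$eps)
  form <- if (log_residuals) leps ~ log(eps_a + a / N^b) else eps ~ eps_a + a / N^b
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      form, data = df,
      start = list(eps_a = st[1], a = st[2], b = st[3]),
      lower = c(0, 0, 1e-8), upper = c(Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(rss = rss, eps_a = cf[["eps_a"]], a = cf[["a"]], b = cf[["b"]])
    }
  }
  if (is.null(best)) {
    warning("power-law fit did not converge; returning log-log fallback",
            call. = FALSE)
    return(list(eps_a = 0, a = a0, b = b0, converged = FALSE,
                b_identifiable = TRUE))
  }
  list(eps_a = best$eps_a, a = best$a, b = best$b, converged = TRUE,
       b_identifiable = TRUE)
}
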