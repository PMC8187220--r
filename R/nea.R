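#' Configuration of the ML nuclear-ensemble spectrum pipeline
#'
#' @param n_batch Training points added per iteration (default 50; the
#'   initial batch has the same size).
#' @param rrmse_threshold Convergence threshold on the relative change of
#'   the geometric-mean validation RMSE (default 0.1).
#' @param delta Gaussian broadening factor in eV (default 0.01); the
#'   lineshape standard deviation is `delta / 2`.
#' @param grid_min,grid_max,grid_step Energy grid in eV.  Defaults: the
#'   labeled transition-energy range padded by `10 * delta`, step
#'   `delta / 5`.
#' @param signed_rrmse Use the literal signed convergence reading
#'   (`rRMSE < threshold`, satisfied by any improvement) instead of the
#'   default absolute-value test `|rRMSE| < threshold`.
#' @return An `nea_config` object.
#' @export
nea_config <- function(n_batch = 50, rrmse_threshold = 0.1, delta = 0.01,
                       grid_min = NULL, grid_max = NULL, grid_step = NULL,
                       signed_rrmse = FALSE) {
  stopifnot(n_batch >= 1, rrmse_threshold > 0, delta > 0)
  structure(list(n_batch = as.integer(n_batch),
                 rrmse_threshold = rrmse_threshold, delta = delta,
                 grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step, signed_rrmse = signed_rrmse),
            class = "nea_config")
}

#' A nuclear ensemble with excited-state labels
#'
#' @param geometries List of [mol_geometry()] (the `N_p` ensemble points).
#' @param energies Optional `N_p x N_fs` matrix of vertical excitation
#'   energies in eV (rows may be NA for unlabeled points).
#' @param strengths Optional `N_p x N_fs` matrix of oscillator strengths
#'   (dimensionless).
#' @return A `spectrum_ensemble` object.
#' @export
spectrum_ensemble <- function(geometries, energies = NULL, strengths = NULL) {
  n <- length(geometries)
  if (!is.null(energies)) {
    energies <- as.matrix(energies)
    if (nrow(energies) != n) stop("energies must have one row per geometry", call. = FALSE)
  }
  if (!is.null(strengths)) {
    strengths <- as.matrix(strengths)
    if (!all(dim(strengths) == dim(energies))) {
      stop("strengths shape must match energies", call. = FALSE)
    }
  }
  structure(list(geometries = geometries, energies = energies,
                 strengths = strengths),
            class = "spectrum_ensemble")
}

#' @export
print.spectrum_ensemble <- function(x, ...) {
  cat("<spectrum_ensemble> ", length(x$geometries), " points",
      if (!is.null(x$energies)) paste0(", ", ncol(x$energies), " states"),
      "\n", sep = "")
  invisible(x)
}

#' Geometric mean of per-model validation RMSEs
#'
#' For `N_fs` excited states the pipeline trains `2 N_fs` models (one per
#' excitation energy, one per oscillator strength); their joint accuracy is
#' the `2 N_fs`-th root of the product of all validation RMSEs.
#'
#' @param rmses Positive numeric vector of per-model RMSEs.
#' @return Scalar geometric mean.
#' @export
rmse_geom <- function(rmses) {
  rmses <- as.double(rmses)
  if (any(rmses <= 0)) {
    stop("geometric mean undefined for nonpositive RMSEs", call. = FALSE)
  }
  exp(mean(log(rmses)))
}

#' Relative change of the geometric-mean RMSE
#'
#' `(rmse_now - rmse_prev) / rmse_now`; signed, so an improving model gives
#' a negative value.  The convergence test uses the absolute value by
#' default (see [nea_config()]).
#'
#' @param rmse_now Current geometric-mean RMSE (> 0).
#' @param rmse_prev Previous iteration's geometric-mean RMSE.
#' @return Signed relative change.
#' @export
rrmse <- function(rmse_now, rmse_prev) {
  if (rmse_now <= 0) stop("rmse_now must be > 0", call. = FALSE)
  (rmse_now - rmse_prev) / rmse_now
}

#' Iteratively train the 2 N_fs excited-state surrogate models
#'
#' Starting from an initial batch of `n_batch` ensemble points (taken in
#' farthest-point order over the descriptor vectors), each iteration labels
#' `n_batch` more points via `label_oracle`, trains one KRR model per
#' excitation energy and one per oscillator strength, and scores each by
#' 5-fold cross-validated RMSE (each fold trains on 80% and validates on
#' 20% of the labeled points; out-of-fold residuals are pooled).  Training
#' stops when the relative change `|rRMSE|` of the geometric-mean RMSE
#' drops below the threshold or the ensemble is exhausted.
#'
#' @param ensemble A [spectrum_ensemble()] (labels not required; they come
#'   from the oracle).
#' @param label_oracle `function(indices)` returning
#'   `list(energies =, strengths =)` matrices (`length(indices) x N_fs`)
#'   for the requested ensemble indices.
#' @param n_states Number of excited states `N_fs`.
#' @param config An [nea_config()].
#' @param kernel A [kernel_spec()] used for every surrogate model.
#' @param descriptor A [descriptor_spec()].
#' @param lambda Regularization for the surrogate models.
#' @param acquisition `"fps"` (default) or `"random"` ordering of ensemble
#'   points for labeling.
#' @param seed Seed for splits (and random acquisition).
#' @return List with `models` (`energy` and `strength` model lists), the
#'   labeled `indices`, and `log` — a tibble with per-iteration `iteration`,
#'   `N_tr`, per-model RMSE columns, `RMSE_geom` and `rRMSE`.
#' @export
nea_iterative_train <- function(ensemble, label_oracle, n_states, config,
                                kernel, descriptor, lambda = 2^-35,
                                acquisition = c("fps", "random"), seed = 1) {
  acquisition <- match.arg(acquisition)
  np <- length(ensemble$geometries)
  X <- descriptor_matrix(descriptor, ensemble$geometries)
  order_all <- if (acquisition == "fps") fps_order(X) else
    with_seed(seed, sample.int(np))

  log_rows <- list()
  prev_geom <- NA_real_
  labeled <- integer(0)
  labels_e <- NULL
  labels_f <- NULL
  models_e <- models_f <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    n_new <- min(config$n_batch, np - length(labeled))
    if (n_new == 0L) {
      warning("ensemble labels exhausted before convergence", call. = FALSE)
      break
    }
    new_idx <- order_all[(length(labeled) + 1L):(length(labeled) + n_new)]
    lab <- tryCatch(label_oracle(new_idx), error = function(e) {
      # abort but keep the partial convergence log on the condition
      stop(structure(
        class = c("krrpes_oracle_error", class(e)[class(e) != "simpleError"],
                  "error", "condition"),
        list(message = paste0("label oracle failed at iteration ", iter, ": ",
                              conditionMessage(e)),
             call = NULL, partial_log = dplyr::bind_rows(log_rows),
             indices = e$indices)
      ))
    })
    labeled <- c(labeled, new_idx)
    labels_e <- rbind(labels_e, as.matrix(lab$energies))
    labels_f <- rbind(labels_f, as.matrix(lab$strengths))

    ntr <- length(labeled)
    X_lab <- X[labeled, , drop = FALSE]
    # validation RMSE by 5-fold cross-validation (each fold keeps the 80:20
    # sub-training:validation proportion); pooling the out-of-fold residuals
    # over the whole labeled set makes the rRMSE convergence signal far less
    # noisy than a single random split
    folds <- kfold_splits(ntr, k = min(5L, ntr),
                          seed = (seed + iter) %% .Machine$integer.max)
    cv_rmse <- function(yv) {
      res <- numeric(ntr)
      for (fd in folds) {
        m <- krr_train(X_lab[fd$training, , drop = FALSE], kernel, descriptor,
                       lambda, values = yv[fd$training])
        res[fd$validation] <-
          predict(m, X_lab[fd$validation, , drop = FALSE]) - yv[fd$validation]
      }
      sqrt(mean(res^2))
    }
    rmses <- c(vapply(seq_len(n_states), function(s) cv_rmse(labels_e[, s]), 0),
               vapply(seq_len(n_states), function(s) cv_rmse(labels_f[, s]), 0))
    rmses <- pmax(rmses, .Machine$double.eps)   # geometric mean needs > 0
    rg <- rmse_geom(rmses)
    rr <- if (iter == 1L) NA_real_ else rrmse(rg, prev_geom)
    row <- tibble::tibble(iteration = iter, N_tr = ntr, RMSE_geom = rg,
                          rRMSE = rr)
    for (s in seq_len(n_states)) {
      row[[paste0("RMSE_dE_", s)]] <- rmses[s]
      row[[paste0("RMSE_f_", s)]] <- rmses[n_states + s]
    }
    log_rows[[iter]] <- row
    conv <- if (is.na(rr)) FALSE else if (config$signed_rrmse) {
      rr < config$rrmse_threshold
    } else {
      abs(rr) < config$rrmse_threshold
    }
    prev_geom <- rg
    if (conv) break
  }
  # final models retrained on all labeled points
  X_lab <- X[labeled, , drop = FALSE]
  models_e <- lapply(seq_len(n_states), function(s) {
    krr_train(X_lab, kernel, descriptor, lambda, values = labels_e[, s])
  })
  models_f <- lapply(seq_len(n_states), function(s) {
    krr_train(X_lab, kernel, descriptor, lambda, values = labels_f[, s])
  })
  list(models = list(energy = models_e, strength = models_f),
       indices = labeled,
       labels = list(energies = labels_e, strengths = labels_f),
       descriptors = X,
       log = dplyr::bind_rows(log_rows))
}

## sigma_prefactor: pi e^2 hbar / (2 m c eps0), CODATA 2018, in SI (m^2 J).
## Dividing by E in J gives a cross section in m^2; we report Angstrom^2
## per molecule with E in eV.
.nea_prefactor_ang2_ev <- function() {
  e <- 1.602176634e-19
  hbar <- 1.054571817e-34
  m <- 9.1093837015e-31
  c <- 299792458
  eps0 <- 8.8541878128e-12
  si <- pi * e^2 * hbar / (2 * m * c * eps0)   # m^2 J
  si / e * 1e20                                # Angstrom^2 eV
}

#' Nuclear-ensemble absorption cross section
#'
#' Gaussian-broadened sum over ensemble points and states:
#' `sigma(E) = prefactor / E * sum_n 1/N_p sum_i dE_i,n f_i,n *
#' N(E; dE_i,n, delta/2)` with `N` the normal density of standard deviation
#' `delta / 2`.  Negative oscillator strengths are set to zero before
#' summation.  The prefactor `pi e^2 hbar / (2 m c eps0)` uses CODATA
#' constants; output units are Angstrom^2 per molecule with the photon
#' energy `E` in eV (the `1/E` factor is evaluated at the grid energy).
#'
#' @param energies `N_p x N_fs` matrix of transition energies (eV).
#' @param strengths `N_p x N_fs` matrix of oscillator strengths.
#' @param config An [nea_config()]; supplies `delta` and the energy grid.
#' @return Tibble with columns `E_eV` and `sigma` (class
#'   `nea_spectrum`).
#' @export
cross_section <- function(energies, strengths, config = nea_config()) {
  energies <- as.matrix(energies)
  strengths <- as.matrix(strengths)
  if (!length(energies)) stop("empty predictions", call. = FALSE)
  if (!all(dim(energies) == dim(strengths))) {
    stop("energies and strengths must have the same shape", call. = FALSE)
  }
  d <- config$delta
  gmin <- config$grid_min %||% (min(energies) - 10 * d)
  gmax <- config$grid_max %||% (max(energies) + 10 * d)
  gstep <- config$grid_step %||% (d / 5)
  E <- seq(gmin, gmax, by = gstep)
  np <- nrow(energies)
  f <- pmax(strengths, 0)                      # clip negative strengths
  sd <- d / 2
  norm <- 1 / sqrt(2 * pi * sd^2)
  total <- numeric(length(E))
  for (s in seq_len(ncol(energies))) {
    w <- energies[, s] * f[, s]
    keep <- w != 0
    if (!any(keep)) next
    # length(E) x n_kept Gaussian evaluations
    G <- exp(-outer(E, energies[keep, s], "-")^2 / (2 * sd^2))
    total <- total + as.vector(G %*% w[keep]) * norm / np
  }
  sigma <- .nea_prefactor_ang2_ev() / E * total
  structure(tibble::tibble(E_eV = E, sigma = sigma),
            class = c("nea_spectrum", class(tibble::tibble())))
}

#' Full ML nuclear-ensemble absorption-spectrum pipeline
#'
#' Runs [nea_iterative_train()] on the ensemble, predicts transition
#' energies and oscillator strengths for all remaining (unlabeled) points
#' with the converged models — labeled points keep their reference labels —
#' and evaluates the broadened cross section.
#'
#' @inheritParams nea_iterative_train
#' @return List with `spectrum` (tibble from [cross_section()]),
#'   `convergence` (the training log), `n_labeled`, and `models`.
#' @export
nea_spectrum <- function(ensemble, label_oracle, n_states, config = nea_config(),
                         kernel = kernel_spec("gaussian", sigma = 1),
                         descriptor, lambda = 2^-35,
                         acquisition = c("fps", "random"), seed = 1) {
  fit <- nea_iterative_train(ensemble, label_oracle, n_states, config,
                             kernel, descriptor, lambda,
                             acquisition = acquisition, seed = seed)
  np <- length(ensemble$geometries)
  dE <- matrix(NA_real_, np, n_states)
  f <- matrix(NA_real_, np, n_states)
  dE[fit$indices, ] <- fit$labels$energies
  f[fit$indices, ] <- fit$labels$strengths
  todo <- setdiff(seq_len(np), fit$indices)
  if (length(todo)) {
    Xq <- fit$descriptors[todo, , drop = FALSE]
    for (s in seq_len(n_states)) {
      dE[todo, s] <- predict(fit$models$energy[[s]], Xq)
      f[todo, s] <- predict(fit$models$strength[[s]], Xq)
    }
  }
  list(spectrum = cross_section(dE, f, config), convergence = fit$log,
       n_labeled = length(fit$indices), indices = fit$indices,
       models = fit$models, energies = dE, strengths = f)
}

#' Spectrum refinement from a precomputed label table
#'
#' Runs the identical pipeline, but labels are read from a table instead of
#' being computed on demand.  If the loop requests points the table does
#' not cover, an error of class `krrpes_needs_labels` lists the missing
#' indices so the user can extend the table.
#'
#' @param ensemble A [spectrum_ensemble()].
#' @param labels Data frame with columns `index`, `state`, `dE_eV`, `f`
#'   (long format, one row per point/state).
#' @inheritParams nea_iterative_train
#' @return As [nea_spectrum()].
#' @export
refine_with_existing <- function(ensemble, labels, n_states,
                                 config = nea_config(),
                                 kernel = kernel_spec("gaussian", sigma = 1),
                                 descriptor, lambda = 2^-35,
                                 acquisition = c("fps", "random"), seed = 1) {
  labels <- as.data.frame(labels)
  need <- c("index", "state", "dE_eV", "f")
  if (!all(need %in% names(labels))) {
    stop("labels table must have columns index, state, dE_eV, f", call. = FALSE)
  }
  oracle <- function(idx) {
    missing_idx <- idx[!vapply(idx, function(i) {
      all(seq_len(n_states) %in% labels$state[labels$index == i])
    }, TRUE)]
    if (length(missing_idx)) {
      stop(structure(
        class = c("krrpes_needs_labels", "error", "condition"),
        list(message = paste0("labels missing for ensemble indices: ",
                              paste(missing_idx, collapse = ", ")),
             call = NULL, indices = missing_idx)
      ))
    }
    e <- matrix(NA_real_, length(idx), n_states)
    f <- matrix(NA_real_, length(idx), n_states)
    for (r in seq_along(idx)) {
      sub <- labels[labels$index == idx[r], ]
      ord <- match(seq_len(n_states), sub$state)
      e[r, ] <- sub$dE_eV[ord]
      f[r, ] <- sub$f[ord]
    }
    list(energies = e, strengths = f)
  }
  tryCatch(
    nea_spectrum(ensemble, oracle, n_states, config, kernel, descriptor,
                 lambda, acquisition = acquisition, seed = seed),
    krrpes_needs_labels = function(e) stop(e)
  )
}

#' Write a spectrum as two-column text (E_eV, sigma)
#' @param spectrum Tibble from [cross_section()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(as.data.frame(spectrum)[, c("E_eV", "sigma")], path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
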