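test_that("geometric-mean RMSE and relative RMSE follow their definitions", {
  expect_equal(rmse_geom(c(3, 3, 3, 3)), 3, tolerance = 1e-14)
  expect_equal(rmse_geom(c(4, 9)), 6, tolerance = 1e-15)
  expect_equal(rmse_geom(c(9, 4)), rmse_geom(c(4, 9)))
  expect_error(rmse_geom(c(1, 0)), "nonpositive|undefined")

  expect_identical(rrmse(2, 2), 0)
  expect_identical(rrmse(2, 1), 0.5)
  expect_identical(rrmse(1, 2), -1)
  expect_error(rrmse(0, 1), "> 0")
})

test_that("a single transition reproduces the closed-form Gaussian line", {
  cfg <- nea_config(delta = 0.01)
  sp <- cross_section(matrix(4.0), matrix(0.1), cfg)
  # closed-form oracle evaluated independently at every grid point
  pref <- krrpes:::.nea_prefactor_ang2_ev()
  sd <- cfg$delta / 2
  oracle <- pref / sp$E_eV * 4.0 * 0.1 *
    exp(-(sp$E_eV - 4.0)^2 / (2 * sd^2)) / sqrt(2 * pi * sd^2)
  expect_lt(max(abs(sp$sigma - oracle) / max(oracle)), 1e-10)
  # peak sits at the transition energy (up to the 1/E tilt over one step)
  expect_lt(abs(sp$E_eV[which.max(sp$sigma)] - 4.0), cfg$delta / 2)
})

test_that("negative strengths contribute exactly zero and the sum is linear in f", {
  cfg <- nea_config(delta = 0.05, grid_min = 3, grid_max = 6, grid_step = 0.01)
  base <- cross_section(matrix(c(4.0, 4.8), 2, 1), matrix(c(0.1, 0.2), 2, 1), cfg)
  with_neg <- cross_section(matrix(c(4.0, 4.8, 4.4), 3, 1),
                            matrix(c(0.1, 0.2, -0.01), 3, 1), cfg)
  # the negative-f point adds nothing beyond the 1/N_p renormalization
  expect_equal(with_neg$sigma * 3, base$sigma * 2, tolerance = 1e-12)

  doubled <- cross_section(matrix(c(4.0, 4.8), 2, 1),
                           matrix(c(0.2, 0.4), 2, 1), cfg)
  expect_equal(doubled$sigma, 2 * base$sigma, tolerance = 1e-12)

  allneg <- cross_section(matrix(c(4, 5), 2, 1), matrix(c(-1, -2), 2, 1), cfg)
  expect_true(all(allneg$sigma == 0))
  expect_true(all(base$sigma >= 0))
})

test_that("each broadened line integrates to its stick weight", {
  cfg <- nea_config(delta = 0.02)
  dE <- 5.0; f <- 0.3
  sp <- cross_section(matrix(dE), matrix(f), cfg)
  integral <- sum(sp$sigma) * (sp$E_eV[2] - sp$E_eV[1])
  expected <- krrpes:::.nea_prefactor_ang2_ev() * dE * f / dE  # 1/E ~ 1/dE
  expect_lt(abs(integral - expected) / expected, 0.005)
})

test_that("the iterative loop converges on an easy ensemble and logs consistently", {
  ens <- generate_labeled_ensemble(400, n_states = 1, seed = 3,
                                   displacement_sd = 0.02)
  oracle <- function(idx) list(energies = ens$energies[idx, , drop = FALSE],
                               strengths = ens$strengths[idx, , drop = FALSE])
  dsp <- descriptor_spec("RE", reference_geometry = ens$geometries[[1]])
  fit <- nea_iterative_train(ens, oracle, 1, nea_config(),
                             kernel_spec("gaussian", 1), dsp, lambda = 1e-8,
                             seed = 3)
  lg <- fit$log
  expect_lte(nrow(lg), 3L)
  expect_lt(abs(lg$rRMSE[nrow(lg)]), 0.1)
  # N_tr grows by exactly n_batch per iteration
  expect_identical(lg$N_tr, 50L * seq_len(nrow(lg)))
  # logged geometric mean is consistent with the per-model RMSE columns
  per_model <- as.matrix(lg[, c("RMSE_dE_1", "RMSE_f_1")])
  expect_equal(lg$RMSE_geom,
               apply(per_model, 1, function(r) exp(mean(log(r)))),
               tolerance = 1e-12)
  # rRMSE column recomputes from successive RMSE_geom entries
  if (nrow(lg) > 1) {
    expect_equal(lg$rRMSE[-1],
                 diff(lg$RMSE_geom) / lg$RMSE_geom[-1], tolerance = 1e-12)
  }
})

test_that("an infinite threshold stops as soon as rRMSE is computable", {
  ens <- generate_labeled_ensemble(300, n_states = 1, seed = 4)
  oracle <- function(idx) list(energies = ens$energies[idx, , drop = FALSE],
                               strengths = ens$strengths[idx, , drop = FALSE])
  dsp <- descriptor_spec("RE", reference_geometry = ens$geometries[[1]])
  fit <- nea_iterative_train(ens, oracle, 1,
                             nea_config(rrmse_threshold = Inf),
                             kernel_spec("gaussian", 1), dsp, lambda = 1e-8,
                             seed = 1)
  expect_identical(nrow(fit$log), 2L)
})

test_that("the full pipeline is deterministic and mixes labels with predictions", {
  ens <- generate_labeled_ensemble(300, n_states = 2, seed = 5)
  oracle <- function(idx) list(energies = ens$energies[idx, , drop = FALSE],
                               strengths = ens$strengths[idx, , drop = FALSE])
  dsp <- descriptor_spec("RE", reference_geometry = ens$geometries[[1]])
  r1 <- nea_spectrum(ens, oracle, 2, nea_config(), kernel_spec("gaussian", 1),
                     dsp, lambda = 1e-8, seed = 6)
  r2 <- nea_spectrum(ens, oracle, 2, nea_config(), kernel_spec("gaussian", 1),
                     dsp, lambda = 1e-8, seed = 6)
  expect_identical(r1$spectrum, r2$spectrum)
  expect_identical(r1$convergence, r2$convergence)
  # labeled points carry their reference labels verbatim
  expect_identical(r1$energies[r1$indices, ], ens$energies[r1$indices, ])
  expect_true(all(r1$spectrum$sigma >= 0))
})

test_that("refinement from a label table matches direct evaluation when complete", {
  ens <- generate_labeled_ensemble(120, n_states = 1, seed = 7)
  tab <- data.frame(index = seq_len(120), state = 1L,
                    dE_eV = ens$energies[, 1], f = ens$strengths[, 1])
  dsp <- descriptor_spec("RE", reference_geometry = ens$geometries[[1]])
  # a tiny threshold forces the loop to consume every label, so the spectrum
  # is computed purely from the table
  res <- suppressWarnings(
    refine_with_existing(ens, tab, 1, nea_config(rrmse_threshold = 1e-12),
                         kernel_spec("gaussian", 1), dsp, lambda = 1e-8, seed = 1)
  )
  direct <- cross_section(ens$energies, ens$strengths,
                          nea_config(rrmse_threshold = 1e-12))
  expect_lt(max(abs(res$spectrum$sigma - direct$sigma)), 1e-10)

  # missing labels are named in an actionable error
  short <- tab[tab$index <= 60, ]
  err <- tryCatch(
    refine_with_existing(ens, short, 1, nea_config(rrmse_threshold = 1e-12),
                         kernel_spec("gaussian", 1), dsp, lambda = 1e-8, seed = 1),
    error = function(e) e
  )
  expect_match(conditionMessage(err), "missing")
  expect_true(length(err$indices) >= 1)
})

test_that("spectra and convergence logs export to plain text", {
  sp <- cross_section(matrix(4), matrix(0.1), nea_config(delta = 0.05))
  f <- withr::local_tempfile()
  write_spectrum(sp, f)
  back <- read.table(f, header = TRUE)
  expect_equal(back$sigma, sp$sigma, tolerance = 1e-12)
})
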