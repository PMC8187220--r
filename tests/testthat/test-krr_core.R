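test_that("training solves the regularized system by factorization", {
  # single point, lambda = 0: k(x1,x1) = 1 so alpha = y1 and the model
  # reproduces y1 exactly
  fx <- morse_fixture(n = 1, seed = 1)
  m <- krr_train(fx$dataset, kernel_spec("gaussian", 1), fx$descriptor, lambda = 0)
  expect_equal(m$alpha, fx$dataset$values[1])
  expect_equal(predict(m, fx$dataset), fx$dataset$values[1])

  # two points: closed-form 2x2 oracle
  fx2 <- morse_fixture(n = 2, seed = 2)
  lam <- 1e-3
  ks <- kernel_spec("gaussian", 0.5)
  x1 <- eval_descriptor(fx2$descriptor, fx2$dataset$geometries[[1]])$x
  x2 <- eval_descriptor(fx2$descriptor, fx2$dataset$geometries[[2]])$x
  k12 <- kernel_value(ks, x1, x2)
  y <- fx2$dataset$values
  det2 <- (1 + lam)^2 - k12^2
  alpha_oracle <- c((1 + lam) * y[1] - k12 * y[2],
                    (1 + lam) * y[2] - k12 * y[1]) / det2
  m2 <- krr_train(fx2$dataset, ks, fx2$descriptor, lambda = lam)
  expect_equal(m2$alpha, alpha_oracle, tolerance = 1e-12)
  expect_lt(m2$residual, 1e-10)

  # heavy-ridge limit: alpha ~ y / lambda, predictions ~ 0
  m3 <- krr_train(fx2$dataset, ks, fx2$descriptor, lambda = 1e12)
  expect_lte(max(abs(m3$alpha)), max(abs(y)) / 1e12 * (1 + 1e-6))
  expect_lt(max(abs(predict(m3, fx2$dataset))), 1e-9)
})

test_that("interpolation and monotone regularization hold", {
  fx <- morse_fixture(n = 50, seed = 3)
  ks <- kernel_spec("gaussian", 0.1)
  m <- suppressWarnings(krr_train(fx$dataset, ks, fx$descriptor, lambda = 1e-14))
  rel <- max(abs(predict(m, fx$dataset) - fx$dataset$values)) /
    diff(range(fx$dataset$values))
  expect_lt(rel, 1e-8)

  lams <- 10^seq(-10, -1, length.out = 10)
  rmses <- vapply(lams, function(l) {
    mm <- suppressWarnings(krr_train(fx$dataset, ks, fx$descriptor, lambda = l))
    sqrt(mean((predict(mm, fx$dataset) - fx$dataset$values)^2))
  }, 0)
  expect_true(all(diff(rmses) >= -1e-12))
})

test_that("all three solvers agree on well-conditioned systems", {
  fx <- morse_fixture(n = 30, seed = 4)
  ks <- kernel_spec("gaussian", 0.3)
  a1 <- krr_train(fx$dataset, ks, fx$descriptor, 1e-6, solver = "cholesky")$alpha
  a2 <- krr_train(fx$dataset, ks, fx$descriptor, 1e-6, solver = "bunch_kaufman")$alpha
  a3 <- krr_train(fx$dataset, ks, fx$descriptor, 1e-6, solver = "lu")$alpha
  expect_lt(max(abs(a1 - a2)) / max(abs(a1)), 1e-8)
  expect_lt(max(abs(a1 - a3)) / max(abs(a1)), 1e-8)
})

test_that("duplicate training points with lambda = 0 raise a singular-system error", {
  g <- mol_geometry(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  ds <- mol_dataset(list(g, g), values = c(0, 1))
  dspec <- descriptor_spec("RE", reference_geometry = g)
  expect_error(
    suppressWarnings(krr_train(ds, kernel_spec("gaussian", 1), dspec, lambda = 0)),
    "singular"
  )
})

test_that("KREG interpolates a Morse curve below 1% of the well depth", {
  spec <- synthetic_pes_spec("morse_diatomic")
  train <- generate_pes_dataset(spec, 50, seed = 5)
  test <- generate_pes_dataset(spec, 200, seed = 6)
  dspec <- descriptor_spec("RE", reference_geometry = train$metadata$equilibrium)
  m <- krr_train(train, kernel_spec("gaussian", 0.3), dspec, lambda = 2^-35)
  rmse <- sqrt(mean((predict(m, test) - test$values)^2))
  expect_lt(rmse, 0.01 * spec$D)
})

test_that("predicted Cartesian gradients match finite differences and exact gradients", {
  fx <- morse_fixture(n = 40, seed = 7)
  # a length scale resolving the sampled range and a moderate lambda keep the
  # regression coefficients small; at alpha ~ 1e6 the finite-difference
  # comparison itself drowns in cancellation noise
  ks <- kernel_spec("gaussian", 0.3)
  m <- krr_train(fx$dataset, ks, fx$descriptor, lambda = 1e-8)

  # chain-rule gradient vs finite differences of the value prediction
  set.seed(7)
  for (i in sample(40, 3)) {
    g <- fx$dataset$geometries[[i]]
    Gan <- predict_xyz_gradients(m, list(g))[[1]]
    Gfd <- fd_geom_grad(function(gg) predict(m, list(gg)), g)
    expect_lt(max(abs(Gan - Gfd)) / max(abs(Gfd)), 1e-6)
  }
  # and against the generator's analytic gradients (model is interpolating)
  gp <- predict_xyz_gradients(m, fx$dataset$geometries[1:10])
  expect_lt(gradient_rmse(gp, fx$dataset$gradients[1:10]), 1e-3)

  # a constant-target model is flat up to the interpolation wiggle of the
  # radial-basis interpolant (orders of magnitude below the PES gradients,
  # which are O(0.1-1) on this surface)
  const_ds <- mol_dataset(fx$dataset$geometries, values = rep(2.5, 40))
  mc <- krr_train(const_ds, kernel_spec("gaussian", 0.2), fx$descriptor,
                  lambda = 1e-10)
  gc <- predict_xyz_gradients(mc, fx$dataset$geometries[1:5])
  expect_lt(max(abs(unlist(gc))), 1e-3)
  # and a model with all coefficients zero predicts exactly zero
  mz <- mc
  mz$alpha <- rep(0, length(mz$alpha))
  expect_identical(predict(mz, fx$dataset$geometries[1:3]), rep(0, 3))
  expect_identical(max(abs(unlist(
    predict_xyz_gradients(mz, fx$dataset$geometries[1:2])))), 0)

  # unsupported-derivative paths refuse loudly
  ml <- krr_train(fx$dataset, kernel_spec("laplacian", 1), fx$descriptor, 1e-10)
  expect_error(predict_xyz_gradients(ml, fx$dataset$geometries[1]),
               "not differentiable")
})

test_that("permuted-RE predictions are invariant under allowed query permutations", {
  fx <- xh3_fixture(n = 25, seed = 8)
  dspec <- descriptor_spec("RE", variant = "permuted",
                           reference_geometry = fx$ref,
                           permutation_groups = fx$groups)
  ks <- kernel_spec("gaussian", 2, permutation_groups = fx$groups)
  m <- krr_train(fx$dataset, ks, dspec, lambda = 1e-8)
  q <- fx$dataset$geometries[1:4]
  p0 <- predict(m, q)
  for (p in fx$h_perms[-1]) {
    qp <- lapply(q, apply_permutation, perm = p)
    expect_lt(max(abs(predict(m, qp) - p0)), 1e-10)
  }
})

test_that("models round-trip through the versioned file format", {
  fx <- morse_fixture(n = 10, seed = 9)
  ks <- kernel_spec("matern", 0.8, matern_n = 2)
  m <- krr_train(fx$dataset, ks, fx$descriptor, lambda = 1e-10)
  path <- withr::local_tempfile(fileext = ".krr")
  save_krr(m, path)
  m2 <- load_krr(path)
  probe <- generate_pes_dataset(synthetic_pes_spec("morse_diatomic"), 10,
                                seed = 10)$geometries
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_identical(m2$kernel$family, "matern")
  expect_identical(m2$kernel$sigma, 0.8)
  expect_identical(m2$lambda, 1e-10)

  # truncated file -> clean error
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), path)
  expect_error(load_krr(path), "corrupt|truncated|incompatible")
  # version mismatch -> explicit error
  jsonlite::write_json(list(format_version = "krrpes-model-99"), path,
                       auto_unbox = TRUE)
  expect_error(load_krr(path), "version")
})

test_that("tidy and glance expose model internals as tibbles", {
  fx <- morse_fixture(n = 8, seed = 10)
  m <- krr_train(fx$dataset, kernel_spec("gaussian", 0.5), fx$descriptor, 1e-10)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 8L)
  gl <- glance(m)
  expect_identical(gl$kernel, "gaussian")
  expect_identical(gl$n_train, 8L)
})
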