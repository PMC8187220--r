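test_that("delta-learning composes baseline plus correction exactly", {
  fx <- morse_fixture(n = 20, seed = 51)
  ks <- kernel_spec("gaussian", 0.5)
  base <- fx$dataset$values   # baseline == target
  dm <- train_delta(fx$dataset, base, ks, fx$descriptor, lambda = 1e-10)
  pred <- predict_delta(dm, fx$dataset$geometries, base)
  expect_lt(max(abs(pred - fx$dataset$values)), 1e-8)

  # composition contract, bitwise
  base2 <- base * 0.9 + 0.05
  dm2 <- train_delta(fx$dataset, base2, ks, fx$descriptor, lambda = 1e-10)
  qs <- fx$dataset$geometries[c(3, 1, 7)]
  bq <- base2[c(3, 1, 7)]
  manual <- bq + predict(dm2$correction, qs)
  expect_identical(predict_delta(dm2, qs, bq), manual)

  # permuting queries permutes outputs identically
  p1 <- predict_delta(dm2, fx$dataset$geometries[1:5], base2[1:5])
  p2 <- predict_delta(dm2, fx$dataset$geometries[5:1], base2[5:1])
  # row order changes BLAS accumulation order, so equality is to rounding
  expect_equal(p2, rev(p1), tolerance = 1e-10)
  expect_identical(predict_delta(dm2, list(), numeric(0)), numeric(0))
  expect_error(predict_delta(dm2, qs, bq[1:2]), "every query")
  expect_error(train_delta(fx$dataset, NULL, ks, fx$descriptor), "baseline")
})

test_that("delta-learning beats direct learning when the correction is smooth", {
  # target = rough baseline + smooth correction; learning the difference is
  # a much easier problem at equal training-set size
  spec <- synthetic_pes_spec("morse_diatomic")
  pool <- generate_pes_dataset(spec, 300, seed = 52)
  rs <- vapply(pool$geometries, function(g) {
    sqrt(sum((g$coordinates[1, ] - g$coordinates[2, ])^2))
  }, 0)
  baseline <- pool$values + 0.15 * sin(9 * rs)    # rough low-level surface
  correction <- 0.02 * sin(2 * rs)
  target <- baseline + correction
  ds <- mol_dataset(pool$geometries, values = target)
  dspec <- descriptor_spec("RE", reference_geometry = pool$metadata$equilibrium)
  ks <- kernel_spec("gaussian", 0.3)

  split <- random_split(300, n_train = 50, seed = 53)
  train <- dataset_subset(ds, split$training)
  test <- dataset_subset(ds, split$test)
  base_tr <- baseline[split$training]
  base_te <- baseline[split$test]

  direct <- suppressWarnings(krr_train(train, ks, dspec, lambda = 2^-35))
  rmse_direct <- sqrt(mean((predict(direct, test) - test$values)^2))

  dm <- suppressWarnings(
    train_delta(train, base_tr, ks, dspec, lambda = 2^-35))
  rmse_delta <- sqrt(mean((predict_delta(dm, test$geometries, base_te) -
                             test$values)^2))
  expect_lt(rmse_delta * 2, rmse_direct)
})

test_that("self-correction layers fit successive residuals", {
  fx <- morse_fixture(n = 25, seed = 54)
  ks <- kernel_spec("gaussian", 0.1)

  # one layer is bitwise a plain KRR model
  sc1 <- train_self_correction(fx$dataset, ks, fx$descriptor, n_layers = 1,
                               lambda = 1e-10)
  plain <- krr_train(fx$dataset, ks, fx$descriptor, lambda = 1e-10)
  expect_identical(predict(sc1, fx$dataset), predict(plain, fx$dataset))

  # interpolating layer 1 leaves layer 2 targets at numerical zero
  sc2 <- train_self_correction(fx$dataset, ks, fx$descriptor, n_layers = 2,
                               lambda = 1e-12)
  expect_lt(max(abs(sc2$layer_targets[[2]])), 1e-8)

  # telescoping: layer-1 targets equal the sum of all layer predictions
  # plus the final residual (on the training set)
  pred_sum <- predict(sc2, fx$dataset)
  expect_equal(sc2$layer_targets[[1]], pred_sum + sc2$final_residual,
               tolerance = 1e-10)
})

test_that("training RMSE is nonincreasing over four noisy self-correction layers", {
  spec <- synthetic_pes_spec("morse_diatomic", noise_sd = 0.01)
  ds <- generate_pes_dataset(spec, 60, seed = 55)
  dspec <- descriptor_spec("RE", reference_geometry = ds$metadata$equilibrium)
  ks <- kernel_spec("gaussian", 1.5)
  sc <- train_self_correction(ds, ks, dspec, n_layers = 4, lambda = 1e-4)
  rmse_by_layer <- vapply(1:4, function(k) {
    part <- Reduce(`+`, lapply(sc$layers[1:k], predict, ds))
    sqrt(mean((part - ds$values)^2))
  }, 0)
  expect_true(all(diff(rmse_by_layer) <= 1e-12))
})

test_that("learning curves record one row per size and repeat, reproducibly", {
  fx <- morse_fixture(n = 80, seed = 56)
  ks <- kernel_spec("gaussian", 0.4)
  lc1 <- learning_curve(fx$dataset, ks, fx$descriptor, sizes = 10, repeats = 1,
                        n_test = 20, seed = 1)
  expect_identical(nrow(lc1$table), 1L)
  expect_identical(lc1$table$Ntrain, 10L)

  lc <- learning_curve(fx$dataset, ks, fx$descriptor, sizes = c(10, 20, 40),
                       repeats = 3, n_test = 20, seed = 2)
  expect_identical(nrow(lc$table), 9L)
  lc_again <- learning_curve(fx$dataset, ks, fx$descriptor, sizes = c(10, 20, 40),
                             repeats = 3, n_test = 20, seed = 2)
  expect_identical(lc$table[setdiff(names(lc$table),
                                    c("t_train_s", "t_predict_s"))],
                   lc_again$table[setdiff(names(lc$table),
                                          c("t_train_s", "t_predict_s"))])

  # CSV round trip preserves the table
  f <- withr::local_tempfile(fileext = ".csv")
  write_learning_curve(lc, f)
  back <- read_learning_curve(f)
  expect_equal(back$RMSE_test, lc$table$RMSE_test, tolerance = 1e-12)
  expect_identical(back$Ntrain, lc$table$Ntrain)

  # oversized requests are skipped with a warning
  expect_warning(
    lc_big <- learning_curve(fx$dataset, ks, fx$descriptor, sizes = c(10, 70),
                             repeats = 1, n_test = 20, seed = 3),
    "skipped"
  )
  expect_identical(unique(lc_big$table$Ntrain), 10L)
})

test_that("power-law fits recover parameters from clean and degenerate data", {
  sizes <- c(100, 200, 400, 800, 1600)
  errs <- 0.1 + 10 / sizes^0.5
  fit <- fit_power_law(sizes, errs)
  expect_equal(fit$eps_a, 0.1, tolerance = 1e-6)
  expect_equal(fit$a, 10, tolerance = 1e-5)
  expect_equal(fit$b, 0.5, tolerance = 1e-6)
  expect_true(fit$converged)

  # constant errors: eps_a takes the constant, amplitude collapses,
  # exponent flagged unidentifiable
  cfit <- fit_power_law(sizes, rep(0.37, 5))
  expect_identical(cfit$eps_a, 0.37)
  expect_identical(cfit$a, 0)
  expect_false(cfit$b_identifiable)

  # pure power law: log-log slope identity
  pure <- 5 / sizes^0.8
  ll <- lm(log(pure) ~ log(sizes))
  expect_equal(-coef(ll)[[2]], 0.8, tolerance = 1e-8)
  pfit <- fit_power_law(sizes, pure)
  expect_equal(pfit$b, 0.8, tolerance = 1e-6)
  expect_error(fit_power_law(c(10, 20), c(1, 2)), "3 distinct")
  expect_error(fit_power_law(sizes, c(-1, 1, 1, 1, 1)), "positive")
})

test_that("power-law recovery tolerates multiplicative noise", {
  # sizes must span into the asymptote-dominated regime or eps_a is barely
  # identified; each protocol replica averages ten noisy repeats into one
  # curve, the fit works on log residuals (the likelihood-matched objective
  # for multiplicative noise), and the median over nine replicas guards against
  # unlucky draws
  sizes <- round(10^seq(2, 5, length.out = 16))
  true <- c(eps_a = 0.1, a = 10, b = 0.5)
  set.seed(57)
  rel_errs <- replicate(9, {
    avg_curve <- rowMeans(replicate(10, {
      (true[["eps_a"]] + true[["a"]] / sizes^true[["b"]]) *
        exp(rnorm(length(sizes), 0, 0.05))
    }))
    est <- unlist(fit_power_law(sizes, avg_curve,
                                log_residuals = TRUE)[c("eps_a", "a", "b")])
    abs(est - true) / true
  })
  med <- apply(rel_errs, 1, median)
  expect_lt(med[["eps_a"]], 0.05)
  expect_lt(med[["a"]], 0.05)
  expect_lt(med[["b"]], 0.05)
})
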