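#' Typed marker for statistically undefined quantities
#'
#' Degenerate inputs (constant reference or estimated values, or too few
#' points) make regression quantities undefined; rather than returning NaN
#' the report stores this marker.
#'
#' @param reason Short explanation.
#' @return An object of class `krr_undefined`.
#' @export
undefined_stat <- function(reason = "undefined") {
  structure(list(reason = reason), class = "krr_undefined")
}

#' Test for the undefined-statistic marker
#' @param x Any object.
#' @return `TRUE` if `x` is an undefined-statistic marker.
#' @export
is_undefined_stat <- function(x) inherits(x, "krr_undefined")

#' @export
print.krr_undefined <- function(x, ...) {
  cat("<undefined: ", x$reason, ">\n", sep = "")
  invisible(x)
}

#' Full error-analysis report for estimated vs reference values
#'
#' Computes MAE, mean signed error (MSE), RMSE, the means of both series,
#' the largest positive/negative outliers of `y_hat - y` (value and index),
#' and the least-squares regression `y_hat = a + b y` with standard errors
#' `SE(a)`, `SE(b)`, correlation `R` and `R^2` via the sums of squares
#' `ss_yy`, `ss_hh`, `ss_yh`.  Regression fields need `N >= 3` and
#' nondegenerate variance in both series; otherwise they carry the typed
#' [undefined_stat()] marker while all other fields are still returned.
#'
#' @param y_hat Estimated values.
#' @param y Reference values (same nonzero length).
#' @return An `error_report` object; see [tidy.error_report()] for a tibble
#'   view.
#' @export
error_report <- function(y_hat, y) {
  y_hat <- as.double(y_hat); y <- as.double(y)
  n <- length(y)
  if (n == 0L || length(y_hat) != n) {
    stop("y_hat and y must have equal nonzero length", call. = FALSE)
  }
  err <- y_hat - y
  mu_h <- mean(y_hat); mu_y <- mean(y)
  rep <- list(
    N = n,
    MAE = mean(abs(err)),
    MSE = mean(err),                     # mean signed error
    RMSE = sqrt(mean(err^2)),
    mean_estimated = mu_h,
    mean_reference = mu_y,
    outlier_positive = list(value = max(err), index = which.max(err)),
    outlier_negative = list(value = min(err), index = which.min(err))
  )
  ss_yy <- sum(y^2) - n * mu_y^2
  ss_hh <- sum(y_hat^2) - n * mu_h^2
  ss_yh <- sum(y * y_hat) - n * mu_y * mu_h
  if (n < 2L) {
    und <- undefined_stat("regression needs at least 2 points")
    rep[c("a", "b", "SE_a", "SE_b", "R", "R2")] <- list(und)
  } else if (ss_yy <= 0 || ss_hh <= 0) {
    und <- undefined_stat("degenerate variance: constant y or y_hat")
    rep[c("a", "b", "SE_a", "SE_b", "R", "R2")] <- list(und)
    if (ss_yy > 0) {
      # slope/intercept only need ss_yy; R^2 and s also need ss_hh
      rep$b <- ss_yh / ss_yy
      rep$a <- mu_h - rep$b * mu_y
    }
  } else {
    b <- ss_yh / ss_yy
    a <- mu_h - b * mu_y
    rep$a <- a
    rep$b <- b
    rep$R2 <- ss_yh^2 / (ss_yy * ss_hh)
    rep$R <- sign(ss_yh) * sqrt(rep$R2)
    if (n > 2L) {
      s <- sqrt(max((ss_hh - ss_yh^2 / ss_yy) / (n - 2), 0))
      rep$SE_a <- s * sqrt(1 / n + mu_y^2 / ss_yy)
      rep$SE_b <- s / sqrt(ss_yy)
    } else {
      und <- undefined_stat("standard errors need N > 2")
      rep$SE_a <- und
      rep$SE_b <- und
    }
  }
  structure(rep, class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  fmt <- function(v) if (is_undefined_stat(v)) "undefined" else format(v, digits = 8)
  cat("Statistical analysis (N = ", x$N, ")\n", sep = "")
  cat("  MAE                 ", fmt(x$MAE), "\n")
  cat("  MSE (mean signed)   ", fmt(x$MSE), "\n")
  cat("  RMSE                ", fmt(x$RMSE), "\n")
  cat("  mean(y_hat)         ", fmt(x$mean_estimated), "\n")
  cat("  mean(y)             ", fmt(x$mean_reference), "\n")
  cat("  largest + outlier   ", fmt(x$outlier_positive$value),
      " (index ", x$outlier_positive$index, ")\n", sep = "")
  cat("  largest - outlier   ", fmt(x$outlier_negative$value),
      " (index ", x$outlier_negative$index, ")\n", sep = "")
  cat("  regression y_hat = a + b*y:\n")
  cat("    a     ", fmt(x$a), "   SE(a) ", fmt(x$SE_a), "\n")
  cat("    b     ", fmt(x$b), "   SE(b) ", fmt(x$SE_b), "\n")
  cat("    R     ", fmt(x$R), "   R^2   ", fmt(x$R2), "\n")
  invisible(x)
}

#' Tidy an error report into a one-row tibble
#'
#' Undefined regression fields become `NA` in the tibble (the typed marker
#' is only available on the report object itself).
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return One-row tibble of all scalar statistics.
#' @export
tidy.error_report <- function(x, ...) {
  num <- function(v) if (is_undefined_stat(v)) NA_real_ else v
  tibble::tibble(
    N = x$N, MAE = x$MAE, MSE = x$MSE, RMSE = x$RMSE,
    mean_estimated = x$mean_estimated, mean_reference = x$mean_reference,
    outlier_pos = x$outlier_positive$value, outlier_pos_index = x$outlier_positive$index,
    outlier_neg = x$outlier_negative$value, outlier_neg_index = x$outlier_negative$index,
    a = num(x$a), b = num(x$b), SE_a = num(x$SE_a), SE_b = num(x$SE_b),
    R = num(x$R), R2 = num(x$R2)
  )
}

#' RMSE over all Cartesian gradient components
#'
#' Every partial derivative is treated as a data point:
#' `sqrt(1/(N * N_at * 3) * sum (g_hat - g_ref)^2)`.
#'
#' @param grad_hat,grad_ref Lists of `N_at x 3` matrices with matching
#'   shapes.
#' @return Scalar RMSE in gradient units.
#' @export
gradient_rmse <- function(grad_hat, grad_ref) {
  if (length(grad_hat) != length(grad_ref)) {
    stop("gradient lists have different lengths", call. = FALSE)
  }
  for (i in seq_along(grad_hat)) {
    if (!all(dim(as.matrix(grad_hat[[i]])) == dim(as.matrix(grad_ref[[i]])))) {
      stop("gradient shape mismatch at geometry ", i, call. = FALSE)
    }
  }
  h <- unlist(lapply(grad_hat, function(m) as.vector(t(as.matrix(m)))))
  r <- unlist(lapply(grad_ref, function(m) as.vector(t(as.matrix(m)))))
  sqrt(mean((h - r)^2))
}
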