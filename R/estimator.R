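# Feed-forward network regression of (MetHb fraction, SaO2) from spectral
# features: a single fitting function returning a classed object, with the
# five performance criteria (MAE, MAPE, MSE, RMSE, R^2) and the
# predicted-vs-actual regression fit.

# run `expr` under a private RNG seed without disturbing the global stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded train/test split
#'
#' Random permutation split with `round(train_fraction * n)` training
#' samples; disjoint and exhaustive, reproducible for a given seed.
#'
#' @param n Number of samples (or a matrix/data frame whose rows are split).
#' @param train_fraction Fraction of samples used for training.
#' @param seed Split seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_data <- function(n, train_fraction = 0.8, seed = 1) {
  if (!is.numeric(n) || length(n) > 1) n <- nrow(n)
  if (n < 5) stop("need at least 5 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  perm <- .with_seed(seed, sample.int(n))
  k <- round(train_fraction * n)
  list(train = sort(perm[seq_len(k)]), test = sort(perm[-seq_len(k)]))
}

#' Fit the feed-forward spectral regression network
#'
#' Trains a single-hidden-layer feed-forward network (sigmoid hidden units,
#' linear outputs, fitted by regularized BFGS via \pkg{nnet}) mapping a
#' feature matrix to the blood-parameter targets. Inputs are z-scored per
#' feature using training statistics; targets are kept on their natural
#' fraction scale in \[0, 1\] so that reported MAE values are directly
#' interpretable as fractions.
#'
#' @param x Feature matrix (samples x features).
#' @param y Target matrix (samples x outputs), fractions in \[0, 1\];
#'   conventionally columns `methb_fraction` and `sao2`.
#' @param hidden Hidden-layer size (default 10).
#' @param decay Weight-decay regularization.
#' @param maxit Maximum optimizer iterations.
#' @param init_seed Seed for the weight initialization (fit is fully
#'   deterministic given data and this seed).
#' @return An object of class `drs_ann`.
#' @export
drs_ann <- function(x, y, hidden = 10, decay = 1e-3, maxit = 2000,
                    init_seed = 1) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(is.finite(x))) stop("features must be finite")
  if (any(y < 0 | y > 1)) stop("targets must be fractions in [0, 1]")
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- .with_seed(init_seed,
    nnet::nnet(xs, y, size = hidden, linout = TRUE, decay = decay,
               maxit = maxit, trace = FALSE, MaxNWts = 5000))
  if (!is.finite(fit$value))
    stop("training failed: non-finite loss (inputs: ",
         nrow(x), " x ", ncol(x), ", hidden = ", hidden, ")")
  structure(list(fit = fit, center = center, scale = scale,
                 feature_names = colnames(x),
                 target_names = colnames(y),
                 n_inputs = ncol(x), n_hidden = hidden,
                 n_outputs = ncol(y),
                 decay = decay, maxit = maxit, init_seed = init_seed,
                 loss = fit$value,
                 x = x, y = y),
            class = "drs_ann")
}

#' Predict blood parameters from features
#'
#' Applies the stored normalization and forward pass; outputs are clipped
#' to \[0, 1\] (attribute `"clipped"` flags affected entries).
#'
#' @param object A fitted [drs_ann()].
#' @param newdata Feature matrix with `n_inputs` columns (a single feature
#'   vector is also accepted).
#' @param clip Clip predictions into \[0, 1\] (default `TRUE`).
#' @param ... Unused.
#' @return Prediction matrix (samples x outputs) with a logical
#'   `"clipped"` attribute of the same shape.
#' @export
predict.drs_ann <- function(object, newdata, clip = TRUE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_inputs)
    stop(sprintf("expected %d features, got %d", object$n_inputs, ncol(newdata)))
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- stats::predict(object$fit, xs)
  p <- matrix(p, nrow = nrow(newdata))
  colnames(p) <- object$target_names
  clipped <- p < 0 | p > 1
  if (clip) p <- pmin(pmax(p, 0), 1)
  attr(p, "clipped") <- clipped
  p
}

#' @export
print.drs_ann <- function(x, ...) {
  cat(sprintf("<drs_ann> %d-%d-%d network (sigmoid hidden, linear output)\n",
              x$n_inputs, x$n_hidden, x$n_outputs))
  cat(sprintf("  trained on %d samples, decay %g, init seed %g, final loss %.4g\n",
              nrow(x$x), x$decay, x$init_seed, x$loss))
  invisible(x)
}

#' @export
summary.drs_ann <- function(object, ...) {
  pr <- predict(object, object$x)
  m <- evaluate_predictions(object$y, pr)
  cat(sprintf("Feed-forward network %d-%d-%d, %d weights, training loss %.4g\n",
              object$n_inputs, object$n_hidden, object$n_outputs,
              length(stats::coef(object$fit)), object$loss))
  cat("Training-set criteria:\n")
  print(m)
  invisible(m)
}

#' @export
coef.drs_ann <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.drs_ann <- function(object, ...) {
  object$y - predict(object, object$x)
}

#' @export
plot.drs_ann <- function(x, newdata = NULL, actual = NULL, ...) {
  a <- if (is.null(actual)) x$y else as.matrix(actual)
  p <- predict(x, if (is.null(newdata)) x$x else newdata)
  old <- graphics::par(mfrow = c(1, ncol(a)))
  on.exit(graphics::par(old))
  for (j in seq_len(ncol(a))) {
    graphics::plot(a[, j], p[, j], xlab = "target", ylab = "predicted",
                   main = x$target_names[j], xlim = c(0, 1), ylim = c(0, 1),
                   ...)
    graphics::abline(0, 1, lty = 2)
    rf <- regression_fit(a[, j], p[, j])
    if (is.finite(rf$slope)) graphics::abline(rf$intercept, rf$slope)
  }
  invisible(x)
}

#' The five performance criteria
#'
#' Per output column: mean absolute error, mean absolute percentage error
#' (samples with zero actual value are excluded from the MAPE sum and
#' counted in `mape_n_excluded`; reported in percent), mean squared error,
#' its square root, and the coefficient of determination
#' `1 - SS_res / SS_tot` (`NA` when the actual values have zero variance).
#'
#' @param actual,predicted Matrices (samples x outputs) or vectors of equal
#'   length (>= 2 samples).
#' @return A `drs_metrics` data frame with one row per output and columns
#'   `output`, `mae`, `mape`, `mse`, `rmse`, `r2`, `mape_n_excluded`.
#' @export
evaluate_predictions <- function(actual, predicted) {
  a <- as.matrix(actual); p <- as.matrix(predicted)
  if (!all(dim(a) == dim(p))) stop("actual and predicted must have equal shape")
  if (nrow(a) < 2) stop("need at least 2 samples")
  out <- lapply(seq_len(ncol(a)), function(j) {
    e <- a[, j] - p[, j]
    nz <- a[, j] != 0
    mape <- if (any(nz)) 100 * mean(abs(e[nz] / a[nz, j])) else NA_real_
    mse <- mean(e^2)
    sst <- sum((a[, j] - mean(a[, j]))^2)
    r2 <- if (sst > 0) 1 - sum(e^2) / sst else NA_real_
    data.frame(output = if (!is.null(colnames(a))) colnames(a)[j]
                        else paste0("y", j),
               mae = mean(abs(e)), mape = mape, mse = mse,
               rmse = sqrt(mse), r2 = r2, mape_n_excluded = sum(!nz))
  })
  structure(do.call(rbind, out), class = c("drs_metrics", "data.frame"))
}

#' @export
print.drs_metrics <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  print(format(y, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Predicted-versus-actual regression line
#'
#' Least-squares slope and intercept of the predictions on the targets and
#' their Pearson correlation (all `NA` when the targets have zero variance).
#'
#' @param actual,predicted Numeric vectors of equal length >= 2.
#' @return List of class `regression_fit` with `slope`, `intercept`,
#'   `correlation`.
#' @export
regression_fit <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2)
    stop("actual and predicted must have equal length >= 2")
  va <- stats::var(actual)
  if (va == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          correlation = NA_real_), class = "regression_fit"))
  slope <- stats::cov(actual, predicted) / va
  intercept <- mean(predicted) - slope * mean(actual)
  corr <- if (stats::sd(predicted) == 0) NA_real_
          else stats::cor(actual, predicted)
  structure(list(slope = slope, intercept = intercept, correlation = corr),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> predicted = %.4g + %.4g * actual (r = %.4g)\n",
              x$intercept, x$slope, x$correlation))
  invisible(x)
}
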