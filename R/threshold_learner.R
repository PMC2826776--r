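# nu-SVR threshold learner: cross-validated hyperparameter selection on a
# logarithmic grid, feature standardization, bounded prediction.

#' Learner configuration
#'
#' Hyperparameter grids for the Gaussian-kernel nu-SVR and the
#' cross-validation settings. Defaults follow standard log-grid practice:
#' cost 2^-3..2^9 and kernel width gamma 2^-11..2^3, both stepping by
#' powers of 4, and nu in {0.25, 0.5, 0.75}.
#'
#' @param nu_grid Fractions in (0, 1]: upper bound on the margin-error
#'   fraction / lower bound on the support-vector fraction.
#' @param cost_grid Positive regularization costs C.
#' @param gamma_grid Positive Gaussian-kernel widths.
#' @param cv_folds Number of cross-validation folds (default 5, minimum 2).
#' @param seed Integer seed for the fold assignment.
#' @return A `learner_config` list.
#' @export
learner_config <- function(nu_grid = c(0.25, 0.5, 0.75),
                           cost_grid = 2^seq(-3, 9, by = 2),
                           gamma_grid = 2^seq(-11, 3, by = 2),
                           cv_folds = 5L, seed = 1L) {
  if (length(nu_grid) == 0L || any(nu_grid <= 0 | nu_grid > 1))
    stop("nu_grid must be non-empty with values in (0, 1]")
  if (length(cost_grid) == 0L || any(cost_grid <= 0))
    stop("cost_grid must be non-empty and positive")
  if (length(gamma_grid) == 0L || any(gamma_grid <= 0))
    stop("gamma_grid must be non-empty and positive")
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be at least 2")
  structure(list(nu_grid = nu_grid, cost_grid = cost_grid,
                 gamma_grid = gamma_grid, cv_folds = cv_folds,
                 seed = as.integer(seed)),
            class = "learner_config")
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fold assignment stratified by the tumour flag so every fold sees
# tumour-free labels; shuffled within strata under the config seed.
.assign_folds <- function(is_tumour, k, seed) {
  n <- length(is_tumour)
  folds <- integer(n)
  with_seed(seed, {
    for (stratum in unique(is_tumour)) {
      idx <- which(is_tumour == stratum)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

.feature_matrix <- function(records) {
  as.matrix(records[, c("area_010", "mean_010", "area_015", "mean_015",
                        "area_020", "mean_020")])
}

# Clamp each column of x into [lo, hi]. Applied to scaled features at
# prediction time: a Gaussian-kernel regressor reverts to its intercept
# far from the training data, so attributes outside the training range
# (e.g. a near-constant attribute whose tiny spread inflates the z-score)
# are mapped to the nearest value the model was trained on.
.clamp_cols <- function(x, lo, hi) {
  for (j in seq_len(ncol(x)))
    x[, j] <- pmin(pmax(x[, j], lo[j]), hi[j])
  x
}

#' Train the nu-SVR threshold predictor
#'
#' Standardizes the six attributes with training-set statistics, selects
#' (nu, cost, gamma) by k-fold cross-validated mean squared error over the
#' configured grid (fold assignment seeded and stratified by the tumour
#' flag), then refits on all training records at the selected point. Ties
#' are broken toward smaller cost, then smaller gamma, then smaller nu.
#'
#' Tumour-free slices participate exactly as labelled (their labels are
#' slice maxima). A constant label vector yields a flagged
#' constant-predictor model; a constant feature gets unit spread and a
#' warning.
#'
#' @param records Data frame of labelled slice records (at least `cv_folds`
#'   rows) as produced by [build_labelled_instances()].
#' @param config A [learner_config()].
#' @return A `threshold_model`: selected hyperparameters, scaling
#'   statistics, the fitted svm (opaque), training size and CV score.
#' @export
train_threshold_model <- function(records, config = learner_config()) {
  stopifnot(inherits(config, "learner_config"))
  n <- nrow(records)
  if (is.null(n) || n < config$cv_folds)
    stop("need at least cv_folds (", config$cv_folds, ") training records")
  x <- .feature_matrix(records)
  if (any(!is.finite(x))) stop("non-finite attribute values")
  y <- records$reference_threshold

  center <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  const_feat <- !is.finite(sdev) | sdev < .Machine$double.eps
  if (any(const_feat)) {
    warning("constant feature(s) given unit spread: ",
            paste(colnames(x)[const_feat], collapse = ", "))
    sdev[const_feat] <- 1
  }
  xs <- scale(x, center = center, scale = sdev)

  if (stats::sd(y) < .Machine$double.eps) {
    model <- structure(list(constant = TRUE, value = y[1],
                            nu = NA_real_, cost = NA_real_, gamma = NA_real_,
                            center = center, scale = sdev, fit = NULL,
                            label_min = y[1], label_max = y[1],
                            n_train = n, cv_mse = 0),
                       class = "threshold_model")
    return(model)
  }

  folds <- .assign_folds(records$is_tumour, config$cv_folds, config$seed)
  # grid ordered so which.min realizes the tie-break priority
  grid <- expand.grid(nu = sort(config$nu_grid),
                      gamma = sort(config$gamma_grid),
                      cost = sort(config$cost_grid))
  grid <- grid[order(grid$cost, grid$gamma, grid$nu), , drop = FALSE]
  mse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    se <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      xtr <- xs[tr, , drop = FALSE]
      xte <- .clamp_cols(xs[!tr, , drop = FALSE],
                         apply(xtr, 2, min), apply(xtr, 2, max))
      fit <- e1071::svm(x = xtr, y = y[tr],
                        type = "nu-regression", kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        nu = grid$nu[g], scale = FALSE)
      pred <- stats::predict(fit, xte)
      se <- se + sum((pred - y[!tr])^2)
    }
    mse[g] <- se / n
  }
  best <- which.min(mse)
  fit <- e1071::svm(x = xs, y = y, type = "nu-regression", kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    nu = grid$nu[best], scale = FALSE)
  structure(list(constant = FALSE, value = NA_real_,
                 nu = grid$nu[best], cost = grid$cost[best],
                 gamma = grid$gamma[best],
                 center = center, scale = sdev,
                 scaled_min = apply(xs, 2, min),
                 scaled_max = apply(xs, 2, max),
                 label_min = min(y), label_max = max(y),
                 fit = fit, n_train = n, cv_mse = mse[best]),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  if (x$constant)
    cat(sprintf("Constant threshold predictor: %g (n = %d)\n", x$value, x$n_train))
  else
    cat(sprintf("nu-SVR threshold predictor: nu = %g, cost = %g, gamma = %g, cv MSE = %.4g (n = %d)\n",
                x$nu, x$cost, x$gamma, x$cv_mse, x$n_train))
  invisible(x)
}

#' Predict the SUV threshold for a slice
#'
#' Applies the training-set feature scaling (scaled attributes are clamped
#' into the training range, so the kernel regressor is never queried
#' outside the attribute regime it was fitted on), evaluates the
#' regressor, and clamps the output: first into the training label range
#' (a predicted threshold outside the range of reference thresholds the
#' model was trained on is an extrapolation artefact, and a threshold
#' below the background uptake contours the whole slice), then into the
#' physically meaningful range `[0, slice_max]` (a threshold above the
#' slice maximum contours an empty region; a negative threshold is
#' meaningless for SUVs).
#'
#' @param model A `threshold_model` from [train_threshold_model()].
#' @param attributes A named list or one-row data frame with the six
#'   attributes, or a data frame of several rows.
#' @param slice_max Maximum SUV of the slice(s); recycled to the number of
#'   rows.
#' @return Numeric vector of predicted thresholds in `[0, slice_max]`.
#' @export
predict_threshold <- function(model, attributes, slice_max) {
  stopifnot(inherits(model, "threshold_model"))
  df <- as.data.frame(attributes)
  x <- .feature_matrix(df)
  raw <- if (model$constant) rep(model$value, nrow(x)) else {
    xs <- scale(x, center = model$center, scale = model$scale)
    xs <- .clamp_cols(xs, model$scaled_min, model$scaled_max)
    as.numeric(stats::predict(model$fit, xs))
  }
  raw <- pmin(pmax(raw, model$label_min), model$label_max)
  slice_max <- rep_len(as.numeric(slice_max), nrow(x))
  pmin(pmax(raw, 0), slice_max)
}
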