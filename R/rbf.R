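# Squared Euclidean cross-distances between rows of A and rows of B.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' K-means cluster centers for RBF hidden units
#'
#' Lloyd iteration tailored to RBF center selection: initial centers are `h`
#' distinct rows of `X` sampled by a seeded generator (or supplied via
#' `centers_init`); samples are assigned to the nearest center by Euclidean
#' distance with ties broken toward the lowest center index; centers are
#' updated to cluster means; iteration stops when no center moves more than
#' `tol` or after `max_iter` sweeps. Empty clusters are re-seeded from the
#' sample farthest from its assigned center.
#'
#' @param X Numeric matrix, rows are (normalized) input samples.
#' @param h Number of centers; must not exceed the number of distinct rows.
#' @param seed Integer seed for the initial sampling.
#' @param max_iter Maximum Lloyd sweeps.
#' @param tol Center-shift stopping tolerance (max Euclidean move).
#' @param centers_init Optional explicit initial centers (h x ncol(X) matrix).
#' @return An `h x ncol(X)` matrix of centers, with attribute
#'   `"objective_trace"` (total within-cluster squared distance per sweep)
#'   and `"iterations"`.
#' @examples
#' X <- matrix(c(0, 1, 9, 10), ncol = 1)
#' kmeans_centers(X, 2, centers_init = matrix(c(0, 9), ncol = 1))
#' @export
kmeans_centers <- function(X, h, seed = 1L, max_iter = 100L, tol = 1e-8,
                           centers_init = NULL) {
  X <- as.matrix(X)
  if (!nrow(X)) abort("`X` is empty")
  distinct <- unique(X)
  if (h > nrow(distinct))
    abort(sprintf("`h` (%d) exceeds the %d distinct rows of `X`", h, nrow(distinct)))
  if (is.null(centers_init)) {
    centers <- with_step_seed(seed, "kmeans-init",
                              distinct[sample.int(nrow(distinct), h), , drop = FALSE])
  } else {
    centers <- as.matrix(centers_init)
    stopifnot(nrow(centers) == h, ncol(centers) == ncol(X))
  }
  obj <- double(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- cross_dist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the farthest sample
    empty <- setdiff(seq_len(h), unique(assign))
    for (j in empty) {
      far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
      centers[j, ] <- X[far, ]
      d2[, j] <- rowSums(sweep(X, 2, centers[j, ])^2)
      assign <- max.col(-d2, ties.method = "first")
    }
    obj <- c(obj, sum(d2[cbind(seq_len(nrow(X)), assign)]))
    new_centers <- centers
    for (j in unique(assign))
      new_centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift <= tol || iter >= max_iter) break
  }
  attr(centers, "objective_trace") <- obj
  attr(centers, "iterations") <- iter
  centers
}

#' Self-organizing RBF widths
#'
#' All hidden units share the width `sigma = c_max / sqrt(2 h)` where `c_max`
#' is the maximum pairwise Euclidean distance among the centers.
#'
#' @param centers Matrix of centers (>= 2 rows).
#' @return Numeric vector of widths, one per center (all equal).
#' @examples
#' rbf_widths(matrix(c(0, 2), ncol = 1))  # 2 / sqrt(4) = 1
#' @export
rbf_widths <- function(centers) {
  centers <- as.matrix(centers)
  h <- nrow(centers)
  if (h < 2)
    abort("c_max is undefined for a single center; supply an explicit spread")
  c_max <- sqrt(max(cross_dist2(centers, centers)))
  rep(c_max / sqrt(2 * h), h)
}

#' Gaussian hidden-layer activations
#'
#' `Phi[p, i] = exp(-||x_p - c_i||^2 / (2 sigma_i^2))`.
#'
#' @param X Matrix of input samples (rows).
#' @param centers Matrix of centers.
#' @param widths Positive widths, one per center.
#' @return An `nrow(X) x nrow(centers)` activation matrix with entries in
#'   `(0, 1]`.
#' @export
rbf_activations <- function(X, centers, widths) {
  X <- as.matrix(X); centers <- as.matrix(centers)
  if (ncol(X) != ncol(centers)) abort("dimension mismatch between `X` and `centers`")
  if (length(widths) != nrow(centers))
    abort("`widths` must have one entry per center")
  if (any(widths <= 0)) abort("`widths` must be positive")
  d2 <- cross_dist2(X, centers)
  exp(sweep(d2, 2, -2 * widths^2, "/"))
}

#' Least-squares output weights
#'
#' Solves `min ||Phi w - y||^2 + ridge ||w||^2`. With `ridge = 0` the solve
#' uses a QR factorization; a rank-deficient system falls back to the
#' Moore-Penrose pseudo-inverse with a message. With `ridge > 0` the
#' regularized normal equations are solved by Cholesky.
#'
#' @param Phi Activation matrix.
#' @param y Numeric target vector, `length(y) == nrow(Phi)`.
#' @param ridge Non-negative ridge penalty.
#' @return Numeric weight vector of length `ncol(Phi)`.
#' @export
fit_rbf_weights <- function(Phi, y, ridge = 1e-10) {
  Phi <- as.matrix(Phi)
  stopifnot(length(y) == nrow(Phi), ncol(Phi) >= 1, ridge >= 0)
  if (ridge == 0) {
    qr_phi <- qr(Phi)
    if (qr_phi$rank < ncol(Phi)) {
      inform("rank-deficient activation matrix; using pseudo-inverse")
      return(drop(MASS::ginv(Phi) %*% y))
    }
    return(drop(qr.coef(qr_phi, y)))
  }
  A <- crossprod(Phi) + diag(ridge, ncol(Phi))
  b <- crossprod(Phi, y)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    inform("ill-conditioned normal equations; using pseudo-inverse")
    return(drop(MASS::ginv(Phi) %*% y))
  }
  drop(backsolve(ch, forwardsolve(t(ch), b)))
}

#' Fit an RBF regression network for photosynthetic rate
#'
#' Trains the three-layer RBF network on condition-level records: inputs are
#' the min-max normalized (blue ratio, PPFD, temperature) triple, the target
#' is the normalized net photosynthetic rate. Centers come from
#' [kmeans_centers()] unless `h` equals the sample count, in which case each
#' sample is its own center. Hidden widths follow `spread_mode`:
#' `"width"` (default) sets every width to `spread`; `"scale"` multiplies the
#' self-organizing [rbf_widths()] by `spread`; `spread = NULL` uses
#' [rbf_widths()] unscaled. Output weights are solved by least squares.
#'
#' @param data Condition-level tibble with columns `temperature`, `ppfd`,
#'   `blue_ratio`, `pn`.
#' @param spread Positive scalar width hyperparameter, or `NULL` for the
#'   self-organizing rule.
#' @param h Number of hidden units; default `nrow(data)`.
#' @param spread_mode `"width"` or `"scale"` (see Details).
#' @param ridge Ridge penalty for the weight solve (default `1e-10`).
#' @param bias If `TRUE`, append a constant output bias unit.
#' @param kmeans_max_iter,kmeans_tol K-means controls.
#' @param seed Integer seed (k-means initialization).
#' @param norm Optional `"pn_norm"` normalisation parameters; fitted on
#'   `data` when `NULL`.
#' @return An object of class `"rbf_model"`.
#' @examples
#' sp <- split_groups(clean_replicates(simulate_gas_exchange()))
#' fit <- fit_rbf(sp$train, spread = 1, norm = sp$norm)
#' head(predict(fit, sp$verify))
#' @export
fit_rbf <- function(data, spread = 1, h = NULL,
                    spread_mode = c("width", "scale"),
                    ridge = 1e-10, bias = FALSE,
                    kmeans_max_iter = 100L, kmeans_tol = 1e-8,
                    seed = 1L, norm = NULL) {
  spread_mode <- match.arg(spread_mode)
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  if (!is.null(spread) && (!is.numeric(spread) || spread <= 0))
    abort("`spread` must be positive or NULL")
  if (is.null(norm)) norm <- fit_normalization(data)
  X <- normalized_inputs(data, norm)
  y <- normalize_value(data$pn, norm, "pn")
  n <- nrow(X)
  h <- h %||% n
  if (h < 1) abort("`h` must be >= 1")
  if (h == n && nrow(unique(X)) == n) {
    centers <- X
  } else {
    centers <- kmeans_centers(X, h, seed = seed, max_iter = kmeans_max_iter,
                              tol = kmeans_tol)
  }
  widths <- rbf_model_widths(centers, spread, spread_mode)
  Phi <- rbf_activations(X, centers, widths)
  if (bias) Phi <- cbind(Phi, 1)
  w <- fit_rbf_weights(Phi, y, ridge)
  fitted_norm <- drop(Phi %*% w)
  structure(
    list(centers = unname(centers), widths = widths, weights = w,
         spread = spread, spread_mode = spread_mode, ridge = ridge,
         bias = bias, h = nrow(centers), seed = as.integer(seed),
         norm = norm, feature_order = c("blue_ratio", "ppfd", "temperature"),
         train_mse_norm = mean((fitted_norm - y)^2), n_train = n),
    class = "rbf_model"
  )
}

rbf_model_widths <- function(centers, spread, spread_mode) {
  if (is.null(spread)) return(rbf_widths(centers))
  switch(spread_mode,
         width = rep(spread, nrow(centers)),
         scale = spread * rbf_widths(centers))
}

#' Predict net photosynthetic rate from a fitted RBF model
#'
#' Applies the trained network `P_h = net(pi, par, T)`: normalizes the inputs
#' with the training-set parameters, evaluates the Gaussian hidden layer and
#' the linear output layer, and denormalizes the result back to
#' umol m-2 s-1. Inputs far from every center decay toward the denormalized
#' zero (the network has no output bias by default).
#'
#' @param object An `"rbf_model"`.
#' @param newdata Tibble with `temperature`, `ppfd`, `blue_ratio` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted rates, umol m-2 s-1.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (!nrow(newdata)) return(double(0))
  X <- normalized_inputs(newdata, object$norm, object$feature_order)
  Phi <- rbf_activations(X, object$centers, object$widths)
  if (object$bias) Phi <- cbind(Phi, 1)
  denormalize_value(drop(Phi %*% object$weights), object$norm, "pn")
}

#' @export
print.rbf_model <- function(x, ...) {
  sp <- if (is.null(x$spread)) "self-organizing" else format(x$spread)
  cat(sprintf("<rbf_model> %d hidden units, spread %s (%s), ridge %g\n",
              x$h, sp, x$spread_mode, x$ridge))
  invisible(x)
}

#' @describeIn fit_rbf One row per hidden unit (center coordinates, width,
#'   output weight).
#' @param x,object An `"rbf_model"`.
#' @param ... Unused.
#' @method tidy rbf_model
#' @export
tidy.rbf_model <- function(x, ...) {
  ctr <- as_tibble(as.data.frame(x$centers))
  names(ctr) <- paste0("center_", x$feature_order)
  dplyr::mutate(ctr,
                unit = dplyr::row_number(),
                width = x$widths,
                weight = x$weights[seq_len(x$h)],
                .before = 1)
}

#' @describeIn fit_rbf One-row model summary (hidden count, spread, training
#'   MSE on the normalized scale).
#' @method glance rbf_model
#' @export
glance.rbf_model <- function(x, ...) {
  tibble(h = x$h, spread = x$spread %||% NA_real_,
         spread_mode = x$spread_mode, ridge = x$ridge, bias = x$bias,
         n_train = x$n_train, train_mse_norm = x$train_mse_norm)
}
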