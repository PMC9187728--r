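#' Fit a generalized regression neural network (GRNN) baseline
#'
#' A GRNN is a Nadaraya-Watson kernel regression: it stores the normalized
#' training samples and predicts with an isotropic-Gaussian kernel-weighted
#' average of the stored targets. The single smoothing parameter is the
#' spread `sigma`.
#'
#' @param data Condition-level tibble with `temperature`, `ppfd`,
#'   `blue_ratio`, `pn` columns.
#' @param spread Positive kernel width on the normalized input scale.
#' @param norm Optional `"pn_norm"` parameters; fitted on `data` when `NULL`.
#' @return An object of class `"grnn_model"`.
#' @examples
#' sp <- split_groups(clean_replicates(simulate_gas_exchange()))
#' g <- fit_grnn(sp$train, spread = 0.1, norm = sp$norm)
#' head(predict(g, sp$verify))
#' @export
fit_grnn <- function(data, spread = 1, norm = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  if (!is.numeric(spread) || length(spread) != 1 || spread <= 0)
    abort("`spread` must be a positive scalar")
  if (is.null(norm)) norm <- fit_normalization(data)
  structure(
    list(X = normalized_inputs(data, norm),
         y = normalize_value(data$pn, norm, "pn"),
         spread = spread, norm = norm,
         feature_order = c("blue_ratio", "ppfd", "temperature")),
    class = "grnn_model"
  )
}

# Kernel weight matrix (rows sum to 1), computed with a per-row max shift in
# the exponent so that all-kernel underflow cannot occur.
grnn_weights <- function(E) {
  W <- exp(E - apply(E, 1, max))
  W / rowSums(W)
}

#' Predict with a GRNN model
#'
#' `yhat(x) = sum_i y_i K_i / sum_i K_i` with
#' `K_i = exp(-||x - x_i||^2 / (2 sigma^2))`. Predictions are convex
#' combinations of the stored targets, hence always within their range.
#'
#' @param object A `"grnn_model"`.
#' @param newdata Tibble with `temperature`, `ppfd`, `blue_ratio` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted rates, umol m-2 s-1.
#' @export
predict.grnn_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (!nrow(newdata)) return(double(0))
  X <- normalized_inputs(newdata, object$norm, object$feature_order)
  E <- -cross_dist2(X, object$X) / (2 * object$spread^2)
  denormalize_value(drop(grnn_weights(E) %*% object$y), object$norm, "pn")
}

#' @export
print.grnn_model <- function(x, ...) {
  cat(sprintf("<grnn_model> %d stored samples, spread %g\n",
              nrow(x$X), x$spread))
  invisible(x)
}

#' @describeIn fit_grnn One-row model summary.
#' @param x A `"grnn_model"`.
#' @param ... Unused.
#' @method glance grnn_model
#' @export
glance.grnn_model <- function(x, ...) {
  tibble(n_stored = nrow(x$X), spread = x$spread)
}
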