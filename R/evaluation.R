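#' Prediction-quality metrics
#'
#' Computes the evaluation report for a set of predictions: mean squared
#' error, maximum and mean absolute error (all in the units of the inputs,
#' umol m-2 s-1 for rates), the ordinary least-squares fit of predicted on
#' measured (`predicted = slope * measured + intercept`), the coefficient of
#' determination of that fit, and the squared Pearson correlation (identical
#' for a simple linear fit, reported separately for transparency).
#'
#' @param data Data frame holding the two columns.
#' @param measured,predicted Column names (tidy-eval) of the measured and
#'   predicted values; defaults `measured` and `predicted`.
#' @return One-row tibble: `n`, `mse`, `max_abs_error`, `mean_abs_error`,
#'   `r_squared`, `pearson_r2`, `slope`, `intercept`. With a constant
#'   measured vector the fit is undefined and those fields are `NA` (with a
#'   warning).
#' @examples
#' pn_metrics(tibble::tibble(measured = c(0, 1, 2), predicted = c(0, 1, 4)))
#' @export
pn_metrics <- function(data, measured = "measured", predicted = "predicted") {
  stopifnot(is.data.frame(data))
  meas <- data[[measured]]
  pred <- data[[predicted]]
  if (is.null(meas) || is.null(pred))
    abort("`measured`/`predicted` columns not found in `data`")
  metrics_vec(meas, pred)
}

metrics_vec <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  err <- predicted - measured
  out <- tibble(
    n = length(measured),
    mse = mean(err^2),
    max_abs_error = max(abs(err)),
    mean_abs_error = mean(abs(err)),
    r_squared = NA_real_, pearson_r2 = NA_real_,
    slope = NA_real_, intercept = NA_real_
  )
  if (sd(measured) == 0) {
    warn("measured values are constant; slope and R^2 are undefined")
    return(out)
  }
  fit <- lm(predicted ~ measured)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  out$r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out$pearson_r2 <- cor(measured, predicted)^2
  out$slope <- unname(coef(fit)[2])
  out$intercept <- unname(coef(fit)[1])
  out
}

#' Sweep the spread over a grid
#'
#' Trains one model per spread value on the split's training set and reports
#' verification-set metrics for each, reproducing the shape of a
#' spread-sensitivity table. The default grid is 0.1 to 15.1 in steps of 1.
#'
#' @param split A `"pn_split"`.
#' @param spreads Numeric grid of spread values.
#' @param family `"rbf"` or `"grnn"`.
#' @param ... Passed to [fit_rbf()] / [fit_grnn()] (e.g. `h`, `ridge`).
#' @return Tibble of class `"pn_sweep"`, one row per spread, columns
#'   `spread`, `mse`, `max_abs_error`, `mean_abs_error`, `r_squared`,
#'   rows in grid order.
#' @examples
#' sp <- split_groups(clean_replicates(simulate_gas_exchange()))
#' spread_sweep(sp, spreads = c(0.5, 1, 2))
#' @export
spread_sweep <- function(split, spreads = seq(0.1, 15.1, by = 1),
                         family = c("rbf", "grnn"), ...) {
  family <- match.arg(family)
  stopifnot(inherits(split, "pn_split"), length(spreads) >= 1)
  rows <- purrr::map(spreads, function(s) {
    model <- if (family == "rbf")
      fit_rbf(split$train, spread = s, norm = split$norm, ...)
    else fit_grnn(split$train, spread = s, norm = split$norm, ...)
    rep <- metrics_vec(split$verify$pn, predict(model, split$verify))
    dplyr::mutate(rep, spread = s, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("pn_sweep", class(out)), family = family)
}

#' Six-model comparison harness
#'
#' Trains and evaluates the six model/optimizer combinations -- RBF, GA-RBF,
#' QGA-RBF, GRNN, GA-GRNN, QGA-GRNN -- on the identical training set and
#' reports each one's verification-set metrics, plus the per-model
#' predicted-vs-measured pairs for plotting. A failure in one model marks
#' its row failed without aborting the others.
#'
#' @param split A `"pn_split"` shared by every model.
#' @param spread Default spread for the un-optimized RBF and GRNN rows.
#' @param seed Integer seed for the optimizer runs.
#' @param ... Passed on to [tune_spread()] (e.g. `lo`, `hi`, `h`,
#'   `max_generations`).
#' @return Tibble of class `"pn_comparison"`, one row per model (`model`,
#'   `optimizer`, `family`, `spread`, metrics, `failed`), with attribute
#'   `"scatter"`: tibble (`model`, `measured`, `predicted`).
#' @examples
#' sp <- split_groups(clean_replicates(simulate_gas_exchange()))
#' cmp <- compare_models(sp, max_generations = 5)
#' cmp[, c("model", "mean_abs_error")]
#' @export
compare_models <- function(split, spread = 1, seed = 1L, ...) {
  stopifnot(inherits(split, "pn_split"))
  combos <- tibble(
    model = c("RBF", "GA-RBF", "QGA-RBF", "GRNN", "GA-GRNN", "QGA-GRNN"),
    family = rep(c("rbf", "grnn"), each = 3),
    optimizer = rep(c("none", "ga", "qga"), 2)
  )
  scatter <- list()
  rows <- purrr::pmap(combos, function(model, family, optimizer) {
    res <- tryCatch({
      tuned <- tune_spread(split, family, optimizer, spread = spread,
                           seed = seed, ...)
      pred <- predict(tuned$model, split$verify)
      scatter[[model]] <<- tibble(model = model, measured = split$verify$pn,
                                  predicted = pred)
      dplyr::mutate(metrics_vec(split$verify$pn, pred),
                    spread = tuned$best_spread, failed = FALSE)
    }, error = function(e) {
      warn(sprintf("model %s failed: %s", model, conditionMessage(e)))
      tibble(n = NA_integer_, mse = NA_real_, max_abs_error = NA_real_,
             mean_abs_error = NA_real_, r_squared = NA_real_,
             pearson_r2 = NA_real_, slope = NA_real_, intercept = NA_real_,
             spread = NA_real_, failed = TRUE)
    })
    dplyr::mutate(res, model = model, family = family, optimizer = optimizer,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("pn_comparison", class(out)),
            scatter = dplyr::bind_rows(scatter))
}

#' @rdname compare_models
#' @param x A `"pn_comparison"`.
#' @export
comparison_scatter <- function(x) {
  s <- attr(x, "scatter")
  if (is.null(s)) abort("`x` carries no scatter data")
  s
}
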