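#' Spread-to-fitness objective for a train/verification split
#'
#' Builds the function the spread optimizers minimize: a candidate spread is
#' mapped to the mean squared error (on the normalized scale, [fitness_mse()])
#' of a model trained on the split's training set and evaluated on its
#' verification set. Centers do not depend on the spread, so they (and all
#' sample-center distances) are computed once and cached; each evaluation
#' then only re-exponentiates the cached distances and re-solves the output
#' weights, which is what makes grid sweeps and population searches cheap.
#'
#' @param split A `"pn_split"` from [split_groups()].
#' @param family `"rbf"` or `"grnn"`.
#' @param h Hidden-unit count for the RBF (default: training-set size).
#' @param spread_mode,ridge,bias,seed RBF controls (see [fit_rbf()]).
#' @param fitness_set `"validation"` (default) evaluates on the verification
#'   set; `"training"` evaluates on the training set itself.
#' @return A function `spread -> fitness` with attribute `"n_eval"` (size of
#'   the evaluation set).
#' @export
spread_objective <- function(split, family = c("rbf", "grnn"),
                             h = NULL, spread_mode = c("width", "scale"),
                             ridge = 1e-10, bias = FALSE, seed = 1L,
                             fitness_set = c("validation", "training")) {
  family <- match.arg(family)
  spread_mode <- match.arg(spread_mode)
  fitness_set <- match.arg(fitness_set)
  stopifnot(inherits(split, "pn_split"))
  norm <- split$norm
  Xtr <- normalized_inputs(split$train, norm)
  ytr <- normalize_value(split$train$pn, norm, "pn")
  eval_df <- if (fitness_set == "validation") split$verify else split$train
  Xev <- normalized_inputs(eval_df, norm)
  yev <- normalize_value(eval_df$pn, norm, "pn")
  if (family == "grnn") {
    D2 <- cross_dist2(Xev, Xtr)
    f <- function(spread) {
      W <- grnn_weights(-D2 / (2 * spread^2))
      fitness_mse(yev, drop(W %*% ytr))
    }
  } else {
    n <- nrow(Xtr)
    h <- h %||% n
    centers <- if (h == n && nrow(unique(Xtr)) == n) Xtr
               else kmeans_centers(Xtr, h, seed = seed)
    base_w <- if (spread_mode == "scale") rbf_widths(centers)[1] else 1
    D2tr <- cross_dist2(Xtr, centers)
    D2ev <- cross_dist2(Xev, centers)
    f <- function(spread) {
      sigma <- spread * base_w
      Phi <- exp(-D2tr / (2 * sigma^2))
      Phi_ev <- exp(-D2ev / (2 * sigma^2))
      if (bias) {
        Phi <- cbind(Phi, 1)
        Phi_ev <- cbind(Phi_ev, 1)
      }
      w <- fit_rbf_weights(Phi, ytr, ridge)
      fitness_mse(yev, drop(Phi_ev %*% w))
    }
  }
  attr(f, "n_eval") <- nrow(eval_df)
  f
}

#' Select the spread by quantum or classical genetic search
#'
#' The end-to-end tuner behind the QGA-RBF, GA-RBF, QGA-GRNN and GA-GRNN
#' models: builds the [spread_objective()] for the split, runs the chosen
#' optimizer over `[lo, hi]`, and refits the final model with the best
#' spread. `optimizer = "none"` skips the search and fits with `spread`.
#'
#' @inheritParams spread_objective
#' @param optimizer `"qga"`, `"ga"` or `"none"`.
#' @param spread Spread used when `optimizer = "none"`.
#' @param lo,hi Search interval for the spread.
#' @param n,m,max_generations,stall_generations Optimizer controls
#'   (see [run_qga()]).
#' @param seed Integer seed driving the whole search.
#' @return A list of class `"spread_tuning"`: `model` (fitted
#'   `"rbf_model"`/`"grnn_model"`), `best_spread`, `best_fitness`
#'   (normalized-scale MSE, `NA` for `"none"`), `trace` (tibble or `NULL`),
#'   `family`, `optimizer`.
#' @examples
#' sp <- split_groups(clean_replicates(simulate_gas_exchange()))
#' tuned <- tune_spread(sp, "rbf", "qga", max_generations = 10, seed = 1)
#' tuned$best_spread
#' @export
tune_spread <- function(split, family = c("rbf", "grnn"),
                        optimizer = c("qga", "ga", "none"),
                        spread = 1, lo = 0.1, hi = 10,
                        h = NULL, spread_mode = c("width", "scale"),
                        ridge = 1e-10, bias = FALSE,
                        fitness_set = c("validation", "training"),
                        n = 20, m = 20, max_generations = 50,
                        stall_generations = 10, seed = 1L) {
  family <- match.arg(family)
  optimizer <- match.arg(optimizer)
  spread_mode <- match.arg(spread_mode)
  fitness_set <- match.arg(fitness_set)
  refit <- function(s) {
    if (family == "rbf")
      fit_rbf(split$train, spread = s, h = h, spread_mode = spread_mode,
              ridge = ridge, bias = bias, seed = seed, norm = split$norm)
    else
      fit_grnn(split$train, spread = s, norm = split$norm)
  }
  if (optimizer == "none") {
    return(structure(list(model = refit(spread), best_spread = spread,
                          best_fitness = NA_real_, trace = NULL,
                          family = family, optimizer = "none"),
                     class = "spread_tuning"))
  }
  obj <- spread_objective(split, family, h = h, spread_mode = spread_mode,
                          ridge = ridge, bias = bias, seed = seed,
                          fitness_set = fitness_set)
  res <- if (optimizer == "qga")
    run_qga(obj, lo, hi, n = n, m = m, max_generations = max_generations,
            stall_generations = stall_generations, seed = seed)
  else
    run_ga(obj, lo, hi, n = n, m = m, max_generations = max_generations,
           stall_generations = stall_generations, seed = seed)
  structure(list(model = refit(res$best_value), best_spread = res$best_value,
                 best_fitness = res$best_fitness, trace = res$trace,
                 family = family, optimizer = optimizer),
            class = "spread_tuning")
}

#' @export
print.spread_tuning <- function(x, ...) {
  cat(sprintf("<spread_tuning> %s-%s: spread %.4g (fitness %s)\n",
              toupper(x$optimizer), toupper(x$family), x$best_spread,
              if (is.na(x$best_fitness)) "not searched"
              else format(x$best_fitness, digits = 4)))
  invisible(x)
}
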