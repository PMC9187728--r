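# Critical values for Dixon's r10 (Q) statistic, two-sided, alpha = 0.05,
# n = 3..10 (Dean & Dixon / Rorabacher tables).
.dixon_r10_05 <- c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
                   `7` = 0.568, `8` = 0.526, `9` = 0.493, `10` = 0.466)

#' Dixon Q-test flag for a small replicate set
#'
#' Computes the r10 statistic Q = gap / range for the more extreme of the two
#' candidate outliers (the minimum and the maximum), where gap is the distance
#' from the extreme to its nearest neighbour and range is max - min. Returns
#' the index of the extreme if Q exceeds the critical value for the sample
#' size, otherwise `NA`.
#'
#' @param values Numeric vector of 3 to 10 replicate measurements.
#' @param alpha Significance level; only 0.05 is tabulated.
#' @return Integer index into `values` of the flagged outlier, or
#'   `NA_integer_` when nothing is flagged (including zero range).
#' @examples
#' dixon_flag(c(1.0, 1.1, 9.9))   # 3
#' dixon_flag(c(1.0, 1.1, 1.2))   # NA
#' @export
dixon_flag <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 10)
    abort("Dixon r10 requires 3 <= n <= 10")
  if (!isTRUE(all.equal(alpha, 0.05)))
    abort("only alpha = 0.05 is tabulated for the Dixon r10 test")
  if (any(!is.finite(values))) abort("`values` must be finite")
  x <- sort(values)
  rng <- x[n] - x[1]
  if (rng == 0) return(NA_integer_)
  q_low <- (x[2] - x[1]) / rng
  q_high <- (x[n] - x[n - 1]) / rng
  crit <- .dixon_r10_05[[as.character(n)]]
  q <- max(q_low, q_high)
  if (q <= crit) return(NA_integer_)
  extreme <- if (q_high >= q_low) x[n] else x[1]
  which(values == extreme)[1]
}

#' Clean replicate measurements with the Dixon criterion
#'
#' Groups records by condition (temperature, PPFD, blue ratio), applies
#' [dixon_flag()] within each replicate set, deletes any group containing a
#' flagged replicate entirely, and averages the replicates of the surviving
#' groups. Groups with fewer than 3 (or more than 10) replicates cannot be
#' tested and pass through unfiltered with a warning.
#'
#' @param data Replicate-level tibble (`temperature`, `ppfd`, `blue_ratio`,
#'   `replicate`, `pn`).
#' @param alpha Dixon significance level (0.05).
#' @return Condition-level tibble (`temperature`, `ppfd`, `blue_ratio`, `pn`)
#'   with attributes `removed` (tibble of deleted condition triples),
#'   `n_removed` and `n_retained`.
#' @examples
#' cleaned <- clean_replicates(simulate_gas_exchange())
#' attr(cleaned, "n_removed")
#' @export
clean_replicates <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  need <- c("temperature", "ppfd", "blue_ratio", "replicate", "pn")
  if (!all(need %in% names(data)))
    abort(paste("`data` must contain columns:", paste(need, collapse = ", ")))
  grouped <- data |>
    dplyr::group_by(.data$temperature, .data$ppfd, .data$blue_ratio) |>
    dplyr::summarise(values = list(.data$pn), .groups = "drop")
  sizes <- lengths(grouped$values)
  untestable <- sizes < 3 | sizes > 10
  if (any(untestable))
    warn(sprintf("%d condition group(s) have replicate counts outside 3..10 and pass through unfiltered",
                 sum(untestable)))
  flagged <- logical(nrow(grouped))
  flagged[!untestable] <- vapply(
    grouped$values[!untestable],
    function(v) !is.na(dixon_flag(v, alpha)),
    logical(1)
  )
  removed <- dplyr::select(grouped[flagged, ], -"values")
  out <- grouped[!flagged, ] |>
    dplyr::mutate(pn = vapply(.data$values, mean, double(1))) |>
    dplyr::select(-"values")
  attr(out, "removed") <- removed
  attr(out, "n_removed") <- nrow(removed)
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Fit min-max normalisation parameters
#'
#' Records per-feature minima and maxima so that each feature maps linearly
#' onto `[0, 1]` via `z' = (z - z_min) / (z_max - z_min)`. Parameters are
#' fitted on the training set only; applying them to other data may give
#' values outside `[0, 1]`, which is intentional (no clipping).
#'
#' @param data Condition-level tibble.
#' @param features Character vector of columns to normalise.
#' @return A tibble of class `"pn_norm"` with columns `feature`, `z_min`,
#'   `z_max`.
#' @export
fit_normalization <- function(data,
                              features = c("blue_ratio", "ppfd",
                                           "temperature", "pn")) {
  stopifnot(is.data.frame(data), all(features %in% names(data)))
  out <- tibble(
    feature = features,
    z_min = unname(vapply(features, function(f) min(data[[f]]), double(1))),
    z_max = unname(vapply(features, function(f) max(data[[f]]), double(1)))
  )
  if (any(out$z_max <= out$z_min))
    abort(sprintf("degenerate feature(s): %s (z_max must exceed z_min)",
                  paste(out$feature[out$z_max <= out$z_min], collapse = ", ")))
  structure(out, class = c("pn_norm", class(out)))
}

#' Apply or invert min-max normalisation
#'
#' @param value Numeric vector.
#' @param norm A `"pn_norm"` object from [fit_normalization()].
#' @param feature Feature name to use.
#' @return Numeric vector of the same length.
#' @examples
#' nrm <- fit_normalization(tibble::tibble(pn = c(0, 10)), "pn")
#' normalize_value(5, nrm, "pn")       # 0.5
#' denormalize_value(0.5, nrm, "pn")   # 5
#' @export
normalize_value <- function(value, norm, feature) {
  p <- norm_row(norm, feature)
  (value - p$z_min) / (p$z_max - p$z_min)
}

#' @rdname normalize_value
#' @export
denormalize_value <- function(value, norm, feature) {
  p <- norm_row(norm, feature)
  value * (p$z_max - p$z_min) + p$z_min
}

norm_row <- function(norm, feature) {
  stopifnot(inherits(norm, "pn_norm"))
  i <- match(feature, norm$feature)
  if (is.na(i)) abort(sprintf("feature '%s' not in normalisation parameters", feature))
  list(z_min = norm$z_min[i], z_max = norm$z_max[i])
}

# Matrix of normalized input features, columns in model order (pi, par, T).
normalized_inputs <- function(data, norm,
                              features = c("blue_ratio", "ppfd", "temperature")) {
  m <- vapply(features, function(f) normalize_value(data[[f]], norm, f),
              double(nrow(data)))
  matrix(m, nrow = nrow(data), dimnames = list(NULL, features))
}

#' Split condition groups into training and verification sets
#'
#' Uniform seeded shuffle; the training size is `train_fraction * n` rounded
#' half away from zero (0.8 * 675 = 540 exactly). Normalisation parameters
#' are fitted on the training set only and stored in the result.
#'
#' @param data Condition-level tibble from [clean_replicates()].
#' @param train_fraction Fraction of groups used for training, in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return A list of class `"pn_split"` with elements `train`, `verify`,
#'   `norm`, `seed`, `train_fraction`.
#' @examples
#' sp <- split_groups(clean_replicates(simulate_gas_exchange()))
#' c(nrow(sp$train), nrow(sp$verify))
#' @export
split_groups <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  if (n < 2) abort("need at least 2 groups to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must lie in (0, 1)")
  n_train <- floor(train_fraction * n + 0.5)  # round half away from zero
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  idx <- with_step_seed(seed, "split", sample.int(n))
  train <- data[sort(idx[seq_len(n_train)]), ]
  verify <- data[sort(idx[(n_train + 1):n]), ]
  structure(
    list(train = train, verify = verify,
         norm = fit_normalization(train),
         seed = as.integer(seed), train_fraction = train_fraction),
    class = "pn_split"
  )
}

#' @export
print.pn_split <- function(x, ...) {
  cat(sprintf("<pn_split> %d training / %d verification groups (seed %d)\n",
              nrow(x$train), nrow(x$verify), x$seed))
  invisible(x)
}
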