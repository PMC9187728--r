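#' Initialize a qubit-chromosome population
#'
#' Every gene of every chromosome starts at the amplitude pair
#' `(1/sqrt(2), 1/sqrt(2))`, so each of the `2^m` basis states has measurement
#' probability `2^-m` (uniform superposition).
#'
#' @param n Population size.
#' @param m Bits per chromosome.
#' @return A list with `alpha` and `beta`, each an `n x m` matrix, of class
#'   `"qga_population"`.
#' @export
qga_population <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  a <- matrix(1 / sqrt(2), n, m)
  structure(list(alpha = a, beta = a), class = "qga_population")
}

#' Measure a qubit chromosome into a bitstring
#'
#' For each gene a uniform number in `[0, 1)` is drawn; the bit collapses to 1
#' when the draw exceeds `alpha^2` (the probability amplitude of state 0
#' squared), otherwise to 0. Bits are independent.
#'
#' @param alpha Numeric vector of alpha amplitudes for one chromosome.
#' @return Integer vector of 0/1 bits.
#' @export
qga_measure <- function(alpha) {
  as.integer(runif(length(alpha)) > alpha^2)
}

#' Decode a bitstring to a spread value
#'
#' Binary coding, most-significant bit first:
#' `value = lo + int(bits) / (2^m - 1) * (hi - lo)`, so the all-zero and
#' all-one strings decode exactly to the interval endpoints.
#'
#' @param bits Integer vector of 0/1 bits.
#' @param lo,hi Interval endpoints (`lo < hi`).
#' @return Decoded value in `[lo, hi]`.
#' @examples
#' decode_bits(c(1, 0, 0, 0), 0, 15)  # 8
#' @export
decode_bits <- function(bits, lo, hi) {
  m <- length(bits)
  if (!m) abort("empty bitstring")
  stopifnot(all(bits %in% c(0, 1)), lo < hi)
  v <- sum(bits * 2^((m - 1):0))
  lo + v / (2^m - 1) * (hi - lo)
}

#' Mean-squared-error fitness
#'
#' The optimizer's objective: mean squared difference between measured and
#' predicted (normalized) rates over the evaluation set.
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return Scalar mean squared error.
#' @export
fitness_mse <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 1)
  mean((measured - predicted)^2)
}

#' Default rotation-angle policy
#'
#' Returns the rotation magnitude for each gene given the individual's bit,
#' the elitist best's bit and whether the individual currently beats the
#' best. The default: no rotation where the bits agree, `0.05 * pi` toward
#' the best's bit where they differ, regardless of the fitness comparison.
#'
#' @param delta Rotation magnitude used when bits differ (radians).
#' @return A function `(x_bit, b_bit, curr_better) -> angle magnitude`,
#'   vectorized over bits.
#' @export
qga_default_policy <- function(delta = 0.05 * pi) {
  force(delta)
  function(x_bit, b_bit, curr_better) ifelse(x_bit == b_bit, 0, delta)
}

#' Rotate a qubit chromosome toward the elitist best
#'
#' Applies the quantum rotation gate
#' `[alpha'; beta'] = [[cos t, -sin t], [sin t, cos t]] [alpha; beta]`
#' gene by gene with `t = s * policy(x_i, b_i, f_curr < f_best)`. The sign
#' `s` steers the measurement probability toward the best individual's bit:
#' to grow `beta^2` (bit 1) it is `+1` when `alpha * beta >= 0` and `-1`
#' otherwise, mirrored for bit 0. The angle is additionally clamped so the
#' amplitude pair never rotates past the nearest target basis state, making
#' the approach to `beta^2 = 1` (or `0`) monotone; at the degenerate
#' equidistant states the positive rotation direction is used by convention.
#'
#' @param alpha,beta Amplitude vectors of one chromosome.
#' @param bits This individual's measured bits.
#' @param best_bits The elitist best bits.
#' @param f_curr,f_best Fitness of the individual and of the best.
#' @param policy Angle policy, as from [qga_default_policy()].
#' @return List with rotated `alpha` and `beta` (unit-norm per gene).
#' @export
qga_rotate <- function(alpha, beta, bits, best_bits, f_curr = Inf,
                       f_best = 0, policy = qga_default_policy()) {
  stopifnot(length(alpha) == length(beta),
            length(bits) == length(alpha),
            length(best_bits) == length(alpha))
  mag <- policy(bits, best_bits, isTRUE(f_curr < f_best))
  phi <- atan2(beta, alpha)
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
  # nearest basis state carrying the best bit: beta^2 = 1 at phi = +/- pi/2,
  # beta^2 = 0 at phi = 0 or pi
  d1 <- wrap(ifelse(best_bits == 1, pi / 2, 0) - phi)
  d2 <- wrap(ifelse(best_bits == 1, -pi / 2, pi) - phi)
  d <- ifelse(abs(d1) < abs(d2), d1,
              ifelse(abs(d2) < abs(d1), d2, pmax(d1, d2)))
  theta <- sign(d) * pmin(abs(d), mag)
  list(alpha = cos(theta) * alpha - sin(theta) * beta,
       beta  = sin(theta) * alpha + cos(theta) * beta)
}

#' Quantum genetic algorithm over a scalar interval
#'
#' Minimizes `objective` over `[lo, hi]` with a population of qubit
#' chromosomes: each generation every chromosome is measured into a
#' bitstring, decoded, and evaluated; the elitist best-ever solution is
#' updated (strict improvement only); every chromosome is then rotated
#' toward the best's bits. Stops after `max_generations`, or after
#' `stall_generations` without improvement. Candidates with non-finite
#' fitness are discarded with a warning.
#'
#' @param objective Function mapping a value in `[lo, hi]` to a scalar
#'   fitness (smaller is better).
#' @param lo,hi Search interval (defaults 0.1 and 10, the spread range).
#' @param n Population size.
#' @param m Bits per chromosome.
#' @param max_generations,stall_generations Stopping controls.
#' @param policy Rotation-angle policy ([qga_default_policy()]).
#' @param seed Integer seed.
#' @return List of class `"qga_result"`: `best_value`, `best_fitness`,
#'   `trace` (tibble: generation, best_fitness, best_value, evaluations),
#'   `population`, and `method = "qga"`.
#' @examples
#' res <- run_qga(function(v) (v - 3)^2, seed = 1, max_generations = 30)
#' res$best_value
#' @export
run_qga <- function(objective, lo = 0.1, hi = 10, n = 20, m = 20,
                    max_generations = 50, stall_generations = 10,
                    policy = qga_default_policy(), seed = 1L) {
  stopifnot(is.function(objective), lo < hi, n >= 2, m >= 4)
  pop <- qga_population(n, m)
  best_bits <- NULL
  best_fit <- Inf
  best_val <- NA_real_
  trace <- vector("list", max_generations)
  evals <- 0L
  stall <- 0L
  withr::with_seed(derive_seed(seed, "qga"), {
    for (g in seq_len(max_generations)) {
      bits <- t(vapply(seq_len(n), function(i) qga_measure(pop$alpha[i, ]),
                       integer(m)))
      vals <- apply(bits, 1, decode_bits, lo = lo, hi = hi)
      fits <- vapply(vals, function(v) as.numeric(objective(v)), double(1))
      evals <- evals + n
      bad <- !is.finite(fits)
      if (any(bad)) {
        warn(sprintf("discarded %d candidate(s) with non-finite fitness", sum(bad)))
        fits[bad] <- Inf
      }
      improved <- FALSE
      i_best <- which.min(fits)
      if (fits[i_best] < best_fit) {
        best_fit <- fits[i_best]
        best_val <- vals[i_best]
        best_bits <- bits[i_best, ]
        improved <- TRUE
      }
      trace[[g]] <- tibble(generation = g, best_fitness = best_fit,
                           best_value = best_val, evaluations = evals)
      if (!is.null(best_bits)) {
        for (i in seq_len(n)) {
          r <- qga_rotate(pop$alpha[i, ], pop$beta[i, ], bits[i, ], best_bits,
                          fits[i], best_fit, policy)
          pop$alpha[i, ] <- r$alpha
          pop$beta[i, ] <- r$beta
        }
      }
      stall <- if (improved) 0L else stall + 1L
      if (stall >= stall_generations) break
    }
  })
  structure(list(best_value = best_val, best_fitness = best_fit,
                 trace = dplyr::bind_rows(trace), population = pop,
                 method = "qga", seed = as.integer(seed)),
            class = c("qga_result", "pn_opt_result"))
}

#' Classical binary genetic algorithm baseline
#'
#' Same encoding and stopping rules as [run_qga()], with the classical
#' operators: tournament selection of size 2, one-point crossover
#' (rate `crossover`), per-bit mutation (rate `mutation`, default `1/m`),
#' and elitism of one (the best-ever bitstring survives each generation).
#'
#' @inheritParams run_qga
#' @param crossover One-point crossover probability.
#' @param mutation Per-bit flip probability; default `1/m`.
#' @return List of class `"ga_result"` with the same fields as [run_qga()].
#' @examples
#' run_ga(function(v) (v - 3)^2, seed = 1, max_generations = 30)$best_value
#' @export
run_ga <- function(objective, lo = 0.1, hi = 10, n = 20, m = 20,
                   max_generations = 50, stall_generations = 10,
                   crossover = 0.8, mutation = NULL, seed = 1L) {
  stopifnot(is.function(objective), lo < hi, n >= 2, m >= 4)
  mutation <- mutation %||% (1 / m)
  best_bits <- NULL; best_fit <- Inf; best_val <- NA_real_
  trace <- vector("list", max_generations)
  evals <- 0L; stall <- 0L
  withr::with_seed(derive_seed(seed, "ga"), {
    bits <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
    for (g in seq_len(max_generations)) {
      vals <- apply(bits, 1, decode_bits, lo = lo, hi = hi)
      fits <- vapply(vals, function(v) as.numeric(objective(v)), double(1))
      evals <- evals + n
      bad <- !is.finite(fits)
      if (any(bad)) {
        warn(sprintf("discarded %d candidate(s) with non-finite fitness", sum(bad)))
        fits[bad] <- Inf
      }
      i_best <- which.min(fits)
      improved <- fits[i_best] < best_fit
      if (improved) {
        best_fit <- fits[i_best]; best_val <- vals[i_best]
        best_bits <- bits[i_best, ]
      }
      trace[[g]] <- tibble(generation = g, best_fitness = best_fit,
                           best_value = best_val, evaluations = evals)
      stall <- if (improved) 0L else stall + 1L
      if (stall >= stall_generations || g == max_generations) break
      # tournament selection (size 2)
      pick <- function() {
        ij <- sample.int(n, 2, replace = TRUE)
        ij[which.min(fits[ij])]
      }
      children <- matrix(0L, n, m)
      i <- 1L
      while (i <= n) {
        p1 <- bits[pick(), ]; p2 <- bits[pick(), ]
        if (runif(1) < crossover && m >= 2) {
          cut <- sample.int(m - 1, 1)
          c1 <- c(p1[1:cut], p2[(cut + 1):m])
          c2 <- c(p2[1:cut], p1[(cut + 1):m])
        } else {
          c1 <- p1; c2 <- p2
        }
        children[i, ] <- c1
        if (i + 1L <= n) children[i + 1L, ] <- c2
        i <- i + 2L
      }
      flip <- matrix(runif(n * m) < mutation, n, m)
      children <- (children + flip) %% 2L
      if (!is.null(best_bits)) children[1, ] <- best_bits  # elitism of 1
      bits <- children
    }
  })
  structure(list(best_value = best_val, best_fitness = best_fit,
                 trace = dplyr::bind_rows(trace), method = "ga",
                 seed = as.integer(seed)),
            class = c("ga_result", "pn_opt_result"))
}

#' @export
print.pn_opt_result <- function(x, ...) {
  cat(sprintf("<%s> best value %.6g, fitness %.6g after %d generation(s)\n",
              toupper(x$method), x$best_value, x$best_fitness, nrow(x$trace)))
  invisible(x)
}

#' @describeIn run_qga Per-generation trace as a tibble.
#' @param x A `"qga_result"` or `"ga_result"`.
#' @param ... Unused.
#' @method tidy pn_opt_result
#' @export
tidy.pn_opt_result <- function(x, ...) x$trace

#' @describeIn run_qga One-row optimization summary.
#' @method glance pn_opt_result
#' @export
glance.pn_opt_result <- function(x, ...) {
  tibble(method = x$method, best_value = x$best_value,
         best_fitness = x$best_fitness, generations = nrow(x$trace),
         evaluations = max(x$trace$evaluations))
}
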