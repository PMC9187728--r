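#' Ground-truth parameters for the synthetic photosynthesis surface
#'
#' The synthetic generator draws net photosynthetic rate from a phenomenological
#' response surface: a non-rectangular hyperbola (NRH) in photon flux density,
#' modulated by a Gaussian response in leaf temperature and a Gaussian response
#' in blue-light ratio whose optimum shifts away from `b_opt` under temperature
#' stress (`b_tshift`), reflecting the observation that the blue-light demand of
#' the leaf rises when temperature departs from its optimum.
#'
#' Defaults describe a healthy cucumber seedling: light-saturated gross rate
#' around 20 umol m-2 s-1, apparent quantum yield 0.06, dark respiration
#' 1.5 umol m-2 s-1, temperature optimum 25 degC.
#'
#' @param pmax0 Asymptotic light-saturated gross rate, umol m-2 s-1 (> 0).
#' @param alpha0 Apparent quantum yield, mol CO2 per mol photons.
#' @param theta Curvature of the non-rectangular hyperbola, in (0, 1).
#' @param rd Dark respiration, umol m-2 s-1.
#' @param t_opt Optimal leaf temperature, degC.
#' @param t_width Width (s.d.) of the Gaussian temperature response, degC (> 0).
#' @param b_opt Optimal blue-light ratio at `t_opt`, in (0, 1).
#' @param b_width Width of the Gaussian blue-ratio response.
#' @param b_tshift Shift of the blue optimum per degC of |T - t_opt|.
#' @param noise_sd Replicate noise s.d., umol m-2 s-1 (>= 0).
#' @param seed Integer seed for the replicate-noise generator.
#' @return A list of class `"pn_truth_params"`.
#' @examples
#' p <- pn_truth_params(noise_sd = 0)
#' true_pn(800, 24, 0.3, p)
#' @export
pn_truth_params <- function(pmax0 = 20, alpha0 = 0.06, theta = 0.8, rd = 1.5,
                            t_opt = 25, t_width = 8, b_opt = 0.3,
                            b_width = 0.35, b_tshift = 0.02,
                            noise_sd = 0.2, seed = 1L) {
  p <- list(pmax0 = pmax0, alpha0 = alpha0, theta = theta, rd = rd,
            t_opt = t_opt, t_width = t_width, b_opt = b_opt,
            b_width = b_width, b_tshift = b_tshift,
            noise_sd = noise_sd, seed = as.integer(seed))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) abort("all ground-truth parameters must be finite scalars")
  if (p$theta <= 0 || p$theta >= 1) abort("`theta` must lie in (0, 1)")
  if (p$pmax0 <= 0) abort("`pmax0` must be positive")
  if (p$t_width <= 0) abort("`t_width` must be positive")
  if (p$b_opt <= 0 || p$b_opt >= 1) abort("`b_opt` must lie in (0, 1)")
  if (p$noise_sd < 0) abort("`noise_sd` must be non-negative")
  structure(p, class = "pn_truth_params")
}

#' Factorial gas-exchange experiment design
#'
#' Defaults reproduce the measurement campaign the pipeline assumes:
#' 5 temperatures (18-30 degC), 15 photon flux densities (0-1600
#' umol m-2 s-1), 9 blue-light ratios (0.1-0.9), 3 replicates per condition,
#' i.e. 675 condition groups. `sixteen_levels = TRUE` adds a 16th PPFD level
#' (300 umol m-2 s-1) giving the 720-group variant used for gross-error
#' filtering fixtures.
#'
#' @param temperatures Numeric vector of leaf temperatures, degC.
#' @param ppfd_levels Numeric vector of photon flux densities, umol m-2 s-1.
#' @param blue_ratios Numeric vector of blue-light ratios in `[0, 1]`.
#' @param replicates Replicates per condition (>= 1).
#' @param sixteen_levels If `TRUE`, add 300 umol m-2 s-1 to the default PPFD
#'   levels (ignored when `ppfd_levels` is supplied explicitly).
#' @return A list of class `"pn_design"`.
#' @examples
#' d <- pn_design()
#' length(d$temperatures) * length(d$ppfd_levels) * length(d$blue_ratios)
#' @export
pn_design <- function(temperatures = c(18, 21, 24, 27, 30),
                      ppfd_levels = NULL,
                      blue_ratios = seq(0.1, 0.9, by = 0.1),
                      replicates = 3L,
                      sixteen_levels = FALSE) {
  default_ppfd <- c(1600, 1400, 1200, 1000, 800, 600, 400, 200,
                    100, 50, 30, 20, 10, 5, 0)
  if (is.null(ppfd_levels)) {
    ppfd_levels <- if (sixteen_levels) sort(c(default_ppfd, 300), decreasing = TRUE)
                   else default_ppfd
  }
  if (!length(temperatures) || !length(ppfd_levels) || !length(blue_ratios))
    abort("design factor lists must be non-empty")
  if (replicates < 1) abort("`replicates` must be >= 1")
  if (any(ppfd_levels < 0)) abort("`ppfd_levels` must be non-negative")
  if (any(blue_ratios < 0 | blue_ratios > 1))
    abort("`blue_ratios` must lie in [0, 1]")
  structure(list(temperatures = temperatures, ppfd_levels = ppfd_levels,
                 blue_ratios = blue_ratios, replicates = as.integer(replicates)),
            class = "pn_design")
}

#' Noise-free net photosynthetic rate surface
#'
#' Evaluates the synthetic ground truth
#' \deqn{P(I, T, b) = \frac{\alpha I + P_{eff} -
#'   \sqrt{(\alpha I + P_{eff})^2 - 4\theta \alpha I P_{eff}}}{2\theta} - R_d}
#' where \eqn{P_{eff}} is `pmax0` scaled by the Gaussian temperature and
#' blue-ratio responses. Vectorised over its first three arguments.
#'
#' @param par Photon flux density, umol m-2 s-1 (>= 0).
#' @param temperature Leaf temperature, degC.
#' @param blue_ratio Blue-light ratio in `[0, 1]`.
#' @param params A [pn_truth_params()] object.
#' @return Net photosynthetic rate, umol m-2 s-1.
#' @examples
#' true_pn(0, 24, 0.3)          # dark: -rd
#' true_pn(1600, 24, 0.3)       # near light saturation
#' @export
true_pn <- function(par, temperature, blue_ratio, params = pn_truth_params()) {
  stopifnot(inherits(params, "pn_truth_params"))
  if (any(!is.finite(par)) || any(!is.finite(temperature)) ||
      any(!is.finite(blue_ratio)))
    abort("`par`, `temperature` and `blue_ratio` must be finite")
  if (any(par < 0)) abort("`par` must be non-negative")
  b_shift <- params$b_tshift * abs(temperature - params$t_opt)
  p_eff <- params$pmax0 *
    exp(-(temperature - params$t_opt)^2 / (2 * params$t_width^2)) *
    exp(-(blue_ratio - params$b_opt - b_shift)^2 / (2 * params$b_width^2))
  a <- params$alpha0 * par + p_eff
  disc <- pmax(a^2 - 4 * params$theta * params$alpha0 * par * p_eff, 0)
  (a - sqrt(disc)) / (2 * params$theta) - params$rd
}

#' Generate a synthetic gas-exchange dataset
#'
#' One record per (temperature x PPFD x blue ratio x replicate). The observed
#' rate is `true_pn()` plus homoscedastic Gaussian replicate noise drawn from a
#' generator seeded by `params$seed`; identical seeds give byte-identical
#' datasets.
#'
#' @param design A [pn_design()] object.
#' @param params A [pn_truth_params()] object.
#' @return A tibble with columns `temperature`, `ppfd`, `blue_ratio`,
#'   `replicate`, `pn`.
#' @examples
#' nrow(simulate_gas_exchange())  # 5 * 15 * 9 * 3 = 2025
#' @export
simulate_gas_exchange <- function(design = pn_design(),
                                  params = pn_truth_params()) {
  stopifnot(inherits(design, "pn_design"), inherits(params, "pn_truth_params"))
  grid <- tidyr::expand_grid(
    temperature = design$temperatures,
    ppfd = design$ppfd_levels,
    blue_ratio = design$blue_ratios,
    replicate = seq_len(design$replicates)
  )
  mu <- true_pn(grid$ppfd, grid$temperature, grid$blue_ratio, params)
  noise <- with_step_seed(params$seed, "replicate-noise",
                          rnorm(nrow(grid), 0, params$noise_sd))
  dplyr::mutate(grid, pn = mu + noise)
}

#' Inject seeded gross errors into replicate measurements
#'
#' Emulates instrument gross errors: in `n_groups` distinct condition groups
#' chosen by a seeded generator, one replicate's rate is shifted by
#' `+/- magnitude`. The corrupted records are described by a manifest attached
#' as the `"manifest"` attribute (retrieve with [gross_error_manifest()]).
#'
#' @param data Replicate-level tibble as from [simulate_gas_exchange()].
#' @param n_groups Number of condition groups to corrupt.
#' @param magnitude Absolute shift, umol m-2 s-1 (> 0).
#' @param seed Integer seed.
#' @return `data` with `n_groups` corrupted records and a manifest attribute.
#' @examples
#' x <- inject_gross_errors(simulate_gas_exchange(), 5, 4)
#' gross_error_manifest(x)
#' @export
inject_gross_errors <- function(data, n_groups, magnitude = 4, seed = 1L) {
  stopifnot(is.data.frame(data), n_groups >= 0)
  if (n_groups == 0) {
    attr(data, "manifest") <- tibble(temperature = double(), ppfd = double(),
                                     blue_ratio = double(),
                                     replicate = integer(), shift = double())
    return(data)
  }
  if (magnitude <= 0) abort("`magnitude` must be positive")
  keys <- dplyr::distinct(data, .data$temperature, .data$ppfd, .data$blue_ratio)
  if (n_groups > nrow(keys))
    abort(sprintf("`n_groups` (%d) exceeds the %d available condition groups",
                  n_groups, nrow(keys)))
  manifest <- with_step_seed(seed, "gross-errors", {
    chosen <- keys[sample.int(nrow(keys), n_groups), ]
    reps <- dplyr::distinct(data, .data$replicate)$replicate
    dplyr::mutate(chosen,
                  replicate = sample(reps, n_groups, replace = TRUE),
                  shift = sample(c(-magnitude, magnitude), n_groups,
                                 replace = TRUE))
  })
  out <- dplyr::left_join(
    data, manifest,
    by = c("temperature", "ppfd", "blue_ratio", "replicate")
  )
  out$pn <- out$pn + dplyr::coalesce(out$shift, 0)
  out$shift <- NULL
  attr(out, "manifest") <- manifest
  out
}

#' @rdname inject_gross_errors
#' @param x A tibble returned by [inject_gross_errors()].
#' @export
gross_error_manifest <- function(x) {
  m <- attr(x, "manifest")
  if (is.null(m)) abort("`x` carries no gross-error manifest")
  m
}
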