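test_that("qubit population starts in the uniform superposition", {
  pop <- qga_population(5, 8)
  expect_true(all(pop$alpha == 1 / sqrt(2)))
  expect_true(all(pop$beta == 1 / sqrt(2)))
  expect_unit_norm(pop)
})

test_that("measurement collapses with the stated probabilities", {
  withr::with_seed(1, {
    expect_true(all(qga_measure(rep(1, 1000)) == 0))
    expect_true(all(qga_measure(rep(0, 1000)) == 1))
    # alpha^2 = 0.5: frequency of ones within a 3.9-sigma binomial band
    freq <- mean(qga_measure(rep(1 / sqrt(2), 1e5)))
    expect_gte(freq, 0.494)
    expect_lte(freq, 0.506)
  })
})

test_that("binary decoding maps endpoints and interior points exactly", {
  expect_equal(decode_bits(rep(0, 20), 0.1, 10), 0.1)
  expect_equal(decode_bits(rep(1, 20), 0.1, 10), 10)
  expect_equal(decode_bits(c(1, 0, 0, 0), 0, 15), 8)
  expect_error(decode_bits(integer(0), 0, 1), "empty")
  # bijection onto a uniform grid, endpoints inclusive
  m <- 6
  vals <- vapply(0:(2^m - 1), function(k) {
    bits <- as.integer(intToBits(k))[m:1]
    decode_bits(bits, -1, 1)
  }, double(1))
  expect_equal(vals, seq(-1, 1, length.out = 2^m))
})

test_that("fitness is the mean squared difference", {
  expect_equal(fitness_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fitness_mse(c(0, 2), c(1, 1)), 1)
  withr::with_seed(2, {
    a <- rnorm(20); b <- rnorm(20); p <- sample(20)
    expect_equal(fitness_mse(a, b), fitness_mse(a[p], b[p]))
  })
  expect_error(fitness_mse(numeric(0), numeric(0)))
})

test_that("rotation preserves the qubit norm and steers toward the best bit", {
  a <- rep(1 / sqrt(2), 4); b <- a
  # zero angle: unchanged
  same <- qga_rotate(a, b, c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(same$alpha, a)
  expect_equal(same$beta, b)
  # norm conservation under random repeated rotations
  withr::with_seed(3, {
    for (i in 1:50) {
      r <- qga_rotate(a, b, sample(0:1, 4, TRUE), sample(0:1, 4, TRUE))
      expect_lt(max(abs(r$alpha^2 + r$beta^2 - 1)), 1e-12)
      a <- r$alpha; b <- r$beta
    }
  })
  # repeated rotation toward bit 1 drives beta^2 -> 1 monotonically
  a <- 1 / sqrt(2); b <- 1 / sqrt(2)
  prev <- b^2
  for (i in 1:100) {
    r <- qga_rotate(a, b, 0, 1)
    expect_gte(r$beta^2, prev - 1e-15)
    prev <- r$beta^2
    a <- r$alpha; b <- r$beta
  }
  expect_gt(prev, 0.999)
})

test_that("QGA finds a known optimum and keeps an elitist trace", {
  obj <- function(v) (v - 3)^2
  hits <- 0
  for (s in 1:5) {
    res <- run_qga(obj, 0.1, 10, seed = s)
    expect_true(all(diff(res$trace$best_fitness) <= 0))
    if (abs(res$best_value - 3) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # constant objective: any value, fitness equals the constant
  flat <- run_qga(function(v) 7, seed = 1, max_generations = 5)
  expect_equal(flat$best_fitness, 7)
  expect_true(flat$best_value >= 0.1 && flat$best_value <= 10)
})

test_that("QGA conserves qubit norms and discards non-finite candidates", {
  res <- run_qga(function(v) (v - 2)^2, seed = 4, max_generations = 20,
                 stall_generations = 20)
  expect_unit_norm(res$population)
  obj_bad <- function(v) if (v > 5) NaN else (v - 2)^2
  expect_warning(run_qga(obj_bad, seed = 1, max_generations = 1,
                         stall_generations = 1), "non-finite")
  bad <- suppressWarnings(run_qga(obj_bad, seed = 1, max_generations = 5,
                                  stall_generations = 5))
  expect_true(is.finite(bad$best_fitness))
})

test_that("an all-zero rotation policy leaves the population stationary", {
  res <- run_qga(function(v) (v - 3)^2, seed = 2, max_generations = 25,
                 stall_generations = 25,
                 policy = function(x, b, cb) rep(0, length(x)))
  expect_true(all(res$population$alpha == 1 / sqrt(2)))
  # per-bit measurement frequency stays 0.5 within 0.01 over 1e5 draws
  freq <- withr::with_seed(6, mean(qga_measure(
    rep(res$population$alpha[1, ], length.out = 1e5))))
  expect_lt(abs(freq - 0.5), 0.01)
})

test_that("classical GA finds the known optimum with an elitist trace", {
  obj <- function(v) (v - 3)^2
  hits <- 0
  for (s in 1:5) {
    res <- run_ga(obj, 0.1, 10, seed = s)
    expect_true(all(diff(res$trace$best_fitness) <= 0))
    if (abs(res$best_value - 3) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 4)
  expect_s3_class(tidy(res), "tbl_df")
  expect_identical(glance(res)$method, "ga")
})

test_that("tune_spread wires optimizers, families and the none-route", {
  sp <- small_split()
  none <- tune_spread(sp, "rbf", "none", spread = 1.7)
  expect_null(none$trace)
  expect_equal(none$best_spread, 1.7)
  expect_equal(none$model$widths, rep(1.7, nrow(sp$train)))
  qgrnn <- tune_spread(sp, "grnn", "qga", max_generations = 8, seed = 2)
  expect_s3_class(qgrnn$model, "grnn_model")
  expect_true(is.finite(qgrnn$best_fitness))
  # reported best fitness is reproducible from the returned spread
  obj <- spread_objective(sp, "grnn")
  expect_equal(obj(qgrnn$best_spread), qgrnn$best_fitness, tolerance = 1e-12)
})

test_that("spread objective matches the fit-and-predict route", {
  sp <- small_split()
  obj <- spread_objective(sp, "rbf")
  for (s in c(0.4, 1, 3)) {
    fit <- fit_rbf(sp$train, spread = s, norm = sp$norm)
    pred_norm <- normalize_value(predict(fit, sp$verify), sp$norm, "pn")
    meas_norm <- normalize_value(sp$verify$pn, sp$norm, "pn")
    expect_equal(obj(s), fitness_mse(meas_norm, pred_norm), tolerance = 1e-9)
  }
})
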