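test_that("k-means reaches the hand-computed fixed point", {
  X <- matrix(c(0, 1, 9, 10), ncol = 1)
  ctr <- kmeans_centers(X, 2, centers_init = matrix(c(0, 9), ncol = 1))
  expect_equal(sort(as.numeric(ctr)), c(0.5, 9.5))
  # h = 1: the grand mean
  expect_equal(as.numeric(kmeans_centers(X, 1)), 5)
  # h = n with distinct rows: fixed point at the rows themselves
  ctr_n <- kmeans_centers(X, 4, seed = 3)
  expect_equal(sort(as.numeric(ctr_n)), c(0, 1, 9, 10))
  expect_error(kmeans_centers(X, 5), "exceeds")
})

test_that("k-means objective is non-increasing and assignments are nearest", {
  X <- withr::with_seed(7, matrix(runif(200), ncol = 2))
  ctr <- kmeans_centers(X, 6, seed = 2)
  obj <- attr(ctr, "objective_trace")
  expect_true(all(diff(obj) <= 1e-12))
  # post hoc: every sample maps to its nearest center
  d2 <- as.matrix(dist(rbind(X, ctr)))[1:100, 101:106]^2
  assign <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(1:100, assign)])
  expect_equal(wss, obj[length(obj)], tolerance = 1e-10)
})

test_that("k-means agrees with the stats::kmeans oracle from shared starts", {
  X <- withr::with_seed(11, matrix(rnorm(60), ncol = 2))
  init <- X[c(1, 10, 20), ]
  ours <- kmeans_centers(X, 3, centers_init = init)
  ref <- stats::kmeans(X, centers = init, algorithm = "Lloyd", iter.max = 100)
  expect_equal(sort(as.numeric(ours)), sort(as.numeric(ref$centers)),
               tolerance = 1e-8)
})

test_that("self-organizing widths follow c_max / sqrt(2h)", {
  expect_equal(rbf_widths(matrix(c(0, 2), ncol = 1)), c(1, 1))
  # homogeneity: scaling centers scales the width
  ctr <- withr::with_seed(2, matrix(runif(12), ncol = 3))
  expect_equal(rbf_widths(3 * ctr), 3 * rbf_widths(ctr))
  # collinear hand computation: c_max = 3, h = 3
  expect_equal(rbf_widths(matrix(c(0, 1, 3), ncol = 1)),
               rep(3 / sqrt(6), 3))
  expect_error(rbf_widths(matrix(1, ncol = 1)), "single center")
})

test_that("activations are Gaussian in the center distances", {
  ctr <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  w <- c(0.5, 2)
  # at a center: activation 1
  expect_equal(rbf_activations(ctr, ctr, w)[cbind(1:2, 1:2)], c(1, 1))
  # at distance sigma * sqrt(2): activation exp(-1)
  x <- matrix(c(0.5 * sqrt(2), 0), ncol = 2)
  expect_equal(rbf_activations(x, ctr[1, , drop = FALSE], 0.5)[1, 1],
               exp(-1))
  # range (0, 1]
  X <- withr::with_seed(3, matrix(runif(40), ncol = 2))
  phi <- rbf_activations(X, ctr, w)
  expect_true(all(phi > 0 & phi <= 1))
  expect_error(rbf_activations(X[, 1, drop = FALSE], ctr, w), "dimension")
})

test_that("least-squares weights solve the stated systems", {
  y <- c(3, -1, 2)
  expect_equal(fit_rbf_weights(diag(3), y, ridge = 0), y)
  # square nonsingular: exact interpolation
  Phi <- withr::with_seed(4, matrix(runif(25), 5, 5) + diag(5))
  y5 <- rnorm(5)
  w <- fit_rbf_weights(Phi, y5, ridge = 0)
  expect_lt(max(abs(Phi %*% w - y5)), 1e-8)
  # cross-check against the lm() oracle on an overdetermined system
  Phi2 <- withr::with_seed(6, matrix(rnorm(40), 10, 4))
  y10 <- rnorm(10)
  expect_equal(fit_rbf_weights(Phi2, y10, ridge = 0),
               unname(coef(lm(y10 ~ Phi2 - 1))), tolerance = 1e-8)
  # shrinkage limit
  expect_lt(sum(fit_rbf_weights(Phi2, y10, ridge = 1e12)^2), 1e-10)
  # rank deficiency falls back to the pseudo-inverse
  Phi3 <- cbind(Phi2, 0)
  expect_message(w3 <- fit_rbf_weights(Phi3, y10, ridge = 0), "pseudo-inverse")
  expect_equal(length(w3), 5L)
})

test_that("h = n RBF interpolates its training data exactly", {
  data <- random_conditions(50, seed = 8)
  fit <- fit_rbf(data, spread = 0.2, ridge = 0)
  pred <- predict(fit, data)
  expect_lt(max(abs(pred - data$pn)), 1e-6)
  expect_lt(fit$train_mse_norm, 1e-10)
})

test_that("constant targets are reproduced everywhere on the training range", {
  # a constant is representable once the output bias unit is enabled
  data <- random_conditions(30, seed = 9)
  data$pn <- seq(2, 7, length.out = 30)  # non-degenerate for normalization
  nrm <- fit_normalization(data)
  data$pn <- 5
  fit <- fit_rbf(data, spread = 0.5, h = 10, ridge = 0, bias = TRUE,
                 norm = nrm)
  probe <- random_conditions(40, seed = 10)
  expect_lt(max(abs(predict(fit, probe) - 5)), 1e-6)
})

test_that("training is deterministic and prediction is spread-continuous", {
  sp <- small_split()
  f1 <- fit_rbf(sp$train, spread = 1.3, h = 20, seed = 5, norm = sp$norm)
  f2 <- fit_rbf(sp$train, spread = 1.3, h = 20, seed = 5, norm = sp$norm)
  expect_equal(f1[names(f1) != "norm"], f2[names(f2) != "norm"])
  g1 <- fit_rbf(sp$train, spread = 0.3, h = 20, norm = sp$norm)
  g2 <- fit_rbf(sp$train, spread = 0.3 * (1 + 1e-9), h = 20, norm = sp$norm)
  expect_lt(max(abs(predict(g1, sp$verify) - predict(g2, sp$verify))), 1e-6)
})

test_that("batch prediction equals per-row prediction", {
  sp <- small_split()
  fit <- fit_rbf(sp$train, spread = 1, norm = sp$norm)
  batch <- predict(fit, sp$verify)
  rows <- vapply(seq_len(nrow(sp$verify)),
                 function(i) predict(fit, sp$verify[i, ]), double(1))
  expect_equal(batch, rows)
  expect_identical(predict(fit, sp$verify[0, ]), double(0))
})

test_that("spread modes and broom methods expose the model structure", {
  sp <- small_split()
  fw <- fit_rbf(sp$train, spread = 2, h = 10, spread_mode = "width",
                norm = sp$norm)
  expect_equal(fw$widths, rep(2, 10))
  fs <- fit_rbf(sp$train, spread = 2, h = 10, spread_mode = "scale",
                seed = 1, norm = sp$norm)
  expect_equal(fs$widths, 2 * rbf_widths(fs$centers))
  td <- tidy(fw)
  expect_identical(nrow(td), 10L)
  expect_named(td, c("unit", "width", "weight", "center_blue_ratio",
                     "center_ppfd", "center_temperature"))
  expect_identical(glance(fw)$h, 10L)
})
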