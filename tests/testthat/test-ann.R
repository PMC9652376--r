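test_that("forward pass matches a hand-rolled matrix-product oracle", {
  set.seed(31)
  net <- mlp_init(3, 5, 8)
  # zeroed network emits zero scores
  zn <- net
  zn$w1[] <- 0; zn$b1[] <- 0; zn$w2[] <- 0; zn$b2[] <- 0
  expect_equal(mlp_forward(zn, c(1, 2, 3)), rep(0, 8))
  # with zero input the output is b2 + w2 tanh(b1)
  expect_equal(mlp_forward(net, c(0, 0, 0)),
               as.vector(net$w2 %*% tanh(net$b1)) + net$b2)
  # random batch against an explicit per-sample oracle
  x <- matrix(rnorm(12), 4, 3)
  y <- mlp_forward(net, x)
  for (i in 1:4) {
    h <- tanh(net$w1 %*% x[i, ] + net$b1)
    expect_equal(y[i, ], as.vector(net$w2 %*% h + net$b2))
  }
  expect_error(mlp_forward(net, c(1, 2)), "dimension")
})

test_that("MSE is the mean over samples and output units", {
  set.seed(32)
  net <- mlp_init(2, 3, 8)
  x <- matrix(rnorm(10), 5, 2)
  t8 <- mlp_forward(net, x)
  expect_equal(mlp_mse(net, x, t8), 0)            # perfect targets
  zn <- net; zn$w1[] <- 0; zn$b1[] <- 0; zn$w2[] <- 0; zn$b2[] <- 0
  expect_equal(mlp_mse(zn, matrix(0, 1, 2), one_hot(3L, 8)), 1 / 8)
  t2 <- matrix(rnorm(40), 5, 8)
  expect_equal(mlp_mse(net, x, t2),
               sum((mlp_forward(net, x) - t2)^2) / 40)
  expect_error(mlp_mse(net, x[0, , drop = FALSE], t2[0, ]), "empty")
})

test_that("the residual Jacobian matches finite differences", {
  set.seed(33)
  net <- mlp_init(3, 4, 2)
  x <- matrix(rnorm(15), 5, 3)
  targets <- matrix(rnorm(10), 5, 2)
  jm <- mlp_jacobian(net, x, targets)
  w0 <- faceage:::pack_params(net)
  eps <- 1e-6
  for (p in sample(length(w0), 12)) {
    wp <- w0; wp[p] <- wp[p] + eps
    wm <- w0; wm[p] <- wm[p] - eps
    rp <- as.vector(t(mlp_forward(faceage:::unpack_params(net, wp), x) - targets))
    rm <- as.vector(t(mlp_forward(faceage:::unpack_params(net, wm), x) - targets))
    expect_equal(jm$J[, p], (rp - rm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("the damped trainer stops immediately when the goal is already met", {
  set.seed(34)
  net <- mlp_init(2, 3, 2)
  x <- matrix(rnorm(8), 4, 2)
  targets <- mlp_forward(net, x)  # targets equal to initial outputs
  fit <- mlp_train(net, x, targets, network_config(hidden_size = 3))
  expect_true(fit$converged)
  expect_equal(max(fit$trace$epoch), 0L)
})

test_that("the damped trainer solves XOR within budget, no slower than the gradient oracle", {
  xor_x <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  xor_lab <- c(0L, 1L, 1L, 0L)
  targets <- one_hot(xor_lab, 2)
  set.seed(35)
  gd_net <- mlp_init(2, 4, 2)
  gd <- mlp_train(gd_net, xor_x, targets,
                  network_config(hidden_size = 4, learning_rate = 0.5,
                                 max_epochs = 2000, trainer = "gdm"))
  # the gradient-descent reference confirms the problem is learnable
  expect_lt(gd$mse, gd$trace$mse[1])
  gd_epochs <- if (gd$converged) max(gd$trace$epoch) else Inf
  set.seed(35)
  lm_net <- mlp_init(2, 4, 2)
  lm <- mlp_train(lm_net, xor_x, targets,
                  network_config(hidden_size = 4, max_epochs = 200))
  expect_true(lm$converged)
  expect_lte(lm$mse, 1e-3)
  expect_lte(max(lm$trace$epoch), gd_epochs)
})

test_that("a separable two-Gaussian set reaches the goal and 100% test accuracy", {
  toy <- two_gaussian_toy(n_per = 25, seed = 36)
  split <- divide_block(length(toy$labels), 0.8)
  ord <- faceage:::stratified_block_order(toy$labels)
  x <- toy$x[ord, ]; lab <- toy$labels[ord]
  set.seed(36)
  net <- mlp_init(2, 4, 2)
  fit <- mlp_train(net, x[split$train, ], one_hot(lab[split$train], 2),
                   network_config(hidden_size = 4))
  expect_true(fit$converged)
  expect_equal(predict_group(fit, x[split$test, ]), lab[split$test])
})

test_that("accepted damped steps never increase the training MSE", {
  set.seed(37)
  net <- mlp_init(3, 5, 2)
  x <- matrix(rnorm(60), 20, 3)
  targets <- one_hot(sample(0:1, 20, replace = TRUE), 2)
  fit <- mlp_train(net, x, targets, network_config(hidden_size = 5, max_epochs = 30))
  expect_true(all(diff(fit$trace$mse) <= 0))
})

test_that("with large mu the damped update approaches scaled gradient descent", {
  set.seed(38)
  net <- mlp_init(2, 3, 2)
  x <- matrix(rnorm(12), 6, 2)
  targets <- one_hot(sample(0:1, 6, replace = TRUE), 2)
  jm <- mlp_jacobian(net, x, targets)
  delta <- faceage:::lm_delta(jm$J, jm$e, mu = 1e8)
  grad_dir <- -as.vector(crossprod(jm$J, jm$e))
  cosine <- sum(delta * grad_dir) / sqrt(sum(delta^2) * sum(grad_dir^2))
  expect_gt(cosine, 0.9999)
})

test_that("argmax prediction breaks ties toward the lowest index", {
  net <- mlp_init(2, 2, 4)
  net$w1[] <- 0; net$b1[] <- 0; net$w2[] <- 0
  net$b2 <- c(0.2, 0.9, 0.1, 0.9)
  expect_equal(predict_group(net, c(0, 0)), 1L)
  net$b2 <- rep(0.5, 4)
  expect_equal(predict_group(net, c(0, 0)), 0L)  # all equal: lowest index
  set.seed(39)
  scores_net <- mlp_init(3, 4, 8)
  x <- matrix(rnorm(30), 10, 3)
  y <- mlp_forward(scores_net, x)
  expect_equal(predict_group(scores_net, x),
               apply(y, 1, function(r) which(r == max(r))[1] - 1L))
})

test_that("the block split is contiguous, disjoint and exhaustive", {
  for (n in c(5, 10, 138, 1355)) {
    sp <- divide_block(n)
    expect_equal(sp$train, seq_len(floor(0.8 * n)))
    expect_equal(sort(c(sp$train, sp$test)), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_equal(sp$test, seq.int(max(sp$train) + 1L, n))
  }
})
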