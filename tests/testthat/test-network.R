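# Small random nets and images used across the network tests.
tiny_net <- function(seed = 2) {
  conv_net(8, n_maps = c(4, 6), pool_after = 1, n_classes = 3, seed = seed)
}
tiny_image <- function(seed = 3) {
  set.seed(seed)
  array(runif(8 * 8 * 3), c(8, 8, 3))
}

feature_field <- function(model, layer, values, mode = "multiplicative") {
  structure(list(layers = stats::setNames(
    list(list(feature = values, spatial = NULL, mode = mode)),
    as.character(layer))), class = "attention_field")
}

test_that("absent and all-zero attention produce identical activations", {
  m <- tiny_net()
  px <- tiny_image()
  f0 <- forward_pass(m, px)
  fz <- forward_pass(m, px, feature_field(m, 2, rep(0, 6)))
  expect_identical(f0$act, fz$act)
  expect_identical(f0$feats, fz$feats)
  # additive mode needs layer means
  expect_error(forward_pass(m, px, feature_field(m, 1, rep(0, 4),
                                                 "additive")),
               "layer means")
  m$layer_means <- rep(1, 2)
  fz2 <- forward_pass(m, px, feature_field(m, 1, rep(0, 4), "additive"))
  expect_identical(f0$act, fz2$act)
})

test_that("multiplicative gain scales rectified activity exactly", {
  m <- tiny_net()
  px <- tiny_image()
  base <- forward_pass(m, px)
  # gain (1 + m) on one map of layer 1
  vals <- c(0, 0, 0.285, 0)
  fwd <- forward_pass(m, px, feature_field(m, 1, vals))
  expect_equal(fwd$act[[1]][, , 3], 1.285 * base$act[[1]][, , 3],
               tolerance = 1e-12)
  expect_identical(fwd$act[[1]][, , 1], base$act[[1]][, , 1])
  # m = -1 silences the map completely
  fz <- forward_pass(m, px, feature_field(m, 1, c(0, -1, 0, 0)))
  expect_true(all(fz$act[[1]][, , 2] == 0))
  # recorded r^lk scales by the gain exactly, incl. negative gain
  g <- -0.4 # 1 + beta f with beta f = -1.4
  fn <- forward_pass(m, px, feature_field(m, 1, c(g - 1, 0, 0, 0)))
  r0 <- record_spatially_averaged_activity(base)[[1]]
  rn <- record_spatially_averaged_activity(fn)[[1]]
  expect_equal(rn[1], g * r0[1], tolerance = 1e-12)
})

test_that("attention at a layer leaves earlier layers untouched", {
  m <- tiny_net()
  px <- tiny_image()
  base <- forward_pass(m, px)
  fwd <- forward_pass(m, px, feature_field(m, 2, runif(6, -0.5, 0.5)))
  expect_identical(fwd$act[[1]], base$act[[1]])
  expect_identical(fwd$pre[[2]], base$pre[[2]])
})

test_that("additive attention shifts the pre-activation by mu_l m", {
  m <- tiny_net()
  m$layer_means <- c(2.5, 1.3)
  px <- tiny_image()
  base <- forward_pass(m, px)
  vals <- c(0.2, -0.3, 0, 0.5)
  fwd <- forward_pass(m, px, feature_field(m, 1, vals, "additive"))
  for (k in 1:4) {
    expected <- pmax(base$pre[[1]][, , k] + 2.5 * vals[k], 0)
    expect_equal(fwd$act[[1]][, , k], expected, tolerance = 1e-12)
  }
})

test_that("pooling halves spatial dimensions and averaging is exact", {
  m <- tiny_net()
  px <- tiny_image()
  fwd <- forward_pass(m, px)
  expect_equal(dim(fwd$act[[1]])[1:2], c(8, 8))
  expect_equal(dim(fwd$act[[2]])[1:2], c(4, 4)) # after the pool
  expect_equal(layer_sizes(m), c(8L, 4L))
  # hand-computed spatial mean
  fake <- list(act = list(array(c(1, 2, 3, 4), c(2, 2, 1))))
  expect_equal(record_spatially_averaged_activity(fake)[[1]], 2.5)
  zero <- list(act = list(array(0, c(3, 3, 2))))
  expect_equal(record_spatially_averaged_activity(zero)[[1]], c(0, 0))
})

test_that("backprop matches finite differences through the full stack", {
  m <- tiny_net()
  px <- tiny_image()
  loss_of <- function(fwd) {
    p <- softmax_scores(m, fwd$feats)
    -log(p[2])
  }
  fwd <- forward_pass(m, px)
  p <- softmax_scores(m, fwd$feats)
  dl <- p
  dl[2] <- dl[2] - 1
  bwd <- backward_pass(m, fwd, drop(m$softmax$W %*% dl),
                       want_weights = TRUE)
  eps <- 1e-5
  set.seed(8)
  for (rep in 1:6) {
    l <- sample(1:2, 1)
    idx <- sample(length(m$layers[[l]]$W), 1)
    mp <- m; mp$layers[[l]]$W[idx] <- mp$layers[[l]]$W[idx] + eps
    mm <- m; mm$layers[[l]]$W[idx] <- mm$layers[[l]]$W[idx] - eps
    fd <- (loss_of(forward_pass(mp, px)) -
             loss_of(forward_pass(mm, px))) / (2 * eps)
    expect_equal(bwd$dW[[l]][idx], fd, tolerance = 1e-5)
  }
  # activity gradients via the perturbation hook
  for (l in 1:2) {
    k <- 2
    up <- forward_pass(m, px, perturb = list(layer = l, map = k,
                                             delta = eps))
    dn <- forward_pass(m, px, perturb = list(layer = l, map = k,
                                             delta = -eps))
    fd <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_equal(sum(bwd$d_act[[l]][, , k]), fd, tolerance = 1e-4)
  }
})

test_that("fixture training is deterministic and reaches its floor", {
  pop <- make_grating_population(orientations = c(0, 60, 120),
                                 colors = c("red", "green"), reps = 4,
                                 size = 16, seed = 5)
  m1 <- train_fixture_network(pop, n_maps = c(4, 6, 6, 8), pool_after = 2,
                              epochs = 6, accuracy_floor = 0, seed = 9)
  m2 <- train_fixture_network(pop, n_maps = c(4, 6, 6, 8), pool_after = 2,
                              epochs = 6, accuracy_floor = 0, seed = 9)
  expect_equal(m1$train_history$loss, m2$train_history$loss,
               tolerance = 1e-10)
  expect_identical(m1$train_history$holdout_accuracy,
                   m2$train_history$holdout_accuracy)
  # learning happened
  expect_lt(m1$train_history$loss[6], m1$train_history$loss[1])
  expect_error(train_fixture_network(pop, n_maps = c(4, 6, 6, 8),
                                     pool_after = 2, epochs = 1,
                                     accuracy_floor = 0.999, seed = 9),
               "training failed")
})

test_that("layer means are positive and scale with input amplitude", {
  m <- tiny_net()
  items <- lapply(1:3, function(i) tiny_image(i))
  m1 <- compute_layer_means(m, items)
  expect_true(all(m1$layer_means > 0))
  expect_true(all(is.finite(m1$layer_means)))
  # the zero-bias rectified stack is positively homogeneous: doubling the
  # input doubles the mean activity at every layer
  m2 <- compute_layer_means(m, lapply(items, function(x) 2 * x))
  expect_equal(m2$layer_means, 2 * m1$layer_means, tolerance = 1e-10)
})

test_that("readout banks fit and score sensibly", {
  pop <- make_grating_population(orientations = c(0, 60, 120),
                                 reps = 3, size = 16, seed = 5)
  m <- train_fixture_network(pop, n_maps = c(4, 6, 6, 8), pool_after = 2,
                             epochs = 6, accuracy_floor = 0, seed = 9)
  m <- attach_binary_readouts(m, c(0, 60, 120), pop)
  expect_length(m$binary_readouts, 3)
  X <- pooled_features(m, pop$items)
  for (cond in c(0, 60, 120)) {
    scores <- apply(X, 1, function(f) binary_score(m, f, cond))
    acc <- mean((scores > 0.5) == (pop$orientation == cond))
    expect_gt(acc, 0.5)
  }
  m <- attach_color_readout(m, pop)
  p <- color_scores(m, X[1, ])
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_length(p, 5)
  pred <- apply(X, 1, function(f) names(which.max(color_scores(m, f))))
  expect_gt(mean(pred == pop$color), 1 / 5)
})
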