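manual_set <- function(items, positive, condition = 40) {
  structure(list(items = items, positive = positive, condition = condition),
            class = "stimulus_set")
}

test_that("detection outcomes follow the rate definitions", {
  m <- conv_net(8, n_maps = c(4, 6), pool_after = 1, n_classes = 3,
                seed = 4)
  set.seed(2)
  items <- lapply(1:8, function(i)
    image_stimulus(array(runif(8 * 8 * 3), c(8, 8, 3)),
                   data.frame(orientation = 40, color = "red",
                              quadrant = NA_integer_)))
  set <- manual_set(items, rep(c(TRUE, FALSE), 4))
  # constant-positive readout: TP = 1, TN = 0, performance = 0.5
  m$binary_readouts[["40"]] <- list(b = 10, w = rep(0, 6), condition = 40)
  out <- evaluate_detection(m, set)
  expect_equal(out$TP, 1)
  expect_equal(out$TN, 0)
  expect_equal(out$performance, 0.5)
  expect_equal(out$TP + out$FN, 1)
  expect_equal(out$FP + out$TN, 1)
  # unbalanced sets warn but still report per-class rates
  unb <- manual_set(items[1:6], c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_warning(out2 <- evaluate_detection(m, unb), "not balanced")
  expect_equal(out2$TP, 1)
})

test_that("SDT metrics reproduce the closed-form values", {
  m <- sdt_metrics(0.5, 0.5)
  expect_equal(m$c, 0)
  expect_equal(m$dprime, 0)
  # qnorm(0.8413) is almost exactly +1, qnorm(0.1587) almost exactly -1
  m2 <- sdt_metrics(0.8413, 0.1587)
  expect_equal(m2$dprime, 2, tolerance = 1e-3)
  expect_equal(m2$c, 0, tolerance = 1e-3)
  # clipping keeps extreme rates finite: both terms become qnorm(0.99)
  m3 <- sdt_metrics(0.999, 0.001)
  expect_true(m3$clipped_TP && m3$clipped_FP)
  expect_equal(m3$dprime, 2 * qnorm(0.99), tolerance = 1e-10)
  expect_equal(m3$c, 0, tolerance = 1e-10)
  m4 <- sdt_metrics(1, 0)
  expect_true(is.finite(m4$dprime) && is.finite(m4$c))
  expect_error(sdt_metrics(1.2, 0), "rates")
  # asymmetric default leaves TP = 0 unclipped; the symmetric flag floors
  # it so degenerate detectors stay finite
  expect_equal(sdt_metrics(0, 0.5)$dprime, -Inf)
  m5 <- sdt_metrics(0, 0.5, symmetric = TRUE)
  expect_true(is.finite(m5$dprime) && is.finite(m5$c))
  expect_equal(m5$dprime, qnorm(0.01) - qnorm(0.5), tolerance = 1e-12)
})

test_that("SDT symmetries hold across the rate range", {
  for (tp in seq(0.05, 0.95, by = 0.15)) {
    expect_equal(sdt_metrics(tp, 1 - tp)$c, 0, tolerance = 1e-12)
    a <- sdt_metrics(tp, 0.3)
    b <- sdt_metrics(0.3, tp)
    if (!a$clipped_FP && !b$clipped_FP)
      expect_equal(a$dprime, -b$dprime, tolerance = 1e-12)
  }
})

test_that("ROC sweeps hit the extremes and are monotone", {
  m <- conv_net(8, n_maps = c(4, 6), pool_after = 1, n_classes = 3,
                seed = 4)
  set.seed(3)
  m$binary_readouts[["40"]] <- list(b = 0.2, w = rnorm(6), condition = 40)
  items <- lapply(1:10, function(i)
    image_stimulus(array(runif(8 * 8 * 3), c(8, 8, 3)),
                   data.frame(orientation = 40, color = "red",
                              quadrant = NA_integer_)))
  set <- manual_set(items, rep(c(TRUE, FALSE), 5))
  roc <- roc_threshold_sweep(m, set, thresholds = c(-1, 0.3, 0.6, 2))
  expect_equal(roc$TP[1], 1)
  expect_equal(roc$FP[1], 1)
  expect_equal(roc$TP[4], 0)
  expect_equal(roc$FP[4], 0)
  expect_true(all(diff(roc$TP) <= 0))
  expect_true(all(diff(roc$FP) <= 0))
  # each sweep point equals rates computed directly from the scores; a
  # strictly monotone transform of scores and thresholds together leaves
  # these decisions (and hence the curve) unchanged
  scores <- vapply(set$items, function(im)
    binary_score(m, forward_pass(m, im)$feats, 40), 0)
  for (i in 2:3) {
    th <- c(-1, 0.3, 0.6, 2)[i]
    expect_equal(roc$TP[i], mean(scores[set$positive] > th))
    expect_equal(roc$FP[i], mean(scores[!set$positive] > th))
    dec_raw <- scores > th
    dec_tr <- qlogis(scores) > qlogis(th)
    expect_identical(dec_raw, dec_tr)
  }
})

test_that("beta matching picks the nearest sweep sample with low-beta
           ties", {
  sweep <- data.frame(beta = c(0, 0.15), FP = c(0.1, 0.2),
                      TP = c(0.2, 0.6))
  # hand check: distances to (0.19, 0.55) are 0.362 and 0.051
  expect_equal(match_beta_to_point(sweep, c(0.19, 0.55)), 0.15)
  # a point exactly on a sample returns that sample's beta
  expect_equal(match_beta_to_point(sweep, c(0.1, 0.2)), 0)
  # exactly equidistant point -> smaller beta
  sym <- data.frame(beta = c(0.3, 0.6), FP = c(0, 2), TP = c(0.5, 0.5))
  expect_equal(match_beta_to_point(sym, c(1, 0.5)), 0.3)
  expect_error(match_beta_to_point(sweep[0, ], c(0, 0)), "non-empty")
})

test_that("behavioral point CSVs round-trip", {
  p <- tempfile(fileext = ".csv")
  df <- data.frame(label = c("cued", "uncued"), FP = c(0.1, 0.05),
                   TP = c(0.8, 0.6))
  write.csv(df, p, row.names = FALSE)
  expect_equal(read_behavioral_points(p), df)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_behavioral_points(bad), "columns")
})

test_that("quadrant detection stimuli respect the attended quadrant", {
  gen <- quadrant_detection_recipe(40, quadrant = 2, canvas_size = 32)
  set <- build_balanced_detection_set(40, 12, gen, seed = 3)
  for (i in seq_along(set$items)) {
    lab <- set$items[[i]]$labels
    in_quad <- any(lab$orientation == 40 & lab$quadrant == 2)
    expect_equal(in_quad, set$positive[i])
  }
})
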