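test_that("full-field gratings render the stated sinusoid", {
  sp <- grating_spec(0, "red", phase = 0.3, size = 64)
  img <- make_full_field_grating(sp, seed = 1)
  expect_s3_class(img, "image_stimulus")
  # red channel spans the full luminance range, others stay zero
  expect_equal(max(img$pixels[, , 2]), 0)
  expect_equal(max(img$pixels[, , 3]), 0)
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 1)
  expect_lt(min(img$pixels[, , 1]), 0.05)
  expect_gt(max(img$pixels[, , 1]), 0.95)

  # 0 and 90 degrees are transposes of the same luminance pattern
  a <- make_full_field_grating(grating_spec(0, "red", phase = 1, size = 32))
  b <- make_full_field_grating(grating_spec(90, "red", phase = 1, size = 32))
  expect_equal(a$pixels[, , 1], t(b$pixels[, , 1]), tolerance = 1e-12)
})

test_that("grating frequency gives the expected zero-crossing count", {
  # independent analytic count for a 0-degree, 0.025 c/px grating at 224 px
  v <- sin(2 * pi * 0.025 * (0:223))
  v <- v[v != 0] # drop the exact zero at the origin
  analytic <- sum(diff(sign(v)) != 0)
  img <- make_full_field_grating(grating_spec(0, "red", phase = 0,
                                              size = 224))
  col1 <- img$pixels[, 1, 1] - 0.5
  rendered <- sum(diff(sign(col1[col1 != 0])) != 0)
  expect_equal(rendered, analytic)
  expect_equal(analytic, 11)
})

test_that("degradation zeroes exactly the requested pixel count", {
  sp <- grating_spec(40, "green", phase = 0.3, size = 48)
  clean <- make_full_field_grating(sp, degrade_fraction = 0, seed = 9)
  for (frac in c(0.1, 0.37, 0.7)) {
    deg <- make_full_field_grating(sp, degrade_fraction = frac, seed = 9)
    zeroed <- sum(deg$pixels[, , 2] == 0 & clean$pixels[, , 2] > 0)
    expect_equal(zeroed, floor(frac * 48^2))
    expect_gte(min(deg$pixels), 0)
  }
  # determinism
  d1 <- make_full_field_grating(sp, degrade_fraction = 0.4, seed = 3)
  d2 <- make_full_field_grating(sp, degrade_fraction = 0.4, seed = 3)
  expect_identical(d1$pixels, d2$pixels)
})

test_that("grating validation rejects bad inputs", {
  expect_error(grating_spec(200, "red"), "orientation")
  expect_error(grating_spec(0, "cyan"), "color")
  expect_error(grating_spec(0, "red", size = 4), "size")
  sp <- grating_spec(0, "red")
  expect_error(make_full_field_grating(sp, degrade_fraction = 0.8),
               "degrade_fraction")
})

test_that("two-grating images occupy exactly two quadrants", {
  img <- make_two_grating_image(grating_spec(0, "red"),
                                grating_spec(40, "blue"),
                                canvas_size = 64, seed = 4)
  occupied <- vapply(1:4, function(q)
    any(img$pixels[fsgain:::quadrant_rows(q, 64),
                   fsgain:::quadrant_cols(q, 64), ] > 0), TRUE)
  expect_equal(sum(occupied), 2)
  expect_setequal(img$labels$quadrant, which(occupied))
  # half-canvas patches and determinism
  img2 <- make_two_grating_image(grating_spec(0, "red"),
                                 grating_spec(40, "blue"),
                                 canvas_size = 64, seed = 4)
  expect_identical(img$pixels, img2$pixels)
  expect_identical(img$labels$quadrant, img2$labels$quadrant)
  expect_error(make_two_grating_image(grating_spec(0, "red"),
                                      grating_spec(0, "blue"), 64),
               "orientations")
  expect_error(make_two_grating_image(grating_spec(0, "red"),
                                      grating_spec(20, "red"), 64),
               "colors")
})

test_that("merging halves and sums pixel values", {
  a <- make_full_field_grating(grating_spec(0, "red", phase = 0, size = 16))
  b <- make_full_field_grating(grating_spec(40, "blue", phase = 1,
                                            size = 16))
  m <- make_merged_image(a, b)
  expect_equal(m$pixels, (a$pixels + b$pixels) / 2)
  # commutative and idempotent
  expect_equal(make_merged_image(b, a)$pixels, m$pixels)
  expect_equal(make_merged_image(a, a)$pixels, a$pixels)
  # all-zero partner halves intensity
  z <- image_stimulus(array(0, c(16, 16, 3)),
                      data.frame(orientation = 90, color = "green",
                                 quadrant = NA_integer_))
  expect_equal(make_merged_image(a, z)$pixels, a$pixels / 2)
  small <- make_full_field_grating(grating_spec(40, "blue", size = 8))
  expect_error(make_merged_image(a, small), "dimensions")
})

test_that("array images tile downscaled inputs without gaps", {
  specs <- list(grating_spec(0, "red", phase = 0.5, size = 64),
                grating_spec(40, "blue", phase = 0.5, size = 64),
                grating_spec(80, "green", phase = 0.5, size = 64),
                grating_spec(120, "orange", phase = 0.5, size = 64))
  imgs <- lapply(specs, make_full_field_grating)
  arr <- make_array_image(imgs, canvas_size = 64)
  expect_equal(dim(arr$pixels), c(64, 64, 3))
  expect_equal(nrow(arr$labels), 4)
  # quadrant k equals an independent 2x2 block mean of input k
  for (q in 1:4) {
    tile <- arr$pixels[fsgain:::quadrant_rows(q, 64),
                       fsgain:::quadrant_cols(q, 64), 1]
    px <- imgs[[q]]$pixels[, , 1]
    oracle <- matrix(0, 32, 32)
    for (i in 1:32) for (j in 1:32)
      oracle[i, j] <- mean(px[2 * i - 1:0, 2 * j - 1:0])
    expect_equal(tile, oracle, tolerance = 1e-12)
  }
  # constants are preserved by tiling
  const <- lapply(c(0, 40, 80, 120), function(o)
    image_stimulus(array(0.4, c(64, 64, 3)),
                   data.frame(orientation = o, color = "red",
                              quadrant = NA_integer_)))
  expect_equal(unique(as.vector(make_array_image(const, 64)$pixels)), 0.4)
  expect_error(make_array_image(imgs[c(1, 1, 2, 3)], 64), "distinct")
})

test_that("balanced detection sets have exact balance and determinism", {
  gen <- two_grating_recipe(40, canvas_size = 32)
  s1 <- build_balanced_detection_set(40, 20, gen, seed = 7)
  expect_equal(sum(s1$positive), 10)
  expect_equal(sum(!s1$positive), 10)
  s2 <- build_balanced_detection_set(40, 20, gen, seed = 7)
  expect_identical(s1$positive, s2$positive)
  expect_identical(s1$items[[3]]$pixels, s2$items[[3]]$pixels)
  expect_error(build_balanced_detection_set(40, 21, gen, 1), "even")
  # positives contain the condition; negatives never do
  for (i in seq_along(s1$items)) {
    has <- 40 %in% s1$items[[i]]$labels$orientation
    expect_equal(has, s1$positive[i])
  }
})

test_that("generated pixels stay in range under all compositions", {
  set.seed(1)
  for (rep in 1:5) {
    o <- sample(default_orientations(), 4)
    cols <- sample(names(grating_palette()), 4)
    imgs <- lapply(1:4, function(i)
      make_full_field_grating(grating_spec(o[i], cols[i], size = 32),
                              degrade_fraction = runif(1, 0, 0.7)))
    m <- make_merged_image(imgs[[1]], imgs[[2]])
    a <- make_array_image(imgs, 32)
    for (px in list(m$pixels, a$pixels)) {
      expect_gte(min(px), 0)
      expect_lte(max(px), 1)
    }
  }
})
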