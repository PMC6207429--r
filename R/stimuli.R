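#' @useDynLib fsgain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor lm median qnorm quantile rnorm runif sd t.test
#' @importFrom utils head write.csv
NULL

#' Color palette for grating stimuli
#'
#' RGB triplets (rows in \[0,1\]) for the five named grating colors. The
#' palette is fixed so that train and test stimuli always share the same
#' color rendering.
#'
#' @return A named list of length-3 numeric RGB vectors.
#' @export
grating_palette <- function() {
  list(
    red    = c(1, 0, 0),
    blue   = c(0, 0, 1),
    green  = c(0, 1, 0),
    orange = c(1, 0.5, 0),
    purple = c(0.5, 0, 0.5)
  )
}

#' The nine standard grating orientations
#'
#' @return Orientations 0, 20, ..., 160 degrees.
#' @export
default_orientations <- function() seq(0, 160, by = 20)

#' Specify an oriented grating
#'
#' @param orientation Orientation in degrees, in \[0, 180).
#' @param color One of `names(grating_palette())`.
#' @param frequency Spatial frequency in cycles per pixel (default 0.025).
#' @param phase Phase in radians, or `NULL` to randomize per rendered image.
#' @param size Side length of the (square) rendered patch in pixels.
#'
#' @return A `grating_spec` object.
#' @export
grating_spec <- function(orientation, color, frequency = 0.025, phase = NULL,
                         size = 64) {
  if (!is.numeric(orientation) || orientation < 0 || orientation >= 180)
    stop("orientation must be in [0, 180)")
  if (!color %in% names(grating_palette()))
    stop("unknown color '", color, "'; see grating_palette()")
  if (frequency <= 0) stop("frequency must be positive")
  if (size < 8) stop("size must be at least 8 pixels")
  structure(
    list(orientation = orientation, color = color, frequency = frequency,
         phase = phase, size = as.integer(size)),
    class = "grating_spec"
  )
}

#' Construct an image stimulus
#'
#' @param pixels `H x W x 3` numeric array with values in \[0,1\].
#' @param labels Data frame with columns `orientation`, `color`, `quadrant`
#'   (`NA` quadrant means full-field).
#' @return An `image_stimulus` object.
#' @export
image_stimulus <- function(pixels, labels) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, labels = labels), class = "image_stimulus")
}

#' @export
print.image_stimulus <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stimulus %dx%d, %d label(s)>\n", d[1], d[2],
              nrow(x$labels)))
  print(x$labels)
  invisible(x)
}

# Luminance pattern varies along (cos(theta), sin(theta)) in (row, col)
# space, so a 0-degree grating varies down the rows and 0 vs 90 degrees are
# transposes of each other.
grating_luminance <- function(orientation, frequency, phase, size) {
  th <- orientation * pi / 180
  i <- seq_len(size) - 1
  j <- seq_len(size) - 1
  arg <- outer(i * cos(th), j * sin(th), `+`)
  0.5 + 0.5 * sin(2 * pi * frequency * arg + phase)
}

# Zero out contiguous square blocks until exactly `target` unique pixels are
# dark; the final block is trimmed (column-major within the block) to land
# on the exact count.
degrade_mask <- function(size, target, block_range = c(4, 16)) {
  mask <- matrix(FALSE, size, size)
  count <- 0L
  sides <- seq(block_range[1], block_range[2])
  while (count < target) {
    side <- if (length(sides) == 1) sides else sample(sides, 1)
    i0 <- sample.int(size, 1)
    j0 <- sample.int(size, 1)
    ii <- i0:min(size, i0 + side - 1)
    jj <- j0:min(size, j0 + side - 1)
    block <- which(!mask[ii, jj, drop = FALSE])
    if (!length(block)) next
    need <- target - count
    if (length(block) > need) block <- block[seq_len(need)]
    sub <- mask[ii, jj, drop = FALSE]
    sub[block] <- TRUE
    mask[ii, jj] <- sub
    count <- count + length(block)
  }
  mask
}

#' Render a full-field oriented grating
#'
#' Renders a sinusoidal luminance grating in one of five colors against
#' black, optionally degraded by zeroing contiguous pixel blocks (used to
#' diversify classifier training images).
#'
#' @param spec A [grating_spec()].
#' @param degrade_fraction Fraction of pixels to zero, in \[0, 0.7\].
#' @param seed Integer seed controlling phase randomization and block
#'   placement; the output is deterministic for a fixed seed.
#'
#' @return An [image_stimulus()] with a single full-field label.
#' @export
make_full_field_grating <- function(spec, degrade_fraction = 0, seed = NULL) {
  stopifnot(inherits(spec, "grating_spec"))
  if (degrade_fraction < 0 || degrade_fraction > 0.7)
    stop("degrade_fraction must be in [0, 0.7]")
  if (!is.null(seed)) set.seed(seed)
  phase <- if (is.null(spec$phase)) runif(1, 0, 2 * pi) else spec$phase
  lum <- grating_luminance(spec$orientation, spec$frequency, phase, spec$size)
  rgb <- grating_palette()[[spec$color]]
  px <- array(0, c(spec$size, spec$size, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch] * lum
  target <- floor(degrade_fraction * spec$size^2)
  if (target > 0) {
    mask <- degrade_mask(spec$size, target)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- 0
      px[, , ch] <- plane
    }
  }
  image_stimulus(px, data.frame(orientation = spec$orientation,
                                color = spec$color, quadrant = NA_integer_,
                                stringsAsFactors = FALSE))
}

quadrant_rows <- function(q, size) if (q %in% c(1, 2)) 1:(size / 2) else (size / 2 + 1):size
quadrant_cols <- function(q, size) if (q %in% c(1, 3)) 1:(size / 2) else (size / 2 + 1):size

#' Compose a two-grating quadrant test image
#'
#' Renders two gratings at half canvas resolution and places them in two
#' distinct randomly chosen quadrants; the remaining two quadrants stay
#' black. Quadrants are numbered 1 (top-left), 2 (top-right), 3
#' (bottom-left), 4 (bottom-right).
#'
#' @param specA,specB [grating_spec()]s with different orientations and
#'   colors; their `size` field is ignored in favor of `canvas_size / 2`.
#' @param canvas_size Even side length of the output canvas in pixels.
#' @param seed Integer seed (quadrant choice and phases).
#'
#' @return An [image_stimulus()] with one label row per grating.
#' @export
make_two_grating_image <- function(specA, specB, canvas_size = 64,
                                   seed = NULL) {
  if (specA$orientation == specB$orientation)
    stop("the two gratings must have different orientations")
  if (specA$color == specB$color)
    stop("the two gratings must have different colors")
  if (canvas_size %% 2 != 0) stop("canvas_size must be even")
  if (!is.null(seed)) set.seed(seed)
  quads <- sample(1:4, 2)
  half <- canvas_size / 2
  px <- array(0, c(canvas_size, canvas_size, 3))
  specs <- list(specA, specB)
  for (t in 1:2) {
    sp <- specs[[t]]
    sp$size <- half
    patch <- make_full_field_grating(
      grating_spec(sp$orientation, sp$color, sp$frequency, sp$phase, half))
    px[quadrant_rows(quads[t], canvas_size),
       quadrant_cols(quads[t], canvas_size), ] <- patch$pixels
  }
  image_stimulus(px, data.frame(
    orientation = c(specA$orientation, specB$orientation),
    color = c(specA$color, specB$color),
    quadrant = quads, stringsAsFactors = FALSE))
}

#' Merge two stimuli transparently
#'
#' Pixel values of the two images are each divided by two and summed;
#' labels are concatenated.
#'
#' @param imageA,imageB [image_stimulus()] objects of identical dimensions.
#' @return The merged [image_stimulus()].
#' @export
make_merged_image <- function(imageA, imageB) {
  if (!identical(dim(imageA$pixels), dim(imageB$pixels)))
    stop("images must have identical dimensions")
  image_stimulus((imageA$pixels + imageB$pixels) / 2,
                 unique(rbind(imageA$labels, imageB$labels)))
}

# Block-mean downscale by an integer factor, per channel.
block_mean_downscale <- function(px, factor) {
  d <- dim(px)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  ho <- d[1] / factor; wo <- d[2] / factor
  out <- array(0, c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) {
    m <- px[, , ch]
    # average factor x factor blocks via two matrix reshapes
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = ho)
    m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = wo))
    out[, , ch] <- m
  }
  out
}

#' Tile four stimuli on a 2x2 grid
#'
#' Each input is block-mean downscaled to half the canvas resolution and
#' placed in quadrants 1-4 in order. Inputs must carry four distinct
#' orientation-color classes.
#'
#' @param images List of exactly four [image_stimulus()] objects.
#' @param canvas_size Even side length of the output canvas.
#' @return An [image_stimulus()] whose labels union the inputs' labels with
#'   quadrant indices.
#' @export
make_array_image <- function(images, canvas_size = 64) {
  if (length(images) != 4) stop("exactly four images are required")
  classes <- vapply(images, function(im)
    paste(im$labels$orientation[1], im$labels$color[1]), "")
  if (anyDuplicated(classes)) stop("the four images must have distinct classes")
  half <- canvas_size / 2
  px <- array(0, c(canvas_size, canvas_size, 3))
  labels <- NULL
  for (q in 1:4) {
    im <- images[[q]]
    factor <- dim(im$pixels)[1] / half
    if (factor != round(factor))
      stop("input size must be an integer multiple of canvas_size / 2")
    small <- if (factor == 1) im$pixels else block_mean_downscale(im$pixels, factor)
    px[quadrant_rows(q, canvas_size), quadrant_cols(q, canvas_size), ] <- small
    lab <- im$labels
    lab$quadrant <- q
    labels <- rbind(labels, lab)
  }
  image_stimulus(px, labels)
}

#' Build a balanced detection test/training set
#'
#' Draws `n/2` stimuli that contain the searched-for condition and `n/2`
#' that do not, in a seed-determined shuffled order.
#'
#' @param condition Label of the searched-for feature (e.g. an orientation).
#' @param n Even total number of stimuli.
#' @param generator Function `(positive, seed) -> image_stimulus` producing
#'   a stimulus that does or does not contain `condition`; see
#'   [two_grating_recipe()] and [full_field_recipe()].
#' @param seed Integer seed; the label sequence and every item are
#'   deterministic given the seed.
#'
#' @return A `stimulus_set`: list with `items`, logical `positive`,
#'   `condition`.
#' @export
build_balanced_detection_set <- function(condition, n, generator, seed = 1) {
  if (n %% 2 != 0) stop("n must be even")
  set.seed(seed)
  positive <- sample(rep(c(TRUE, FALSE), each = n / 2))
  item_seeds <- sample.int(.Machine$integer.max - 1L, n)
  items <- lapply(seq_len(n), function(i) generator(positive[i], item_seeds[i]))
  structure(list(items = items, positive = positive, condition = condition),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d items, %d positive, condition %s>\n",
              length(x$items), sum(x$positive), format(x$condition)))
  invisible(x)
}

#' Recipe: two-grating quadrant test images for orientation detection
#'
#' Positive draws place the searched-for orientation in one of the two
#' gratings; negative draws use two other orientations. Orientations and
#' colors of the two gratings always differ.
#'
#' @param condition Searched-for orientation in degrees.
#' @param orientations Pool of orientations (default 0,20,...,160).
#' @param colors Pool of color names.
#' @param canvas_size Canvas side length in pixels.
#' @return A generator function for [build_balanced_detection_set()].
#' @export
two_grating_recipe <- function(condition,
                               orientations = default_orientations(),
                               colors = names(grating_palette()),
                               canvas_size = 64) {
  others <- setdiff(orientations, condition)
  function(positive, seed) {
    set.seed(seed)
    oris <- if (positive) c(condition, sample(others, 1)) else sample(others, 2)
    cols <- sample(colors, 2)
    make_two_grating_image(grating_spec(oris[1], cols[1]),
                           grating_spec(oris[2], cols[2]),
                           canvas_size = canvas_size)
  }
}

#' Recipe: full-field gratings for detection training sets
#'
#' Positive draws render the searched-for orientation, negatives one of the
#' remaining orientations; color is random and images are randomly degraded
#' by zeroed pixel blocks covering 0-70% of the image.
#'
#' @inheritParams two_grating_recipe
#' @param size Image side length in pixels.
#' @param degrade_range Range of the uniform degradation fraction.
#' @return A generator function for [build_balanced_detection_set()].
#' @export
full_field_recipe <- function(condition,
                              orientations = default_orientations(),
                              colors = names(grating_palette()),
                              size = 64, degrade_range = c(0, 0.7)) {
  others <- setdiff(orientations, condition)
  function(positive, seed) {
    set.seed(seed)
    ori <- if (positive) condition else sample(others, 1)
    col <- sample(colors, 1)
    dg <- runif(1, degrade_range[1], degrade_range[2])
    make_full_field_grating(grating_spec(ori, col, size = size),
                            degrade_fraction = dg)
  }
}

#' Generate a labelled grating training population
#'
#' Full factorial orientations x colors, `reps` images per class with random
#' phase and (optionally) random block degradation. This is the population
#' used both to train the fixture classifier and to measure tuning.
#'
#' @param orientations,colors Class factors.
#' @param reps Images per orientation-color class.
#' @param size Image side length in pixels.
#' @param seed Integer seed.
#' @param degrade Logical; apply random 0-70% block degradation.
#' @return A list with `items` (stimuli), `orientation`, `color`, and
#'   integer `class` (orientation-major order).
#' @export
make_grating_population <- function(orientations = default_orientations(),
                                    colors = names(grating_palette()),
                                    reps = 2, size = 64, seed = 1,
                                    degrade = TRUE) {
  set.seed(seed)
  grid <- expand.grid(color = colors, orientation = orientations,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[rep(seq_len(nrow(grid)), each = reps), ]
  n <- nrow(grid)
  dg <- if (degrade) runif(n, 0, 0.7) else rep(0, n)
  items <- lapply(seq_len(n), function(i)
    make_full_field_grating(grating_spec(grid$orientation[i], grid$color[i],
                                         size = size),
                            degrade_fraction = dg[i]))
  class_id <- as.integer(factor(paste(grid$orientation, grid$color),
                                levels = unique(paste(grid$orientation,
                                                      grid$color))))
  list(items = items, orientation = grid$orientation, color = grid$color,
       class = class_id, n_classes = length(unique(class_id)))
}

#' Write a stimulus set to PNG files with a JSON-lines manifest
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_stimulus_set <- function(set, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write stimuli")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (i in seq_along(set$items)) {
    fn <- sprintf("stim_%04d.png", i)
    png::writePNG(set$items[[i]]$pixels, file.path(dir, fn))
    rec <- list(filename = fn, positive = set$positive[i],
                condition = set$condition,
                labels = set$items[[i]]$labels)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(manifest)
}
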