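# Per-layer spatially averaged, negated error gradients for one image:
# -(1/HW) sum_ij dE/dx_ij^lk, one value per feature map.
image_activity_gradients <- function(model, fwd, d_feats) {
  bwd <- backward_pass(model, fwd, d_feats)
  lapply(bwd$d_act, function(g) -apply(g, 3, mean))
}

#' Category gradient values for a set of images
#'
#' Backpropagates the softmax readout's cross-entropy error (against the
#' given target classes) to every feature map, averages the per-unit
#' partial derivatives over space and images, and negates, so that a
#' positive gradient value means raising the map's activity moves the
#' network toward the target classification.
#'
#' @param model A `conv_net` with its softmax readout.
#' @param items List of stimuli (all nominally containing the condition of
#'   interest).
#' @param target_class Integer class target(s); length 1 or one per image.
#' @return List (per layer) of per-map gradient values: one table slice.
#' @export
compute_category_gradients <- function(model, items, target_class) {
  if (!length(items)) stop("at least one image is required")
  target_class <- rep_len(target_class, length(items))
  acc <- NULL
  for (i in seq_along(items)) {
    fwd <- forward_pass(model, items[[i]])
    p <- softmax_scores(model, fwd$feats)
    dlogit <- p
    dlogit[target_class[i]] <- dlogit[target_class[i]] - 1
    d_feats <- drop(model$softmax$W %*% dlogit)
    g <- image_activity_gradients(model, fwd, d_feats)
    acc <- if (is.null(acc)) g else Map(`+`, acc, g)
  }
  lapply(acc, function(v) v / length(items))
}

#' Category gradient table over orientations
#'
#' Assembles [compute_category_gradients()] slices into a `value_table`
#' with one column per orientation. For each orientation the images of
#' that orientation are used with their own orientation-by-color class as
#' the softmax target, so values are color-averaged.
#'
#' @param model A trained `conv_net` (with `$classes` metadata).
#' @param population A [make_grating_population()] result.
#' @param conditions Orientations to include (default: all present).
#' @return A `value_table` (type `"gradient"`, task `category_softmax`).
#' @export
category_gradient_table <- function(model, population,
                                    conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(population$orientation)
  slices <- lapply(conditions, function(cc) {
    idx <- which(population$orientation == cc)
    compute_category_gradients(model, population$items[idx],
                               population$class[idx])
  })
  values <- lapply(seq_along(model$layers), function(l)
    do.call(cbind, lapply(slices, `[[`, l)))
  tab <- new_value_table(values, conditions, "gradient")
  tab$task <- "category_softmax"
  tab
}

#' Task gradient values for binary-detection or color readouts
#'
#' Gradient values represent the averaged activity change that would
#' improve task performance. Images the readout already classifies
#' correctly contribute zero (they are masked out before averaging);
#' misclassified images contribute their negated error gradient.
#'
#' @param model A `conv_net` with the relevant readout attached.
#' @param sets Named list (by condition) of `stimulus_set`s, e.g. from
#'   [build_balanced_detection_set()].
#' @param task `"binary"` (detection cross-entropy for the condition's
#'   detector) or `"color"` (5-way color cross-entropy, target = the color
#'   of the grating with the condition's orientation).
#' @return A `value_table` (type `"gradient"`) with the task recorded in
#'   `$task`. Warns if every image was already classified correctly.
#' @export
compute_task_gradients <- function(model, sets, task = c("binary", "color")) {
  task <- match.arg(task)
  conditions <- as.numeric(names(sets))
  n_layers <- length(model$layers)
  any_error <- FALSE
  slices <- lapply(seq_along(sets), function(s) {
    set <- sets[[s]]
    cond <- conditions[s]
    acc <- lapply(seq_len(n_layers), function(l)
      numeric(dim(model$layers[[l]]$W)[4]))
    n_used <- 0L
    for (i in seq_along(set$items)) {
      im <- set$items[[i]]
      if (task == "color" && !cond %in% im$labels$orientation) next
      n_used <- n_used + 1L
      fwd <- forward_pass(model, im)
      if (task == "binary") {
        p <- binary_score(model, fwd$feats, cond)
        y <- set$positive[i]
        if ((p > 0.5) == y) next
        rd <- model$binary_readouts[[as.character(cond)]]
        d_feats <- (p - as.numeric(y)) * rd$w
      } else {
        p <- color_scores(model, fwd$feats)
        target <- im$labels$color[match(cond, im$labels$orientation)]
        if (names(which.max(p)) == target) next
        dlogit <- p
        dlogit[target] <- dlogit[target] - 1
        d_feats <- drop(model$color_readout$W %*% dlogit)
      }
      any_error <<- TRUE
      acc <- Map(`+`, acc, image_activity_gradients(model, fwd, d_feats))
    }
    lapply(acc, function(v) v / max(n_used, 1L))
  })
  if (!any_error)
    warning("all images classified correctly: gradient table is all zero")
  values <- lapply(seq_len(n_layers), function(l)
    do.call(cbind, lapply(slices, `[[`, l)))
  tab <- new_value_table(values, conditions, "gradient")
  tab$task <- if (task == "binary") "binary_detection" else
    "color_classification"
  tab
}

#' Normalize gradient values by the layer maximum
#'
#' Each layer/condition column is divided by its maximum absolute value so
#' that normalized gradients are of the same order of magnitude as tuning
#' values (max |g| = 1 per layer). All-zero columns are left unchanged and
#' flagged in `$degenerate`.
#'
#' @param table A gradient `value_table`.
#' @return The normalized table (idempotent).
#' @export
normalize_gradients <- function(table) {
  degenerate <- FALSE
  table$values <- lapply(table$values, function(v) {
    for (j in seq_len(ncol(v))) {
      mx <- max(abs(v[, j]))
      if (mx > 0) v[, j] <- v[, j] / mx else degenerate <<- TRUE
    }
    v
  })
  table$normalized <- TRUE
  table$degenerate <- degenerate
  table
}

#' Correlate tuning values with gradient values
#'
#' Pearson correlation across conditions between each feature map's tuning
#' curve and its gradient curve, averaged per layer, with a shuffled
#' control that pairs each feature map's tuning values with a random other
#' feature map's gradient values.
#'
#' @param tuning,grads `value_table`s over the same conditions.
#' @param n_shuffles Number of shuffled pairings.
#' @param seed Integer seed.
#' @return Data frame per layer: `mean_r`, `sem_r`, `n_maps`,
#'   `shuffled_mean`, `shuffled_sem`.
#' @export
correlate_tuning_gradients <- function(tuning, grads, n_shuffles = 100,
                                       seed = 1) {
  stopifnot(length(tuning$values) == length(grads$values))
  common <- intersect(tuning$conditions, grads$conditions)
  if (length(common) < 2)
    stop("tuning and gradient tables share fewer than two conditions")
  ti <- match(common, tuning$conditions)
  gi <- match(common, grads$conditions)
  tuning$values <- lapply(tuning$values, function(v) v[, ti, drop = FALSE])
  grads$values <- lapply(grads$values, function(v) v[, gi, drop = FALSE])
  set.seed(seed)
  map_cor <- function(f, g) {
    ok <- apply(f, 1, sd) > 0 & apply(g, 1, sd) > 0
    r <- rep(NA_real_, nrow(f))
    r[ok] <- vapply(which(ok), function(k) cor(f[k, ], g[k, ]), 0)
    r
  }
  out <- lapply(seq_along(tuning$values), function(l) {
    f <- tuning$values[[l]]
    g <- grads$values[[l]]
    r <- map_cor(f, g)
    shuf <- unlist(lapply(seq_len(n_shuffles), function(s) {
      K <- nrow(f)
      partner <- vapply(seq_len(K), function(k)
        sample(setdiff(seq_len(K), k), 1), 1L)
      map_cor(f, g[partner, , drop = FALSE])
    }))
    data.frame(layer = l,
               mean_r = mean(r, na.rm = TRUE),
               sem_r = sd(r, na.rm = TRUE) / sqrt(sum(!is.na(r))),
               n_maps = sum(!is.na(r)),
               shuffled_mean = mean(shuf, na.rm = TRUE),
               shuffled_sem = sd(shuf, na.rm = TRUE) /
                 sqrt(sum(!is.na(shuf))))
  })
  do.call(rbind, out)
}
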