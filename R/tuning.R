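#' Record spatially averaged activity for an image population
#'
#' Runs the forward pass over a stimulus population and collects, per
#' layer, the `n_images x n_maps` matrix of spatially averaged feature-map
#' activities `r^lk(n)`, with one condition label per image.
#'
#' @param model A `conv_net`.
#' @param items List of stimuli.
#' @param condition Vector of condition labels, one per image (e.g. the
#'   orientation of each grating).
#' @param attention Optional attention field applied during recording.
#' @return An `activity_record`.
#' @export
activity_record <- function(model, items, condition, attention = NULL) {
  stopifnot(length(items) == length(condition))
  n_layers <- length(model$layers)
  rows <- lapply(items, function(im)
    record_spatially_averaged_activity(forward_pass(model, im, attention)))
  activity <- lapply(seq_len(n_layers), function(l)
    do.call(rbind, lapply(rows, `[[`, l)))
  structure(list(activity = activity, condition = condition),
            class = "activity_record")
}

new_value_table <- function(values, conditions, type, dead = NULL) {
  if (is.null(dead))
    dead <- lapply(values, function(v) rep(FALSE, nrow(v)))
  structure(list(values = values, conditions = conditions, type = type,
                 dead = dead), class = "value_table")
}

#' @export
print.value_table <- function(x, ...) {
  cat(sprintf("<value_table (%s): %d layers, %d conditions>\n", x$type,
              length(x$values), length(x$conditions)))
  invisible(x)
}

#' Compute feature-map tuning values
#'
#' For each feature map, the tuning value for condition `c` is the mean
#' activity over images of that condition, minus the grand mean activity,
#' divided by the population standard deviation of the activity over all
#' images. Dead maps (zero variance) are flagged and assigned tuning 0.
#'
#' @param record An [activity_record()].
#' @return A `value_table` (type `"tuning"`) with per-layer `K x C` value
#'   matrices and dead-map flags.
#' @export
compute_tuning_values <- function(record) {
  conds <- unique(record$condition)
  if (length(conds) < 2) stop("at least two conditions are required")
  if (any(table(record$condition) < 2))
    stop("each condition needs at least two images")
  values <- dead <- vector("list", length(record$activity))
  for (l in seq_along(record$activity)) {
    A <- record$activity[[l]]
    n <- nrow(A)
    rbar <- colMeans(A)
    dev <- sweep(A, 2, rbar)
    pop_sd <- sqrt(colMeans(dev^2))
    f <- matrix(vapply(conds, function(cc)
      colMeans(A[record$condition == cc, , drop = FALSE]) - rbar,
      numeric(ncol(A))), nrow = ncol(A))
    f <- sweep(f, 1, pop_sd, "/")
    is_dead <- pop_sd == 0
    f[is_dead, ] <- 0
    values[[l]] <- f
    dead[[l]] <- is_dead
  }
  new_value_table(values, conds, "tuning", dead)
}

#' Tuning quality per feature map
#'
#' Tuning quality is the maximum absolute tuning value of a feature map
#' over conditions.
#'
#' @param table A `value_table`.
#' @return List (per layer) of numeric per-map qualities.
#' @export
tuning_quality <- function(table) {
  lapply(table$values, function(v) apply(abs(v), 1, max))
}

#' Shuffled-control tuning quality
#'
#' Within each layer, permutes the individual image responses across both
#' images and feature maps (preserving the layer's multiset of responses),
#' recomputes tuning, and records the per-map quality. Repeats
#' `n_shuffles` times.
#'
#' @param record An [activity_record()].
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @return List (per layer) of `n_shuffles x n_maps` quality matrices
#'   (zero-row matrices when `n_shuffles = 0`).
#' @export
shuffled_tuning_quality <- function(record, n_shuffles, seed = 1) {
  set.seed(seed)
  single <- length(unique(record$condition)) < 2
  out <- vector("list", length(record$activity))
  for (l in seq_along(record$activity)) {
    A <- record$activity[[l]]
    qs <- matrix(0, n_shuffles, ncol(A))
    if (n_shuffles > 0 && !single) {
      for (s in seq_len(n_shuffles)) {
        shuf <- record
        shuf$activity <- list(matrix(sample(A), nrow(A), ncol(A)))
        qs[s, ] <- tuning_quality(compute_tuning_values(shuf))[[1]]
      }
    }
    out[[l]] <- qs
  }
  out
}

#' Condition preference ordering of a feature map
#'
#' @param table A `value_table`.
#' @param layer,map Indices of the feature map.
#' @return List with `order` (conditions sorted by descending value, ties
#'   broken by ascending condition index), `preferred`, `anti_preferred`.
#' @export
preference_order <- function(table, layer, map) {
  f <- table$values[[layer]][map, ]
  idx <- order(-f, seq_along(f))
  ord <- table$conditions[idx]
  list(order = ord, preferred = ord[1], anti_preferred = ord[length(ord)])
}

#' Flatten a value table to a data frame
#'
#' @param x A `value_table`.
#' @param ... Unused.
#' @return Data frame with columns `layer`, `feature_map`, `condition`,
#'   `value`, `dead`.
#' @export
as.data.frame.value_table <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$values), function(l) {
    v <- x$values[[l]]
    data.frame(layer = l,
               feature_map = rep(seq_len(nrow(v)), times = ncol(v)),
               condition = rep(x$conditions, each = nrow(v)),
               value = as.vector(v),
               dead = rep(x$dead[[l]], times = ncol(v)))
  }))
}
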