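#' Record attention-induced activity ratios on full-field gratings
#'
#' For every attended orientation, applies the configured attention and
#' records spatially averaged feature-map activity in response to every
#' full-field grating, color-averaged per stimulus orientation, divided by
#' the same activity without attention. Maps whose color-averaged baseline
#' falls below `baseline_floor` are excluded (`NA`) and counted.
#'
#' @param model A `conv_net`.
#' @param population A [make_grating_population()] result covering the full
#'   orientation-by-color factorial (typically undegraded, `reps = 1`).
#' @param table `value_table` driving the attention field.
#' @param config An [attention_config()] template; its `attended_condition`
#'   is replaced by each orientation in turn (recording protocol default:
#'   `beta = 0.5`).
#' @param baseline_floor Exclusion threshold for near-zero baselines.
#' @return An `activity_ratio_record`: per layer, `ratios` (array
#'   `maps x attended x stimulus` orientation), `baseline`
#'   (`maps x stimulus`), and `n_excluded`.
#' @export
record_activity_ratios <- function(model, population, table, config,
                                   baseline_floor = 1e-8) {
  orientations <- unique(population$orientation)
  n_layers <- length(model$layers)
  K <- model$n_maps
  base_rec <- activity_record(model, population$items,
                              population$orientation)
  color_avg <- function(A) t(sapply(orientations, function(o)
    colMeans(A[population$orientation == o, , drop = FALSE])))
  baseline <- lapply(base_rec$activity, color_avg) # n_ori x K per layer
  ratios <- lapply(seq_len(n_layers), function(l)
    array(NA_real_, c(K[l], length(orientations), length(orientations))))
  for (a in seq_along(orientations)) {
    cfg <- config
    cfg$attended_condition <- orientations[a]
    field <- build_attention_field(cfg, table, model)
    att_rec <- activity_record(model, population$items,
                               population$orientation, attention = field)
    for (l in seq_len(n_layers)) {
      att <- color_avg(att_rec$activity[[l]]) # n_ori x K
      for (s in seq_along(orientations)) {
        ok <- baseline[[l]][s, ] > baseline_floor
        ratios[[l]][ok, a, s] <- att[s, ok] / baseline[[l]][s, ok]
      }
    }
  }
  structure(list(
    ratios = ratios,
    baseline = lapply(baseline, t),
    orientations = orientations,
    n_excluded = vapply(seq_len(n_layers), function(l)
      sum(baseline[[l]] <= baseline_floor), 0),
    beta = config$beta, applied_layers = config$layers
  ), class = "activity_ratio_record")
}

ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(slope = slope, intercept = yb - slope * xb)
}

# Collapse 9 preference-ordered ratios to the 5 plotted points: most
# preferred alone at position 0, then means of successive pairs.
pair_average_points <- function(ordered_ratios) {
  c(ordered_ratios[1],
    vapply(1:4, function(p) mean(ordered_ratios[2 * p + 0:1]), 0))
}

#' Fit the FSGM slope/intercept diagnostic per feature map
#'
#' For each feature map, takes the activity ratio when each orientation is
#' both present and attended, orders the nine ratios from most to least
#' preferred orientation (preference from the map's tuning curve at the
#' recorded layer), collapses them to five points (most preferred at
#' position 0, then the mean of each successive preference pair), and fits
#' an ordinary least squares line. Feature-similarity gain predicts a
#' negative slope and an intercept above one.
#'
#' @param record An [record_activity_ratios()] result.
#' @param tuning A tuning `value_table` for the same model (preference
#'   ordering).
#' @param layer Recorded layer to analyse.
#' @return Data frame per feature map: `feature_map`, `slope`,
#'   `intercept` (raw; report `intercept - 1` for the deviation from no
#'   modulation), `complete` (all nine ratios available).
#' @export
fsgm_ratio_fit <- function(record, tuning, layer) {
  orientations <- record$orientations
  if (length(orientations) != 9)
    stop("the ratio fit expects nine stimulus orientations")
  R <- record$ratios[[layer]]
  out <- lapply(seq_len(dim(R)[1]), function(k) {
    diag_ratios <- vapply(seq_along(orientations), function(o) R[k, o, o], 0)
    pref_idx <- order(-tuning$values[[layer]][k, ],
                      seq_along(orientations))
    y <- diag_ratios[pref_idx]
    if (anyNA(y))
      return(data.frame(feature_map = k, slope = NA_real_,
                        intercept = NA_real_, complete = FALSE))
    pts <- pair_average_points(y)
    fit <- ols_line(0:4, pts)
    data.frame(feature_map = k, slope = fit[["slope"]],
               intercept = fit[["intercept"]], complete = TRUE)
  })
  do.call(rbind, out)
}

#' Fraction of feature maps showing feature-matching behaviour
#'
#' A feature map displays feature matching if (1) when attending its
#' preferred orientation, its activity ratio is larger with the preferred
#' stimulus present than with the anti-preferred present, and (2) when
#' attending its anti-preferred orientation, the ratio is larger with the
#' anti-preferred stimulus present than with the preferred present. The
#' second condition separates feature matching from feature-similarity
#' gain, under which modulation depends only on the attended orientation.
#'
#' @param record An [record_activity_ratios()] result.
#' @param tuning A tuning `value_table` (preference per map).
#' @return Data frame per layer: `layer`, `fm_fraction`, `n_maps`.
#' @export
feature_matching_fraction <- function(record, tuning) {
  orientations <- record$orientations
  out <- lapply(seq_along(record$ratios), function(l) {
    R <- record$ratios[[l]]
    flags <- vapply(seq_len(dim(R)[1]), function(k) {
      f <- tuning$values[[l]][k, ]
      p <- which.max(f)
      a <- which.min(f)
      vals <- c(R[k, p, p], R[k, p, a], R[k, a, a], R[k, a, p])
      if (anyNA(vals) || p == a) return(NA)
      vals[1] > vals[2] && vals[3] > vals[4]
    }, NA)
    data.frame(layer = l, fm_fraction = mean(flags, na.rm = TRUE),
               n_maps = sum(!is.na(flags)))
  })
  do.call(rbind, out)
}

#' Per-image FSGM slope and paired performance change
#'
#' For each condition-positive image, plots each feature map's
#' with/without-attention activity ratio at the recorded layer against the
#' map's tuning value for the attended orientation and takes the least
#' squares slope (positive slopes are more FSGM-like). Returns the median
#' slope over images paired with the attention-induced change in the true
#' positive rate on those images.
#'
#' @param model A `conv_net` with binary readouts.
#' @param set A balanced `stimulus_set` for the attended orientation.
#' @param config An [attention_config()] (attention to `set$condition`).
#' @param table The tuning `value_table` (x-axis values and field source).
#' @param layer Recorded layer; must be at or after the applied layer(s).
#' @param baseline_floor Maps with baseline activity below this are
#'   excluded from the fit.
#' @return List: `median_slope`, per-image `slopes`, `tp_without`,
#'   `tp_with`, `tp_change`.
#' @export
per_image_fsgm_slope <- function(model, set, config, table, layer,
                                 baseline_floor = 1e-8) {
  if (layer < max(config$layers))
    stop("activity is only recorded at or after the applied layer")
  field <- if (config$beta == 0) NULL else
    build_attention_field(config, table, model)
  ci <- match(config$attended_condition, table$conditions)
  f <- table$values[[layer]][, ci]
  pos <- which(set$positive)
  slopes <- numeric(length(pos))
  correct_without <- correct_with <- logical(length(pos))
  for (i in seq_along(pos)) {
    im <- set$items[[pos[i]]]
    fwd0 <- forward_pass(model, im)
    fwd1 <- forward_pass(model, im, field)
    r0 <- apply(fwd0$act[[layer]], 3, mean)
    r1 <- apply(fwd1$act[[layer]], 3, mean)
    keep <- r0 > baseline_floor & !table$dead[[layer]]
    slopes[i] <- ols_line(f[keep], r1[keep] / r0[keep])[["slope"]]
    correct_without[i] <- binary_score(model, fwd0$feats,
                                       set$condition) > 0.5
    correct_with[i] <- binary_score(model, fwd1$feats, set$condition) > 0.5
  }
  list(median_slope = median(slopes), slopes = slopes,
       tp_without = mean(correct_without), tp_with = mean(correct_with),
       tp_change = mean(correct_with) - mean(correct_without))
}

#' Vector-angle measure of attention's downstream effect
#'
#' Characterizes activity changes by their alignment with the direction in
#' activity space that drives positive classification, rather than by
#' stimulus tuning. Activity (spatially averaged, at the given layer, no
#' attention) over all images is reduced to principal components retaining
#' at least 90% of the variance; the positive-classification direction is
#' the mean reduced activity over images the readout classifies as
#' positive. For condition-present images, the cosine between each image's
#' reduced activity and that direction is computed with and without
#' attention, and the difference of the medians is returned.
#'
#' @param model A `conv_net` with binary readouts.
#' @param set A `stimulus_set` (positives and negatives).
#' @param config An [attention_config()].
#' @param table `value_table` for the attention field.
#' @param layer Recorded layer.
#' @param retain Minimum fraction of variance retained by the principal
#'   components (default 0.90).
#' @return A `vector_angle_measure` list: `median_cos_with`,
#'   `median_cos_without`, `difference`, `n_components`,
#'   `retained_variance`.
#' @export
vector_angle_measure <- function(model, set, config, table, layer,
                                 retain = 0.90) {
  field <- if (config$beta == 0) NULL else
    build_attention_field(config, table, model)
  acts0 <- t(vapply(set$items, function(im)
    apply(forward_pass(model, im)$act[[layer]], 3, mean),
    numeric(model$n_maps[layer])))
  if (all(apply(acts0, 2, sd) == 0))
    stop("degenerate activity: no variance at the recorded layer")
  pc <- stats::prcomp(acts0, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum >= retain)[1]
  reduce <- function(A) sweep(A, 2, pc$center) %*% pc$rotation[, seq_len(ncomp),
                                                              drop = FALSE]
  red0 <- reduce(acts0)
  classified_pos <- vapply(seq_along(set$items), function(i)
    binary_score(model, forward_pass(model, set$items[[i]])$feats,
                 set$condition) > 0.5, TRUE)
  if (!any(classified_pos))
    stop("no image is classified positive; direction undefined")
  direction <- colMeans(red0[classified_pos, , drop = FALSE])
  cosine <- function(v) sum(v * direction) /
    (sqrt(sum(v^2)) * sqrt(sum(direction^2)))
  pos <- which(set$positive)
  acts1 <- t(vapply(set$items[pos], function(im)
    apply(forward_pass(model, im, field)$act[[layer]], 3, mean),
    numeric(model$n_maps[layer])))
  red1 <- reduce(acts1)
  cos_with <- apply(red1, 1, cosine)
  cos_without <- apply(red0[pos, , drop = FALSE], 1, cosine)
  structure(list(median_cos_with = median(cos_with),
                 median_cos_without = median(cos_without),
                 difference = median(cos_with) - median(cos_without),
                 n_components = ncomp, retained_variance = cum[ncomp]),
            class = "vector_angle_measure")
}

#' Correlate activity-change measures with performance and compare by
#' bootstrap
#'
#' Computes the Pearson correlation between each measure and the paired
#' performance changes, then resamples the pairs with replacement
#' `n_boot` times, recomputing both coefficients per replicate, and
#' compares the two bootstrap samples with a two-sided t-test. When the
#' two measures are observed on the same sweep combinations (equal
#' lengths) the resampling is joint.
#'
#' @param measure1,measure2 Numeric vectors of activity-change measures.
#' @param performance1,performance2 Paired performance changes
#'   (`performance2` defaults to `performance1`).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List: `r1`, `r2`, `boot1`, `boot2`, `p_value`, and percentile
#'   `ci1`/`ci2` (2.5-97.5%).
#' @export
correlate_and_bootstrap <- function(measure1, measure2, performance1,
                                    performance2 = performance1,
                                    n_boot = 100, seed = 1) {
  stopifnot(length(measure1) == length(performance1),
            length(measure2) == length(performance2))
  set.seed(seed)
  r1 <- cor(measure1, performance1)
  r2 <- cor(measure2, performance2)
  joint <- length(measure1) == length(measure2)
  boot1 <- boot2 <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i1 <- sample.int(length(measure1), replace = TRUE)
    i2 <- if (joint) i1 else sample.int(length(measure2), replace = TRUE)
    # a resample can be degenerate (zero variance); recorded as NA and
    # dropped from the comparison
    boot1[b] <- suppressWarnings(cor(measure1[i1], performance1[i1]))
    boot2[b] <- suppressWarnings(cor(measure2[i2], performance2[i2]))
  }
  ok <- is.finite(boot1) & is.finite(boot2)
  p_value <- if (sum(ok) >= 2 &&
                 (sd(boot1[ok]) > 0 || sd(boot2[ok]) > 0))
    t.test(boot1[ok], boot2[ok])$p.value else NA_real_
  list(r1 = r1, r2 = r2, boot1 = boot1, boot2 = boot2,
       p_value = p_value, n_degenerate = sum(!ok),
       ci1 = quantile(boot1[is.finite(boot1)], c(0.025, 0.975),
                      names = FALSE),
       ci2 = quantile(boot2[is.finite(boot2)], c(0.025, 0.975),
                      names = FALSE))
}
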