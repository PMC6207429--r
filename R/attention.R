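#' Configure an attention manipulation
#'
#' Describes where attention values come from (feature-map tuning values,
#' layer-normalized gradient values, a spatial quadrant mask, a combined
#' feature + spatial field, or negated tuning values as a control), how
#' they are applied (multiplicative ReLU-slope scaling or an additive
#' pre-activation shift), whether suppression of non-preferring maps is
#' allowed (`bidirectional`) or values are positively rectified first
#' (`positive_only`), the target layers and the overall strength `beta`.
#'
#' @param source One of `"tuning"`, `"gradient"`, `"spatial"`,
#'   `"feature+spatial"`, `"negated_tuning"`.
#' @param mode `"multiplicative"` or `"additive"`.
#' @param sign `"bidirectional"` or `"positive_only"`.
#' @param layers Integer vector of target layers.
#' @param beta Attention strength, >= 0 (feature attention at most 11.85;
#'   spatial attention at most 1).
#' @param attended_condition Condition whose values drive feature modes.
#' @param attended_quadrant Quadrant index 1-4 for spatial modes.
#' @param all_layers_scale Logical; when targeting all layers
#'   simultaneously the effective strength is `beta / 10`.
#'
#' @return An `attention_config`.
#' @export
attention_config <- function(source = "tuning", mode = "multiplicative",
                             sign = "bidirectional", layers, beta = 0,
                             attended_condition = NULL,
                             attended_quadrant = NULL,
                             all_layers_scale = FALSE) {
  source <- match.arg(source, c("tuning", "gradient", "spatial",
                                "feature+spatial", "negated_tuning"))
  mode <- match.arg(mode, c("multiplicative", "additive"))
  sign <- match.arg(sign, c("bidirectional", "positive_only"))
  if (beta < 0) stop("beta must be non-negative")
  if (source == "spatial" && beta > 1)
    stop("spatial attention strength is limited to beta <= 1")
  if (source != "spatial" && beta > 11.85)
    stop("feature attention strength is limited to beta <= 11.85")
  uses_feature <- source %in% c("tuning", "gradient", "negated_tuning",
                                "feature+spatial")
  uses_spatial <- source %in% c("spatial", "feature+spatial")
  if (uses_feature && is.null(attended_condition))
    stop("feature attention requires an attended condition")
  if (uses_spatial &&
      (is.null(attended_quadrant) || !attended_quadrant %in% 1:4))
    stop("spatial attention requires an attended quadrant in 1..4")
  structure(list(source = source, mode = mode, sign = sign,
                 layers = as.integer(layers), beta = beta,
                 attended_condition = attended_condition,
                 attended_quadrant = attended_quadrant,
                 all_layers_scale = isTRUE(all_layers_scale)),
            class = "attention_config")
}

quadrant_mask <- function(size, quadrant) {
  s <- matrix(-1, size, size)
  s[quadrant_rows(quadrant, size), quadrant_cols(quadrant, size)] <- 1
  s
}

#' Build an attention field from a configuration
#'
#' Feature modes produce per-feature-map modulations `m_lk = beta v_c^lk`,
#' constant over space; `v` comes from tuning values, from layer-normalized
#' gradient values, or is negated for the `negated_tuning` control, and is
#' positively rectified first under `sign = "positive_only"`. Spatial modes
#' set `m_lkij = +beta` inside the attended quadrant and `-beta` outside.
#' Combined feature + spatial fields add the two terms under the shared
#' `beta`.
#'
#' @param config An [attention_config()].
#' @param table A `value_table` (required for feature modes). Gradient
#'   tables are layer-normalized automatically if they are not already.
#' @param model The `conv_net` the field will be applied to (for layer
#'   geometry).
#' @return An `attention_field`: per-layer `feature` vectors and/or
#'   `spatial` matrices with the mode flag, consumed by [forward_pass()].
#' @export
build_attention_field <- function(config, table = NULL, model) {
  uses_feature <- config$source %in% c("tuning", "gradient", "negated_tuning",
                                       "feature+spatial")
  beta <- config$beta * if (config$all_layers_scale) 0.1 else 1
  if (uses_feature) {
    if (is.null(table)) stop("feature attention requires a value table")
    if (table$type == "gradient" && !isTRUE(table$normalized))
      table <- normalize_gradients(table)
    ci <- match(config$attended_condition, table$conditions)
    if (is.na(ci))
      stop("attended condition not present in the value table")
  }
  sizes <- layer_sizes(model)
  layers <- stats::setNames(lapply(config$layers, function(l) {
    feature <- NULL
    spatial <- NULL
    if (uses_feature) {
      v <- table$values[[l]][, ci]
      if (config$sign == "positive_only") v <- pmax(v, 0)
      if (config$source == "negated_tuning") v <- -v
      feature <- beta * v
    }
    if (config$source %in% c("spatial", "feature+spatial"))
      spatial <- beta * quadrant_mask(sizes[l], config$attended_quadrant)
    list(feature = feature, spatial = spatial, mode = config$mode)
  }), as.character(config$layers))
  structure(list(layers = layers, beta = config$beta,
                 source = config$source), class = "attention_field")
}

#' Sweep attention strength over a beta grid
#'
#' Re-evaluates detection on the same stimulus set for every strength in
#' the grid and reports rates and performance per beta, plus the
#' best-performing strength.
#'
#' @param model A `conv_net` with binary readouts.
#' @param set A balanced `stimulus_set`.
#' @param config An [attention_config()] template; its `beta` is replaced
#'   by each grid value in turn (`beta = 0` means no modulation).
#' @param betas Numeric grid of strengths; must include 0.
#' @param table `value_table` for feature modes.
#' @return Data frame (`beta`, `TP`, `FP`, `TN`, `FN`, `performance`) with
#'   attributes `best_beta` and `best_performance`.
#' @export
sweep_beta <- function(model, set, config, betas = seq(0, 0.9, by = 0.15),
                       table = NULL) {
  if (!length(betas)) stop("beta grid must be non-empty")
  rows <- lapply(betas, function(b) {
    cfg <- config
    cfg$beta <- b
    field <- if (b == 0) NULL else build_attention_field(cfg, table, model)
    out <- evaluate_detection(model, set, attention = field)
    data.frame(beta = b, TP = out$TP, FP = out$FP, TN = out$TN, FN = out$FN,
               performance = out$performance)
  })
  df <- do.call(rbind, rows)
  best <- which.max(df$performance)
  attr(df, "best_beta") <- df$beta[best]
  attr(df, "best_performance") <- df$performance[best]
  df
}
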