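#' Final-layer pooled feature matrix for a set of stimuli
#'
#' @param model A `conv_net`.
#' @param items List of stimuli.
#' @param attention Optional attention field applied during the pass.
#' @return `n x K` matrix of spatially averaged final-layer activities.
#' @export
pooled_features <- function(model, items, attention = NULL) {
  t(vapply(items, function(im) forward_pass(model, im, attention)$feats,
           numeric(model$n_maps[length(model$n_maps)])))
}

# Ridge-regularized logistic fit; full-field gratings are linearly
# separable in fixture feature space, so a small fixed penalty keeps the
# readout weights finite and its error gradients informative.
fit_logistic_ridge <- function(X, y, lambda = 1e-2) {
  fit <- glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  co <- as.numeric(coef(fit, s = lambda))
  list(b = co[1], w = co[-1])
}

#' Attach binary detection readouts
#'
#' Trains one independent ridge-regularized logistic classifier per
#' condition on final-layer pooled features of full-field training stimuli
#' (positives: the condition's orientation; negatives: all others). The
#' softmax readout used for category-gradient calculations is preserved.
#'
#' @param model A `conv_net`.
#' @param conditions Orientations (degrees) to build detectors for.
#' @param population A [make_grating_population()] result used as the
#'   training set.
#' @param lambda Ridge penalty.
#' @return The model with `$binary_readouts` populated (named by condition).
#' @export
attach_binary_readouts <- function(model, conditions, population,
                                   lambda = 1e-2) {
  X <- pooled_features(model, population$items)
  if (any(apply(X, 2, sd) == 0) && all(apply(X, 2, sd) == 0))
    stop("degenerate features: all-constant final-layer activity")
  for (cond in conditions) {
    y <- population$orientation == cond
    if (!any(y) || all(y))
      stop("training population must contain both classes for condition ",
           cond)
    model$binary_readouts[[as.character(cond)]] <-
      c(fit_logistic_ridge(X, y, lambda), list(condition = cond))
  }
  model
}

#' Attach the 5-way color readout
#'
#' Replaces the task readout with a ridge-regularized multinomial (softmax)
#' color classifier trained on full-field gratings of every
#' orientation-color combination.
#'
#' @param model A `conv_net`.
#' @param population A [make_grating_population()] result.
#' @param lambda Ridge penalty.
#' @return The model with `$color_readout` set (`W`: K x 5, `b`, `colors`).
#' @export
attach_color_readout <- function(model, population, lambda = 1e-2) {
  X <- pooled_features(model, population$items)
  colors <- names(grating_palette())
  y <- factor(population$color, levels = colors)
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  co <- coef(fit, s = lambda)
  model$color_readout <- list(
    W = do.call(cbind, lapply(co, function(m) as.numeric(m)[-1])),
    b = vapply(co, function(m) as.numeric(m)[1], 0),
    colors = colors
  )
  model
}

#' Binary detection probability for one condition
#'
#' @param model A `conv_net` with binary readouts attached.
#' @param feats Final-layer pooled feature vector.
#' @param condition The detector to query.
#' @return Probability that the condition is present.
#' @export
binary_score <- function(model, feats, condition) {
  rd <- model$binary_readouts[[as.character(condition)]]
  if (is.null(rd)) stop("no binary readout for condition ", condition)
  1 / (1 + exp(-(sum(rd$w * feats) + rd$b)))
}

#' Color class probabilities
#'
#' @param model A `conv_net` with the color readout attached.
#' @param feats Final-layer pooled feature vector.
#' @return Named probability vector over the five colors.
#' @export
color_scores <- function(model, feats) {
  if (is.null(model$color_readout)) stop("no color readout attached")
  cr <- model$color_readout
  p <- softmax(drop(crossprod(cr$W, feats)) + cr$b)
  names(p) <- cr$colors
  p
}
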