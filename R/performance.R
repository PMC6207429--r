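#' Evaluate detection performance on a stimulus set
#'
#' Scores every stimulus with the binary readout for the set's condition
#' (optionally under an attention field) and computes true/false positive
#' and negative rates; overall performance is the average of the true
#' positive and true negative rates.
#'
#' @param model A `conv_net` with binary readouts attached.
#' @param set A `stimulus_set` from [build_balanced_detection_set()].
#' @param attention Optional attention field.
#' @param threshold Decision threshold on the readout probability.
#' @return A `detection_outcome`: `TP`, `FP`, `TN`, `FN` rates,
#'   `n_positives`, `n_negatives`, `performance`, `condition`.
#' @export
evaluate_detection <- function(model, set, attention = NULL,
                               threshold = 0.5) {
  if (sum(set$positive) != sum(!set$positive))
    warning("stimulus set is not balanced; rates are still per-class")
  scores <- vapply(set$items, function(im)
    binary_score(model, forward_pass(model, im, attention)$feats,
                 set$condition), 0)
  decision <- scores > threshold
  TP <- mean(decision[set$positive])
  FP <- mean(decision[!set$positive])
  structure(list(TP = TP, FP = FP, TN = 1 - FP, FN = 1 - TP,
                 n_positives = sum(set$positive),
                 n_negatives = sum(!set$positive),
                 performance = (TP + (1 - FP)) / 2,
                 condition = set$condition, scores = scores),
            class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf(
    "<detection_outcome %s: TP %.3f FP %.3f performance %.3f (n=%d+%d)>\n",
    format(x$condition), x$TP, x$FP, x$performance, x$n_positives,
    x$n_negatives))
  invisible(x)
}

#' Signal detection theory metrics from hit and false alarm rates
#'
#' Criteria `c = -0.5 (qnorm(TP) + qnorm(FP))` measures the distance of
#' the decision threshold from the neutral point between the two stimulus
#' distributions (positive = stricter); sensitivity
#' `d' = qnorm(TP) - qnorm(FP)` measures their separation. To keep both
#' finite, false positive rates below 0.01 are raised to 0.01 and true
#' positive rates above 0.99 lowered to 0.99 before the transform. That
#' asymmetric rule is the default; `symmetric = TRUE` additionally floors
#' `TP` at 0.01 and caps `FP` at 0.99, which keeps both metrics finite
#' even for degenerate detectors that never fire.
#'
#' @param TP,FP True and false positive rates in \[0,1\].
#' @param symmetric Clip both tails of both rates (default `FALSE`).
#' @return An `sdt_metrics` list: `c`, `dprime`, `clipped_TP`,
#'   `clipped_FP`.
#' @export
sdt_metrics <- function(TP, FP, symmetric = FALSE) {
  if (TP < 0 || TP > 1 || FP < 0 || FP > 1)
    stop("rates must lie in [0, 1]")
  clipped_TP <- TP > 0.99 || (symmetric && TP < 0.01)
  clipped_FP <- FP < 0.01 || (symmetric && FP > 0.99)
  TP <- min(TP, 0.99)
  FP <- max(FP, 0.01)
  if (symmetric) {
    TP <- max(TP, 0.01)
    FP <- min(FP, 0.99)
  }
  zt <- qnorm(TP)
  zf <- qnorm(FP)
  structure(list(c = -0.5 * (zt + zf), dprime = zt - zf,
                 clipped_TP = clipped_TP, clipped_FP = clipped_FP),
            class = "sdt_metrics")
}

#' @export
print.sdt_metrics <- function(x, ...) {
  cat(sprintf("<sdt_metrics: c = %.3f, d' = %.3f%s>\n", x$c, x$dprime,
              if (x$clipped_TP || x$clipped_FP) " (clipped)" else ""))
  invisible(x)
}

#' Receiver operating characteristic threshold sweep
#'
#' Scores the set once with no attention and sweeps the readout decision
#' threshold, reporting the (FP, TP) operating point per threshold.
#'
#' @param model A `conv_net` with binary readouts.
#' @param set A `stimulus_set`.
#' @param thresholds Decreasingly strict thresholds to sweep.
#' @return Data frame `threshold`, `FP`, `TP` (rates non-increasing in
#'   threshold).
#' @export
roc_threshold_sweep <- function(model, set,
                                thresholds = seq(0, 1, by = 0.05)) {
  scores <- vapply(set$items, function(im)
    binary_score(model, forward_pass(model, im)$feats, set$condition), 0)
  do.call(rbind, lapply(thresholds, function(th) {
    decision <- scores > th
    data.frame(threshold = th, FP = mean(decision[!set$positive]),
               TP = mean(decision[set$positive]))
  }))
}

#' Match an attention strength to a behavioral operating point
#'
#' Finds the strength whose sweep sample lies nearest (Euclidean distance
#' in (FP, TP) space) to a given operating point; ties go to the smaller
#' beta. Behavioral points can be read from a 3-column CSV
#' (label, FP, TP) with [read_behavioral_points()].
#'
#' @param sweep A [sweep_beta()] result (columns `beta`, `FP`, `TP`).
#' @param point Numeric `c(FP, TP)` operating point.
#' @return The matched beta.
#' @export
match_beta_to_point <- function(sweep, point) {
  if (!nrow(sweep)) stop("sweep must be non-empty")
  d <- sqrt((sweep$FP - point[1])^2 + (sweep$TP - point[2])^2)
  sweep$beta[order(d, sweep$beta)][1]
}

#' Read behavioral operating points from CSV
#'
#' @param path CSV file with columns `label`, `FP`, `TP`.
#' @return Data frame of labelled operating points.
#' @export
read_behavioral_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "FP", "TP") %in% names(df)))
    stop("behavioral points file needs columns label, FP, TP")
  df
}

#' Recipe: joint feature-and-spatial detection task
#'
#' Stimuli for deciding whether a given orientation is present in a given
#' quadrant. Positive draws place the searched-for orientation in the
#' attended quadrant; negative draws either place it in a different
#' quadrant (half of them) or omit it entirely.
#'
#' @inheritParams two_grating_recipe
#' @param quadrant Attended quadrant, 1-4.
#' @return A generator function for [build_balanced_detection_set()].
#' @export
quadrant_detection_recipe <- function(condition, quadrant,
                                      orientations = default_orientations(),
                                      colors = names(grating_palette()),
                                      canvas_size = 64) {
  others <- setdiff(orientations, condition)
  function(positive, seed) {
    set.seed(seed)
    include_target <- positive || runif(1) < 0.5
    oris <- if (include_target) c(condition, sample(others, 1)) else
      sample(others, 2)
    cols <- sample(colors, 2)
    img <- make_two_grating_image(grating_spec(oris[1], cols[1]),
                                  grating_spec(oris[2], cols[2]),
                                  canvas_size = canvas_size)
    if (include_target) {
      tq <- img$labels$quadrant[match(condition, img$labels$orientation)]
      ok <- if (positive) tq == quadrant else tq != quadrant
      while (!ok) {
        img <- make_two_grating_image(grating_spec(oris[1], cols[1]),
                                      grating_spec(oris[2], cols[2]),
                                      canvas_size = canvas_size)
        tq <- img$labels$quadrant[match(condition, img$labels$orientation)]
        ok <- if (positive) tq == quadrant else tq != quadrant
      }
    }
    img
  }
}
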