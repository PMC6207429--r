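#' Construct a layered convolutional network
#'
#' Builds an untrained convolution + rectification (+ optional 2x2 max-pool)
#' stack with an N-way softmax readout on spatially pooled final-layer
#' features. Each convolutional filter application yields one feature map;
#' all convolutions use same-padding so spatial dimensions only change at
#' pooling stages.
#'
#' @param input_size Side length of square RGB input images; must be
#'   divisible by `2^length(pool_after)`.
#' @param n_maps Integer vector: feature maps per convolutional layer.
#' @param pool_after Layer indices after which a 2x2 max-pool is applied.
#' @param n_classes Number of softmax output classes.
#' @param kernel Odd convolution kernel size (default 3).
#' @param seed Integer seed for weight initialization.
#'
#' @return A `conv_net` object.
#' @export
conv_net <- function(input_size, n_maps = c(8, 16, 16, 32, 32),
                     pool_after = c(2, 4), n_classes = 45, kernel = 3,
                     seed = 1) {
  if (length(n_maps) < 1) stop("at least one convolutional layer is required")
  if (kernel %% 2 == 0) stop("kernel size must be odd")
  set.seed(seed)
  n_layers <- length(n_maps)
  c_in <- c(3, n_maps[-n_layers])
  layers <- vector("list", n_layers)
  size <- input_size
  for (l in seq_len(n_layers)) {
    fan_in <- kernel^2 * c_in[l]
    layers[[l]] <- list(
      W = array(rnorm(kernel^2 * c_in[l] * n_maps[l], sd = sqrt(2 / fan_in)),
                c(kernel, kernel, c_in[l], n_maps[l])),
      b = rep(0, n_maps[l]),
      pool = l %in% pool_after,
      size = size
    )
    if (layers[[l]]$pool) {
      if (size %% 2 != 0) stop("pooling requires even spatial dimensions")
      size <- size / 2
    }
  }
  k_out <- n_maps[n_layers]
  structure(list(
    layers = layers, input_size = as.integer(input_size),
    n_maps = n_maps, n_classes = n_classes,
    softmax = list(W = matrix(rnorm(k_out * n_classes, sd = 0.01),
                              k_out, n_classes),
                   b = rep(0, n_classes)),
    binary_readouts = list(), color_readout = NULL,
    layer_means = NULL, classes = NULL
  ), class = "conv_net")
}

#' @export
print.conv_net <- function(x, ...) {
  cat(sprintf("<conv_net: %d conv layers (%s maps), input %dx%d, %d classes>\n",
              length(x$layers), paste(x$n_maps, collapse = "/"),
              x$input_size, x$input_size, x$n_classes))
  if (length(x$binary_readouts))
    cat(sprintf("  binary readouts: %s\n",
                paste(names(x$binary_readouts), collapse = ", ")))
  if (!is.null(x$color_readout))
    cat("  5-way color readout attached\n")
  invisible(x)
}

#' Spatial dimensions of each layer's feature maps
#'
#' @param model A `conv_net`.
#' @return Integer vector of per-layer side lengths.
#' @export
layer_sizes <- function(model) {
  vapply(model$layers, function(l) as.integer(l$size), 1L)
}

attention_for_layer <- function(attention, l) {
  if (is.null(attention)) return(NULL)
  attention$layers[[as.character(l)]]
}

#' Run the network forward pass
#'
#' Computes `x = [(W * X_prev)]+` at every layer (2-D convolution of the
#' layer below plus positive rectification), optionally modulated by an
#' attention field.
#' Multiplicative attention scales the ReLU slope: `x = (1 + m) [I]+`;
#' additive attention shifts the pre-activation: `x = [I + mu_l m]+`. With
#' `attention = NULL` the result is bitwise identical to an all-zero field.
#'
#' @param model A `conv_net`.
#' @param image An [image_stimulus()] or a raw `H x W x 3` pixel array.
#' @param attention An [build_attention_field()] result, or `NULL`.
#' @param perturb Optional list `(layer, map, delta)` adding a constant to
#'   every unit of one feature map post-rectification (used for
#'   finite-difference checks).
#'
#' @return A `layer_activations` list: `act` (post-rectification per-layer
#'   `H x W x K` arrays), `pre` (pre-rectification inputs), `inputs`
#'   (post-pool inputs to each layer), `argmax` (pool routing), and `feats`
#'   (final-layer spatially averaged feature vector).
#' @export
forward_pass <- function(model, image, attention = NULL, perturb = NULL) {
  px <- if (inherits(image, "image_stimulus")) image$pixels else image
  if (dim(px)[1] != model$input_size)
    stop("image dimensions do not match model input size")
  n_layers <- length(model$layers)
  act <- pre <- inputs <- argmax <- vector("list", n_layers)
  cur <- px
  for (l in seq_len(n_layers)) {
    ly <- model$layers[[l]]
    inputs[[l]] <- cur
    I <- .conv2d_forward(cur, ly$W, ly$b)
    af <- attention_for_layer(attention, l)
    if (is.null(af)) {
      x <- pmax(I, 0)
    } else if (af$mode == "multiplicative") {
      gain <- attention_gain_array(af, dim(I))
      x <- gain * pmax(I, 0)
    } else {
      if (is.null(model$layer_means))
        stop("additive attention requires layer means; see compute_layer_means()")
      shift <- model$layer_means[l] * attention_m_array(af, dim(I))
      x <- pmax(I + shift, 0)
    }
    if (!is.null(perturb) && perturb$layer == l) {
      x[, , perturb$map] <- x[, , perturb$map] + perturb$delta
    }
    pre[[l]] <- I
    act[[l]] <- x
    if (ly$pool) {
      mp <- .maxpool_forward(x)
      cur <- mp$out
      argmax[[l]] <- mp$argmax
    } else {
      cur <- x
    }
  }
  feats <- apply(act[[n_layers]], 3, mean)
  structure(list(act = act, pre = pre, inputs = inputs, argmax = argmax,
                 feats = feats), class = "layer_activations")
}

# Materialize the modulation m_lkij (feature + spatial terms, beta already
# folded in) for one layer as an H x W x K array.
attention_m_array <- function(af, d) {
  m <- array(0, d)
  if (!is.null(af$feature)) {
    if (length(af$feature) != d[3])
      stop("attention field references an unknown feature-map count")
    m <- m + rep(af$feature, each = d[1] * d[2])
  }
  if (!is.null(af$spatial)) {
    if (!all(dim(af$spatial) == d[1:2]))
      stop("spatial attention mask does not match layer dimensions")
    m <- m + as.vector(af$spatial)
  }
  m
}

attention_gain_array <- function(af, d) 1 + attention_m_array(af, d)

#' Backpropagate an error gradient through the network
#'
#' Given the gradient of a loss with respect to the final-layer spatially
#' averaged features, computes the gradient with respect to every unit's
#' post-rectification activity at every layer (and optionally with respect
#' to the weights, for training).
#'
#' @param model A `conv_net`.
#' @param fwd A [forward_pass()] result.
#' @param d_feats Numeric vector: loss gradient w.r.t. `fwd$feats`.
#' @param attention The attention field used in the forward pass, if any.
#' @param want_weights Logical; also return `dW`/`db` per layer.
#'
#' @return List with `d_act` (per-layer `H x W x K` gradients w.r.t.
#'   activities) and, when requested, `dW` and `db`.
#' @export
backward_pass <- function(model, fwd, d_feats, attention = NULL,
                          want_weights = FALSE) {
  n_layers <- length(model$layers)
  d_act <- vector("list", n_layers)
  dW <- db <- if (want_weights) vector("list", n_layers) else NULL
  dL <- dim(fwd$act[[n_layers]])
  d_act[[n_layers]] <- array(rep(d_feats / (dL[1] * dL[2]),
                                 each = dL[1] * dL[2]), dL)
  for (l in rev(seq_len(n_layers))) {
    ly <- model$layers[[l]]
    dx <- d_act[[l]]
    af <- attention_for_layer(attention, l)
    I <- fwd$pre[[l]]
    if (is.null(af)) {
      dI <- dx * (I > 0)
    } else if (af$mode == "multiplicative") {
      dI <- dx * attention_gain_array(af, dim(I)) * (I > 0)
    } else {
      shift <- model$layer_means[l] * attention_m_array(af, dim(I))
      dI <- dx * ((I + shift) > 0)
    }
    if (want_weights) {
      dW[[l]] <- .conv2d_backward_weights(fwd$inputs[[l]], dI,
                                          dim(ly$W)[1], dim(ly$W)[2])
      db[[l]] <- apply(dI, 3, sum)
    }
    if (l > 1) {
      d_in <- .conv2d_backward_input(dI, ly$W)
      prev <- model$layers[[l - 1]]
      if (prev$pool) {
        d_act[[l - 1]] <- .maxpool_backward(d_in, fwd$argmax[[l - 1]],
                                            prev$size, prev$size)
      } else {
        d_act[[l - 1]] <- d_in
      }
    }
  }
  list(d_act = d_act, dW = dW, db = db)
}

#' Spatially averaged feature-map activity
#'
#' @param activations A [forward_pass()] result.
#' @return List (one per layer) of numeric vectors `r^lk`, the mean over all
#'   units of each feature map.
#' @export
record_spatially_averaged_activity <- function(activations) {
  lapply(activations$act, function(a) apply(a, 3, mean))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Softmax class scores for a feature vector
#'
#' @param model A `conv_net` with its softmax readout.
#' @param feats Final-layer pooled feature vector.
#' @return Numeric probability vector over classes.
#' @export
softmax_scores <- function(model, feats) {
  softmax(drop(crossprod(model$softmax$W, feats)) + model$softmax$b)
}

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adam_step <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), state = st)
}

#' Train the fixture network on synthetic grating classes
#'
#' Trains the convolutional stack plus softmax head to classify
#' orientation-by-color grating classes with minibatch Adam updates on the
#' cross-entropy loss, and verifies a held-out accuracy floor. Training is
#' deterministic for a fixed seed (up to floating-point reduction order).
#'
#' @param population A [make_grating_population()] result (the training
#'   stimuli and class labels), or `NULL` to generate one from
#'   `input_size` and `seed` with default study conditions.
#' @param input_size Input side length used when generating the default
#'   population.
#' @param n_maps,pool_after Architecture of the stack (defaults: 5 layers of
#'   8-32 maps, pools after layers 2 and 4).
#' @param epochs Number of passes over the training population.
#' @param lr Adam learning rate.
#' @param batch Minibatch size for gradient averaging.
#' @param holdout_fraction Fraction of the population held out for the
#'   accuracy check.
#' @param accuracy_floor Minimum held-out accuracy; training failure raises
#'   an error with diagnostics.
#' @param seed Integer seed (population, initialization, shuffling).
#'
#' @return A trained `conv_net` with `$classes` metadata and
#'   `$train_history` (per-epoch mean loss, final held-out accuracy).
#' @export
train_fixture_network <- function(population = NULL, input_size = 32,
                                  n_maps = c(8, 16, 16, 32, 32),
                                  pool_after = c(2, 4), epochs = 30,
                                  lr = 2e-3, batch = 15,
                                  holdout_fraction = 0.2,
                                  accuracy_floor = 2 / 45 * 2, seed = 1) {
  if (is.null(population))
    population <- make_grating_population(size = input_size, reps = 4,
                                          seed = seed)
  input_size <- dim(population$items[[1]]$pixels)[1]
  model <- conv_net(input_size, n_maps = n_maps, pool_after = pool_after,
                    n_classes = population$n_classes, seed = seed)
  model$classes <- unique(data.frame(class = population$class,
                                     orientation = population$orientation,
                                     color = population$color,
                                     stringsAsFactors = FALSE))
  n <- length(population$items)
  set.seed(seed + 1)
  holdout <- sample.int(n, max(1, round(holdout_fraction * n)))
  train_idx <- setdiff(seq_len(n), holdout)
  n_layers <- length(model$layers)
  st_W <- adam_state(lapply(model$layers, function(l) dim(l$W)))
  st_b <- adam_state(lapply(model$layers, function(l) length(l$b)))
  st_hW <- adam_state(list(dim(model$softmax$W)))[[1]]
  st_hb <- adam_state(list(length(model$softmax$b)))[[1]]
  t <- 0
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / batch))
    losses <- numeric(0)
    for (bb in batches) {
      gW <- lapply(model$layers, function(l) array(0, dim(l$W)))
      gb <- lapply(model$layers, function(l) numeric(length(l$b)))
      ghW <- array(0, dim(model$softmax$W))
      ghb <- numeric(length(model$softmax$b))
      for (i in bb) {
        y <- population$class[i]
        fwd <- forward_pass(model, population$items[[i]])
        p <- softmax_scores(model, fwd$feats)
        losses <- c(losses, -log(max(p[y], 1e-12)))
        dlogit <- p
        dlogit[y] <- dlogit[y] - 1
        d_feats <- drop(model$softmax$W %*% dlogit)
        bwd <- backward_pass(model, fwd, d_feats, want_weights = TRUE)
        ghW <- ghW + outer(fwd$feats, dlogit)
        ghb <- ghb + dlogit
        for (l in seq_len(n_layers)) {
          gW[[l]] <- gW[[l]] + bwd$dW[[l]]
          gb[[l]] <- gb[[l]] + bwd$db[[l]]
        }
      }
      nb <- length(bb)
      t <- t + 1
      up <- adam_step(model$softmax$W, ghW / nb, st_hW, lr, t)
      model$softmax$W <- up$par; st_hW <- up$state
      up <- adam_step(model$softmax$b, ghb / nb, st_hb, lr, t)
      model$softmax$b <- up$par; st_hb <- up$state
      for (l in seq_len(n_layers)) {
        up <- adam_step(model$layers[[l]]$W, gW[[l]] / nb, st_W[[l]], lr, t)
        model$layers[[l]]$W <- up$par; st_W[[l]] <- up$state
        up <- adam_step(model$layers[[l]]$b, gb[[l]] / nb, st_b[[l]], lr, t)
        model$layers[[l]]$b <- up$par; st_b[[l]] <- up$state
      }
    }
    history[ep] <- mean(losses)
  }
  preds <- vapply(holdout, function(i) {
    which.max(softmax_scores(model, forward_pass(model,
                                                 population$items[[i]])$feats))
  }, 1L)
  acc <- mean(preds == population$class[holdout])
  if (acc < accuracy_floor)
    stop(sprintf(paste0("fixture training failed: held-out accuracy %.3f ",
                        "below floor %.3f (final loss %.3f)"),
                 acc, accuracy_floor, history[epochs]))
  model$train_history <- list(loss = history, holdout_accuracy = acc)
  model
}

#' Compute per-layer mean activity levels
#'
#' `mu_l` is the average activity over all images, feature maps and spatial
#' positions of layer `l`; it scales additive attention so that additive and
#' multiplicative modulations are of comparable magnitude.
#'
#' @param model A `conv_net`.
#' @param items List of stimuli (the reference image population).
#' @return The model with `$layer_means` set (numeric, one value per layer).
#' @export
compute_layer_means <- function(model, items) {
  sums <- numeric(length(model$layers))
  counts <- numeric(length(model$layers))
  for (im in items) {
    fwd <- forward_pass(model, im)
    for (l in seq_along(fwd$act)) {
      sums[l] <- sums[l] + sum(fwd$act[[l]])
      counts[l] <- counts[l] + length(fwd$act[[l]])
    }
  }
  model$layer_means <- sums / counts
  model
}
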