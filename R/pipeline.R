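#' Build a run configuration
#'
#' Collects every knob of an end-to-end experiment (stimuli, fixture
#' architecture, tasks, attention grid, analyses) with documented
#' defaults. All randomness downstream funnels through the single `seed`.
#'
#' @param seed Master integer seed.
#' @param size Stimulus side length in pixels.
#' @param train_reps Training images per orientation-color class.
#' @param epochs Fixture training epochs.
#' @param accuracy_floor Held-out accuracy floor for fixture training.
#' @param n_maps,pool_after Fixture architecture.
#' @param conditions Orientations whose detection tasks are run (default:
#'   all nine).
#' @param n_test Test images per condition.
#' @param betas Attention strength grid (must include 0).
#' @param attention_layers Layers at which attention sweeps are applied.
#' @param source `"tuning"` or `"gradient"` attention values for sweeps.
#' @param ratio_layers Layers at which attention is applied for the
#'   activity-ratio recordings (`NULL` to skip the stage).
#' @param ratio_beta Strength used in the recording protocol (default 0.5).
#' @param stages Character vector of stages to run, in dependency order.
#' @param output_dir Directory for CSV/JSON artifacts (`NULL`: tempdir).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, size = 32, train_reps = 4, epochs = 30,
                       accuracy_floor = 2 / 45 * 2,
                       n_maps = c(8, 16, 16, 32, 32), pool_after = c(2, 4),
                       conditions = default_orientations(), n_test = 40,
                       betas = seq(0, 0.9, by = 0.15),
                       attention_layers = NULL,
                       source = "tuning", ratio_layers = NULL,
                       ratio_beta = 0.5,
                       stages = c("stimuli", "fixture", "readouts",
                                  "tuning", "gradients", "sweep", "sdt",
                                  "ratios"),
                       output_dir = NULL) {
  if (is.null(attention_layers)) attention_layers <- length(n_maps)
  if (is.null(ratio_layers)) ratio_layers <- length(n_maps)
  cfg <- list(seed = seed, size = size, train_reps = train_reps,
              epochs = epochs, accuracy_floor = accuracy_floor,
              n_maps = n_maps, pool_after = pool_after,
              conditions = conditions, n_test = n_test, betas = betas,
              attention_layers = attention_layers, source = source,
              ratio_layers = ratio_layers, ratio_beta = ratio_beta,
              stages = stages,
              output_dir = if (is.null(output_dir))
                file.path(tempdir(), paste0("fsgain_run_", seed)) else
                  output_dir)
  class(cfg) <- "run_config"
  cfg
}

stage_path <- function(cfg, name) file.path(cfg$output_dir, name)

#' Run an end-to-end attention experiment
#'
#' Executes the requested stages in dependency order: stimulus generation,
#' fixture training, readout attachment, tuning and gradient tables,
#' attention strength sweeps per condition and layer, signal detection
#' metrics, and activity-ratio recordings with FSGM fits and
#' feature-matching fractions. Stage failures are recorded in the manifest
#' and downstream dependents are skipped.
#'
#' @param config A [run_config()].
#' @return A `run_manifest`: per-stage status, artifact paths, wall-clock
#'   seconds, the resolved configuration, and the in-memory `results`
#'   (model, tables, sweep data frames).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  paths <- list()
  res <- new.env(parent = emptyenv())
  done <- character()
  run_stage <- function(name, deps, fn) {
    if (!name %in% config$stages) {
      status[[name]] <<- "not requested"
      return(invisible())
    }
    if (!all(deps %in% done)) {
      status[[name]] <<- paste("skipped (needs",
                               paste(setdiff(deps, done), collapse = ", "),
                               ")")
      return(invisible())
    }
    t0 <- proc.time()[3]
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) { status[[name]] <<-
                     paste("failed:", conditionMessage(e)); FALSE })
    if (ok) {
      status[[name]] <<- sprintf("ok (%.1fs)", proc.time()[3] - t0)
      done <<- c(done, name)
    }
  }

  run_stage("stimuli", character(), function() {
    res$train_pop <- make_grating_population(size = config$size,
                                             reps = config$train_reps,
                                             seed = config$seed)
    res$clean_pop <- make_grating_population(size = config$size, reps = 1,
                                             seed = config$seed + 10,
                                             degrade = FALSE)
  })
  run_stage("fixture", "stimuli", function() {
    res$model <- train_fixture_network(res$train_pop,
                                       n_maps = config$n_maps,
                                       pool_after = config$pool_after,
                                       epochs = config$epochs,
                                       accuracy_floor = config$accuracy_floor,
                                       seed = config$seed)
  })
  run_stage("readouts", "fixture", function() {
    res$model <- attach_binary_readouts(res$model, config$conditions,
                                        res$train_pop)
    res$model <- attach_color_readout(res$model, res$train_pop)
    res$model <- compute_layer_means(res$model, res$clean_pop$items)
  })
  run_stage("tuning", "readouts", function() {
    rec <- activity_record(res$model, res$train_pop$items,
                           res$train_pop$orientation)
    res$tuning <- compute_tuning_values(rec)
    p <- stage_path(config, "tuning.csv")
    write.csv(as.data.frame(res$tuning), p, row.names = FALSE)
    paths$tuning <<- p
  })
  run_stage("gradients", "tuning", function() {
    res$gradients <- category_gradient_table(res$model, res$train_pop,
                                             config$conditions)
    res$tg_cor <- correlate_tuning_gradients(res$tuning, res$gradients,
                                             n_shuffles = 20,
                                             seed = config$seed)
    p <- stage_path(config, "gradients.csv")
    write.csv(as.data.frame(res$gradients), p, row.names = FALSE)
    p2 <- stage_path(config, "tuning_gradient_correlation.csv")
    write.csv(res$tg_cor, p2, row.names = FALSE)
    paths$gradients <<- p; paths$tg_cor <<- p2
  })
  run_stage("sweep", "gradients", function() {
    table <- if (config$source == "gradient")
      normalize_gradients(res$gradients) else res$tuning
    rows <- list()
    for (layer in config$attention_layers) {
      for (cond in config$conditions) {
        set <- build_balanced_detection_set(
          cond, config$n_test,
          two_grating_recipe(cond, canvas_size = config$size),
          seed = config$seed + 100 + cond)
        cfg <- attention_config(source = config$source, layers = layer,
                                beta = 0, attended_condition = cond)
        df <- sweep_beta(res$model, set, cfg, config$betas, table)
        df$condition <- cond
        df$layer <- layer
        rows[[length(rows) + 1]] <- df
      }
    }
    res$sweep <- do.call(rbind, rows)
    p <- stage_path(config, "sweep.csv")
    write.csv(res$sweep, p, row.names = FALSE)
    paths$sweep <<- p
  })
  run_stage("sdt", "sweep", function() {
    res$sdt <- cbind(res$sweep[, c("condition", "layer", "beta")],
                     do.call(rbind, lapply(seq_len(nrow(res$sweep)),
                                           function(i) {
      m <- sdt_metrics(res$sweep$TP[i], res$sweep$FP[i])
      data.frame(criteria = m$c, dprime = m$dprime)
    })))
    p <- stage_path(config, "sdt.csv")
    write.csv(res$sdt, p, row.names = FALSE)
    paths$sdt <<- p
  })
  run_stage("ratios", "tuning", function() {
    fits <- list()
    for (layer in config$ratio_layers) {
      cfg <- attention_config(source = "tuning", layers = layer,
                              beta = config$ratio_beta,
                              attended_condition = config$conditions[1])
      rec <- record_activity_ratios(res$model, res$clean_pop, res$tuning,
                                    cfg)
      for (rl in seq_along(res$model$layers)) {
        if (rl < layer) next
        ft <- fsgm_ratio_fit(rec, res$tuning, rl)
        fits[[length(fits) + 1]] <- data.frame(
          applied = layer, recorded = rl,
          median_slope = median(ft$slope, na.rm = TRUE),
          median_intercept = median(ft$intercept, na.rm = TRUE))
      }
      res$fm <- feature_matching_fraction(rec, res$tuning)
    }
    res$ratio_fits <- do.call(rbind, fits)
    p <- stage_path(config, "ratio_fits.csv")
    write.csv(res$ratio_fits, p, row.names = FALSE)
    paths$ratio_fits <<- p
  })

  manifest <- structure(list(
    config = config, status = status, paths = paths,
    results = as.list(res),
    versions = list(R = R.version.string,
                    fsgain = as.character(utils::packageVersion("fsgain"))),
    finished = Sys.time()
  ), class = "run_manifest")
  write_manifest_json(manifest, stage_path(config, "manifest.json"))
  manifest
}

# Manifest metadata (not the in-memory results) as JSON.
write_manifest_json <- function(manifest, path) {
  meta <- list(status = manifest$status,
               paths = lapply(manifest$paths, as.character),
               versions = manifest$versions,
               seed = manifest$config$seed,
               stages = manifest$config$stages)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Summarize a run manifest
#'
#' Prints per-stage status plus the headline tables: per-layer performance
#' deltas from the sweeps, SDT metrics at the best strength, ratio-fit
#' medians, and tuning-gradient correlations. Missing stages are marked as
#' skipped rather than raising errors.
#'
#' @param manifest A [run_experiment()] result.
#' @return Invisibly, a list of the summary tables.
#' @export
summarize_run <- function(manifest) {
  cat("== fsgain run summary ==\n")
  for (nm in names(manifest$status))
    cat(sprintf("  stage %-9s %s\n", nm, manifest$status[[nm]]))
  out <- list()
  res <- manifest$results
  if (!is.null(res$sweep)) {
    agg <- do.call(rbind, lapply(split(res$sweep,
                                       res$sweep[c("condition", "layer")]),
                                 function(d) {
      base <- d$performance[d$beta == 0]
      data.frame(condition = d$condition[1], layer = d$layer[1],
                 baseline = base, best = max(d$performance),
                 delta = max(d$performance) - base)
    }))
    rownames(agg) <- NULL
    cat("\nPerformance deltas (best beta vs beta = 0):\n")
    print(agg, row.names = FALSE)
    out$performance <- agg
  } else cat("\n  sweep: skipped\n")
  if (!is.null(res$ratio_fits)) {
    cat("\nFSGM ratio fits (medians across maps):\n")
    print(res$ratio_fits, row.names = FALSE)
    out$ratio_fits <- res$ratio_fits
  } else cat("  ratios: skipped\n")
  if (!is.null(res$tg_cor)) {
    cat("\nTuning-gradient correlation by layer:\n")
    print(res$tg_cor, row.names = FALSE)
    out$tg_cor <- res$tg_cor
  } else cat("  gradients: skipped\n")
  invisible(out)
}
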