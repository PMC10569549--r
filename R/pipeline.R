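#' Published honey-bee cohort summary statistics
#'
#' The printed summary of total brain and neuropil volumes of 110 forager
#' honey bees (mean, s.d., min, max, percent variation, relative volumes and
#' hive F-tests), shipped with the package for recomputation checks and for
#' parameterizing the generator presets.
#'
#' @return data.frame with columns region, side, mean, sd, min, max,
#'   pct_variation, rel_mean, rel_sd, F_value, p_printed.
#' @export
honeybee_reference_summary <- function() {
  utils::read.csv(system.file("extdata", "honeybee_cohort_summary.csv",
                              package = "hivemorph"),
                  stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts.
#' @param profile network profile name (see [net_profile()]).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_train,n_val,n_test phantom counts per split.
#' @param phantom a [phantom_params()]; grid defaults to the profile's
#'   working shape.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "preprocess", "train", "predict", "postprocess",
#'   "evaluate", "stats")`.
#' @param denoise apply the 3x3x3 mean filter before training/inference.
#' @param write_volumes write phantom volumes and predictions as NRRD.
#' @param net optional [net_config()] overriding the profile.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("hivemorph_run_"),
                            profile = "micro", seed = 1L,
                            n_train = 4, n_val = 1, n_test = 2,
                            phantom = NULL,
                            stages = c("simulate", "preprocess", "train",
                                       "predict", "postprocess", "evaluate",
                                       "stats"),
                            denoise = TRUE, write_volumes = FALSE,
                            net = NULL) {
  known <- c("simulate", "preprocess", "train", "predict", "postprocess",
             "evaluate", "stats")
  if (!all(stages %in% known))
    stop("pipeline_config: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  if (is.null(net)) net <- net_profile(profile, seed = seed)
  if (is.null(phantom))
    phantom <- phantom_params(grid_shape = net$scaled_shape, seed = seed)
  structure(list(out_dir = out_dir, profile = profile, seed = as.integer(seed),
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 phantom = phantom, stages = stages, denoise = denoise,
                 write_volumes = write_volumes, net = net),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(
    list(profile = cfg$profile, seed = cfg$seed, n_train = cfg$n_train,
         n_val = cfg$n_val, n_test = cfg$n_test, stages = cfg$stages,
         denoise = cfg$denoise,
         phantom = cfg$phantom[setdiff(names(cfg$phantom), "tissue_gray")],
         net = cfg$net[c("patch_size", "stride", "scaled_shape",
                         "base_channels", "max_channels", "epochs",
                         "batch_size", "learning_rate")]),
    f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the end-to-end phantom pipeline
#'
#' Executes the enabled stages in order: cohort simulation and phantom
#' rendering, denoising, network training, inference on the held-out test
#' phantoms, island cleanup + left/right splitting + volume measurement,
#' Dice/ASSD evaluation against the ground-truth labels, and cohort
#' statistics on the measured specimen table. All artifacts, the seed and a
#' config hash go to `cfg$out_dir`; the returned summary is written as
#' `summary.json` and is identical across runs with the same config.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  summary <- list(seed = cfg$seed, profile = cfg$profile,
                  config_hash = config_hash(cfg))
  stage_on <- function(s) s %in% cfg$stages
  n_total <- cfg$n_train + cfg$n_val + cfg$n_test

  phantoms <- NULL; cohort <- NULL
  if (stage_on("simulate")) {
    say("simulate: %d phantoms on %s grid", n_total,
        paste(cfg$phantom$grid_shape, collapse = "x"))
    plan <- c(H1 = n_total)
    cohort <- sample_cohort(cfg$phantom, hive_plan = plan, seed = cfg$seed)
    phantoms <- lapply(seq_len(n_total), function(i)
      render_phantom(cohort[i, ], cfg$phantom, seed = cfg$seed + i))
    cohort_to_table(cohort, file.path(cfg$out_dir, "cohort.csv"))
    if (cfg$write_volumes) {
      for (i in seq_len(n_total)) {
        write_nrrd(phantoms[[i]]$image,
                   file.path(cfg$out_dir, sprintf("phantom_%02d.nrrd", i)))
        write_nrrd(phantoms[[i]]$labels,
                   file.path(cfg$out_dir, sprintf("phantom_%02d_labels.nrrd", i)))
      }
    }
    summary$n_phantoms <- n_total
  }
  if (is.null(phantoms))
    stop("run_pipeline: later stages need 'simulate' (external inputs go ",
         "through the module functions directly)")

  pairs <- lapply(phantoms, function(p) list(image = p$image, labels = p$labels))
  if (stage_on("preprocess") && cfg$denoise) {
    say("preprocess: mean-filter denoising")
    pairs <- lapply(pairs, function(p) {
      p$image <- denoise_mean3(p$image); p
    })
  }
  idx_train <- seq_len(cfg$n_train)
  idx_val <- cfg$n_train + seq_len(cfg$n_val)
  idx_test <- cfg$n_train + cfg$n_val + seq_len(cfg$n_test)

  model <- NULL
  if (stage_on("train")) {
    say("train: %d epochs on %d phantoms", cfg$net$epochs, cfg$n_train)
    model <- train_unet(pairs[idx_train], pairs[idx_val], cfg$net)
    utils::write.csv(model$history, file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
    summary$best_epoch <- model$best_epoch
    summary$best_val_dice <- max(model$history$val_dice, na.rm = TRUE)
  }

  preds <- NULL
  if (stage_on("predict")) {
    if (is.null(model)) stop("run_pipeline: predict: model not found")
    say("predict: %d test phantoms", length(idx_test))
    preds <- lapply(idx_test, function(i) predict_volume(model, pairs[[i]]$image))
  }

  records <- NULL
  if (stage_on("postprocess")) {
    if (is.null(preds)) stop("run_pipeline: postprocess: predictions not found")
    say("postprocess: islands + left/right + morphometry")
    records <- do.call(rbind, lapply(seq_along(preds), function(j) {
      clean <- remove_islands(preds[[j]])
      measure_volumes(clean, meta = cohort[idx_test[j], ])
    }))
    utils::write.csv(records, file.path(cfg$out_dir, "specimens.csv"),
                     row.names = FALSE)
  }

  if (stage_on("evaluate")) {
    if (is.null(preds)) stop("run_pipeline: evaluate: predictions not found")
    evs <- lapply(seq_along(preds), function(j)
      evaluate_segmentation(preds[[j]], pairs[[idx_test[j]]]$labels))
    ev_tab <- data.frame(
      specimen = cohort$specimen[idx_test],
      total_dice = vapply(evs, `[[`, numeric(1), "total_dice"),
      total_assd = vapply(evs, `[[`, numeric(1), "total_assd"),
      error_pct = vapply(evs, `[[`, numeric(1), "error_pct"),
      category = vapply(evs, `[[`, character(1), "category"))
    utils::write.csv(ev_tab, file.path(cfg$out_dir, "evaluation.csv"),
                     row.names = FALSE)
    summary$mean_test_dice <- mean(ev_tab$total_dice)
    summary$mean_test_assd <- mean(ev_tab$total_assd)
  }

  if (stage_on("stats")) {
    say("stats: cohort statistics")
    tab <- cohort_to_table(cohort)
    stats_out <- list(
      pct_variation_total = percent_variation(tab$total),
      allometry_MB = allometric_slope(tab$total, tab$MB)[c("slope", "isometric")],
      lateralization_OL = unclass(lateralization_test(tab, "OL"))[
        c("value", "p", "pct_smaller_left", "n_used")]
    )
    jsonlite::write_json(stats_out, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$stats <- stats_out
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("config_hash: %s", summary$config_hash),
               sprintf("stages: %s", paste(cfg$stages, collapse = ","))),
             file.path(cfg$out_dir, "run.log"))
  invisible(summary)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may carry any [pipeline_config()] field plus nested `phantom`
#' (fields of [phantom_params()]) and `net` (fields of [net_config()])
#' sections.
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", tolower(path))) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  devec <- function(x) if (is.list(x)) unlist(x) else x
  args <- raw[setdiff(names(raw), c("phantom", "net"))]
  if (!is.null(raw$phantom))
    args$phantom <- do.call(phantom_params, lapply(raw$phantom, devec))
  if (!is.null(raw$net)) args$net <- do.call(net_config, lapply(raw$net, devec))
  do.call(pipeline_config, args)
}
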