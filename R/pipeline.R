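#' Assemble a pipeline run configuration
#'
#' A run configuration collects the seeds, the acquisition/grid/phantom
#' specifications, the stage hyperparameters and the output directory for
#' [run_pipeline()]. It can be built from a YAML file or an R list; missing
#' fields take the package defaults.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Object of class `mrf_run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  defaults <- list(
    seed = 1L,
    out_dir = "mrfepi-run",
    schedule = list(),            # make_schedule() arguments
    grid = list(),                # grid_spec() arguments
    phantom = list(enabled = TRUE),  # phantom_spec() arguments (or stack paths)
    stack_path = NULL, mask_path = NULL,
    noise = list(model = "gaussian", target_snr_db = 21.78),
    split = list(type = "increment", interval = 2L),
    stage1 = list(),              # stage1_config() + spec overrides
    stage1_spec = list(),         # denoiser_spec() arguments
    stage2 = list(),              # stage2_config() arguments
    stage2_spec = list()          # regressor_spec() arguments
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "mrf_run_config")
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

write_manifest <- function(cfg, stage, path, extra = list()) {
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     config_hash = config_hash(cfg),
                     package_version = as.character(utils::packageVersion("mrfepi"))),
                extra)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

pipeline_paths <- function(cfg) {
  d <- cfg$out_dir
  list(
    dict = file.path(d, "dictionary.h5"),
    noise = file.path(d, "noise_bank.h5"),
    denoiser = file.path(d, "denoiser.h5"),
    regressor = file.path(d, "regressor.rds"),
    stack = file.path(d, "stack.nii.gz"),
    mask = file.path(d, "mask.nii.gz"),
    maps_prefix = file.path(d, "predicted"),
    matched_prefix = file.path(d, "matched"),
    eval_csv = file.path(d, "evaluation.csv"),
    phantom = file.path(d, "phantom.rds")
  )
}

require_artifact <- function(path, what, producer) {
  if (!file.exists(path)) {
    abort(sprintf(
      "missing prerequisite artifact for this stage: %s (expected at '%s'; run stage '%s' first).",
      what, path, producer
    ))
  }
  invisible(path)
}

#' Run the MRF-EPI pipeline end to end
#'
#' Executes the requested stages in order, each reading its inputs from and
#' writing its outputs (with a JSON manifest: stage, seed, config hash) to
#' `config$out_dir`:
#'
#' * `"simulate-dict"`: build the dictionary from the schedule and grid.
#' * `"make-phantom"`: generate the digital phantom and render the noisy
#'   baseline stack (skipped automatically when `stack_path` points at real
#'   data, which is copied in instead).
#' * `"match"`: inner-product matching of the stack, written as maps.
#' * `"extract-noise"`: residual noise bank + SNR map from the stack.
#' * `"train-denoiser"`: stage-I training on dictionary + bank.
#' * `"train-regressor"`: stage-II training on the configured split.
#' * `"predict"`: two-stage parametric maps for the stack.
#' * `"evaluate"`: agreement report of predicted vs matched maps
#'   (vs phantom ground truth when available), written as CSV.
#'
#' Reruns with an identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param config An `mrf_run_config`, list, or YAML path.
#' @param stages Character vector, ordered subset of the stages above;
#'   `"all"` runs the full sequence.
#' @param quiet Suppress per-stage progress messages.
#' @return Named list of artifact paths produced, invisibly.
#' @export
run_pipeline <- function(config, stages = "all", quiet = FALSE) {
  cfg <- if (inherits(config, "mrf_run_config")) config else run_config(config)
  all_stages <- c("simulate-dict", "make-phantom", "match", "extract-noise",
                  "train-denoiser", "train-regressor", "predict", "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  schedule <- do.call(make_schedule, cfg$schedule)
  grid <- do.call(grid_spec, cfg$grid)

  for (stage in stages) {
    ts <- Sys.time()
    switch(stage,
      "simulate-dict" = {
        dict <- generate_dictionary(schedule, grid)
        write_dictionary(dict, paths$dict)
        write_manifest(cfg, stage, paths$dict, list(entries = nrow(dict$params)))
      },
      "make-phantom" = {
        if (!is.null(cfg$stack_path)) {
          file.copy(cfg$stack_path, paths$stack, overwrite = TRUE)
          if (!is.null(cfg$mask_path)) {
            file.copy(cfg$mask_path, paths$mask, overwrite = TRUE)
          }
        } else {
          ph_args <- cfg$phantom; ph_args$enabled <- NULL
          ph_args$seed <- ph_args$seed %||% derive_seed(cfg$seed, 21L)
          phantom <- make_phantom(do.call(phantom_spec, ph_args))
          saveRDS(phantom, paths$phantom)
          stack <- render_stack(
            phantom, schedule, noise = cfg$noise$model,
            target_snr_db = cfg$noise$target_snr_db,
            seed = derive_seed(cfg$seed, 22L)
          )
          write_stack_nifti(stack, paths$stack, mask_path = paths$mask)
        }
        write_manifest(cfg, stage, paths$stack)
      },
      "match" = {
        require_artifact(paths$dict, "dictionary", "simulate-dict")
        require_artifact(paths$stack, "baseline stack", "make-phantom")
        dict <- read_dictionary(paths$dict)
        stack <- read_stack_nifti(paths$stack, paths$mask)
        matched <- match_stack(stack, dict)
        write_maps_nifti(matched, paths$matched_prefix)
        write_manifest(cfg, stage, paths$matched_prefix,
                       list(n_unmatched = matched$n_unmatched))
      },
      "extract-noise" = {
        require_artifact(paths$dict, "dictionary", "simulate-dict")
        require_artifact(paths$stack, "baseline stack", "make-phantom")
        dict <- read_dictionary(paths$dict)
        stack <- read_stack_nifti(paths$stack, paths$mask)
        nb <- extract_noise_bank(stack, dict)
        write_noise_bank(nb$bank, paths$noise)
        write_manifest(cfg, stage, paths$noise,
                       list(n_residuals = nrow(nb$bank$residuals),
                            median_snr_db = median(nb$snr_map[stack$brain_mask != 0])))
      },
      "train-denoiser" = {
        require_artifact(paths$dict, "dictionary", "simulate-dict")
        require_artifact(paths$noise, "noise bank", "extract-noise")
        dict <- read_dictionary(paths$dict)
        bank <- read_noise_bank(paths$noise)
        s1cfg <- do.call(stage1_config,
                         utils::modifyList(list(seed = derive_seed(cfg$seed, 31L)),
                                           cfg$stage1))
        s1spec <- do.call(denoiser_spec, cfg$stage1_spec)
        den <- train_denoiser(dict, bank, s1cfg, s1spec, quiet = TRUE)
        write_denoiser(den, paths$denoiser)
        write_manifest(cfg, stage, paths$denoiser,
                       list(best_epoch = den$best_epoch))
      },
      "train-regressor" = {
        require_artifact(paths$dict, "dictionary", "simulate-dict")
        dict <- read_dictionary(paths$dict)
        split <- switch(cfg$split$type,
          increment = split_by_increment(dict, cfg$split$interval),
          range = split_by_range(dict,
                                 cfg$split$t1_train %||% c(500, 2500),
                                 cfg$split$t2s_train %||% c(50, 1500)),
          abort("`split$type` must be 'increment' or 'range'.")
        )
        s2cfg <- do.call(stage2_config,
                         utils::modifyList(list(seed = derive_seed(cfg$seed, 32L)),
                                           cfg$stage2))
        s2spec <- do.call(regressor_spec, cfg$stage2_spec)
        reg <- train_regressor(dict, split, s2spec, s2cfg)
        saveRDS(reg, paths$regressor)
        write_manifest(cfg, stage, paths$regressor,
                       list(best_epoch = reg$best_epoch,
                            variant = s2spec$variant))
      },
      "predict" = {
        require_artifact(paths$regressor, "stage-II checkpoint", "train-regressor")
        require_artifact(paths$stack, "baseline stack", "make-phantom")
        require_artifact(paths$denoiser, "stage-I checkpoint", "train-denoiser")
        den <- read_denoiser(paths$denoiser)
        reg <- readRDS(paths$regressor)
        stack <- read_stack_nifti(paths$stack, paths$mask)
        maps <- predict_two_stage(den, reg, stack)
        write_maps_nifti(maps, paths$maps_prefix)
        write_manifest(cfg, stage, paths$maps_prefix)
      },
      "evaluate" = {
        require_artifact(paste0(paths$maps_prefix, "_t1.nii.gz"),
                         "predicted maps", "predict")
        require_artifact(paste0(paths$matched_prefix, "_t1.nii.gz"),
                         "matched maps", "match")
        predicted <- read_maps_nifti(paste0(paths$maps_prefix, "_t1.nii.gz"),
                                     paste0(paths$maps_prefix, "_t2s.nii.gz"))
        reference <- read_maps_nifti(paste0(paths$matched_prefix, "_t1.nii.gz"),
                                     paste0(paths$matched_prefix, "_t2s.nii.gz"))
        masks <- if (file.exists(paths$phantom)) {
          phantom_masks(readRDS(paths$phantom))
        } else {
          list(brain = read_mask_nifti(paths$mask))
        }
        report <- evaluate_maps(reference, predicted, masks)
        write_eval_csv(report, paths$eval_csv)
        write_manifest(cfg, stage, paths$eval_csv)
      }
    )
    say("[%s] done in %.1fs", stage,
        as.numeric(difftime(Sys.time(), ts, units = "secs")))
  }
  say("pipeline finished in %.1fs",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(paths)
}
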