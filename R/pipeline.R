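#' Package and provenance information
#'
#' Version, configuration hash and seed, echoed into every run manifest so
#' any artifact on disk is reproducible from its manifest alone.
#'
#' @param config Optional configuration list to hash.
#' @param seed Optional seed to record.
#' @return List with `package`, `version`, `config_hash`, `seed`,
#'   `timestamp`.
#' @export
version_info <- function(config = NULL, seed = NULL) {
  list(
    package = "tissuegan",
    version = as.character(utils::packageVersion("tissuegan")),
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Hash a configuration
#'
#' Double polynomial rolling hash of the canonical JSON serialization;
#' stable across sessions and sensitive to any value change.
#'
#' @param config Any JSON-serializable list.
#' @return 16-character hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h1 <- 17; h2 <- 40389
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 65599 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

# Per-stage seed derived from the global seed and the stage name, keeping
# RNG streams of different stages decoupled (kept below 2^31).
stage_seed <- function(seed, stage) {
  bytes <- utf8ToInt(stage)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full virtual-staining workflow end to end
#'
#' Desk-scale orchestration of every stage on a synthetic phantom:
#' generate the phantom, assemble unpaired patch training sets
#' (membrane as domain A, a target structure channel as domain B),
#' train the translation model, predict the target channel for the whole
#' volume, evaluate the prediction cube-wise against the ground-truth
#' channel, and run morphometry on the prediction. Writes all artifacts
#' plus a manifest capturing versions, seeds, configuration and paths.
#'
#' @param out_dir Output directory.
#' @param phantom_cfg A [phantom_config()] (default: a small demo phantom).
#' @param train_cfg A [train_config()] (default: a 2-epoch smoke setting).
#' @param target Channel to predict from the membrane (default `"bc"`).
#' @param patch_size,n_patches 2D patch edge and per-domain patch count.
#' @param gen_spec,disc_spec Architecture strings (defaults: reduced
#'   desk-scale layouts).
#' @param cube_edge Cube edge for the metric report.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param verbose Progress messages.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
run_end_to_end <- function(out_dir,
                           phantom_cfg = phantom_config(shape = c(64, 64, 64),
                                                        n_cells = 12,
                                                        attenuation_depth = 60),
                           train_cfg = train_config(epochs = 2, seed = 1L),
                           target = "bc",
                           patch_size = 32L, n_patches = 8L,
                           gen_spec = "c7s1-8, d16, R16 (x2), u8, c7s1-1",
                           disc_spec = "C8, C16, F1",
                           cube_edge = 32L,
                           seed = 1L, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[tissuegan] ", ...)
  stages <- character(0)
  run_stage <- function(name, fun) {
    say("stage: ", name)
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  phantom_cfg$seed <- stage_seed(seed, "phantom")
  phantom <- run_stage("phantom", function() {
    ph <- generate_phantom(phantom_cfg)
    write_phantom(ph, file.path(out_dir, "phantom"))
    ph
  })

  pats <- run_stage("datapipe", function() {
    vs <- phantom_cfg$voxel_size
    volA <- normalize(as_volume(phantom$channels$membrane, vs, "membrane"))
    volB <- normalize(as_volume(phantom$channels[[target]], vs, target))
    sA <- extract_patches_2d(volA, size = patch_size, n_per_image = n_patches,
                             seed = stage_seed(seed, "patchesA"), domain = "A")
    sB <- extract_patches_2d(volB, size = patch_size, n_per_image = n_patches,
                             seed = stage_seed(seed, "patchesB"), domain = "B")
    list(A = sA, B = sB, volA = volA, volB = volB)
  })

  fit <- run_stage("train", function() {
    cfg <- train_cfg
    cfg$seed <- stage_seed(seed, "train")
    train_unpaired(cfg, pats$A, pats$B, gen_spec = gen_spec,
                   disc_spec = disc_spec, dims = 2L,
                   checkpoint_dir = file.path(out_dir, "checkpoints"))
  })

  pred <- run_stage("predict", function() {
    pv <- predict_volume(fit$G_AB, pats$volA, tiling_plan(patch_size, 0.5))
    write_stack(pv, file.path(out_dir, "prediction.tif"))
    pv
  })

  report <- run_stage("evaluate", function() {
    part <- partition_cubes(pats$volB$data, edge = cube_edge)
    rep <- evaluate_cubewise(pred$data, pats$volB$data, part)
    utils::write.csv(rep, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(summary(rep), file.path(out_dir, "metrics_summary.json"),
                         digits = NA)
    rep
  })

  morpho <- run_stage("morpho", function() {
    m <- morphometry(denormalize(pred)$data, phantom_cfg$voxel_size,
                     lobule_axis = phantom$truth$lobule_axis)
    out <- list(
      mean_radius_um = if (!is.null(m$radius)) m$radius$mean_radius_um else NA,
      mean_branch_length_um = if (!is.null(m$branch_length))
        m$branch_length$mean_length_um else NA,
      n_branches = if (!is.null(m$branch_length)) m$branch_length$n_branches else 0
    )
    jsonlite::write_json(out, file.path(out_dir, "morphometry.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  cfg_all <- list(phantom = unclass(phantom_cfg), train = unclass(train_cfg),
                  target = target, patch_size = patch_size,
                  n_patches = n_patches, gen_spec = gen_spec,
                  disc_spec = disc_spec, cube_edge = cube_edge, seed = seed)
  manifest <- list(
    info = version_info(cfg_all, seed),
    stages = stages,
    config = cfg_all,
    outputs = list(
      phantom = file.path(out_dir, "phantom"),
      checkpoints = file.path(out_dir, "checkpoints"),
      prediction = file.path(out_dir, "prediction.tif"),
      metrics = file.path(out_dir, "metrics.csv"),
      morphometry = file.path(out_dir, "morphometry.json")
    ),
    results = list(
      median_ssim = median(report$SSIM),
      median_mse = median(report$MSE),
      morphometry = morpho
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: ", length(stages), " stages -> ", out_dir)
  invisible(manifest)
}

#' Validate a run configuration list
#'
#' Strict schema check for configurations read from YAML: unknown keys are
#' rejected by name, required blocks are type-checked.
#'
#' @param config Named list (e.g. from [yaml::read_yaml()]).
#' @return The validated config, invisibly; errors name the offending key.
#' @export
validate_run_config <- function(config) {
  known <- c("phantom", "train", "target", "patch_size", "n_patches",
             "gen_spec", "disc_spec", "cube_edge", "seed", "out_dir",
             "log_level")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(config$phantom)) {
    pk <- setdiff(names(config$phantom), names(formals(phantom_config)))
    if (length(pk)) stop("unknown phantom key(s): ", paste(pk, collapse = ", "))
  }
  if (!is.null(config$train)) {
    tk <- setdiff(names(config$train), names(formals(train_config)))
    if (length(tk)) stop("unknown train key(s): ", paste(tk, collapse = ", "))
  }
  invisible(config)
}
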