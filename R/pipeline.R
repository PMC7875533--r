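# Unified stage runner: validated configs, seeded runs, atomic outputs and a
# JSON manifest so every analysis stage is reproducible from a single config.

stage_schemas <- list(
  synth = list(required = c("generator"),
               optional = c("args")),
  simulate = list(required = c("n_beads"),
                  optional = c("valence", "n_steps", "binding_energy",
                               "excluded_volume", "snapshot_every",
                               "bead_density")),
  scaling = list(required = c("input"),
                 optional = c("piecewise")),
  hic = list(required = c("n_beads", "valence"),
             optional = c("n_steps", "block_beads", "r_c_nm",
                          "binding_energy")),
  traces = list(required = c("op", "input"),
                optional = c("kind", "savgol_window", "savgol_order",
                             "genome_kbp", "threshold")),
  morphology = list(required = c("op", "input"),
                    optional = c("min_height", "k", "flatten_order"))
)

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$stage))
    stop("run_stage: config field 'stage' is missing")
  if (!config$stage %in% names(stage_schemas))
    stop("run_stage: unknown stage '", config$stage, "' (field 'stage'; ",
         "must be one of ", paste(names(stage_schemas), collapse = ", "), ")")
  if (is.null(config$output_dir))
    stop("run_stage: config field 'output_dir' is missing")
  if (is.null(config$seed)) stop("run_stage: config field 'seed' is missing")
  sch <- stage_schemas[[config$stage]]
  params <- config$params
  missing <- setdiff(sch$required, names(params))
  if (length(missing) > 0)
    stop("run_stage: stage '", config$stage, "' is missing required field(s) ",
         paste0("params$", missing, collapse = ", "))
  unknown <- setdiff(names(params), c(sch$required, sch$optional))
  if (length(unknown) > 0)
    stop("run_stage: stage '", config$stage, "' has unknown field(s) ",
         paste0("params$", unknown, collapse = ", "))
  config
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run a pipeline stage from a config
#'
#' Validates the config against the stage schema (unknown stages or fields
#' fail with a named-field error before any computation), seeds the RNG, runs
#' the stage, and writes its artifacts plus a JSON run manifest (resolved
#' config, seed, wall time, package version) into `output_dir`. Artifacts are
#' written to temporaries and renamed into place, so a failed run leaves no
#' partial outputs at the final paths; inputs are never mutated. Deterministic
#' stages rerun bit-identically from the same config.
#'
#' Stages: `synth` (any `gen_*` generator), `simulate`, `scaling`, `hic`,
#' `traces` (op: compaction | frap | dissociation | steps), `morphology`
#' (op: circularity | grains | diameter).
#'
#' @param config named list or path to a YAML file with fields `stage`,
#'   `seed`, `output_dir` and stage-specific `params`.
#' @return invisibly, a list with the manifest and artifact paths.
#' @export
run_stage <- function(config) {
  config <- validate_config(config)
  t0 <- Sys.time()
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  p <- config$params
  out <- list()

  if (config$stage == "synth") {
    gen <- get(p$generator, envir = asNamespace("bipsim"))
    args <- if (is.null(p$args)) list() else p$args
    args$seed <- config$seed
    res <- do.call(gen, args)
    if (!is.null(res$trace)) {
      path <- file.path(config$output_dir, "trace.tsv")
      tmp <- paste0(path, ".tmp")
      write_trace(res$trace, tmp)
      file.rename(tmp, path)
      out$trace <- path
    }
    if (!is.null(res$kymo)) {
      path <- file.path(config$output_dir, "kymograph.tif")
      write_image_tiff(res$kymo$mat, path,
                       list(pixel_size_um = res$kymo$pixel_size,
                            frame_interval_s = res$kymo$frame_interval,
                            seed = config$seed))
      out$kymograph <- path
    }
    if (!is.null(res$image)) {
      path <- file.path(config$output_dir, "image.tif")
      write_image_tiff(res$image$mat, path,
                       list(pixel_size_um = res$image$pixel_size_um,
                            seed = config$seed))
      out$image <- path
    }
    if (!is.null(res$map) && inherits(res$map, "afm_heightmap")) {
      path <- file.path(config$output_dir, "heightmap.tif")
      write_image_tiff(res$map$mat, path,
                       list(pixel_size_nm = res$map$pixel_size_nm,
                            seed = config$seed))
      out$heightmap <- path
    }
    truth <- res$truth
    truth$clean_kymo <- NULL
    out$truth <- write_json_atomic(truth,
                                   file.path(config$output_dir, "truth.json"))
  } else if (config$stage == "simulate") {
    chain <- chain_config(p$n_beads)
    br <- if (is.null(p$valence)) NULL else
      bridge_config(p$valence,
                    binding_energy = p$binding_energy %||% 4)
    params <- sim_params(
      n_steps = p$n_steps %||% 1e4,
      snapshot_every = p$snapshot_every %||% max(1, (p$n_steps %||% 1e4) / 10),
      bead_density = p$bead_density %||% 0.012,
      seed = config$seed)
    traj <- simulate_bips(chain, br, params,
                          excluded_volume = p$excluded_volume %||% TRUE)
    path <- file.path(config$output_dir, "trajectory.xyz")
    tmp <- paste0(path, ".tmp")
    write_trajectory_xyz(traj, tmp)
    file.rename(paste0(tmp, ".bonds.tsv"), paste0(path, ".bonds.tsv"))
    file.rename(tmp, path)
    out$trajectory <- path
  } else if (config$stage == "scaling") {
    df <- read.table(p$input, header = TRUE, sep = "\t")
    fit <- if (isTRUE(p$piecewise))
      piecewise_scaling_fit(df$length_bp, df$rg_nm) else
      fit_power_law(df$length_bp, df$rg_nm)
    med <- stats::aggregate(rg_nm ~ length_bp, data = df, FUN = median)
    mpath <- file.path(config$output_dir, "medians.tsv")
    tmp <- paste0(mpath, ".tmp")
    write.table(med, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, mpath)
    out$medians <- mpath
    out$fit <- write_json_atomic(
      list(alpha = fit$alpha, alpha_sd = fit$alpha_sd,
           prefactor = fit$prefactor, breakpoint_bp = fit$breakpoint_bp,
           fallback = fit$fallback),
      file.path(config$output_dir, "fit.json"))
  } else if (config$stage == "hic") {
    block <- p$block_beads %||% 20
    chain <- chain_config(p$n_beads,
                          bindable = rep(c(TRUE, FALSE), each = block,
                                         length.out = p$n_beads))
    br <- bridge_config(p$valence, binding_energy = p$binding_energy %||% 4)
    params <- sim_params(n_steps = p$n_steps %||% 1e5,
                         snapshot_every = max(1, (p$n_steps %||% 1e5) / 50),
                         seed = config$seed)
    traj <- simulate_bips(chain, br, params)
    map <- aggregate_map(traj, r_c_nm = p$r_c_nm %||% 25)
    path <- file.path(config$output_dir, "contact_map.tsv")
    tmp <- paste0(path, ".tmp")
    write_contact_map(map, tmp)
    file.rename(paste0(tmp, ".json"), paste0(path, ".json"))
    file.rename(tmp, path)
    out$map <- path
    out$score <- write_json_atomic(
      list(compartment_strength = compartment_strength(map)),
      file.path(config$output_dir, "score.json"))
  } else if (config$stage == "traces") {
    tr <- read_trace(p$input)
    rep <- switch(p$op,
      compaction = list(
        compaction_time_s = compaction_time(
          tr, p$savgol_window %||% 250, p$savgol_order %||% 2)),
      frap = {
        f <- fit_exponential(tr, "recovery")
        list(tau_s = f$tau, tau_sd_s = f$tau_sd, amplitude = f$amplitude,
             baseline = f$baseline)
      },
      dissociation = {
        f <- fit_exponential(tr, "decay")
        list(tau_s = f$tau, tau_sd_s = f$tau_sd, amplitude = f$amplitude,
             baseline = f$baseline)
      },
      steps = {
        s <- find_steps(tr, threshold = p$threshold %||% 1.5)
        list(n_steps = length(s$step_sizes), step_times_s = s$step_times,
             step_sizes = s$step_sizes, levels = s$levels)
      },
      stop("run_stage: unknown traces op '", p$op, "' (field params$op)"))
    out$report <- write_json_atomic(rep,
                                    file.path(config$output_dir, "report.json"))
  } else if (config$stage == "morphology") {
    img <- read_image_tiff(p$input)
    rep <- switch(p$op,
      circularity = {
        im <- bips_image(img$mat, img$meta$pixel_size_um %||% 1)
        list(circularity = circularity(droplet_mask(im)))
      },
      diameter = {
        im <- bips_image(img$mat, img$meta$pixel_size_um %||% 1)
        list(diameter_um = as.numeric(gaussian_diameter(im)))
      },
      grains = {
        hm <- afm_heightmap(img$mat, img$meta$pixel_size_nm %||% 1)
        hm <- afm_flatten(hm, order = p$flatten_order %||% 1)
        gs <- grain_volumes(hm, p$min_height)
        list(n_grains = nrow(gs), volumes_nm3 = gs$volume_nm3,
             threshold_nm = attr(gs, "min_height"))
      },
      stop("run_stage: unknown morphology op '", p$op, "' (field params$op)"))
    out$report <- write_json_atomic(rep,
                                    file.path(config$output_dir, "report.json"))
  }

  manifest <- list(
    stage = config$stage, seed = config$seed,
    params = config$params, artifacts = out[names(out) != "truth"],
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("bipsim")))
  write_json_atomic(manifest, file.path(config$output_dir, "manifest.json"))
  invisible(list(manifest = manifest, artifacts = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
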