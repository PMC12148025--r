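# Stack I/O with JSON metadata sidecars, run configuration, and the
# end-to-end synthetic benchmark pipeline.

#' Write an image stack as multi-page 16-bit TIFF with a metadata sidecar
#'
#' Counts are rounded, clipped to `[0, 65535]` and stored as 16-bit
#' grayscale. Acquisition metadata (pixel size, frame interval, exposure,
#' and any extra scene parameters) is written to `<path>.json` — TIFF tag
#' dialects vary between writers, so the sidecar is the authoritative
#' metadata source.
#'
#' @param stack Numeric array `[y, x, frame]` of counts.
#' @param path Output TIFF path.
#' @param metadata Named list; must include `pixel_size_nm`,
#'   `frame_interval_s`, `exposure_s`. Extra fields (e.g. `seed`, scene
#'   parameters) are preserved.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata) {
  stopifnot(length(dim(stack)) == 3L)
  validate_stack_metadata(metadata)
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(round(stack[, , f]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

validate_stack_metadata <- function(metadata) {
  required <- c("pixel_size_nm", "frame_interval_s", "exposure_s")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    stop("stack metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  if (metadata$pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (metadata$exposure_s <= 0) stop("exposure_s must be positive")
  if (metadata$frame_interval_s < metadata$exposure_s) {
    stop("frame_interval_s must be at least exposure_s")
  }
  invisible(metadata)
}

#' Read an image stack and its metadata sidecar
#'
#' Reads a multi-page grayscale TIFF back into a counts array, bit depth
#' preserved (a 16-bit file written by [write_stack()] round-trips
#' bit-identically). Metadata comes from the `<path>.json` sidecar unless
#' supplied directly.
#'
#' @param path TIFF path.
#' @param metadata Optional named list overriding the sidecar.
#' @return List with `stack` (numeric array `[y, x, frame]`, counts) and
#'   `metadata` (validated list; also usable to build an [optics_model()]
#'   via [optics_from_metadata()]).
#' @export
read_stack <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("not a readable grayscale TIFF (", path, "): ",
                             conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) != 2L, logical(1)))) {
    stop("RGB or multi-channel TIFF not supported; expected grayscale")
  }
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  for (f in seq_along(frames)) stack[, , f] <- frames[[f]]
  if (is.null(metadata)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("metadata sidecar not found: ", sidecar,
           " (pass metadata explicitly if there is no sidecar)")
    }
    metadata <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  validate_stack_metadata(metadata)
  list(stack = stack, metadata = metadata)
}

#' @rdname read_stack
#' @details `optics_from_metadata()` builds an [optics_model()] from sidecar
#'   metadata, defaulting the PSF FWHM to 200 nm and blur substeps to 10 when
#'   the sidecar does not record them.
#' @export
optics_from_metadata <- function(metadata) {
  validate_stack_metadata(metadata)
  optics_model(
    pixel_size = metadata$pixel_size_nm,
    psf_fwhm = if (!is.null(metadata$psf_fwhm_nm)) metadata$psf_fwhm_nm else 200,
    exposure = metadata$exposure_s,
    frame_interval = metadata$frame_interval_s,
    n_blur_substeps = if (!is.null(metadata$n_blur_substeps))
      metadata$n_blur_substeps else 10L)
}

#' Read a spot-seed coordinate table
#'
#' CSV with columns `cell_id`, `x_px`, `y_px` (0-based pixel coordinates,
#' pixel-center convention) naming the particles to quantify — the file-based
#' replacement for interactive spot selection.
#'
#' @param path CSV path.
#' @return Data.frame with the three columns.
#' @export
read_seeds <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "x_px", "y_px")
  missing <- setdiff(required, names(s))
  if (length(missing)) {
    stop("seed file is missing column(s): ", paste(missing, collapse = ", "))
  }
  s
}

#' Published benchmark values for common fluorescent proteins
#'
#' Reference table of printed benchmark measurements for FP-tagged nanocage
#' imaging on a spinning-disc system: relative brightness (fold versus the
#' per-channel reference FP — EGFP for green FPs, mCherry for red FPs) and
#' photobleaching half-life in seconds at matched irradiance. `NA` marks
#' values not reported numerically.
#'
#' @return Data.frame with columns `fp`, `channel`, `reference_fp`,
#'   `relative_brightness`, `half_life_s`.
#' @export
fp_reference <- function() {
  path <- system.file("extdata", "fp_reference.csv",
                      package = "nanocagebench", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Jittered-grid placement of n positions in [margin, field - 1 - margin]^2:
# guaranteed separation of one grid cell minus twice the jitter.
place_separated <- function(n, field_size, margin, jitter = 2, seed) {
  set.seed(seed)
  lo <- margin
  hi <- field_size - 1 - margin
  if (hi <= lo) stop("field too small for the requested margin")
  side <- ceiling(sqrt(n))
  centers <- lo + (seq_len(side) - 0.5) * (hi - lo) / side
  cells <- expand.grid(x = centers, y = centers)
  pick <- sample.int(nrow(cells), n)
  cbind(cells$x[pick] + stats::runif(n, -jitter, jitter),
        cells$y[pick] + stats::runif(n, -jitter, jitter))
}

#' Simulate a spinning-disc-style nanocage intensity stack
#'
#' Builds the standard intensity-measurement fixture: `n_cages` slowly
#' diffusing nanocages placed on a jittered grid with guaranteed separation
#' (quantification, like interactive particle selection, assumes isolated
#' spots), rendered over a short stack. The slow default diffusion mimics
#' hyperosmotically slowed cytoplasm.
#'
#' @param cage A [cage_spec()].
#' @param optics An [optics_model()].
#' @param camera A [camera_model()].
#' @param n_cages Number of cages in the field.
#' @param field_size Field side length in pixels.
#' @param diffusion Diffusion coefficient in um^2/s (default 0.002, slowed
#'   motion).
#' @param n_frames Frames to render (default 3, a short focus stack).
#' @param seed Integer seed.
#' @param noise Apply camera noise?
#' @return List with `stack`, `truth` (per-frame ground truth) and `seeds`
#'   (rounded frame-1 positions, ready for [quantify_spots()]).
#' @export
simulate_cage_stack <- function(cage, optics, camera = camera_model(),
                                n_cages = 6L, field_size = 96L,
                                diffusion = 0.002, n_frames = 3L, seed = 1L,
                                noise = TRUE) {
  motion <- motion_spec(diffusion, c(field_size, field_size))
  truth <- simulate_tracks(motion, n_cages, n_frames, optics, seed)
  anchors <- place_separated(n_cages, field_size,
                             margin = 4 * psf_sigma_px(optics),
                             seed = derive_seed(seed, 3L))
  for (p in seq_len(n_cages)) {
    truth$pos[p, , , 1] <- truth$pos[p, , , 1] - truth$pos[p, 1, 1, 1] +
      anchors[p, 1]
    truth$pos[p, , , 2] <- truth$pos[p, , , 2] - truth$pos[p, 1, 1, 2] +
      anchors[p, 2]
  }
  rend <- render_stack(simulation_scene(truth, cage, camera, seed = seed),
                       noise = noise)
  t1 <- rend$truth[rend$truth$frame == 1L, ]
  list(stack = rend$stack, truth = rend$truth,
       seeds = data.frame(cell_id = "cell1", x_px = round(t1$x_px),
                          y_px = round(t1$y_px)))
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    reference_fp = NULL,
    channel = "synthetic_confocal",
    optics = list(pixel_size = 27, psf_fwhm = 200, exposure = 0.5,
                  frame_interval = 0.5, n_blur_substeps = 10L),
    tirf_optics = list(pixel_size = 110, psf_fwhm = 250, exposure = 0.010,
                       frame_interval = 1 / 85, n_blur_substeps = 4L),
    camera = list(offset = 100, read_noise_sd = 1.5, counts_per_photon = 1,
                  max_count = 65535),
    fps = list(),
    simulate = list(n_cells = 3L, n_cages_per_cell = 6L, field_size = 96L,
                    slow_diffusion = 0.002, bleach_frames = 60L,
                    bleach_initial_photons = 40, bleach_mask_size = 32L),
    quantify = list(anisotropy_max = 1.3, sigma_band = c(0.7, 1.6),
                    radius_in_sigmas = 2),
    bleach = list(with_plateau = TRUE),
    track = list(enabled = FALSE, diffusion = 1.0, n_particles = 40L,
                 n_frames = 120L, field_size = 128L),
    compare = list(alpha = 0.05))
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with one section per stage (`optics`, `camera`, `fps`,
#' `simulate`, `quantify`, `bleach`, `track`, `compare`) plus top-level
#' `seed`, `out_dir`, `reference_fp`, `channel`. Unknown keys are rejected so
#' typos cannot silently fall back to defaults; omitted keys take defaults.
#'
#' @param path YAML file, or a named list already in config form.
#' @return Validated config list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(cfg))
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sect in c("optics", "tirf_optics", "camera", "simulate", "quantify",
                 "bleach", "track", "compare")) {
    if (!is.null(cfg[[sect]])) {
      unknown <- setdiff(names(cfg[[sect]]), names(defaults[[sect]]))
      if (length(unknown)) {
        stop(sprintf("unknown key(s) in config section '%s': %s", sect,
                     paste(unknown, collapse = ", ")))
      }
    }
  }
  fps <- cfg$fps          # unnamed list: merge manually, not via modifyList
  cfg$fps <- NULL
  cfg <- utils::modifyList(defaults, cfg)
  cfg$fps <- if (is.null(fps)) list() else fps
  if (length(cfg$fps) == 0L) stop("config must define at least one FP")
  fp_names <- vapply(cfg$fps, function(f) f$name, character(1))
  if (anyDuplicated(fp_names)) stop("duplicate FP names in config")
  if (is.null(cfg$reference_fp)) cfg$reference_fp <- fp_names[1]
  if (!cfg$reference_fp %in% fp_names) {
    stop("reference_fp is not among the configured FPs")
  }
  cfg
}

#' @rdname read_run_config
#' @param config A validated config list.
#' @details `config_hash()` returns the MD5 hash of the canonical JSON
#'   serialization of the config; it stamps every pipeline output so results
#'   are traceable to the exact parameters that produced them. The output
#'   directory is excluded: the same analysis written elsewhere is still the
#'   same analysis.
#' @export
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic FP benchmark pipeline
#'
#' Chains the stages end to end for each configured FP: render short
#' spinning-disc-like stacks of slowly moving nanocages and quantify them
#' (spot fits, 2-sigma disc intensities, per-cell cage-count estimates),
#' simulate and fit whole-cell photobleaching movies, optionally simulate
#' fast TIRF-like tracking data and estimate per-cell diffusion
#' coefficients, and combine everything into an FP comparison table with
#' ANOVA/Tukey statistics. All randomness derives from the master seed, so a
#' rerun with the same config is bit-identical. When `out_dir` is set,
#' outputs are written under `out_dir/<config-hash>/` (a changed config gets
#' a fresh directory and never overwrites earlier results); every CSV carries
#' the config hash and seed in a leading comment line.
#'
#' @param config Path to a YAML config or a config list (see
#'   [read_run_config()]).
#' @return List with `spots`, `cells`, `bleach`, `diffusion` (NULL unless the
#'   tracking stage is enabled), `comparison`, `stats`, `config_hash`,
#'   `out_dir`, `log` (character vector of per-stage messages).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  hash <- config_hash(cfg)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  optics <- do.call(optics_model, cfg$optics)
  tirf <- do.call(optics_model, cfg$tirf_optics)
  camera <- do.call(camera_model, cfg$camera)
  sim <- cfg$simulate
  fp_names <- vapply(cfg$fps, function(f) f$name, character(1))

  spots_all <- list(); cells_all <- list(); bleach_all <- list()
  diff_all <- list()
  for (fi in seq_along(cfg$fps)) {
    fp <- cfg$fps[[fi]]
    cage <- cage_spec(n_fp = fp$n_fp, photons_per_fp = fp$photons_per_fp,
                      bleach_half_life = fp$bleach_half_life)
    for (ci in seq_len(sim$n_cells)) {
      cell_id <- sprintf("%s_cell%02d", fp$name, ci)
      cell_seed <- derive_seed(cfg$seed, 1000L * fi + ci)
      # --- intensity stack: slow (mannitol-like) cages, short stack ---
      rend <- simulate_cage_stack(cage, optics, camera,
                                  n_cages = sim$n_cages_per_cell,
                                  field_size = sim$field_size,
                                  diffusion = sim$slow_diffusion,
                                  seed = cell_seed)
      seeds <- rend$seeds
      seeds$cell_id <- cell_id
      spots <- quantify_spots(rend$stack, seeds, optics,
                              anisotropy_max = cfg$quantify$anisotropy_max,
                              sigma_band = cfg$quantify$sigma_band,
                              radius_in_sigmas = cfg$quantify$radius_in_sigmas)
      spots$fp <- fp$name
      total <- sum(rend$stack[, , 1]) - camera$offset * sim$field_size^2
      cells <- cell_summary(spots, stats::setNames(total, cell_id))
      cells$fp <- fp$name
      spots_all[[length(spots_all) + 1L]] <- spots
      cells_all[[length(cells_all) + 1L]] <- cells
      # --- photobleaching movie ---
      movie <- simulate_bleach_movie(
        c(sim$bleach_mask_size, sim$bleach_mask_size),
        sim$bleach_initial_photons, fp$bleach_half_life, optics, camera,
        n_frames = sim$bleach_frames, seed = derive_seed(cell_seed, 7L))
      curve <- roi_mean_trace(movie, NULL, optics,
                              camera_offset = camera$offset,
                              roi_id = cell_id)
      bf <- fit_decay(curve, with_plateau = cfg$bleach$with_plateau)
      bleach_all[[length(bleach_all) + 1L]] <- data.frame(
        cell_id = cell_id, fp = fp$name, k_per_s = bf$k,
        half_life_s = bf$half_life, plateau = bf$plateau,
        r_squared = bf$r_squared, status = bf$status)
      # --- optional TIRF-like tracking stage ---
      if (isTRUE(cfg$track$enabled)) {
        tmotion <- motion_spec(cfg$track$diffusion,
                               c(cfg$track$field_size, cfg$track$field_size),
                               boundary = "periodic")
        ttruth <- simulate_tracks(tmotion, cfg$track$n_particles,
                                  cfg$track$n_frames, tirf,
                                  derive_seed(cell_seed, 11L))
        trks <- filter_tracks(tracks_from_truth(ttruth))
        if (length(unique(trks$track_id)) >= 1L && nrow(trks) > 0L) {
          est <- fit_diffusion(msd_per_cell(trks, tirf), cell_id = cell_id)
          diff_all[[length(diff_all) + 1L]] <- data.frame(
            cell_id = cell_id, fp = fp$name, D_um2_s = est$D,
            slope_um2_s = est$slope, intercept_um2 = est$intercept,
            n_tracks = est$n_tracks, status = est$status)
        }
      }
    }
    say("[%s] quantified %d cells (%d cages each), %d bleach movies",
        fp$name, sim$n_cells, sim$n_cages_per_cell, sim$n_cells)
  }
  spots <- do.call(rbind, spots_all)
  cells <- do.call(rbind, cells_all)
  bleach <- do.call(rbind, bleach_all)
  diffusion <- if (length(diff_all)) do.call(rbind, diff_all) else NULL

  ok_cells <- cells[!is.na(cells$mean_cage_intensity_counts), ]
  bright <- relative_brightness(ok_cells$mean_cage_intensity_counts,
                                ok_cells$fp, cfg$reference_fp)
  hl_ok <- bleach[bleach$status == "ok", ]
  hl_sum <- if (length(unique(hl_ok$fp)) >= 2L &&
                all(table(hl_ok$fp) >= 3L)) {
    compare_half_lives(hl_ok$half_life_s, hl_ok$fp)
  } else {
    # too few fits for box statistics; report plain group means
    means <- tapply(hl_ok$half_life_s, hl_ok$fp, mean)
    data.frame(fp = names(means), mean_half_life_s = as.numeric(means))
  }
  comparison <- fp_comparison(bright, hl_sum, channel = cfg$channel)
  stats_res <- if (length(fp_names) >= 2L &&
                   all(table(ok_cells$fp) >= 3L)) {
    anova_tukey(ok_cells$mean_cage_intensity_counts, ok_cells$fp,
                alpha = cfg$compare$alpha)
  } else NULL
  say("comparison table: %d FPs, reference %s", nrow(comparison),
      cfg$reference_fp)

  out_dir <- NULL
  if (!is.null(cfg$out_dir)) {
    out_dir <- file.path(cfg$out_dir, hash)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# config_hash=%s seed=%d", hash, cfg$seed)
    wcsv <- function(df, name) {
      path <- file.path(out_dir, name)
      con <- file(path, "w")
      writeLines(stamp, con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    wcsv(spots, "spots.csv")
    wcsv(cells, "cells.csv")
    wcsv(bleach, "bleach.csv")
    if (!is.null(diffusion)) wcsv(diffusion, "diffusion.csv")
    wcsv(comparison, "comparison.csv")
    if (!is.null(stats_res)) {
      jsonlite::write_json(
        list(config_hash = hash, seed = cfg$seed,
             anova_F = stats_res$anova_F, anova_p = stats_res$anova_p,
             pairwise = as.data.frame(stats_res$pairwise),
             letters = as.list(stats_res$letters)),
        file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }
    writeLines(c(stamp, log), file.path(out_dir, "run.log"))
  }
  list(spots = spots, cells = cells, bleach = bleach, diffusion = diffusion,
       comparison = comparison, stats = stats_res, config_hash = hash,
       out_dir = out_dir, log = log)
}
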