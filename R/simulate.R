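# Synthetic-microscopy generator: Brownian trajectories, exposure-integrated
# PSF rendering with shot/read noise, and whole-cell photobleaching movies.

# Deterministic sub-stream seeds derived from one master seed, so that
# trajectories do not change when unrelated particles are added.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) + 1000003 * as.double(stream)) %% 2147483629)
}

reflect_fold <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  period <- 2 * (hi - lo)
  y <- (x - lo) %% period
  y <- ifelse(y > (hi - lo), period - y, y)
  y + lo
}

#' Simulate Brownian nanocage trajectories
#'
#' Generates ground-truth particle positions at sub-exposure resolution.
#' Within each frame the particle advances through `n_blur_substeps` positions
#' spread over the exposure window; between frames it advances through the
#' inter-frame gap. Every per-axis displacement between consecutive sub-steps
#' is Gaussian with variance `2 * D * dt_substep`, the defining property of
#' Brownian motion. Positions are in pixel units with the pixel-center
#' convention (0-based; pixel centers at integers).
#'
#' @param motion A [motion_spec()].
#' @param n_particles Number of particles (>= 1).
#' @param n_frames Number of frames (>= 1).
#' @param optics An [optics_model()] supplying exposure, frame interval,
#'   pixel size and the number of blur sub-steps.
#' @param seed Integer master seed; per-particle sub-streams are derived from
#'   it so results are reproducible and independent of particle count.
#' @return An object of class `track_truth`: a list with `pos` (wrapped
#'   positions after applying the boundary rule; array
#'   `[particle, frame, substep, axis]`, axes x then y), `pos_raw` (unwrapped
#'   free-space positions, the physical ground truth for displacement
#'   statistics), `times` (substep midpoint times, `[frame, substep]` matrix,
#'   seconds from the start of the first exposure), plus the inputs.
#' @export
simulate_tracks <- function(motion, n_particles, n_frames, optics, seed) {
  stopifnot(inherits(motion, "motion_spec"), inherits(optics, "optics_model"))
  n_particles <- as.integer(n_particles)
  n_frames <- as.integer(n_frames)
  stopifnot(n_particles >= 1L, n_frames >= 1L)
  if (!is.finite(motion$diffusion_coefficient) ||
      motion$diffusion_coefficient < 0) {
    stop("diffusion coefficient must be finite and non-negative")
  }
  D <- motion$diffusion_coefficient
  n_sub <- optics$n_blur_substeps
  px_per_um <- 1000 / optics$pixel_size
  h <- motion$field_size[1]
  w <- motion$field_size[2]

  # Substep midpoint times within each frame's exposure window.
  sub_mid <- (seq_len(n_sub) - 0.5) * optics$exposure / n_sub
  times <- outer((seq_len(n_frames) - 1) * optics$frame_interval, sub_mid, "+")
  # Time gaps between consecutive substeps across the whole acquisition.
  tvec <- as.vector(t(times))
  dts <- diff(tvec)

  n_steps <- n_frames * n_sub
  sd_px <- sqrt(2 * D * c(0, dts)) * px_per_um  # first entry unused

  pos <- array(NA_real_, dim = c(n_particles, n_frames, n_sub, 2L))
  pos_raw <- pos
  for (p in seq_len(n_particles)) {
    set.seed(derive_seed(seed, p))
    x0 <- stats::runif(1, 0, w - 1)
    y0 <- stats::runif(1, 0, h - 1)
    if (n_steps > 1L) {
      dx <- stats::rnorm(n_steps - 1L, 0, sd_px[-1L])
      dy <- stats::rnorm(n_steps - 1L, 0, sd_px[-1L])
    } else {
      dx <- dy <- numeric(0)
    }
    x <- cumsum(c(x0, dx))
    y <- cumsum(c(y0, dy))
    if (motion$boundary == "reflecting") {
      xb <- reflect_fold(x, 0, w - 1)
      yb <- reflect_fold(y, 0, h - 1)
    } else {
      xb <- x %% w
      yb <- y %% h
    }
    pos_raw[p, , , 1L] <- matrix(x, n_frames, n_sub, byrow = TRUE)
    pos_raw[p, , , 2L] <- matrix(y, n_frames, n_sub, byrow = TRUE)
    pos[p, , , 1L] <- matrix(xb, n_frames, n_sub, byrow = TRUE)
    pos[p, , , 2L] <- matrix(yb, n_frames, n_sub, byrow = TRUE)
  }
  structure(list(pos = pos, pos_raw = pos_raw, times = times,
                 motion = motion, optics = optics, seed = as.integer(seed),
                 n_particles = n_particles, n_frames = n_frames),
            class = "track_truth")
}

#' Assemble a simulation scene
#'
#' Binds ground-truth trajectories to the photophysics ([cage_spec()]),
#' optics and camera models needed to render an image stack. A fixed seed
#' makes re-rendering bit-identical.
#'
#' @param tracks A `track_truth` from [simulate_tracks()].
#' @param cage A [cage_spec()].
#' @param camera A [camera_model()].
#' @param seed Integer seed for the rendering noise stream.
#' @return An object of class `simulation_scene`.
#' @export
simulation_scene <- function(tracks, cage, camera = camera_model(),
                             seed = tracks$seed) {
  stopifnot(inherits(tracks, "track_truth"), inherits(cage, "cage_spec"),
            inherits(camera, "camera_model"))
  structure(list(tracks = tracks, cage = cage, optics = tracks$optics,
                 camera = camera, seed = as.integer(seed)),
            class = "simulation_scene")
}

# Add a pixel-integrated Gaussian of given total photon mass at (x, y)
# (0-based pixel-center coords) to an image matrix [y, x].
stamp_gaussian <- function(img, x, y, sigma, photons) {
  if (photons <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(6 * sigma)
  ix <- max(0, floor(x) - r):min(w - 1, ceiling(x) + r)
  iy <- max(0, floor(y) - r):min(h - 1, ceiling(y) + r)
  if (length(ix) == 0L || length(iy) == 0L) return(img)
  gx <- stats::pnorm((ix + 0.5 - x) / sigma) - stats::pnorm((ix - 0.5 - x) / sigma)
  gy <- stats::pnorm((iy + 0.5 - y) / sigma) - stats::pnorm((iy - 0.5 - y) / sigma)
  img[iy + 1L, ix + 1L] <- img[iy + 1L, ix + 1L] + photons * outer(gy, gx)
  img
}

apply_camera <- function(photons, camera, noise, rng_seed = NULL) {
  if (noise) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    counts <- stats::rpois(length(photons), photons) * camera$counts_per_photon
    counts <- counts + stats::rnorm(length(photons), 0, camera$read_noise_sd)
    counts <- round(counts + camera$offset)
    counts <- pmin(pmax(counts, 0), camera$max_count)
  } else {
    counts <- photons * camera$counts_per_photon + camera$offset
  }
  out <- photons
  out[] <- counts
  out
}

#' Render an image stack from a simulation scene
#'
#' Forward model: for each frame, each particle deposits a pixel-integrated
#' Gaussian PSF at each of its blur sub-step positions, carrying `1/n` of the
#' frame's expected photon budget per sub-step, so fast-moving particles blur
#' into elongated or diffuse shapes at long exposures. The expected photon
#' budget is `n_fp * photons_per_fp * exposure * 2^(-t / bleach_half_life)`
#' averaged over the exposure window. Photon images are then passed through
#' the camera: Poisson shot noise, gain, additive Gaussian read noise, offset,
#' rounding and clipping at saturation (all skipped, except gain and offset,
#' when `noise = FALSE`).
#'
#' @param scene A [simulation_scene()].
#' @param noise Apply shot/read noise and quantization? Set `FALSE` for exact
#'   expectation images (useful for calibration and testing).
#' @return A list with `stack` (numeric array `[y, x, frame]` of counts) and
#'   `truth` (data.frame with columns `frame`, `particle_id`, `x_px`, `y_px`
#'   — the exposure-averaged true position — and `photons`, the expected
#'   emitted photons of that particle in that frame).
#' @export
render_stack <- function(scene, noise = TRUE) {
  stopifnot(inherits(scene, "simulation_scene"))
  tr <- scene$tracks
  cage <- scene$cage
  optics <- scene$optics
  camera <- scene$camera
  sigma <- psf_sigma_px(optics)
  h <- tr$motion$field_size[1]
  w <- tr$motion$field_size[2]
  if (min(h, w) < ceiling(6 * sigma)) {
    stop("field too small to contain the PSF support")
  }
  n_sub <- optics$n_blur_substeps
  n_frames <- tr$n_frames
  rate0 <- cage$n_fp * cage$photons_per_fp          # photons/s per particle
  dt_sub <- optics$exposure / n_sub

  stack <- array(0, dim = c(h, w, n_frames))
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(0, h, w)
    ph <- numeric(tr$n_particles)
    for (p in seq_len(tr$n_particles)) {
      decay <- if (is.finite(cage$bleach_half_life)) {
        2^(-tr$times[f, ] / cage$bleach_half_life)
      } else rep(1, n_sub)
      sub_photons <- rate0 * dt_sub * decay
      ph[p] <- sum(sub_photons)
      for (s in seq_len(n_sub)) {
        img <- stamp_gaussian(img, tr$pos[p, f, s, 1L], tr$pos[p, f, s, 2L],
                              sigma, sub_photons[s])
      }
    }
    stack[, , f] <- img
    truth[[f]] <- data.frame(
      frame = f, particle_id = seq_len(tr$n_particles),
      x_px = apply(tr$pos[, f, , 1L, drop = FALSE], 1, mean),
      y_px = apply(tr$pos[, f, , 2L, drop = FALSE], 1, mean),
      photons = ph)
  }
  stack <- apply_camera(stack, camera, noise,
                        rng_seed = derive_seed(scene$seed, 999983))
  list(stack = stack, truth = do.call(rbind, truth))
}

#' Simulate a whole-cell photobleaching movie
#'
#' Renders the diffuse whole-cell fluorescence signal used for photobleaching
#' measurements: inside the cell mask the expected photon flux decays as
#' `2^(-t / half_life)` from `initial_intensity` (expected photons per pixel
#' per frame at t = 0); outside the mask only camera offset and noise remain.
#' Time is measured from the first exposure, so frame 1 is at t = 0.
#'
#' @param cell_mask Logical matrix marking in-cell pixels, or an integer
#'   `(height, width)` pair for an all-in-cell field.
#' @param initial_intensity Expected photons per in-mask pixel per frame at
#'   t = 0.
#' @param half_life Photobleaching half-life in seconds; `Inf` for a constant
#'   (non-bleaching) signal.
#' @param optics An [optics_model()] (frame interval sets the time base).
#' @param camera A [camera_model()].
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param noise Apply shot/read noise and quantization?
#' @return Numeric array `[y, x, frame]` of counts.
#' @export
simulate_bleach_movie <- function(cell_mask, initial_intensity, half_life,
                                  optics, camera = camera_model(),
                                  n_frames = 100L, seed = 1L, noise = TRUE) {
  stopifnot(inherits(optics, "optics_model"), inherits(camera, "camera_model"))
  if (!is.matrix(cell_mask)) {
    dims <- as.integer(cell_mask)
    stopifnot(length(dims) == 2L, all(dims >= 1L))
    cell_mask <- matrix(TRUE, dims[1], dims[2])
  }
  mode(cell_mask) <- "logical"
  stopifnot(is.numeric(initial_intensity), initial_intensity >= 0,
            is.numeric(half_life), !is.na(half_life), half_life > 0)
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 2L)
  t <- (seq_len(n_frames) - 1) * optics$frame_interval
  decay <- if (is.finite(half_life)) 2^(-t / half_life) else rep(1, n_frames)
  photons <- array(0, dim = c(nrow(cell_mask), ncol(cell_mask), n_frames))
  for (f in seq_len(n_frames)) {
    fr <- matrix(0, nrow(cell_mask), ncol(cell_mask))
    fr[cell_mask] <- initial_intensity * decay[f]
    photons[, , f] <- fr
  }
  apply_camera(photons, camera, noise, rng_seed = derive_seed(seed, 424243))
}

#' Extract per-frame tracks from simulation ground truth
#'
#' Converts `track_truth` sub-step positions into the per-frame track table
#' used by the MSD analysis (one exposure-averaged position per particle per
#' frame). With `unwrapped = TRUE` (default) the free-space positions are
#' used, which is the physically meaningful ground truth for displacement
#' statistics; `FALSE` gives the boundary-wrapped positions that rendering
#' uses. An optional `windows` table restricts each particle to an observation
#' window, emulating particles entering and leaving the thin TIRF illumination
#' zone and producing the broad track-length distributions seen in fast
#' time-lapse data.
#'
#' @param truth A `track_truth` from [simulate_tracks()].
#' @param windows Optional data.frame with columns `particle_id`,
#'   `first_frame`, `last_frame` (inclusive, 1-based).
#' @param unwrapped Use unwrapped free-space positions?
#' @return A `track_set` data.frame with columns `track_id`, `frame`, `x_px`,
#'   `y_px`.
#' @export
tracks_from_truth <- function(truth, windows = NULL, unwrapped = TRUE) {
  stopifnot(inherits(truth, "track_truth"))
  pos <- if (unwrapped) truth$pos_raw else truth$pos
  x <- apply(pos[, , , 1L, drop = FALSE], c(1, 2), mean)
  y <- apply(pos[, , , 2L, drop = FALSE], c(1, 2), mean)
  if (is.null(windows)) {
    windows <- data.frame(particle_id = seq_len(truth$n_particles),
                          first_frame = 1L, last_frame = truth$n_frames)
  }
  stopifnot(all(c("particle_id", "first_frame", "last_frame") %in%
                  names(windows)))
  out <- lapply(seq_len(nrow(windows)), function(i) {
    p <- windows$particle_id[i]
    fr <- seq.int(max(1L, windows$first_frame[i]),
                  min(truth$n_frames, windows$last_frame[i]))
    data.frame(track_id = p, frame = fr, x_px = x[p, fr], y_px = y[p, fr])
  })
  out <- do.call(rbind, out)
  class(out) <- c("track_set", "data.frame")
  out
}
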