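# Particle tracking for fast time-lapse stacks: local-maximum detection with
# Gaussian refinement, frame-to-frame optimal assignment linking, the
# track-length filter, and diffusion estimation from averaged MSD curves.

#' Detect sub-diffraction particles in one frame
#'
#' Local maxima above `background median + min_snr * robust noise SD` (MAD),
#' each refined to sub-pixel precision by a single-Gaussian fit in a small
#' window; detections closer than one PSF sigma are merged keeping the
#' brighter one. A simplification of Gaussian-mixture-model detection that is
#' adequate for well-separated particles.
#'
#' @param image Numeric matrix (one frame), all values finite.
#' @param min_snr Detection threshold in robust noise SDs above background.
#' @param optics An [optics_model()] (expected PSF sigma).
#' @param frame Frame index recorded in the output.
#' @return Data.frame with columns `frame`, `x`, `y` (sub-pixel, 0-based),
#'   `intensity` (fitted amplitude in counts). Zero rows when nothing is
#'   detected.
#' @export
detect_spots <- function(image, min_snr = 5, optics, frame = 1L) {
  stopifnot(is.matrix(image), all(is.finite(image)),
            inherits(optics, "optics_model"))
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0))
  bg <- stats::median(image)
  noise_sd <- stats::mad(image)
  thr <- bg + min_snr * noise_sd
  h <- nrow(image); w <- ncol(image)
  if (h < 3 || w < 3) return(empty)
  core <- image[2:(h - 1), 2:(w - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- image[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  sigma <- psf_sigma_px(optics)
  win <- max(2L, ceiling(3 * sigma))
  dets <- lapply(seq_len(nrow(idx)), function(k) {
    y <- idx[k, 1]  # core offset by 1 row/col; convert to 0-based full coords
    x <- idx[k, 2]
    ft <- fit_spot(image, c(x, y), win, psf_sigma = sigma,
                   pixel_size = optics$pixel_size)
    if (identical(ft$status, "ok")) {
      data.frame(frame = frame, x = ft$x0, y = ft$y0, intensity = ft$amplitude)
    } else {
      data.frame(frame = frame, x = x, y = y,
                 intensity = image[y + 1, x + 1] - bg)
    }
  })
  dets <- do.call(rbind, dets)
  # merge duplicates within one PSF sigma, brightest wins
  dets <- dets[order(-dets$intensity), ]
  keep <- rep(TRUE, nrow(dets))
  for (k in seq_len(nrow(dets))) {
    if (!keep[k]) next
    if (k < nrow(dets)) {
      later <- (k + 1):nrow(dets)
      d2 <- (dets$x[later] - dets$x[k])^2 + (dets$y[later] - dets$y[k])^2
      keep[later[d2 <= sigma^2]] <- FALSE
    }
  }
  dets <- dets[keep, , drop = FALSE]
  rownames(dets) <- NULL
  dets
}

#' @rdname detect_spots
#' @param stack Numeric array `[y, x, frame]`.
#' @export
detect_stack <- function(stack, min_snr = 5, optics) {
  stopifnot(length(dim(stack)) == 3L)
  do.call(rbind, lapply(seq_len(dim(stack)[3]), function(f) {
    detect_spots(stack[, , f], min_snr, optics, frame = f)
  }))
}

# Square linear assignment problem, Jonker-Volgenant shortest augmenting
# paths with potentials. Returns for each row the assigned column.
# Written here because no installed package exposes a weighted bipartite
# assignment solver.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0L) return(integer(0))
  u <- numeric(n)
  v <- numeric(n)
  v0 <- 0
  p <- integer(n + 1L)      # p[j + 1]: row assigned to column j (0 = virtual)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      jsel <- free[which.min(minv[free])]
      delta <- minv[jsel]
      usedj <- which(used) - 1L
      real_used <- usedj[usedj > 0L]
      u[p[usedj + 1L]] <- u[p[usedj + 1L]] + delta
      if (length(real_used)) v[real_used] <- v[real_used] - delta
      if (used[1L]) v0 <- v0 - delta
      minv[free] <- minv[free] - delta
      j0 <- jsel
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  assignment[p[-1L]] <- seq_len(n)
  assignment
}

# Gated frame-pair linking: minimum total squared displacement over allowed
# pairs, with unmatched detections allowed (augmented-matrix construction).
# Returns integer vector over rows of a: index into b, or NA if unlinked.
link_frame_pair <- function(ax, ay, bx, by, max_disp) {
  n1 <- length(ax)
  n2 <- length(bx)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  gate2 <- max_disp^2
  big <- 1e9 * max(gate2, 1)
  cmat <- ifelse(d2 <= gate2, d2, big)
  n <- n1 + n2
  A <- matrix(big, n, n)
  A[seq_len(n1), seq_len(n2)] <- cmat
  A[cbind(seq_len(n1), n2 + seq_len(n1))] <- gate2          # death of i
  A[cbind(n1 + seq_len(n2), seq_len(n2))] <- gate2          # birth of j
  A[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0                # dummy-dummy
  assign_col <- solve_lap(A)
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- assign_col[i]
    if (j <= n2 && d2[i, j] <= gate2) out[i] <- j
  }
  out
}

#' Link detections into tracks
#'
#' Frame-to-frame particle linking: for each consecutive frame pair, the
#' assignment of detections minimizing total squared displacement is computed
#' (optimal bipartite assignment), with links above `max_disp` forbidden.
#' Unmatched detections start new tracks; there is no gap closing, merging or
#' splitting, so a missed detection terminates a track and a new one begins.
#'
#' @param detections Data.frame with columns `frame`, `x`, `y` (as from
#'   [detect_spots()]/[detect_stack()]).
#' @param max_disp Hard displacement gate in pixels per frame. The default,
#'   when `optics` is given, is `5 * sqrt(4 * D_prior * dt) / pixel_size` with
#'   a diffusion prior of `D_prior = 1` um^2/s — five times the expected rms
#'   frame displacement.
#' @param optics Optional [optics_model()] used for the default gate.
#' @param d_prior Diffusion prior in um^2/s for the default gate.
#' @return A `track_set` data.frame: `track_id`, `frame`, `x_px`, `y_px`,
#'   ordered by track then frame; frames within a track are strictly
#'   consecutive.
#' @export
link_tracks <- function(detections, max_disp = NULL, optics = NULL,
                        d_prior = 1) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  if (is.null(max_disp)) {
    if (is.null(optics)) stop("supply max_disp or optics")
    max_disp <- 5 * sqrt(4 * d_prior * optics$frame_interval) * 1000 /
      optics$pixel_size
  }
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0))
  class(empty) <- c("track_set", "data.frame")
  if (nrow(detections) == 0L) return(empty)
  detections <- detections[order(detections$frame), ]
  frames <- sort(unique(detections$frame))
  next_id <- 1L
  rows <- list()
  prev <- NULL       # data.frame of previous frame's detections + track ids
  for (f in frames) {
    cur <- detections[detections$frame == f, , drop = FALSE]
    ids <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && prev$frame[1] == f - 1L) {
      match_j <- link_frame_pair(prev$x, prev$y, cur$x, cur$y, max_disp)
      for (i in seq_along(match_j)) {
        if (!is.na(match_j[i])) ids[match_j[i]] <- prev$track_id[i]
      }
    }
    new <- is.na(ids)
    if (any(new)) {
      ids[new] <- seq.int(next_id, next_id + sum(new) - 1L)
      next_id <- next_id + sum(new)
    }
    cur$track_id <- ids
    rows[[length(rows) + 1L]] <-
      data.frame(track_id = ids, frame = cur$frame, x_px = cur$x,
                 y_px = cur$y)
    prev <- cur
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

#' Filter tracks by length
#'
#' Retains tracks strictly longer than `min_frames` and strictly shorter than
#' `max_frames` frames. With the defaults this keeps tracks of 21-249 frames:
#' long enough for a meaningful time-averaged MSD, short enough (under 3 s at
#' 85 frames per second) that slow drifts and bleaching do not dominate.
#'
#' @param tracks A `track_set` data.frame (`track_id`, `frame`, `x_px`,
#'   `y_px`).
#' @param min_frames Exclusive lower length bound (default 20).
#' @param max_frames Exclusive upper length bound (default 250).
#' @return The filtered `track_set`.
#' @export
filter_tracks <- function(tracks, min_frames = 20L, max_frames = 250L) {
  stopifnot(all(c("track_id", "frame") %in% names(tracks)))
  len <- table(tracks$track_id)
  keep_ids <- names(len)[len > min_frames & len < max_frames]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

#' Per-cell averaged mean-square-displacement curve
#'
#' For each track, the time-averaged MSD over all ordered position pairs at
#' each lag (overlapping pairs, lags up to track length minus one); the cell
#' curve averages across tracks, by default weighting each lag by its number
#' of displacement pairs. Positions are converted to microns before squaring.
#'
#' @param tracks A `track_set` with frames strictly consecutive within each
#'   track (as produced by [link_tracks()] / [filter_tracks()] /
#'   [tracks_from_truth()]).
#' @param optics An [optics_model()] (pixel size, frame interval).
#' @param weighting `"pairs"` (pool displacement pairs across tracks, the
#'   default) or `"tracks"` (unweighted mean of per-track MSDs).
#' @param max_lag Optional cap on the number of lags.
#' @return An `msd_curve` data.frame: `lag_s`, `msd_um2`, `n_pairs`, with
#'   attribute `n_tracks`.
#' @export
msd_per_cell <- function(tracks, optics, weighting = c("pairs", "tracks"),
                         max_lag = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(optics, "optics_model"),
            all(c("track_id", "frame", "x_px", "y_px") %in% names(tracks)))
  ids <- unique(tracks$track_id)
  if (length(ids) == 0L) stop("no tracks to analyze")
  um_per_px <- optics$pixel_size / 1000
  max_len <- max(table(tracks$track_id))
  n_lag_tot <- max_len - 1L
  if (!is.null(max_lag)) n_lag_tot <- min(n_lag_tot, max_lag)
  if (n_lag_tot < 1L) stop("all tracks have fewer than 2 points")
  sum_d2 <- numeric(n_lag_tot)
  n_pairs <- numeric(n_lag_tot)
  sum_msd <- numeric(n_lag_tot)   # for track weighting
  n_trk <- numeric(n_lag_tot)
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (any(diff(tr$frame) != 1L)) {
      stop("track frames must be strictly consecutive (no gaps)")
    }
    x <- tr$x_px * um_per_px
    y <- tr$y_px * um_per_px
    len <- length(x)
    if (len < 2L) next
    for (L in seq_len(min(len - 1L, n_lag_tot))) {
      d2 <- (x[(1L + L):len] - x[1:(len - L)])^2 +
        (y[(1L + L):len] - y[1:(len - L)])^2
      sum_d2[L] <- sum_d2[L] + sum(d2)
      n_pairs[L] <- n_pairs[L] + (len - L)
      sum_msd[L] <- sum_msd[L] + mean(d2)
      n_trk[L] <- n_trk[L] + 1L
    }
  }
  used <- n_pairs > 0
  msd <- if (weighting == "pairs") {
    sum_d2[used] / n_pairs[used]
  } else {
    sum_msd[used] / n_trk[used]
  }
  out <- data.frame(lag_s = which(used) * optics$frame_interval,
                    msd_um2 = msd, n_pairs = n_pairs[used])
  attr(out, "n_tracks") <- length(ids)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD versus lag time over the initial fraction of
#' the curve (default the first 25% of lags, minimum 2), where Brownian
#' motion predicts `MSD = 4 D t`. The intercept is free by default: static
#' localization error adds a constant positive MSD offset without biasing the
#' slope. `D = slope / 4`.
#'
#' @param msd An `msd_curve` from [msd_per_cell()].
#' @param fit_fraction Fraction of lags fitted, from the start;
#'   `ceil(fit_fraction * n_lags)` lags, at least 2.
#' @param zero_intercept Force the line through the origin?
#' @param cell_id Label carried into the output.
#' @return A `diffusion_estimate`: list with `D` (um^2/s), `slope` (um^2/s),
#'   `intercept` (um^2), `fit_fraction`, `n_lags_fit`, `cell_id`, `status`
#'   (`ok`, or `negative_slope` when the fitted slope is negative — D is
#'   still reported).
#' @export
fit_diffusion <- function(msd, fit_fraction = 0.25, zero_intercept = FALSE,
                          cell_id = NA_character_) {
  stopifnot(inherits(msd, "data.frame"), nrow(msd) >= 1L,
            fit_fraction > 0, fit_fraction <= 1)
  n_fit <- max(2L, ceiling(fit_fraction * nrow(msd)))
  if (nrow(msd) < 2L || n_fit > nrow(msd)) {
    stop("fewer than 2 usable lags in the fitted prefix")
  }
  d <- msd[seq_len(n_fit), ]
  fit <- if (zero_intercept) {
    stats::lm(msd_um2 ~ lag_s - 1, data = d)
  } else {
    stats::lm(msd_um2 ~ lag_s, data = d)
  }
  co <- stats::coef(fit)
  slope <- unname(co[["lag_s"]])
  intercept <- if (zero_intercept) 0 else unname(co[["(Intercept)"]])
  structure(list(D = slope / 4, slope = slope, intercept = intercept,
                 fit_fraction = fit_fraction, n_lags_fit = n_fit,
                 n_tracks = attr(msd, "n_tracks"), cell_id = cell_id,
                 status = if (slope < 0) "negative_slope" else "ok"),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "diffusion_estimate [%s]: D = %.4g um^2/s (slope %.4g, intercept %.3g um^2, %d lags fitted)\n",
    x$status, x$D, x$slope, x$intercept, x$n_lags_fit))
  invisible(x)
}
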