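test_that("blank noise frames produce essentially no detections", {
  optics <- tirf_optics()
  set.seed(1)
  n_det <- vapply(1:400, function(i) {
    frame <- matrix(rnorm(64 * 64, 100, 2), 64, 64)
    nrow(detect_spots(frame, min_snr = 5, optics))
  }, numeric(1))
  expect_gte(mean(n_det == 0), 0.99)
})

test_that("well-separated particles are detected within 0.2 px at SNR 10", {
  optics <- tirf_optics()   # sigma ~ 0.97 px at 110 nm pixels
  # ~730 photons/frame: peak amplitude ~114 counts, so amplitude over total
  # per-pixel noise at the peak (shot + read) is ~10
  cage <- cage_spec(60, 1220, Inf)
  motion <- motion_spec(0, c(128, 128))
  tr <- simulate_tracks(motion, 20L, 1L, optics, seed = 15)
  gx <- rep(seq(15, 113, length.out = 5), 4)
  gy <- rep(seq(15, 113, length.out = 4), each = 5)
  set.seed(15)
  tr$pos[, 1, , 1] <- gx + runif(20, -0.4, 0.4)
  tr$pos[, 1, , 2] <- gy + runif(20, -0.4, 0.4)
  cam <- camera_model(offset = 100, read_noise_sd = 4)
  r <- render_stack(simulation_scene(tr, cage, cam, seed = 15))
  dets <- detect_spots(r$stack[, , 1], min_snr = 5, optics)
  expect_equal(nrow(dets), 20L)
  truth <- r$truth
  err <- vapply(seq_len(nrow(dets)), function(k) {
    min(sqrt((truth$x_px - dets$x[k])^2 + (truth$y_px - dets$y[k])^2))
  }, numeric(1))
  expect_lt(max(err), 0.2)
})

test_that("detections closer than one PSF sigma merge into one", {
  optics <- confocal_optics(n_blur_substeps = 1L)
  sig <- psf_sigma_px(optics)
  cage <- cage_spec(60, 50, Inf)
  tr <- simulate_tracks(motion_spec(0, c(64, 64)), 2L, 1L, optics, seed = 6)
  tr$pos[, 1, , 1] <- c(30, 30 + 0.5 * sig)
  tr$pos[, 1, , 2] <- 30
  r <- render_stack(simulation_scene(tr, cage, camera_model(100, 1.5)))
  dets <- detect_spots(r$stack[, , 1], min_snr = 5, optics)
  expect_equal(nrow(dets), 1L)
})

test_that("the assignment solver is optimal against brute-force enumeration", {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n)
    a <- nanocagebench:::solve_lap(cost)
    got <- sum(cost[cbind(seq_len(n), a)])
    best <- min(vapply(perms(seq_len(n)),
                       function(p) sum(cost[cbind(seq_len(n), p)]),
                       numeric(1)))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("a single particle with small steps yields one full-length track", {
  optics <- tirf_optics()
  det <- data.frame(frame = 1:30, x = cumsum(rnorm(30, 0, 0.1)) + 50,
                    y = cumsum(rnorm(30, 0, 0.1)) + 50)
  trk <- link_tracks(det, max_disp = 5)
  expect_equal(length(unique(trk$track_id)), 1L)
  expect_equal(nrow(trk), 30L)
  expect_equal(trk$frame, 1:30)
})

test_that("well-separated simulated particles are linked to true identities", {
  # 5 particles, pairwise separation always > 4 x gate: linking must
  # reproduce the ground-truth identity mapping exactly
  optics <- tirf_optics()
  max_disp <- 3
  # each particle wanders inside its own small reflecting box; boxes are
  # spaced 100 px apart, so inter-particle distance always exceeds 4 x gate
  tr <- simulate_tracks(motion_spec(0.3, c(40, 40)), 5L, 40L, optics,
                        seed = 33)
  trk_true <- tracks_from_truth(tr, unwrapped = FALSE)
  trk_true$x_px <- trk_true$x_px + (trk_true$track_id - 1) * 100
  dets <- data.frame(frame = trk_true$frame, x = trk_true$x_px,
                     y = trk_true$y_px)
  linked <- link_tracks(dets, max_disp = max_disp)
  expect_equal(length(unique(linked$track_id)), 5L)
  for (id in unique(linked$track_id)) {
    sub <- linked[linked$track_id == id, ]
    true_id <- trk_true$track_id[trk_true$frame == 1 &
                                   trk_true$x_px == sub$x_px[1]]
    ref <- trk_true[trk_true$track_id == true_id, ]
    expect_equal(sub$x_px, ref$x_px)
    expect_equal(sub$y_px, ref$y_px)
  }
})

test_that("a detection gap terminates the track; no gap closing", {
  det <- data.frame(frame = c(1:10, 12:20), x = 50, y = 50)
  trk <- link_tracks(det, max_disp = 5)
  expect_equal(length(unique(trk$track_id)), 2L)
  lens <- as.vector(table(trk$track_id))
  expect_setequal(lens, c(10L, 9L))
})

test_that("track length filter bounds are strict", {
  mk <- function(id, len) data.frame(track_id = id, frame = seq_len(len),
                                     x_px = 0, y_px = 0)
  tracks <- do.call(rbind, Map(mk, 1:5, c(20, 21, 100, 249, 250)))
  kept <- filter_tracks(tracks)
  expect_setequal(unique(kept$track_id), c(2L, 3L, 4L))
  expect_equal(nrow(filter_tracks(tracks[0, ])), 0L)
  short <- do.call(rbind, Map(mk, 1:3, c(10, 10, 10)))
  expect_equal(nrow(filter_tracks(short)), 0L)
})

test_that("MSD handles stationary, ballistic and Brownian cases", {
  optics <- tirf_optics(pixel_size = 1000)  # 1 um pixels for round numbers
  still <- data.frame(track_id = 1L, frame = 1:30, x_px = 5, y_px = 7)
  m0 <- msd_per_cell(still, optics)
  expect_true(all(m0$msd_um2 == 0))
  # straight line, step s per frame: MSD(n dt) = (n s)^2
  s <- 0.25
  line <- data.frame(track_id = 1L, frame = 1:40, x_px = s * (1:40), y_px = 0)
  mb <- msd_per_cell(line, optics)
  expect_equal(mb$msd_um2, (seq_len(39) * s)^2, tolerance = 1e-12)
  expect_true(all(diff(mb$n_pairs) <= 0))
  expect_equal(mb$lag_s[1], optics$frame_interval)
  # gaps are refused
  gap <- data.frame(track_id = 1L, frame = c(1:5, 7:10), x_px = 0, y_px = 0)
  expect_error(msd_per_cell(gap, optics), "consecutive")
})

test_that("diffusion fit is exact on an ideal linear MSD curve", {
  optics <- tirf_optics()
  lag <- (1:40) * optics$frame_interval
  msd <- data.frame(lag_s = lag, msd_um2 = 4 * 0.5 * lag, n_pairs = 100)
  class(msd) <- c("msd_curve", "data.frame")
  est <- fit_diffusion(msd)
  expect_equal(est$D, 0.5, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  expect_equal(est$n_lags_fit, 10L)   # ceil(0.25 * 40)
  expect_equal(est$status, "ok")
  est0 <- fit_diffusion(msd, zero_intercept = TRUE)
  expect_equal(est0$D, 0.5, tolerance = 1e-12)
  expect_error(fit_diffusion(msd[1, , drop = FALSE]), "2 usable lags")
})

test_that("localization noise adds an MSD offset without biasing the slope", {
  optics <- tirf_optics()
  trk <- tracks_from_truth(
    simulate_tracks(motion_spec(1, c(256, 256), boundary = "periodic"),
                    80L, 120L, optics, seed = 55))
  set.seed(56)
  noisy <- trk
  sigma_loc_px <- 0.3
  noisy$x_px <- noisy$x_px + rnorm(nrow(noisy), 0, sigma_loc_px)
  noisy$y_px <- noisy$y_px + rnorm(nrow(noisy), 0, sigma_loc_px)
  est_clean <- fit_diffusion(msd_per_cell(trk, optics))
  est_noisy <- fit_diffusion(msd_per_cell(noisy, optics))
  expect_gt(est_noisy$intercept, est_clean$intercept)
  expect_lt(abs(est_noisy$D / est_clean$D - 1), 0.05)
})
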