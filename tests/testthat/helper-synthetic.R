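# Shared fixture builders: everything is generated in code at test time.

noiseless_camera <- function() {
  camera_model(offset = 0, read_noise_sd = 0, counts_per_photon = 1,
               max_count = 65535)
}

# Render a single stationary spot at a given sub-pixel position in its own
# field. Returns the image, the true position and the total photon count.
render_single_spot <- function(x, y, photons_per_frame = 1500,
                               optics = confocal_optics(n_blur_substeps = 1L),
                               field = 64L, camera = noiseless_camera(),
                               noise = FALSE, half_life = Inf, n_frames = 1L,
                               seed = 1L) {
  cage <- cage_spec(n_fp = 60L,
                    photons_per_fp = photons_per_frame / (60 * optics$exposure),
                    bleach_half_life = half_life)
  motion <- motion_spec(0, c(field, field))
  tr <- simulate_tracks(motion, 1L, n_frames, optics, seed = seed)
  tr$pos[1, , , 1] <- x
  tr$pos[1, , , 2] <- y
  rend <- render_stack(simulation_scene(tr, cage, camera, seed = seed),
                       noise = noise)
  list(image = rend$stack[, , 1], stack = rend$stack, truth = rend$truth,
       x = x, y = y, photons = photons_per_frame, optics = optics)
}

# Ground-truth Brownian tracks with per-particle observation windows,
# mimicking particles entering/leaving the TIRF illumination zone.
simulate_windowed_tracks <- function(n_particles, n_frames, d_um2_s, optics,
                                     seed, len_range = c(21L, 150L),
                                     field = 256L) {
  motion <- motion_spec(d_um2_s, c(field, field), boundary = "periodic")
  tr <- simulate_tracks(motion, n_particles, n_frames, optics, seed = seed)
  set.seed(seed)
  len <- sample(len_range[1]:len_range[2], n_particles, replace = TRUE)
  start <- vapply(len, function(l) sample.int(n_frames - l + 1L, 1L),
                  integer(1))
  win <- data.frame(particle_id = seq_len(n_particles), first_frame = start,
                    last_frame = start + len - 1L)
  tracks_from_truth(tr, win)
}
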