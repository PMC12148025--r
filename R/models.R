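#' Optical configuration of an imaging modality
#'
#' Bundles the acquisition parameters that every stage of the pipeline needs:
#' the effective pixel size, the point-spread-function (PSF) width, and the
#' exposure/frame timing. Two presets cover the regimes used for nanocage
#' imaging: a spinning-disc confocal configuration (27 nm pixels, 500 ms
#' exposure) for intensity and photobleaching work, and a TIRF configuration
#' (110 nm pixels, 85 frames per second) for particle tracking.
#'
#' @param pixel_size Effective pixel size in nm per pixel. Must be > 0.
#' @param psf_fwhm PSF full width at half maximum in nm. Must be > 0. A
#'   sub-diffraction emitter images as an approximately Gaussian spot with
#'   `sigma = psf_fwhm / (2 * sqrt(2 * log(2)))`.
#' @param exposure Exposure time per frame in seconds; `0 < exposure <=
#'   frame_interval`.
#' @param frame_interval Time between frame starts in seconds.
#' @param n_blur_substeps Number of sub-steps used to integrate particle motion
#'   over one exposure when rendering (motion blur). Must be >= 1.
#'
#' @return An object of class `optics_model`.
#' @examples
#' confocal <- optics_model(pixel_size = 27, psf_fwhm = 200,
#'                          exposure = 0.5, frame_interval = 0.5)
#' psf_sigma_px(confocal)
#' @export
optics_model <- function(pixel_size, psf_fwhm, exposure, frame_interval,
                         n_blur_substeps = 10L) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L,
            is.finite(pixel_size), pixel_size > 0)
  stopifnot(is.numeric(psf_fwhm), length(psf_fwhm) == 1L,
            is.finite(psf_fwhm), psf_fwhm > 0)
  stopifnot(is.numeric(exposure), length(exposure) == 1L,
            is.finite(exposure), exposure > 0)
  stopifnot(is.numeric(frame_interval), length(frame_interval) == 1L,
            is.finite(frame_interval), frame_interval >= exposure)
  n_blur_substeps <- as.integer(n_blur_substeps)
  stopifnot(n_blur_substeps >= 1L)
  structure(list(pixel_size = pixel_size, psf_fwhm = psf_fwhm,
                 exposure = exposure, frame_interval = frame_interval,
                 n_blur_substeps = n_blur_substeps),
            class = "optics_model")
}

#' @rdname optics_model
#' @param optics An `optics_model`.
#' @details `psf_sigma_px()` returns the Gaussian PSF standard deviation in
#'   pixel units, `psf_fwhm / (2 * sqrt(2 * log(2)) * pixel_size)`.
#' @export
psf_sigma_px <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  optics$psf_fwhm / (2 * sqrt(2 * log(2)) * optics$pixel_size)
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(
    "optics_model: %g nm/px, PSF FWHM %g nm (sigma %.2f px), exposure %g s, frame interval %g s, %d blur substeps\n",
    x$pixel_size, x$psf_fwhm, psf_sigma_px(x), x$exposure, x$frame_interval,
    x$n_blur_substeps))
  invisible(x)
}

#' Camera noise model
#'
#' Generic scientific-camera abstraction used when rendering synthetic stacks:
#' detected photons are Poisson-distributed, converted to counts with a fixed
#' gain, and read out with additive Gaussian noise on top of a constant offset,
#' clipped at the saturation value. Defaults are sCMOS-like (gain 1
#' count/photon, 1.5 counts read noise, offset 100, 16-bit saturation).
#'
#' @param offset Constant camera offset in counts (>= 0).
#' @param read_noise_sd Read noise standard deviation in counts (>= 0).
#' @param counts_per_photon Gain in counts per detected photon (> 0).
#' @param max_count Saturation value in counts (> offset).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(offset = 100, read_noise_sd = 1.5,
                         counts_per_photon = 1, max_count = 65535) {
  stopifnot(is.numeric(offset), length(offset) == 1L, offset >= 0,
            is.numeric(read_noise_sd), length(read_noise_sd) == 1L,
            read_noise_sd >= 0,
            is.numeric(counts_per_photon), length(counts_per_photon) == 1L,
            counts_per_photon > 0,
            is.numeric(max_count), length(max_count) == 1L,
            max_count > offset)
  structure(list(offset = offset, read_noise_sd = read_noise_sd,
                 counts_per_photon = counts_per_photon, max_count = max_count),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "camera_model: offset %g, read noise %g counts, gain %g counts/photon, saturation %g\n",
    x$offset, x$read_noise_sd, x$counts_per_photon, x$max_count))
  invisible(x)
}

#' Nanocage photophysics specification
#'
#' Describes the fluorophore payload of one nanocage species: the number of FP
#' molecules per cage (60 for single-tagged, 120 for tandem-tagged
#' constructs), the photon emission rate per FP at the imaging irradiance, and
#' the photobleaching half-life. The per-FP photon rate is a free parameter of
#' the simulation; it is not derived from a physical irradiance.
#'
#' @param n_fp FP molecules per cage (>= 1); typically 60 or 120.
#' @param photons_per_fp Detected photons per second per FP (>= 0).
#' @param bleach_half_life Photobleaching half-life in seconds (> 0); may be
#'   `Inf` for a non-bleaching fluorophore.
#' @return An object of class `cage_spec`.
#' @export
cage_spec <- function(n_fp = 60L, photons_per_fp = 50,
                      bleach_half_life = Inf) {
  n_fp <- as.integer(n_fp)
  stopifnot(n_fp >= 1L,
            is.numeric(photons_per_fp), length(photons_per_fp) == 1L,
            is.finite(photons_per_fp), photons_per_fp >= 0,
            is.numeric(bleach_half_life), length(bleach_half_life) == 1L,
            !is.na(bleach_half_life), bleach_half_life > 0)
  structure(list(n_fp = n_fp, photons_per_fp = photons_per_fp,
                 bleach_half_life = bleach_half_life),
            class = "cage_spec")
}

#' Particle motion specification
#'
#' Brownian-motion parameters for simulated nanocage trajectories. The default
#' diffusion coefficient of 1 square micron per second matches free cytoplasmic
#' diffusion of ~26 nm nanoparticles; a much smaller value mimics the slowed
#' motion of hyperosmotic (D-mannitol) treatment used for long-exposure
#' intensity imaging.
#'
#' @param diffusion_coefficient Diffusion coefficient D in um^2/s (>= 0).
#' @param field_size Integer `(height, width)` of the simulated field in
#'   pixels; each dimension >= 16.
#' @param boundary Either `"reflecting"` (confined cytoplasm region, the
#'   default) or `"periodic"` (edge-effect-free, convenient for MSD checks).
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(diffusion_coefficient = 1.0,
                        field_size = c(128L, 128L),
                        boundary = c("reflecting", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(diffusion_coefficient),
            length(diffusion_coefficient) == 1L,
            is.finite(diffusion_coefficient), diffusion_coefficient >= 0)
  field_size <- as.integer(field_size)
  stopifnot(length(field_size) == 2L, all(field_size >= 16L))
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 field_size = field_size, boundary = boundary),
            class = "motion_spec")
}

#' Spinning-disc confocal and TIRF optics presets
#'
#' Convenience constructors for the two imaging regimes: a high-resolution
#' spinning-disc configuration (27 nm effective pixels, 500 ms exposures,
#' 200 nm FWHM PSF) used for nanocage intensity and photobleaching
#' measurements, and a TIRF configuration (110 nm pixels, 85 frames per
#' second) used for particle tracking.
#'
#' @param ... Overrides passed to [optics_model()].
#' @return An `optics_model`.
#' @export
confocal_optics <- function(...) {
  args <- utils::modifyList(
    list(pixel_size = 27, psf_fwhm = 200, exposure = 0.5,
         frame_interval = 0.5, n_blur_substeps = 10L),
    list(...))
  do.call(optics_model, args)
}

#' @rdname confocal_optics
#' @export
tirf_optics <- function(...) {
  args <- utils::modifyList(
    list(pixel_size = 110, psf_fwhm = 250, exposure = 0.010,
         frame_interval = 1 / 85, n_blur_substeps = 4L),
    list(...))
  do.call(optics_model, args)
}
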