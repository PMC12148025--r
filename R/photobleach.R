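# Photobleaching analysis: whole-cell ROI traces and single-exponential
# decay fits reporting half-lives.

#' Whole-cell intensity trace from a stack
#'
#' Per-frame mean of in-ROI pixels, camera offset subtracted, normalized to
#' the first frame. Time is measured from the first exposure (frame 1 at
#' t = 0) using the frame interval from the optics metadata.
#'
#' @param stack Numeric array `[y, x, frame]` with at least 5 frames.
#' @param roi_mask Logical matrix marking the cell ROI (non-empty). `NULL`
#'   uses the whole frame.
#' @param optics An [optics_model()] (supplies the frame interval).
#' @param camera_offset Camera offset in counts, subtracted before
#'   normalization (offsets left in place bias the decay rate downward).
#' @param roi_id Label carried through to outputs.
#' @return A `bleach_curve`: list with `times` (s), `intensities`
#'   (normalized, first element 1) and `roi_id`.
#' @export
roi_mean_trace <- function(stack, roi_mask = NULL, optics,
                           camera_offset = 0, roi_id = "cell1") {
  stopifnot(length(dim(stack)) == 3L, inherits(optics, "optics_model"))
  n_frames <- dim(stack)[3]
  if (n_frames < 5L) stop("need at least 5 frames for a bleach trace")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(stack)[1], dim(stack)[2])
  mode(roi_mask) <- "logical"
  if (!any(roi_mask)) stop("ROI mask is empty")
  vals <- vapply(seq_len(n_frames),
                 function(f) mean(stack[, , f][roi_mask]) - camera_offset,
                 numeric(1))
  if (vals[1] <= 0) {
    stop("first-frame ROI mean is not positive after offset subtraction")
  }
  structure(list(times = (seq_len(n_frames) - 1) * optics$frame_interval,
                 intensities = vals / vals[1], roi_id = roi_id),
            class = "bleach_curve")
}

#' Build a bleach curve from an arbitrary intensity trace
#'
#' Normalizes a raw intensity vector (e.g. per-frame integrated spot
#' intensities) into the same `bleach_curve` form that [roi_mean_trace()]
#' produces, so spot-level and whole-cell traces share one fitting path.
#'
#' @param times Strictly increasing times in seconds.
#' @param intensities Positive raw intensities; normalized to the first value.
#' @param roi_id Label.
#' @return A `bleach_curve`.
#' @export
bleach_curve <- function(times, intensities, roi_id = "trace") {
  stopifnot(length(times) == length(intensities), length(times) >= 5L,
            all(diff(times) > 0))
  if (intensities[1] <= 0) stop("first intensity must be positive")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities / intensities[1]),
                 roi_id = roi_id),
            class = "bleach_curve")
}

#' Fit a single-exponential photobleaching decay
#'
#' Least-squares fit of `I(t) = (1 - c) * exp(-k * t) + c` to a normalized
#' bleach curve, reporting the decay rate `k`, the half-life
#' `t_1/2 = ln(2) / k` of the decaying component, the plateau `c`, and R
#' squared. The plateau absorbs non-bleaching background; with
#' `with_plateau = FALSE` it is fixed at 0. Initialized from a log-linear
#' regression; fit problems are reported via `status`, never as errors.
#'
#' @param curve A `bleach_curve` with at least 5 points, all positive.
#' @param with_plateau Include the plateau term, bounded to `[0, 0.5]`
#'   (default TRUE)?
#' @return A `bleach_fit`: list with `k` (1/s), `half_life` (s), `plateau`,
#'   `r_squared`, `status` (`ok` or `failed`), `roi_id`.
#' @export
fit_decay <- function(curve, with_plateau = TRUE) {
  stopifnot(inherits(curve, "bleach_curve"))
  t <- curve$times
  y <- curve$intensities
  if (length(t) < 5L) stop("need at least 5 points")
  if (any(y <= 0)) stop("intensities must be positive")

  out <- function(k, c, r2, status) {
    structure(list(k = k, half_life = if (is.finite(k) && k > 0) log(2) / k
                   else NA_real_,
                   plateau = c, r_squared = r2, status = status,
                   roi_id = curve$roi_id),
              class = "bleach_fit")
  }
  # log-linear initialization on the early part of the trace
  n_init <- max(5L, ceiling(length(t) / 3))
  k0 <- unname(-stats::coef(stats::lm(log(y[1:n_init]) ~ t[1:n_init]))[2])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1e-3 / max(diff(t))
  c0 <- min(max(min(y), 0), 0.45)

  if (with_plateau) {
    resid_fn <- function(p) (1 - p[2]) * exp(-p[1] * t) + p[2] - y
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(k = k0, c = c0), fn = resid_fn,
                         lower = c(1e-12, 0), upper = c(Inf, 0.5),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    resid_fn <- function(p) exp(-p[1] * t) - y
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(k = k0), fn = resid_fn,
                         lower = 1e-12, upper = Inf,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(out(NA_real_, NA_real_, NA_real_, "failed"))
  }
  k <- unname(fit$par[1])
  c_hat <- if (with_plateau) unname(fit$par[2]) else 0
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  # no measurable decay over the observation window
  if (k * (max(t) - min(t)) < 1e-3) {
    return(out(k, c_hat, r2, "failed"))
  }
  out(k, c_hat, r2, "ok")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf(
    "bleach_fit [%s] %s: k = %.4g 1/s, half-life = %.3g s, plateau = %.3g, R^2 = %.4f\n",
    x$status, x$roi_id, x$k, x$half_life, x$plateau, x$r_squared))
  invisible(x)
}

#' Box-plot statistics (1.5 IQR whisker convention)
#'
#' Median, first and third quartile (linear-interpolation quartiles), and
#' whiskers extending to the most extreme observations within 1.5 times the
#' interquartile range from the quartile boundaries.
#'
#' @param x Numeric vector.
#' @return Named list: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- x[x >= q[1] - 1.5 * iqr]
  hi <- x[x <= q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = if (length(lo)) min(lo) else NA_real_,
       whisker_high = if (length(hi)) max(hi) else NA_real_)
}

#' Summarize photobleaching half-lives by FP group
#'
#' Per-group mean, SD and box-plot statistics of fitted half-lives, for
#' comparing photostability across fluorescent proteins.
#'
#' @param half_lives Numeric vector of fitted half-lives in seconds.
#' @param groups Factor or character vector of FP labels, same length.
#' @return Data.frame with one row per group: `fp`, `n`, `mean_half_life_s`,
#'   `sd_half_life_s`, `median_s`, `q1_s`, `q3_s`, `whisker_low_s`,
#'   `whisker_high_s`.
#' @export
compare_half_lives <- function(half_lives, groups) {
  stopifnot(length(half_lives) == length(groups))
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) < 2L) stop("need at least 2 groups")
  rows <- lapply(gs, function(g) {
    v <- half_lives[groups == g & is.finite(half_lives)]
    if (length(v) < 3L) stop(sprintf("group '%s' has fewer than 3 fits", g))
    b <- box_stats(v)
    data.frame(fp = g, n = length(v), mean_half_life_s = mean(v),
               sd_half_life_s = stats::sd(v), median_s = b$median,
               q1_s = b$q1, q3_s = b$q3, whisker_low_s = b$whisker_low,
               whisker_high_s = b$whisker_high)
  })
  do.call(rbind, rows)
}
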