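# FP comparison metrics and statistics: relative brightness, emission yield,
# one-way ANOVA with Tukey-Kramer HSD and compact letter display, plus the
# Fibonacci-lattice fluorophore spacing and spectral throughput utilities.

#' Relative brightness of FPs from per-cell cage intensities
#'
#' Each FP's mean cage intensity divided by the reference FP's mean, giving
#' fold brightness per FP molecule (every cage carries the same number of FP
#' copies, so cage intensity ratios are molecular brightness ratios).
#'
#' @param cell_means Numeric vector of per-cell mean cage intensities
#'   (counts).
#' @param fp Character/factor vector of FP labels, same length.
#' @param reference_fp Label of the reference FP (must be present).
#' @return Data.frame `fp`, `n_cells`, `mean_cage_intensity_counts`,
#'   `relative_brightness` (reference = 1).
#' @export
relative_brightness <- function(cell_means, fp, reference_fp) {
  stopifnot(length(cell_means) == length(fp))
  fp <- as.character(fp)
  if (!reference_fp %in% fp) {
    stop(sprintf("reference FP '%s' not present", reference_fp))
  }
  gs <- unique(fp)
  means <- vapply(gs, function(g) mean(cell_means[fp == g]), numeric(1))
  ref <- means[[reference_fp]]
  if (!is.finite(ref) || ref <= 0) stop("reference mean must be positive")
  data.frame(fp = gs, n_cells = as.integer(table(factor(fp, levels = gs))),
             mean_cage_intensity_counts = unname(means),
             relative_brightness = unname(means) / ref)
}

#' Relative emission yield
#'
#' Figure of merit for live-imaging FP performance: the product of relative
#' brightness (fold versus a reference FP) and photobleaching half-life (s)
#' measured at the same irradiance. It is proportional to the total photon
#' budget an FP delivers before bleaching, so an FP with yield r times the
#' reference supports ~r times as many exposures at equal starting signal.
#' Yields are only comparable within one imaging configuration (excitation
#' line, emission filter, irradiance).
#'
#' @param relative_brightness Fold brightness versus the reference
#'   (unitless); vectorized.
#' @param half_life Photobleaching half-life in seconds (> 0); vectorized.
#' @return Emission yield in fold-seconds.
#' @export
emission_yield <- function(relative_brightness, half_life) {
  if (any(!is.finite(relative_brightness)) || any(!is.finite(half_life)) ||
      any(half_life <= 0)) {
    stop("inputs must be finite with positive half-life")
  }
  relative_brightness * half_life
}

# Compact letter display: groups not significantly different share a letter.
# Letters are the maximal cliques of the non-significance graph, ordered
# (and tie-broken) alphabetically by group label.
compact_letters <- function(pairwise_p, groups, alpha) {
  k <- length(groups)
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    nsd[i, j] <- nsd[j, i] <- pairwise_p[groups[i], groups[j]] >= alpha
  }
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cliques <- lapply(cliques, function(cl) sort(names(cl)))
  cliques <- cliques[order(vapply(cliques, `[`, character(1), 1))]
  letters_out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(cliques)) {
    for (gname in cliques[[i]]) {
      letters_out[gname] <- paste0(letters_out[gname], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey-Kramer HSD comparisons
#'
#' Omnibus one-way ANOVA followed by all-pairs comparisons using the
#' studentized range with Tukey-Kramer standard errors (valid for unequal
#' group sizes), plus a compact letter display: groups sharing a letter are
#' not significantly different at `alpha`.
#'
#' @param values Numeric response (e.g. per-cell mean cage intensities or
#'   half-lives).
#' @param groups FP labels, same length; at least 2 groups with >= 3
#'   observations each.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `group_test_result`: list with `groups`, `anova_F`, `anova_p`,
#'   `pairwise` (symmetric matrix of Tukey-adjusted p values), `letters`
#'   (compact letter display), `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups), alpha > 0, alpha < 1)
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n_by <- table(groups)
  if (any(n_by < 3L)) stop("every group needs at least 3 observations")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  lv <- levels(groups)
  pw <- matrix(NA_real_, nlevels(groups), nlevels(groups),
               dimnames = list(lv, lv))
  diag(pw) <- 1
  pair_names <- rownames(tk)
  for (r in seq_along(pair_names)) {
    ab <- strsplit(pair_names[r], "-", fixed = TRUE)[[1]]
    pw[ab[1], ab[2]] <- pw[ab[2], ab[1]] <- tk[r, "p adj"]
  }
  structure(list(groups = lv,
                 anova_F = an[["F value"]][1],
                 anova_p = an[["Pr(>F)"]][1],
                 pairwise = pw,
                 letters = compact_letters(pw, lv, alpha),
                 alpha = alpha),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g (alpha = %g)\n",
              x$anova_F, x$anova_p, x$alpha))
  cat("compact letter display:\n")
  for (g in x$groups) cat(sprintf("  %s: %s\n", g, x$letters[g]))
  invisible(x)
}

#' Fibonacci lattice on a sphere
#'
#' Places `n` points quasi-uniformly on a sphere with the golden-angle
#' construction: point `i` (0-based) at height `z = 1 - 2 (i + 0.5) / n` and
#' azimuth `i` times the golden angle `2 pi (1 - 1/phi)`.
#'
#' @param n Number of points (>= 1).
#' @param radius Sphere radius (default 1).
#' @return `n x 3` matrix of coordinates (columns x, y, z).
#' @export
fibonacci_sphere <- function(n, radius = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1L, radius >= 0)
  i <- seq_len(n) - 1
  golden_angle <- 2 * pi * (1 - 2 / (1 + sqrt(5)))
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- golden_angle * i
  radius * cbind(x = rho * cos(theta), y = rho * sin(theta), z = z)
}

#' Average nearest-neighbor spacing of FPs on a nanocage surface
#'
#' Mean over all points of the 3D Euclidean distance to the nearest other
#' point, for `n_points` placed on a sphere of the given diameter by the
#' Fibonacci lattice. For 60 FP molecules whose chromophore centers sit on a
#' ~35 nm sphere (a ~26 nm cage plus linkers and the FP barrel) this spacing
#' is 7-8 nm — above the <5 nm range where fluorophore self-quenching becomes
#' noticeable.
#'
#' @param n_points Number of FPs on the sphere (>= 2).
#' @param sphere_diameter Sphere diameter in nm (>= 0).
#' @return Mean nearest-neighbor distance in nm. Scales exactly linearly with
#'   the diameter.
#' @examples
#' fibonacci_spacing(60, 35)  # ~7.5 nm
#' @export
fibonacci_spacing <- function(n_points, sphere_diameter) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("need at least 2 points")
  stopifnot(is.numeric(sphere_diameter), sphere_diameter >= 0)
  pts <- fibonacci_sphere(n_points, sphere_diameter / 2)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Spectral throughput of an FP in an imaging channel
#'
#' How efficiently an imaging channel excites and collects an FP's
#' fluorescence: excitation efficiency is the FP's excitation amplitude at
#' the laser line (spectrum normalized to unit peak), and emission capture is
#' the fraction of the unit-area emission spectrum falling inside the filter
#' pass-band (trapezoidal integration). The combined throughput is their
#' product; the correction factor between two channel/FP combinations is the
#' ratio of their combined throughputs.
#'
#' @param excitation_line Laser wavelength in nm; must lie inside the
#'   excitation spectrum's support.
#' @param emission_band Filter pass-band `c(low, high)` in nm; use
#'   `c(edge, Inf)` for a long-pass filter.
#' @param excitation_spectrum,emission_spectrum Two-column data.frames
#'   (`wavelength_nm`, `amplitude`), amplitudes non-negative.
#' @return List with `excitation_efficiency`, `emission_capture` (both
#'   fractions) and `throughput` (their product).
#' @export
spectral_throughput <- function(excitation_line, emission_band,
                                excitation_spectrum, emission_spectrum) {
  check_spec <- function(s, what) {
    stopifnot(is.data.frame(s), ncol(s) >= 2L)
    wl <- s[[1]]; amp <- s[[2]]
    if (any(amp < 0)) stop(sprintf("%s spectrum has negative amplitudes", what))
    if (any(diff(wl) <= 0)) stop(sprintf("%s wavelengths must increase", what))
    list(wl = wl, amp = amp)
  }
  ex <- check_spec(excitation_spectrum, "excitation")
  em <- check_spec(emission_spectrum, "emission")
  if (excitation_line < min(ex$wl) || excitation_line > max(ex$wl)) {
    stop("excitation line outside the excitation spectrum support")
  }
  ex_eff <- stats::approx(ex$wl, ex$amp / max(ex$amp),
                          xout = excitation_line)$y
  stopifnot(length(emission_band) == 2L, emission_band[1] < emission_band[2])
  area <- trapz(em$wl, em$amp)
  if (area <= 0) stop("emission spectrum has zero area")
  lo <- max(emission_band[1], min(em$wl))
  hi <- min(emission_band[2], max(em$wl))
  capture <- if (lo >= hi) 0 else {
    grid <- sort(unique(c(lo, hi, em$wl[em$wl > lo & em$wl < hi])))
    vals <- stats::approx(em$wl, em$amp, xout = grid)$y
    trapz(grid, vals) / area
  }
  list(excitation_efficiency = ex_eff, emission_capture = capture,
       throughput = ex_eff * capture)
}

#' Combine brightness and photostability into an FP comparison table
#'
#' Joins per-FP relative brightness (from [relative_brightness()]) with
#' per-FP mean half-lives and computes the relative emission yield. The
#' channel label records the imaging configuration the numbers belong to;
#' comparisons across configurations are only meaningful at matched
#' irradiance.
#'
#' @param brightness Data.frame from [relative_brightness()].
#' @param half_life_summary Data.frame from [compare_half_lives()] (`fp`,
#'   `mean_half_life_s`).
#' @param channel Label for the imaging configuration.
#' @return Data.frame `fp`, `n_cells`, `mean_cage_intensity_counts`,
#'   `relative_brightness`, `half_life_s`, `emission_yield_fold_s`,
#'   `channel`.
#' @export
fp_comparison <- function(brightness, half_life_summary, channel = "default") {
  m <- merge(brightness,
             half_life_summary[, c("fp", "mean_half_life_s")],
             by = "fp", all.x = TRUE)
  m$half_life_s <- m$mean_half_life_s
  m$mean_half_life_s <- NULL
  m$emission_yield_fold_s <- NA_real_
  valid <- is.finite(m$half_life_s) & m$half_life_s > 0 &
    is.finite(m$relative_brightness)
  if (any(valid)) {
    m$emission_yield_fold_s[valid] <-
      emission_yield(m$relative_brightness[valid], m$half_life_s[valid])
  }
  m$channel <- channel
  m[order(m$fp), ]
}
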