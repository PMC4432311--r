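#' Far-field angular spectrum of a phase ROI
#'
#' Independent route to the anisotropy: the measured phase is converted to a
#' thin-object, phase-only transmission \eqn{t(r) = \exp(i\phi(r))} over the
#' ROI bounding box (pixels outside the mask are replaced by the mean
#' in-mask transmission), apodized with a Hann window to suppress leakage
#' from hard edges, and Fourier transformed; the far-field intensity is the
#' squared modulus of the transform.  Spatial-frequency axes are returned in
#' radians per micron, centered (DC in the middle).
#'
#' @param img a [phase_image()].
#' @param roi an [roi_mask()]; its bounding box must be at least 16 x 16
#'   pixels for usable frequency support.
#' @param subtract_specular remove the coherent (unscattered) component by
#'   subtracting the mean windowed transmission before transforming; the
#'   remaining intensity is the scattered far field only.  Default FALSE so
#'   the raw spectrum keeps the zero-frequency (specular) beam.
#' @return a `farfield_spectrum`: `intensity` matrix, `qx`, `qy` axes
#'   (rad/um), `k0`, `pixel_size`, and `energy_spatial` (windowed
#'   \eqn{|t|^2} energy, for Parseval checks).
#' @export
farfield_spectrum <- function(img, roi, subtract_specular = FALSE) {
  check_roi(img, roi)
  idx <- which(roi$mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  if (nr < 16L || nc < 16L)
    stop_data(sprintf(
      "ROI bounding box %dx%d is below the 16x16 minimum for frequency support",
      nr, nc))
  phi <- img$values[r0:r1, c0:c1]
  m <- roi$mask[r0:r1, c0:c1]
  t_complex <- exp(1i * phi)
  t_complex[!m] <- mean(t_complex[m])
  if (subtract_specular) {
    ## coherent background: the incident plane wave with the ROI-mean
    ## transmission amplitude; removing it leaves the scattered field and
    ## keeps its windowed leakage out of the small-angle bins
    t_complex <- t_complex - mean(t_complex[m])
  }
  ## periodic Hann: a constant input transforms into exactly 3 DFT bins
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  w <- outer(hann(nr), hann(nc))
  tw <- t_complex * w
  F <- stats::fft(tw)
  I <- Mod(F)^2
  shift <- function(v) {
    n <- length(v); k <- ceiling(n / 2)
    c(v[(k + 1):n], v[1:k])
  }
  shift2 <- function(M) {
    n1 <- nrow(M); n2 <- ncol(M)
    k1 <- ceiling(n1 / 2); k2 <- ceiling(n2 / 2)
    M[c((k1 + 1):n1, 1:k1), c((k2 + 1):n2, 1:k2)]
  }
  freq <- function(n, h) {
    f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * h)
    2 * pi * f
  }
  structure(list(intensity = shift2(I),
                 qy = shift(freq(nr, img$pixel_size)),
                 qx = shift(freq(nc, img$pixel_size)),
                 k0 = img$k0, pixel_size = img$pixel_size,
                 energy_spatial = sum(Mod(tw)^2)),
            class = "farfield_spectrum")
}

#' Azimuthally averaged angular scattering profile
#'
#' Maps spatial frequency to scattering angle via
#' \eqn{\theta = \arcsin(q / k_0)} and averages the far-field intensity over
#' azimuth in equal-width angle bins.  The specular (q = 0) component is
#' excluded — it is unscattered light, not part of the phase function — and
#' so are evanescent frequencies (q >= k0).  Empty bins are reported as
#' missing (NA intensity, zero count), never as zero intensity.  Intensities
#' are normalized to unit total over the profile.
#'
#' @param spectrum a `farfield_spectrum`.
#' @param n_bins number of equal-width angle bins (default 90).
#' @param theta_min,theta_max angular range in degrees; `theta_max` must not
#'   exceed the collection limit `asin(na)` of the objective.
#' @param na numerical aperture bound (default 0.75, i.e. about 48.6 deg).
#' @return an `angular_profile`: data frame columns `theta_deg` (bin
#'   centers, strictly increasing), `intensity`, `count`.
#' @export
angular_profile <- function(spectrum, n_bins = 90, theta_min = 0,
                            theta_max = 45, na = 0.75) {
  if (!inherits(spectrum, "farfield_spectrum"))
    stop_parameter("`spectrum` must be a farfield_spectrum")
  check_number(n_bins, "n_bins", lower = 1)
  check_number(na, "na", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(theta_min, "theta_min", lower = 0)
  theta_na <- asin(na) * 180 / pi
  check_number(theta_max, "theta_max", lower = theta_min, upper = theta_na,
               strict_lower = TRUE)
  q <- sqrt(outer(spectrum$qy^2, spectrum$qx^2, `+`))
  keep <- q > 0 & q < spectrum$k0
  theta <- asin(q[keep] / spectrum$k0) * 180 / pi
  inten <- spectrum$intensity[keep]
  edges <- seq(theta_min, theta_max, length.out = n_bins + 1)
  bin <- findInterval(theta, edges, rightmost.closed = TRUE)
  inrange <- bin >= 1 & bin <= n_bins & theta > theta_min
  bin <- bin[inrange]; inten <- inten[inrange]
  counts <- tabulate(bin, nbins = n_bins)
  sums <- rep(0, n_bins)
  agg <- tapply(inten, bin, sum)
  sums[as.integer(names(agg))] <- agg
  mean_int <- ifelse(counts > 0, sums / counts, NA_real_)
  tot <- sum(mean_int, na.rm = TRUE)
  if (tot > 0) mean_int <- mean_int / tot
  structure(data.frame(theta_deg = (edges[-1] + edges[-length(edges)]) / 2,
                       intensity = mean_int, count = counts),
            class = c("angular_profile", "data.frame"))
}

#' Henyey-Greenstein phase function
#'
#' Probability density per unit solid angle of scattering at polar angle
#' theta for anisotropy g:
#' \deqn{p(\theta) = \frac{1}{4\pi}\,
#'   \frac{1 - g^2}{(1 + g^2 - 2 g \cos\theta)^{3/2}}}
#' It integrates to 1 over the sphere and reduces to the isotropic
#' \eqn{1/4\pi} at g = 0.
#'
#' @param theta_deg scattering angle(s), degrees.
#' @param g anisotropy, strictly inside (-1, 1).
#' @return density values, per steradian.
#' @export
hg_pdf <- function(theta_deg, g) {
  check_number(g, "g")
  if (abs(g) >= 1)
    stop_parameter(sprintf("`g` must satisfy -1 < g < 1 (got %g)", g))
  if (!is.numeric(theta_deg) || !all(is.finite(theta_deg)))
    stop_parameter("`theta_deg` must be finite numeric")
  ct <- cos(theta_deg * pi / 180)
  (1 / (4 * pi)) * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
}

## unchecked vectorized HG density used inside optimizer loops
.hg_pdf_raw <- function(theta_deg, g) {
  ct <- cos(theta_deg * pi / 180)
  (1 / (4 * pi)) * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
}

#' Fit the Henyey-Greenstein phase function to an angular profile
#'
#' Unweighted nonlinear least squares of `c * hg_pdf(theta, g)` against the
#' measured profile over `fit_range`, free parameters (c, g).  g starts at
#' 0.9 (tissue-typical, strongly forward scattering); on non-convergence the
#' fit restarts from 0.5 and 0.99.  Deterministic for a given profile.
#'
#' @param profile an `angular_profile`.
#' @param fit_range angular window `c(lo, hi)` in degrees, half-open
#'   `(lo, hi]`; default `c(2, 45)` — the lower cut keeps residual specular
#'   leakage out of the fit.
#' @return an `hg_fit_result`: `g_fit`, `r_squared`, `normalization`,
#'   `fit_range`, `n_bins_used`.
#' @export
fit_hg <- function(profile, fit_range = c(2, 45)) {
  if (!inherits(profile, "angular_profile"))
    stop_parameter("`profile` must be an angular_profile")
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    stop_parameter("`fit_range` must be c(lo, hi) with lo < hi")
  use <- profile$theta_deg > fit_range[1] &
    profile$theta_deg <= fit_range[2] &
    !is.na(profile$intensity) & profile$count > 0
  th <- profile$theta_deg[use]
  y <- profile$intensity[use]
  if (length(y) < 5L)
    stop_data(sprintf(
      "only %d non-empty bins in fit range [%g, %g]; at least 5 required",
      length(y), fit_range[1], fit_range[2]))
  if (max(y) - min(y) <= .Machine$double.eps * max(abs(y), 1)) {
    warning("degenerate (flat) profile: returning isotropic g = 0",
            call. = FALSE)
    return(structure(list(g_fit = 0, r_squared = NA_real_,
                          normalization = mean(y) * 4 * pi,
                          fit_range = fit_range, n_bins_used = length(y)),
                     class = "hg_fit_result"))
  }
  obj <- function(par) {
    g <- tanh(par[1])
    ## tanh saturates numerically at +-1 for |par| > ~19; keep strictly inside
    g <- max(min(g, 1 - 1e-12), -1 + 1e-12)
    cc <- exp(par[2])
    sum((y - cc * .hg_pdf_raw(th, g))^2)
  }
  fit_from <- function(g0) {
    c0 <- mean(y) / mean(.hg_pdf_raw(th, g0))
    stats::optim(c(atanh(g0), log(c0)), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
  }
  best <- NULL
  for (g0 in c(0.9, 0.5, 0.99)) {
    res <- tryCatch(fit_from(g0), error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop_stat("Henyey-Greenstein fit failed to converge from all starts")
  ## polish with Nelder-Mead from the BFGS optimum
  pol <- stats::optim(best$par, obj,
                      control = list(maxit = 2000, reltol = 1e-15))
  if (pol$value < best$value) best <- pol
  g_fit <- max(min(tanh(best$par[1]), 1 - 1e-12), -1 + 1e-12)
  ss_res <- best$value
  ss_tot <- sum((y - mean(y))^2)
  structure(list(g_fit = g_fit, r_squared = 1 - ss_res / ss_tot,
                 normalization = exp(best$par[2]),
                 fit_range = fit_range, n_bins_used = length(y)),
            class = "hg_fit_result")
}

#' @export
print.hg_fit_result <- function(x, ...) {
  cat(sprintf(
    "<hg_fit_result> g = %.4f, R^2 = %.4f (%d bins in (%g, %g] deg)\n",
    x$g_fit, x$r_squared, x$n_bins_used, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Anisotropy of an ROI via the far-field Henyey-Greenstein oracle
#'
#' Convenience composition: [farfield_spectrum()] then [angular_profile()]
#' then [fit_hg()].
#'
#' @inheritParams farfield_spectrum
#' @param n_bins,theta_max,na passed to [angular_profile()].
#' @param fit_range passed to [fit_hg()].
#' @return an `hg_fit_result`.
#' @export
anisotropy_from_oracle <- function(img, roi, n_bins = 90, theta_max = 45,
                                   na = 0.75, fit_range = c(2, 45)) {
  sp <- farfield_spectrum(img, roi, subtract_specular = TRUE)
  pr <- angular_profile(sp, n_bins = n_bins, theta_min = 0,
                        theta_max = theta_max, na = na)
  fit_hg(pr, fit_range = fit_range)
}
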