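#' Texture specification for synthetic stromal phase maps
#'
#' Describes a stationary random phase texture: overall phase contrast
#' (`sigma_phi`), correlation structure (`corr_len`, `anisotropy_ratio`,
#' `orientation`) and fiber fragmentation.  The isotropic Gaussian-covariance
#' case (`anisotropy_ratio = 1`, `fragmentation = 0`) has closed-form
#' gradient statistics, which makes it the analytic test bed for the
#' scattering-phase-theorem estimator: for covariance
#' \eqn{C(r) = \sigma_\phi^2 \exp(-|r|^2/\ell_c^2)} the mean squared
#' gradient magnitude is \eqn{4\sigma_\phi^2/\ell_c^2} and hence
#' \eqn{g = 1 - 2/(k_0^2 \ell_c^2)}.
#'
#' @param shape integer vector `c(rows, cols)` in pixels.
#' @param pixel_size microns per pixel (> 0).
#' @param sigma_phi phase standard deviation, radians (>= 0).
#' @param corr_len correlation length across fibers, microns (> 0).
#' @param orientation fiber axis angle, degrees (image x-axis = columns).
#' @param anisotropy_ratio ratio of correlation length along / across the
#'   fiber axis (>= 1); 1 = isotropic.
#' @param fragmentation fraction in \[0, 1\] of fiber texture replaced by
#'   short-correlation gaps.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return a `texture_spec` object.
#' @export
texture_spec <- function(shape = c(512, 512), pixel_size = 0.05,
                         sigma_phi = 0.3, corr_len = 0.5, orientation = 0,
                         anisotropy_ratio = 1, fragmentation = 0, seed = 1) {
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape)))
    stop_parameter("`shape` must be two positive integers c(rows, cols)")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(sigma_phi, "sigma_phi", lower = 0)
  check_number(corr_len, "corr_len", lower = 0, strict_lower = TRUE)
  check_number(orientation, "orientation")
  check_number(anisotropy_ratio, "anisotropy_ratio", lower = 1)
  check_number(fragmentation, "fragmentation", lower = 0, upper = 1)
  check_number(seed, "seed")
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 sigma_phi = sigma_phi, corr_len = corr_len,
                 orientation = orientation,
                 anisotropy_ratio = anisotropy_ratio,
                 fragmentation = fragmentation, seed = seed),
            class = "texture_spec")
}

is_texture_spec <- function(x) inherits(x, "texture_spec")

## Spectral synthesis of a zero-mean stationary Gaussian field with the
## (rotated, anisotropic) Gaussian covariance
##   C(dx, dy) = sigma^2 exp(-(u/l_par)^2 - (v/l_perp)^2),
## u, v = lag components along/across the fiber axis.  The target covariance
## is sampled on the torus (wrapped lags), H = sqrt(Re fft(C)) is the exact
## circulant filter, and the field is Re ifft(fft(white) * H).  Exact up to
## wrap-around, which is negligible when the domain spans many correlation
## lengths.
.grf_realization <- function(nr, nc, pixel_size, sigma, l_perp, l_par,
                             orientation_deg) {
  lag <- function(n) {
    i <- 0:(n - 1)
    ifelse(i <= n / 2, i, i - n) * pixel_size
  }
  dy <- lag(nr)                       # row lags
  dx <- lag(nc)                       # column lags
  th <- orientation_deg * pi / 180
  ## quadratic form of the rotated anisotropic Gaussian covariance
  u <- outer(dy, dx, function(y, x) x * cos(th) + y * sin(th))
  v <- outer(dy, dx, function(y, x) -x * sin(th) + y * cos(th))
  C <- sigma^2 * exp(-(u / l_par)^2 - (v / l_perp)^2)
  Chat <- Re(stats::fft(C))
  Chat[Chat < 0] <- 0                 # clip tiny negative wrap-around leakage
  H <- sqrt(Chat)
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (nr * nc)
}

#' Gaussian-random-field phase image
#'
#' Generates a stationary zero-mean Gaussian random field with Gaussian
#' covariance (isotropic when `anisotropy_ratio = 1`).  `fragmentation` must
#' be 0 here; use [gen_fiber_texture()] for fragmented textures.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [texture_spec()].
#' @return a [phase_image()] (wavelength defaults to 552 nm).
#' @seealso [gen_fiber_texture()]
#' @export
gen_grf_phase <- function(spec) {
  if (!is_texture_spec(spec)) stop_parameter("`spec` must be a texture_spec")
  if (spec$fragmentation != 0)
    stop_parameter("gen_grf_phase generates pure Gaussian fields; use gen_fiber_texture for fragmentation > 0")
  nr <- spec$shape[1]; nc <- spec$shape[2]
  vals <- if (spec$sigma_phi == 0) {
    matrix(0, nr, nc)
  } else {
    with_seed(spec$seed, {
      .grf_realization(nr, nc, spec$pixel_size, spec$sigma_phi,
                       l_perp = spec$corr_len,
                       l_par = spec$corr_len * spec$anisotropy_ratio,
                       orientation_deg = spec$orientation)
    })
  }
  phase_image(vals, pixel_size = spec$pixel_size)
}

#' Oriented fiber texture with controllable fragmentation
#'
#' Emulates stromal fiber bundles as an elongated-correlation Gaussian field
#' (correlation length `anisotropy_ratio * corr_len` along the fiber axis,
#' `corr_len` across).  Fragmentation models the breaking of long fibers
#' into shorter segments as a continuous shortening of the along-fiber
#' correlation length,
#' \deqn{\ell_{par}(f) = \ell_{perp} + (1 - f)\,(\ell_{par} - \ell_{perp}),}
#' so at `fragmentation = 1` the along-fiber correlation collapses to the
#' across-fiber value (fully fractionated, isotropic texture).  Because the
#' mean squared gradient of the anisotropic Gaussian covariance is
#' \eqn{2\sigma^2(1/\ell_{par}^2 + 1/\ell_{perp}^2)}, the anisotropy
#' \eqn{g = 1 - (1/\ell_{par}^2 + 1/\ell_{perp}^2)/k_0^2} decreases
#' *strictly monotonically* with fragmentation by construction — more
#' fractionated stroma scatters more isotropically.
#'
#' @inheritParams gen_grf_phase
#' @return a [phase_image()].
#' @export
gen_fiber_texture <- function(spec) {
  if (!is_texture_spec(spec)) stop_parameter("`spec` must be a texture_spec")
  nr <- spec$shape[1]; nc <- spec$shape[2]
  if (spec$sigma_phi == 0)
    return(phase_image(matrix(0, nr, nc), pixel_size = spec$pixel_size))
  l_perp <- spec$corr_len
  l_par_full <- spec$corr_len * spec$anisotropy_ratio
  l_par <- l_perp + (1 - spec$fragmentation) * (l_par_full - l_perp)
  vals <- with_seed(spec$seed, {
    .grf_realization(nr, nc, spec$pixel_size, spec$sigma_phi,
                     l_perp = l_perp, l_par = l_par,
                     orientation_deg = spec$orientation)
  })
  phase_image(vals, pixel_size = spec$pixel_size)
}

## sample autocorrelation of a matrix via FFT (biased, normalized to 1 at 0)
.autocorr2d <- function(m) {
  m <- m - mean(m)
  F <- stats::fft(m)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE))
  ac / ac[1, 1]
}

#' Measure autocorrelation 1/e lengths along and across an axis
#'
#' Utility used to validate generated textures: returns the lag (in microns)
#' at which the sample autocorrelation first drops below 1/e, along the given
#' axis and perpendicular to it.
#'
#' @param img a [phase_image()].
#' @param orientation axis angle in degrees.
#' @return named numeric `c(along =, across =)` in microns.
#' @export
autocorr_lengths <- function(img, orientation = 0) {
  if (!is_phase_image(img)) stop_parameter("`img` must be a phase_image")
  ac <- .autocorr2d(img$values)
  nr <- nrow(ac); nc <- ncol(ac)
  th <- orientation * pi / 180
  trace_len <- function(vx, vy) {
    ## walk outward along direction (vx, vy) in pixel steps
    max_steps <- floor(min(nr, nc) / 2) - 1L
    for (s in seq_len(max_steps)) {
      r <- (round(s * vy)) %% nr + 1L
      c <- (round(s * vx)) %% nc + 1L
      if (ac[r, c] < exp(-1)) return(s * img$pixel_size)
    }
    max_steps * img$pixel_size
  }
  c(along = trace_len(cos(th), sin(th)),
    across = trace_len(-sin(th), cos(th)))
}

#' Scattering-consistent stromal texture with target anisotropy
#'
#' Generates a stationary Gaussian phase texture whose far-field scattering
#' is a physically consistent model of smooth stroma with anisotropy `g`:
#' a forward lobe whose in-band angular profile is Henyey-Greenstein-shaped
#' with parameter `g` (coarse fiber bundles), plus a quasi-periodic
#' fine-fibril component appearing as a diffraction ring at spatial
#' frequency `ring_q` (scattering angle about `asin(ring_q/k0)`, ~35 deg at
#' the defaults).  The energy fraction of the ring is not free: it is fixed
#' by requiring the total in-band second moment of the spectrum to equal
#' `2 k0^2 (1 - g)` — i.e. the texture's mean-cosine anisotropy equals the
#' shape parameter of its forward lobe, as must hold for any tissue on
#' which the moment-based theorem and the phase-function fit agree.  Both
#' estimation routes therefore measure the *same* g on these fields, up to
#' estimator bias.  Targets outside the feasible band (ring weight leaving
#' \[0, 1\], roughly g in (0.83, 0.99) at the defaults) raise a parameter
#' error.
#'
#' When fitting these textures with [fit_hg()], restrict the fit range to
#' the forward lobe (e.g. `c(2, 25)` degrees) so the fibril ring is not fit
#' as part of the phase function.
#'
#' @param g target anisotropy, inside the feasible band.
#' @param shape `c(rows, cols)` pixels.
#' @param pixel_size microns per pixel.
#' @param sigma_phi phase sd, radians (keep modest, ~0.3, so the thin-object
#'   Born picture holds).
#' @param ring_q fibril-ring spatial frequency, rad/um (default 6.5).
#' @param ring_width ring Gaussian width, rad/um (default 0.8).
#' @param na numerical aperture defining the band limit (default 0.75).
#' @param wavelength center wavelength, nm.
#' @param seed RNG seed.
#' @return a [phase_image()]; attribute `ring_weight` records the fibril
#'   energy fraction.
#' @export
gen_scattering_texture <- function(g, shape = c(1024, 1024),
                                   pixel_size = 0.05, sigma_phi = 0.3,
                                   ring_q = 6.5, ring_width = 0.8,
                                   na = 0.75, wavelength = 552, seed = 1) {
  check_number(g, "g", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(sigma_phi, "sigma_phi", lower = 0, strict_lower = TRUE)
  check_number(ring_q, "ring_q", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  k0 <- 2 * pi / (wavelength * 1e-3)
  fq <- function(n) {
    f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * pixel_size)
    2 * pi * f
  }
  qy <- fq(nr); qx <- fq(nc)
  q <- sqrt(outer(qy^2, qx^2, `+`))
  band <- q > 0 & q < k0 * na
  th <- asin(pmin(q[band] / k0, 1))
  S_core <- matrix(0, nr, nc)
  S_core[band] <- hg_pdf(th * 180 / pi, g)
  S_ring <- matrix(0, nr, nc)
  S_ring[band] <- exp(-(q[band] - ring_q)^2 / (2 * ring_width^2))
  ## moment matching uses the *discrete* central-difference gradient
  ## response sin(q h)/h, the operator the theorem estimator actually
  ## applies, so the designed anisotropy is pixel-size exact
  h <- pixel_size
  q2_disc <- outer(sin(qy * h)^2, sin(qx * h)^2, `+`) / h^2
  E_core <- sum(q2_disc * S_core) / sum(S_core)
  E_ring <- sum(q2_disc * S_ring) / sum(S_ring)
  w <- (2 * k0^2 * (1 - g) - E_core) / (E_ring - E_core)
  if (!is.finite(w) || w < 0 || w > 1)
    stop_parameter(sprintf(
      "g = %g is outside the feasible anisotropy band of this texture family (ring weight %.3f)",
      g, w))
  S <- (1 - w) * S_core / sum(S_core) + w * S_ring / sum(S_ring)
  vals <- with_seed(seed, {
    wht <- matrix(stats::rnorm(nr * nc), nr, nc)
    Re(stats::fft(stats::fft(wht) * sqrt(S), inverse = TRUE)) / (nr * nc)
  })
  vals <- vals * sigma_phi / stats::sd(as.vector(vals))
  out <- phase_image(vals, pixel_size = pixel_size, wavelength = wavelength)
  attr(out, "ring_weight") <- w
  out
}
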