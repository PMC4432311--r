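test_that("phase_gradient: constant and linear-ramp fields are exact", {
  img <- phase_image(matrix(3.2, 8, 8), pixel_size = 0.1)
  gr <- phase_gradient(img)
  expect_true(all(gr$ddx == 0) && all(gr$ddy == 0))

  # ramp along columns (x): a = 2 rad/um, pixel 0.1 um
  a <- 2
  ramp <- matrix(rep(a * 0.1 * (0:9), each = 6), 6, 10)
  gr2 <- phase_gradient(phase_image(ramp, pixel_size = 0.1))
  expect_equal(gr2$ddx[, 2:9], matrix(a, 6, 8), tolerance = 1e-12)
  expect_equal(max(abs(gr2$ddy)), 0, tolerance = 1e-12)

  expect_data_error(phase_gradient(phase_image(matrix(0, 2, 5), 0.1)))
})

test_that("phase_gradient: sinusoid mean squared gradient matches analytic value", {
  # phi = A sin(2 pi x / L) over whole periods: mean |grad|^2 = A^2 (2pi/L)^2 / 2
  A <- 0.7; L <- 4; h <- 0.05
  n <- 320  # 320 px * 0.05 um = 16 um = 4 whole periods
  x <- (0:(n - 1)) * h
  img <- phase_image(matrix(rep(A * sin(2 * pi * x / L), each = 64), 64, n),
                     pixel_size = h)
  gr <- phase_gradient(img)
  interior <- gr$ddx[, 2:(n - 1)]
  expect_equal(mean(interior^2), A^2 * (2 * pi / L)^2 / 2, tolerance = 0.01)
})

test_that("roi_moments: two-point field and restriction to the mask", {
  v <- matrix(0, 10, 10); v[, 6:10] <- 1
  img <- phase_image(v, pixel_size = 0.1)
  roi <- roi_mask(matrix(TRUE, 10, 10))
  m <- roi_moments(img, roi = roi)
  expect_equal(m$var_term, 0.25)
  expect_equal(m$n_pixels, 100L)

  # moments must ignore out-of-mask pixels entirely
  v2 <- v; v2[1, 1] <- 1e6
  mask <- matrix(TRUE, 10, 10); mask[1, ] <- FALSE
  m2a <- roi_moments(phase_image(v, 0.1), roi = roi_mask(mask))
  m2b <- roi_moments(phase_image(v2, 0.1), roi = roi_mask(mask))
  expect_equal(m2a$var_term, m2b$var_term)

  const <- phase_image(matrix(1.5, 8, 8), 0.1)
  mc <- roi_moments(const, roi = full_mask(const))
  expect_equal(mc$grad_term, 0)
  expect_equal(mc$var_term, 0)
})

test_that("anisotropy: offset invariance and undefined-variance error", {
  img <- small_grf(seed = 5, n = 256)
  roi <- full_mask(img)
  g1 <- anisotropy_from_phase(img, roi)$g
  shifted <- phase_image(img$values + 1.7, img$pixel_size, img$wavelength)
  expect_equal(anisotropy_from_phase(shifted, roi)$g, g1, tolerance = 1e-12)

  const <- phase_image(matrix(2, 8, 8), 0.1)
  expect_error(anisotropy_from_phase(const, full_mask(const)),
               class = "qpianiso_error_undefined_anisotropy")
})

test_that("anisotropy of the isotropic GRF matches the closed form, independent of sigma_phi", {
  # g = 1 - 2/(k0^2 l^2), no dependence on the phase contrast
  ell <- 0.5
  k0 <- 2 * pi / 0.552
  expected <- 1 - 2 / (k0^2 * ell^2)
  g_lo <- anisotropy_from_phase(small_grf(seed = 11, n = 512, corr_len = ell,
                                          sigma_phi = 0.2),
                                roi_mask(matrix(TRUE, 512, 512)))$g
  g_hi <- anisotropy_from_phase(small_grf(seed = 11, n = 512, corr_len = ell,
                                          sigma_phi = 0.8),
                                roi_mask(matrix(TRUE, 512, 512)))$g
  expect_equal(g_lo, expected, tolerance = 0.01)
  # same seed, amplitude scaled: the ratio is exactly amplitude-free
  expect_equal(g_lo, g_hi, tolerance = 1e-10)
})

test_that("out-of-range g is flagged and warned, not clipped", {
  # white noise at fine pixels has huge gradient term -> g < 0
  set.seed(3)
  img <- phase_image(matrix(rnorm(64 * 64), 64, 64), pixel_size = 0.05)
  expect_warning(res <- anisotropy_from_phase(img, full_mask(img)),
                 "outside")
  expect_true(res$out_of_range)
  expect_lt(res$g, 0)
})

test_that("variant B uses the alternative moment combination", {
  img <- small_grf(seed = 5, n = 256)
  roi <- full_mask(img)
  mA <- roi_moments(img, roi = roi, variant = "A")
  mB <- roi_moments(img, roi = roi, variant = "B")
  # Cauchy-Schwarz: (mean |grad|)^2 <= mean |grad|^2
  expect_lt(mB$grad_term, mA$grad_term)
  resB <- suppressWarnings(anisotropy_from_phase(img, roi, variant = "B"))
  expect_equal(resB$g, 1 - mB$grad_term / (2 * img$k0^2 * mB$var_term^2),
               tolerance = 1e-12)
  expect_identical(resB$variant, "B")
})

test_that("variant selection: A agrees with the HG oracle, B does not", {
  tex <- gen_scattering_texture(0.94, shape = c(512, 512), pixel_size = 0.1,
                                ring_q = 7.2, ring_width = 0.5, seed = 2)
  roi <- full_mask(tex)
  gA <- anisotropy_from_phase(tex, roi, variant = "A")$g
  gB <- suppressWarnings(anisotropy_from_phase(tex, roi, variant = "B")$g)
  hg <- anisotropy_from_oracle(tex, roi, fit_range = c(2, 20))$g_fit
  expect_lt(abs(gA - hg), 0.05)   # single small field: loose agreement
  expect_gt(abs(gB - hg), 0.1)    # variant B is not even close
})

test_that("background_noise estimates moment noise within 15% of a Monte-Carlo oracle", {
  noise_sd <- 0.02; h <- 0.05
  nbg <- 512
  set.seed(31)
  bg_img <- phase_image(matrix(rnorm(nbg * nbg, 0, noise_sd), nbg, nbg), h)
  bg <- roi_mask(matrix(TRUE, nbg, nbg))
  est <- background_noise(bg_img, bg, block_size = 32)
  expect_equal(est$n_blocks, 256L)

  # oracle: repeat the full-region measurement under fresh noise; moments
  # taken over an interior region so all gradients are central differences,
  # matching the interior blocks of the estimator
  set.seed(32)
  interior <- matrix(FALSE, nbg + 4, nbg + 4)
  interior[3:(nbg + 2), 3:(nbg + 2)] <- TRUE
  mc <- replicate(150, {
    ni <- phase_image(matrix(rnorm((nbg + 4)^2, 0, noise_sd), nbg + 4,
                             nbg + 4), h)
    m <- roi_moments(ni, roi = roi_mask(interior))
    c(m$grad_term, m$var_term)
  })
  expect_equal(est$sd_grad_term, sd(mc[1, ]), tolerance = 0.15)
  expect_equal(est$sd_var_term, sd(mc[2, ]), tolerance = 0.15)

  # doubled noise raises both components
  set.seed(31)
  bg2 <- phase_image(matrix(rnorm(nbg * nbg, 0, 2 * noise_sd), nbg, nbg), h)
  est2 <- background_noise(bg2, bg, block_size = 32)
  expect_gt(est2$sd_grad_term, est$sd_grad_term)
  expect_gt(est2$sd_var_term, est$sd_var_term)

  # exactly zero background: both stds zero
  z <- phase_image(matrix(0, 128, 128), h)
  ez <- background_noise(z, roi_mask(matrix(TRUE, 128, 128)))
  expect_equal(ez$sd_grad_term, 0)
  expect_equal(ez$sd_var_term, 0)

  # fewer than 2 full blocks
  tiny <- phase_image(matrix(rnorm(40 * 40), 40, 40), h)
  expect_data_error(background_noise(tiny, roi_mask(matrix(TRUE, 40, 40)),
                                     block_size = 32))
})

test_that("g_uncertainty: zero noise, single-term and Monte-Carlo agreement", {
  img <- small_grf(seed = 5, n = 256)
  res <- anisotropy_from_phase(img, full_mask(img))
  mk_noise <- function(sg, sv) structure(
    list(sd_grad_term = sg, sd_var_term = sv, n_blocks = 8, n_pixels = 64,
         block_size = 32, variant = "A"), class = "noise_estimate")

  expect_equal(g_uncertainty(res, mk_noise(0, 0))$sigma_g, 0)

  # noise in the gradient term only: |dg/da| * sd exactly
  sg <- 0.05
  expect_equal(g_uncertainty(res, mk_noise(sg, 0))$sigma_g,
               sg / (2 * res$k0^2 * res$var_term), tolerance = 1e-12)

  # both terms noisy: first-order propagation within 20% of moment-space MC
  sv <- 0.1 * res$var_term; sa <- 0.1 * res$grad_term
  prop <- g_uncertainty(res, mk_noise(sa, sv))$sigma_g
  set.seed(12)
  mc <- replicate(20000, {
    a <- res$grad_term + rnorm(1, 0, sa)
    b <- res$var_term + rnorm(1, 0, sv)
    1 - a / (2 * res$k0^2 * b)
  })
  expect_equal(prop, sd(mc), tolerance = 0.2)

  # variant mismatch is refused
  resB <- suppressWarnings(anisotropy_from_phase(img, full_mask(img),
                                                 variant = "B"))
  expect_parameter_error(g_uncertainty(resB, mk_noise(1, 1)))
})
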