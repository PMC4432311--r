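## binary dilation with a 3x3 cross, `iter` times (used for the stromal band)
.dilate <- function(m, iter) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(iter)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nr, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -nc, drop = FALSE])
    m <- m | up | dn | lf | rt
  }
  m
}

#' Synthetic tissue-core phase image with glands and stromal bands
#'
#' Builds the synthetic analogue of a single tissue-microarray core: a
#' fiber-textured stromal background (from [gen_fiber_texture()]) into which
#' low-phase gland lumens are punched.  Glands are ellipses with an
#' irregular (harmonically perturbed) boundary, laid out on a jittered grid.
#' Each stromal region of interest is the morphological band of
#' `band_width` pixels immediately outside one gland boundary, minus the
#' interiors of all glands — mirroring the single adjoining fiber layer a
#' pathologist would outline, whose width varies with gland size and fiber
#' swelling, hence the parameter.
#'
#' @param n_glands number of glands (>= 1).
#' @param canvas integer `c(rows, cols)`, pixels.
#' @param gland_radius_px mean gland radius, pixels.
#' @param band_width stromal band width, pixels (> 0 for non-empty ROIs).
#' @param texture a [texture_spec()] for the stroma; its `shape` is replaced
#'   by `canvas`.
#' @param lumen_sigma phase sd inside gland lumens, radians (near-empty
#'   lumen).
#' @param seed RNG seed for layout and lumen noise.
#' @return list with `image` ([phase_image()]), `gland_masks` (list of
#'   [roi_mask()]), `stromal_rois` (list of [roi_mask()], one per gland,
#'   disjoint from every gland interior).
#' @export
gen_core_image <- function(n_glands = 4, canvas = c(1000, 1000),
                           gland_radius_px = 120, band_width = 10,
                           texture = texture_spec(), lumen_sigma = 0.02,
                           seed = 1) {
  check_number(n_glands, "n_glands", lower = 1)
  if (length(canvas) != 2L || any(canvas < 32))
    stop_parameter("`canvas` must be two integers >= 32")
  check_number(gland_radius_px, "gland_radius_px", lower = 4)
  check_number(band_width, "band_width", lower = 0)
  if (band_width == 0)
    stop_parameter("`band_width` = 0 yields empty stromal ROIs")
  if (!is_texture_spec(texture))
    stop_parameter("`texture` must be a texture_spec")
  nr <- as.integer(canvas[1]); nc <- as.integer(canvas[2])

  ## jittered-grid layout; refuse layouts that cannot fit
  kr <- ceiling(sqrt(n_glands * nr / nc))
  kc <- ceiling(n_glands / kr)
  cell_r <- nr / kr; cell_c <- nc / kc
  margin <- gland_radius_px * 1.35 + band_width
  if (cell_r < 2 * margin || cell_c < 2 * margin)
    stop_data(sprintf(
      "%d gland(s) of radius %g px (+band %g) do not fit a %dx%d canvas",
      n_glands, gland_radius_px, band_width, nr, nc))

  tx <- texture
  tx$shape <- c(nr, nc)
  stroma <- gen_fiber_texture(tx)

  res <- with_seed(seed, {
    img <- stroma$values
    cells <- expand.grid(gr = seq_len(kr), gc = seq_len(kc))[seq_len(n_glands), ]
    gland_masks <- vector("list", n_glands)
    row_grid <- matrix(seq_len(nr), nr, nc)
    col_grid <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(n_glands)) {
      cy <- (cells$gr[i] - 0.5) * cell_r + stats::runif(1, -0.1, 0.1) * cell_r
      cx <- (cells$gc[i] - 0.5) * cell_c + stats::runif(1, -0.1, 0.1) * cell_c
      a <- gland_radius_px * stats::runif(1, 0.85, 1.15)
      b <- a * stats::runif(1, 0.7, 1)
      rot <- stats::runif(1, 0, pi)
      nharm <- 3L
      amp <- stats::runif(nharm, 0, 0.08)
      ph <- stats::runif(nharm, 0, 2 * pi)
      dyp <- row_grid - cy; dxp <- col_grid - cx
      u <- dxp * cos(rot) + dyp * sin(rot)
      v <- -dxp * sin(rot) + dyp * cos(rot)
      rho <- sqrt((u / a)^2 + (v / b)^2)
      ang <- atan2(v / b, u / a)
      pert <- 1
      for (h in seq_len(nharm))
        pert <- pert + amp[h] * cos((h + 1) * ang + ph[h])
      gmask <- rho <= pert
      gland_masks[[i]] <- gmask
      img[gmask] <- stats::rnorm(sum(gmask), 0, lumen_sigma)
    }
    list(img = img, gland_masks = gland_masks)
  })

  all_glands <- Reduce(`|`, res$gland_masks)
  ## 2-px standoff: central-difference gradients one pixel outside a gland
  ## reach into the lumen, so the band starts 2 px clear of every boundary
  standoff <- .dilate(all_glands, 2L)
  stromal_rois <- vector("list", n_glands)
  for (i in seq_len(n_glands)) {
    band <- .dilate(res$gland_masks[[i]], as.integer(band_width) + 2L) &
      !standoff
    if (!any(band))
      stop_data(sprintf("stromal ROI for gland %d is empty", i))
    stromal_rois[[i]] <- roi_mask(band, label = sprintf("stroma_%02d", i),
                                  gland_id = i)
  }
  list(image = phase_image(res$img, pixel_size = texture$pixel_size),
       gland_masks = lapply(seq_len(n_glands), function(i)
         roi_mask(res$gland_masks[[i]], label = sprintf("gland_%02d", i),
                  gland_id = i)),
       stromal_rois = stromal_rois)
}
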