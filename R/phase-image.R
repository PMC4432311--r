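#' Phase image
#'
#' A quantitative phase map: a 2-D matrix of optical phase shifts (radians)
#' with the physical pixel size and the illumination center wavelength.  The
#' wavenumber \eqn{k_0 = 2\pi/\bar\lambda} (radians per micron) is derived.
#' All anisotropy computations operate on this container.
#'
#' @param values numeric matrix of phase values, radians. Must be finite.
#' @param pixel_size physical pixel size, microns per pixel (> 0).
#' @param wavelength center wavelength of illumination, nanometres (> 0).
#'   Default 552 nm (white-light phase-contrast center wavelength).
#' @return an object of class `phase_image` with elements `values`,
#'   `pixel_size`, `wavelength` (nm) and `k0` (rad/um).
#' @examples
#' img <- phase_image(matrix(0, 8, 8), pixel_size = 0.1)
#' img$k0   # 2*pi / 0.552
#' @export
phase_image <- function(values, pixel_size, wavelength = 552) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_parameter("`values` must be a numeric matrix")
  if (!all(is.finite(values)))
    stop_parameter("`values` must be finite everywhere")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  structure(
    list(values = values,
         pixel_size = pixel_size,
         wavelength = wavelength,
         k0 = 2 * pi / (wavelength * 1e-3)),  # rad per micron
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf(
    "<phase_image> %d x %d px, %.4g um/px, lambda = %g nm (k0 = %.4g rad/um)\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$wavelength, x$k0))
  cat(sprintf("  phase range [%.4g, %.4g] rad, sd %.4g rad\n",
              min(x$values), max(x$values), stats::sd(as.vector(x$values))))
  invisible(x)
}

#' @export
dim.phase_image <- function(x) dim(x$values)

is_phase_image <- function(x) inherits(x, "phase_image")

#' Region-of-interest mask
#'
#' A binary mask congruent with a [phase_image()] grid, designating e.g. a
#' stromal region adjoining a gland.  Any computation requires at least one
#' selected pixel.
#'
#' @param mask logical matrix (or 0/1 numeric matrix) selecting pixels.
#' @param label optional character label.
#' @param gland_id optional identifier of the gland the region adjoins.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = NULL, gland_id = NULL) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop_parameter("numeric `mask` must contain only 0/1")
    mask <- array(mask != 0, dim = dim(mask))
  }
  if (!is.matrix(mask) || !is.logical(mask))
    stop_parameter("`mask` must be a logical matrix")
  if (anyNA(mask)) stop_parameter("`mask` must not contain NA")
  structure(list(mask = mask, label = label, gland_id = gland_id),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d selected%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

is_roi_mask <- function(x) inherits(x, "roi_mask")

check_roi <- function(img, roi, require_nonempty = TRUE) {
  if (!is_phase_image(img)) stop_parameter("`img` must be a phase_image")
  if (!is_roi_mask(roi)) stop_parameter("`roi` must be a roi_mask")
  if (!identical(dim(img$values), dim(roi$mask)))
    stop_data(sprintf("ROI shape (%s) does not match image shape (%s)",
                      paste(dim(roi$mask), collapse = "x"),
                      paste(dim(img$values), collapse = "x")))
  if (require_nonempty && !any(roi$mask))
    stop_data("ROI is empty: at least one selected pixel is required")
  invisible(TRUE)
}
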