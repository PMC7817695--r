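#' Calibrated plateau image
#'
#' Container for a joint-surface-replica image: pixel values, the area of a
#' pixel in micrometres squared, and a logical mask of the current selection
#' (pixels outside the selection are excluded from every measurement).
#'
#' The default geometry mirrors the acquisition setup: a 1536 x 1536 pixel
#' field of view of 1800 x 1800 um gives a pixel area of
#' (1800/1536)^2 = 1.3733 um^2.
#'
#' @param pixels numeric matrix of gray values.
#' @param pixel_area area per pixel in um^2 (> 0).
#' @param mask logical selection matrix; defaults to the full frame.
#' @param bits image bit depth (8 or 16).
#' @return an object of class `plateau_image`.
#' @export
plateau_image <- function(pixels, pixel_area, mask = NULL, bits = 16L) {
  stopifnot(is.matrix(pixels), pixel_area > 0, bits %in% c(8L, 16L))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(identical(dim(mask), dim(pixels)))
  structure(list(pixels = pixels, pixel_area = pixel_area,
                 mask = mask, bits = as.integer(bits)),
            class = "plateau_image")
}

#' @export
print.plateau_image <- function(x, ...) {
  cat(sprintf("<plateau_image> %d x %d px, %.4f um^2/px, %d-bit, %d px selected\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_area, x$bits,
              sum(x$mask)))
  invisible(x)
}

#' Microradiograph with calibration standards
#'
#' @param pixels numeric matrix of raw gray values.
#' @param pixel_size pixel size in um.
#' @param standards named numeric vector `c(plastic = , steel = )` of raw
#'   gray levels of the plastic (minimum) and steel (maximum) standards;
#'   plastic must be below steel.
#' @return an object of class `radiograph`.
#' @export
radiograph <- function(pixels, pixel_size, standards) {
  stopifnot(is.matrix(pixels), pixel_size > 0,
            all(c("plastic", "steel") %in% names(standards)))
  if (standards[["plastic"]] >= standards[["steel"]])
    stop("plastic standard level must be below the steel level")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 standards = standards),
            class = "radiograph")
}

#' Mineral density volume
#'
#' A 3D field of mineral density in mg HA/cm^3 with isotropic voxels.
#' Axis convention: dimension 1 is x (medial-lateral), dimension 2 is y
#' (anterior-posterior), dimension 3 is z (proximal-distal, increasing
#' distally, i.e. away from the articular surface).
#'
#' @param voxels 3D numeric array of densities.
#' @param voxel_size voxel edge length in um (> 0).
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(voxels, voxel_size) {
  stopifnot(length(dim(voxels)) == 3, voxel_size > 0, all(is.finite(voxels)))
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<density_volume> %d x %d x %d voxels at %.3g um, %.0f-%.0f mg HA/cm^3\n",
              d[1], d[2], d[3], x$voxel_size, min(x$voxels), max(x$voxels)))
  invisible(x)
}
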