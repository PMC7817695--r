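#' Specification of a synthetic calibrated microradiograph
#'
#' A radiograph containing uniform rectangular plastic (minimum) and steel
#' (maximum) calibration standards and a bone-like object of width
#' `tibia_width_px` with its growth-plate landmark at `growth_plate_row`.
#' The standards are exact uniform patches before noise is added.
#'
#' @param image_shape integer (rows, cols).
#' @param plastic_gray,steel_gray raw gray levels of the standards
#'   (plastic < steel, both within 16-bit range).
#' @param bone_gray_range range of raw gray levels of bone pixels; must lie
#'   within (plastic_gray, steel_gray].
#' @param growth_plate_row pixel row of the growth-plate landmark.
#' @param tibia_width_px width of the bone object at the growth plate.
#' @param bone_top_row topmost row of the bone object (the subchondral
#'   anchor); defaults to a third of the way down.
#' @param noise_sd gaussian pixel noise, gray levels.
#' @param pixel_size pixel size in um (10 um matches the acquisition setup).
#' @param seed integer seed.
#' @return an object of class `radiograph_spec`.
#' @export
radiograph_spec <- function(image_shape = c(400L, 300L),
                            plastic_gray = 10000,
                            steel_gray = 50000,
                            bone_gray_range = c(22000, 40000),
                            growth_plate_row = 260L,
                            tibia_width_px = 120L,
                            bone_top_row = NULL,
                            noise_sd = 200,
                            pixel_size = 10,
                            seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            growth_plate_row > 1, tibia_width_px > 1, noise_sd >= 0)
  if (plastic_gray >= steel_gray)
    stop("plastic_gray must be below steel_gray")
  grays <- c(plastic_gray, steel_gray, bone_gray_range)
  if (any(grays < 0 | grays > 65535))
    stop("gray levels outside the 16-bit range")
  if (bone_gray_range[1] <= plastic_gray || bone_gray_range[2] > steel_gray)
    stop("bone grays must lie within (plastic_gray, steel_gray]")
  bone_top_row <- bone_top_row %||% max(2L, round(image_shape[1] / 3))
  if (bone_top_row >= growth_plate_row)
    stop("bone_top_row must be above growth_plate_row")
  structure(as.list(environment()), class = "radiograph_spec")
}

#' Generate a synthetic microradiograph with standards and bone mask
#'
#' @param spec a [radiograph_spec()].
#' @return a list with `radiograph` (a [radiograph] whose standard levels
#'   are the exact patch values), `standards_boxes` (1-based row/col extents
#'   of the plastic and steel patches), `bone_mask` (logical), and
#'   `anchor_row` (topmost bone row, the subchondral ROI anchor).
#' @export
generate_radiograph <- function(spec) {
  stopifnot(inherits(spec, "radiograph_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  with_seed(split_seed(spec$seed, 1L), {
    pixels <- matrix(2000, nr, nc)  # unexposed background
    # plastic patch: right edge; steel patch: bottom edge
    pw <- max(8L, round(nc / 8)); ph <- max(12L, round(nr / 5))
    plastic_box <- c(row0 = 10L, row1 = 10L + ph, col0 = nc - pw - 4L,
                     col1 = nc - 4L)
    steel_box <- c(row0 = nr - ph - 4L, row1 = nr - 4L, col0 = 10L,
                   col1 = 10L + pw)
    pixels[plastic_box["row0"]:plastic_box["row1"],
           plastic_box["col0"]:plastic_box["col1"]] <- spec$plastic_gray
    pixels[steel_box["row0"]:steel_box["row1"],
           steel_box["col0"]:steel_box["col1"]] <- spec$steel_gray
    # bone object: vertical shaft spanning tibia_width_px, top at anchor row
    mid <- round(nc / 2)
    half <- floor(spec$tibia_width_px / 2)
    cols <- clip(seq(mid - half, mid - half + spec$tibia_width_px - 1), 1, nc)
    rows <- spec$bone_top_row:min(nr, spec$growth_plate_row + 20L)
    bone_mask <- matrix(FALSE, nr, nc)
    bone_mask[rows, cols] <- TRUE
    pixels[bone_mask] <- runif(sum(bone_mask), spec$bone_gray_range[1],
                               spec$bone_gray_range[2])
    if (spec$noise_sd > 0)
      pixels <- pixels + rnorm(length(pixels), 0, spec$noise_sd)
    pixels <- round(clip(pixels, 0, 65535))
    list(radiograph = radiograph(pixels, spec$pixel_size,
                                 c(plastic = spec$plastic_gray,
                                   steel = spec$steel_gray)),
         standards_boxes = list(plastic = plastic_box, steel = steel_box),
         bone_mask = bone_mask,
         anchor_row = spec$bone_top_row,
         spec = spec)
  })
}
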