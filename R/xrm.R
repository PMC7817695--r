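# Subchondral X-ray microradiography: stretch raw grays between the
# plastic (minimum) and steel (maximum) standards into 256 bins, place a
# scaled subchondral ROI, and report the median bin as relative bone
# mineral content. The aluminium standard present in acquisition images is
# not used by the calibration.

#' Calibrate a radiograph against its plastic and steel standards
#'
#' Each raw gray g maps to bin round(255 * (g - plastic)/(steel - plastic)),
#' rounded half up and clipped to 0..255, so the plastic level lands in bin
#' 0 and the steel level in bin 255.
#'
#' @param raw a [radiograph] with its `standards` levels set.
#' @return an object of class `calibrated_image`: integer bin matrix
#'   (0..255) plus the standards used.
#' @export
calibrate <- function(raw) {
  stopifnot(inherits(raw, "radiograph"))
  p <- raw$standards[["plastic"]]; s <- raw$standards[["steel"]]
  if (s <= p) stop("steel standard level must exceed the plastic level")
  bins <- clip(round_half_up(255 * (raw$pixels - p) / (s - p)), 0, 255)
  structure(list(bins = bins, pixel_size = raw$pixel_size,
                 standards = raw$standards),
            class = "calibrated_image")
}

#' Place a scaled subchondral region of interest
#'
#' The ROI is a box of height 9% and width 34% of the growth-plate width
#' (rounded to the nearest pixel, halves up), horizontally centred on the
#' plateau column range, with its top edge at the topmost bone pixel (first
#' bin at or above `bone_bin_threshold`) within that column range -- the
#' bone directly beneath the tibial plateau.
#'
#' @param image a `calibrated_image` from [calibrate()].
#' @param side `"medial"` or `"lateral"` (recorded, not used geometrically).
#' @param growth_plate_width tibial width at the growth plate, px.
#' @param plateau_column_range inclusive (first, last) columns under the
#'   plateau.
#' @param bone_bin_threshold calibrated bin that counts as bone; default 48
#'   (the top of the lowest pseudocolour band of the 16-colour LUT).
#' @return a list of class `subchondral_roi` with `side`,
#'   `box` = c(row0, row1, col0, col1), `height`, `width`, `anchor_row`.
#' @export
place_roi <- function(image, side = c("medial", "lateral"),
                      growth_plate_width, plateau_column_range,
                      bone_bin_threshold = 48) {
  stopifnot(inherits(image, "calibrated_image"), growth_plate_width > 0)
  side <- match.arg(side)
  cols <- plateau_column_range[1]:plateau_column_range[2]
  sub <- image$bins[, cols, drop = FALSE]
  rows_hit <- which(apply(sub >= bone_bin_threshold, 1, any))
  if (!length(rows_hit))
    stop("no pixel at or above the bone bin threshold in the plateau columns")
  top <- min(rows_hit)
  h <- max(1, round_half_up(0.09 * growth_plate_width))
  w <- max(1, round_half_up(0.34 * growth_plate_width))
  centre <- mean(plateau_column_range)
  c0 <- round_half_up(centre - w / 2)
  box <- c(row0 = top, row1 = top + h - 1, col0 = c0, col1 = c0 + w - 1)
  if (box["row1"] > nrow(image$bins) || box["col0"] < 1 ||
      box["col1"] > ncol(image$bins))
    stop("scaled ROI exceeds the image bounds")
  structure(list(side = side, box = box, height = h, width = w,
                 anchor_row = top,
                 growth_plate_width = growth_plate_width,
                 bone_bin_threshold = bone_bin_threshold),
            class = "subchondral_roi")
}

#' Median calibrated gray of an ROI: the relative bone mineral content
#'
#' Builds the 256-bin histogram of the ROI and returns the smallest bin at
#' which the cumulative pixel count reaches 50%.
#'
#' @param calibrated a `calibrated_image`.
#' @param roi a `subchondral_roi` (or a c(row0, row1, col0, col1) box).
#' @return a list of class `bmc_result` with `median_bin` (relative BMC)
#'   and `histogram` (counts for bins 0..255).
#' @export
median_gray <- function(calibrated, roi) {
  stopifnot(inherits(calibrated, "calibrated_image"))
  box <- if (inherits(roi, "subchondral_roi")) roi$box else roi
  vals <- calibrated$bins[box[1]:box[2], box[3]:box[4]]
  n <- length(vals)
  if (n == 0) stop("empty ROI")
  h <- tabulate(as.vector(vals) + 1L, nbins = 256L)
  cum <- cumsum(h)
  median_bin <- which(cum >= n / 2)[1] - 1L
  structure(list(median_bin = median_bin,
                 histogram = stats::setNames(h, 0:255),
                 n_pixels = n),
            class = "bmc_result")
}

#' @export
print.bmc_result <- function(x, ...) {
  cat(sprintf("<bmc_result> relative BMC = bin %d of 255 (%d px)\n",
              x$median_bin, x$n_pixels))
  invisible(x)
}
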