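#' Label connected components of a binary image
#'
#' 8-connected labelling (the particle-analysis convention). `NA` pixels
#' count as background.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask[is.na(mask)] <- FALSE
  .cc_label2d(mask, as.integer(connectivity))
}

# assign enclosed background holes to their surrounding particle label
# (8-connected foreground pairs with 4-connected background)
fill_particle_holes <- function(lab) {
  bg <- lab == 0
  bglab <- .cc_label2d(bg, 4L)
  kb <- attr(bglab, "n_labels")
  if (kb == 0) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(bglab[1, ], bglab[nr, ], bglab[, 1], bglab[, nc]))
  holes <- setdiff(seq_len(kb), border[border > 0])
  for (h in holes) {
    idx <- which(bglab == h, arr.ind = TRUE)
    i <- idx[1, 1]; j <- idx[1, 2]
    owner <- 0L
    for (k in seq_len(9)) {
      ni <- i + (k - 1) %% 3 - 1; nj <- j + (k - 1) %/% 3 - 1
      if (ni >= 1 && nj >= 1 && ni <= nr && nj <= nc && lab[ni, nj] > 0) {
        owner <- lab[ni, nj]; break
      }
    }
    if (owner > 0) lab[idx] <- owner
  }
  lab
}

#' Particle analysis with size and circularity filters
#'
#' Finds 8-connected components of a binary image and keeps those with
#' area strictly greater than `min_area_px` and circularity
#' 4*pi*area/perimeter^2 (capped at 1) within `circularity_range`.
#' Perimeters are measured by a boundary walk in which straight steps weigh
#' 1 and diagonal steps sqrt(2).
#'
#' @param binary logical matrix (NA = background).
#' @param min_area_px keep particles with area > this many pixels.
#' @param circularity_range inclusive (lo, hi) circularity window; the
#'   damage filter uses (0, 0.5) to reject compact near-circular objects
#'   that are unlikely to be genuine surface damage.
#' @param pixel_area um^2 per pixel, used for `area_um2`.
#' @param fill_holes include enclosed holes in each particle (default),
#'   so a thresholded outline measures the object it encloses and compact
#'   objects keep a circularity near 1.
#' @return a data frame of class `particle_set` with columns `label`,
#'   `area_px`, `area_um2`, `perimeter`, `circularity`, `centroid_row`,
#'   `centroid_col`, and attribute `labels` (the label image).
#' @export
analyze_particles <- function(binary, min_area_px = 20,
                              circularity_range = c(0, 0.5),
                              pixel_area = 1, fill_holes = TRUE) {
  if (circularity_range[1] > circularity_range[2])
    stop("circularity_range lower bound exceeds upper bound")
  lab <- label_components(binary)
  if (fill_holes) {
    n_labels <- attr(lab, "n_labels")
    lab <- fill_particle_holes(lab)
    attr(lab, "n_labels") <- n_labels
  }
  k <- attr(lab, "n_labels")
  if (k == 0) {
    out <- data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), perimeter = numeric(),
                      circularity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
  } else {
    area <- tabulate(lab[lab > 0], nbins = k)
    per <- .cc_perimeters(lab, k)
    circ <- ifelse(per > 0, pmin(1, 4 * pi * area / per^2), 1)
    idx <- which(lab > 0)
    rows <- (idx - 1) %% nrow(lab) + 1
    cols <- (idx - 1) %/% nrow(lab) + 1
    l <- lab[idx]
    out <- data.frame(label = seq_len(k), area_px = area,
                      area_um2 = area * pixel_area, perimeter = per,
                      circularity = circ,
                      centroid_row = as.numeric(tapply(rows, l, mean)),
                      centroid_col = as.numeric(tapply(cols, l, mean)))
    out <- out[out$area_px > min_area_px &
                 out$circularity >= circularity_range[1] &
                 out$circularity <= circularity_range[2], , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "labels") <- lab
  attr(out, "min_area_px") <- min_area_px
  attr(out, "circularity_range") <- circularity_range
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Total plateau area from the Macro-1 selection
#'
#' With the threshold set to minimum every selected pixel is foreground;
#' the plateau area is then the summed area of components larger than
#' `min_area_px` pixels (no circularity restriction).
#'
#' @param selection logical matrix (the plateau selection).
#' @param min_area_px keep components with area > this (default 100 px).
#' @param pixel_area um^2 per pixel.
#' @return area in um^2.
#' @export
measure_plateau_area <- function(selection, min_area_px = 100,
                                 pixel_area = 1) {
  selection[is.na(selection)] <- FALSE
  if (!any(selection)) stop("empty plateau selection")
  lab <- .cc_label2d(selection)
  k <- attr(lab, "n_labels")
  area <- tabulate(lab[lab > 0], nbins = k)
  keep <- area > min_area_px
  if (!any(keep)) {
    warning("all plateau fragments are at or below the size filter; area 0")
    return(0)
  }
  sum(area[keep]) * pixel_area
}
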