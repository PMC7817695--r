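#' Specification of a synthetic joint-surface-replica image
#'
#' Describes a textured plateau carrying crack-like surface lesions
#' (elongated, low circularity), compact near-circular debris blobs, and
#' bright sub-4-pixel speckle, emulating back-scattered-electron images of
#' joint surface casts. Default geometry: 1536 x 1536 px over an
#' 1800 x 1800 um field.
#'
#' Cracks are dark polylines dilated to width = length / aspect ratio with
#' anti-aliasing off, so the ground-truth damage mask is binary and
#' countable. The aspect ratio must be at least 6, which keeps the digital
#' circularity of a crack below the 0.5 particle filter. No noise model for
#' the BSE-SEM background texture is available, so its amplitude is a free
#' knob.
#'
#' @param image_shape integer (rows, cols).
#' @param field_of_view physical side length of the square field, um.
#' @param n_cracks number of crack lesions.
#' @param crack_length_px range (min, max) of crack path lengths in px.
#' @param crack_aspect_ratio length/width ratio of cracks, >= 6.
#' @param n_debris_blobs number of compact near-circular debris blobs.
#' @param n_speckles number of bright speckles of area < 4 px.
#' @param background_texture_amplitude texture standard deviation, gray
#'   levels (16-bit scale).
#' @param background_level mean background gray level.
#' @param crack_depth how far below background the crack interior sits.
#' @param crack_noise_sd gray-level noise inside cracks/debris; this is what
#'   gives lesions their high local gradient.
#' @param debris_radius_px range of debris blob radii (>= 10 px keeps them
#'   safely in circularity-filter territory).
#' @param speckle_delta brightness of speckles above background.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   images.
#' @return an object of class `surface_spec`.
#' @export
surface_spec <- function(image_shape = c(1536L, 1536L),
                         field_of_view = 1800,
                         n_cracks = 4L,
                         crack_length_px = c(80, 220),
                         crack_aspect_ratio = 8,
                         n_debris_blobs = 2L,
                         n_speckles = 40L,
                         background_texture_amplitude = 500,
                         background_level = 32000,
                         crack_depth = 12000,
                         crack_noise_sd = 3500,
                         debris_radius_px = c(10, 16),
                         speckle_delta = 20000,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            field_of_view > 0, n_cracks >= 0,
            length(crack_length_px) == 2,
            crack_length_px[1] <= crack_length_px[2],
            n_debris_blobs >= 0, n_speckles >= 0,
            background_texture_amplitude >= 0)
  if (crack_aspect_ratio < 6)
    stop("crack_aspect_ratio must be >= 6 so cracks fall below the ",
         "circularity 0.5 filter")
  structure(as.list(environment()), class = "surface_spec")
}

# rasterise a jittered polyline and dilate it to the crack width;
# returns row/col indices of the crack mask within the full image
rasterize_crack <- function(shape, start, angle, length, width) {
  n_seg <- 3L
  seg_len <- length / n_seg
  pts <- matrix(start, 1, 2)
  a <- angle
  for (s in seq_len(n_seg)) {
    a <- a + runif(1, -0.35, 0.35)
    step <- seq(0, seg_len, by = 0.25)[-1]
    last <- pts[nrow(pts), ]
    pts <- rbind(pts, cbind(last[1] + step * sin(a), last[2] + step * cos(a)))
  }
  ri <- round(pts[, 1]); ci <- round(pts[, 2])
  keep <- ri >= 1 & ri <= shape[1] & ci >= 1 & ci <= shape[2]
  ri <- ri[keep]; ci <- ci[keep]
  if (!length(ri)) return(NULL)
  # dilate within a padded bounding box using the distance transform
  r <- width / 2
  pad <- ceiling(r) + 1
  r0 <- max(1, min(ri) - pad); r1 <- min(shape[1], max(ri) + pad)
  c0 <- max(1, min(ci) - pad); c1 <- min(shape[2], max(ci) + pad)
  sub <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
  sub[cbind(ri - r0 + 1, ci - c0 + 1)] <- TRUE
  d2 <- .edt_sq(as.vector(sub), dim(sub))
  hit <- which(matrix(d2 <= r * r, nrow(sub)), arr.ind = TRUE)
  cbind(row = hit[, 1] + r0 - 1, col = hit[, 2] + c0 - 1)
}

#' Generate a synthetic joint-surface-replica image with ground truth
#'
#' Renders the surface described by a [surface_spec()]: a smoothly textured
#' background, dark noisy-interior cracks (the ground-truth damage), dark
#' compact debris blobs (not damage; removed downstream by the circularity
#' filter), and bright sub-4-px speckles (not damage; removed by the
#' bright-outlier filter). Crack placements are rejected until their
#' bounding boxes are disjoint so the damage mask has exactly `n_cracks`
#' connected components.
#'
#' @param spec a [surface_spec()].
#' @return a list with elements `image` (a [plateau_image]), `damage_mask`
#'   (logical, exactly the crack pixels), `plateau_mask` (logical), and
#'   `spec`.
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  shape <- as.integer(spec$image_shape)
  margin <- ceiling(max(spec$crack_length_px) / spec$crack_aspect_ratio) + 4
  if (spec$n_cracks > 0 &&
      max(spec$crack_length_px) + 2 * margin > min(shape))
    stop("image too small for the requested crack length")
  px_area <- (spec$field_of_view / shape[1]) * (spec$field_of_view / shape[2])
  with_seed(split_seed(spec$seed, 0L), {
    pixels <- spec$background_level +
      smooth_noise_field(shape, spec$background_texture_amplitude)
    damage <- matrix(FALSE, shape[1], shape[2])
    boxes <- list()
    overlaps <- function(b) any(vapply(boxes, function(o)
      b[1] <= o[2] && o[1] <= b[2] && b[3] <= o[4] && o[3] <= b[4], TRUE))
    for (k in seq_len(spec$n_cracks)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        len <- runif(1, spec$crack_length_px[1], spec$crack_length_px[2])
        width <- max(1, round(len / spec$crack_aspect_ratio))
        ang <- runif(1, 0, 2 * pi)
        reach <- len + width + 8
        if (shape[1] - 2 * margin < 1 || shape[2] - 2 * margin < 1) break
        start <- c(runif(1, margin, shape[1] - margin),
                   runif(1, margin, shape[2] - margin))
        end_r <- start[1] + len * sin(ang); end_c <- start[2] + len * cos(ang)
        if (end_r < margin || end_r > shape[1] - margin ||
            end_c < margin || end_c > shape[2] - margin) next
        idx <- rasterize_crack(shape, start, ang, len, width)
        if (is.null(idx)) next
        b <- c(range(idx[, 1]) + c(-3, 3), range(idx[, 2]) + c(-3, 3))
        if (length(boxes) && overlaps(b)) next
        boxes[[length(boxes) + 1]] <- b
        damage[idx] <- TRUE
        pixels[idx] <- spec$background_level - spec$crack_depth +
          rnorm(nrow(idx), 0, spec$crack_noise_sd)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("image too small to place ", spec$n_cracks,
             " non-overlapping cracks")
    }
    # compact debris: dark, noisy, near-circular -- excluded from the damage
    # mask on purpose
    for (k in seq_len(spec$n_debris_blobs)) {
      for (try in seq_len(200L)) {
        r <- runif(1, spec$debris_radius_px[1], spec$debris_radius_px[2])
        ctr <- c(runif(1, r + 2, shape[1] - r - 2),
                 runif(1, r + 2, shape[2] - r - 2))
        b <- c(ctr[1] - r - 3, ctr[1] + r + 3, ctr[2] - r - 3, ctr[2] + r + 3)
        if (length(boxes) && overlaps(b)) next
        boxes[[length(boxes) + 1]] <- b
        rr <- seq(max(1, floor(ctr[1] - r)), min(shape[1], ceiling(ctr[1] + r)))
        cc <- seq(max(1, floor(ctr[2] - r)), min(shape[2], ceiling(ctr[2] + r)))
        g <- expand.grid(row = rr, col = cc)
        inside <- (g$row - ctr[1])^2 + (g$col - ctr[2])^2 <= r^2
        idx <- as.matrix(g[inside, ])
        pixels[idx] <- spec$background_level - spec$crack_depth +
          rnorm(nrow(idx), 0, spec$crack_noise_sd)
        break
      }
    }
    # bright speckle, area strictly < 4 px, kept clear of the damage so
    # despeckling can never touch a lesion neighbourhood
    avoid <- if (any(damage))
      array(.edt_sq(as.vector(damage), dim(damage)) <= 36, dim(damage))
    else damage
    shapes <- list(rbind(c(0, 0)), rbind(c(0, 0), c(0, 1)),
                   rbind(c(0, 0), c(0, 1), c(1, 0)))
    for (k in seq_len(spec$n_speckles)) {
      sh <- shapes[[sample.int(3L, 1)]]
      ctr <- c(sample.int(shape[1] - 2L, 1), sample.int(shape[2] - 2L, 1))
      idx <- cbind(ctr[1] + sh[, 1], ctr[2] + sh[, 2])
      if (any(avoid[idx])) next
      pixels[idx] <- spec$background_level + spec$speckle_delta
    }
    pixels <- round(clip(pixels, 0, 65535))
    list(image = plateau_image(pixels, px_area),
         damage_mask = damage,
         plateau_mask = matrix(TRUE, shape[1], shape[2]),
         spec = spec)
  })
}
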