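# Contrast-enhanced uCT morphometry: scaled volumes of interest, density
# thresholds at 200 (cartilage, below) and 300 (subchondral bone, above)
# mg HA/cm^3, component labelling keeping the 5 / 20 largest particles,
# morphological closing with 5- / 3-voxel spherical elements, and the
# seven morphometric parameters. Thresholds are applied to densities only,
# never to raw gray.

#' Tibial landmark set for VOI scaling
#'
#' Landmark determination (rotation of the tibia to a standard position) is
#' an acquisition step; landmarks enter here as explicit voxel coordinates.
#'
#' @param ml_extent (a, b) first/last x-voxel of the tibia (medial-lateral).
#' @param ap_extent (c, d) first/last y-voxel (anterior-posterior).
#' @param plateau_edges list with `medial` and `lateral` x-ranges.
#' @param growth_plate_z z-voxel of the growth plate.
#' @param surface_z z-voxel of the articular surface (top of cartilage).
#' @return an object of class `tibia_landmarks`.
#' @export
tibia_landmarks <- function(ml_extent, ap_extent, plateau_edges,
                            growth_plate_z, surface_z = 1L) {
  stopifnot(ml_extent[1] < ml_extent[2], ap_extent[1] < ap_extent[2],
            all(c("medial", "lateral") %in% names(plateau_edges)),
            growth_plate_z > surface_z)
  for (pe in plateau_edges)
    stopifnot(pe[1] >= ml_extent[1], pe[2] <= ml_extent[2])
  structure(list(ml_extent = ml_extent, ap_extent = ap_extent,
                 plateau_edges = plateau_edges,
                 growth_plate_z = growth_plate_z, surface_z = surface_z),
            class = "tibia_landmarks")
}

#' Place the medial and lateral volumes of interest
#'
#' Each VOI is 14% of the medial-lateral axis wide and 33% of the
#' anterior-posterior axis deep. It is centred medial-laterally on its
#' plateau midpoint, with the lateral VOI additionally shifted medially by
#' 7% of the medial-lateral axis. Anterior-posterior midpoints sit at
#' 61.5% (medial) and 68.5% (lateral) of the AP axis -- a 7% posterior
#' shift that captures the thickest part of each plateau. Axially the VOI
#' spans from the articular surface to the growth plate.
#'
#' @param landmarks a [tibia_landmarks].
#' @param volume_dim optional c(nx, ny, nz); when supplied, boxes exceeding
#'   the volume are clipped with a warning.
#' @return list with `medial` and `lateral` VOI objects, each of class
#'   `voi` with `side` and `box` = c(x0, x1, y0, y1, z0, z1).
#' @export
place_vois <- function(landmarks, volume_dim = NULL) {
  stopifnot(inherits(landmarks, "tibia_landmarks"))
  L <- diff(landmarks$ml_extent)
  D <- diff(landmarks$ap_extent)
  width <- max(1, round_half_up(0.14 * L))
  depth <- max(1, round_half_up(0.33 * D))
  medial_is_low <- mean(landmarks$plateau_edges$medial) <=
    mean(landmarks$plateau_edges$lateral)
  mk <- function(side) {
    cx <- mean(landmarks$plateau_edges[[side]])
    if (side == "lateral")  # shift medially by 7% of the ML axis
      cx <- cx + (if (medial_is_low) -1 else 1) * 0.07 * L
    frac <- if (side == "medial") 0.615 else 0.685
    cy <- landmarks$ap_extent[1] + frac * D
    x0 <- round_half_up(cx - width / 2); x1 <- x0 + width - 1
    y0 <- round_half_up(cy - depth / 2); y1 <- y0 + depth - 1
    box <- c(x0 = x0, x1 = x1, y0 = y0, y1 = y1,
             z0 = landmarks$surface_z, z1 = landmarks$growth_plate_z)
    if (!is.null(volume_dim)) {
      lo <- c(1, 1, 1); hi <- volume_dim
      cl <- c(max(box[1], 1), min(box[2], hi[1]), max(box[3], 1),
              min(box[4], hi[2]), max(box[5], 1), min(box[6], hi[3]))
      if (any(cl != box)) {
        warning(side, " VOI exceeded the volume bounds; clipped")
        box[] <- cl
      }
    }
    structure(list(side = side, box = box), class = "voi")
  }
  list(medial = mk("medial"), lateral = mk("lateral"))
}

gauss3_kernel <- function(sigma) {
  if (sigma <= 0) return(c(0, 1, 0))
  w <- exp(-c(1, 0, 1)^2 / (2 * sigma^2))
  w[2] <- 1
  w / sum(w)
}

#' Gaussian filtration of a density volume
#'
#' Separable Gaussian smoothing with the scanner-protocol parameters:
#' sigma 0.8 voxels truncated at a support of 1 voxel (a normalised 3-tap
#' kernel per axis). `sigma = 0` is the identity.
#'
#' @param volume a [density_volume].
#' @param sigma standard deviation in voxels.
#' @param support kernel truncation radius in voxels (only 1 is
#'   implemented, matching the protocol).
#' @return the filtered [density_volume].
#' @export
preprocess <- function(volume, sigma = 0.8, support = 1) {
  stopifnot(inherits(volume, "density_volume"), support == 1)
  if (sigma <= 0) return(volume)
  w <- gauss3_kernel(sigma)
  v <- volume$voxels
  d <- dim(v)
  rep_idx <- function(n) list(c(1, seq_len(n - 1)), c(seq_len(n - 1) + 1, n))
  i1 <- rep_idx(d[1]); i2 <- rep_idx(d[2]); i3 <- rep_idx(d[3])
  v <- w[1] * v[i1[[1]], , , drop = FALSE] + w[2] * v +
    w[3] * v[i1[[2]], , , drop = FALSE]
  v <- w[1] * v[, i2[[1]], , drop = FALSE] + w[2] * v +
    w[3] * v[, i2[[2]], , drop = FALSE]
  v <- w[1] * v[, , i3[[1]], drop = FALSE] + w[2] * v +
    w[3] * v[, , i3[[2]], drop = FALSE]
  density_volume(v, volume$voxel_size)
}

# --- binary 3D morphology via the Euclidean distance transform ----------

dilate3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d2 <- .edt_sq(as.vector(mask), dim(mask))
  array(d2 <= radius^2 + 1e-9, dim = dim(mask))
}

erode3d <- function(mask, radius, pad = TRUE) {
  if (radius <= 0) return(mask)
  if (pad) {  # outside the array is background
    d <- dim(mask); r <- ceiling(radius)
    big <- array(FALSE, d + 2 * r)
    big[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- mask
    out <- erode3d(big, radius, pad = FALSE)
    return(out[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]),
               drop = FALSE])
  }
  d2 <- .edt_sq(as.vector(!mask), dim(mask))
  array(d2 > radius^2 + 1e-9, dim = dim(mask))
}

# closing = dilation then erosion with a spherical structuring element;
# the volume is padded by the radius so the element is not clipped at the
# crop boundary
close3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  r <- ceiling(radius)
  pd <- d + 2 * r
  pad <- array(FALSE, pd)
  pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- mask
  out <- erode3d(dilate3d(pad, radius), radius, pad = FALSE)
  out[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]), drop = FALSE]
}

keep_largest <- function(mask, n_keep) {
  lab <- .cc_label3d(as.vector(mask), dim(mask))
  k <- attr(lab, "n_labels")
  if (k == 0) return(list(mask = array(FALSE, dim(mask)), labels = lab,
                          kept = integer()))
  sizes <- tabulate(lab[lab > 0], nbins = k)
  kept <- order(sizes, decreasing = TRUE)[seq_len(min(n_keep, k))]
  m <- array(lab %in% kept, dim = dim(mask))
  list(mask = m, labels = lab, kept = kept)
}

crop_box <- function(v, box) {
  v[box[1]:box[2], box[3]:box[4], box[5]:box[6], drop = FALSE]
}

# expand a box laterally (x, y) by a margin, clamped to the volume
expand_box <- function(box, margin, dims) {
  c(max(1, box[1] - margin), min(dims[1], box[2] + margin),
    max(1, box[3] - margin), min(dims[2], box[4] + margin),
    box[5], box[6])
}

box_mask <- function(box, dims) {
  out <- array(FALSE, dims)
  out[box[1]:box[2], box[3]:box[4], box[5]:box[6]] <- TRUE
  out
}

embed_box <- function(sub, box, dim_full) {
  out <- array(FALSE, dim_full)
  out[box[1]:box[2], box[3]:box[4], box[5]:box[6]] <- sub
  out
}

#' Segment articular cartilage within a VOI
#'
#' All tissue below `upper` mg HA/cm^3 inside the VOI is a candidate; the
#' five largest 26-connected components are kept and closed with a
#' five-voxel spherical element. With `surface_connect = TRUE` (default) a
#' kept component must reach the top (articular-surface) face of the VOI
#' within `surface_tol` voxels, which stops contrast-free marrow pockets
#' below the subchondral plate from masquerading as cartilage.
#'
#' @param volume a (filtered) [density_volume].
#' @param voi a `voi` from [place_vois()].
#' @param upper cartilage density threshold, mg HA/cm^3.
#' @param n_keep number of largest components retained.
#' @param closing_radius closing radius, voxels.
#' @param surface_connect require surface connection.
#' @param surface_tol tolerance in voxels for the surface test.
#' @param margin_voxels lateral context margin: segmentation also runs in
#'   a band this wide around the VOI so that thickness spheres near the
#'   VOI face are supported by the structure outside it. Measurements are
#'   always restricted to the VOI.
#' @return logical array (full volume dimensions) restricted to the VOI;
#'   attribute `context` holds the segmentation over the margin-expanded
#'   box. Empty with a warning if nothing qualifies.
#' @export
segment_cartilage <- function(volume, voi, upper = 200, n_keep = 5,
                              closing_radius = 5, surface_connect = TRUE,
                              surface_tol = 2, margin_voxels = 24) {
  stopifnot(inherits(volume, "density_volume"), inherits(voi, "voi"))
  dims <- dim(volume$voxels)
  ebox <- expand_box(voi$box, margin_voxels, dims)
  sub <- crop_box(volume$voxels, ebox) < upper
  kl <- keep_largest(sub, n_keep)
  m <- kl$mask
  if (surface_connect && length(kl$kept)) {
    lab <- array(kl$labels, dim = dim(sub))
    top <- lab[, , seq_len(min(1 + surface_tol, dim(sub)[3])), drop = FALSE]
    touching <- intersect(kl$kept, unique(top[top > 0]))
    m <- array(kl$labels %in% touching, dim = dim(sub))
  }
  if (!any(m)) {
    warning("no cartilage found in the VOI; empty mask")
    out <- array(FALSE, dims)
    attr(out, "context") <- out
    return(out)
  }
  m <- close3d(m, closing_radius)
  context <- embed_box(m, ebox, dims)
  out <- context & box_mask(voi$box, dims)
  if (!any(out)) warning("no cartilage found in the VOI; empty mask")
  attr(out, "context") <- context
  out
}

#' Segment subchondral bone within a VOI
#'
#' All tissue above `lower` mg HA/cm^3 in the slab between the base of the
#' articular cartilage and the growth plate is a candidate; the twenty
#' largest components are kept and closed with a three-voxel element. The
#' slab bound excludes the contrast bath above the cartilage even though
#' its density also exceeds the threshold.
#'
#' @param volume a (filtered) [density_volume].
#' @param voi a `voi`.
#' @param cartilage_mask the [segment_cartilage()] result (bounds the top).
#' @param growth_plate_z z-voxel of the growth plate (bounds the bottom).
#' @param lower bone density threshold, mg HA/cm^3.
#' @param n_keep number of largest components retained.
#' @param closing_radius closing radius, voxels.
#' @param margin_voxels lateral context margin (see
#'   [segment_cartilage()]).
#' @return logical array restricted to the analysed slab of the VOI, with
#'   attributes `region` (the slab within the VOI, the tissue-volume
#'   reference for BV/TV) and `context` (segmentation over the
#'   margin-expanded slab, for thickness support).
#' @export
segment_subchondral_bone <- function(volume, voi, cartilage_mask,
                                     growth_plate_z, lower = 300,
                                     n_keep = 20, closing_radius = 3,
                                     margin_voxels = 24) {
  stopifnot(inherits(volume, "density_volume"), inherits(voi, "voi"))
  box <- voi$box
  cart_sub <- crop_box(cartilage_mask, box)
  zs <- apply(cart_sub, 3, any)
  cart_base <- if (any(zs)) box[5] + max(which(zs)) - 1 else box[5] - 1
  z0 <- cart_base + 1
  z1 <- min(growth_plate_z - 1, box[6])
  dims <- dim(volume$voxels)
  region <- array(FALSE, dims)
  if (z0 > z1) {
    warning("no slab between cartilage base and growth plate; empty mask")
    out <- array(FALSE, dims)
    attr(out, "region") <- region
    attr(out, "context") <- out
    return(out)
  }
  rbox <- c(box[1:4], z0, z1)
  ebox <- expand_box(rbox, margin_voxels, dims)
  region[box[1]:box[2], box[3]:box[4], z0:z1] <- TRUE
  sub <- crop_box(volume$voxels, ebox) > lower
  kl <- keep_largest(sub, n_keep)
  if (!any(kl$mask)) {
    warning("no subchondral bone above threshold; empty mask")
    out <- array(FALSE, dims)
    attr(out, "region") <- region
    attr(out, "context") <- out
    return(out)
  }
  m <- close3d(kl$mask, closing_radius)
  context <- embed_box(m, ebox, dims)
  out <- context & region
  attr(out, "region") <- region
  attr(out, "context") <- context
  out
}

#' Local thickness field of a 3D mask
#'
#' Maximal-inscribed-sphere (distance-transform) thickness: the value at a
#' voxel is the diameter of the largest sphere that contains it and fits
#' inside the structure.
#'
#' @param mask logical 3D array. Space beyond the array counts as
#'   background.
#' @param voxel_size voxel edge, um.
#' @return numeric array of thicknesses in um (0 outside the mask).
#' @export
thickness_field <- function(mask, voxel_size = 1) {
  d <- dim(mask)
  big <- array(FALSE, d + 2L)
  big[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask
  th <- array(.local_thickness(as.vector(big), dim(big)), dim = dim(big))
  th <- th[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]),
           drop = FALSE]
  array(th * voxel_size, dim = d)
}

#' Articular cartilage metrics
#'
#' @param mask cartilage mask (logical 3D array), restricted to the VOI.
#' @param voxel_size voxel edge, um.
#' @param context optional wider segmentation (the `context` attribute of
#'   [segment_cartilage()]); thickness spheres are fitted in the context
#'   and summarised over the VOI voxels, so VOI faces do not truncate
#'   them.
#' @return list with `cg_v_mm3` (volume), `median_cg_th_mm` and
#'   `max_cg_th_mm` (median / maximum of the maximal-sphere thickness
#'   field over cartilage voxels).
#' @export
cartilage_metrics <- function(mask, voxel_size,
                              context = attr(mask, "context")) {
  if (!any(mask)) {
    warning("empty cartilage mask; zero metrics")
    return(list(cg_v_mm3 = 0, median_cg_th_mm = 0, max_cg_th_mm = 0))
  }
  context <- context %||% mask
  bb <- mask_bbox(context)
  th <- thickness_field(crop_box(context, bb), voxel_size)
  vals <- th[crop_box(mask, bb)]
  list(cg_v_mm3 = sum(mask) * (voxel_size * 1e-3)^3,
       median_cg_th_mm = median(vals) * 1e-3,
       max_cg_th_mm = max(vals) * 1e-3)
}

#' Subchondral trabecular metrics
#'
#' BV/TV is bone voxels over tissue (region) voxels; Tb.Th is the mean
#' maximal-sphere thickness over bone; Tb.N follows the direct
#' model-independent convention 1 / (mean mid-axis spacing), with the mean
#' mid-axis spacing taken as Tb.Th + Tb.Sp (Tb.Sp being the maximal-sphere
#' thickness of the marrow space within the region); TMD is the mean
#' density over the bone mask after a one-voxel peel (partial-volume
#' surface voxels are excluded). The plate-model alternative
#' Tb.N = (BV/TV)/Tb.Th is also reported.
#'
#' @param mask bone mask (logical 3D array), restricted to the analysed
#'   slab of the VOI.
#' @param volume the (filtered) [density_volume] the mask was derived from.
#' @param region logical array of the analysed tissue volume (defaults to
#'   the `region` attribute of the mask).
#' @param context optional wider segmentation (the `context` attribute);
#'   thickness and spacing spheres are fitted in the context and
#'   summarised over the region voxels.
#' @return list with `bvtv`, `tb_th_mm`, `tb_sp_mm`, `tb_n_per_mm`,
#'   `tb_n_plate_per_mm`, `tmd`.
#' @export
trabecular_metrics <- function(mask, volume, region = NULL,
                               context = attr(mask, "context")) {
  region <- region %||% attr(mask, "region")
  stopifnot(!is.null(region))
  voxel_size <- volume$voxel_size
  if (!any(mask & region)) {
    warning("empty bone mask; zero metrics")
    return(list(bvtv = 0, tb_th_mm = 0, tb_sp_mm = 0, tb_n_per_mm = 0,
                tb_n_plate_per_mm = 0, tmd = 0))
  }
  context <- context %||% mask
  bb <- mask_bbox(context | region)
  msub <- crop_box(mask, bb) & crop_box(region, bb)
  rsub <- crop_box(region, bb)
  csub <- crop_box(context, bb)
  bvtv <- sum(msub) / sum(rsub)
  th <- thickness_field(csub, voxel_size)
  tb_th <- mean(th[msub])
  sp_context <- !csub
  sp_mask <- rsub & !msub
  tb_sp <- if (any(sp_mask))
    mean(thickness_field(sp_context, voxel_size)[sp_mask]) else 0
  core <- erode3d(msub, 1)
  vsub <- crop_box(volume$voxels, bb)
  tmd <- if (any(core)) mean(vsub[core]) else mean(vsub[msub])
  list(bvtv = bvtv,
       tb_th_mm = tb_th * 1e-3,
       tb_sp_mm = tb_sp * 1e-3,
       tb_n_per_mm = 1000 / (tb_th + tb_sp),
       tb_n_plate_per_mm = bvtv / (tb_th * 1e-3),
       tmd = tmd)
}

mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(c(1, 1, 1, 1, 1, 1))
  c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]),
    min(w[, 3]), max(w[, 3]))
}

#' Run the full morphometry chain for one plateau
#'
#' Gaussian filtration, VOI placement, cartilage and subchondral bone
#' segmentation, and the seven morphometric parameters.
#'
#' @param volume a raw [density_volume].
#' @param landmarks a [tibia_landmarks].
#' @param side `"medial"` or `"lateral"`.
#' @param upper_cartilage,lower_bone density thresholds, mg HA/cm^3.
#' @param sigma Gaussian filtration sigma (voxels).
#' @return a list of class `morphometry_result` with the metric fields of
#'   [cartilage_metrics()] and [trabecular_metrics()] plus `side`, `voi`,
#'   and the two masks.
#' @export
run_ct_morphometry <- function(volume, landmarks,
                               side = c("medial", "lateral"),
                               upper_cartilage = 200, lower_bone = 300,
                               sigma = 0.8) {
  side <- match.arg(side)
  filt <- preprocess(volume, sigma = sigma)
  voi <- place_vois(landmarks, dim(volume$voxels))[[side]]
  cart <- segment_cartilage(filt, voi, upper = upper_cartilage)
  bone <- segment_subchondral_bone(filt, voi, cart,
                                   landmarks$growth_plate_z,
                                   lower = lower_bone)
  cm <- cartilage_metrics(cart, volume$voxel_size)
  tm <- trabecular_metrics(bone, filt)
  structure(c(list(side = side, voi = voi), cm, tm,
              list(cartilage_mask = cart, bone_mask = bone)),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_result> %s plateau: Cg.V %.4g mm^3, ",
                     "Cg.Th med/max %.3g/%.3g mm, BV/TV %.3f, Tb.Th %.3g mm, ",
                     "Tb.N %.3g /mm, TMD %.0f mg HA/cm^3\n"),
              x$side, x$cg_v_mm3, x$median_cg_th_mm, x$max_cg_th_mm,
              x$bvtv, x$tb_th_mm, x$tb_n_per_mm, x$tmd))
  invisible(x)
}
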