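#' Specification of a synthetic contrast-enhanced density volume
#'
#' A cartilage slab over a trabecular lattice in a contrast-bath volume,
#' emulating iodine contrast-enhanced uCT of the tibial epiphysis: the bath
#' (contrast agent, bone-like absorption) fills the space above the
#' articular surface, the cartilage slab sits below it with density under
#' the 200 mg HA/cm^3 segmentation threshold, and subchondral bone is a
#' square lattice of orthogonal walls (thickness `trabecular_rod_thickness`,
#' period `trabecular_rod_spacing`) above the growth plate. Marrow spaces
#' inside the lattice are soft-tissue density (contrast does not reach
#' them), so the 300 mg HA/cm^3 bone threshold recovers the lattice.
#'
#' Analytic ground truths follow from the construction: slab thickness
#' equals `cartilage_thickness`; the lattice area fraction is
#' 1 - (1 - t/s)^2 for wall thickness t and period s (in voxels, as
#' realised); tissue mineral density equals `bone_density`.
#'
#' The default densities keep each phase on the correct side of its
#' segmentation threshold even after the protocol's Gaussian filtration:
#' a boundary voxel blends about a quarter of its neighbour's density, so
#' phases are placed such that the blend of any adjacent pair does not
#' cross 200 or 300 mg HA/cm^3. Default proportions mirror the anatomy at
#' desk scale: thin articular cartilage over a subchondral plate and
#' trabecular lattice, with the VOI wider than the cartilage is thick.
#'
#' @param volume_shape integer (nx, ny, nz) voxels; x medial-lateral,
#'   y anterior-posterior, z proximal-distal.
#' @param voxel_size isotropic voxel size, um.
#' @param cartilage_thickness slab thickness, um (>= 2 voxels).
#' @param cartilage_density slab density, mg HA/cm^3 (< 200).
#' @param bath_density contrast bath density, mg HA/cm^3 (> 300).
#' @param trabecular_rod_spacing,trabecular_rod_thickness lattice period and
#'   wall thickness, um.
#' @param lattice `"crossed"` (orthogonal walls in x and y; area fraction
#'   1 - (1 - t/s)^2) or `"parallel"` (walls in x only; area fraction
#'   t/s). Under the maximal-sphere definition the parallel lattice has
#'   exactly thickness t and spacing s - t, whereas crossed-wall junctions
#'   admit larger spheres, so the parallel variant is the phantom with
#'   exact analytic thickness ground truth.
#' @param bone_density lattice density, mg HA/cm^3 (> 300).
#' @param marrow_density soft-tissue density of marrow spaces (< 200).
#' @param subchondral_plate_thickness solid bone plate between cartilage
#'   and the trabecular lattice, um; anatomically this is what separates
#'   articular cartilage from marrow. Default equals the wall thickness so
#'   the whole bone phase shares one characteristic thickness.
#' @param bath_depth_voxels z-extent of the bath above the cartilage.
#' @param growth_plate_margin_voxels z-extent of the soft layer below the
#'   subchondral lattice (the growth-plate landmark sits at its top).
#' @param noise_sd density noise, mg HA/cm^3.
#' @param seed integer seed.
#' @return an object of class `volume_spec`.
#' @export
volume_spec <- function(volume_shape = c(128L, 128L, 96L),
                        voxel_size = 2,
                        cartilage_thickness = 32,
                        cartilage_density = 120,
                        bath_density = 350,
                        trabecular_rod_spacing = 60,
                        trabecular_rod_thickness = 16,
                        lattice = c("crossed", "parallel"),
                        bone_density = 450,
                        marrow_density = 100,
                        subchondral_plate_thickness = 16,
                        bath_depth_voxels = 10L,
                        growth_plate_margin_voxels = 8L,
                        noise_sd = 0,
                        seed = 1L) {
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 8),
            voxel_size > 0, noise_sd >= 0,
            trabecular_rod_thickness < trabecular_rod_spacing)
  if (!(cartilage_density < 200 && marrow_density < 200))
    stop("cartilage and marrow densities must be below 200 mg HA/cm^3")
  if (!(bath_density > 300 && bone_density > 300))
    stop("bath and bone densities must exceed 300 mg HA/cm^3")
  if (cartilage_thickness < 2 * voxel_size)
    stop("cartilage_thickness below 2 voxels cannot be resolved")
  lattice <- match.arg(lattice)
  structure(as.list(environment()), class = "volume_spec")
}

#' Generate a synthetic density volume with analytic ground truth
#'
#' @param spec a [volume_spec()].
#' @return a list with `volume` (a [density_volume]), `cartilage_mask` and
#'   `bone_mask` (logical arrays, the constructed geometry),
#'   `landmarks` (a [tibia_landmarks] covering the full cross-section), and
#'   `ground_truth`: `cg_th_um` (slab thickness), `cg_v_mm3_per_voxelcol`
#'   omitted in favour of the mask itself, `bvtv` (realised lattice
#'   fraction over the full cross-section), `bvtv_analytic`
#'   (1 - (1 - t/s)^2 on realised voxel dimensions), `tb_th_um`,
#'   `tb_n_per_mm` (1/realised spacing), and `tmd` (assigned bone density).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  nx <- spec$volume_shape[1]; ny <- spec$volume_shape[2]
  nz <- spec$volume_shape[3]
  vs <- spec$voxel_size
  t_vox <- max(1L, round(spec$trabecular_rod_thickness / vs))
  s_vox <- max(t_vox + 1L, round(spec$trabecular_rod_spacing / vs))
  cg_vox <- round(spec$cartilage_thickness / vs)
  p_vox <- max(1L, round(spec$subchondral_plate_thickness / vs))
  z_surface <- spec$bath_depth_voxels + 1L
  z_cart <- z_surface:(z_surface + cg_vox - 1L)
  z_gp <- nz - spec$growth_plate_margin_voxels  # growth-plate landmark
  z_plate <- (max(z_cart) + 1L):(max(z_cart) + p_vox)
  if (max(z_plate) + 2L >= z_gp)
    stop("volume too shallow for cartilage slab plus subchondral lattice")
  z_bone <- (max(z_plate) + 1L):(z_gp - 1L)
  vol <- array(spec$bath_density, dim = c(nx, ny, nz))
  cart <- array(FALSE, dim = dim(vol))
  cart[, , z_cart] <- TRUE
  vol[cart] <- spec$cartilage_density
  # orthogonal walls: lattice in x and y, extruded through the bone slab
  wall_x <- ((seq_len(nx) - 1L) %% s_vox) < t_vox
  wall_y <- ((seq_len(ny) - 1L) %% s_vox) < t_vox
  plane <- if (spec$lattice == "crossed") outer(wall_x, wall_y, `|`)
    else matrix(wall_x, nx, ny)
  bone <- array(FALSE, dim = dim(vol))
  bone[, , z_plate] <- TRUE   # solid subchondral plate
  bone[, , z_bone] <- plane   # trabecular lattice below it
  slab <- array(FALSE, dim = dim(vol))
  slab[, , z_bone] <- TRUE
  vol[slab] <- spec$marrow_density
  vol[bone] <- spec$bone_density
  vol[, , z_gp:nz] <- spec$marrow_density  # growth plate and below: soft
  if (spec$noise_sd > 0)
    vol <- with_seed(split_seed(spec$seed, 2L),
                     vol + array(rnorm(length(vol), 0, spec$noise_sd),
                                 dim = dim(vol)))
  n_plate <- length(z_plate) * nx * ny
  n_latt <- sum(plane) * length(z_bone)
  gt <- list(
    cg_th_um = cg_vox * vs,
    bvtv = (n_plate + n_latt) / (nx * ny * (length(z_plate) + length(z_bone))),
    bvtv_lattice = mean(plane),
    bvtv_analytic = if (spec$lattice == "crossed")
      1 - (1 - t_vox / s_vox)^2 else t_vox / s_vox,
    tb_th_um = (n_plate * p_vox + n_latt * t_vox) * vs / (n_plate + n_latt),
    tb_sp_um = (s_vox - t_vox) * vs,
    tb_n_per_mm = 1000 /
      ((n_plate * p_vox + n_latt * t_vox) * vs / (n_plate + n_latt) +
         (s_vox - t_vox) * vs),
    tmd = spec$bone_density,
    z_plate = range(z_plate), z_bone = range(z_bone), z_cart = range(z_cart))
  lm <- tibia_landmarks(ml_extent = c(1L, nx), ap_extent = c(1L, ny),
                        plateau_edges = list(medial = c(1L, floor(nx / 2)),
                                             lateral = c(floor(nx / 2) + 1L, nx)),
                        growth_plate_z = z_gp, surface_z = z_surface)
  list(volume = density_volume(vol, vs),
       cartilage_mask = cart, bone_mask = bone,
       landmarks = lm, ground_truth = gt, spec = spec)
}
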