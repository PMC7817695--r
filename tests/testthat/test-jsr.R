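# Damage quantitation chain: selection, despeckle, edges, threshold,
# particle analysis, end-to-end percentages.

flat_image <- function(nr = 64, nc = 64, value = 1000, pixel_area = 1.3733) {
  plateau_image(matrix(value, nr, nc), pixel_area)
}

test_that("select_plateau: identity, halving, and degenerate polygons", {
  img <- flat_image()
  full <- rbind(c(0.5, 0.5), c(0.5, 64.5), c(64.5, 64.5), c(64.5, 0.5))
  expect_equal(select_plateau(img, full)$mask, img$mask)

  half <- rbind(c(0.5, 0.5), c(0.5, 32.5), c(64.5, 32.5), c(64.5, 0.5))
  sel <- select_plateau(img, half)
  expect_equal(sum(sel$mask), 64 * 32)
  expect_true(all(is.na(sel$pixels[, 33:64])))

  expect_error(select_plateau(img, rbind(c(1, 1), c(1, 1), c(1, 1))),
               "degenerate")
  bowtie <- rbind(c(10, 10), c(30, 30), c(10, 30), c(30, 10))
  expect_error(select_plateau(img, bowtie), "self-intersecting")
})

test_that("plateau polygon area drives measured plateau area", {
  img <- flat_image()
  half <- rbind(c(0.5, 0.5), c(0.5, 32.5), c(64.5, 32.5), c(64.5, 0.5))
  sel <- select_plateau(img, half)
  expect_equal(measure_plateau_area(sel$mask, 100, img$pixel_area),
               64 * 32 * img$pixel_area)
  expect_equal(measure_plateau_area(img$mask, 100, img$pixel_area),
               64 * 64 * img$pixel_area)
})

test_that("measure_plateau_area edge cases", {
  expect_error(measure_plateau_area(matrix(FALSE, 8, 8)), "empty")
  frag <- matrix(FALSE, 32, 32); frag[1:5, 1:5] <- TRUE
  expect_warning(a <- measure_plateau_area(frag, 100), "filter")
  expect_equal(a, 0)
  expect_equal(measure_plateau_area(frag, 10), 25)
})

test_that("remove_bright_outliers removes sub-threshold speckle only", {
  img <- flat_image()
  expect_equal(remove_bright_outliers(img)$pixels, img$pixels)

  px <- matrix(1000, 64, 64)
  px[10, 10:12] <- 5000          # 3-px speckle: removed
  px[30:31, 30:31] <- 5000       # 4-px speckle: retained (area not < 4)
  noisy <- plateau_image(px + matrix(rnorm(64 * 64, 0, 5), 64), 1)
  out <- remove_bright_outliers(noisy, max_area_px = 4,
                                brightness_delta = 1000)
  expect_true(all(out$pixels[10, 10:12] < 2000))
  expect_true(all(out$pixels[30:31, 30:31] > 4000))
  untouched <- !(row(px) == 10 & col(px) %in% 10:12)
  expect_equal(out$pixels[untouched], noisy$pixels[untouched])
})

test_that("speckle pixels never reach the damage mask", {
  sp <- surface_spec(image_shape = c(256L, 256L), field_of_view = 300,
                     n_cracks = 2L, crack_length_px = c(50, 90),
                     n_debris_blobs = 0L, n_speckles = 50L, seed = 12L)
  s <- generate_surface(sp)
  r <- run_jsr_pipeline(s$image)
  speckle <- s$image$pixels >= sp$background_level + sp$speckle_delta - 100
  expect_equal(sum(r$damage_mask & speckle), 0L)
})

test_that("find_edges: zero on constant, 4h on a step, rotation-covariant", {
  img <- flat_image()
  expect_true(all(find_edges(img)$pixels == 0))

  px <- matrix(100, 32, 32); px[, 17:32] <- 600  # vertical step h = 500
  e <- find_edges(plateau_image(px, 1))
  expect_equal(e$pixels[16, 16], 4 * 500)
  expect_equal(e$pixels[16, 17], 4 * 500)
  expect_true(all(e$pixels[, c(1:14, 19:32)] == 0))

  set.seed(42)
  rnd <- matrix(sample(0:255, 30 * 30, TRUE), 30, 30)
  e1 <- find_edges(plateau_image(rnd, 1))$pixels
  rot <- t(rnd)[30:1, , drop = FALSE]  # 90 degree rotation
  e2 <- find_edges(plateau_image(rot, 1))$pixels
  expect_equal(e2, t(e1)[30:1, , drop = FALSE])
})

test_that("apply_debris_mask zeroes pixels and validates shape", {
  img <- flat_image()
  expect_equal(apply_debris_mask(img)$pixels, img$pixels)
  expect_error(apply_debris_mask(img, matrix(TRUE, 2, 2)), "shape")
  m <- matrix(FALSE, 64, 64); m[5:10, 5:10] <- TRUE
  out <- apply_debris_mask(img, m)
  expect_true(all(out$pixels[m] == 0))
})

test_that("a debris mask removes the covered particle from the results", {
  sp <- surface_spec(image_shape = c(256L, 256L), field_of_view = 300,
                     n_cracks = 2L, crack_length_px = c(50, 90),
                     n_debris_blobs = 0L, n_speckles = 0L, seed = 31L)
  s <- generate_surface(sp)
  base <- run_jsr_pipeline(s$image)
  expect_equal(base$n_damage_particles, 2L)
  # erase the first crack with a bounding-box debris mask
  lab <- oracle_label(s$damage_mask)
  idx <- which(lab == 1, arr.ind = TRUE)
  m <- matrix(FALSE, 256, 256)
  m[max(1, min(idx[, 1]) - 4):min(256, max(idx[, 1]) + 4),
    max(1, min(idx[, 2]) - 4):min(256, max(idx[, 2]) + 4)] <- TRUE
  masked <- run_jsr_pipeline(s$image, debris_mask = m)
  expect_equal(masked$n_damage_particles, 1L)
})

test_that("full debris coverage yields zero damage with a warning", {
  s <- generate_surface(surface_spec(image_shape = c(128L, 128L),
                                     field_of_view = 150, n_cracks = 1L,
                                     crack_length_px = c(40, 50),
                                     n_debris_blobs = 0L, n_speckles = 0L,
                                     seed = 2L))
  expect_warning(
    r <- run_jsr_pipeline(s$image,
                          debris_mask = matrix(TRUE, 128, 128)),
    "debris")
  expect_equal(r$damage_percent, 0)
})

test_that("threshold_damage: degenerate manual values and otsu bimodality", {
  px <- matrix(c(rep(40, 500), rep(200, 524)), 32, 32)
  img <- plateau_image(px, 1)
  all_fg <- threshold_damage(img, "manual", value = 0)
  expect_true(all(all_fg))
  none <- threshold_damage(img, "manual", value = 201)
  expect_false(any(none))
  expect_error(threshold_damage(img, "manual"), "value")
  expect_error(threshold_damage(img, "manual", value = 1e6), "bit depth")

  set.seed(3)
  v <- c(rnorm(4000, 50, 6), rnorm(2000, 200, 10))
  thr <- otsu_threshold(v)
  expect_gt(thr, 62); expect_lt(thr, 180)  # between the two modes
  expect_lt(abs(thr - oracle_otsu(v)), 2 * diff(range(v)) / 256)
})

test_that("analyze_particles matches closed-form shapes", {
  # 10 x 100 rectangle: low circularity, kept by the damage filter
  bin <- matrix(FALSE, 40, 130)
  bin[11:20, 11:110] <- TRUE
  ps <- analyze_particles(bin, min_area_px = 20,
                          circularity_range = c(0, 0.5))
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$area_px, 1000L)
  expect_equal(ps$circularity, 4 * pi * 1000 / (2 * (9 + 99))^2,
               tolerance = 0.05)
  expect_lt(ps$circularity, 0.5)

  # filled disk of radius 20: excluded by circularity
  disk <- matrix(FALSE, 60, 60)
  ctr <- 30
  for (i in 1:60) for (j in 1:60)
    if ((i - ctr)^2 + (j - ctr)^2 <= 400) disk[i, j] <- TRUE
  ps_disk <- analyze_particles(disk, 20, c(0, 0.5))
  expect_equal(nrow(ps_disk), 0L)
  ps_all <- analyze_particles(disk, 20, c(0, 1))
  expect_gt(ps_all$circularity, 0.9)

  # 15-px fragment excluded by the size filter
  frag <- matrix(FALSE, 20, 20); frag[3, 1:15] <- TRUE
  expect_equal(nrow(analyze_particles(frag, 20, c(0, 1))), 0L)
  expect_equal(nrow(analyze_particles(frag, 10, c(0, 1))), 1L)
})

test_that("particle labelling and areas equal the flood-fill oracle", {
  set.seed(11)
  for (rep in 1:5) {
    bin <- matrix(runif(64 * 64) < 0.35, 64, 64)
    ps <- analyze_particles(bin, min_area_px = 0,
                            circularity_range = c(0, 1), fill_holes = FALSE)
    lab <- oracle_label(bin)
    expect_equal(nrow(ps), max(lab))
    expect_equal(sort(ps$area_px), sort(tabulate(lab[lab > 0])))
  }
})

test_that("crack-free surfaces give zero damage", {
  s <- generate_surface(surface_spec(image_shape = c(256L, 256L),
                                     field_of_view = 300, n_cracks = 0L,
                                     n_debris_blobs = 0L, n_speckles = 25L,
                                     seed = 8L))
  r <- run_jsr_pipeline(s$image)
  expect_equal(r$damage_percent, 0)
})

test_that("pipeline recovers crack area and rejects debris disks", {
  sp <- surface_spec(image_shape = c(384L, 384L), field_of_view = 450,
                     n_cracks = 3L, crack_length_px = c(80, 160),
                     n_debris_blobs = 2L, n_speckles = 20L, seed = 17L)
  s <- generate_surface(sp)
  r <- run_jsr_pipeline(s$image)
  expect_equal(r$n_damage_particles, 3L)
  ratio <- sum(r$particles$area_px) / sum(s$damage_mask)
  expect_gt(ratio, 0.85); expect_lt(ratio, 1.15)
  expect_true(all(r$particles$circularity <= 0.5))
  expect_gte(r$damage_percent, 0); expect_lte(r$damage_percent, 100)
  expect_lte(r$damage_area_um2, r$plateau_area_um2)
})

test_that("lowering the manual threshold never decreases damage area", {
  s <- generate_surface(surface_spec(image_shape = c(256L, 256L),
                                     field_of_view = 300, n_cracks = 2L,
                                     crack_length_px = c(50, 90),
                                     n_debris_blobs = 0L, n_speckles = 0L,
                                     seed = 23L))
  areas <- vapply(c(30000, 20000, 12000, 6000), function(thr) {
    r <- run_jsr_pipeline(s$image, config = jsr_config(threshold = thr))
    r$damage_area_um2
  }, 1.0)
  expect_true(all(diff(areas) >= 0))
})

test_that("default pipeline on default-geometry surfaces stays in the
           wild-type damage band", {
  # near-native frame so crack sizes keep their default proportion of the
  # plateau; wild-type damage sits in the low single digits
  pct <- vapply(1:2, function(sd) {
    sp <- surface_spec(image_shape = c(1024L, 1024L), field_of_view = 1200,
                       seed = sd)
    run_jsr_pipeline(generate_surface(sp)$image)$damage_percent
  }, 1.0)
  expect_true(all(pct >= 0 & pct < 3))
})
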