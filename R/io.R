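#' Read a grayscale image (TIFF or PNG)
#'
#' Returns an integer-valued matrix on the native scale of the file
#' (0..255 for 8-bit, 0..65535 for 16-bit), with a `bits` attribute.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return numeric matrix of pixel values.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3) x <- x[, , 1]
    bits <- if (max(x) > 255 || !is.null(attr(x, "bits.per.sample")) &&
                identical(attr(x, "bits.per.sample"), 16L)) 16L else 8L
    storage.mode(x) <- "double"
  } else if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3) x <- x[, , 1]
    # png values are scaled to [0,1]; recover the native integer scale
    bits <- if (any(abs(x * 255 - round(x * 255)) > 1e-6)) 16L else 8L
    x <- round(x * (2^bits - 1))
  } else {
    stop("unsupported image format: ", ext)
  }
  attr(x, "bits") <- bits
  x
}

#' Write a grayscale image
#'
#' @param pixels numeric matrix of pixel values on the integer scale.
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param bits bit depth, 8 or 16.
#' @export
write_gray_image <- function(pixels, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  x <- clip(pixels, 0, 2^bits - 1) / (2^bits - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits != 8L)
      stop("PNG output is 8-bit; use TIFF for 16-bit images")
    png::writePNG(x, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Write / read a binary mask as 8-bit PNG
#' @param mask logical matrix.
#' @param path png path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x > 0.5
}

#' Write a density volume as a TIFF stack plus JSON sidecar
#'
#' Mineral densities (mg HA/cm^3) are stored as 16-bit integers, one TIFF
#' page per z-slice; voxel size and dimensions go to `<base>.json`.
#'
#' @param volume a [density_volume] object.
#' @param base output path without extension; writes `<base>.tif` and
#'   `<base>.json`.
#' @export
write_volume <- function(volume, base) {
  v <- volume$voxels
  d <- dim(v)
  pages <- lapply(seq_len(d[3]), function(z) clip(v[, , z], 0, 65535) / 65535)
  tiff::writeTIFF(pages, paste0(base, ".tif"), bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxel_size = volume$voxel_size, dim = d,
         units = "mg HA/cm^3", axis = c("x: medial-lateral",
                                        "y: anterior-posterior",
                                        "z: proximal-distal")),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_volume
#' @export
read_volume <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE, as.is = TRUE)
  v <- array(0, dim = meta$dim)
  for (z in seq_along(pages)) v[, , z] <- pages[[z]]
  density_volume(v, meta$voxel_size)
}

#' Write / read a phenotype cohort table as CSV
#'
#' Columns: `line`, `animal_id`, then one column per phenotype parameter.
#'
#' @param table a `phenotype_table` data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("line", "animal_id") %in% names(x)))
  class(x) <- c("phenotype_table", "data.frame")
  x
}
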