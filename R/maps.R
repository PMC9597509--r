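#' Density map and SRS image containers
#'
#' A `density_map` holds co-registered per-pixel absolute concentrations
#' (g/ml) of protein, lipid and water, plus pixel geometry. An `srs_image`
#' holds the three raw SRS band intensity planes (arbitrary units) at the
#' 2853, 2935 and 3420 cm^-1 bands.
#'
#' @param protein,lipid,water Numeric matrices of equal dimension, g/ml.
#' @param pixel_size Pixel edge length, micrometres.
#' @param z_spacing Optical section spacing, micrometres.
#' @return An object of class `density_map`.
#' @export
density_map <- function(protein, lipid, water, pixel_size = 0.25, z_spacing = 1) {
  stopifnot(
    is.matrix(protein), is.matrix(lipid), is.matrix(water),
    identical(dim(protein), dim(lipid)), identical(dim(protein), dim(water))
  )
  structure(
    list(
      protein = protein, lipid = lipid, water = water,
      pixel_size = pixel_size, z_spacing = z_spacing
    ),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d x %d px (%.2f um/px), mean protein %.1f mg/ml, mean lipid %.1f mg/ml\n",
    nrow(x$protein), ncol(x$protein), x$pixel_size,
    1000 * mean(x$protein), 1000 * mean(x$lipid)
  ))
  invisible(x)
}

#' Dry-mass density plane
#'
#' Dry-mass density is the sum of the protein and lipid concentration
#' planes (g/ml).
#'
#' @param map A `density_map`.
#' @return Numeric matrix, g/ml.
#' @export
dry_mass_density <- function(map) {
  stopifnot(inherits(map, "density_map"))
  map$protein + map$lipid
}

#' @rdname density_map
#' @param bands List of three numeric matrices (band order 2853, 2935,
#'   3420 cm^-1).
#' @export
srs_image <- function(bands, pixel_size = 0.25, z_spacing = 1) {
  stopifnot(is.list(bands), length(bands) == 3)
  dims <- lapply(bands, dim)
  if (!all(vapply(bands, is.matrix, logical(1))) ||
    !identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("srs_image needs three equally sized matrices", call. = FALSE)
  }
  if (any(!vapply(bands, function(b) all(is.finite(b)), logical(1)))) {
    stop("SRS band intensities must be finite", call. = FALSE)
  }
  names(bands) <- c("2853", "2935", "3420")
  structure(
    list(bands = bands, pixel_size = pixel_size, z_spacing = z_spacing),
    class = "srs_image"
  )
}

#' @export
print.srs_image <- function(x, ...) {
  cat(sprintf(
    "<srs_image> %d x %d px, bands 2853/2935/3420 cm^-1\n",
    nrow(x$bands[[1]]), ncol(x$bands[[1]])
  ))
  invisible(x)
}

#' Write or read images as multi-page float TIFF
#'
#' Density maps are written as 3-page 32-bit float TIFF (page order
#' protein, lipid, water); SRS images as 3-page float TIFF (page order
#' 2853, 2935, 3420 cm^-1); label images as single-page 16-bit TIFF.
#'
#' Because TIFF writers store floats on a [0, 1] scale, pages are written
#' affinely mapped into that range, with the offset and scale recorded in
#' a plain-text sidecar (`<path>.meta`); the readers restore the original
#' values.
#'
#' @param x Object to write.
#' @param path File path.
#' @return The path, invisibly; readers return the reconstructed object.
#' @export
write_density_tiff <- function(x, path) {
  stopifnot(inherits(x, "density_map"))
  write_scaled_tiff(list(x$protein, x$lipid, x$water), path)
}

# map pages affinely into [0, 1]; offset and scale go in the description tag
write_scaled_tiff <- function(pages, path) {
  lo <- min(unlist(lapply(pages, min)))
  hi <- max(unlist(lapply(pages, max)))
  scale <- max(hi - lo, 1e-12)
  pages <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  writeLines(sprintf("offset=%.17g\nscale=%.17g", lo, scale),
             paste0(path, ".meta"))
  invisible(path)
}

read_scaled_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  offset <- 0
  scale <- 1
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    kv <- readLines(meta)
    offset <- as.numeric(sub("offset=", "", kv[grepl("^offset=", kv)]))
    scale <- as.numeric(sub("scale=", "", kv[grepl("^scale=", kv)]))
  }
  lapply(pages, function(p) p * scale + offset)
}

#' @rdname write_density_tiff
#' @param pixel_size,z_spacing Geometry to attach on read (not stored in
#'   the TIFF tags).
#' @export
read_density_tiff <- function(path, pixel_size = 0.25, z_spacing = 1) {
  pages <- read_scaled_tiff(path)
  stopifnot(length(pages) == 3)
  density_map(pages[[1]], pages[[2]], pages[[3]], pixel_size, z_spacing)
}

#' @rdname write_density_tiff
#' @export
write_srs_tiff <- function(x, path) {
  stopifnot(inherits(x, "srs_image"))
  write_scaled_tiff(x$bands, path)
}

#' @rdname write_density_tiff
#' @export
read_srs_tiff <- function(path, pixel_size = 0.25, z_spacing = 1) {
  pages <- read_scaled_tiff(path)
  stopifnot(length(pages) == 3)
  srs_image(pages, pixel_size, z_spacing)
}

#' @rdname write_density_tiff
#' @export
write_label_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  if (max(x) > 65535) stop("label image exceeds 16-bit range", call. = FALSE)
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' @rdname write_density_tiff
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * 65535)), nrow = nrow(img))
}
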