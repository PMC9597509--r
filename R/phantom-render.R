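#' Render a noise-free density map from a cell population
#'
#' Paints each pixel with the density of its innermost compartment
#' (nucleolus over nucleoplasm over cytoplasm), leaves the background at
#' zero protein and lipid, and fills the water plane by the volume-fraction
#' closure `v_p c_p + v_l c_l + v_w c_w = 1` (so background water is
#' `1 / v_w` g/ml).
#'
#' @param cells Population tibble from [sample_population()].
#' @param spec The [phantom_spec()] the population was drawn with.
#' @param z Optical-section height, um (0 = mid-section).
#' @param psv [partial_specific_volumes()] closing the water plane.
#' @return A [density_map()].
#' @export
render_density_map <- function(cells, spec, z = 0,
                               psv = partial_specific_volumes()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$image_shape
  protein <- matrix(0, shape[1], shape[2])
  lipid <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, ])
    m <- cell_slice_masks(cell, spec, z)
    if (is.null(m)) next
    p <- protein[m$rows, m$cols]
    l <- lipid[m$rows, m$cols]
    cyto <- m$body & !m$nucleus
    nup <- m$nucleus & !m$nucleoli
    p[cyto] <- cell$cyto_protein
    p[nup] <- cell$nup_protein
    p[m$nucleoli] <- cell$nul_protein
    l[cyto] <- cell$cyto_lipid
    l[m$nucleus] <- cell$nuc_lipid
    protein[m$rows, m$cols] <- p
    lipid[m$rows, m$cols] <- l
  }
  water <- (1 - psv[["protein"]] * protein - psv[["lipid"]] * lipid) / psv[["water"]]
  density_map(protein, lipid, water,
              pixel_size = spec$pixel_size, z_spacing = spec$z_spacing)
}

#' Render ground-truth label images
#'
#' Integer label images (cell body, nucleus, nucleolus) sharing cell ids,
#' for one optical section.
#'
#' @inheritParams render_density_map
#' @return List of three integer matrices: `cell`, `nucleus`, `nucleolus`.
#' @export
render_labels <- function(cells, spec, z = 0) {
  shape <- spec$image_shape
  lab <- list(
    cell = matrix(0L, shape[1], shape[2]),
    nucleus = matrix(0L, shape[1], shape[2]),
    nucleolus = matrix(0L, shape[1], shape[2])
  )
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, ])
    m <- cell_slice_masks(cell, spec, z)
    if (is.null(m)) next
    id <- cell$cell_id
    for (nm in c("cell", "nucleus", "nucleolus")) {
      msk <- switch(nm, cell = m$body, nucleus = m$nucleus, nucleolus = m$nucleoli)
      sub <- lab[[nm]][m$rows, m$cols]
      sub[msk] <- id
      lab[[nm]][m$rows, m$cols] <- sub
    }
  }
  lab
}

#' Render a full z-stack of density maps and 3-D labels
#'
#' Slices every cell ellipsoid at the spec's `z_spacing`, returning one
#' density map and label set per section. Used for whole-cell (z-stack)
#' quantification; [integrate_zstack()] recovers each cell's ground-truth
#' mass from this stack exactly.
#'
#' @inheritParams render_density_map
#' @return List with `z` (section heights, um), `maps` (list of
#'   [density_map()]), and `labels3d` (list of three `rows x cols x nz`
#'   integer arrays: `cell`, `nucleus`, `nucleolus`).
#' @export
render_density_stack <- function(cells, spec,
                                 psv = partial_specific_volumes()) {
  kmax <- if (nrow(cells) == 0) 0L else floor(max(cells$rz_um) / spec$z_spacing)
  z <- seq(-kmax, kmax) * spec$z_spacing
  maps <- lapply(z, function(zz) render_density_map(cells, spec, zz, psv))
  labs <- lapply(z, function(zz) render_labels(cells, spec, zz))
  shape <- spec$image_shape
  labels3d <- lapply(c("cell", "nucleus", "nucleolus"), function(nm) {
    arr <- array(0L, c(shape[1], shape[2], length(z)))
    for (k in seq_along(z)) arr[, , k] <- labs[[k]][[nm]]
    arr
  })
  names(labels3d) <- c("cell", "nucleus", "nucleolus")
  list(z = z, maps = maps, labels3d = labels3d)
}

#' Simulate raw SRS band images from a density map
#'
#' Forward model of the three-band acquisition: per pixel the intensity
#' vector is `I = S c` with `S` the reference spectra and `c` the
#' (protein, lipid, water) concentration vector, plus band-space Gaussian
#' noise. Noise is injected in band space but calibrated in density units:
#' the noise added is `S e` with `e` a zero-mean Gaussian density
#' perturbation with channel SDs `sigma`, so the unmixed protein noise SD
#' equals `sigma[1]` (default 0.015 g/ml, the protein-channel
#' sensitivity) up to the small effect of clipping and renormalisation.
#'
#' @param truth A noise-free [density_map()].
#' @param spectra [reference_spectra()]; a singular matrix is rejected.
#' @param noise_sigma_density Protein-channel per-pixel noise SD, g/ml.
#' @param noise_sigma_lipid,noise_sigma_water Lipid/water channel SDs,
#'   g/ml; default equal to the protein value.
#' @param seed Integer seed for the noise realisation.
#' @return An [srs_image()].
#' @examples
#' spec <- phantom_spec(n_cells = 1, image_shape = c(96, 96), seed = 1)
#' cells <- sample_population(spec)
#' truth <- render_density_map(cells, spec)
#' srs <- srs_forward(truth, noise_sigma_density = 0, seed = 1)
#' @export
srs_forward <- function(truth, spectra = reference_spectra(),
                        noise_sigma_density = 0.015,
                        noise_sigma_lipid = noise_sigma_density,
                        noise_sigma_water = noise_sigma_density,
                        seed = 1L) {
  stopifnot(inherits(truth, "density_map"))
  spectra <- reference_spectra(unclass(spectra))
  dm <- dim(truth$protein)
  n <- prod(dm)
  C <- cbind(as.numeric(truth$protein), as.numeric(truth$lipid),
             as.numeric(truth$water))
  if (noise_sigma_density > 0 || noise_sigma_lipid > 0 || noise_sigma_water > 0) {
    set.seed(as.integer(seed))
    eps <- cbind(
      stats::rnorm(n, 0, noise_sigma_density),
      stats::rnorm(n, 0, noise_sigma_lipid),
      stats::rnorm(n, 0, noise_sigma_water)
    )
    C <- C + eps
  }
  I <- C %*% t(unclass(spectra))
  srs_image(
    list(
      matrix(I[, 1], dm[1], dm[2]),
      matrix(I[, 2], dm[1], dm[2]),
      matrix(I[, 3], dm[1], dm[2])
    ),
    pixel_size = truth$pixel_size, z_spacing = truth$z_spacing
  )
}
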