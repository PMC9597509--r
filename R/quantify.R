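disc_brush <- function(r) EBImage::makeBrush(2 * as.integer(r) + 1, "disc")

erode_mask <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  ebi(EBImage::erode(mask * 1, disc_brush(r))) > 0
}

dilate_mask <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  ebi(EBImage::dilate(mask * 1, disc_brush(r))) > 0
}

#' Per-cell compartment densities from one optical section
#'
#' Computes, per cell, the mean protein density over the cytoplasm
#' (cell body minus nucleus), mean lipid density over the cytoplasm
#' (lipid is only analysed in the cytoplasm, since nuclear lipid is a few
#' mg/ml), mean protein over the nucleoplasm (nucleus minus nucleoli) and
#' mean protein over the nucleoli. Means are taken on the unsmoothed
#' closure-normalised planes, using the unclipped versions when the map
#' carries them (see [unmix_image()]): averaging before clipping is the
#' unbiased order for estimating a mean concentration whose per-pixel
#' noise straddles zero.
#'
#' Before averaging, each compartment mask is eroded by its
#' `measure_erosion_*` radius and the neighbouring inner compartment is
#' dilated by `measure_exclusion` and excluded, so that the one-pixel
#' uncertainty of threshold boundaries does not mix compartments (if the
#' eroded nucleolus mask would be empty the uneroded mask is used).
#' Cells without a nucleus or nucleolus get missing values and a flag.
#'
#' @param map A [density_map()].
#' @param labels A [compartment_labels()] object.
#' @param params The [segmentation_params()] used (for the measurement
#'   erosion radii).
#' @return Tibble: `cell_id`, `cyto_protein`, `cyto_lipid`, `nup_protein`,
#'   `nul_protein` (g/ml), pixel counts `cyto_npix`, `nup_npix`,
#'   `nul_npix`, and `flags`.
#' @export
compartment_densities <- function(map, labels,
                                  params = segmentation_params()) {
  stopifnot(inherits(map, "density_map"), inherits(labels, "compartment_labels"))
  ids <- sort(unique(labels$cell[labels$cell > 0]))
  pad <- max(params$measure_exclusion, 1) + 1
  nr <- nrow(labels$cell); nc <- ncol(labels$cell)
  purrr::map_dfr(ids, function(id) {
    w <- which(labels$cell == id, arr.ind = TRUE)
    rows <- max(1, min(w[, 1]) - pad):min(nr, max(w[, 1]) + pad)
    cols <- max(1, min(w[, 2]) - pad):min(nc, max(w[, 2]) + pad)
    body <- labels$cell[rows, cols] == id
    nuc <- labels$nucleus[rows, cols] == id
    nul <- labels$nucleolus[rows, cols] == id
    prot <- raw_plane(map, "protein")[rows, cols]
    lip <- raw_plane(map, "lipid")[rows, cols]

    flags <- character(0)
    body_er <- erode_mask(body, params$measure_erosion_body)
    cyto <- body_er & !dilate_mask(nuc, params$measure_exclusion)
    nup <- erode_mask(nuc, params$measure_erosion_nucleus) &
      !dilate_mask(nul, params$measure_exclusion)
    # erosion fallback: shrink as far as the nucleolus size allows
    nul_m <- nul
    for (r in rev(seq_len(params$measure_erosion_nucleolus))) {
      cand_m <- erode_mask(nul, r)
      if (any(cand_m)) {
        nul_m <- cand_m
        break
      }
    }

    if (!any(nuc)) flags <- c(flags, "no_nucleus")
    if (any(nuc) && !any(nul)) flags <- c(flags, "no_nucleolus")
    if (!any(cyto)) flags <- c(flags, "empty_cytoplasm")
    if (any(nuc) && !any(nup)) flags <- c(flags, "empty_nucleoplasm")

    mean_or_na <- function(v, m) if (any(m)) mean(v[m]) else NA_real_
    tibble::tibble(
      cell_id = id,
      cyto_protein = mean_or_na(prot, cyto),
      cyto_lipid = mean_or_na(lip, cyto),
      nup_protein = mean_or_na(prot, nup),
      nul_protein = mean_or_na(prot, nul_m),
      cyto_npix = sum(cyto),
      nup_npix = sum(nup),
      nul_npix = sum(nul_m) * as.integer(any(nul)),
      flags = paste(flags, collapse = ";")
    )
  })
}

#' Whole-cell masses and volumes from a z-stack
#'
#' Integrates density over the segmented cell volume: volume is the voxel
#' count times the voxel volume, mass is the sum of density times voxel
#' volume (1 g/ml = 1 pg/um^3), and the mean density is mass over volume.
#'
#' @param maps List of [density_map()] objects, one per optical section
#'   (shared geometry).
#' @param labels3d 3-D integer array of cell labels
#'   (`rows x cols x sections`), e.g. `render_density_stack()$labels3d$cell`.
#' @param ids Optional cell ids to quantify; an id with no voxels is an
#'   error. Default: all ids present.
#' @return Tibble: `cell_id`, `volume_um3`, `protein_mass_pg`,
#'   `lipid_mass_pg`, `dry_mass_pg`, `mean_protein`, `mean_lipid` (g/ml).
#' @examples
#' spec <- phantom_spec(n_cells = 2, image_shape = c(160, 160), seed = 4)
#' cells <- sample_population(spec)
#' st <- render_density_stack(cells, spec)
#' integrate_zstack(st$maps, st$labels3d$cell)
#' @export
integrate_zstack <- function(maps, labels3d, ids = NULL) {
  stopifnot(is.list(maps), length(maps) == dim(labels3d)[3])
  m1 <- maps[[1]]
  voxvol <- m1$pixel_size^2 * m1$z_spacing
  nz <- length(maps)
  prot <- array(0, dim(labels3d))
  lip <- array(0, dim(labels3d))
  for (k in seq_len(nz)) {
    prot[, , k] <- maps[[k]]$protein
    lip[, , k] <- maps[[k]]$lipid
  }
  present <- sort(unique(labels3d[labels3d > 0]))
  if (is.null(ids)) ids <- present
  missing <- setdiff(ids, present)
  if (length(missing)) {
    stop("cell id(s) with no voxels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(ids, function(id) {
    m <- labels3d == id
    nvox <- sum(m)
    vol <- nvox * voxvol
    pm <- sum(prot[m]) * voxvol
    lm <- sum(lip[m]) * voxvol
    tibble::tibble(
      cell_id = id, volume_um3 = vol,
      protein_mass_pg = pm, lipid_mass_pg = lm, dry_mass_pg = pm + lm,
      mean_protein = pm / vol, mean_lipid = lm / vol
    )
  })
}

#' Integer-shift image registration by normalised cross-correlation
#'
#' Exhaustively searches integer shifts within `max_shift` for the one
#' maximising the normalised cross-correlation (Pearson correlation of
#' the overlapping pixels) between the shifted moving image and the fixed
#' image. NCC is invariant to affine intensity rescaling of either image.
#'
#' The returned shift `(dr, dc)` is the displacement of the moving
#' image's content relative to the fixed image: if
#' `moving[r, c] == fixed[r - dr, c - dc]`, the search recovers
#' `(dr, dc)` and `registered[r, c] = moving[r + dr, c + dc]` aligns it
#' back onto the fixed frame (zero-filled outside the overlap).
#'
#' @param moving,fixed Numeric matrices of equal dimension with nonzero
#'   variance.
#' @param max_shift Maximum absolute shift searched, pixels.
#' @return List: `shift` (c(dr, dc)), `score` (NCC at the optimum),
#'   `registered`.
#' @examples
#' fx <- matrix(stats::rnorm(400), 20, 20)
#' register_ncc(fx, fx, max_shift = 3)$shift
#' @export
register_ncc <- function(moving, fixed, max_shift = 10) {
  stopifnot(is.matrix(moving), is.matrix(fixed),
            identical(dim(moving), dim(fixed)))
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0) {
    stop("cannot register a flat (zero-variance) image", call. = FALSE)
  }
  nr <- nrow(fixed); nc <- ncol(fixed)
  best <- list(shift = c(0L, 0L), score = -Inf)
  for (dr in -max_shift:max_shift) {
    rf <- max(1, 1 - dr):min(nr, nr - dr) # fixed rows with valid moving rows rf+dr
    if (length(rf) < 2) next
    for (dc in -max_shift:max_shift) {
      cf <- max(1, 1 - dc):min(nc, nc - dc)
      if (length(cf) < 2) next
      a <- fixed[rf, cf]
      b <- moving[rf + dr, cf + dc]
      sa <- stats::sd(a); sb <- stats::sd(b)
      if (sa == 0 || sb == 0) next
      sc <- stats::cor(as.numeric(a), as.numeric(b))
      if (sc > best$score) best <- list(shift = c(dr, dc), score = sc)
    }
  }
  if (!is.finite(best$score)) {
    stop("no valid overlap found within max_shift", call. = FALSE)
  }
  dr <- best$shift[1]; dc <- best$shift[2]
  reg <- matrix(0, nr, nc)
  rf <- max(1, 1 - dr):min(nr, nr - dr)
  cf <- max(1, 1 - dc):min(nc, nc - dc)
  reg[rf, cf] <- moving[rf + dr, cf + dc]
  list(shift = best$shift, score = best$score, registered = reg)
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean intensity over the nucleus mask divided by the mean over the
#' cytoplasm mask (e.g. YAP localisation). Missing nucleus gives `NA`.
#'
#' @param intensity Numeric matrix.
#' @param nucleus_mask,cyto_mask Logical matrices.
#' @return Scalar ratio, or `NA` if the nucleus mask is empty.
#' @export
nc_ratio <- function(intensity, nucleus_mask, cyto_mask) {
  stopifnot(identical(dim(intensity), dim(nucleus_mask)),
            identical(dim(intensity), dim(cyto_mask)))
  if (!any(nucleus_mask)) return(NA_real_)
  if (!any(cyto_mask)) return(NA_real_)
  mean(intensity[nucleus_mask]) / mean(intensity[cyto_mask])
}

#' Attach fluorescence features to cell records
#'
#' Left-joins a per-cell feature table (columns `cell_id`, features) onto
#' quantified cell records; registration between feature images and
#' density maps is assumed already applied (see [register_ncc()]).
#'
#' @param records Tibble of per-cell records (from
#'   [compartment_densities()] or [integrate_zstack()]).
#' @param features Tibble with `cell_id` and feature columns.
#' @return `records` with the feature columns joined.
#' @export
link_fluorescence <- function(records, features) {
  stopifnot("cell_id" %in% names(records), "cell_id" %in% names(features))
  dplyr::left_join(records, features, by = "cell_id")
}
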