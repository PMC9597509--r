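#' Segmentation parameters
#'
#' Parameters of the automated compartment segmentation. Cell bodies are
#' pixels whose protein density exceeds `protein_threshold` (default
#' 0.0666 g/ml); nuclei are the largest region inside each cell body with
#' lipid density below `nuclear_lipid_threshold` (default 0.0099 g/ml);
#' nucleoli are segmented per nucleus by Otsu's method on protein density.
#' Density planes are Gaussian-smoothed (`smooth_sigma` pixels) before
#' thresholding, and segmentation statistics use the unclipped raw
#' component planes when available (symmetric noise); compartment means
#' are always measured on the unsmoothed, clipped, closure-normalised
#' map.
#'
#' With `refine_boundaries` (default), each fixed-threshold mask is used
#' to estimate the density levels inside and outside the compartment and
#' the contour is then re-drawn at their midpoint (the half-maximum
#' contour). A fixed threshold close to one of the two levels places the
#' contour systematically inside or outside the true edge once the image
#' is smoothed (e.g. the 9.9 mg/ml lipid threshold sits only ~5 mg/ml
#' above the nuclear level but ~19 below the cytoplasmic one); the
#' midpoint contour is unbiased and far from both levels relative to the
#' noise. The paper-style fixed thresholds still decide what counts as a
#' compartment; refinement only repositions its boundary.
#'
#' `nucleolus_contrast_min` is the minimum Otsu class separation, in units
#' of the within-class SD, for a nucleolus call: a nucleolus-free nucleus
#' split by Otsu yields a separation around 1.6 (pure Gaussian noise),
#' genuine nucleoli sit near 4-7, and strongly osmotically compressed
#' nuclei whose nucleolar contrast has collapsed fall below the default
#' of 3, in which case no nucleolus is reported.
#'
#' `measure_erosion_*` and `measure_exclusion` control the mask shrinkage
#' used when averaging intensities (see [compartment_densities()]):
#' compartment masks are eroded and neighbouring compartments dilated
#' before measurement so residual boundary jitter does not leak foreign
#' pixels into the means.
#'
#' @param protein_threshold Cell-body protein threshold, g/ml.
#' @param nuclear_lipid_threshold Nuclear lipid threshold, g/ml.
#' @param min_cell_area,min_nucleus_area,min_nucleolus_area Size filters,
#'   pixels (defaults 200/50/5 at 0.25 um/px).
#' @param max_nucleolus_frac Maximum nucleolus component area as a
#'   fraction of its nucleus.
#' @param border_policy `"exclude"` (drop cells touching the image border;
#'   default) or `"keep"`.
#' @param nucleolus_contrast_min Minimum Otsu class separation z (see
#'   Details).
#' @param smooth_sigma Gaussian pre-smoothing SD, pixels.
#' @param nucleolus_smooth_sigma Gaussian pre-smoothing SD for the
#'   nucleolus stage. Smaller than `smooth_sigma` so that nucleoli near
#'   the optical resolution limit (~1 um) keep enough of their protein
#'   contrast to clear the Otsu contrast gate; the ~28 mg/ml nucleolar
#'   contrast tolerates the higher residual noise.
#' @param refine_boundaries Re-draw threshold contours at the
#'   inside/outside midpoint level (see Details). The nucleus refinement
#'   is iterated twice so that an initial fragment (a noise-bitten
#'   largest component) cannot corrupt the outside-level estimate.
#' @param closing_radius Morphological closing radius applied to the
#'   nucleus mask to heal noise bites at its boundary (a convex nucleus
#'   outline is unchanged by closing).
#' @param watershed_tolerance Watershed minimum object-height tolerance on
#'   the distance transform, pixels.
#' @param measure_erosion_body,measure_erosion_nucleus,measure_erosion_nucleolus
#'   Erosion radius (px) applied to each compartment mask before
#'   intensity measurement.
#' @param measure_exclusion Dilation radius (px) of the inner compartment
#'   excluded from the surrounding one before measurement.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(protein_threshold = 0.0666,
                                nuclear_lipid_threshold = 0.0099,
                                min_cell_area = 200,
                                min_nucleus_area = 50,
                                min_nucleolus_area = 5,
                                max_nucleolus_frac = 0.5,
                                border_policy = c("exclude", "keep"),
                                nucleolus_contrast_min = 3,
                                smooth_sigma = 1.5,
                                nucleolus_smooth_sigma = 1.2,
                                refine_boundaries = TRUE,
                                closing_radius = 2,
                                watershed_tolerance = 10,
                                measure_erosion_body = 2,
                                measure_erosion_nucleus = 2,
                                measure_erosion_nucleolus = 2,
                                measure_exclusion = 2) {
  border_policy <- match.arg(border_policy)
  if (protein_threshold <= 0 || nuclear_lipid_threshold <= 0) {
    stop("density thresholds must be > 0", call. = FALSE)
  }
  if (min_cell_area < 0 || min_nucleus_area < 0 || min_nucleolus_area < 0) {
    stop("size thresholds must be >= 0", call. = FALSE)
  }
  structure(
    list(
      protein_threshold = protein_threshold,
      nuclear_lipid_threshold = nuclear_lipid_threshold,
      min_cell_area = min_cell_area,
      min_nucleus_area = min_nucleus_area,
      min_nucleolus_area = min_nucleolus_area,
      max_nucleolus_frac = max_nucleolus_frac,
      border_policy = border_policy,
      nucleolus_contrast_min = nucleolus_contrast_min,
      smooth_sigma = smooth_sigma,
      nucleolus_smooth_sigma = nucleolus_smooth_sigma,
      refine_boundaries = isTRUE(refine_boundaries),
      closing_radius = closing_radius,
      watershed_tolerance = watershed_tolerance,
      measure_erosion_body = measure_erosion_body,
      measure_erosion_nucleus = measure_erosion_nucleus,
      measure_erosion_nucleolus = measure_erosion_nucleolus,
      measure_exclusion = measure_exclusion
    ),
    class = "segmentation_params"
  )
}

# light wrapper: EBImage returns Image objects; we keep plain matrices
ebi <- function(x) EBImage::imageData(x)

smooth_plane <- function(x, sigma, median_radius = 0) {
  if (median_radius > 0) {
    # medianFilter expects values in [0, 1]; an affine map commutes with
    # the median, so rescale, filter, and map back
    rng <- range(x)
    if (diff(rng) > 0) {
      xn <- (x - rng[1]) / diff(rng)
      xn <- ebi(EBImage::medianFilter(xn, size = median_radius))
      x <- xn * diff(rng) + rng[1]
    }
  }
  if (sigma > 0) x <- ebi(EBImage::gblur(x, sigma = sigma))
  x
}

# unclipped raw plane when the map carries one (see unmix_image)
raw_plane <- function(map, channel) {
  map[[paste0(channel, "_raw")]] %||% map[[channel]]
}

# dense relabelling 1..K, stable in raster (column-major) order
relabel_dense <- function(lab) {
  ids <- unique(lab[lab > 0])
  if (length(ids) == 0) return(lab)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- lab
  out[out > 0] <- lut[out[out > 0]]
  out
}

drop_small <- function(lab, min_area) {
  sz <- tabulate(lab[lab > 0])
  bad <- which(sz < min_area)
  if (length(bad)) lab[lab %in% bad] <- 0L
  lab
}

#' Otsu threshold by exhaustive between-class variance maximisation
#'
#' Computes Otsu's threshold on a 256-bin histogram spanning the data's
#' own range: the bin edge maximising the between-class variance
#' `w0 w1 (mu0 - mu1)^2`. Ties are broken toward the lower threshold.
#' Also reports the between- and within-class variances at the optimum
#' and the class separation `(mu1 - mu0) / sd_within` used as a
#' nucleolus-contrast statistic.
#'
#' @param x Numeric vector.
#' @param nbins Number of histogram bins.
#' @return List: `threshold` (NA for a degenerate, constant input),
#'   `between_var`, `within_var`, `total_var` (binned), `separation_z`.
#' @examples
#' otsu_threshold(c(rep(0.08, 90), rep(0.11, 10)))$threshold
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) < 2 || diff(rng) == 0) {
    return(list(
      threshold = NA_real_, between_var = 0, within_var = 0,
      total_var = 0, separation_z = 0
    ))
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins) / length(x)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mu_t <- m0[nbins]
  total_var <- sum(p * (mids - mu_t)^2)
  k <- seq_len(nbins - 1)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mu_t * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  kstar <- which.max(bcv) # first maximum = lower threshold on ties
  between_var <- bcv[kstar]
  within_var <- max(total_var - between_var, 0)
  mu0 <- m0[kstar] / w0[kstar]
  mu1 <- (mu_t - m0[kstar]) / (1 - w0[kstar])
  sep <- if (within_var > 0) (mu1 - mu0) / sqrt(within_var) else Inf
  list(
    threshold = breaks[kstar + 1],
    between_var = between_var,
    within_var = within_var,
    total_var = total_var,
    separation_z = sep
  )
}

threshold_mask <- function(sm, thr, min_area) {
  mask <- sm > thr
  if (!any(mask)) return(mask)
  mask <- ebi(EBImage::fillHull(mask * 1)) > 0
  mask <- ebi(EBImage::opening(mask * 1, EBImage::makeBrush(3, "disc"))) > 0
  lab <- ebi(EBImage::bwlabel(mask * 1))
  lab <- drop_small(lab, min_area)
  lab > 0
}

#' Segment cell bodies by protein-density thresholding
#'
#' Foreground is protein density above `protein_threshold` on the
#' smoothed map (optionally boundary-refined to the half-maximum
#' contour); holes are filled, components below `min_cell_area` are
#' removed, touching cells are split by the watershed transform of the
#' distance map, and border-touching cells are handled per
#' `border_policy`.
#'
#' @param map A [density_map()].
#' @param params [segmentation_params()].
#' @return Integer label matrix (dense ids from 1; 0 = background).
#' @export
segment_cell_bodies <- function(map, params = segmentation_params()) {
  stopifnot(inherits(map, "density_map"))
  plane <- raw_plane(map, "protein")
  if (any(!is.finite(plane))) {
    stop("protein plane contains non-finite values", call. = FALSE)
  }
  sm <- smooth_plane(plane, params$smooth_sigma)
  mask <- threshold_mask(sm, params$protein_threshold, params$min_cell_area)
  if (!any(mask)) return(matrix(0L, nrow(sm), ncol(sm)))
  if (params$refine_boundaries) {
    m_in <- stats::median(plane[erode_mask(mask, 2)])
    m_out <- stats::median(plane[!dilate_mask(mask, 2)])
    if (is.finite(m_in) && is.finite(m_out) &&
      m_out < params$protein_threshold && params$protein_threshold < m_in) {
      mask <- threshold_mask(sm, (m_in + m_out) / 2, params$min_cell_area)
    }
  }
  if (!any(mask)) return(matrix(0L, nrow(sm), ncol(sm)))
  dm <- ebi(EBImage::distmap(mask * 1))
  ws <- ebi(EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1))
  ws <- drop_small(ws, params$min_cell_area)
  if (params$border_policy == "exclude") {
    edge_ids <- unique(c(ws[1, ], ws[nrow(ws), ], ws[, 1], ws[, ncol(ws)]))
    edge_ids <- edge_ids[edge_ids > 0]
    if (length(edge_ids)) ws[ws %in% edge_ids] <- 0L
  }
  storage.mode(ws) <- "integer"
  relabel_dense(ws)
}

label_bbox <- function(lab, id) {
  w <- which(lab == id, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  list(
    rows = min(w[, 1]):max(w[, 1]),
    cols = min(w[, 2]):max(w[, 2])
  )
}

largest_component <- function(cand) {
  cc <- ebi(EBImage::bwlabel(cand * 1))
  sz <- tabulate(cc[cc > 0])
  if (length(sz) == 0) return(NULL)
  list(mask = cc == which.max(sz), size = max(sz))
}

#' Segment nuclei inside cell bodies by the lipid threshold
#'
#' Within each cell body, the nucleus is the largest connected region with
#' lipid density below `nuclear_lipid_threshold` and area at least
#' `min_nucleus_area` (holes filled, boundary optionally refined to the
#' per-cell half-maximum lipid contour). Cells without a qualifying
#' nucleus (e.g. mitotic cells) are flagged in attribute `no_nucleus` and
#' carry no nucleus label.
#'
#' @param map A [density_map()].
#' @param cell_labels Label matrix from [segment_cell_bodies()].
#' @param params [segmentation_params()].
#' @return Integer nucleus label matrix sharing cell ids; attribute
#'   `no_nucleus` lists flagged cell ids.
#' @export
segment_nuclei <- function(map, cell_labels, params = segmentation_params()) {
  stopifnot(inherits(map, "density_map"),
            identical(dim(map$lipid), dim(cell_labels)))
  plane <- raw_plane(map, "lipid")
  sm <- smooth_plane(plane, params$smooth_sigma)
  out <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  flagged <- integer(0)
  for (id in ids) {
    bb <- label_bbox(cell_labels, id)
    cellm <- cell_labels[bb$rows, bb$cols] == id
    smc <- sm[bb$rows, bb$cols]
    rawc <- plane[bb$rows, bb$cols]
    lc <- largest_component(cellm & (smc < params$nuclear_lipid_threshold))
    if (is.null(lc) || lc$size < params$min_nucleus_area) {
      flagged <- c(flagged, id)
      next
    }
    nuc <- lc$mask
    if (params$refine_boundaries) {
      for (iter in 1:2) {
        core <- erode_mask(nuc, 2)
        if (!any(core)) core <- nuc
        m_in <- stats::median(rawc[core])
        outside <- cellm & !dilate_mask(nuc, 2)
        if (!any(outside)) break
        m_out <- stats::median(rawc[outside])
        if (!(m_in < params$nuclear_lipid_threshold &&
          params$nuclear_lipid_threshold < m_out)) {
          break
        }
        lc2 <- largest_component(cellm & (smc < (m_in + m_out) / 2))
        if (is.null(lc2) || lc2$size < params$min_nucleus_area) break
        nuc <- lc2$mask
      }
    }
    nuc <- ebi(EBImage::fillHull(nuc * 1)) > 0
    if (params$closing_radius > 0) {
      nuc <- ebi(EBImage::closing(
        nuc * 1, EBImage::makeBrush(2 * params$closing_radius + 1, "disc")
      )) > 0
      nuc <- ebi(EBImage::fillHull(nuc * 1)) > 0
    }
    nuc <- nuc & cellm
    sub <- out[bb$rows, bb$cols]
    sub[nuc] <- id
    out[bb$rows, bb$cols] <- sub
  }
  attr(out, "no_nucleus") <- flagged
  out
}

#' Segment nucleoli within nuclei by Otsu's method on protein density
#'
#' Per nucleus, [otsu_threshold()] is applied to the (smoothed) protein
#' densities of the nucleus pixels; supra-threshold connected components
#' with area in `[min_nucleolus_area, max_nucleolus_frac * nucleus area]`
#' become nucleoli. If the Otsu class separation falls below
#' `nucleolus_contrast_min` (in within-class SD units) the nucleus is
#' reported nucleolus-free — the behaviour of strongly compressed nuclei
#' whose nucleolar density no longer stands out from the nucleoplasm.
#'
#' @param map A [density_map()].
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @param params [segmentation_params()].
#' @return Integer nucleolus label matrix sharing cell ids; attribute
#'   `no_nucleolus` lists nucleus ids without a detected nucleolus.
#' @export
segment_nucleoli <- function(map, nucleus_labels,
                             params = segmentation_params()) {
  stopifnot(inherits(map, "density_map"),
            identical(dim(map$protein), dim(nucleus_labels)))
  # 3x3 median + light blur: suppresses per-pixel noise (so the Otsu
  # noise-split cannot out-compete a small nucleolus) without erasing
  # nucleoli near the resolution limit
  sm <- smooth_plane(raw_plane(map, "protein"), params$nucleolus_smooth_sigma,
                     median_radius = 1)
  # coarser field for the final measurement contour: its boundary jitter
  # is nearly uncorrelated with per-pixel measurement noise, so the mask
  # does not preferentially select up-noise pixels
  sm2 <- if (params$refine_boundaries) {
    smooth_plane(raw_plane(map, "protein"), 2 * params$nucleolus_smooth_sigma,
                 median_radius = 1)
  } else {
    NULL
  }
  out <- matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels))
  ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  flagged <- integer(0)
  for (id in ids) {
    bb <- label_bbox(nucleus_labels, id)
    nucm <- nucleus_labels[bb$rows, bb$cols] == id
    vals <- sm[bb$rows, bb$cols][nucm]
    ot <- otsu_threshold(vals)
    if (is.na(ot$threshold) || ot$separation_z < params$nucleolus_contrast_min) {
      flagged <- c(flagged, id)
      next
    }
    cand <- nucm & (sm[bb$rows, bb$cols] > ot$threshold)
    if (!any(cand)) {
      flagged <- c(flagged, id)
      next
    }
    cc <- ebi(EBImage::bwlabel(cand * 1))
    sz <- tabulate(cc[cc > 0])
    keep <- which(sz >= params$min_nucleolus_area &
                    sz <= params$max_nucleolus_frac * sum(nucm))
    if (length(keep) == 0) {
      flagged <- c(flagged, id)
      next
    }
    nul <- matrix(cc %in% keep, nrow(cc)) & nucm
    if (!is.null(sm2)) {
      # redraw detected components on the coarse field at the same
      # threshold; components too small to survive the coarse scale keep
      # their fine-scale mask
      cand2 <- nucm & (sm2[bb$rows, bb$cols] > ot$threshold)
      if (any(cand2)) {
        cc2 <- ebi(EBImage::bwlabel(cand2 * 1))
        keep2 <- setdiff(unique(cc2[nul]), 0)
        nul2 <- matrix(cc2 %in% keep2, nrow(cc2))
        covered <- setdiff(unique(cc[nul2 & nul]), 0)
        lost <- nul & !(cc %in% covered)
        nul <- (nul2 & nucm) | lost
      }
    }
    sub <- out[bb$rows, bb$cols]
    sub[nul] <- id
    out[bb$rows, bb$cols] <- sub
  }
  attr(out, "no_nucleolus") <- flagged
  out
}

#' Compartment label set with enforced nesting
#'
#' Bundles the three label images and asserts the nesting invariant
#' (nucleolus inside nucleus inside cell body, per cell id).
#'
#' @param cell,nucleus,nucleolus Integer label matrices sharing cell ids.
#' @return List of class `compartment_labels`.
#' @export
compartment_labels <- function(cell, nucleus, nucleolus) {
  stopifnot(identical(dim(cell), dim(nucleus)),
            identical(dim(cell), dim(nucleolus)))
  if (any(nucleus > 0 & nucleus != cell)) {
    stop("nucleus labels are not nested inside their cell bodies", call. = FALSE)
  }
  if (any(nucleolus > 0 & nucleolus != nucleus)) {
    stop("nucleolus labels are not nested inside their nuclei", call. = FALSE)
  }
  structure(
    list(cell = cell, nucleus = nucleus, nucleolus = nucleolus,
         no_nucleus = attr(nucleus, "no_nucleus") %||% integer(0),
         no_nucleolus = attr(nucleolus, "no_nucleolus") %||% integer(0)),
    class = "compartment_labels"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full compartment segmentation
#'
#' Runs [segment_cell_bodies()], [segment_nuclei()] and
#' [segment_nucleoli()] and returns the validated label set.
#'
#' @param map A [density_map()].
#' @param params [segmentation_params()].
#' @return A [compartment_labels()] object.
#' @examples
#' spec <- phantom_spec(n_cells = 2, image_shape = c(192, 192), seed = 5)
#' cells <- sample_population(spec)
#' truth <- render_density_map(cells, spec)
#' labs <- segment_compartments(truth)
#' max(labs$cell)
#' @export
segment_compartments <- function(map, params = segmentation_params()) {
  cell <- segment_cell_bodies(map, params)
  nucleus <- segment_nuclei(map, cell, params)
  nucleolus <- segment_nucleoli(map, nucleus, params)
  compartment_labels(cell, nucleus, nucleolus)
}

#' Match predicted labels to ground-truth labels by overlap
#'
#' For each predicted label, finds the ground-truth label with the largest
#' pixel overlap and reports the Jaccard index of the pair.
#'
#' @param pred,truth Integer label matrices of equal dimension.
#' @return Tibble: `pred`, `truth` (0 if no overlap), `jaccard`.
#' @export
match_labels <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  ids <- sort(unique(pred[pred > 0]))
  purrr::map_dfr(ids, function(id) {
    pm <- pred == id
    ov <- truth[pm]
    ov <- ov[ov > 0]
    if (length(ov) == 0) {
      return(tibble::tibble(pred = id, truth = 0L, jaccard = 0))
    }
    tid <- as.integer(names(which.max(table(ov))))
    tm <- truth == tid
    tibble::tibble(
      pred = id, truth = tid,
      jaccard = sum(pm & tm) / sum(pm | tm)
    )
  })
}
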