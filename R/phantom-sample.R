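# Geometry helpers ---------------------------------------------------------

# Membership of pixel centers in a rotated ellipse over a bounding box.
# Returns NULL when the box is empty. rows/cols are image indices (1-based).
ellipse_box <- function(cx, cy, ax, ay, theta, shape) {
  if (ax <= 0 || ay <= 0) return(NULL)
  half <- max(ax, ay) + 1
  r0 <- max(1L, floor(cx - half)); r1 <- min(shape[1], ceiling(cx + half))
  c0 <- max(1L, floor(cy - half)); c1 <- min(shape[2], ceiling(cy + half))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  X <- matrix(rows - cx, length(rows), length(cols))
  Y <- matrix(cols - cy, length(rows), length(cols), byrow = TRUE)
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  list(rows = rows, cols = cols, inside = (u / ax)^2 + (v / ay)^2 <= 1)
}

# Axial slice factor of an ellipsoid with axial semi-axis rz at height z (um).
slice_factor <- function(z, rz) {
  if (abs(z) >= rz) return(0)
  sqrt(1 - (z / rz)^2)
}

# Body / nucleus / nucleoli masks of one cell in one optical section.
# `cell` is one row of the population tibble (as a list). Masks are nested
# by construction. Returns NULL if the body does not intersect the slice.
cell_slice_masks <- function(cell, spec, z = 0) {
  ps <- spec$pixel_size
  sb <- slice_factor(z, cell$rz_um)
  if (sb == 0) return(NULL)
  body <- ellipse_box(
    cell$cx, cell$cy, cell$ax * sb, cell$ay * sb, cell$theta,
    spec$image_shape
  )
  if (is.null(body) || !any(body$inside)) return(NULL)
  nucleus <- matrix(FALSE, length(body$rows), length(body$cols))
  nucleoli <- matrix(FALSE, length(body$rows), length(body$cols))
  sn <- slice_factor(z, cell$nuc_rz_um)
  if (sn > 0) {
    nb <- ellipse_box(
      cell$cx + cell$nuc_dx, cell$cy + cell$nuc_dy,
      cell$nuc_ax * sn, cell$nuc_ay * sn, cell$theta,
      spec$image_shape
    )
    if (!is.null(nb)) {
      ri <- match(nb$rows, body$rows); ci <- match(nb$cols, body$cols)
      ok <- !is.na(ri) & seq_along(nb$rows) > 0
      nucleus[ri[!is.na(ri)], ci[!is.na(ci)]] <-
        nb$inside[!is.na(ri), !is.na(ci), drop = FALSE]
    }
    nucleus <- nucleus & body$inside
    nl <- cell$nucleoli[[1]]
    if (!is.null(nl) && nrow(nl) > 0) {
      for (k in seq_len(nrow(nl))) {
        r_um <- nl$r_px[k] * ps
        if (abs(z) >= r_um) next
        r_slice <- sqrt(r_um^2 - z^2) / ps
        ob <- ellipse_box(
          cell$cx + cell$nuc_dx + nl$dx[k],
          cell$cy + cell$nuc_dy + nl$dy[k],
          r_slice, r_slice, 0, spec$image_shape
        )
        if (is.null(ob)) next
        ri <- match(ob$rows, body$rows); ci <- match(ob$cols, body$cols)
        nucleoli[ri[!is.na(ri)], ci[!is.na(ci)]] <-
          nucleoli[ri[!is.na(ri)], ci[!is.na(ci)], drop = FALSE] |
          ob$inside[!is.na(ri), !is.na(ci), drop = FALSE]
      }
      nucleoli <- nucleoli & nucleus
    }
  }
  list(rows = body$rows, cols = body$cols, body = body$inside,
       nucleus = nucleus, nucleoli = nucleoli)
}

# z positions of the optical sections intersecting a cell.
cell_slice_z <- function(cell, spec) {
  k <- floor(cell$rz_um / spec$z_spacing)
  seq(-k, k) * spec$z_spacing
}

# Truncated-normal draw (at zero); truncation events are counted by caller.
rnorm_trunc0 <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

# Population sampling -------------------------------------------------------

#' Sample a ground-truth cell population
#'
#' Draws `spec$n_cells` cells with non-overlapping placements (rejection
#' sampling), per-cell compartment densities from the spec's distributions
#' multiplied by the preset's fold changes and truncated at zero, cell-cycle
#' stages with DNA content (1x in G1, 2x in G2-M, uniform in between for S),
#' and exact voxelised ground-truth volumes and masses (mass is the sum of
#' density times voxel volume over the rendered cell, so the rendered stack
#' integrates back to it exactly; 1 g/ml = 1 pg/um^3).
#'
#' @param spec A [phantom_spec()].
#' @param preset A preset name or the list returned by [condition_preset()].
#' @return A tibble with one row per cell: geometry (pixel units), true
#'   compartment densities (g/ml), stage, `dna_content`, `volume_um3`,
#'   `protein_mass_pg`, `lipid_mass_pg`, `dry_mass_pg`. The number of
#'   zero-truncated density draws is in attribute `truncated_draws`.
#' @examples
#' cells <- sample_population(phantom_spec(n_cells = 3, seed = 2))
#' cells$cyto_protein
#' @export
sample_population <- function(spec, preset = "control") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.character(preset)) preset <- condition_preset(preset)
  set.seed(spec$seed)
  n <- spec$n_cells
  if (n == 0) {
    out <- empty_population()
    attr(out, "truncated_draws") <- 0L
    return(out)
  }
  ps <- spec$pixel_size
  shape <- spec$image_shape
  margin <- spec$placement_margin_um / ps
  radius_scale <- preset$mass^(1 / 3)

  # geometry: rejection-sample non-overlapping centers
  r_um <- rnorm_trunc0(n, spec$cell_radius_um * radius_scale,
                       spec$cell_radius_sd_um * radius_scale)
  r_um <- pmax(r_um, 0.2 * spec$cell_radius_um * radius_scale)
  ratio <- stats::runif(n, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
  theta <- stats::runif(n, 0, pi)
  ax <- r_um / ps / sqrt(ratio) # major semi-axis, px
  ay <- r_um / ps * sqrt(ratio) # minor semi-axis, px
  rmax <- pmax(ax, ay)
  cx <- cy <- numeric(n)
  placed <- 0L
  for (i in seq_len(n)) {
    lo_r <- rmax[i] + margin; hi_r <- shape[1] - rmax[i] - margin
    lo_c <- rmax[i] + margin; hi_c <- shape[2] - rmax[i] - margin
    if (lo_r >= hi_r || lo_c >= hi_c) {
      stop(sprintf(
        "cannot place cell %d: radius %.1f px exceeds image; placed %d of %d cells",
        i, rmax[i], placed, n
      ), call. = FALSE)
    }
    ok <- FALSE
    for (att in seq_len(2000L)) {
      px <- stats::runif(1, lo_r, hi_r)
      py <- stats::runif(1, lo_c, hi_c)
      if (placed == 0L ||
        all(sqrt((cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2) >
          rmax[seq_len(placed)] + rmax[i] + margin)) {
        cx[i] <- px; cy[i] <- py; ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "could only place %d of %d cells in a %d x %d px image; reduce n_cells or enlarge the image",
        placed, n, shape[1], shape[2]
      ), call. = FALSE)
    }
    placed <- placed + 1L
  }

  rz_um <- spec$z_aspect * pmin(ax, ay) * ps
  nuc_frac <- pmin(pmax(stats::rnorm(n, spec$nucleus_fraction[1],
                                     spec$nucleus_fraction[2]), 0.35), 0.8)
  nuc_ax <- nuc_frac * ax
  nuc_ay <- nuc_frac * ay
  nuc_rz_um <- nuc_frac * rz_um
  # small nuclear offset, keeping the nucleus inside the body
  off_r <- stats::runif(n, 0, 0.10) * pmin(ax, ay) * (1 - nuc_frac)
  off_a <- stats::runif(n, 0, 2 * pi)
  nuc_dx <- off_r * cos(off_a)
  nuc_dy <- off_r * sin(off_a)

  nucleoli <- vector("list", n)
  for (i in seq_len(n)) {
    k_choices <- seq(spec$n_nucleoli_range[1], spec$n_nucleoli_range[2])
    k <- if (length(k_choices) == 1) k_choices else sample(k_choices, 1)
    frac <- pmin(pmax(stats::rnorm(k, spec$nucleolus_fraction[1],
                                   spec$nucleolus_fraction[2]), 0.18), 0.45)
    rr <- frac * min(nuc_ax[i], nuc_ay[i])
    dx <- dy <- numeric(k)
    kept <- logical(k)
    for (j in seq_len(k)) {
      for (att in seq_len(200L)) {
        rho <- stats::runif(1, 0, max(0, 0.85 * min(nuc_ax[i], nuc_ay[i]) - rr[j]))
        ang <- stats::runif(1, 0, 2 * pi)
        dxj <- rho * cos(ang); dyj <- rho * sin(ang)
        if (!any(kept) ||
          all(sqrt((dx[kept] - dxj)^2 + (dy[kept] - dyj)^2) >
            rr[kept] + rr[j] + 1)) {
          dx[j] <- dxj; dy[j] <- dyj; kept[j] <- TRUE
          break
        }
      }
    }
    nucleoli[[i]] <- tibble::tibble(dx = dx[kept], dy = dy[kept], r_px = rr[kept])
  }

  # per-cell compartment densities: spec distribution x preset fold
  dd <- spec$densities
  # protein compartments share a per-cell crowding factor g (the paper's
  # compartment density ratios are tightly conserved across cells), with
  # residual SDs shrunk so that each marginal keeps its stated mean/SD
  g <- stats::rnorm(n, 1, spec$shared_protein_cv)
  draw_protein <- function(d) {
    resid_sd <- sqrt(max(d[[2]]^2 - (d[[1]] * spec$shared_protein_cv)^2, 0))
    (d[[1]] + stats::rnorm(n, 0, resid_sd)) * g
  }
  raw <- list(
    cyto_protein = draw_protein(dd$cyto_protein),
    cyto_lipid = stats::rnorm(n, dd$cyto_lipid[[1]], dd$cyto_lipid[[2]]),
    nup_protein = draw_protein(dd$nup_protein),
    nul_protein = draw_protein(dd$nul_protein),
    nuc_lipid = stats::rnorm(n, dd$nuc_lipid[[1]], dd$nuc_lipid[[2]])
  )
  truncated <- sum(vapply(raw, function(x) sum(x < 0), integer(1)))
  dens <- list(
    cyto_protein = pmax(raw$cyto_protein, 0) * preset$cyto_protein,
    cyto_lipid = pmax(raw$cyto_lipid, 0) * preset$cyto_lipid,
    nup_protein = pmax(raw$nup_protein, 0) * preset$nup_protein,
    nul_protein = pmax(raw$nul_protein, 0) * preset$nul_protein,
    nuc_lipid = pmax(raw$nuc_lipid, 0)
  )

  stage <- sample(names(spec$stage_fractions), n,
                  replace = TRUE, prob = spec$stage_fractions)
  dna <- ifelse(stage == "G1", 1, ifelse(stage == "G2M", 2, NA))
  dna[is.na(dna)] <- stats::runif(sum(is.na(dna)), 1, 2)

  cells <- tibble::tibble(
    cell_id = seq_len(n),
    cx = cx, cy = cy, ax = ax, ay = ay, theta = theta, rz_um = rz_um,
    nuc_dx = nuc_dx, nuc_dy = nuc_dy, nuc_ax = nuc_ax, nuc_ay = nuc_ay,
    nuc_rz_um = nuc_rz_um,
    nucleoli = nucleoli,
    cyto_protein = dens$cyto_protein,
    cyto_lipid = dens$cyto_lipid,
    nup_protein = dens$nup_protein,
    nul_protein = dens$nul_protein,
    nuc_lipid = dens$nuc_lipid,
    stage = stage,
    dna_content = dna
  )

  # exact voxelised ground truth volume and mass
  voxvol <- ps^2 * spec$z_spacing
  vols <- purrr::map(seq_len(n), function(i) {
    cell <- as.list(cells[i, ])
    nb <- nn <- nl <- 0
    for (z in cell_slice_z(cell, spec)) {
      m <- cell_slice_masks(cell, spec, z)
      if (is.null(m)) next
      nb <- nb + sum(m$body)
      nn <- nn + sum(m$nucleus)
      nl <- nl + sum(m$nucleoli)
    }
    c(body = nb, nucleus = nn, nucleoli = nl)
  })
  vb <- vapply(vols, `[[`, numeric(1), "body")
  vn <- vapply(vols, `[[`, numeric(1), "nucleus")
  vl <- vapply(vols, `[[`, numeric(1), "nucleoli")
  cells$volume_um3 <- vb * voxvol
  cells$protein_mass_pg <-
    ((vb - vn) * cells$cyto_protein + (vn - vl) * cells$nup_protein +
      vl * cells$nul_protein) * voxvol
  cells$lipid_mass_pg <-
    ((vb - vn) * cells$cyto_lipid + vn * cells$nuc_lipid) * voxvol
  cells$dry_mass_pg <- cells$protein_mass_pg + cells$lipid_mass_pg
  attr(cells, "truncated_draws") <- truncated
  cells
}

empty_population <- function() {
  tibble::tibble(
    cell_id = integer(), cx = numeric(), cy = numeric(), ax = numeric(),
    ay = numeric(), theta = numeric(), rz_um = numeric(), nuc_dx = numeric(),
    nuc_dy = numeric(), nuc_ax = numeric(), nuc_ay = numeric(),
    nuc_rz_um = numeric(), nucleoli = list(),
    cyto_protein = numeric(), cyto_lipid = numeric(), nup_protein = numeric(),
    nul_protein = numeric(), nuc_lipid = numeric(), stage = character(),
    dna_content = numeric(), volume_um3 = numeric(),
    protein_mass_pg = numeric(), lipid_mass_pg = numeric(),
    dry_mass_pg = numeric()
  )
}
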