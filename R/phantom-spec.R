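#' HeLa-like compartment density distributions
#'
#' Per-compartment population distributions (mean, SD in g/ml) for a
#' HeLa-like control population: cytoplasmic protein 74.5 +/- 5.2 mg/ml,
#' cytoplasmic lipid 29.1 +/- 5.3 mg/ml, nucleoplasmic protein
#' 81.9 +/- 5.4 mg/ml, nucleolar protein 110.0 +/- 5.9 mg/ml, and a low
#' nuclear lipid density around 5 mg/ml. These satisfy the compartment
#' ordering nucleolus > nucleoplasm > cytoplasm with protein density ratio
#' about 1.5 : 1.1 : 1.
#'
#' @return Named list of `c(mean, sd)` pairs, g/ml.
#' @export
hela_densities <- function() {
  list(
    cyto_protein = c(mean = 0.0745, sd = 0.0052),
    cyto_lipid   = c(mean = 0.0291, sd = 0.0053),
    nup_protein  = c(mean = 0.0819, sd = 0.0054),
    nul_protein  = c(mean = 0.1100, sd = 0.0059),
    nuc_lipid    = c(mean = 0.0050, sd = 0.0010)
  )
}

#' Phantom specification
#'
#' Declarative parameter set for the synthetic-image generator. Cells are
#' ellipsoids (mildly elliptical in-plane, flattened axially) with one
#' nucleus and 1-3 spherical nucleoli; optical sections are slices of the
#' ellipsoids at `z_spacing`. Per-cell compartment densities are drawn
#' from normal distributions truncated at zero. The default pixel size of
#' 0.25 um makes a ~15 um cell span several hundred pixels at
#' mid-section.
#'
#' The default per-pixel noise of 0.015 g/ml is the protein-channel
#' sensitivity of the imaging model; the lipid and water channels default
#' to the same value (`noise_sigma_lipid`, `noise_sigma_water`) since no
#' separate figure is specified for them.
#'
#' The default cell-radius SD is derived from `volume_cv` (volume CV of
#' 28%, matching the dispersion of cell volume and dry mass in cultured
#' populations): for an ellipsoid, radius CV ~ volume CV / 3.
#'
#' @param image_shape Integer vector `c(rows, cols)`, pixels.
#' @param pixel_size Pixel edge, um/pixel.
#' @param z_spacing Optical section spacing, um.
#' @param n_cells Number of cells to place; >= 0.
#' @param cell_radius_um Mean in-plane cell radius, um.
#' @param cell_radius_sd_um SD of the cell radius, um; default derived
#'   from `volume_cv`.
#' @param volume_cv Target coefficient of variation of cell volume.
#' @param nucleus_fraction `c(mean, sd)` of nuclear/cell radius.
#' @param nucleolus_fraction `c(mean, sd)` of nucleolar/nuclear radius
#'   (truncated to `[0.18, 0.45]`).
#' @param n_nucleoli_range Integer `c(min, max)` nucleoli per cell,
#'   sampled uniformly.
#' @param densities Named list of `c(mean, sd)` density distributions in
#'   g/ml with entries `cyto_protein`, `cyto_lipid`, `nup_protein`,
#'   `nul_protein`, `nuc_lipid`; see [hela_densities()].
#' @param noise_sigma_density Per-pixel protein-channel noise SD after
#'   unmixing, g/ml.
#' @param noise_sigma_lipid,noise_sigma_water Per-pixel lipid/water noise
#'   SD, g/ml; default equal to `noise_sigma_density`.
#' @param shared_protein_cv CV of the per-cell crowding factor shared by
#'   the three protein-compartment densities. Compartment protein
#'   densities co-vary within a cell (their ratios are tightly conserved
#'   across cells), so the generator draws a common multiplicative factor
#'   per cell and shrinks the compartment-specific residual SDs so that
#'   every marginal distribution keeps exactly the stated mean and SD.
#' @param stage_fractions Named fractions for G1, S and G2M (defaults
#'   0.70/0.15/0.15, the proportions of a cycling population).
#' @param z_aspect Axial semi-axis as a fraction of the minor in-plane
#'   semi-axis.
#' @param axis_ratio_range In-plane minor/major axis ratio range.
#' @param placement_margin_um Minimum clearance between cell rims and to
#'   the image border, um.
#' @param seed Integer seed; identical seed and spec give bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(n_cells = 4, image_shape = c(256, 256), seed = 1)
#' @export
phantom_spec <- function(image_shape = c(448, 448),
                         pixel_size = 0.25,
                         z_spacing = 1,
                         n_cells = 12,
                         cell_radius_um = 7.5,
                         cell_radius_sd_um = NULL,
                         volume_cv = 0.28,
                         nucleus_fraction = c(0.60, 0.04),
                         nucleolus_fraction = c(0.30, 0.05),
                         n_nucleoli_range = c(1L, 3L),
                         densities = hela_densities(),
                         noise_sigma_density = 0.015,
                         noise_sigma_lipid = noise_sigma_density,
                         noise_sigma_water = noise_sigma_density,
                         shared_protein_cv = 0.05,
                         stage_fractions = c(G1 = 0.70, S = 0.15, G2M = 0.15),
                         z_aspect = 0.8,
                         axis_ratio_range = c(0.85, 1),
                         placement_margin_um = 1,
                         seed = 1L) {
  if (is.null(cell_radius_sd_um)) cell_radius_sd_um <- cell_radius_um * volume_cv / 3
  need <- c("cyto_protein", "cyto_lipid", "nup_protein", "nul_protein", "nuc_lipid")
  if (!all(need %in% names(densities))) {
    stop(
      "densities must contain: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  means <- vapply(densities[need], function(d) d[[1]], numeric(1))
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("all density means must be positive", call. = FALSE)
  }
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  if (noise_sigma_density < 0 || noise_sigma_lipid < 0 || noise_sigma_water < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  stage_fractions <- stage_fractions / sum(stage_fractions)
  structure(
    list(
      image_shape = as.integer(image_shape),
      pixel_size = pixel_size,
      z_spacing = z_spacing,
      n_cells = as.integer(n_cells),
      cell_radius_um = cell_radius_um,
      cell_radius_sd_um = cell_radius_sd_um,
      volume_cv = volume_cv,
      nucleus_fraction = nucleus_fraction,
      nucleolus_fraction = nucleolus_fraction,
      n_nucleoli_range = as.integer(n_nucleoli_range),
      densities = densities,
      noise_sigma_density = noise_sigma_density,
      noise_sigma_lipid = noise_sigma_lipid,
      noise_sigma_water = noise_sigma_water,
      shared_protein_cv = shared_protein_cv,
      stage_fractions = stage_fractions,
      z_aspect = z_aspect,
      axis_ratio_range = axis_ratio_range,
      placement_margin_um = placement_margin_um,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d cells in %d x %d px (%.2f um/px), seed %d\n",
    x$n_cells, x$image_shape[1], x$image_shape[2], x$pixel_size, x$seed
  ))
  invisible(x)
}

#' Condition presets
#'
#' Multiplicative fold-change parameter sets describing how a perturbation
#' shifts the control population: per-compartment density folds, a dry-mass
#' fold, and fluorescence-feature shifts (protein-synthesis OPP/SE fold,
#' ribosome anti-RPS6/SE fold, EdU labelling rate multiplier, senescence
#' marker scaling and fraction, YAP nuclear/cytoplasmic ratio). The control
#' preset has all folds equal to 1.
#'
#' Shipped presets model the perturbation panel of a densitometry study:
#' sodium-potassium pump inhibition (`ouabain`: protein densities 0.6/0.6/0.8
#' of control in cytoplasm/nucleoplasm/nucleolus, lipid 0.7), strong
#' hyperosmotic compression (`hyperosmotic_400`: nucleoplasm approaches
#' nucleolar density so nucleoli lose contrast), hypoosmotic dilution,
#' actin depolymerisation (`cytochalasin_d`), protein-synthesis inhibition
#' (`cycloheximide`), proteasome inhibition (`mg132`), mTOR inhibition
#' (`rapamycin`), serum starvation (`starvation`), and genotoxic
#' senescence (`senescence`: cytoplasmic protein 0.87, nucleoplasmic 0.9,
#' nucleolar 1.08, lipid 1.66, dry mass 12.6, OPP/SE one fifth, EdU
#' labelling near zero, 87% of cells senescent).
#'
#' @return A tibble with one row per preset.
#' @examples
#' condition_presets()$name
#' @export
condition_presets <- function() {
  tibble::tribble(
    ~name, ~cyto_protein, ~cyto_lipid, ~nup_protein, ~nul_protein, ~mass,
    ~opp_se, ~rps6_se, ~edu_rate, ~sabgal_scale, ~senescent_frac, ~yap_nc,
    "control",          1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.000, 1.0, 0.00, 1.5,
    "ouabain",          0.60, 0.70, 0.60, 0.80, 1.00, 1.00, 1.00, 1.000, 1.0, 0.00, 1.5,
    "hyperosmotic_400", 1.41, 1.40, 1.59, 1.18, 1.00, 1.00, 1.00, 1.000, 1.0, 0.00, 1.5,
    "hypoosmotic",      0.74, 0.75, 0.74, 0.90, 1.00, 1.00, 1.00, 1.000, 1.0, 0.00, 1.5,
    "cytochalasin_d",   1.07, 1.10, 1.06, 1.05, 1.07, 1.00, 1.00, 1.000, 1.0, 0.00, 1.5,
    "cycloheximide",    0.96, 1.13, 0.97, 0.97, 0.80, 0.30, 1.60, 0.700, 1.0, 0.00, 1.5,
    "mg132",            1.04, 1.12, 1.04, 1.04, 1.37, 1.00, 1.00, 0.800, 1.0, 0.00, 1.5,
    "rapamycin",        0.94, 0.93, 0.94, 0.95, 0.72, 0.70, 1.00, 0.800, 1.0, 0.00, 1.5,
    "starvation",       1.12, 1.00, 1.13, 1.18, 0.85, 0.75, 0.29, 0.500, 1.0, 0.00, 1.5,
    "senescence",       0.87, 1.66, 0.90, 1.08, 12.6, 0.20, 1.00, 0.007, 4.0, 0.87, 1.5
  )
}

#' @rdname condition_presets
#' @param name Preset name (see `condition_presets()$name`).
#' @export
condition_preset <- function(name = "control") {
  tab <- condition_presets()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop(
      "unknown preset '", name, "'; available: ",
      paste(tab$name, collapse = ", "),
      call. = FALSE
    )
  }
  as.list(tab[i, ])
}
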