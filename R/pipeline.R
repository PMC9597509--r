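#' Pipeline configuration
#'
#' Bundles and validates every stage parameter of the end-to-end run:
#' phantom generation, SRS forward rendering, unmixing, segmentation and
#' quantification. Validation happens here, before any compute. Densities
#' are handled internally in g/ml; summaries report mg/ml (factor 1000),
#' the conventional reporting unit.
#'
#' Cells are simulated in fields of `field_shape` pixels with
#' `cells_per_field` cells each (non-overlapping placements), enough
#' fields to reach `n_cells`.
#'
#' @param preset Condition preset name (see [condition_presets()]).
#' @param n_cells Total number of cells to simulate.
#' @param cells_per_field Cells per simulated field of view.
#' @param field_shape Field size `c(rows, cols)`, pixels.
#' @param seed Integer master seed; all per-field seeds derive from it.
#' @param densities Compartment density distributions
#'   (see [hela_densities()]).
#' @param noise_sigma_density Per-pixel protein-channel noise SD, g/ml.
#' @param spectra [reference_spectra()].
#' @param psv [partial_specific_volumes()].
#' @param params [segmentation_params()].
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes images, tables and the config there.
#' @param write_images Write per-field TIFF images when `out_dir` is set
#'   (tables and config are always written).
#' @return List of class `nori_config`.
#' @export
nori_config <- function(preset = "control",
                        n_cells = 60,
                        cells_per_field = 12,
                        field_shape = c(448, 448),
                        seed = 1L,
                        densities = hela_densities(),
                        noise_sigma_density = 0.015,
                        spectra = reference_spectra(),
                        psv = partial_specific_volumes(),
                        params = segmentation_params(),
                        out_dir = NULL,
                        write_images = FALSE) {
  preset_l <- condition_preset(preset) # validates the name
  stopifnot(inherits(params, "segmentation_params"), inherits(psv, "psv"))
  if (n_cells < 0 || cells_per_field < 1) {
    stop("n_cells must be >= 0 and cells_per_field >= 1", call. = FALSE)
  }
  if (noise_sigma_density < 0) stop("noise SD must be >= 0", call. = FALSE)
  structure(
    list(
      preset = preset, preset_params = preset_l,
      n_cells = as.integer(n_cells),
      cells_per_field = as.integer(cells_per_field),
      field_shape = as.integer(field_shape),
      seed = as.integer(seed),
      densities = densities,
      noise_sigma_density = noise_sigma_density,
      spectra = spectra, psv = psv, params = params,
      out_dir = out_dir, write_images = isTRUE(write_images),
      version = as.character(utils::packageVersion("noripipe"))
    ),
    class = "nori_config"
  )
}

config_as_list <- function(config) {
  list(
    preset = config$preset,
    n_cells = config$n_cells,
    cells_per_field = config$cells_per_field,
    field_shape = config$field_shape,
    seed = config$seed,
    densities = lapply(config$densities, as.numeric),
    noise_sigma_density = config$noise_sigma_density,
    spectra = lapply(seq_len(3), function(i) as.numeric(unclass(config$spectra)[i, ])),
    psv = as.numeric(config$psv),
    segmentation = unclass(config$params),
    version = config$version
  )
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes simulate -> render SRS -> unmix -> segment -> quantify ->
#' link features -> summarise, field by field, and (optionally) writes
#' every artifact with its provenance. Measured cells are matched back to
#' the generating ground-truth cells by label overlap, so the returned
#' population table carries both measured and true per-cell quantities.
#'
#' @param config A [nori_config()].
#' @return List of class `nori_run`: `population` (per-cell tibble with
#'   measured densities in g/ml, matched truth columns `true_*`, and
#'   fluorescence features), `summary` (mg/ml summary via
#'   [summarize_population()]), `qc` (per-field clipped fraction,
#'   flagged-cell counts), `truth` (generator populations, stacked),
#'   `config`.
#' @examples
#' \donttest{
#' run <- run_pipeline(nori_config(n_cells = 12, seed = 1))
#' run$summary
#' }
#' @export
run_pipeline <- function(config = nori_config()) {
  stopifnot(inherits(config, "nori_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  n_fields <- ceiling(config$n_cells / config$cells_per_field)
  pops <- list()
  truths <- list()
  qcs <- list()
  remaining <- config$n_cells
  for (i in seq_len(n_fields)) {
    k <- min(config$cells_per_field, remaining)
    remaining <- remaining - k
    seed_i <- config$seed + 7919L * i
    spec_i <- phantom_spec(
      image_shape = config$field_shape,
      n_cells = k,
      densities = config$densities,
      noise_sigma_density = config$noise_sigma_density,
      seed = seed_i
    )
    cells <- sample_population(spec_i, config$preset_params)
    truth_map <- render_density_map(cells, spec_i, psv = config$psv)
    srs <- srs_forward(
      truth_map, config$spectra,
      noise_sigma_density = config$noise_sigma_density,
      noise_sigma_lipid = config$noise_sigma_density,
      noise_sigma_water = config$noise_sigma_density,
      seed = seed_i + 1L
    )
    dmap <- unmix_image(srs, config$spectra, config$psv)
    labs <- segment_compartments(dmap, config$params)
    rec <- compartment_densities(dmap, labs, config$params)
    truth_labels <- render_labels(cells, spec_i)
    feats <- sample_fluorescence_features(cells, config$preset_params,
                                          seed = seed_i + 2L)

    if (nrow(rec) > 0) {
      mm <- match_labels(labs$cell, truth_labels$cell)
      rec <- dplyr::left_join(
        rec,
        dplyr::rename(mm, cell_id = "pred", true_cell_id = "truth",
                      body_jaccard = "jaccard"),
        by = "cell_id"
      )
      truth_cols <- cells |>
        dplyr::select(
          true_cell_id = "cell_id",
          true_cyto_protein = "cyto_protein",
          true_cyto_lipid = "cyto_lipid",
          true_nup_protein = "nup_protein",
          true_nul_protein = "nul_protein",
          true_volume_um3 = "volume_um3",
          true_dry_mass_pg = "dry_mass_pg"
        )
      rec <- dplyr::left_join(rec, truth_cols, by = "true_cell_id")
      rec <- dplyr::left_join(
        rec,
        dplyr::rename(feats, true_cell_id = "cell_id"),
        by = "true_cell_id"
      )
      rec$field <- i
      rec$condition <- config$preset
      rec$cell_uid <- (i - 1L) * 10000L + rec$cell_id
    }
    qcs[[i]] <- tibble::tibble(
      field = i,
      clipped_fraction = attr(dmap, "clipped_fraction"),
      zero_pixels = attr(dmap, "zero_pixels"),
      n_cells_true = k,
      n_cells_segmented = max(labs$cell),
      n_no_nucleus = length(labs$no_nucleus),
      n_no_nucleolus = length(labs$no_nucleolus),
      truncated_draws = attr(cells, "truncated_draws")
    )
    cells$field <- i
    truths[[i]] <- cells
    pops[[i]] <- rec

    if (!is.null(out_dir) && config$write_images) {
      fd <- file.path(out_dir, sprintf("field_%03d", i))
      dir.create(fd, showWarnings = FALSE)
      write_srs_tiff(srs, file.path(fd, "srs.tiff"))
      write_density_tiff(dmap, file.path(fd, "density.tiff"))
      write_label_tiff(labs$cell, file.path(fd, "cell_labels.tiff"))
      write_label_tiff(labs$nucleus, file.path(fd, "nucleus_labels.tiff"))
      write_label_tiff(labs$nucleolus, file.path(fd, "nucleolus_labels.tiff"))
    }
  }
  population <- dplyr::bind_rows(pops)
  truth <- dplyr::bind_rows(truths)
  qc <- dplyr::bind_rows(qcs)

  channels <- c("cyto_protein", "cyto_lipid", "nup_protein", "nul_protein")
  summary <- population
  summary[channels] <- lapply(summary[channels], function(x) 1000 * x) # mg/ml
  summary <- summarize_population(summary, channels, group = "condition")

  if (!is.null(out_dir)) {
    utils::write.csv(population[, setdiff(names(population), "nucleoli")],
                     file.path(out_dir, "population.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  }
  structure(
    list(population = population, summary = summary, qc = qc,
         truth = truth, config = config),
    class = "nori_run"
  )
}

#' @export
print.nori_run <- function(x, ...) {
  cat(sprintf(
    "<nori_run> preset '%s': %d cells segmented (%d simulated), seed %d\n",
    x$config$preset, nrow(x$population), x$config$n_cells, x$config$seed
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `nori_run`.
#' @param ... Unused.
#' @return `glance()` returns a one-row tibble of run-level recovery
#'   statistics (means in mg/ml).
#' @export
glance.nori_run <- function(x, ...) {
  p <- x$population
  tibble::tibble(
    n_cells = nrow(p),
    cyto_protein_mgml = 1000 * mean(p$cyto_protein, na.rm = TRUE),
    cyto_lipid_mgml = 1000 * mean(p$cyto_lipid, na.rm = TRUE),
    nup_protein_mgml = 1000 * mean(p$nup_protein, na.rm = TRUE),
    nul_protein_mgml = 1000 * mean(p$nul_protein, na.rm = TRUE),
    nul_cyto_ratio = mean(p$nul_protein, na.rm = TRUE) /
      mean(p$cyto_protein, na.rm = TRUE),
    mean_clipped_fraction = mean(x$qc$clipped_fraction)
  )
}
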