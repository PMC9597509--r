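#' Simulate matched fluorescence features for a population
#'
#' Emits the per-cell fluorescence feature table that accompanies the
#' imaging assays: total nuclear Hoechst (proportional to DNA content with
#' lognormal staining noise, so a cycling population is bimodal with the
#' G2-M mode at twice the G1 mode), SE protein-stain total (proportional
#' to true dry mass), OPP pulse label (proportional to SE through the
#' synthesis-rate constant `k_opp`, scaled by the preset's OPP/SE fold),
#' anti-RPS6 immunostain (proportional to SE, preset fold), EdU intensity
#' (high iff the cell is in S phase and labelled at the preset's rate),
#' SA-beta-galactosidase activity (linear in SE with Gaussian residual in
#' control; senescent cells scaled up by the preset), and YAP
#' nuclear/cytoplasmic intensities at the preset's localisation ratio.
#'
#' @param cells Population tibble from [sample_population()].
#' @param preset Preset name or [condition_preset()] list.
#' @param seed Integer seed.
#' @param k_opp,k_rps6 Control OPP/SE and anti-RPS6/SE ratio constants.
#' @param sab_slope Control SA-beta-gal per SE-unit slope.
#' @param sab_resid_sd SD of the control SA-beta-gal residual (intensity
#'   units).
#' @param hoechst_g1 Mean Hoechst total of a G1 cell (intensity units).
#' @param hoechst_sdlog Lognormal staining-noise sdlog for Hoechst.
#' @param se_per_pg SE intensity per pg dry mass.
#' @return Tibble: `cell_id`, `stage`, `senescent_truth`, `hoechst`, `se`,
#'   `opp`, `edu`, `edu_labelled_truth`, `rps6`, `sabgal`, `yap_nuc`,
#'   `yap_cyto`.
#' @examples
#' spec <- phantom_spec(n_cells = 5, seed = 3)
#' cells <- sample_population(spec)
#' sample_fluorescence_features(cells, "control", seed = 3)
#' @export
sample_fluorescence_features <- function(cells, preset = "control", seed = 1L,
                                         k_opp = 0.5, k_rps6 = 0.3,
                                         sab_slope = 0.02, sab_resid_sd = 0.8,
                                         hoechst_g1 = 1000,
                                         hoechst_sdlog = 0.06,
                                         se_per_pg = 1) {
  if (nrow(cells) == 0) stop("cells must be nonempty", call. = FALSE)
  if (is.character(preset)) preset <- condition_preset(preset)
  set.seed(as.integer(seed))
  n <- nrow(cells)

  hoechst <- hoechst_g1 * cells$dna_content *
    stats::rlnorm(n, 0, hoechst_sdlog)
  se <- se_per_pg * cells$dry_mass_pg * stats::rlnorm(n, 0, 0.05)
  opp <- k_opp * preset$opp_se * se * stats::rlnorm(n, 0, 0.15)
  rps6 <- k_rps6 * preset$rps6_se * se * stats::rlnorm(n, 0, 0.15)

  senescent <- stats::runif(n) < preset$senescent_frac
  sab_scale <- ifelse(senescent, preset$sabgal_scale, 1)
  sabgal <- sab_scale * sab_slope * se + stats::rnorm(n, 0, sab_resid_sd)

  labelled <- cells$stage == "S" & stats::runif(n) < preset$edu_rate
  edu <- ifelse(
    labelled,
    stats::rlnorm(n, log(1000), 0.3),
    stats::rlnorm(n, log(30), 0.25)
  )

  yap_cyto <- 100 * stats::rlnorm(n, 0, 0.10)
  yap_nuc <- yap_cyto * preset$yap_nc * stats::rlnorm(n, 0, 0.08)

  tibble::tibble(
    cell_id = cells$cell_id,
    stage = cells$stage,
    senescent_truth = senescent,
    hoechst = hoechst,
    se = se,
    opp = opp,
    edu = edu,
    edu_labelled_truth = labelled,
    rps6 = rps6,
    sabgal = sabgal,
    yap_nuc = yap_nuc,
    yap_cyto = yap_cyto
  )
}
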