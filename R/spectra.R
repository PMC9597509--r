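#' Reference band-response spectra
#'
#' Builds the 3x3 matrix `S` that maps component concentrations (protein,
#' lipid, water, in g/ml) to stimulated-Raman band intensities at the
#' 2853, 2935 and 3420 cm^-1 bands (CH2, CH3 and water stretch bands).
#' Rows are bands, columns are components; entries are instrument response
#' coefficients in arbitrary intensity units per (g/ml).
#'
#' The default coefficients are a declared instrument model chosen to have
#' the qualitative band assignments of the method (lipid dominates the CH2
#' band, protein the CH3 band, water the 3420 band) and a modest condition
#' number; reference spectra are calibration data and are instrument
#' specific, so any well-conditioned nonnegative matrix plays the same role.
#'
#' @param mat Optional 3x3 numeric matrix of response coefficients
#'   (rows = bands 2853/2935/3420, columns = protein/lipid/water). All
#'   entries must be nonnegative and the matrix invertible.
#' @param max_condition Maximum acceptable condition number (kappa, 2-norm);
#'   a near-singular matrix is rejected with an error.
#' @return An object of class `reference_spectra`: the matrix with band and
#'   component dimnames, with the condition number in attribute `"kappa"`.
#' @examples
#' S <- reference_spectra()
#' attr(S, "kappa")
#' @export
reference_spectra <- function(mat = NULL, max_condition = 1e6) {
  if (is.null(mat)) {
    mat <- matrix(
      c(
        0.30, 1.00, 0.05, # 2853 cm-1: CH2, lipid-dominated
        1.00, 0.60, 0.10, # 2935 cm-1: CH3, protein-dominated
        0.05, 0.05, 1.00  # 3420 cm-1: water OH stretch
      ),
      nrow = 3, byrow = TRUE
    )
  }
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || !identical(dim(mat), c(3L, 3L))) {
    stop("reference spectra must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("reference spectra entries must be finite and nonnegative", call. = FALSE)
  }
  kap <- kappa(mat, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop(
      sprintf(
        "reference spectra matrix is singular or ill-conditioned (kappa = %.3g, limit %.3g)",
        kap, max_condition
      ),
      call. = FALSE
    )
  }
  dimnames(mat) <- list(
    band = c("2853", "2935", "3420"),
    component = c("protein", "lipid", "water")
  )
  structure(mat, kappa = kap, class = c("reference_spectra", "matrix", "array"))
}

#' Partial specific volumes
#'
#' Partial specific volumes (ml/g) of the three components, used by the
#' volume-fraction closure that converts unmixed raw components into
#' absolute concentrations: at every foreground pixel
#' `v_p * c_p + v_l * c_l + v_w * c_w = 1`.
#'
#' Defaults are the textbook values for globular protein (0.735 ml/g),
#' phospholipid (1.087 ml/g) and water (1.0 ml/g).
#'
#' @param protein,lipid,water Partial specific volumes in ml/g; all > 0.
#' @return Named numeric vector of class `psv`.
#' @examples
#' partial_specific_volumes()
#' @export
partial_specific_volumes <- function(protein = 0.735, lipid = 1.087, water = 1.0) {
  v <- c(protein = protein, lipid = lipid, water = water)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("partial specific volumes must be finite and > 0", call. = FALSE)
  }
  structure(v, class = c("psv", "numeric"))
}

#' Read or write a reference-spectra CSV
#'
#' The on-disk format is a labelled 3x3 table: first column `band`
#' (2853, 2935, 3420), then columns `protein`, `lipid`, `water`.
#'
#' @param path File path.
#' @return `read_spectra()` returns a `reference_spectra` object.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("band", "protein", "lipid", "water")
  if (!all(need %in% names(df))) {
    stop("spectra CSV must have columns band, protein, lipid, water", call. = FALSE)
  }
  df <- df[order(df$band), ]
  reference_spectra(as.matrix(df[, c("protein", "lipid", "water")]))
}

#' @rdname read_spectra
#' @param spectra A `reference_spectra` object.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(band = c(2853, 2935, 3420), unclass(spectra))
  names(df) <- c("band", "protein", "lipid", "water")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
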