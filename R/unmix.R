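#' Spectral unmixing of SRS band images into absolute concentrations
#'
#' Implements the normalisation-based decomposition at the heart of the
#' method: at each pixel the three band intensities `I` are decomposed
#' against the reference spectra `S` by solving `S x = I` for the raw
#' protein, lipid and water components; negative raw components (noise
#' excursions) are clipped to zero and the clipped fraction recorded; and
#' the raw components are rescaled by the unique positive factor that
#' enforces the volume-fraction closure
#' `v_p c_p + v_l c_l + v_w c_w = 1`, yielding absolute concentrations in
#' g/ml. The closure makes the result invariant to any global intensity
#' gain: `unmix(a * I)` equals `unmix(I)` for any `a > 0`.
#'
#' Pixels with an all-zero intensity vector carry no normalisation
#' reference; they are returned with all densities zero and counted in the
#' `zero_pixels` attribute.
#'
#' @param srs An [srs_image()].
#' @param spectra A [reference_spectra()] matrix.
#' @param psv [partial_specific_volumes()] used for the closure.
#' @param max_condition Condition-number limit on `spectra`.
#' @return A [density_map()] with QC attributes `clipped_fraction` (fraction
#'   of pixels with at least one clipped raw component) and `zero_pixels`.
#'   Closure-normalised but *unclipped* planes are kept as `protein_raw`
#'   and `lipid_raw` (g/ml): their noise is symmetric (clipping skews
#'   near-zero concentrations upward and, through the closure, biases the
#'   other components), which is what threshold statistics and unbiased
#'   compartment-mean estimation want; the displayed concentration planes
#'   are always the clipped, closure-normalised ones.
#' @examples
#' S <- reference_spectra()
#' conc <- c(0.0745, 0.0291, 0) # g/ml protein, lipid
#' psv <- partial_specific_volumes()
#' conc[3] <- (1 - sum(psv[1:2] * conc[1:2])) / psv[3]
#' I <- as.numeric(S %*% conc)
#' img <- srs_image(lapply(I, function(v) matrix(v, 2, 2)))
#' m <- unmix_image(img, S, psv)
#' m$protein[1, 1] # recovers 0.0745
#' @export
unmix_image <- function(srs, spectra = reference_spectra(),
                        psv = partial_specific_volumes(),
                        max_condition = 1e6) {
  stopifnot(inherits(srs, "srs_image"))
  spectra <- reference_spectra(unclass(spectra), max_condition = max_condition)
  dm <- dim(srs$bands[[1]])
  n <- prod(dm)
  I <- cbind(
    as.numeric(srs$bands[[1]]),
    as.numeric(srs$bands[[2]]),
    as.numeric(srs$bands[[3]])
  )
  # raw components: solve S x = I pixel-wise, vectorised as I %*% t(inv(S))
  Sinv <- solve(unclass(spectra))
  X <- I %*% t(Sinv)
  X0 <- X # unclipped raw components, kept for segmentation statistics

  zero <- rowSums(abs(I)) == 0
  clipped <- rowSums(X < 0) > 0 & !zero
  X[X < 0] <- 0

  # volume-fraction closure: rescale each pixel so v . x = 1
  denom <- as.numeric(X %*% as.numeric(psv))
  scale <- ifelse(denom > 0, 1 / denom, 0)
  scale[zero] <- 0
  X <- X * scale

  out <- density_map(
    protein = matrix(X[, 1], dm[1], dm[2]),
    lipid = matrix(X[, 2], dm[1], dm[2]),
    water = matrix(X[, 3], dm[1], dm[2]),
    pixel_size = srs$pixel_size, z_spacing = srs$z_spacing
  )
  # closure-normalised but unclipped planes (g/ml): same absolute scale
  # and gain invariance as the main output, but with symmetric noise.
  # Segmentation statistics and compartment-mean estimation use these;
  # clipping before averaging would bias means of low concentrations
  # (e.g. nuclear lipid) upward and, through the closure, protein
  # densities downward.
  denom0 <- as.numeric(X0 %*% as.numeric(psv))
  scale0 <- ifelse(denom0 > 0.1, 1 / denom0, 0)
  scale0[zero] <- 0
  X0n <- X0 * scale0
  out$protein_raw <- matrix(X0n[, 1], dm[1], dm[2])
  out$lipid_raw <- matrix(X0n[, 2], dm[1], dm[2])
  attr(out, "clipped_fraction") <- mean(clipped)
  attr(out, "zero_pixels") <- sum(zero)
  out
}

#' Per-section measurement error from pixel averaging
#'
#' The per-pixel sensitivity sigma shrinks with the square root of the
#' number of pixels averaged, so the error of a compartment mean over
#' `n_pixels` pixels is `sigma_pixel / sqrt(n_pixels)`. With the protein
#' channel's 15 mg/ml per-pixel sensitivity and a mid-section cell area of
#' several hundred pixels this puts the per-cell protein density error
#' below 1.5 mg/ml (under 2% of a typical 80 mg/ml cell).
#'
#' @param sigma_pixel Per-pixel noise SD, g/ml; > 0.
#' @param n_pixels Number of pixels averaged; >= 1.
#' @return Standard error of the mean, g/ml.
#' @examples
#' estimate_section_error(0.015, 100) # 0.0015 g/ml
#' @export
estimate_section_error <- function(sigma_pixel, n_pixels) {
  if (!is.numeric(sigma_pixel) || any(sigma_pixel <= 0)) {
    stop("sigma_pixel must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_pixels) || any(n_pixels < 1)) {
    stop("n_pixels must be >= 1", call. = FALSE)
  }
  sigma_pixel / sqrt(n_pixels)
}
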