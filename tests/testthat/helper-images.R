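# Hand-built noise-free images for segmentation/quantification tests.

noise_free_map <- function(protein, lipid = NULL,
                           psv = partial_specific_volumes()) {
  if (is.null(lipid)) lipid <- matrix(0, nrow(protein), ncol(protein))
  water <- (1 - psv[["protein"]] * protein - psv[["lipid"]] * lipid) / psv[["water"]]
  density_map(protein, lipid, water)
}

disc_mask <- function(dims, cx, cy, r) {
  X <- matrix(seq_len(dims[1]) - cx, dims[1], dims[2])
  Y <- matrix(seq_len(dims[2]) - cy, dims[1], dims[2], byrow = TRUE)
  X^2 + Y^2 <= r^2
}
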