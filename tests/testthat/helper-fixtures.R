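# Shared fixtures, memoised per test run. Everything is generated in code
# at fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# One small noisy field pushed through the full imaging chain, plus its
# ground truth.
small_field <- function(seed = 11, n_cells = 6, shape = c(384, 384)) {
  memo(paste0("field_", seed, "_", n_cells), function() {
    spec <- phantom_spec(n_cells = n_cells, image_shape = shape, seed = seed)
    cells <- sample_population(spec)
    truth <- render_density_map(cells, spec)
    srs <- srs_forward(truth, seed = seed + 1000L)
    dmap <- unmix_image(srs)
    labs <- segment_compartments(dmap)
    tl <- render_labels(cells, spec)
    list(spec = spec, cells = cells, truth = truth, srs = srs,
         dmap = dmap, labs = labs, tl = tl)
  })
}

# Several small fields pooled (for per-cell segmentation statistics).
pooled_fields <- function(seeds = 301:305) {
  memo(paste0("pool_", paste(seeds, collapse = "_")), function() {
    lapply(seeds, function(s) small_field(seed = s))
  })
}

# The full-scale recovery run used by the acceptance tests.
hela_recovery_run <- function() {
  memo("hela600", function() {
    run_pipeline(nori_config(n_cells = 600, seed = 42))
  })
}

# Ground-truth cells pooled over fields (no imaging), arbitrary n.
make_cells <- function(n, seed,
                       stage_fractions = c(G1 = 0.70, S = 0.15, G2M = 0.15)) {
  per <- 20
  dplyr::bind_rows(lapply(seq_len(ceiling(n / per)), function(i) {
    sample_population(phantom_spec(
      n_cells = per, image_shape = c(640, 640),
      stage_fractions = stage_fractions, seed = seed + i
    ))
  }))[seq_len(n), ]
}

# A pure population sample (no imaging) pooled over several fields.
hela_truth_sample <- function(n_fields = 30, n_per_field = 20, seed0 = 500) {
  memo("truth_sample", function() {
    dplyr::bind_rows(lapply(seq_len(n_fields), function(i) {
      sample_population(phantom_spec(
        n_cells = n_per_field, image_shape = c(640, 640), seed = seed0 + i
      ))
    }))
  })
}
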