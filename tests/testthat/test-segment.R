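test_that("a uniform supra-threshold disc becomes exactly one label", {
  disc <- disc_mask(c(128, 128), 64, 64, 25)
  prot <- matrix(0, 128, 128)
  prot[disc] <- 0.07 # just above the 0.0666 g/ml threshold
  lab <- segment_cell_bodies(noise_free_map(prot))
  expect_identical(max(lab), 1L)
  expect_gt(sum(lab == 1 & disc) / sum(lab == 1 | disc), 0.98)
})

test_that("an all-zero map yields zero labels", {
  lab <- segment_cell_bodies(noise_free_map(matrix(0, 64, 64)))
  expect_true(all(lab == 0))
})

test_that("cell bodies reach Jaccard >= 0.9 per cell at default noise", {
  for (f in pooled_fields()) {
    mm <- match_labels(f$labs$cell, f$tl$cell)
    expect_identical(nrow(mm), nrow(f$cells))
    expect_true(all(mm$jaccard >= 0.9))
  }
})

test_that("a low-lipid core inside a cell is segmented as its nucleus", {
  disc <- disc_mask(c(128, 128), 64, 64, 30)
  core <- disc_mask(c(128, 128), 64, 64, 15)
  prot <- matrix(0, 128, 128); prot[disc] <- 0.075; prot[core] <- 0.082
  lip <- matrix(0, 128, 128); lip[disc] <- 0.03; lip[core] <- 0.005
  map <- noise_free_map(prot, lip)
  celllab <- segment_cell_bodies(map)
  nuclab <- segment_nuclei(map, celllab)
  expect_gt(sum(nuclab == 1 & core) / sum(nuclab == 1 | core), 0.95)
  expect_length(attr(nuclab, "no_nucleus"), 0)
})

test_that("a cell with uniformly high lipid has no nucleus and is flagged", {
  disc <- disc_mask(c(128, 128), 64, 64, 30)
  prot <- matrix(0, 128, 128); prot[disc] <- 0.075
  lip <- matrix(0, 128, 128); lip[disc] <- 0.03
  map <- noise_free_map(prot, lip)
  celllab <- segment_cell_bodies(map)
  nuclab <- segment_nuclei(map, celllab)
  expect_true(all(nuclab == 0))
  expect_identical(attr(nuclab, "no_nucleus"), 1L)
})

test_that("nuclei reach Jaccard >= 0.9 per cell at default noise", {
  for (f in pooled_fields()) {
    mm <- match_labels(f$labs$nucleus, f$tl$nucleus)
    expect_true(all(mm$jaccard >= 0.9))
  }
})

test_that("Otsu puts the threshold strictly between two well-separated levels", {
  x <- c(rep(0.08, 90), rep(0.11, 10))
  ot <- otsu_threshold(x)
  expect_gt(ot$threshold, 0.08)
  expect_lt(ot$threshold, 0.11)
  hi <- x > ot$threshold
  expect_identical(sum(hi), 10L)
})

test_that("a degenerate constant histogram yields no threshold", {
  ot <- otsu_threshold(rep(0.09, 50))
  expect_true(is.na(ot$threshold))
  expect_identical(ot$separation_z, 0)
})

test_that("Otsu equals brute-force between-class variance search", {
  brute_otsu <- function(x, nbins = 256) {
    rng <- range(x)
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
    v <- mids[idx] # binned values, as the histogram method sees them
    best <- -Inf; kbest <- NA
    for (k in seq_len(nbins - 1)) {
      lo <- v[idx <= k]; hi <- v[idx > k]
      if (length(lo) == 0 || length(hi) == 0) next
      w0 <- length(lo) / length(v)
      bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
      if (bcv > best + 1e-15) { # strict improvement: ties keep lower k
        best <- bcv; kbest <- k
      }
    }
    breaks[kbest + 1]
  }
  set.seed(17)
  for (i in 1:20) {
    x <- c(rnorm(300, 0.082, 0.004), rnorm(sample(10:150, 1), 0.11, 0.004))
    expect_equal(otsu_threshold(x)$threshold, brute_otsu(x), tolerance = 1e-12)
  }
})

test_that("Otsu attains at least the EBImage reference's class separation", {
  # near-flat BCV plateaus make exact threshold agreement meaningless, so
  # compare the objective value the two thresholds achieve on the data
  bcv_at <- function(x, t) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  set.seed(23)
  for (i in 1:5) {
    x <- c(rnorm(2000, 0.3, 0.05), rnorm(500, 0.7, 0.03 + 0.01 * i))
    x <- pmin(pmax(x, 0), 1)
    ours <- otsu_threshold(x, nbins = 256)$threshold
    ref <- EBImage::otsu(matrix(x, 50), range = range(x), levels = 256)
    expect_gte(bcv_at(x, ours), bcv_at(x, ref) * (1 - 1e-3))
    # both land in the valley between the two classes
    expect_gt(ours, 0.3); expect_lt(ours, 0.7)
    expect_gt(ref, 0.3); expect_lt(ref, 0.7)
  }
})

test_that("nucleoli are detected with high contrast and flagged without", {
  # 90% of nucleus pixels at nucleoplasmic density, 10% nucleolar
  disc <- disc_mask(c(128, 128), 64, 64, 30)
  core <- disc_mask(c(128, 128), 64, 64, 20)
  nul <- disc_mask(c(128, 128), 60, 60, 6)
  prot <- matrix(0, 128, 128)
  prot[disc] <- 0.075; prot[core] <- 0.0819; prot[nul] <- 0.110
  lip <- matrix(0, 128, 128); lip[disc] <- 0.03; lip[core & !nul] <- 0.005
  lip[nul] <- 0.005
  map <- noise_free_map(prot, lip)
  labs <- segment_compartments(map)
  expect_gt(sum(labs$nucleolus == 1 & nul) / sum(labs$nucleolus == 1 | nul), 0.9)
  # uniform nucleus: no nucleolus
  prot[nul] <- 0.0819
  labs2 <- segment_compartments(noise_free_map(prot, lip))
  expect_true(all(labs2$nucleolus == 0))
  expect_identical(labs2$no_nucleolus, 1L)
})

test_that("segmentation is idempotent and enforces nesting", {
  f <- small_field()
  labs2 <- segment_compartments(f$dmap)
  expect_identical(f$labs$cell, labs2$cell)
  expect_identical(f$labs$nucleus, labs2$nucleus)
  expect_identical(f$labs$nucleolus, labs2$nucleolus)
  nz <- f$labs$nucleolus > 0
  expect_true(all(f$labs$nucleus[nz] == f$labs$nucleolus[nz]))
  nz <- f$labs$nucleus > 0
  expect_true(all(f$labs$cell[nz] == f$labs$nucleus[nz]))
  bad <- matrix(0L, 4, 4); bad[2, 2] <- 1L
  expect_error(compartment_labels(matrix(0L, 4, 4), bad, matrix(0L, 4, 4)),
               "nested")
})

test_that("raising the protein threshold never grows a cell mask", {
  f <- small_field()
  p_lo <- segmentation_params(refine_boundaries = FALSE)
  p_hi <- segmentation_params(protein_threshold = 0.072,
                              refine_boundaries = FALSE)
  lo <- segment_cell_bodies(f$dmap, p_lo) > 0
  hi <- segment_cell_bodies(f$dmap, p_hi) > 0
  expect_true(all(lo[hi])) # hi-threshold foreground is a subset
})

test_that("collapsed nucleolar contrast suppresses nucleolus calls", {
  det_rate <- function(preset) {
    hits <- 0; total <- 0
    for (s in 1:3) {
      spec <- phantom_spec(n_cells = 6, image_shape = c(384, 384),
                           seed = 700 + s)
      cells <- sample_population(spec, preset)
      dmap <- unmix_image(srs_forward(render_density_map(cells, spec),
                                      seed = 800 + s))
      labs <- segment_compartments(dmap)
      total <- total + length(unique(labs$nucleus[labs$nucleus > 0]))
      hits <- hits + length(unique(labs$nucleolus[labs$nucleolus > 0]))
    }
    hits / total
  }
  expect_lt(det_rate("hyperosmotic_400"), 0.5)
  expect_gt(det_rate("control"), 0.8)
})

test_that("invalid segmentation parameters are rejected", {
  expect_error(segmentation_params(protein_threshold = -1), "> 0")
  expect_error(segmentation_params(nuclear_lipid_threshold = 0), "> 0")
  expect_error(segmentation_params(min_cell_area = -5), ">= 0")
})
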