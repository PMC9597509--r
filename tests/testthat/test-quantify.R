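test_that("a constant cytoplasm measures exactly its density", {
  spec <- phantom_spec(n_cells = 1, image_shape = c(160, 160), seed = 33)
  cells <- sample_population(spec)
  truth <- render_density_map(cells, spec)
  tl <- render_labels(cells, spec)
  labs <- compartment_labels(tl$cell, tl$nucleus, tl$nucleolus)
  rec <- compartment_densities(truth, labs)
  expect_equal(rec$cyto_protein, cells$cyto_protein[1], tolerance = 1e-12)
  expect_equal(rec$cyto_lipid, cells$cyto_lipid[1], tolerance = 1e-12)
  expect_equal(rec$nup_protein, cells$nup_protein[1], tolerance = 1e-12)
  expect_equal(rec$nul_protein, cells$nul_protein[1], tolerance = 1e-12)
})

test_that("per-cell section noise shrinks with compartment area", {
  # repeated noisy renders of the same cell: SD of the measured cytoplasm
  # mean approaches sigma / sqrt(n_pixels)
  spec <- phantom_spec(n_cells = 1, image_shape = c(160, 160), seed = 33)
  cells <- sample_population(spec)
  truth <- render_density_map(cells, spec)
  tl <- render_labels(cells, spec)
  labs <- compartment_labels(tl$cell, tl$nucleus, tl$nucleolus)
  vals <- npix <- numeric(40)
  for (i in 1:40) {
    dmap <- unmix_image(srs_forward(truth, seed = 4000 + i))
    rec <- compartment_densities(dmap, labs)
    vals[i] <- rec$cyto_protein
    npix[i] <- rec$cyto_npix
  }
  predicted <- estimate_section_error(0.015, mean(npix))
  expect_lt(abs(sd(vals) / predicted - 1), 0.5) # 40 replicates: coarse check
  expect_lt(abs(mean(vals) - cells$cyto_protein[1]), 4 * predicted / sqrt(40))
})

test_that("z-stack integration converts units exactly", {
  lab3 <- array(0L, c(3, 3, 1)); lab3[2, 2, 1] <- 1L
  one <- density_map(matrix(1, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3),
                     pixel_size = 1, z_spacing = 1)
  rec <- integrate_zstack(list(one), lab3)
  expect_equal(rec$protein_mass_pg, 1) # 1 g/ml over 1 um^3 = 1 pg
  expect_equal(rec$volume_um3, 1)

  lab3 <- array(1L, c(10, 10, 10))
  maps <- replicate(10, density_map(
    matrix(0.1, 10, 10), matrix(0, 10, 10), matrix(0, 10, 10),
    pixel_size = 1, z_spacing = 1
  ), simplify = FALSE)
  rec <- integrate_zstack(maps, lab3)
  expect_equal(rec$volume_um3, 1000)
  expect_equal(rec$protein_mass_pg, 100)
  expect_equal(rec$mean_protein, 0.1)
  expect_error(integrate_zstack(maps, lab3, ids = c(1, 7)), "no voxels")
})

test_that("mass is conserved between per-cell sums and the whole stack", {
  spec <- phantom_spec(n_cells = 3, image_shape = c(192, 192), seed = 4)
  cells <- sample_population(spec)
  st <- render_density_stack(cells, spec)
  rec <- integrate_zstack(st$maps, st$labels3d$cell)
  voxvol <- spec$pixel_size^2 * spec$z_spacing
  total <- sum(vapply(st$maps, function(m) sum(m$protein), numeric(1))) * voxvol
  background <- 0 # protein is zero outside cells in the rendered truth
  expect_equal(sum(rec$protein_mass_pg) + background, total, tolerance = 1e-9)
})

test_that("mid-section and whole-cell densities agree for z-uniform compartments", {
  spec <- phantom_spec(n_cells = 3, image_shape = c(192, 192), seed = 4)
  cells <- sample_population(spec)
  mid <- render_density_map(cells, spec, z = 0)
  tl <- render_labels(cells, spec)
  labs <- compartment_labels(tl$cell, tl$nucleus, tl$nucleolus)
  rec2d <- compartment_densities(mid, labs)
  st <- render_density_stack(cells, spec)
  voxvol <- spec$pixel_size^2 * spec$z_spacing
  for (i in seq_len(3)) {
    cyto3d <- st$labels3d$cell == i & st$labels3d$nucleus == 0
    prot <- vapply(seq_along(st$maps),
                   function(k) sum(st$maps[[k]]$protein[cyto3d[, , k]]),
                   numeric(1))
    mean3d <- sum(prot) / sum(cyto3d)
    expect_equal(rec2d$cyto_protein[rec2d$cell_id == i], mean3d,
                 tolerance = 1e-12)
  }
})

test_that("NCC registration recovers known integer shifts", {
  set.seed(55)
  fixed <- matrix(rnorm(60 * 60), 60, 60)
  res <- register_ncc(fixed, fixed, max_shift = 4)
  expect_identical(res$shift, c(0L, 0L))
  expect_equal(res$score, 1)

  moving <- matrix(0, 60, 60)
  moving[6:60, 4:60] <- fixed[1:55, 1:57] # content displaced by (5, 3)
  res <- register_ncc(moving, fixed, max_shift = 8)
  expect_identical(res$shift, c(5L, 3L))
  expect_gt(res$score, 0.99)
  expect_equal(res$registered[1:55, 1:57], fixed[1:55, 1:57])
})

test_that("NCC is invariant to affine intensity rescaling", {
  set.seed(56)
  fixed <- matrix(rnorm(50 * 50), 50, 50)
  moving <- matrix(0, 50, 50)
  moving[3:50, 1:48] <- fixed[1:48, 3:50] # shift (2, -2)
  a <- register_ncc(moving, fixed, max_shift = 5)
  b <- register_ncc(7.7 * moving + 100, fixed, max_shift = 5)
  c_ <- register_ncc(moving, 0.5 * fixed + 5, max_shift = 5)
  expect_identical(a$shift, b$shift)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  expect_identical(c_$shift, a$shift)
  expect_equal(c_$score, a$score, tolerance = 1e-12)
  expect_error(register_ncc(matrix(1, 50, 50), fixed), "flat")
})

test_that("nc_ratio behaves on uniform and structured intensities", {
  img <- matrix(1, 20, 20)
  nuc <- disc_mask(c(20, 20), 10, 10, 4)
  cyto <- disc_mask(c(20, 20), 10, 10, 8) & !nuc
  expect_equal(nc_ratio(img, nuc, cyto), 1)
  img[nuc] <- 2
  expect_equal(nc_ratio(img, nuc, cyto), 2)
  expect_true(is.na(nc_ratio(img, matrix(FALSE, 20, 20), cyto)))
})

test_that("fluorescence features join records by cell id", {
  rec <- tibble::tibble(cell_id = 1:3, cyto_protein = c(0.07, 0.08, 0.075))
  ft <- tibble::tibble(cell_id = c(2, 1), se = c(10, 20))
  out <- link_fluorescence(rec, ft)
  expect_equal(out$se, c(20, 10, NA))
})

test_that("density and volume stay independent through the generator", {
  cells <- hela_truth_sample()
  r <- cor(cells$cyto_protein, cells$volume_um3)
  expect_lt(abs(r), 0.1)
})
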