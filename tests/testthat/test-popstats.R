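vector_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  mean + sd * (x - mean(x)) / sd(x) # exact sample moments
}

test_that("summaries report mean, SD and CV per group", {
  x <- vector_with_moments(200, 74.5, 5.2)
  df <- tibble::tibble(condition = "control", v = x)
  s <- summarize_population(df, "v")
  expect_equal(s$mean, 74.5)
  expect_equal(s$sd, 5.2)
  expect_equal(round(s$cv, 2), 0.07)
  # constant vector: zero CV; scaling: CV unchanged
  s0 <- summarize_population(tibble::tibble(condition = "c", v = rep(3, 10)), "v")
  expect_equal(s0$cv, 0)
  s10 <- summarize_population(dplyr::mutate(df, v = 10 * v), "v")
  expect_equal(s10$cv, s$cv)
  # n < 2: flagged, missing SD
  s1 <- summarize_population(tibble::tibble(condition = "c", v = 1), "v")
  expect_true(is.na(s1$sd))
  expect_identical(s1$flag, "n<2")
})

test_that("Pearson correlation handles exact and degenerate input", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  expect_error(pearson_cor(1:2, 1:2), "3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "variance")
  set.seed(2)
  null_r <- pearson_cor(rnorm(1000), rnorm(1000))
  expect_lt(abs(null_r$r), 0.1)
})

test_that("mass-volume correlation follows the CV closed form", {
  # mass = density x volume with independent density (CV 7%) and volume
  # (CV 28%): R = CV_V / sqrt(CV_V^2 + CV_rho^2) = 0.970
  set.seed(3)
  n <- 20000
  vol <- rlnorm(n, log(2000), sqrt(log(1 + 0.28^2)))
  rho <- rlnorm(n, log(0.08), sqrt(log(1 + 0.07^2)))
  mass <- rho * vol
  closed_form <- 0.28 / sqrt(0.28^2 + 0.07^2)
  expect_lt(abs(pearson_cor(mass, vol)$r - closed_form), 0.01)
})

test_that("significance codes map the conventional thresholds exactly", {
  # strict inequalities: a p-value exactly at a cut stays in the weaker class
  expect_identical(
    significance_code(c(0.2, 0.05, 0.03, 0.01, 0.009, 0.0005, 0.0001, 0.00005)),
    c("N.S.", "N.S.", "*", "*", "**", "***", "***", "****")
  )
})

test_that("one-way ANOVA handles identical, separated and degenerate groups", {
  df <- data.frame(g = rep(c("a", "b"), each = 10), y = rep(1:10, 2))
  res <- anova_groups(df, "y", "g") # identical groups
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_identical(res$code, "N.S.")

  set.seed(4)
  df2 <- data.frame(
    g = rep(c("a", "b"), each = 50),
    y = c(rnorm(50, 0, 1), rnorm(50, 3, 1)) # 3 SD effect
  )
  res2 <- anova_groups(df2, "y", "g")
  expect_lt(res2$p, 0.0001)
  expect_identical(res2$code, "****")

  expect_error(anova_groups(data.frame(g = "a", y = 1:5), "y", "g"), "2 groups")
  expect_error(
    anova_groups(data.frame(g = c("a", "a", "b"), y = 1:3), "y", "g"),
    "n >= 2"
  )
  expect_s3_class(tidy(res2), "tbl_df")
})

test_that("ANOVA p agrees with a permutation oracle at moderate effect", {
  set.seed(5)
  df <- data.frame(
    g = rep(c("a", "b"), each = 25),
    y = c(rnorm(25, 0, 1), rnorm(25, 0.55, 1))
  )
  p_aov <- anova_groups(df, "y", "g")$p
  obs_f <- summary(stats::aov(y ~ g, df))[[1]]$`F value`[1]
  perm <- replicate(4000, {
    yp <- sample(df$y)
    summary(stats::aov(yp ~ df$g))[[1]]$`F value`[1]
  })
  p_perm <- (1 + sum(perm >= obs_f)) / (1 + length(perm))
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_aov - p_perm), 4 * mc_se + 0.005)
})

test_that("fold changes are medians relative to the control median", {
  fc <- fold_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(attr(fc, "median_fold"), 1)
  a <- fold_change(c(2, 4, 8), c(1, 3, 5))
  b <- fold_change(10 * c(2, 4, 8), 10 * c(1, 3, 5))
  expect_equal(a$fold, b$fold)
  expect_error(fold_change(1:3, c(-1, 0, 1)), "median")
  expect_error(fold_change(1:3, numeric(0)), "empty")
})

test_that("an ouabain population recovers the 0.6 density fold", {
  spec <- phantom_spec(n_cells = 40, image_shape = c(900, 900), seed = 71)
  ctrl <- sample_population(spec, "control")
  spec2 <- phantom_spec(n_cells = 40, image_shape = c(900, 900), seed = 72)
  treat <- sample_population(spec2, "ouabain")
  fc <- fold_change(treat$cyto_protein, ctrl$cyto_protein)
  expect_lt(abs(attr(fc, "median_fold") - 0.6), 0.05)
})

test_that("synthesis rate k is the median OPP/SE ratio and is robust", {
  sr <- synthesis_rate(c(2, 4, 6), c(1, 2, 3))
  expect_equal(sr$k, 2)
  sr2 <- synthesis_rate(c(2, 4, 6, 1e6), c(1, 2, 3, 1))
  expect_equal(sr2$k, 2) # one extreme outlier moves the median only slightly
  sr3 <- synthesis_rate(c(2, 4), c(1, 0))
  expect_identical(sr3$ratios$excluded, c(FALSE, TRUE))
  expect_equal(sr3$k, 2)
})

test_that("variability decomposition recovers the hierarchical closed form", {
  df0 <- data.frame(g = rep(letters[1:4], each = 5), y = rep(rep(1:5, 4)))
  expect_equal(variability_decomposition(df0, "y", "g")$between_sd, 0)
  expect_error(variability_decomposition(df0[1:5, ], "y", "g"), "2 groups")

  set.seed(6)
  sigma_day <- 1.7; sigma_cell <- 5.2; n_per_day <- 400; n_days <- 300
  day_mean <- rnorm(n_days, 74.5, sigma_day)
  df <- data.frame(
    day = rep(seq_len(n_days), each = n_per_day),
    y = rnorm(n_days * n_per_day, rep(day_mean, each = n_per_day), sigma_cell)
  )
  vd <- variability_decomposition(df, "y", "day")
  expected_between <- sqrt(sigma_day^2 + sigma_cell^2 / n_per_day)
  expect_lt(abs(vd$between_sd - expected_between), 0.15 * expected_between)
  expect_lt(abs(vd$cell_sd - sigma_cell), 0.05 * sigma_cell)
})

test_that("replicates from one distribution show SEM-level between-group SD", {
  # many same-day replicates of n = 430 cells from a single distribution:
  # the SD of replicate means approaches sigma_cell / sqrt(430)
  set.seed(7)
  n_rep <- 60; n <- 430; sigma <- 5.2
  df <- data.frame(
    rep = rep(seq_len(n_rep), each = n),
    y = rnorm(n_rep * n, 74.5, sigma)
  )
  vd <- variability_decomposition(df, "y", "rep")
  expect_lt(abs(vd$between_sd - sigma / sqrt(n)), 0.25 * sigma / sqrt(n))
})

test_that("Hoechst normalisation finds the G1 peak and gates stages", {
  set.seed(8)
  h <- c(rnorm(700, 1000, 40), rnorm(300, 2000, 80))
  g <- hoechst_gates(h)
  expect_lt(abs(attr(g, "g1_peak") - 1000), 30)
  modes <- sort(c(1, 2))
  expect_lt(abs(median(g$hoechst_norm[h < 1400]) - 1), 0.05)
  expect_lt(abs(median(g$hoechst_norm[h > 1600]) - 2), 0.1)
  # scaling invariance of the calls
  g2 <- hoechst_gates(7.3 * h)
  expect_identical(g$stage, g2$stage)
  expect_error(hoechst_gates(c(1, 2)), "few")
  expect_error(hoechst_gates(h, g1_upper = 0.9), "gates")
})

test_that("stage calls recover generated stages with >= 90% accuracy", {
  cells <- make_cells(2000, seed = 160)
  ft <- sample_fluorescence_features(cells, "control", seed = 9)
  g <- hoechst_gates(ft$hoechst)
  acc <- mean(as.character(g$stage) == cells$stage)
  expect_gte(acc, 0.90)
})

test_that("the EdU gate sits 3 robust SDs above the negative mode", {
  set.seed(10)
  neg <- rnorm(1000, log(30), 0.25)
  g0 <- edu_gate(NULL, neg)
  expect_lt(attr(g0, "fraction"), 0.01) # all-background: ~0%
  mixed <- c(rnorm(700, log(30), 0.25), rnorm(300, log(1000), 0.3))
  g1 <- edu_gate(NULL, mixed)
  expect_lt(abs(attr(g1, "fraction") - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("an arrested population has far fewer EdU-positive cells", {
  cells <- make_cells(800, seed = 180)
  ctrl <- sample_fluorescence_features(cells, "control", seed = 11)
  doxo <- sample_fluorescence_features(cells, "senescence", seed = 11)
  f_ctrl <- attr(edu_gate(NULL, log(ctrl$edu)), "fraction")
  f_doxo <- attr(edu_gate(NULL, log(doxo$edu), control_log_edu = log(ctrl$edu)),
                 "fraction")
  expect_gt(f_ctrl, 0.10)
  expect_lt(f_doxo, f_ctrl / 5)
})

test_that("senescence threshold y = ax + 3b behaves in the b = 0 limit", {
  se <- seq(10, 100, length.out = 20)
  sab <- 0.5 * se
  m <- senescence_fit(sab, se)
  expect_equal(m$a, 0.5)
  expect_equal(m$b, 0)
  res <- senescence_call(c(0.5 * 50, 0.5 * 50 + 1e-9), c(50, 50), model = m)
  expect_identical(res$calls$senescent, c(FALSE, TRUE))
  expect_error(senescence_fit(sab[1:5], se[1:5]), "10")
  expect_error(senescence_call(sab, -se, model = m), "positive")
})

test_that("control false-positive rate matches the 3-sigma tail", {
  set.seed(12)
  n <- 20000
  se <- runif(n, 100, 500)
  sab <- 0.02 * se + rnorm(n, 0, 0.8)
  res <- senescence_call(sab, se, control_sabgal = sab, control_se = se)
  expect_gt(res$fraction, 0.0004)
  expect_lt(res$fraction, 0.0035) # ~0.13% for Gaussian residuals
  expect_s3_class(tidy(res$model), "tbl_df")
  expect_identical(glance(res$model)$n_control, as.integer(n))
})

test_that("a scaled senescent population is called at the generated fraction", {
  cells <- make_cells(800, seed = 200)
  ctrl <- sample_fluorescence_features(cells, "control", seed = 13)
  doxo <- sample_fluorescence_features(cells, "senescence", seed = 13)
  res <- senescence_call(doxo$sabgal, doxo$se,
                         control_sabgal = ctrl$sabgal, control_se = ctrl$se)
  expect_lt(abs(res$fraction - mean(doxo$senescent_truth)), 0.03)
})
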