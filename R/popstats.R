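#' Population summary statistics
#'
#' Per-group, per-channel sample mean, SD (n - 1 denominator) and
#' coefficient of variation (CV = SD / mean). Groups with fewer than two
#' observations get a missing SD and a flag.
#'
#' @param pop Data frame of per-cell records.
#' @param channels Character vector of value columns to summarise.
#' @param group Grouping column name (default `"condition"`; use `NULL`
#'   for a single group).
#' @return Tibble: `group`, `channel`, `n`, `mean`, `sd`, `cv`, `flag`.
#' @examples
#' df <- tibble::tibble(condition = "control", x = rnorm(50, 74.5, 5.2))
#' summarize_population(df, "x")
#' @export
summarize_population <- function(pop, channels, group = "condition") {
  pop <- tibble::as_tibble(pop)
  if (is.null(group)) {
    pop$.group <- "all"
    group <- ".group"
  }
  long <- tidyr::pivot_longer(
    pop[, c(group, channels)],
    cols = dplyr::all_of(channels),
    names_to = "channel", values_to = "value"
  )
  out <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(group = .data[[group]], .data$channel) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2) stats::sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv = .data$sd / .data$mean,
      flag = ifelse(.data$n < 2, "n<2", "")
    )
  out
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return One-row tibble: `r`, `p`, `n`.
#' @examples
#' pearson_cor(1:10, (1:10) + rnorm(10, 0, 0.1))
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Significance code for a p-value
#'
#' Maps a p-value to the conventional code set: `N.S.` for p > 0.05,
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001 and `****`
#' for p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @examples
#' significance_code(c(0.2, 0.03, 0.0005))
#' @export
significance_code <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.0001) "****"
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "N.S."
  }, character(1))
}

#' One-way ANOVA with significance code
#'
#' Classic equal-variance one-way ANOVA across groups (no multiple-testing
#' correction), with the p-value mapped to a significance code by
#' [significance_code()]. Identical groups give F = 0, p = 1, `N.S.`.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @return One-row tibble of class `nori_anova`: `f`, `p`, `code`,
#'   `df_between`, `df_within`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 20), y = rnorm(40))
#' anova_groups(df, "y", "g")
#' @export
anova_groups <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (stats::sd(y) == 0) {
    # all observations identical: no variance anywhere
    out <- tibble::tibble(
      f = 0, p = 1, code = "N.S.",
      df_between = nlevels(g) - 1L, df_within = length(y) - nlevels(g)
    )
    class(out) <- c("nori_anova", class(out))
    return(out)
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) { # zero within-group variance with identical groups
    f <- 0; p <- 1
  }
  out <- tibble::tibble(
    f = f, p = p, code = significance_code(p),
    df_between = tab$Df[1], df_within = tab$Df[2]
  )
  class(out) <- c("nori_anova", class(out))
  out
}

#' Per-cell fold change to the control median
#'
#' Divides each treated value by the median of the control values; the
#' summary fold change of a condition is the median of the per-cell
#' folds. Scale-invariant: multiplying both groups by a constant leaves
#' folds unchanged.
#'
#' @param treated,control Numeric vectors; the control median must be
#'   positive.
#' @return Tibble with column `fold`; the median fold is in attribute
#'   `median_fold`.
#' @examples
#' fc <- fold_change(c(2, 4), c(1, 2, 3))
#' attr(fc, "median_fold")
#' @export
fold_change <- function(treated, control) {
  control <- control[is.finite(control)]
  if (length(control) == 0) stop("control is empty", call. = FALSE)
  m <- stats::median(control)
  if (!is.finite(m) || m <= 0) {
    stop("control median must be > 0", call. = FALSE)
  }
  out <- tibble::tibble(fold = treated / m)
  attr(out, "median_fold") <- stats::median(out$fold, na.rm = TRUE)
  out
}

#' Protein-synthesis rate statistic
#'
#' Per-cell ratio of the OPP pulse label to the SE protein stain, and the
#' population constant `k` defined as the median OPP/SE ratio (the slope
#' of the line `y = k x` through the scatter). Cells with non-positive SE
#' are excluded and flagged.
#'
#' @param opp,se Numeric vectors of per-cell OPP and SE totals.
#' @return List: `k` (median ratio), `ratios` tibble
#'   (`opp`, `se`, `ratio`, `excluded`).
#' @examples
#' synthesis_rate(c(2, 4, 6), c(1, 2, 3))$k
#' @export
synthesis_rate <- function(opp, se) {
  stopifnot(length(opp) == length(se))
  excluded <- !is.finite(se) | se <= 0 | !is.finite(opp)
  ratio <- ifelse(excluded, NA_real_, opp / se)
  list(
    k = stats::median(ratio[!excluded]),
    ratios = tibble::tibble(opp = opp, se = se, ratio = ratio,
                            excluded = excluded)
  )
}

#' Decompose population variability into cell-level and group-level parts
#'
#' Given per-cell values grouped by day or replicate, reports the pooled
#' within-group (cell-to-cell) SD and the SD of the group means
#' (day-to-day or sample-to-sample variability). For groups of size `n`
#' drawn from a common distribution the SD of group means approaches
#' `sd_cell / sqrt(n)`; a real between-group component adds in
#' quadrature.
#'
#' @param data Data frame.
#' @param value,group Column names (strings).
#' @return One-row tibble: `n_groups`, `cell_sd` (pooled within-group
#'   SD), `between_sd` (SD of group means), `grand_mean`.
#' @export
variability_decomposition <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- tapply(y, g, length)
  vars <- tapply(y, g, stats::var)
  means <- tapply(y, g, mean)
  pooled <- sqrt(sum((ns - 1) * vars) / (sum(ns) - nlevels(g)))
  tibble::tibble(
    n_groups = nlevels(g),
    cell_sd = pooled,
    between_sd = stats::sd(means),
    grand_mean = mean(y)
  )
}
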