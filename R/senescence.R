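#' Fit the control SA-beta-gal vs dry-mass scaling model
#'
#' Senescence-associated beta-galactosidase activity scales with cell dry
#' mass (SE stain), so calling senescence requires correcting for mass:
#' the control population is fit by least squares through the origin,
#' `sabgal = a * se`, and `b` is the root-mean-square error of that fit.
#' A cell is called senescent when its activity exceeds the line by three
#' RMSE: `sabgal > a * se + 3 b`.
#'
#' @param control_sabgal,control_se Control-population activity and SE
#'   totals; `control_se` must be positive, with n >= 10.
#' @return Object of class `senescence_model`: `a` (slope), `b` (RMSE),
#'   `n_control`.
#' @export
senescence_fit <- function(control_sabgal, control_se) {
  ok <- is.finite(control_sabgal) & is.finite(control_se)
  x <- control_se[ok]; y <- control_sabgal[ok]
  if (length(x) < 10) stop("need at least 10 control cells", call. = FALSE)
  if (any(x <= 0)) stop("SE (mass) values must be positive", call. = FALSE)
  a <- sum(x * y) / sum(x^2) # least squares through the origin
  b <- sqrt(mean((y - a * x)^2))
  structure(list(a = a, b = b, n_control = length(x)),
            class = "senescence_model")
}

#' @export
print.senescence_model <- function(x, ...) {
  cat(sprintf(
    "<senescence_model> threshold y > %.4g x + 3 * %.4g (n_control = %d)\n",
    x$a, x$b, x$n_control
  ))
  invisible(x)
}

#' Call senescent cells against a control scaling line
#'
#' Applies the `y > a x + 3 b` rule of a fitted [senescence_fit()] model
#' (or fits one from supplied control vectors) to a population.
#'
#' @param sabgal,se Activity and SE totals of the cells to call; `se`
#'   must be positive.
#' @param model A `senescence_model`, or `NULL` to fit from
#'   `control_sabgal` / `control_se`.
#' @param control_sabgal,control_se Control vectors used when `model` is
#'   `NULL`.
#' @return List: `model`, `calls` tibble (`sabgal`, `se`, `senescent`),
#'   `fraction` senescent.
#' @examples
#' se_c <- runif(200, 100, 400)
#' sab_c <- 0.02 * se_c + rnorm(200, 0, 0.5)
#' res <- senescence_call(sab_c * 5, se_c, control_sabgal = sab_c,
#'                        control_se = se_c)
#' res$fraction
#' @export
senescence_call <- function(sabgal, se, model = NULL,
                            control_sabgal = NULL, control_se = NULL) {
  if (is.null(model)) {
    model <- senescence_fit(control_sabgal, control_se)
  }
  stopifnot(inherits(model, "senescence_model"))
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("SE (mass) values must be positive", call. = FALSE)
  }
  senescent <- sabgal > model$a * se + 3 * model$b
  list(
    model = model,
    calls = tibble::tibble(sabgal = sabgal, se = se, senescent = senescent),
    fraction = mean(senescent)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a senescence model
#'
#' @param x A `senescence_model`.
#' @param ... Unused.
#' @return Tibble with one row per model quantity.
#' @export
tidy.senescence_model <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "rmse"),
    estimate = c(x$a, x$b)
  )
}

#' @rdname tidy.senescence_model
#' @export
glance.senescence_model <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n_control = x$n_control)
}

#' Tidy a one-way ANOVA result
#'
#' @param x A `nori_anova` row from [anova_groups()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.nori_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
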