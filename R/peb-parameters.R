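#' PEB parameter set
#'
#' Container for the three quantities that drive every PEB threshold: the
#' population mean and SD on a stated working scale, and the intraclass
#' correlation `B1 = sigma_G^2 / (sigma_G^2 + sigma_I^2)`, the regression
#' slope of one result on the previous.  The implied variance split is
#' `sigma_G^2 = b1 * sigma_pop^2` (between subjects) and
#' `sigma_I^2 = (1 - b1) * sigma_pop^2` (within subject, analytical noise
#' included).
#'
#' `b1` estimates that fall slightly outside `[0, 1]` (as can happen with a
#' noisy regression slope on a small sample) are clipped to the boundary
#' with a warning; values further than 0.1 outside are rejected.
#'
#' @param mu_pop population mean on the working scale.
#' @param sigma_pop population SD on the working scale; must be positive.
#' @param b1 intraclass correlation in `[0, 1]`.
#' @param scale working scale: `"log"` (natural log) or `"boxcox"`.
#' @param lambda Box-Cox exponent; required when `scale = "boxcox"`.
#' @param analyte,subgroup free-text labels carried through to output.
#' @return an object of class `peb_parameters`.
#' @examples
#' p <- peb_parameters(3.181, 0.241, 0.66, scale = "boxcox", lambda = 0.89,
#'                     analyte = "albumin")
#' coef(p)
#' @seealso [bv_to_peb()], [fit_peb_lis()], [predict.peb_parameters()]
#' @export
peb_parameters <- function(mu_pop, sigma_pop, b1, scale = c("log", "boxcox"),
                           lambda = NULL, analyte = "", subgroup = "") {
  scale <- match.arg(scale)
  stopifnot(is.numeric(mu_pop), length(mu_pop) == 1L, is.finite(mu_pop),
            is.numeric(sigma_pop), length(sigma_pop) == 1L,
            is.numeric(b1), length(b1) == 1L, is.finite(b1))
  if (sigma_pop <= 0) stop("`sigma_pop` must be positive", call. = FALSE)
  if (b1 < 0 || b1 > 1) {
    if (b1 >= -0.1 && b1 <= 1.1) {
      warning("b1 = ", format(b1), " outside [0, 1]; clipped to the boundary",
              call. = FALSE)
      b1 <- min(max(b1, 0), 1)
    } else {
      stop("`b1` must lie in [0, 1]; got ", format(b1), call. = FALSE)
    }
  }
  if (scale == "boxcox") {
    if (is.null(lambda) || !is.numeric(lambda) || length(lambda) != 1L ||
        !is.finite(lambda))
      stop("`lambda` is required for scale = \"boxcox\"", call. = FALSE)
  } else {
    lambda <- 0
  }
  structure(
    list(mu_pop = mu_pop, sigma_pop = sigma_pop, b1 = b1, scale = scale,
         lambda = lambda, analyte = analyte, subgroup = subgroup),
    class = "peb_parameters"
  )
}

#' @export
print.peb_parameters <- function(x, digits = 4, ...) {
  lbl <- paste0(if (nzchar(x$analyte)) x$analyte else "PEB parameters",
                if (nzchar(x$subgroup)) paste0(" (", x$subgroup, ")"))
  cat(lbl, "\n")
  cat("  working scale:", if (x$scale == "log") "natural log"
      else sprintf("Box-Cox (lambda = %s)", format(x$lambda, digits = digits)),
      "\n")
  cat(sprintf("  mu_pop = %s, sigma_pop = %s, B1 = %s\n",
              format(x$mu_pop, digits = digits),
              format(x$sigma_pop, digits = digits),
              format(x$b1, digits = digits)))
  cat(sprintf("  variance split: sigma_G^2 = %s, sigma_I^2 = %s\n",
              format(x$b1 * x$sigma_pop^2, digits = digits),
              format((1 - x$b1) * x$sigma_pop^2, digits = digits)))
  invisible(x)
}

#' @export
coef.peb_parameters <- function(object, ...) {
  c(mu_pop = object$mu_pop, sigma_pop = object$sigma_pop, b1 = object$b1,
    lambda = object$lambda)
}

#' @export
summary.peb_parameters <- function(object, z = 1.96, ...) {
  out <- list(params = object,
              ri_pop = peb_threshold(numeric(), object, n_use = 0, z = z),
              limit_halfwidth = z * sqrt(1 - object$b1) * object$sigma_pop)
  class(out) <- "summary.peb_parameters"
  out
}

#' @export
print.summary.peb_parameters <- function(x, digits = 4, ...) {
  print(x$params, digits = digits)
  cat(sprintf("  population interval (n = 0): [%s, %s] (original scale)\n",
              format(x$ri_pop$lower, digits = digits),
              format(x$ri_pop$upper, digits = digits)))
  cat(sprintf("  limiting personalized half-width (n -> Inf): %s (working scale)\n",
              format(x$limit_halfwidth, digits = digits)))
  invisible(x)
}

#' PEB shrinkage factor
#'
#' Weight `B_n` placed on the individual mean after `n` prior results,
#' expressed through the intraclass correlation:
#' `B_n = B1 * n / (B1 * n + (1 - B1))`.  Equivalent to the variance-ratio
#' form `sigma_G^2 / (sigma_G^2 + sigma_I^2 / n)` and additionally covers
#' `n = 0`, where `B_n = 0` and the posterior set point collapses to the
#' population mean.
#'
#' @param b1 intraclass correlation in `[0, 1]`.
#' @param n non-negative integer count of prior results (vectorized).
#' @return shrinkage factor(s) in `[0, 1]`, non-decreasing in `n`.
#' @examples
#' shrinkage_factor(0.66, 0:9)
#' @export
shrinkage_factor <- function(b1, n) {
  if (!is.numeric(b1) || length(b1) != 1L || !is.finite(b1) ||
      b1 < 0 || b1 > 1)
    stop("`b1` must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) ||
      any(abs(n - round(n)) > 1e-8))
    stop("`n` must be non-negative integer(s)", call. = FALSE)
  n <- round(n)
  # n = 0 handled explicitly so that b1 = 1 does not produce 0/0
  ifelse(n == 0, 0, b1 * n / (b1 * n + (1 - b1)))
}

#' Posterior set point
#'
#' Shrinkage estimate of an individual's homeostatic set point:
#' `Y_hat = mu_pop + (x_bar - mu_pop) * B_n`, a weighted average of the
#' individual mean of `n` prior results and the population mean, both on the
#' working scale.  With no prior results (`n = 0`) it equals the population
#' mean and `x_bar` may be omitted.
#'
#' @param x_bar individual mean of the `n` prior results (working scale);
#'   ignored (may be `NULL`/`NA`) when `n = 0`.
#' @param params a [peb_parameters] object.
#' @param n non-negative integer count of prior results.
#' @return posterior set point on the working scale, always between
#'   `mu_pop` and `x_bar`.
#' @examples
#' p <- peb_parameters(3.181, 0.241, 0.66, scale = "boxcox", lambda = 0.89)
#' posterior_mean(3.5, p, n = 1)
#' @export
posterior_mean <- function(x_bar, params, n) {
  stopifnot(inherits(params, "peb_parameters"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 ||
      abs(n - round(n)) > 1e-8)
    stop("`n` must be a single non-negative integer", call. = FALSE)
  n <- round(n)
  if (n == 0) return(params$mu_pop)
  if (is.null(x_bar) || length(x_bar) != 1L || is.na(x_bar))
    stop("`x_bar` is required when n > 0", call. = FALSE)
  params$mu_pop + (x_bar - params$mu_pop) * shrinkage_factor(params$b1, n)
}

#' Prediction-interval half-width
#'
#' Working-scale half-width of the two-sided PEB prediction interval for the
#' next result given `n` priors: `Z * sqrt(1 - B1 * B_n) * sigma_pop`.  At
#' `n = 0` this is the population interval half-width `Z * sigma_pop`; as
#' `n` grows it decreases monotonically toward the fully personalized limit
#' `Z * sqrt(1 - B1) * sigma_pop = Z * sigma_I`.
#'
#' @param params a [peb_parameters] object.
#' @param n non-negative integer count of prior results (vectorized).
#' @param z Z-score of the two-sided confidence level (default 1.96 for 95%).
#' @return half-width(s) on the working scale.
#' @examples
#' p <- peb_parameters(3.181, 0.241, 0.66, scale = "boxcox", lambda = 0.89)
#' prediction_halfwidth(p, n = 0:9)
#' @export
prediction_halfwidth <- function(params, n, z = 1.96) {
  stopifnot(inherits(params, "peb_parameters"))
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0)
    stop("`z` must be a single positive number", call. = FALSE)
  bn <- shrinkage_factor(params$b1, n)
  z * sqrt(1 - params$b1 * bn) * params$sigma_pop
}
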