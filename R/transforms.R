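#' Box-Cox power transform and its inverse
#'
#' The one-parameter Box-Cox transform `(x^lambda - 1) / lambda`, with the
#' exact logarithmic branch `log(x)` at `lambda = 0`.  Used to bring skewed
#' biomarker distributions to approximate normality before any PEB
#' arithmetic; all thresholds are computed on the transformed (working)
#' scale and only final limits are mapped back.
#'
#' @param x positive numeric vector (original scale).
#' @param lambda transform exponent; `0` selects the log branch exactly.
#' @return `boxcox()` returns the transformed values; `boxcox_inverse()`
#'   maps working-scale values back to the original scale.
#' @examples
#' boxcox(2.7, 0.89)
#' boxcox_inverse(boxcox(2.7, 0.89), 0.89)  # 2.7
#' @export
boxcox <- function(x, lambda) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("Box-Cox transform requires finite positive values; offending value: ",
         format(x[which(!is.finite(x) | x <= 0)[1]]), call. = FALSE)
  if (abs(lambda) < .Machine$double.eps) log(x) else (x^lambda - 1) / lambda
}

#' @rdname boxcox
#' @param t numeric vector on the working (transformed) scale.
#' @export
boxcox_inverse <- function(t, lambda) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  if (abs(lambda) < .Machine$double.eps) return(exp(t))
  base <- 1 + lambda * t
  if (any(base <= 0)) {
    bad <- t[which(base <= 0)[1]]
    stop("value ", format(bad), " lies outside the image of the Box-Cox ",
         "transform with lambda = ", format(lambda), call. = FALSE)
  }
  base^(1 / lambda)
}

# working-scale transform pair dispatched on a peb_parameters object
to_working <- function(x, params) {
  if (params$scale == "log") {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("log working scale requires positive values; offending value: ",
           format(x[which(!is.finite(x) | x <= 0)[1]]), call. = FALSE)
    log(x)
  } else {
    boxcox(x, params$lambda)
  }
}

from_working <- function(t, params) {
  if (params$scale == "log") exp(t) else boxcox_inverse(t, params$lambda)
}

# lower edge of the working-scale image: values below it have no original-
# scale counterpart (the original-scale limit is then 0)
working_floor <- function(params) {
  if (params$scale == "log") -Inf
  else if (params$lambda > 0) -1 / params$lambda
  else -Inf
}

working_ceiling <- function(params) {
  if (params$scale == "boxcox" && params$lambda < 0) -1 / params$lambda
  else Inf
}
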