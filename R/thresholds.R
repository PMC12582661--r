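#' PEB threshold for the next result
#'
#' Computes the two-sided prediction interval for a subject's next result
#' given their history.  The history is transformed to the working scale,
#' the baseline mean of the `n_use` most recent prior results (equally
#' weighted) is shrunk toward the population mean, and the interval
#' `Y_hat +/- Z * sqrt(1 - B1 * B_n) * sigma_pop` is back-transformed to the
#' original scale.  `n_use = 0` gives the population reference interval,
#' identical for all subjects; `n_use = 1` is the PEB analogue of the
#' reference change value.
#'
#' When the lower working-scale limit falls outside the image of a Box-Cox
#' transform with positive exponent, the original-scale lower limit is
#' reported as 0 (the transform maps `(0, Inf)` onto a half-line, so no
#' positive value can fall below it).
#'
#' @param history numeric vector of the subject's prior results, original
#'   scale, oldest first.  May be empty when `n_use = 0`.
#' @param params a [peb_parameters] object.
#' @param n_use how many of the most recent prior results form the baseline
#'   mean; defaults to all of them.
#' @param z Z-score of the two-sided level (default 1.96).
#' @return an object of class `peb_threshold`: list with `y_hat` (working
#'   scale), `n_prior`, `b_n`, `lower`, `upper` (original scale), `z`.
#' @examples
#' p <- bv_to_peb(bv_estimates(2.3, 6.0, 1.8, 4.522))
#' peb_threshold(c(4.4, 4.6, 4.5), p)
#' @export
peb_threshold <- function(history, params, n_use = length(history), z = 1.96) {
  stopifnot(inherits(params, "peb_parameters"))
  if (!is.numeric(n_use) || length(n_use) != 1L || n_use < 0 ||
      abs(n_use - round(n_use)) > 1e-8)
    stop("`n_use` must be a single non-negative integer", call. = FALSE)
  n_use <- round(n_use)
  if (length(history) < n_use)
    stop("history holds ", length(history), " results but n_use = ", n_use,
         call. = FALSE)
  if (n_use > 0) {
    w <- to_working(tail(history, n_use), params)
    x_bar <- mean(w)
  } else {
    x_bar <- NULL
  }
  y_hat <- posterior_mean(x_bar, params, n_use)
  hw <- prediction_halfwidth(params, n_use, z)
  lo_w <- y_hat - hw
  up_w <- y_hat + hw
  floor_w <- working_floor(params)
  ceil_w <- working_ceiling(params)
  lower <- if (lo_w <= floor_w) 0 else from_working(lo_w, params)
  upper <- if (up_w >= ceil_w) Inf else from_working(up_w, params)
  structure(
    list(y_hat = y_hat, n_prior = n_use,
         b_n = shrinkage_factor(params$b1, n_use),
         lower = lower, upper = upper, z = z, scale = params$scale),
    class = "peb_threshold"
  )
}

#' @export
print.peb_threshold <- function(x, digits = 4, ...) {
  cat(sprintf("PEB %s (n = %d priors, Z = %s)\n",
              if (x$n_prior == 0) "population interval"
              else if (x$n_prior == 1) "result-pair (RCV) interval"
              else "personalized interval",
              x$n_prior, format(x$z, digits = digits)))
  cat(sprintf("  set point Y_hat = %s (working scale), B_n = %s\n",
              format(x$y_hat, digits = digits),
              format(x$b_n, digits = digits)))
  cat(sprintf("  limits (original scale): [%s, %s]\n",
              format(x$lower, digits = digits),
              format(x$upper, digits = digits)))
  invisible(x)
}

#' Evaluate one new result against a PEB threshold
#'
#' @param x_next the new result on the original scale.
#' @param threshold a `peb_threshold` from [peb_threshold()].
#' @return an object of class `peb_decision` extending the threshold with
#'   `x_next` and `flagged`.  A result exactly on a limit is not flagged
#'   (the exceedance criterion is a strict inequality).
#' @examples
#' p <- bv_to_peb(bv_estimates(2.3, 6.0, 1.8, 4.522))
#' peb_decision(5.4, peb_threshold(c(4.4, 4.6, 4.5), p))
#' @export
peb_decision <- function(x_next, threshold) {
  stopifnot(inherits(threshold, "peb_threshold"),
            is.numeric(x_next), length(x_next) == 1L, is.finite(x_next))
  threshold$x_next <- x_next
  threshold$flagged <- x_next < threshold$lower || x_next > threshold$upper
  class(threshold) <- c("peb_decision", "peb_threshold")
  threshold
}

#' @export
print.peb_decision <- function(x, digits = 4, ...) {
  NextMethod()
  cat(sprintf("  next result %s: %s\n", format(x$x_next, digits = digits),
              if (x$flagged) "FLAGGED" else "within limits"))
  invisible(x)
}

#' Predict method: threshold (or decision) for the next result
#'
#' @param object a [peb_parameters] object.
#' @param history prior results, original scale, oldest first.
#' @param n_use number of most recent priors forming the baseline.
#' @param z two-sided Z-score.
#' @param x_next optional new result; when supplied a `peb_decision` with a
#'   flag is returned instead of a bare threshold.
#' @param ... unused.
#' @return a `peb_threshold` or `peb_decision`.
#' @export
predict.peb_parameters <- function(object, history = numeric(),
                                   n_use = length(history), z = 1.96,
                                   x_next = NULL, ...) {
  th <- peb_threshold(history, object, n_use = n_use, z = z)
  if (is.null(x_next)) th else peb_decision(x_next, th)
}

#' Classic log-normal reference change value interval
#'
#' The conventional RCV limits for a new result given a single baseline,
#' symmetric on the log scale: `x_baseline * exp(+/- Z * sqrt(2) * s)` with
#' `s^2 = log(1 + (CV_I^2 + CV_A^2) / 100^2)`.  Unlike the PEB result-pair
#' interval, the band is centered at the baseline itself (no correction for
#' regression toward the mean) and its upper/lower ratio does not depend on
#' the baseline.
#'
#' @param cv_i_pct within-subject coefficient of variation, percent.
#' @param cv_a_pct analytical coefficient of variation, percent.
#' @param x_baseline the baseline result, original scale, positive.
#' @param z two-sided Z-score (default 1.96).
#' @return numeric `c(lower, upper)` on the original scale.
#' @examples
#' classic_rcv_interval(23.0, 4.8, 60, 1.96)
#' @export
classic_rcv_interval <- function(cv_i_pct, cv_a_pct, x_baseline, z = 1.96) {
  if (!is.numeric(cv_i_pct) || !is.numeric(cv_a_pct) ||
      cv_i_pct < 0 || cv_a_pct < 0)
    stop("CVs must be non-negative percentages", call. = FALSE)
  if (!is.numeric(x_baseline) || x_baseline <= 0)
    stop("`x_baseline` must be positive", call. = FALSE)
  if (z <= 0) stop("`z` must be positive", call. = FALSE)
  s_ln <- sqrt(log(1 + (cv_i_pct^2 + cv_a_pct^2) / 1e4))
  hw <- z * sqrt(2) * s_ln
  c(lower = x_baseline * exp(-hw), upper = x_baseline * exp(hw))
}
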