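#' Flag one subject's serial results
#'
#' Applies a thresholding mode to a time-ordered series of results and
#' records, per result, the interval used and whether the result fell
#' outside it (strictly; a result exactly on a limit is not flagged).
#'
#' Modes:
#' \describe{
#'   \item{`ri_pop`}{every result judged against the fixed population
#'     interval (the `n = 0` PEB case).}
#'   \item{`rcv_pair`}{result `i >= 2` judged with result `i - 1` as the
#'     baseline (`n = 1`); the first result is not evaluable.}
#'   \item{`ri_per_dynamic`}{result `i` judged with all `i - 1` prior
#'     results as baseline, so the first result is the `n = 0` case and the
#'     interval narrows as history accumulates.}
#'   \item{`rcv_ln_formula`}{the conventional log-normal RCV band around the
#'     previous result ([classic_rcv_interval()]); requires `bv`.}
#'   \item{`rcv_ratio`}{result ratio `x_i / x_{i-1}` judged against an
#'     empirical ratio band ([rcv_ratio_interval()]); requires `ratio_band`.}
#' }
#'
#' @param series numeric vector of positive results in time order, or a data
#'   frame with a `value` column.
#' @param params a [peb_parameters] object (PEB modes).
#' @param mode one of the modes above.
#' @param z two-sided Z-score (default 1.96).
#' @param bv a [bv_estimates] object, required for `rcv_ln_formula`.
#' @param ratio_band numeric `c(lower, upper)`, required for `rcv_ratio`.
#' @return data frame with one row per evaluable result: `index`, `x`,
#'   `n_prior`, `y_hat` (working scale; `NA` for non-PEB modes), `lower`,
#'   `upper`, `flagged`.
#' @export
flag_series <- function(series, params, mode = c("ri_pop", "rcv_pair",
                                                 "ri_per_dynamic",
                                                 "rcv_ln_formula",
                                                 "rcv_ratio"),
                        z = 1.96, bv = NULL, ratio_band = NULL) {
  mode <- match.arg(mode)
  x <- if (is.data.frame(series)) series$value else series
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("series values must be finite and positive", call. = FALSE)
  m <- length(x)
  empty <- data.frame(index = integer(), x = numeric(), n_prior = integer(),
                      y_hat = numeric(), lower = numeric(), upper = numeric(),
                      flagged = logical())
  if (m == 0) return(empty)

  row_of <- function(i, n_prior, y_hat, lo, up) data.frame(
    index = i, x = x[i], n_prior = n_prior, y_hat = y_hat,
    lower = lo, upper = up, flagged = x[i] < lo || x[i] > up)

  if (mode %in% c("ri_pop", "rcv_pair", "ri_per_dynamic")) {
    stopifnot(inherits(params, "peb_parameters"))
    idx <- if (mode == "rcv_pair") seq_len(m)[-1] else seq_len(m)
    out <- lapply(idx, function(i) {
      n_use <- switch(mode, ri_pop = 0L, rcv_pair = 1L,
                      ri_per_dynamic = i - 1L)
      hist <- if (n_use > 0) x[seq_len(i - 1)] else numeric()
      th <- peb_threshold(hist, params, n_use = n_use, z = z)
      row_of(i, n_use, th$y_hat, th$lower, th$upper)
    })
  } else if (mode == "rcv_ln_formula") {
    if (is.null(bv)) stop("`bv` is required for mode rcv_ln_formula",
                          call. = FALSE)
    out <- lapply(seq_len(m)[-1], function(i) {
      lim <- classic_rcv_interval(bv$cv_i_pct, bv$cv_a_pct, x[i - 1], z)
      row_of(i, 1L, NA_real_, lim[1], lim[2])
    })
  } else {
    if (is.null(ratio_band) || length(ratio_band) != 2L)
      stop("`ratio_band` (lower, upper) is required for mode rcv_ratio",
           call. = FALSE)
    out <- lapply(seq_len(m)[-1], function(i)
      row_of(i, 1L, NA_real_, x[i - 1] * ratio_band[1],
             x[i - 1] * ratio_band[2]))
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cohort-level flagging proportions
#'
#' Aggregates [flag_series()] over a cohort and reports the fraction of
#' evaluable results flagged -- the quantity that should sit near the nominal
#' level (5% at Z = 1.96) when the thresholds are calibrated to the cohort's
#' true variation.
#'
#' @param cohort data frame with columns `subject_id`, `value` and
#'   optionally `timestamp` (results are taken in row order within subject;
#'   supply them time-sorted).
#' @inheritParams flag_series
#' @return an object of class `flagging_report`: `mode`, `n_evaluated`,
#'   `n_flagged`, `proportion_pct`, and a `per_subject` data frame.
#' @export
flagging_summary <- function(cohort, params, mode = c("ri_pop", "rcv_pair",
                                                      "ri_per_dynamic",
                                                      "rcv_ln_formula",
                                                      "rcv_ratio"),
                             z = 1.96, bv = NULL, ratio_band = NULL) {
  mode <- match.arg(mode)
  if (!is.data.frame(cohort) ||
      !all(c("subject_id", "value") %in% names(cohort)))
    stop("`cohort` must have columns subject_id and value", call. = FALSE)
  if (nrow(cohort) == 0) stop("`cohort` is empty", call. = FALSE)
  parts <- split(cohort$value, cohort$subject_id)
  per <- lapply(parts, flag_series, params = params, mode = mode, z = z,
                bv = bv, ratio_band = ratio_band)
  n_eval <- sum(vapply(per, nrow, integer(1)))
  n_flag <- sum(vapply(per, function(d) sum(d$flagged), integer(1)))
  per_subject <- data.frame(
    subject_id = names(per),
    n_evaluated = vapply(per, nrow, integer(1)),
    n_flagged = vapply(per, function(d) sum(d$flagged), integer(1)),
    row.names = NULL
  )
  structure(
    list(mode = mode, n_evaluated = n_eval, n_flagged = n_flag,
         proportion_pct = if (n_eval > 0) 100 * n_flag / n_eval else NA_real_,
         per_subject = per_subject, detail = per),
    class = "flagging_report"
  )
}

#' @export
print.flagging_report <- function(x, digits = 3, ...) {
  cat(sprintf("Flagging report [%s]: %d / %d results flagged (%s%%)\n",
              x$mode, x$n_flagged, x$n_evaluated,
              format(x$proportion_pct, digits = digits)))
  invisible(x)
}

#' Empirical ratio-based RCV band
#'
#' The indirect reference-change-value method: the 2.5th and 97.5th
#' percentiles of the ratio of each result to its predecessor over a large
#' calibration set of repeat patient measurements.  A new pair is flagged
#' when its ratio falls outside the band.  The band is scale-invariant
#' (ratios do not change when all values are multiplied by a constant).
#'
#' @param pairs data frame with original-scale columns `x_prev`, `x_next`.
#' @param probs percentile pair (default `c(0.025, 0.975)`).
#' @return numeric `c(lower, upper)` ratio band.
#' @export
rcv_ratio_interval <- function(pairs, probs = c(0.025, 0.975)) {
  if (!is.data.frame(pairs) || !all(c("x_prev", "x_next") %in% names(pairs)))
    stop("`pairs` must have columns x_prev and x_next", call. = FALSE)
  if (any(pairs$x_prev <= 0) || any(pairs$x_next <= 0))
    stop("ratio RCV requires positive values in both pair members",
         call. = FALSE)
  if (nrow(pairs) < 200)
    warning("only ", nrow(pairs),
            " pairs; at least 200 are recommended for stable percentiles",
            call. = FALSE)
  q <- stats::quantile(pairs$x_next / pairs$x_prev, probs, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Compare flagging across all threshold methods
#'
#' Runs [flagging_summary()] for the three PEB modes (population interval,
#' result-pair RCV, dynamic personalized interval) and the two comparator
#' RCV methods (log-normal formula, empirical result-ratio band) on the same
#' cohort, mirroring the layout of a method-comparison table.
#'
#' @param cohort data frame `subject_id`, `value` (time-sorted within
#'   subject).
#' @param params a [peb_parameters] object.
#' @param bv a [bv_estimates] object for the log-normal RCV; `NULL` skips
#'   that mode.
#' @param z two-sided Z-score.
#' @param ratio_pairs calibration pairs for the ratio band (defaults to the
#'   cohort's own consecutive pairs, with a note that calibration and
#'   evaluation then share data).
#' @param ratio_band explicit `c(lower, upper)` ratio band, overriding
#'   `ratio_pairs`.
#' @return data frame with one row per mode: `mode`, `n_evaluated`,
#'   `n_flagged`, `proportion_pct`; the full reports are attached as
#'   attribute `"reports"`.
#' @export
compare_methods <- function(cohort, params, bv = NULL, z = 1.96,
                            ratio_pairs = NULL, ratio_band = NULL) {
  modes <- c("ri_pop", "rcv_pair", "ri_per_dynamic")
  if (!is.null(bv)) modes <- c(modes, "rcv_ln_formula")
  if (is.null(ratio_band)) {
    if (is.null(ratio_pairs)) {
      parts <- split(cohort$value, cohort$subject_id)
      ratio_pairs <- do.call(rbind, lapply(parts, function(v) {
        if (length(v) < 2) return(NULL)
        data.frame(x_prev = v[-length(v)], x_next = v[-1])
      }))
    }
    if (!is.null(ratio_pairs) && nrow(ratio_pairs) >= 2)
      ratio_band <- suppressWarnings(rcv_ratio_interval(ratio_pairs))
  }
  if (!is.null(ratio_band)) modes <- c(modes, "rcv_ratio")
  reports <- lapply(modes, function(mo)
    flagging_summary(cohort, params, mode = mo, z = z, bv = bv,
                     ratio_band = ratio_band))
  names(reports) <- modes
  out <- data.frame(
    mode = modes,
    n_evaluated = vapply(reports, `[[`, integer(1), "n_evaluated"),
    n_flagged = vapply(reports, `[[`, integer(1), "n_flagged"),
    proportion_pct = vapply(reports, `[[`, numeric(1), "proportion_pct"),
    row.names = NULL
  )
  attr(out, "reports") <- reports
  out
}

#' Plot a subject's series against dynamic PEB bands
#'
#' Draws one subject's results over their visit index with the dynamically
#' updated PEB prediction band shaded behind them; flagged results are
#' marked with diamonds.  The band for result `i` uses the `i - 1` prior
#' results, so it starts at the population interval and narrows toward the
#' personalized interval.
#'
#' @param x a [peb_parameters] object.
#' @param values the subject's results, original scale, time order.
#' @param z two-sided Z-score.
#' @param mode thresholding mode passed to [flag_series()].
#' @param main,xlab,ylab usual plot annotations.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the [flag_series()] data frame that was drawn.
#' @export
plot.peb_parameters <- function(x, values, z = 1.96,
                                mode = "ri_per_dynamic",
                                main = NULL, xlab = "result index",
                                ylab = "value", ...) {
  fl <- flag_series(values, x, mode = mode, z = z)
  if (nrow(fl) == 0) stop("nothing evaluable to plot", call. = FALSE)
  up <- ifelse(is.finite(fl$upper), fl$upper, max(values) * 1.5)
  ylim <- range(c(values, fl$lower, up))
  graphics::plot(seq_along(values), values, type = "n", ylim = ylim,
                 main = if (is.null(main))
                   paste0("PEB ", mode, if (nzchar(x$analyte))
                     paste0(" - ", x$analyte)) else main,
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(fl$index, rev(fl$index)), c(fl$lower, rev(up)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(fl$index, fl$lower, col = "steelblue")
  graphics::lines(fl$index, up, col = "steelblue")
  graphics::points(seq_along(values), values, pch = 16)
  if (any(fl$flagged))
    graphics::points(fl$index[fl$flagged], fl$x[fl$flagged], pch = 5,
                     cex = 1.6, col = "firebrick", lwd = 2)
  invisible(fl)
}
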