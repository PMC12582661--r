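#' Central-peak Box-Cox-normal population fit
#'
#' Estimates the population mean, SD and Box-Cox exponent of the
#' non-pathological "central peak" of a routine laboratory result
#' distribution.  Indirect reference-interval estimators of this style
#' assume that most results (ideally > 70%) come from non-diseased patients
#' and that this bulk is Box-Cox-normal; pathological results sit in the
#' tails or in secondary modes.
#'
#' For each candidate exponent on a grid the data are transformed, a robust
#' center and scale (median and MAD) are taken, and the normality of the
#' central region (within 2.5758 robust SDs of the center, the central 99%
#' of the fitted normal) is scored with the Anderson-Darling statistic.  The
#' exponent minimizing the statistic is selected and the location/scale are
#' the median and MAD of the data transformed at that exponent.  The whole
#' procedure is deterministic for a fixed input.
#'
#' Intended for large extracts: at least 5000 first-per-patient results with
#' a pathological fraction not exceeding roughly 30%.  Below 5000 values a
#' warning is issued; below 500 the fit is refused.
#'
#' @param first_results positive numeric vector, one (first) result per
#'   patient, original scale.
#' @param lambda_grid candidate Box-Cox exponents (default `seq(-1, 2, 0.02)`).
#' @return an object of class `population_fit`: list with `mu_pop`,
#'   `sigma_pop`, `lambda`, `n_used`, `central99_bounds` (working scale) and
#'   the objective profile.
#' @examples
#' set.seed(1)
#' x <- exp(rnorm(5000, 1.5, 0.3))
#' fit_population(x, lambda_grid = seq(-0.5, 1, 0.1))
#' @export
fit_population <- function(first_results, lambda_grid = seq(-1, 2, by = 0.02)) {
  x <- first_results
  if (!is.numeric(x) || length(x) == 0)
    stop("`first_results` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all results must be finite and positive", call. = FALSE)
  if (length(x) < 500)
    stop("population fit refused: only ", length(x),
         " results (at least 500 required)", call. = FALSE)
  if (length(x) < 5000)
    warning("population fit on ", length(x),
            " results; at least 5000 are recommended", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate data: all results identical", call. = FALSE)

  objective <- vapply(lambda_grid, function(l) {
    t <- boxcox(x, l)
    m <- stats::median(t)
    s <- stats::mad(t)
    if (s == 0) return(Inf)
    w <- t[abs(t - m) <= 2.5758 * s]
    if (length(w) < 8 || stats::sd(w) == 0) return(Inf)
    as.numeric(nortest::ad.test(w)$statistic)
  }, numeric(1))
  if (all(!is.finite(objective)))
    stop("degenerate data: no Box-Cox exponent yields a usable central region",
         call. = FALSE)
  k <- which.min(objective)
  lambda <- lambda_grid[k]
  if (k == 1L || k == length(lambda_grid))
    warning("selected lambda = ", format(lambda),
            " lies at the edge of the search grid", call. = FALSE)
  t <- boxcox(x, lambda)
  mu <- stats::median(t)
  sigma <- stats::mad(t)
  structure(
    list(mu_pop = mu, sigma_pop = sigma, lambda = lambda,
         n_used = length(x),
         central99_bounds = c(mu - 2.5758 * sigma, mu + 2.5758 * sigma),
         objective = data.frame(lambda = lambda_grid, ad_stat = objective)),
    class = "population_fit"
  )
}

#' @export
print.population_fit <- function(x, digits = 4, ...) {
  cat("Central-peak Box-Cox-normal population fit\n")
  cat(sprintf("  n = %d, lambda = %s\n", x$n_used, format(x$lambda)))
  cat(sprintf("  mu_pop = %s, sigma_pop = %s (working scale)\n",
              format(x$mu_pop, digits = digits),
              format(x$sigma_pop, digits = digits)))
  cat(sprintf("  central-99%% bounds: [%s, %s]\n",
              format(x$central99_bounds[1], digits = digits),
              format(x$central99_bounds[2], digits = digits)))
  invisible(x)
}

#' Central-99% filter
#'
#' Retains the values whose working-scale transform lies within
#' `mu_pop +/- 2.5758 * sigma_pop` of a [fit_population()] fit -- the
#' central 99% of the fitted normal, taken to represent the non-pathological
#' fraction.  Input order is preserved.
#'
#' @param values positive numeric vector on the original scale.
#' @param fit a `population_fit`.
#' @return the retained subset of `values`.
#' @export
central99_filter <- function(values, fit) {
  values[central99_keep(values, fit)]
}

central99_keep <- function(values, fit) {
  stopifnot(inherits(fit, "population_fit"))
  t <- boxcox(values, fit$lambda)
  t >= fit$central99_bounds[1] & t <= fit$central99_bounds[2]
}

#' Sequential result pairs
#'
#' Builds the result pairs used to estimate the intraclass correlation by
#' regression: within each subject, consecutive retained results form a pair
#' when more than `min_gap_hours` separate them, so a subject with `k`
#' eligible results contributes up to `k - 1` overlapping sequential pairs.
#' The minimum gap guards against short-term autocorrelation.
#'
#' @param data data frame with columns `subject_id`, `timestamp` (POSIXct or
#'   numeric hours) and `value` (already filtered and transformed to the
#'   working scale).  Must be time-sorted within subject; unsorted input is
#'   an error, not silently reordered.
#' @param min_gap_hours minimum spacing between pair members (default 24).
#' @return data frame with columns `subject_id`, `x_prev`, `x_next`,
#'   `gap_hours`.
#' @export
build_pairs <- function(data, min_gap_hours = 24) {
  need <- c("subject_id", "timestamp", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must have columns subject_id, timestamp, value",
         call. = FALSE)
  hrs <- if (inherits(data$timestamp, "POSIXct"))
    as.numeric(data$timestamp) / 3600 else as.numeric(data$timestamp)
  parts <- split(seq_len(nrow(data)), data$subject_id)
  out <- lapply(parts, function(idx) {
    h <- hrs[idx]
    if (is.unsorted(h, strictly = FALSE))
      stop("timestamps for subject ", data$subject_id[idx[1]],
           " are not time-sorted", call. = FALSE)
    if (length(idx) < 2) return(NULL)
    gap <- diff(h)
    keep <- gap > min_gap_hours
    if (!any(keep)) return(NULL)
    i <- which(keep)
    data.frame(subject_id = data$subject_id[idx[1]],
               x_prev = data$value[idx[i]],
               x_next = data$value[idx[i + 1]],
               gap_hours = gap[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject_id = character(), x_prev = numeric(),
                      x_next = numeric(), gap_hours = numeric())
  rownames(out) <- NULL
  out
}

#' Robust regression slope of sequential result pairs
#'
#' Regresses each result on the previous one (free intercept) with an
#' iteratively reweighted M-estimator (Tukey bisquare, tuning constant
#' 4.685, MAD scale, at most 200 iterations, coefficient tolerance 1e-8),
#' which down-weights pairs with large residuals so that residual
#' pathological values do not drag the slope.  Under the hierarchical model
#' the slope of a result on its predecessor is the intraclass correlation
#' B1.  The 95% CI is a nonparametric percentile bootstrap that resamples
#' subjects (not pairs) to respect within-subject dependence between
#' overlapping pairs.
#'
#' @param pairs data frame from [build_pairs()] (working scale).
#' @param n_boot bootstrap resamples for the CI (default 1999); `0` skips
#'   the CI.
#' @param seed seed for the bootstrap resampling.
#' @param conf confidence level of the bootstrap interval.
#' @return an object of class `robust_slope_fit`: `slope`, `intercept`,
#'   `n_pairs`, `ci95`, `converged`, `weights_summary`.
#' @export
robust_slope <- function(pairs, n_boot = 1999, seed = 1L, conf = 0.95) {
  if (!is.data.frame(pairs) || !all(c("x_prev", "x_next") %in% names(pairs)))
    stop("`pairs` must have columns x_prev and x_next", call. = FALSE)
  if (nrow(pairs) < 2)
    stop("at least 2 result pairs are required for a slope fit",
         call. = FALSE)
  if (stats::var(pairs$x_prev) == 0)
    stop("degenerate pairs: x_prev has zero variance", call. = FALSE)
  if (nrow(pairs) < 100)
    warning("only ", nrow(pairs),
            " result pairs; at least 100 are recommended", call. = FALSE)

  fit1 <- function(d) {
    # an (almost) exact linear relation degenerates the IRLS scale estimate;
    # the OLS fit is then already the robust answer
    ols <- stats::lm(x_next ~ x_prev, data = d)
    if (stats::sd(ols$residuals) <= 1e-10 * stats::sd(d$x_next)) {
      ols$w <- rep(1, nrow(d))
      ols$converged <- TRUE
      return(ols)
    }
    MASS::rlm(x_next ~ x_prev, data = d,
              psi = MASS::psi.bisquare, c = 4.685,
              scale.est = "MAD", maxit = 200, acc = 1e-8)
  }
  fit <- fit1(pairs)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    sid <- if ("subject_id" %in% names(pairs)) pairs$subject_id
           else seq_len(nrow(pairs))
    groups <- split(seq_len(nrow(pairs)), sid)
    slopes <- local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(length(groups), replace = TRUE)
        d <- pairs[unlist(groups[pick], use.names = FALSE), , drop = FALSE]
        if (stats::var(d$x_prev) == 0) return(NA_real_)
        tryCatch(unname(coef(fit1(d))[2]), error = function(e) NA_real_)
      }, numeric(1))
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(slopes, c(a, 1 - a), na.rm = TRUE))
  }
  w <- fit$w
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_pairs = nrow(pairs), ci95 = ci, converged = isTRUE(fit$converged),
         weights_summary = c(min = min(w), median = stats::median(w))),
    class = "robust_slope_fit"
  )
}

#' @export
print.robust_slope_fit <- function(x, digits = 4, ...) {
  cat("Robust regression of sequential result pairs\n")
  cat(sprintf("  slope (B1 estimate) = %s, intercept = %s, n_pairs = %d\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits), x$n_pairs))
  if (!any(is.na(x$ci95)))
    cat(sprintf("  95%% CI (subject bootstrap): [%s, %s]\n",
                format(x$ci95[1], digits = digits),
                format(x$ci95[2], digits = digits)))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' Fit PEB parameters from routine laboratory (LIS) data
#'
#' End-to-end estimation pathway for routine serial results:
#' \enumerate{
#'   \item exclude values below the reporting limit;
#'   \item optionally keep only samples drawn inside a morning window
#'     (default 08:00--10:00) to suppress diurnal variation;
#'   \item fit the non-pathological population (mean, SD, Box-Cox exponent)
#'     to each patient's first retained result with [fit_population()];
#'   \item drop results outside the central 99% of that fit;
#'   \item transform the remainder, form per-subject sequential pairs more
#'     than `min_gap_hours` apart, and estimate B1 as the robust regression
#'     slope of each result on the previous one.
#' }
#' A stage-by-stage audit of retained/excluded counts is kept on the
#' returned object.
#'
#' @param data data frame with columns `subject_id`, `timestamp` (POSIXct or
#'   ISO-8601 text) and `value`.
#' @param reporting_limit exclude values strictly below this limit
#'   (`NULL` = no limit).
#' @param diurnal_window length-2 character vector `c("08:00", "10:00")` to
#'   keep only samples collected in that clock-time window, or `NULL` to
#'   keep all.
#' @param min_gap_hours minimum spacing between pair members (default 24).
#' @param lambda_grid candidate Box-Cox exponents for [fit_population()].
#' @param n_boot bootstrap resamples for the B1 CI (default 1999; `0` skips).
#' @param seed seed for the bootstrap.
#' @param analyte,subgroup labels carried into the result.
#' @return an object of classes `peb_lis_fit` and [peb_parameters], with
#'   additional elements `pop_fit`, `slope_fit` and `audit`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(simulation_config(n_subjects = 800,
#'   visits_per_subject = 3, seed = 7))
#' fit <- fit_peb_lis(as.data.frame(cohort), n_boot = 0)
#' }
#' @export
fit_peb_lis <- function(data, reporting_limit = NULL, diurnal_window = NULL,
                        min_gap_hours = 24,
                        lambda_grid = seq(-1, 2, by = 0.02),
                        n_boot = 1999, seed = 1L,
                        analyte = "", subgroup = "") {
  validate_results_schema(data)
  audit <- list()
  note <- function(stage, n_in, n_out) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_excluded = n_in - n_out, n_retained = n_out)
  }
  n0 <- nrow(data)
  note("input", n0, n0)

  if (!is.null(reporting_limit)) {
    keep <- data$value >= reporting_limit
    note("reporting_limit", nrow(data), sum(keep))
    data <- data[keep, , drop = FALSE]
  }
  if (!is.null(diurnal_window)) {
    keep <- in_clock_window(data$timestamp, diurnal_window)
    note("diurnal_window", nrow(data), sum(keep))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0)
    stop("stage 'filters': no results remain after exclusion filters",
         call. = FALSE)

  # stable sort: identical timestamps keep input order
  ord <- order(data$subject_id, as.numeric(data$timestamp))
  data <- data[ord, , drop = FALSE]

  first_idx <- !duplicated(data$subject_id)
  pop_fit <- tryCatch(
    fit_population(data$value[first_idx], lambda_grid = lambda_grid),
    error = function(e) stop("stage 'population_fit': ", conditionMessage(e),
                             call. = FALSE))
  note("first_results", nrow(data), sum(first_idx))

  keep <- central99_keep(data$value, pop_fit)
  note("central99_filter", nrow(data), sum(keep))
  data <- data[keep, , drop = FALSE]

  work <- data
  work$value <- boxcox(data$value, pop_fit$lambda)
  pairs <- build_pairs(work, min_gap_hours = min_gap_hours)
  note("result_pairs", nrow(data), nrow(pairs))
  if (nrow(pairs) < 2)
    stop("stage 'result_pairs': population fit succeeded but only ",
         nrow(pairs), " sequential result pair(s) with > ", min_gap_hours,
         " h spacing exist, so B1 cannot be estimated", call. = FALSE)

  slope_fit <- tryCatch(
    robust_slope(pairs, n_boot = n_boot, seed = seed),
    error = function(e) stop("stage 'robust_slope': ", conditionMessage(e),
                             call. = FALSE))

  params <- peb_parameters(pop_fit$mu_pop, pop_fit$sigma_pop,
                           slope_fit$slope, scale = "boxcox",
                           lambda = pop_fit$lambda,
                           analyte = analyte, subgroup = subgroup)
  params$pop_fit <- pop_fit
  params$slope_fit <- slope_fit
  params$audit <- do.call(rbind, audit)
  class(params) <- c("peb_lis_fit", class(params))
  params
}

#' @export
print.peb_lis_fit <- function(x, digits = 4, ...) {
  cat("PEB parameters estimated from routine laboratory data\n")
  NextMethod()
  if (!any(is.na(x$slope_fit$ci95)))
    cat(sprintf("  B1 95%% CI: [%s, %s] (%d pairs)\n",
                format(x$slope_fit$ci95[1], digits = digits),
                format(x$slope_fit$ci95[2], digits = digits),
                x$slope_fit$n_pairs))
  cat("  pipeline audit:\n")
  a <- x$audit
  for (i in seq_len(nrow(a)))
    cat(sprintf("    %-18s in %8d  excluded %8d  retained %8d\n",
                a$stage[i], a$n_in[i], a$n_excluded[i], a$n_retained[i]))
  invisible(x)
}

# clock-time window filter; window = c("HH:MM", "HH:MM"), inclusive ends
in_clock_window <- function(timestamp, window) {
  stopifnot(length(window) == 2L)
  mins <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }
  lo <- mins(window[1]); hi <- mins(window[2])
  if (lo >= hi) stop("diurnal window start must precede its end",
                     call. = FALSE)
  lt <- as.POSIXlt(timestamp)
  tod <- lt$hour * 60 + lt$min
  tod >= lo & tod <= hi
}
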