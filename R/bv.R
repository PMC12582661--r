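#' Biological-variation estimates
#'
#' Container for the coefficient-of-variation triplet of a designed
#' biological-variation study -- within-subject `CV_I`, between-subject
#' `CV_G` and analytical `CV_A`, all in percent -- together with the
#' population mean on the original scale.  This is the input of the log-scale
#' PEB pathway, [bv_to_peb()].
#'
#' @param cv_i_pct,cv_g_pct,cv_a_pct non-negative CVs in percent.
#' @param mu_pop_original positive population mean, original scale.
#' @param ci_cv_i,ci_cv_g optional length-2 confidence bounds bracketing the
#'   point estimates.
#' @return an object of class `bv_estimates`.
#' @examples
#' bv_estimates(cv_i_pct = 2.3, cv_g_pct = 6.0, cv_a_pct = 1.8,
#'              mu_pop_original = 4.522)
#' @export
bv_estimates <- function(cv_i_pct, cv_g_pct, cv_a_pct, mu_pop_original,
                         ci_cv_i = NULL, ci_cv_g = NULL) {
  for (v in list(cv_i_pct, cv_g_pct, cv_a_pct))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("CVs must be single non-negative percentages", call. = FALSE)
  if (!is.numeric(mu_pop_original) || mu_pop_original <= 0)
    stop("`mu_pop_original` must be positive", call. = FALSE)
  chk_ci <- function(ci, est, nm) {
    if (is.null(ci)) return(NULL)
    stopifnot(length(ci) == 2L)
    if (ci[1] > est || ci[2] < est)
      stop("confidence bounds for ", nm, " do not bracket the estimate",
           call. = FALSE)
    as.numeric(ci)
  }
  structure(
    list(cv_i_pct = cv_i_pct, cv_g_pct = cv_g_pct, cv_a_pct = cv_a_pct,
         mu_pop_original = mu_pop_original,
         ci_cv_i = chk_ci(ci_cv_i, cv_i_pct, "CV_I"),
         ci_cv_g = chk_ci(ci_cv_g, cv_g_pct, "CV_G")),
    class = "bv_estimates"
  )
}

#' @export
print.bv_estimates <- function(x, digits = 4, ...) {
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" (%s, %s)", format(ci[1], digits = digits),
            format(ci[2], digits = digits))
  cat("Biological-variation estimates (percent)\n")
  cat(sprintf("  CV_I = %s%s, CV_G = %s%s, CV_A = %s\n",
              format(x$cv_i_pct, digits = digits), fmt_ci(x$ci_cv_i),
              format(x$cv_g_pct, digits = digits), fmt_ci(x$ci_cv_g),
              format(x$cv_a_pct, digits = digits)))
  cat(sprintf("  population mean (original scale) = %s\n",
              format(x$mu_pop_original, digits = digits)))
  invisible(x)
}

#' Convert biological-variation estimates to log-scale PEB parameters
#'
#' Biological-variation studies report proportional variation (constant CV),
#' so the PEB formulae are applied on the natural-log scale where
#' proportional variation becomes additive.  The conversion uses the exact
#' lognormal relation between a CV and the log-scale variance:
#' `sigma_I^2 = log(1 + (CV_I^2 + CV_A^2)/100^2)` (the analytical component
#' is folded into the within-subject term because every measured result
#' carries it), `sigma_G^2 = log(1 + CV_G^2/100^2)`,
#' `b1 = sigma_G^2 / (sigma_G^2 + sigma_I^2)`, and
#' `mu_pop = log(mu_pop_original)`.
#'
#' @param bv a [bv_estimates] object.
#' @param analyte,subgroup labels carried into the result.
#' @return a [peb_parameters] object with `scale = "log"`.
#' @examples
#' bv_to_peb(bv_estimates(2.3, 6.0, 1.8, 4.522))  # b1 close to 0.81
#' @export
bv_to_peb <- function(bv, analyte = "", subgroup = "") {
  stopifnot(inherits(bv, "bv_estimates"))
  s_i2 <- log(1 + (bv$cv_i_pct^2 + bv$cv_a_pct^2) / 1e4)
  s_g2 <- log(1 + bv$cv_g_pct^2 / 1e4)
  tot <- s_g2 + s_i2
  if (tot <= 0)
    stop("all variation is zero; PEB parameters are undefined", call. = FALSE)
  peb_parameters(mu_pop = log(bv$mu_pop_original), sigma_pop = sqrt(tot),
                 b1 = s_g2 / tot, scale = "log",
                 analyte = analyte, subgroup = subgroup)
}

#' Four-level outlier-exclusion cascade for biological-variation data
#'
#' Cleans a subjects x visits (x replicates) biological-variation dataset
#' before variance decomposition, applying in order:
#' \enumerate{
#'   \item \strong{analytical} -- a Burnett-type test on replicate
#'     disagreement: samples whose replicate scatter is incompatible with
#'     the pooled analytical variance (Bonferroni-adjusted level
#'     `alpha_burnett`) are removed.  Skipped, with an audit note, when no
#'     sample has replicates.
#'   \item \strong{mean} -- the Reed criterion on subject means: an extreme
#'     mean is excluded when its gap to the nearest other mean exceeds one
#'     third of the total range; applied iteratively at both ends.
#'   \item \strong{trend} -- subjects whose results drift over the study
#'     (linear regression of visit means on visit index, slope p <
#'     `trend_p`) are excluded, since a moving set point violates the
#'     steady-state assumption.
#'   \item \strong{homogeneity} -- within-subject variances are tested for
#'     homogeneity (Bartlett by default, Cochran's C optional); the subject
#'     with the most extreme variance is excluded iteratively until
#'     homogeneity is achieved at level `homog_alpha`.
#' }
#'
#' @param data data frame with columns `subject_id`, `visit`, `value` and
#'   optionally `replicate`.
#' @param log_scale work on `log(value)` (the usual choice when variation is
#'   proportional); otherwise on the raw values.
#' @param alpha_burnett familywise level of the analytical outlier test.
#' @param trend_p slope p-value threshold of the trend test (default 0.01).
#' @param homog_alpha level of the homogeneity test (default 0.05).
#' @param homog_method `"bartlett"` or `"cochran"`.
#' @return list with `data` (cleaned rows, original scale) and `exclusions`
#'   (data frame `level`, `id`, `reason`).
#' @export
outlier_cascade <- function(data, log_scale = TRUE, alpha_burnett = 0.05,
                            trend_p = 0.01, homog_alpha = 0.05,
                            homog_method = c("bartlett", "cochran")) {
  homog_method <- match.arg(homog_method)
  need <- c("subject_id", "visit", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must have columns subject_id, visit, value", call. = FALSE)
  if (any(!is.finite(data$value)) || (log_scale && any(data$value <= 0)))
    stop("values must be finite", if (log_scale) " and positive", call. = FALSE)
  excl <- data.frame(level = character(), id = character(),
                     reason = character(), stringsAsFactors = FALSE)
  add_excl <- function(level, id, reason)
    excl <<- rbind(excl, data.frame(level = level, id = as.character(id),
                                    reason = reason))
  y_of <- function(d) if (log_scale) log(d$value) else d$value
  guard <- function(d) {
    if (length(unique(d$subject_id)) < 3)
      stop("cascade failure: fewer than 3 subjects remain", call. = FALSE)
    d
  }

  # 1. analytical (Burnett-type) on replicate scatter within samples
  has_rep <- "replicate" %in% names(data) &&
    any(duplicated(data[c("subject_id", "visit")]))
  if (has_rep) {
    y <- y_of(data)
    key <- interaction(data$subject_id, data$visit, drop = TRUE)
    per <- split(y, key)
    per <- per[lengths(per) >= 2]
    m <- length(per)
    ss <- vapply(per, function(v) sum((v - mean(v))^2), numeric(1))
    df <- vapply(per, function(v) length(v) - 1, numeric(1))
    var_a <- sum(ss) / sum(df)
    if (var_a > 0) {
      # per-sample chi-square test of replicate variance against the pool
      pvals <- stats::pchisq(ss / var_a, df, lower.tail = FALSE)
      bad <- names(per)[pvals < alpha_burnett / m]
      if (length(bad)) {
        keep <- !(as.character(key) %in% bad)
        for (b in bad)
          add_excl("analytical", b,
                   "replicate disagreement beyond pooled analytical variance")
        data <- guard(data[keep, , drop = FALSE])
      }
    }
  } else {
    add_excl("analytical", "-", "skipped: no replicate measurements")
  }

  # 2. Reed criterion on subject means
  repeat {
    y <- y_of(data)
    means <- tapply(y, data$subject_id, mean)
    if (length(means) < 3) break
    s <- sort(means)
    rng <- s[length(s)] - s[1]
    if (rng == 0) break
    drop_id <- NULL
    if ((s[2] - s[1]) > rng / 3) drop_id <- names(s)[1]
    else if ((s[length(s)] - s[length(s) - 1]) > rng / 3)
      drop_id <- names(s)[length(s)]
    if (is.null(drop_id)) break
    add_excl("mean", drop_id,
             sprintf("Reed criterion: gap to nearest mean exceeds range/3"))
    data <- guard(data[data$subject_id != drop_id, , drop = FALSE])
  }

  # 3. per-subject linear time trend
  y <- y_of(data)
  vm <- stats::aggregate(list(y = y),
                         by = list(subject_id = data$subject_id,
                                   visit = data$visit), FUN = mean)
  for (id in unique(vm$subject_id)) {
    d <- vm[vm$subject_id == id, ]
    if (nrow(d) < 3 || stats::var(d$visit) == 0) next
    fit <- stats::lm(y ~ visit, data = d)
    p <- summary(fit)$coefficients["visit", "Pr(>|t|)"]
    if (is.finite(p) && p < trend_p) {
      add_excl("trend", id, sprintf("linear drift over study (p = %.2g)", p))
      data <- data[data$subject_id != id, , drop = FALSE]
    }
  }
  data <- guard(data)

  # 4. homogeneity of within-subject variances, iterative exclusion
  repeat {
    y <- y_of(data)
    vm <- stats::aggregate(list(y = y),
                           by = list(subject_id = data$subject_id,
                                     visit = data$visit), FUN = mean)
    grp <- factor(vm$subject_id)
    nv <- table(grp)
    if (any(nv < 2) || length(levels(grp)) < 3) break
    vars <- tapply(vm$y, grp, stats::var)
    if (homog_method == "bartlett") {
      p <- stats::bartlett.test(vm$y, grp)$p.value
      homogeneous <- is.na(p) || p >= homog_alpha
    } else {
      homogeneous <- !cochran_c_reject(vars, nv, homog_alpha)
    }
    if (homogeneous) break
    # exclude the subject whose variance is most extreme on the log scale
    lv <- log(pmax(vars, .Machine$double.xmin))
    worst <- names(vars)[which.max(abs(lv - stats::median(lv)))]
    add_excl("homogeneity", worst,
             "within-subject variance incompatible with the rest")
    data <- guard(data[data$subject_id != worst, , drop = FALSE])
  }

  list(data = data, exclusions = excl)
}

# Cochran's C test: reject homogeneity when the largest variance dominates.
# Critical value via the F-quantile identity for k groups with nu df each.
cochran_c_reject <- function(vars, nv, alpha) {
  k <- length(vars)
  nu <- mean(nv) - 1
  C <- max(vars) / sum(vars)
  f <- stats::qf(alpha / k, nu, (k - 1) * nu, lower.tail = FALSE)
  C_crit <- 1 / (1 + (k - 1) / f)
  C > C_crit
}

#' Nested ANOVA variance components as coefficients of variation
#'
#' Method-of-moments decomposition of a (near-)balanced subjects x visits
#' (x replicates) design into analytical, within-subject and between-subject
#' components, reported as CVs in percent.
#'
#' In `cv_anova` mode every subject's results are first divided by that
#' subject's mean, so variance components of the scaled data are squared
#' CVs directly.  In `ln_anova` mode the decomposition runs on
#' `log(value)` and components convert through the lognormal relation
#' `CV = sqrt(exp(sigma^2) - 1)`.  The analytical component comes from
#' replicate scatter when replicates exist; otherwise supply `cv_a_pct`
#' (from quality-control data) and it is subtracted from the within-subject
#' component, so `CV_I` is always reported net of `CV_A`.  Negative
#' method-of-moments components are truncated at zero with a warning.
#'
#' @param data data frame with columns `subject_id`, `visit`, `value` and
#'   optionally `replicate`.
#' @param mode `"cv_anova"` or `"ln_anova"`.
#' @param cv_a_pct analytical CV in percent, used when the design has no
#'   replicates; defaults to 0 with a warning when absent.
#' @param max_missing largest tolerated fraction of missing subject-visit
#'   cells (default 0.2); a sparser design is refused.
#' @return list with `variance_components` (analytical, within, between, on
#'   the analysis scale, plus `n_subjects_used`) and `estimates`, a
#'   [bv_estimates] object.
#' @export
nested_anova_cv <- function(data, mode = c("cv_anova", "ln_anova"),
                            cv_a_pct = NULL, max_missing = 0.2) {
  mode <- match.arg(mode)
  need <- c("subject_id", "visit", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must have columns subject_id, visit, value", call. = FALSE)
  if (any(!is.finite(data$value)) || any(data$value <= 0))
    stop("values must be finite and positive", call. = FALSE)

  subj <- factor(data$subject_id)
  k <- nlevels(subj)
  if (k < 3) stop("at least 3 subjects are required", call. = FALSE)
  cells <- unique(data[c("subject_id", "visit")])
  visits_per <- table(factor(cells$subject_id, levels = levels(subj)))
  m_max <- max(visits_per)
  if (any(visits_per < (1 - max_missing) * m_max))
    stop("design is unbalanced beyond ", 100 * max_missing,
         "% missingness; a (near-)balanced design is required", call. = FALSE)
  if (any(visits_per < 2))
    stop("every subject needs at least 2 visits", call. = FALSE)

  mu_orig <- mean(data$value)
  subj_mean_orig <- tapply(data$value, subj, mean)
  y <- switch(mode,
    cv_anova = data$value / subj_mean_orig[as.character(subj)],
    ln_anova = log(data$value))

  truncated <- FALSE
  trunc0 <- function(v) {
    if (v < 0) truncated <<- TRUE
    max(v, 0)
  }

  # analytical level: pooled replicate variance within samples
  key <- interaction(data$subject_id, data$visit, drop = TRUE)
  reps_per <- table(key)
  has_rep <- any(reps_per >= 2)
  if (has_rep) {
    per <- split(y, key)
    ss <- vapply(per, function(v) sum((v - mean(v))^2), numeric(1))
    df <- vapply(per, function(v) length(v) - 1, numeric(1))
    var_a <- if (sum(df) > 0) sum(ss) / sum(df) else 0
    r_bar <- mean(reps_per)
  } else {
    var_a <- NA_real_  # not estimable; handled below via cv_a_pct
    r_bar <- 1
  }

  # sample means (over replicates) and the nested moments
  agg <- stats::aggregate(list(y = y),
                          by = list(subject_id = data$subject_id,
                                    visit = data$visit), FUN = mean)
  g <- factor(agg$subject_id)
  s_w2 <- mean(tapply(agg$y, g, stats::var))  # E = sigma_I^2 + var_a / r
  m_bar <- mean(table(g))
  # between-subject moment: in cv_anova mode the per-subject scaling removes
  # between-subject spread, so the component comes from the original-scale
  # subject means relative to the grand mean
  s_b2 <- switch(mode,                     # E = sigma_G^2 + E[s_w2] / m
    cv_anova = stats::var(subj_mean_orig / mu_orig),
    ln_anova = stats::var(tapply(agg$y, g, mean)))

  if (has_rep) {
    sigma_a2 <- var_a
    sigma_i2 <- trunc0(s_w2 - sigma_a2 / r_bar)
  } else {
    if (is.null(cv_a_pct)) {
      warning("no replicates and no `cv_a_pct` supplied; ",
              "analytical variation assumed 0", call. = FALSE)
      cv_a_pct <- 0
    }
    sigma_a2 <- switch(mode,
      cv_anova = (cv_a_pct / 100)^2,
      ln_anova = log(1 + cv_a_pct^2 / 1e4))
    sigma_i2 <- trunc0(s_w2 - sigma_a2)
  }
  sigma_g2 <- trunc0(s_b2 - s_w2 / m_bar)
  if (truncated)
    warning("negative method-of-moments component truncated at 0",
            call. = FALSE)

  to_cv <- function(v) switch(mode,
    cv_anova = 100 * sqrt(v),
    ln_anova = 100 * sqrt(exp(v) - 1))
  est <- bv_estimates(cv_i_pct = to_cv(sigma_i2), cv_g_pct = to_cv(sigma_g2),
                      cv_a_pct = if (has_rep) to_cv(sigma_a2) else cv_a_pct,
                      mu_pop_original = mu_orig)
  list(
    variance_components = list(var_analytical = sigma_a2,
                               var_within = sigma_i2,
                               var_between = sigma_g2,
                               n_subjects_used = k, mode = mode),
    estimates = est
  )
}

#' Fit PEB parameters from a biological-variation study
#'
#' Convenience pathway composing the outlier cascade, the nested-ANOVA
#' variance decomposition and the log-scale conversion: cleaned data go
#' through [nested_anova_cv()] and the resulting CVs through [bv_to_peb()].
#'
#' @param data long-format data frame: `subject_id`, `visit`, optional
#'   `replicate`, `value`.
#' @param mode `"ln_anova"` (default, matches proportional variation) or
#'   `"cv_anova"`.
#' @param cv_a_pct analytical CV (percent) when the design lacks replicates.
#' @param mu_pop optional population mean on the original scale to use in
#'   place of the study grand mean (e.g. one estimated from routine data,
#'   which usually represents the target population better than 30
#'   volunteers).
#' @param cascade run [outlier_cascade()] first (default `TRUE`).
#' @param analyte,subgroup labels.
#' @param ... passed to [outlier_cascade()].
#' @return an object of classes `peb_bv_fit` and [peb_parameters], with
#'   elements `bv`, `variance_components`, `exclusions`.
#' @export
fit_peb_bv <- function(data, mode = c("ln_anova", "cv_anova"),
                       cv_a_pct = NULL, mu_pop = NULL, cascade = TRUE,
                       analyte = "", subgroup = "", ...) {
  mode <- match.arg(mode)
  exclusions <- NULL
  if (cascade) {
    cc <- outlier_cascade(data, log_scale = (mode == "ln_anova"), ...)
    data <- cc$data
    exclusions <- cc$exclusions
  }
  an <- nested_anova_cv(data, mode = mode, cv_a_pct = cv_a_pct)
  bv <- an$estimates
  if (!is.null(mu_pop))
    bv <- bv_estimates(bv$cv_i_pct, bv$cv_g_pct, bv$cv_a_pct, mu_pop,
                       ci_cv_i = bv$ci_cv_i, ci_cv_g = bv$ci_cv_g)
  params <- bv_to_peb(bv, analyte = analyte, subgroup = subgroup)
  params$bv <- bv
  params$variance_components <- an$variance_components
  params$exclusions <- exclusions
  class(params) <- c("peb_bv_fit", class(params))
  params
}

#' @export
print.peb_bv_fit <- function(x, digits = 4, ...) {
  cat("PEB parameters estimated from a biological-variation study\n")
  NextMethod()
  print(x$bv, digits = digits)
  if (!is.null(x$exclusions) && nrow(x$exclusions))
    cat("  exclusions:", nrow(x$exclusions), "entries (see $exclusions)\n")
  invisible(x)
}
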