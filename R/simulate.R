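#' Simulation configuration
#'
#' Describes a synthetic cohort with the statistical structure the PEB
#' method assumes -- individual set points drawn around a population mean
#' with between-subject variance, repeated results drawn around the set
#' point with within-subject plus analytical variance -- together with the
#' laboratory artifacts the estimation pipeline must survive: skew (log or
#' Box-Cox working scale), persistent pathological set-point shifts,
#' censoring below a reporting limit, morning-window sampling timestamps and
#' optional within-subject variance heterogeneity.
#'
#' Defaults reproduce a designed biological-variation study on an
#' albumin-like analyte: 30 subjects sampled weekly for 10 weeks in the
#' 08:00--10:00 window, CV_G = 6.0%, CV_I = 2.3%, CV_A = 1.8%, population
#' mean 4.522 on the original scale, lognormal (proportional) variation, no
#' contamination.
#'
#' @param mu_pop_original population mean, original scale.
#' @param cv_g_pct,cv_i_pct,cv_a_pct between-subject, within-subject and
#'   analytical CVs in percent.
#' @param lambda_shape `"log"` for lognormal (proportional) variation, or a
#'   numeric Box-Cox exponent; the hierarchical normal model lives on this
#'   working scale.
#' @param n_subjects,visits_per_subject,replicate_count design size.
#' @param pathological_fraction fraction of subjects whose set point is
#'   shifted (persistent pathology), in `[0, 1)`.
#' @param pathological_shift_sd size of that shift in units of the
#'   working-scale population SD.
#' @param reporting_limit results below this original-scale limit are
#'   labelled censored.
#' @param gap_hours_range uniform range of the gap between visits, hours.
#' @param morning_window draw collection clock times inside 08:00--10:00
#'   (`TRUE`, default) or uniformly across the day (`FALSE`), the latter to
#'   exercise the diurnal filter.
#' @param heteroscedastic_multiplier within-subject SD multiplier (>= 1)
#'   applied to a random `affected_fraction` of subjects.
#' @param affected_fraction fraction of subjects receiving the multiplier.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(mu_pop_original = 4.522, cv_g_pct = 6.0,
                              cv_i_pct = 2.3, cv_a_pct = 1.8,
                              lambda_shape = "log", n_subjects = 30,
                              visits_per_subject = 10, replicate_count = 1,
                              pathological_fraction = 0,
                              pathological_shift_sd = 4,
                              reporting_limit = 0,
                              gap_hours_range = c(144, 192),
                              morning_window = TRUE,
                              heteroscedastic_multiplier = 1,
                              affected_fraction = 0, seed = 1L) {
  stopifnot(mu_pop_original > 0, cv_g_pct >= 0, cv_i_pct >= 0, cv_a_pct >= 0,
            n_subjects >= 1, visits_per_subject >= 1, replicate_count >= 1,
            pathological_fraction >= 0, pathological_fraction < 1,
            reporting_limit >= 0, length(gap_hours_range) == 2L,
            gap_hours_range[1] <= gap_hours_range[2],
            heteroscedastic_multiplier >= 1,
            affected_fraction >= 0, affected_fraction <= 1)
  if (!identical(lambda_shape, "log") &&
      !(is.numeric(lambda_shape) && length(lambda_shape) == 1L &&
        is.finite(lambda_shape)))
    stop("`lambda_shape` must be \"log\" or a single numeric exponent",
         call. = FALSE)
  cfg <- list(mu_pop_original = mu_pop_original, cv_g_pct = cv_g_pct,
              cv_i_pct = cv_i_pct, cv_a_pct = cv_a_pct,
              lambda_shape = lambda_shape, n_subjects = as.integer(n_subjects),
              visits_per_subject = as.integer(visits_per_subject),
              replicate_count = as.integer(replicate_count),
              pathological_fraction = pathological_fraction,
              pathological_shift_sd = pathological_shift_sd,
              reporting_limit = reporting_limit,
              gap_hours_range = gap_hours_range,
              morning_window = morning_window,
              heteroscedastic_multiplier = heteroscedastic_multiplier,
              affected_fraction = affected_fraction, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# working-scale parameters implied by a config: exact lognormal conversion
# for the log shape, delta-method approximation for a Box-Cox shape
working_truth <- function(cfg) {
  if (identical(cfg$lambda_shape, "log")) {
    mu_w <- log(cfg$mu_pop_original)
    sg2 <- log(1 + cfg$cv_g_pct^2 / 1e4)
    si2 <- log(1 + cfg$cv_i_pct^2 / 1e4)
    sa2 <- log(1 + cfg$cv_a_pct^2 / 1e4)
    lambda <- 0
  } else {
    lambda <- cfg$lambda_shape
    mu_w <- boxcox(cfg$mu_pop_original, lambda)
    d <- cfg$mu_pop_original^(lambda - 1)   # transform derivative at the mean
    sg2 <- (cfg$cv_g_pct / 100 * cfg$mu_pop_original * d)^2
    si2 <- (cfg$cv_i_pct / 100 * cfg$mu_pop_original * d)^2
    sa2 <- (cfg$cv_a_pct / 100 * cfg$mu_pop_original * d)^2
  }
  tot <- sg2 + si2 + sa2
  list(mu_w = mu_w, sigma_g2 = sg2, sigma_i2 = si2, sigma_a2 = sa2,
       sigma_pop = sqrt(tot), b1 = if (tot > 0) sg2 / tot else 0,
       lambda = lambda)
}

#' Simulate a serial-results cohort
#'
#' Draws a cohort from the two-level hierarchical normal model on the
#' configured working scale: one set point per subject from
#' `N(mu_pop, sigma_G^2)`, each result from
#' `N(set point, sigma_I^2 + sigma_A^2)`, then back-transforms to the
#' original scale.  A `pathological_fraction` of subjects get their set
#' point shifted by `pathological_shift_sd` population SDs (persistent
#' pathology); an `affected_fraction` get their within-subject SD multiplied
#' (heteroscedasticity); results below the reporting limit are labelled
#' `below_limit`.  Collection timestamps step forward by uniform draws from
#' `gap_hours_range`, with the clock time placed in the 08:00--10:00 window
#' unless `morning_window = FALSE`.
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `synthetic_cohort`: list with `data` (data
#'   frame `subject_id`, `timestamp`, `value`, `pathological`,
#'   `below_limit`) and `truth` (the config, the working-scale parameters
#'   and the per-subject set points).  `as.data.frame()` returns the data
#'   with censored rows dropped by default.
#' @examples
#' coh <- simulate_cohort(simulation_config(seed = 42))
#' head(as.data.frame(coh))
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  wt <- working_truth(cfg)
  ns <- cfg$n_subjects; nv <- cfg$visits_per_subject
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  set_points <- rnorm(ns, wt$mu_w, sqrt(wt$sigma_g2))
  n_path <- round(cfg$pathological_fraction * ns)
  path_ids <- if (n_path > 0) sample(ns, n_path) else integer()
  set_points[path_ids] <- set_points[path_ids] +
    cfg$pathological_shift_sd * wt$sigma_pop
  n_het <- round(cfg$affected_fraction * ns)
  het_ids <- if (n_het > 0) sample(ns, n_het) else integer()
  sd_within <- rep(sqrt(wt$sigma_i2), ns)
  sd_within[het_ids] <- sd_within[het_ids] * cfg$heteroscedastic_multiplier
  sd_result <- sqrt(sd_within^2 + wt$sigma_a2)

  subj <- rep(seq_len(ns), each = nv)
  w <- rnorm(ns * nv, mean = set_points[subj], sd = sd_result[subj])
  value <- if (wt$lambda == 0) exp(w) else {
    base <- 1 + wt$lambda * w
    # working-scale draws below the transform image have no original-scale
    # counterpart; map them to the boundary (0)
    ifelse(base <= 0, 0, base^(1 / wt$lambda))
  }

  gaps <- matrix(runif(ns * nv, cfg$gap_hours_range[1],
                       cfg$gap_hours_range[2]), nrow = nv)
  elapsed <- apply(gaps, 2, cumsum)          # hours since start, per subject
  start <- as.POSIXct("2022-01-03 00:00:00", tz = "UTC")
  hours <- as.numeric(elapsed)               # column-major = visit within subject
  day <- floor(hours / 24)
  clock <- if (cfg$morning_window) runif(ns * nv, 8, 10)
           else runif(ns * nv, 0, 24)
  ts <- start + (day * 24 + clock) * 3600

  data <- data.frame(
    subject_id = sprintf("S%04d", subj),
    timestamp = ts,
    value = value,
    pathological = subj %in% path_ids,
    below_limit = value < cfg$reporting_limit
  )
  structure(
    list(data = data,
         truth = list(config = cfg, working = wt,
                      set_points = data.frame(
                        subject_id = sprintf("S%04d", seq_len(ns)),
                        set_point = set_points,
                        pathological = seq_len(ns) %in% path_ids,
                        heteroscedastic = seq_len(ns) %in% het_ids))),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic cohort: %d subjects x %d visits (%d rows)\n",
              cfg$n_subjects, cfg$visits_per_subject, nrow(x$data)))
  cat(sprintf("  CV_G = %s%%, CV_I = %s%%, CV_A = %s%%, true B1 = %s\n",
              format(cfg$cv_g_pct), format(cfg$cv_i_pct),
              format(cfg$cv_a_pct), format(x$truth$working$b1, digits = 4)))
  cat(sprintf("  pathological subjects: %d, censored results: %d\n",
              sum(x$truth$set_points$pathological), sum(x$data$below_limit)))
  invisible(x)
}

#' @export
#' @rdname simulate_cohort
#' @param x a `synthetic_cohort`.
#' @param include_censored keep rows below the reporting limit
#'   (default `FALSE`, mirroring laboratory practice of not reporting them).
#' @param ... unused.
as.data.frame.synthetic_cohort <- function(x, ...,
                                           include_censored = FALSE) {
  d <- x$data
  if (!include_censored) d <- d[!d$below_limit, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Simulate a balanced biological-variation study
#'
#' Generates the subjects x visits x replicates table of a designed study:
#' weekly sampling of every subject with analytical replicate noise at the
#' replicate level.  Optional engineered protocol violations exercise the
#' outlier cascade: a drifting subject (linear set-point drift over the
#' study) and a variance-inflated subject.
#'
#' @param cfg a [simulation_config()]; `replicate_count` sets the number of
#'   analytical replicates per sample.
#' @param drift_subject give subject 1 a linear drift totalling
#'   `drift_sd` within-subject SDs across the study.
#' @param drift_sd total drift magnitude, within-subject SDs (default 5).
#' @param variance_subject multiply the last subject's within-subject SD by
#'   `variance_multiplier`.
#' @param variance_multiplier SD inflation for that subject (default 4).
#' @return data frame `subject_id`, `visit`, `replicate`, `value` with the
#'   working-scale truth attached as attribute `truth`.
#' @export
simulate_bv_study <- function(cfg, drift_subject = FALSE, drift_sd = 5,
                              variance_subject = FALSE,
                              variance_multiplier = 4) {
  stopifnot(inherits(cfg, "sim_config"))
  wt <- working_truth(cfg)
  ns <- cfg$n_subjects; nv <- cfg$visits_per_subject
  nr <- cfg$replicate_count
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  set_points <- rnorm(ns, wt$mu_w, sqrt(wt$sigma_g2))
  sd_within <- rep(sqrt(wt$sigma_i2), ns)
  if (variance_subject) sd_within[ns] <- sd_within[ns] * variance_multiplier

  subj <- rep(seq_len(ns), each = nv)
  visit <- rep(seq_len(nv), times = ns)
  sample_level <- rnorm(ns * nv, 0, sd_within[subj])
  if (drift_subject) {
    drift <- drift_sd * sqrt(wt$sigma_i2) *
      (visit - (nv + 1) / 2) / (nv - 1)
    sample_level[subj == 1] <- sample_level[subj == 1] + drift[subj == 1]
  }
  w_sample <- set_points[subj] + sample_level

  idx <- rep(seq_len(ns * nv), each = nr)
  w <- w_sample[idx] + rnorm(ns * nv * nr, 0, sqrt(wt$sigma_a2))
  value <- if (wt$lambda == 0) exp(w) else {
    base <- 1 + wt$lambda * w
    ifelse(base <= 0, 0, base^(1 / wt$lambda))
  }
  out <- data.frame(
    subject_id = sprintf("S%02d", subj[idx]),
    visit = visit[idx],
    replicate = rep(seq_len(nr), times = ns * nv),
    value = value
  )
  attr(out, "truth") <- list(config = cfg, working = wt,
                             set_points = set_points)
  out
}

#' Simulate serial cohorts matched to a PEB parameter set
#'
#' Draws cohorts directly from the hierarchical model implied by a
#' [peb_parameters] object -- set points `N(mu_pop, b1 * sigma_pop^2)`,
#' results `N(set point, (1 - b1) * sigma_pop^2)` on the working scale,
#' back-transformed -- so that threshold calibration can be checked against
#' exactly matched generating conditions.
#'
#' @param object a [peb_parameters] object.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_subjects,visits design size per cohort (default 30 x 10, the
#'   layout of a typical biological-variation study).
#' @param ... unused.
#' @return a list of `nsim` data frames (`subject_id`, `timestamp`,
#'   `value`), each one cohort.
#' @export
simulate.peb_parameters <- function(object, nsim = 1, seed = NULL,
                                    n_subjects = 30, visits = 10, ...) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (!is.null(seed)) set.seed(seed)
  sg <- sqrt(object$b1) * object$sigma_pop
  si <- sqrt(1 - object$b1) * object$sigma_pop
  start <- as.POSIXct("2022-01-03 09:00:00", tz = "UTC")
  lapply(seq_len(nsim), function(i) {
    mu_i <- rnorm(n_subjects, object$mu_pop, sg)
    subj <- rep(seq_len(n_subjects), each = visits)
    w <- rnorm(n_subjects * visits, mu_i[subj], si)
    data.frame(
      subject_id = sprintf("S%04d", subj),
      timestamp = start + rep(seq_len(visits) - 1, times = n_subjects) *
        7 * 24 * 3600,
      value = from_working(w, object)
    )
  })
}
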