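make_bc_sample <- function(n, lambda, mu, sigma, seed) {
  set.seed(seed)
  w <- rnorm(n, mu, sigma)
  if (lambda == 0) exp(w) else (1 + lambda * w)^(1 / lambda)
}

test_that("population fit recovers Box-Cox-normal generating parameters", {
  x <- make_bc_sample(20000, 0.5, 10, 2, seed = 11)
  fit <- fit_population(x)
  expect_lt(abs(fit$lambda - 0.5) / 0.5, 0.10)
  expect_lt(abs(fit$mu_pop - 10) / 10, 0.10)
  expect_lt(abs(fit$sigma_pop - 2) / 2, 0.10)
  expect_equal(fit$central99_bounds,
               c(fit$mu_pop - 2.5758 * fit$sigma_pop,
                 fit$mu_pop + 2.5758 * fit$sigma_pop))
  expect_equal(fit$n_used, 20000)
})

test_that("population fit identifies a lognormal shape", {
  x <- exp(rnorm(20000, 1.5, 0.4))
  fit <- fit_population(x)
  expect_lt(abs(fit$lambda - 0), 0.15)
  expect_lt(abs(fit$mu_pop - 1.5), 0.1)
})

test_that("central-peak fit resists pathological contamination", {
  set.seed(13)
  clean <- rnorm(16000, 10, 2)
  x <- c(clean, rnorm(4000, 18, 2))       # 20% shifted pathological values
  fit <- suppressWarnings(fit_population(x, lambda_grid = seq(0.3, 1.5, 0.02)))
  # compare on the original scale (back-transformed centers), where the
  # naive moment fit of the full mixture is the benchmark
  center_robust <- if (fit$lambda == 0) exp(fit$mu_pop) else
    (1 + fit$lambda * fit$mu_pop)^(1 / fit$lambda)
  expect_lt(abs(center_robust - 10), abs(mean(x) - 10))
  expect_lt(abs(center_robust - 10) / 10, 0.10)
})

test_that("population fit refuses degenerate or undersized input", {
  expect_error(fit_population(rnorm(100, 10) + 10), "500")
  expect_error(suppressWarnings(fit_population(rep(2, 1000))),
               "degenerate|identical")
  expect_warning(fit_population(exp(rnorm(600, 1, 0.2))), "5000")
  expect_error(fit_population(c(-1, rep(2, 999))), "positive")
})

test_that("central-99% filter keeps exactly the central mass", {
  fit <- structure(list(mu_pop = 9, sigma_pop = 1, lambda = 1,
                        central99_bounds = c(9 - 2.5758, 9 + 2.5758)),
                   class = "population_fit")
  # lambda = 1 shifts by 1: working value t = x - 1
  expect_equal(central99_filter(10, fit), 10)         # exactly at mu_pop
  expect_length(central99_filter(13 + 1e-6, fit), 0)  # 3 sigma out
  set.seed(5)
  x <- rnorm(50000, 10, 1)
  frac <- length(central99_filter(x, fit)) / length(x)
  expect_equal(frac, 0.99, tolerance = 3 * sqrt(0.99 * 0.01 / 50000) / 0.99)
  # order preserved
  xs <- c(10.5, 9.4, 10.2)
  expect_equal(central99_filter(xs, fit), xs)
})

test_that("sequential pairs respect the gap rule and overlap", {
  h <- function(x) as.POSIXct("2022-01-01", tz = "UTC") + x * 3600
  d1 <- data.frame(subject_id = "a", timestamp = h(c(0, 12)), value = c(1, 2))
  expect_equal(nrow(build_pairs(d1)), 0)
  d2 <- data.frame(subject_id = "a", timestamp = h(c(0, 48, 96)),
                   value = c(1, 2, 3))
  p2 <- build_pairs(d2)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$x_prev, c(1, 2))
  expect_equal(p2$x_next, c(2, 3))
  # mixed gaps: only qualifying consecutive pairs survive
  d3 <- data.frame(subject_id = "a", timestamp = h(c(0, 10, 50)),
                   value = c(1, 2, 3))
  p3 <- build_pairs(d3)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$x_prev, 2)
  # 100 subjects x 3 results, all gaps > 24 h -> 200 pairs
  big <- data.frame(subject_id = rep(sprintf("s%03d", 1:100), each = 3),
                    timestamp = h(rep(c(0, 48, 96), 100)),
                    value = rnorm(300))
  expect_equal(nrow(build_pairs(big)), 200)
  # unsorted input is an error, never silently reordered
  bad <- data.frame(subject_id = "a", timestamp = h(c(48, 0)), value = 1:2)
  expect_error(build_pairs(bad), "sorted")
})

test_that("robust slope recovers the intraclass correlation", {
  expect_error(robust_slope(data.frame(x_prev = 1, x_next = 1)), "2")
  expect_error(robust_slope(data.frame(x_prev = rep(1, 200),
                                       x_next = rnorm(200))), "variance")
  # identity data
  d <- data.frame(x_prev = seq(1, 5, length.out = 200),
                  x_next = seq(1, 5, length.out = 200))
  fit <- robust_slope(d, n_boot = 0)
  expect_equal(fit$slope, 1, tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_true(fit$converged)
  # simulated pairs with true B1 = 0.7
  pr <- draw_pairs(10000, 0.7, seed = 21)
  fit2 <- robust_slope(pr, n_boot = 0)
  expect_lt(abs(fit2$slope - 0.7), 0.03)
  # bootstrap CI brackets the estimate
  fit3 <- robust_slope(pr[1:2000, ], n_boot = 99, seed = 4)
  expect_true(fit3$ci95[1] <= fit3$slope && fit3$slope <= fit3$ci95[2])
})

test_that("robust slope resists gross outlier pairs better than OLS", {
  pr <- draw_pairs(4000, 0.7, seed = 31)
  set.seed(32)
  bad <- sample(nrow(pr), 400)             # 10% gross contamination
  # gross outlier pairs: x_next replaced by values unrelated to x_prev,
  # which attenuates the least-squares slope
  pr$x_next[bad] <- rnorm(length(bad), mean(pr$x_next) + 5, 1)
  rob <- robust_slope(pr, n_boot = 0)$slope
  ols <- unname(coef(lm(x_next ~ x_prev, data = pr))[2])
  expect_lt(abs(rob - 0.7), abs(ols - 0.7))
})

test_that("LIS pipeline recovers parameters end to end with an audit trail", {
  cfg <- config_for_b1(0.7, n_subjects = 2000, visits_per_subject = 3,
                       seed = 41)
  coh <- simulate_cohort(cfg)
  fit <- suppressWarnings(fit_peb_lis(as.data.frame(coh), n_boot = 0))
  expect_s3_class(fit, "peb_lis_fit")
  expect_s3_class(fit, "peb_parameters")
  expect_lt(abs(fit$b1 - 0.7), 0.05)
  # back-transformed center close to the generating mean
  center <- boxcox_inverse(fit$mu_pop, fit$lambda)
  expect_lt(abs(center - 10) / 10, 0.05)
  # audit conservation: excluded + retained = input at every stage
  a <- fit$audit
  expect_true(all(a$n_excluded + a$n_retained == a$n_in))
  expect_true(all(diff(a$n_retained[a$stage != "first_results"]) <= 0))
  # determinism: identical input and seed give identical parameters
  fit2 <- suppressWarnings(fit_peb_lis(as.data.frame(coh), n_boot = 0))
  expect_identical(coef(fit), coef(fit2))
})

test_that("pipeline applies reporting-limit and diurnal filters", {
  cfg <- config_for_b1(0.6, n_subjects = 4000, visits_per_subject = 3,
                       morning_window = FALSE, seed = 43)
  d <- as.data.frame(simulate_cohort(cfg))
  fit <- suppressWarnings(
    fit_peb_lis(d, reporting_limit = 7, diurnal_window = c("08:00", "10:00"),
                n_boot = 0))
  a <- fit$audit
  expect_gt(a$n_excluded[a$stage == "reporting_limit"], 0)
  expect_gt(a$n_excluded[a$stage == "diurnal_window"], 0)
})

test_that("pipeline refuses B1 when no sequential pairs exist", {
  cfg <- config_for_b1(0.6, n_subjects = 1000, visits_per_subject = 1,
                       seed = 47)
  d <- as.data.frame(simulate_cohort(cfg))
  expect_error(suppressWarnings(fit_peb_lis(d, n_boot = 0)),
               "result_pairs.*B1 cannot be estimated")
  expect_error(fit_peb_lis(d[0, ]), "empty")
  expect_error(fit_peb_lis(data.frame(x = 1)), "missing required column")
})

test_that("slope recovery holds across the intraclass correlation range", {
  for (b1 in c(0.3, 0.9)) {
    pr <- draw_pairs(5000, b1, seed = round(1000 * b1))
    fit <- robust_slope(pr, n_boot = 0)
    expect_lt(abs(fit$slope - b1), 0.05)
  }
})
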