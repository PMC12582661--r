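test_that("shrinkage factor matches its closed form and boundary cases", {
  expect_identical(shrinkage_factor(0.66, 0), 0)
  expect_equal(shrinkage_factor(0.5, 1), 0.5)
  expect_equal(shrinkage_factor(0.66, 9), 0.94586, tolerance = 1e-5)
  expect_identical(shrinkage_factor(1, 0), 0)
  expect_equal(shrinkage_factor(1, 3), 1)
  expect_error(shrinkage_factor(1.2, 1), "b1")
  expect_error(shrinkage_factor(0.5, -1), "non-negative")
  expect_error(shrinkage_factor(0.5, 1.5), "integer")
})

test_that("shrinkage agrees with the variance-ratio form and is monotone", {
  set.seed(42)
  for (i in 1:1000) {
    b1 <- runif(1, 0.01, 0.99)
    n <- sample(0:50, 1)
    ratio <- b1 / (1 - b1)               # sigma_G^2 / sigma_I^2
    expected <- if (n == 0) 0 else ratio / (ratio + 1 / n)
    expect_equal(shrinkage_factor(b1, n), expected, tolerance = 1e-12)
  }
  bn <- shrinkage_factor(0.3, 0:30)
  expect_true(all(diff(bn) > 0))
  expect_true(all(bn >= 0 & bn <= 1))
})

test_that("posterior mean is the stated weighted average", {
  p <- albumin_lis_params()
  expect_equal(posterior_mean(99, p, 0), 3.181)   # x_bar ignored at n = 0
  expect_equal(posterior_mean(NULL, p, 0), 3.181)
  expect_equal(posterior_mean(3.5, p, 1), 3.39154, tolerance = 1e-10)
  # full weight on the individual mean in the b1 -> 1 limit
  p1 <- peb_parameters(0, 1, 1, scale = "log")
  expect_equal(posterior_mean(2.5, p1, 1), 2.5)
  expect_error(posterior_mean(NULL, p, 1), "x_bar")
  # always between mu_pop and x_bar
  set.seed(7)
  for (i in 1:50) {
    b1 <- runif(1); xb <- rnorm(1, 3.181, 1); n <- sample(1:20, 1)
    pp <- peb_parameters(3.181, 0.241, b1, scale = "boxcox", lambda = 0.89)
    y <- posterior_mean(xb, pp, n)
    expect_true(y >= min(3.181, xb) - 1e-12 && y <= max(3.181, xb) + 1e-12)
  }
})

test_that("prediction half-width hits its limiting cases and narrows with n", {
  p <- albumin_lis_params()
  expect_equal(prediction_halfwidth(p, 0), 0.47236, tolerance = 1e-5)
  sigma_i <- sqrt(1 - p$b1) * p$sigma_pop
  expect_equal(prediction_halfwidth(p, 1e6), 1.96 * sigma_i,
               tolerance = 1e-6)
  p0 <- peb_parameters(0, 0.241, 0, scale = "log")
  expect_equal(prediction_halfwidth(p0, 25), 1.96 * 0.241)
  hw <- prediction_halfwidth(p, 0:20)
  expect_true(all(diff(hw) < 0))
  expect_true(all(hw[-1] < prediction_halfwidth(p, 0)))
})

test_that("thresholds compose the formulae and back-transform correctly", {
  p <- albumin_lis_params()
  # population interval: back-transformed mu_pop +/- Z sigma_pop
  th0 <- peb_threshold(numeric(), p, n_use = 0)
  expect_equal(th0$lower, boxcox_inverse(3.181 - 1.96 * 0.241, 0.89))
  expect_equal(th0$upper, boxcox_inverse(3.181 + 1.96 * 0.241, 0.89))
  expect_equal(th0$y_hat, 3.181)
  expect_true(th0$lower < th0$upper)
  # b1 -> 1 with one prior: interval centered at that value on working scale
  p1 <- peb_parameters(1.0, 0.3, 1, scale = "log")
  v <- 3.7
  th1 <- peb_threshold(v, p1, n_use = 1)
  expect_equal(th1$y_hat, log(v))
  expect_equal(sqrt(th1$lower * th1$upper), v, tolerance = 1e-10)
  # three identical values at the back-transformed population mean
  v0 <- boxcox_inverse(3.181, 0.89)
  th3 <- peb_threshold(rep(v0, 3), p, n_use = 3)
  b3 <- shrinkage_factor(0.66, 3)
  hw3 <- 1.96 * sqrt(1 - 0.66 * b3) * 0.241
  expect_equal(th3$y_hat, 3.181, tolerance = 1e-10)
  expect_equal(th3$lower, boxcox_inverse(3.181 - hw3, 0.89))
  expect_equal(th3$upper, boxcox_inverse(3.181 + hw3, 0.89))
  # errors: short history, non-positive value under log scale
  expect_error(peb_threshold(numeric(), p, n_use = 1), "history")
  plog <- peb_parameters(1, 0.2, 0.5, scale = "log")
  expect_error(peb_threshold(-1, plog, n_use = 1), "positive")
})

test_that("decision flags strictly outside the limits only", {
  p <- bv_row_params(bv_rows$albumin)
  th <- peb_threshold(numeric(), p, n_use = 0)
  expect_false(peb_decision(th$lower, th)$flagged)   # on the boundary
  expect_false(peb_decision(th$upper, th)$flagged)
  expect_true(peb_decision(th$upper * 1.001, th)$flagged)
  expect_true(peb_decision(th$lower * 0.999, th)$flagged)
  d <- predict(p, history = c(4.4, 4.5), x_next = 20)
  expect_true(d$flagged)
  expect_equal(d$n_prior, 2L)
})

test_that("Box-Cox transform pair round-trips and guards its domain", {
  expect_equal(boxcox(1, 0.3), 0)
  expect_equal(boxcox(1, 0), 0)
  expect_equal(boxcox(exp(1), 0), 1)
  expect_equal(boxcox_inverse(boxcox(2.7, 0.89), 0.89), 2.7,
               tolerance = 1e-10)
  set.seed(3)
  for (i in 1:100) {
    l <- runif(1, -1, 2); x <- runif(1, 0.01, 50)
    expect_equal(boxcox_inverse(boxcox(x, l), l), x, tolerance = 1e-10)
  }
  expect_error(boxcox(0, 0.5), "positive")
  expect_error(boxcox(-2, 0), "positive")
  expect_error(boxcox_inverse(-10, 0.5), "image")
})

test_that("classic RCV interval follows the log-normal formula", {
  expect_equal(unname(classic_rcv_interval(0, 0, 10)), c(10, 10))
  lim <- classic_rcv_interval(23.0, 4.8, 60, 1.96)
  hw <- 1.96 * sqrt(2) * sqrt(log(1 + (23^2 + 4.8^2) / 1e4))
  expect_equal(log(lim[["upper"]] / 60), hw, tolerance = 1e-10)
  expect_equal(log(60 / lim[["lower"]]), hw, tolerance = 1e-10)
  # ratio of limits independent of the baseline
  r1 <- classic_rcv_interval(12, 3, 10)
  r2 <- classic_rcv_interval(12, 3, 100)
  expect_equal(r1[["upper"]] / r1[["lower"]], r2[["upper"]] / r2[["lower"]])
  expect_error(classic_rcv_interval(-1, 2, 10), "non-negative")
})

test_that("PEB result-pair interval is narrower than the classic RCV", {
  # sqrt(1 - B1^2) * sigma_pop < sqrt(2) * sigma_I whenever sigma_G > 0
  grid <- expand.grid(sg = seq(0.02, 1, length.out = 25),
                      si = seq(0.02, 1, length.out = 25))
  b1 <- grid$sg^2 / (grid$sg^2 + grid$si^2)
  sigma_pop <- sqrt(grid$sg^2 + grid$si^2)
  expect_true(all(sqrt(1 - b1^2) * sigma_pop < sqrt(2) * grid$si))
})

test_that("prediction intervals achieve nominal conditional coverage", {
  # Monte-Carlo draws from the hierarchical model: the bound on
  # |X_{n+1} - Y_hat| should be exceeded in ~5% of draws for every n
  p <- peb_parameters(0, 0.241, 0.66, scale = "log")
  sg <- sqrt(p$b1) * p$sigma_pop
  si <- sqrt(1 - p$b1) * p$sigma_pop
  n_draw <- 1e5
  for (n in c(0L, 1L, 5L, 9L)) {
    set.seed(100 + n)
    mu_i <- rnorm(n_draw, 0, sg)
    x_next <- rnorm(n_draw, mu_i, si)
    x_bar <- if (n > 0) rnorm(n_draw, mu_i, si / sqrt(n)) else 0
    y_hat <- shrinkage_factor(p$b1, n) * x_bar
    exceed <- abs(x_next - y_hat) > prediction_halfwidth(p, n)
    expect_equal(mean(exceed), 0.05,
                 tolerance = 3 * sqrt(0.05 * 0.95 / n_draw) / 0.05)
  }
})

test_that("parameter container validates and clips as documented", {
  expect_error(peb_parameters(1, -1, 0.5, scale = "log"), "sigma_pop")
  expect_error(peb_parameters(1, 1, 0.5, scale = "boxcox"), "lambda")
  expect_error(peb_parameters(1, 1, 1.5, scale = "log"), "b1")
  expect_warning(p <- peb_parameters(1, 1, 1.04, scale = "log"), "clipped")
  expect_equal(p$b1, 1)
  p2 <- peb_parameters(1, 2, 0.3, scale = "log")
  expect_equal(p2$b1 * p2$sigma_pop^2 + (1 - p2$b1) * p2$sigma_pop^2,
               p2$sigma_pop^2)
  expect_equal(unname(coef(p2)), c(1, 2, 0.3, 0))
})
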