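test_that("describe reproduces hand-computed survey statistics", {
  d <- describe(c(2, 4, 6))
  expect_equal(d$mean, 4)
  expect_equal(d$range, 4)
  expect_equal(d$variance, 4)   # sample (n-1) denominator
  expect_equal(d$sd, 2)
  expect_equal(d$minimum, 2)
  expect_equal(d$maximum, 6)
  expect_equal(describe(c(-1, 0, 1))$skewness, 0)
  # excess-kurtosis convention: a flat symmetric vector is platykurtic (< 0)
  expect_lt(describe(c(1, 2, 3, 4))$kurtosis, 0)
  expect_error(describe(c(1)), "n >= 2")
  expect_error(describe(c(1, NA, 3)), "non-finite")
  expect_error(describe(rep(5, 4)), "zero-variance")
  flagged <- describe(rep(5, 4), strict = FALSE)
  expect_true(flagged$zero_variance)
  expect_true(is.na(flagged$skewness))
})

test_that("describe is order-invariant and shift/scale equivariant", {
  withr::with_seed(8, x <- rnorm(40, 10, 3))
  a <- describe(x); b <- describe(sample(x))
  expect_equal(a, b)
  shifted <- describe(2 * x + 7)
  expect_equal(shifted$mean, 2 * a$mean + 7)
  expect_equal(shifted$sd, 2 * a$sd)
  expect_equal(shifted$skewness, a$skewness)
  expect_equal(shifted$kurtosis, a$kurtosis)
})

test_that("fit_polynomial recovers exact polynomials and the OLS closed form", {
  x <- 1:10
  # suppress summary.lm's perfect-fit warning: the data are exact by design
  f1 <- suppressWarnings(fit_polynomial(x, 2 * x + 1, degree = 1))
  expect_equal(unname(f1$coefficients), c(1, 2))
  expect_equal(f1$r_squared, 1)

  x2 <- -2:2
  f2 <- suppressWarnings(fit_polynomial(x2, x2^2, degree = 2))
  expect_equal(unname(f2$coefficients), c(0, 0, 1), tolerance = 1e-10)

  # independent closed-form OLS oracle for degree 1
  withr::with_seed(13, { xr <- runif(25, 0, 10); yr <- 3 - 0.5 * xr + rnorm(25) })
  fr <- fit_polynomial(xr, yr, degree = 1)
  slope <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  intercept <- mean(yr) - slope * mean(xr)
  expect_equal(fr$coefficients[["b1"]], slope, tolerance = 1e-10)
  expect_equal(fr$coefficients[["b0"]], intercept, tolerance = 1e-10)
  expect_equal(fr$r_squared, stats::cor(xr, yr)^2, tolerance = 1e-10)

  expect_error(fit_polynomial(1:3, 1:3, degree = 2), "n > degree")
  expect_error(fit_polynomial(rep(1, 10), rnorm(10), degree = 1),
               "rank deficiency")
  expect_error(fit_polynomial(1:4, 1:3, degree = 1), "length")
})

test_that("polynomial fits satisfy orthogonality and nested-R2 properties", {
  withr::with_seed(99, { x <- runif(30, -3, 3); y <- 1 + x - 0.3 * x^2 + rnorm(30) })
  f2 <- fit_polynomial(x, y, degree = 2)
  for (p in 0:2) expect_lt(abs(sum(f2$residuals * x^p)), 1e-8)
  f3 <- fit_polynomial(x, y, degree = 3)
  expect_gte(f3$r_squared, f2$r_squared)
  expect_equal(predict_polynomial(f2, x), f2$fitted, tolerance = 1e-10)
})

test_that("a linear synthetic phenology trend is recovered within its CI", {
  withr::with_seed(4, {
    year <- 1980:2020
    dta <- 130 - 1.4 * (year - 1980) + rnorm(41, 0, 4)
  })
  f <- fit_polynomial(year, dta, degree = 1)
  se <- summary(f$model)$coefficients[2, 2]
  expect_lt(abs(f$coefficients[["b1"]] - (-1.4)), 2.5 * se)
})

test_that("decadal_summary groups like a manual split", {
  years <- 1980:1989
  expect_equal(decadal_summary(years, rep(5, 10), edges = c(1980, 1990))$mean, 5)
  expect_identical(decadal_summary(years, rep(5, 10),
                                   edges = c(1980, 1990))$value_range, "5-5")

  # linear decline 133 -> 74 over 41 seasons: endpoint containment by decade
  yr <- 1980:2020
  v <- seq(133, 74, length.out = 41)
  d <- decadal_summary(yr, v, edges = c(1980, 1990, 2000, 2010, 2021))
  expect_equal(d$max[1], 133)
  expect_equal(d$min[4], 74)
  expect_identical(d$n, c(10L, 10L, 10L, 11L))

  # brute-force group-by oracle on two decades
  withr::with_seed(3, vals <- rnorm(20))
  got <- decadal_summary(2000:2019, vals, edges = c(2000, 2010, 2020))
  expect_equal(got$mean, c(mean(vals[1:10]), mean(vals[11:20])))
  expect_equal(got$min, c(min(vals[1:10]), min(vals[11:20])))

  # empty decades flagged, not dropped
  e <- decadal_summary(c(1981, 2015), c(1, 2),
                       edges = c(1980, 1990, 2000, 2010, 2021))
  expect_identical(e$empty, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(nrow(e), 4L)
})

test_that("pearson_matrix matches a brute-force covariance computation", {
  withr::with_seed(17, {
    tab <- as.data.frame(matrix(rnorm(5 * 12), ncol = 5,
                                dimnames = list(NULL, letters[1:5])))
  })
  m <- pearson_matrix(tab)
  expect_equal(diag(m), setNames(rep(1, 5), letters[1:5]))
  expect_equal(m, t(m))
  brute <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:5) for (j in 1:5) {
    expect_equal(m[i, j], brute(tab[[i]], tab[[j]]), tolerance = 1e-12)
  }
  expect_equal(unname(pearson_matrix(data.frame(x = 1:5, y = -(1:5)))[1, 2]), -1)
  tab$f <- 1
  expect_error(pearson_matrix(tab), "f")
})
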