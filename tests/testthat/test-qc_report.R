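test_that("summarize_cnr reproduces hand-computed and brute-force summaries", {
  res <- list(fake_result(5, 2), fake_result(6, 2), fake_result(7, 2))
  s <- summarize_cnr(res, "demo")
  expect_equal(s$mean_contrast, 6)
  expect_equal(s$sd_contrast, 1)
  expect_equal(s$mean_cnr, mean(c(2.5, 3, 3.5)))
  expect_equal(s$sd_cnr, sd(c(2.5, 3, 3.5)))

  one <- summarize_cnr(list(fake_result(6, 3)), "single")
  expect_true(one$n1)
  expect_equal(one$sd_cnr, 0)

  expect_error(summarize_cnr(list()), "empty")
})

test_that("percent difference uses the reference series denominator", {
  a <- summarize_cnr(list(fake_result(5.6, 2), fake_result(5.6, 2)), "auto")
  b <- summarize_cnr(list(fake_result(5.2, 2), fake_result(5.2, 2)), "manual")
  expect_equal(percent_difference(a, b, "contrast"),
               abs(5.6 - 5.2) / 5.2 * 100)
  expect_equal(percent_difference(a, a, "cnr"), 0)

  z <- summarize_cnr(list(fake_result(0, 2), fake_result(0, 2)), "zero")
  expect_error(percent_difference(a, z, "contrast"), "reference mean is zero")
})

test_that("Mann-Whitney U matches hand values on the canonical cases", {
  tie <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tie$u_statistic, 4.5)
  expect_equal(tie$p_value, 1)

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_statistic, 0)
  expect_equal(sep$p_value, 0.1)

  expect_error(mann_whitney_u(1, c(1, 2)), "at least 2")
})

test_that("exact Mann-Whitney p equals full enumeration on random small samples", {
  set.seed(301)
  for (k in 1:12) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(stats::rnorm(nx, 5, 2), 1)
    y <- round(stats::rnorm(ny, 6, 2), 1)
    got <- mann_whitney_u(x, y)
    expect_equal(got$u_statistic, brute_mw_u(x, y))
    expect_equal(got$p_value, brute_mw_p(x, y))
  }
})

test_that("Mann-Whitney agrees with wilcox.test and is symmetric", {
  set.seed(302)
  for (k in 1:8) {
    x <- stats::rnorm(5); y <- stats::rnorm(6)  # continuous: no ties
    got <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
    swapped <- mann_whitney_u(y, x)
    expect_equal(swapped$u_statistic, length(x) * length(y) - got$u_statistic)
    expect_equal(swapped$p_value, got$p_value)
  }
})

test_that("exact and normal-approximation paths agree for n = 6 + 6", {
  set.seed(303)
  for (k in 1:6) {
    x <- stats::rnorm(6); y <- stats::rnorm(6, 0.5)
    exact <- mann_whitney_u(x, y)$p_value
    approx <- mann_whitney_u(x, y, exact_limit = 0L)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("ACR tolerance check passes at and above a mean CNR of 1.0", {
  mk <- function(cnr) summarize_cnr(list(fake_result(cnr * 2, 2),
                                         fake_result(cnr * 2, 2)), "")
  expect_true(acr_tolerance_check(mk(2.4))$pass)
  expect_true(acr_tolerance_check(mk(1.0))$pass)
  expect_false(acr_tolerance_check(mk(0.1))$pass)
})

test_that("series comparison reports percent difference and significance", {
  set.seed(304)
  a <- summarize_cnr(lapply(stats::rnorm(6, 2.8, 0.1), fake_result, noise = 1), "auto")
  b <- summarize_cnr(lapply(stats::rnorm(6, 2.6, 0.1), fake_result, noise = 1), "manual")
  cmp <- compare_series(a, b, "cnr")
  expect_equal(cmp$percent_difference,
               abs(a$mean_cnr - b$mean_cnr) / b$mean_cnr * 100)
  expect_gte(cmp$p_value, 0)
  expect_lte(cmp$p_value, 1)
  expect_identical(cmp$significant, cmp$p_value < 0.05)
  expect_output(print(cmp), "percent difference")
})

test_that("CSV report round-trips losslessly", {
  set.seed(305)
  res <- lapply(1:5, function(k) fake_result(stats::rnorm(1, 6, 0.5),
                                             stats::rnorm(1, 3, 0.2)))
  s <- summarize_cnr(res, "120 kV")
  path <- tempfile(fileext = ".csv")
  write_cnr_csv(s, path)
  back <- read_cnr_csv(path)
  expect_equal(back$label, "120 kV")
  expect_identical(back$per_slice$cnr, s$per_slice$cnr)
  expect_identical(back$mean_cnr, s$mean_cnr)
  expect_identical(back$sd_noise, s$sd_noise)
})
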