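# Ejection-fraction arithmetic, cohort summaries and the exact test.

test_that("ejection fraction reproduces the printed per-patient values", {
  expect_equal(ejection_fraction(406.91, 254.49), 37.46, tolerance = 1e-4)
  expect_equal(ejection_fraction(204.64, 113.82), 44.38, tolerance = 1e-4)
  expect_equal(ejection_fraction(100, 100), 0)
  # scale invariance
  expect_equal(ejection_fraction(2 * 406.91, 2 * 254.49),
               ejection_fraction(406.91, 254.49))
  expect_error(ejection_fraction(100, 120), "esv exceeds")
  # whole cohort table at printed (1-decimal) precision
  t1 <- load_reference_table("cohort")
  expect_equal(round(ejection_fraction(t1$rv_edv_ml, t1$rv_esv_ml), 1),
               t1$rv_ef_pct, tolerance = 0.051)
})

test_that("delta EF is a sign-preserving difference", {
  expect_equal(delta_ef(41.58, 37.38), 4.20)
  expect_equal(delta_ef(33.78, 37.38), -3.60)
  expect_equal(delta_ef(40, 40), 0)
})

test_that("cohort mean/SD reproduce the printed summary rows", {
  t1 <- load_reference_table("cohort")
  s <- summarize_mean_sd(t1$rv_ef_pct)
  expect_equal(unname(s["mean"]), 39.00, tolerance = 1e-8)
  expect_equal(unname(s["sd"]), 5.53, tolerance = 0.005)
  t4 <- load_reference_table("plans20")
  e <- t4[t4$plan == "E", ]
  expect_equal(unname(summarize_mean_sd(e$ef_pct)["mean"]), 42.90,
               tolerance = 0.02)
  expect_equal(unname(summarize_mean_sd(e$delta_ef_pct)["mean"]), 4.19,
               tolerance = 0.02)
  expect_equal(unname(summarize_mean_sd(rep(3, 5))["sd"]), 0)
  expect_error(summarize_mean_sd(numeric(0)), "empty")
})

test_that("simpson volume matches closed forms and converges at order >= 2", {
  # cylinder r = 20, h = 60
  z <- seq(0, 60, length.out = 21)
  expect_equal(simpson_volume(rep(pi * 400, 21), z), pi * 400 * 60 / 1000,
               tolerance = 1e-10)
  # half-ellipsoid a=b=20, c=50 sampled over z in [0, c)
  half <- function(n) {
    z <- seq(0, 49.9999, length.out = n)
    a <- pi * 400 * (1 - (z / 50)^2)
    simpson_volume(a, z)
  }
  vtrue <- 0.5 * 4 / 3 * pi * 400 * 50 / 1000
  expect_equal(half(21), vtrue, tolerance = 0.005 * vtrue)
  # refinement on a non-polynomial profile: order >= 2 (error ratio >= 4)
  bump <- function(n) {
    z <- seq(0, 1, length.out = n)
    simpson_volume(1e3 * exp(2 * z), z)
  }
  vref <- (exp(2) - 1) / 2
  e1 <- abs(bump(11) - vref); e2 <- abs(bump(21) - vref)
  expect_lt(e2, e1 / 4)
  expect_error(simpson_volume(c(1, 2), c(0, 1)), "3 slices")
  expect_error(simpson_volume(rep(1, 4), c(0, 1, 0.5, 2)), "increasing")
})

test_that("max principal value is the largest eigenvalue, rotation-invariant", {
  expect_equal(max_principal(diag(c(3, 1, -2))), 3)
  expect_equal(max_principal(matrix(0, 3, 3)), 0)
  set.seed(42)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(max_principal(q %*% diag(c(3, 1, -2)) %*% t(q)), 3,
                 tolerance = 1e-10)
  }
  expect_error(max_principal(matrix(rnorm(9), 3)), "symmetric")
})

test_that("exact Wilcoxon matches brute-force enumeration and wilcox.test", {
  # all-positive differences, n = 7: p = 2 / 2^7
  post <- c(41.58, 40.46, 33.58, 45.40, 46.28, 51.75, 41.29)
  pre <- post - c(4.20, 3.02, 3.98, 5.16, 6.01, 2.87, 4.21)
  res <- wilcoxon_signed_rank_exact(post, pre)
  expect_equal(res$p.value, 2 / 2^7)
  expect_equal(res$statistic, 28)
  # identical samples
  expect_warning(r0 <- wilcoxon_signed_rank_exact(1:5, 1:5), "zero")
  expect_equal(r0$p.value, 1)
  # random paired data vs brute force and stats::wilcox.test
  set.seed(7)
  for (n in c(5, 8, 10)) {
    a <- rnorm(n); b <- rnorm(n)
    r <- wilcoxon_signed_rank_exact(a, b)
    expect_equal(r$p.value, wilcoxon_brute(a, b), tolerance = 1e-12)
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(r$p.value, wt$p.value, tolerance = 1e-12)
  }
  # null distribution sums to 1 implicitly: p for extreme stat is 2/2^n
  a <- 1:7; b <- rep(0, 7)
  expect_equal(wilcoxon_signed_rank_exact(a, b)$p.value, 2 / 2^7)
})

test_that("baseline EF reconstruction is consistent across plan tables", {
  base <- baseline_ef_from_tables()
  t4 <- load_reference_table("plans20")
  a <- t4[t4$plan == "A", ]
  expect_equal(unname(base[a$patient]), a$ef_pct - a$delta_ef_pct,
               tolerance = 0.011)
  expect_equal(unname(summarize_mean_sd(base)["mean"]), 38.71,
               tolerance = 0.02)
})
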