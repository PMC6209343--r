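test_that("zero-age augmentation appends exactly the requested records", {
  d <- curve_data("vb", 26, 58, 1.98)
  d$length <- d$length + 0.1 # not used; just any data
  n0 <- nrow(d)
  a <- augment_with_zero_age(d, 26, 4)
  expect_equal(nrow(a), n0 + 4)
  expect_equal(a[seq_len(n0), c("age", "length")], d[, c("age", "length")])
  expect_true(all(a$age[(n0 + 1):(n0 + 4)] == 0))
  expect_true(all(a$length[(n0 + 1):(n0 + 4)] == 26))
  expect_identical(augment_with_zero_age(d, 26, 0), d)
  # 186 real fish plus four hypothetical newborns: the augmented n of 190
  d186 <- data.frame(age = runif(186, 0.2, 4.6), length = runif(186, 31, 66))
  expect_equal(nrow(augment_with_zero_age(d186, 26, 4)), 190)
})

test_that("noise-free curves are recovered near-exactly by every strategy", {
  d <- curve_data("vb", 26, 58, 1.98)
  f3 <- fit_growth(d, family = "vb", strategy = "three_param")
  expect_equal(unname(coef(f3)[c("L0", "Linf", "coeff")]), c(26, 58, 1.98),
               tolerance = 1e-6)
  f2 <- fit_growth(d, family = "vb", strategy = "two_param_fixed_L0",
                   fixed_L0_value = 26)
  # the fixed-L0 constraint is inactive on data generated at L0 = 26
  expect_equal(unname(coef(f2)), c(58, 1.98), tolerance = 1e-6)
  expect_equal(f2$params$L0, 26)
})

test_that("the three-parameter fit never has larger RSS than the nested two-parameter fit", {
  set.seed(99)
  for (fam in c("vb", "logistic", "gompertz")) {
    d <- curve_data(fam, 26, 58, 1.8)
    d$length <- d$length + rnorm(nrow(d), 0, 4)
    f3 <- fit_growth(d, spec = model_spec(fam, "three_param"))
    f2 <- fit_growth(d, spec = model_spec(fam, "two_param_fixed_L0", 26))
    expect_lte(f3$rss, f2$rss + 1e-6)
  }
})

test_that("fits are invariant to record order; duplication shrinks SEs only", {
  set.seed(17)
  d <- curve_data("vb", 26, 58, 1.98)
  d$length <- d$length + rnorm(nrow(d), 0, 5)
  f <- fit_growth(d, family = "vb", strategy = "two_param_fixed_L0")
  fp <- fit_growth(d[sample(nrow(d)), ], family = "vb",
                   strategy = "two_param_fixed_L0")
  expect_equal(coef(f), coef(fp), tolerance = 1e-8)
  fd <- fit_growth(rbind(d, d), family = "vb", strategy = "two_param_fixed_L0")
  expect_equal(coef(fd), coef(f), tolerance = 1e-6)
  expect_true(all(fd$se < f$se))
})

test_that("fit bookkeeping: RSE, k and AICc follow their definitions", {
  set.seed(23)
  d <- curve_data("vb", 26, 58, 1.98)
  d$length <- d$length + rnorm(nrow(d), 0, 5)
  f <- fit_growth(d, family = "vb", strategy = "three_param")
  expect_equal(f$rse, sqrt(f$rss / (f$n - 3)))
  expect_equal(f$k_aic, 4L)
  expect_equal(f$aic, f$n * log(f$rss / f$n) + 2 * 4)
  expect_equal(f$aicc, f$aic + 2 * 4 * 5 / (f$n - 4 - 1))
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-8)
  expect_equal(as.numeric(logLik(f)),
               -f$n / 2 * (log(2 * pi * f$rss / f$n) + 1))
})

test_that("bootstrap intervals are seed-deterministic and sensibly scaled", {
  set.seed(31)
  d <- curve_data("vb", 26, 58, 1.98,
                  ages = runif(131, 0.2, 4.6))
  d$length <- pmax(d$length + rnorm(nrow(d), 0, 5.4), 1)
  f <- fit_growth(d, family = "vb", strategy = "two_param_fixed_L0")
  b1 <- bootstrap_ci(f, B = 200, seed = 5)
  b2 <- bootstrap_ci(f, B = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci[, "lower"] <= coef(f) & coef(f) <= b1$ci[, "upper"]))
  # curvature-based SEs and bootstrap SDs agree to within ~30% here
  expect_true(all(abs(b1$se - f$se) / f$se < 0.3))
  expect_error(bootstrap_ci(f, B = 50), ">= 100")
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- curve_data("vb", 26, 58, 1.98)
  expect_error(fit_growth(d[1:2, ], family = "vb", strategy = "three_param"),
               "more records")
  d0 <- data.frame(age = rep(1, 10), length = rep(40, 10))
  expect_error(fit_growth(d0, family = "vb", strategy = "two_param_fixed_L0"),
               "span")
  dn <- d; dn$length[1] <- NA
  expect_error(fit_growth(dn, family = "vb", strategy = "three_param"),
               "missing")
})
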