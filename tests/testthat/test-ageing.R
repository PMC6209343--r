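test_that("partial ages add the elapsed year fraction since the birth pulse", {
  # one band pair, caught 30 August: 227 days past 15 January
  expect_equal(assign_partial_age(1, as.Date("2015-08-30")), 1 + 227 / 365,
               tolerance = 1e-12)
  expect_equal(round(assign_partial_age(1, as.Date("2015-08-30")), 2), 1.62)
  # capture on the anniversary itself: zero elapsed fraction
  expect_equal(assign_partial_age(2, as.Date("2015-01-15")), 2)
  # 17 June: 153 elapsed days under the calendar-day convention
  expect_equal(round(assign_partial_age(1, as.Date("2015-06-17")), 2), 1.42)
  # capture before the birthday rolls back to the previous year's pulse
  expect_equal(assign_partial_age(0, as.Date("2015-01-10")),
               (as.numeric(as.Date("2015-01-10") - as.Date("2014-01-15"))) / 365)
})

test_that("partial age minus band count always lies in [0, 1)", {
  set.seed(42)
  dates <- as.Date("2014-01-01") + sample.int(900, 200, replace = TRUE)
  counts <- sample(0:6, 200, replace = TRUE)
  ages <- assign_partial_age(counts, dates)
  frac <- ages - counts
  expect_true(all(frac >= 0 & frac < 1))
})

test_that("partial ageing rejects bad inputs and propagates missing counts", {
  expect_error(assign_partial_age(1, "not-a-date"))
  expect_error(assign_partial_age(-1, as.Date("2015-03-01")), "non-negative")
  expect_error(assign_partial_age(1.5, as.Date("2015-03-01")), "integer")
  expect_true(is.na(assign_partial_age(NA, as.Date("2015-03-01"))))
})

test_that("consensus uses agreement, then the resolution table, then excludes", {
  rec <- data.frame(specimen_id = c("a", "b", "c"),
                    band_count_r1 = c(2L, 3L, 3L),
                    band_count_r2 = c(2L, 4L, 4L))
  res <- data.frame(specimen_id = "b", consensus = 4L)
  expect_message(out <- consensus_ages(rec, res), "1 specimen")
  expect_equal(out$consensus_band_count, c(2L, 4L, NA))
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE))
  expect_equal(attr(out, "n_excluded"), 1L)
  # resolution matching neither read is an error
  bad <- data.frame(specimen_id = "b", consensus = 7L)
  expect_error(consensus_ages(rec, bad), "neither read")
})

test_that("APE, CV and PA reproduce hand-computed values", {
  expect_equal(average_percent_error(cbind(c(1, 2), c(1, 2))), 0)
  expect_equal(average_percent_error(cbind(1, 2)), 100 / 3, tolerance = 1e-9)
  expect_equal(average_percent_error(cbind(c(1, 2), c(2, 2))), 100 / 6,
               tolerance = 1e-9)
  expect_equal(chang_cv(cbind(c(3, 5), c(3, 5))), 0)
  expect_equal(chang_cv(cbind(1, 2)), 100 * sd(c(1, 2)) / 1.5,
               tolerance = 1e-9)
  # CV is scale invariant
  m <- cbind(c(1, 2, 4), c(2, 3, 4))
  expect_equal(chang_cv(m), chang_cv(3 * m), tolerance = 1e-12)
  expect_equal(percent_agreement(cbind(c(1, 2), c(1, 2)), tolerance = 0), 100)
  expect_equal(percent_agreement(cbind(c(1, 1), c(2, 3)), tolerance = 1), 50)
})

test_that("precision statistics match brute-force oracles on random reads", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    m <- matrix(sample(0:6, 2 * n, replace = TRUE), ncol = 2)
    if (all(rowMeans(m) == 0)) next
    expect_equal(average_percent_error(m), oracle_ape(m), tolerance = 1e-10)
    expect_equal(chang_cv(m), oracle_cv(m), tolerance = 1e-10)
    tol <- sample(0:3, 1)
    expect_equal(percent_agreement(m, tol), oracle_pa(m, tol),
                 tolerance = 1e-10)
  }
})

test_that("APE and CV are zero iff readers agree, and order invariant", {
  set.seed(13)
  m <- matrix(sample(1:5, 60, replace = TRUE), ncol = 2)
  perm <- sample(nrow(m))
  expect_equal(average_percent_error(m), average_percent_error(m[perm, ]))
  expect_equal(chang_cv(m), chang_cv(m[perm, ]))
  agree <- cbind(1:5, 1:5)
  expect_equal(average_percent_error(agree), 0)
  expect_equal(chang_cv(agree), 0)
  expect_gt(average_percent_error(rbind(agree, c(2, 3))), 0)
})

test_that("PA is non-decreasing in tolerance", {
  set.seed(21)
  m <- matrix(sample(0:6, 80, replace = TRUE), ncol = 2)
  pa <- vapply(0:6, function(t) percent_agreement(m, t), numeric(1))
  expect_true(all(diff(pa) >= 0))
  expect_equal(pa[7], 100)
})

test_that("Bowker's statistic follows the pairwise formula", {
  # symmetric table has no asymmetry signal
  sym <- matrix(c(5, 2, 2, 7), 2)
  b <- bowker_symmetry(sym)
  expect_equal(unname(b$statistic), 0)
  # 2x2 with n12 = 3, n21 = 1: (3 - 1)^2 / 4 = 1
  t2 <- matrix(c(10, 1, 3, 8), 2) # column-major: n21 = 1, n12 = 3
  b2 <- bowker_symmetry(t2)
  expect_equal(unname(b2$statistic), 1)
  expect_equal(unname(b2$parameter), 1L)
  # empty off-diagonal pairs contribute neither statistic nor df
  t3 <- matrix(0, 3, 3)
  t3[1, 2] <- 2 # pair (1,2) = (2, 0); pairs (1,3), (2,3) empty
  b3 <- bowker_symmetry(t3)
  expect_equal(unname(b3$statistic), 2)
  expect_equal(unname(b3$parameter), 1L)
  # all off-diagonals empty: statistic 0, p undefined
  b0 <- bowker_symmetry(diag(c(3, 4)))
  expect_equal(unname(b0$statistic), 0)
  expect_true(is.na(b0$p.value))
})

test_that("Bowker agrees with brute-force and mcnemar oracles on random tables", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    tab <- matrix(rpois(k * k, 2), k)
    b <- bowker_symmetry(tab)
    o <- oracle_bowker(tab)
    expect_equal(unname(b$statistic), o$chi2, tolerance = 1e-10)
    expect_equal(unname(b$parameter), o$df)
    # stats::mcnemar.test implements the same statistic when every
    # off-diagonal pair is populated
    if (all(tab + t(tab) > 0 | diag(k) == 1)) {
      m <- suppressWarnings(stats::mcnemar.test(tab, correct = FALSE))
      expect_equal(unname(b$statistic), unname(m$statistic), tolerance = 1e-10)
    }
  }
})

test_that("precision_report bundles the statistics consistently", {
  set.seed(5)
  cls <- sample(0:4, 120, replace = TRUE)
  m <- simulate_reader_counts(cls, c(0.15, 0.7, 0.15), seed = 9)
  pr <- precision_report(m[, 1], m[, 2])
  expect_s3_class(pr, "precision_report")
  expect_equal(pr$ape_percent, average_percent_error(m))
  expect_equal(pr$cv_percent, chang_cv(m))
  expect_equal(pr$pa_percent, percent_agreement(m, 1))
  expect_true(pr$ape_percent >= 0 && pr$ape_percent <= 100)
  expect_equal(pr$n, 120L)
  expect_equal(sum(pr$crosstab), 120)
})
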