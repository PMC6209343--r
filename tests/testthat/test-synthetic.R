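test_that("simulation is a deterministic function of config and seed", {
  cfg <- sim_config(n_female = 40, n_male = 20)
  a <- simulate_population(cfg, seed = 5)
  b <- simulate_population(cfg, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_population(cfg, seed = 6)
  expect_false(identical(a, c2))
})

test_that("simulated tables satisfy the specimen invariants and round-trip CSV", {
  pop <- simulate_population(sim_config(), seed = 7)
  expect_equal(nrow(pop), 186)
  expect_silent(validated <- validate_specimens(pop))
  expect_true(all(pop$total_length_cm > 0))
  expect_true(all(pop$band_count_r1 >= 0 & pop$band_count_r2 >= 0))
  expect_true(all(pop$band_count_r1 == floor(pop$band_count_r1)))
  # partial ages derived from consensus counts stay inside the class
  age <- assign_partial_age(pop$consensus_band_count, pop$capture_date)
  expect_true(all(age >= pop$consensus_band_count &
                  age < pop$consensus_band_count + 1))
  # stage codes agree with the latent binary state
  expect_equal(binarize_stage(pop$maturity_stage, pop$sex), pop$mature)
  tf <- tempfile(fileext = ".csv")
  write_specimens(pop, tf)
  back <- read_specimens(tf)
  sch <- c("specimen_id", "sex", "total_length_cm", "capture_date",
           "band_count_r1", "band_count_r2", "consensus_band_count",
           "maturity_stage")
  expect_identical(back[sch], pop[sch])
  unlink(tf)
})

test_that("the noiseless limit lies exactly on the generating curve", {
  cfg <- sim_config(n_female = 60, n_male = 0, noise_sd_female = 0,
                    reader_error = c(0, 1, 0))
  pop <- simulate_population(cfg, seed = 9)
  on_curve <- predict_length(cfg$params_female, pop$true_age)
  # lengths are recorded to 0.1 cm
  expect_true(all(abs(pop$total_length_cm - on_curve) <= 0.05 + 1e-9))
  m <- cbind(pop$band_count_r1, pop$band_count_r2)
  expect_equal(average_percent_error(m), 0)
  expect_equal(chang_cv(m), 0)
  expect_equal(percent_agreement(m, 0), 100)
  expect_equal(unname(bowker_symmetry(age_crosstab(m[, 1], m[, 2]))$statistic), 0)
})

test_that("default female arm matches the expected length and age ranges", {
  pop <- simulate_population(sim_config(), seed = 11)
  f <- pop[pop$sex == "F", ]
  # compatible with a 31-66 cm, 0.2-4.6 yr sampled population (the
  # Gaussian residual tails reach a little beyond the observed range)
  expect_gt(min(f$total_length_cm), 10)
  expect_lt(max(f$total_length_cm), 85)
  expect_true(median(f$total_length_cm) > 31 & median(f$total_length_cm) < 66)
  expect_true(any(f$total_length_cm > 55))
  expect_true(all(f$true_age >= 0 & f$true_age < 5))
  expect_gt(mean(f$consensus_band_count == 0), 0.3) # age class 0 dominates
})

test_that("mean length of an age class tracks the generating curve", {
  cfg <- sim_config(n_female = 10000, n_male = 0,
                    params_female = growth_params("vb", 26, 58, 1.98),
                    noise_sd_female = 5.4)
  pop <- simulate_population(cfg, seed = 99)
  i1 <- pop$consensus_band_count == 1
  mu <- mean(pop$total_length_cm[i1])
  pred <- predict_length(cfg$params_female, mean(pop$true_age[i1]))
  se <- 5.4 / sqrt(sum(i1))
  expect_lt(abs(mu - pred), 3 * se)
})

test_that("reader count simulation honours the displacement distribution", {
  cls <- sample(0:4, 200, replace = TRUE)
  m <- simulate_reader_counts(cls, c(0, 1, 0), seed = 1)
  expect_equal(m[, "r1"], m[, "r2"])
  expect_equal(percent_agreement(m, 0), 100)
  m2 <- simulate_reader_counts(cls, c(0.1, 0.8, 0.1), seed = 2)
  expect_true(all(abs(m2[, 1] - cls) <= 1))
  expect_true(all(m2 >= 0))
  expect_identical(m2, simulate_reader_counts(cls, c(0.1, 0.8, 0.1), seed = 2))
  expect_error(simulate_reader_counts(cls, c(0.5, 0.5)), "probabilities")
})

test_that("symmetric reader error rarely triggers Bowker; asymmetric error does", {
  set.seed(101)
  sym_rej <- vapply(1:100, function(i) {
    cls <- sample(0:4, 186, replace = TRUE, prob = 0.45^(0:4))
    m <- simulate_reader_counts(cls, c(0.1, 0.8, 0.1), seed = 5000 + i)
    b <- bowker_symmetry(age_crosstab(m[, 1], m[, 2]))
    !is.na(b$p.value) && b$p.value < 0.05
  }, logical(1))
  expect_lte(mean(sym_rej), 0.10) # non-significant in >= 90% of replicates
  asym_rej <- vapply(1:50, function(i) {
    set.seed(6000 + i)
    cls <- sample(0:4, 186, replace = TRUE, prob = 0.45^(0:4))
    hi <- cls > 2
    m <- simulate_reader_counts(cls, c(0.1, 0.8, 0.1), seed = 6000 + i)
    # reader 1 undercounts by one with probability 0.3 above age 2
    m[hi, ] <- simulate_reader_counts(cls[hi],
      list(c(0.3, 0.7, 0), c(0.1, 0.8, 0.1)), seed = 7000 + i)
    b <- bowker_symmetry(age_crosstab(m[, 1], m[, 2]))
    !is.na(b$p.value) && b$p.value < 0.05
  }, logical(1))
  expect_gt(mean(asym_rej), 0.5)
})

test_that("specimen validation catches schema violations", {
  pop <- simulate_population(sim_config(n_female = 20, n_male = 10), seed = 3)
  bad <- pop; bad$total_length_cm[1] <- -4
  expect_error(validate_specimens(bad), "positive")
  bad <- pop; bad$sex[1] <- "U"
  expect_error(validate_specimens(bad), "sex")
  bad <- pop; bad$band_count_r1[2] <- 1.5
  expect_error(validate_specimens(bad), "integer")
  bad <- pop; bad$maturity_stage[3] <- "9"
  expect_error(validate_specimens(bad), "stage")
  expect_error(validate_specimens(pop[, -3]), "missing column")
})
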