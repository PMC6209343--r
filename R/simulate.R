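#' Simulation configuration for a synthetic specimen table
#'
#' Describes a seasonally reproducing, fast-growing coastal shark
#' population sampled by a fishery: per-sex growth curves with additive
#' Gaussian length residuals, a single annual birth pulse, a bounded
#' sampling window, a geometric decline in age-class frequency, per-sex
#' maturity ogives in length, and two readers whose band-pair counts are
#' the true age class plus an independent displacement.
#'
#' Defaults emulate the study population the package was written around:
#' 131 females and 55 males captured June 2014–August 2015, female growth
#' `Linf = 57.78` cm, `k = 1.17` /yr and male `Linf = 46.11` cm,
#' `k = 3.69` /yr on a fixed-`L0` (26 cm) von Bertalanffy curve, residual
#' scales matching the reported residual standard errors (5.40 / 4.44 cm),
#' female ogive `L50 = 47.0`, `L95 = 53.5` cm and male `L50 = 41.7`,
#' `L95 = 47.2` cm, a mid-January birth pulse, age classes 0–4 declining
#' geometrically by 0.45 per class, and symmetric reader error
#' (-1/0/+1 with probabilities 0.1/0.8/0.1).
#'
#' @param n_female,n_male Sample sizes per sex.
#' @param params_female,params_male [growth_params] generating curves.
#' @param noise_sd_female,noise_sd_male Gaussian length residual SD, cm.
#' @param ogive_female,ogive_male Named vectors `c(x50 =, x95 =)` in cm.
#' @param birth_month_day Birth pulse, `"MM-DD"`. Default `"01-15"`.
#' @param window Two dates bounding the capture window.
#' @param max_age Oldest age class sampled.
#' @param age_decay Geometric ratio of successive age-class frequencies,
#'   in (0, 1).
#' @param reader_error Probability vector over count displacements
#'   `(-1, 0, +1)`, either one vector for both readers or a list of two.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_female = 131L, n_male = 55L,
                       params_female = growth_params("vb", 26, 57.78, 1.17),
                       params_male = growth_params("vb", 26, 46.11, 3.69),
                       noise_sd_female = 5.40, noise_sd_male = 4.44,
                       ogive_female = c(x50 = 47.0, x95 = 53.5),
                       ogive_male = c(x50 = 41.7, x95 = 47.2),
                       birth_month_day = "01-15",
                       window = as.Date(c("2014-06-01", "2015-08-31")),
                       max_age = 4L, age_decay = 0.45,
                       reader_error = c(0.1, 0.8, 0.1)) {
  stopifnot(n_female >= 0, n_male >= 0, n_female + n_male > 0,
            inherits(params_female, "growth_params"),
            inherits(params_male, "growth_params"),
            noise_sd_female >= 0, noise_sd_male >= 0,
            length(window) == 2L, window[1] <= window[2],
            max_age >= 0, age_decay > 0, age_decay < 1)
  for (og in list(ogive_female, ogive_male))
    stopifnot(all(c("x50", "x95") %in% names(og)), og["x95"] > og["x50"])
  check_err <- function(p) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("'reader_error' must be 3 probabilities over (-1, 0, +1) summing to 1")
  }
  if (is.list(reader_error)) lapply(reader_error, check_err)
  else check_err(reader_error)
  structure(list(n_female = as.integer(n_female), n_male = as.integer(n_male),
                 params_female = params_female, params_male = params_male,
                 noise_sd_female = noise_sd_female,
                 noise_sd_male = noise_sd_male,
                 ogive_female = ogive_female, ogive_male = ogive_male,
                 birth_month_day = birth_month_day,
                 window = as.Date(window), max_age = as.integer(max_age),
                 age_decay = age_decay, reader_error = reader_error),
            class = "sim_config")
}

#' Simulate a specimen table
#'
#' Draws a synthetic sample under a [sim_config]: capture dates uniform
#' over the window; integer age classes geometric (ratio `age_decay`,
#' truncated at `max_age`); true age = class + the day fraction implied by
#' the capture date and birth pulse; length = growth curve at the true age
#' plus Gaussian noise, floored at 1 cm and recorded to 0.1 cm; band-pair
#' counts for two readers displaced independently from the true class;
#' consensus count = the true class; maturity a Bernoulli draw from the
#' sex's length ogive, back-mapped to a stage code consistent with the
#' binary state.
#'
#' @param config A [sim_config].
#' @param seed Integer seed; the table is a deterministic function of
#'   `(config, seed)`.
#' @return A specimen data frame with columns `specimen_id`, `sex`,
#'   `total_length_cm`, `capture_date`, `band_count_r1`, `band_count_r2`,
#'   `consensus_band_count`, `maturity_stage`, plus the latent truth
#'   columns `true_age` and `mature` used by validation code.
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  arm <- function(sex, n, params, noise_sd, ogive, offset) {
    if (n == 0L) return(NULL)
    days <- as.integer(config$window[2] - config$window[1])
    capture <- config$window[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
    probs <- config$age_decay^(0:config$max_age)
    cls <- sample(0:config$max_age, n, replace = TRUE, prob = probs)
    frac <- as.numeric(capture -
      birth_anniversary(capture, config$birth_month_day)) / 365
    true_age <- cls + pmin(frac, 1 - 1e-9)
    len <- predict_length(params, true_age) + stats::rnorm(n, 0, noise_sd)
    len <- round(pmax(len, 1), 1)
    err <- config$reader_error
    err1 <- if (is.list(err)) err[[1]] else err
    err2 <- if (is.list(err)) err[[2]] else err
    r1 <- pmax(cls + sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = err1), 0L)
    r2 <- pmax(cls + sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = err2), 0L)
    p_mat <- maturity_prob(len, ogive[["x50"]], ogive[["x95"]])
    mature <- stats::rbinom(n, 1L, p_mat)
    stage <- map_stage(mature, sex, n)
    data.frame(specimen_id = sprintf("%s%04d", sex, offset + seq_len(n)),
               sex = sex,
               total_length_cm = len,
               capture_date = capture,
               band_count_r1 = r1, band_count_r2 = r2,
               consensus_band_count = cls,
               maturity_stage = stage,
               true_age = true_age, mature = mature,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    arm("F", config$n_female, config$params_female,
        config$noise_sd_female, config$ogive_female, 0L),
    arm("M", config$n_male, config$params_male,
        config$noise_sd_male, config$ogive_male, config$n_female))
  rownames(out) <- NULL
  out
}

# uniform stage code within the binary class
map_stage <- function(mature, sex, n) {
  if (sex == "F") {
    imm <- c("1", "2"); mat <- c("3", "4", "5")
  } else {
    imm <- c("NC", "PC"); mat <- "FC"
  }
  ifelse(mature == 1L,
         sample(mat, n, replace = TRUE),
         sample(imm, n, replace = TRUE))
}

#' Simulate two readers' band-pair counts
#'
#' Displaces true integer age classes independently for each reader by
#' -1/0/+1 with the given probabilities, flooring at zero.
#'
#' @param true_counts Integer vector of true age classes.
#' @param reader_error Probability vector over displacements `(-1, 0, +1)`,
#'   or a list of two such vectors (reader 1, reader 2).
#' @param seed Integer seed.
#' @return Integer matrix with columns `r1`, `r2`.
#' @export
simulate_reader_counts <- function(true_counts, reader_error = c(0.1, 0.8, 0.1),
                                   seed = 1L) {
  err1 <- if (is.list(reader_error)) reader_error[[1]] else reader_error
  err2 <- if (is.list(reader_error)) reader_error[[2]] else reader_error
  for (p in list(err1, err2))
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("'reader_error' must be 3 probabilities over (-1, 0, +1) summing to 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(true_counts)
  r1 <- pmax(true_counts + sample(c(-1L, 0L, 1L), n, TRUE, err1), 0L)
  r2 <- pmax(true_counts + sample(c(-1L, 0L, 1L), n, TRUE, err2), 0L)
  cbind(r1 = r1, r2 = r2)
}
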