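#' Binary maturity from macroscopic stage codes
#'
#' Maps the macroscopic maturity staging used for small carcharhinids to a
#' binary state. Females are staged 1–5 on uterus/ovary condition: 1
#' (immature) and 2 (maturing) map to 0; 3 (mature), 4 (pregnant) and 5
#' (post-partum) map to 1. Males are staged on clasper calcification:
#' NC (not calcified) and PC (partially calcified) map to 0; FC (fully
#' calcified) maps to 1.
#'
#' @param stage Stage codes (character or numeric for females).
#' @param sex `"F"` or `"M"`, recycled to the length of `stage`.
#' @return Integer vector of 0 (immature) / 1 (mature).
#' @examples
#' binarize_stage(c("2", "5"), "F") # 0 1
#' binarize_stage("PC", "M")        # 0
#' @export
binarize_stage <- function(stage, sex) {
  stage <- toupper(trimws(as.character(stage)))
  sex <- toupper(trimws(as.character(sex)))
  n <- max(length(stage), length(sex))
  stage <- rep_len(stage, n)
  sex <- rep_len(sex, n)
  female_map <- c("1" = 0L, "2" = 0L, "3" = 1L, "4" = 1L, "5" = 1L)
  male_map <- c(NC = 0L, PC = 0L, FC = 1L)
  out <- integer(n)
  for (i in seq_len(n)) {
    map <- switch(sex[i], F = female_map, M = male_map,
                  stop("sex must be 'F' or 'M', got: ", sex[i]))
    if (!stage[i] %in% names(map))
      stop(sprintf("unknown maturity stage '%s' for sex %s; valid codes: %s",
                   stage[i], sex[i], paste(names(map), collapse = ", ")))
    out[i] <- map[[stage[i]]]
  }
  out
}

#' Logistic maturity ogive
#'
#' Proportion mature as a function of length (or age) in the `ln(19)`
#' parameterization:
#' `P(x) = Pmax * (1 + exp(-ln(19) * (x - x50) / (x95 - x50)))^-1`,
#' so that `P(x50) = Pmax / 2` and `P(x95) = 0.95 * Pmax` exactly.
#'
#' @param x Covariate values (cm TL or years).
#' @param x50,x95 Covariate values at which 50% and 95% of the population
#'   are mature (`x95 > x50`).
#' @param pmax Maximum proportion mature (0 < pmax <= 1). Default 1.
#' @return Proportions mature.
#' @examples
#' maturity_prob(47.0, 47.0, 53.5) # 0.5
#' @export
maturity_prob <- function(x, x50, x95, pmax = 1) {
  if (x95 <= x50) stop("'x95' must exceed 'x50'")
  if (pmax <= 0 || pmax > 1) stop("'pmax' must lie in (0, 1]")
  pmax / (1 + exp(-log(19) * (x - x50) / (x95 - x50)))
}

#' Fit a maturity ogive
#'
#' Estimates the length- (or age-) at-maturity ogive by a binomial GLM with
#' a logit link: `logit(P) = b0 + b1 x`, giving `x50 = -b0 / b1` and
#' `x95 = (ln(19) - b0) / b1`. Standard errors for `x50`/`x95` come from
#' the delta method; optional percentile bootstrap intervals from case
#' resampling. The age- and length-scale fits share this single code path
#' (`scale` is a label). The asymptote `pmax` is fixed at 1 by default; set
#' `estimate_pmax = TRUE` to estimate it by direct maximum likelihood
#' (fragile at small sample sizes).
#'
#' @param x Covariate (cm TL or years), positive.
#' @param mature Binary maturity states (0/1 or logical).
#' @param scale `"length"` or `"age"`; stored label only.
#' @param estimate_pmax Estimate the asymptote rather than fixing it at 1.
#' @param boot_B Bootstrap replicates for percentile CIs (0 = skip).
#' @param boot_seed Seed for the bootstrap.
#' @param level CI level. Default 0.95.
#' @return An object of class `ogive_fit`: list with `scale`, `pmax`,
#'   `x50`, `x95`, `se_x50`, `se_x95`, `coef` (b0, b1), `vcov`, `ci`
#'   (bootstrap, or `NULL`), `n`, `separation` flag.
#' @export
fit_ogive <- function(x, mature, scale = c("length", "age"),
                      estimate_pmax = FALSE, boot_B = 0L, boot_seed = 1L,
                      level = 0.95) {
  scale <- match.arg(scale)
  mature <- as.integer(mature)
  ok <- !is.na(x) & !is.na(mature)
  x <- x[ok]; mature <- mature[ok]
  if (any(x <= 0)) stop("covariate values must be positive")
  if (!all(mature %in% c(0L, 1L))) stop("'mature' must be binary 0/1")
  if (length(unique(mature)) < 2L)
    stop("both maturity classes must be present to fit an ogive")
  if (length(x) < 10L) stop("need at least 10 observations")

  fit1 <- ogive_point_fit(x, mature, estimate_pmax)
  if (fit1$coef[2L] <= 0)
    stop("fitted ogive does not rise with the covariate (slope <= 0)")

  ci <- NULL
  if (boot_B > 0L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(boot_seed)
    reps <- matrix(NA_real_, boot_B, 2L, dimnames = list(NULL, c("x50", "x95")))
    for (b in seq_len(boot_B)) {
      i <- sample.int(length(x), replace = TRUE)
      rb <- tryCatch(ogive_point_fit(x[i], mature[i], estimate_pmax),
                     error = function(e) NULL)
      if (!is.null(rb) && rb$coef[2L] > 0)
        reps[b, ] <- c(rb$x50, rb$x95)
    }
    okb <- stats::complete.cases(reps)
    if (sum(okb) < 0.5 * boot_B)
      warning("more than half of ogive bootstrap replicates failed")
    alpha <- (1 - level) / 2
    ci <- t(apply(reps[okb, , drop = FALSE], 2L, stats::quantile,
                  probs = c(alpha, 1 - alpha)))
    colnames(ci) <- c("lower", "upper")
  }
  structure(c(fit1, list(scale = scale, ci = ci, n = length(x),
                         level = level)),
            class = "ogive_fit")
}

# single ML fit; pmax fixed (glm) or estimated (direct NLL)
ogive_point_fit <- function(x, mature, estimate_pmax) {
  sep <- FALSE
  if (!estimate_pmax) {
    g <- withCallingHandlers(
      stats::glm(mature ~ x, family = stats::binomial("logit")),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    b <- unname(stats::coef(g))
    V <- stats::vcov(g)
    pmax_hat <- 1
  } else {
    nll <- function(th) {
      p <- stats::plogis(th[3L]) * stats::plogis(th[1L] + th[2L] * x)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(mature * log(p) + (1 - mature) * log(1 - p))
    }
    g0 <- stats::glm(mature ~ x, family = stats::binomial("logit"))
    op <- stats::optim(c(stats::coef(g0), 5), nll, method = "BFGS",
                       hessian = TRUE)
    b <- op$par[1:2]
    V <- tryCatch(solve(op$hessian)[1:2, 1:2],
                  error = function(e) matrix(NA_real_, 2, 2))
    pmax_hat <- stats::plogis(op$par[3L])
  }
  x50 <- -b[1L] / b[2L]
  x95 <- (log(19) - b[1L]) / b[2L]
  # delta method on (b0, b1)
  g50 <- c(-1 / b[2L], b[1L] / b[2L]^2)
  g95 <- c(-1 / b[2L], -(log(19) - b[1L]) / b[2L]^2)
  list(pmax = pmax_hat, x50 = x50, x95 = x95,
       se_x50 = sqrt(drop(t(g50) %*% V %*% g50)),
       se_x95 = sqrt(drop(t(g95) %*% V %*% g95)),
       coef = b, vcov = V, separation = sep)
}

#' @export
print.ogive_fit <- function(x, ...) {
  unit <- if (x$scale == "length") "cm" else "yr"
  lab <- if (x$scale == "length") c("L50", "L95") else c("A50", "A95")
  cat(sprintf("Maturity ogive (%s scale, n = %d)\n", x$scale, x$n))
  cat(sprintf("  %s = %.2f %s (SE %.2f), %s = %.2f %s (SE %.2f)\n",
              lab[1], x$x50, unit, x$se_x50, lab[2], x$x95, unit, x$se_x95))
  if (x$pmax < 1) cat(sprintf("  Pmax = %.3f\n", x$pmax))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %.0f%% CI: %s %.2f-%.2f, %s %.2f-%.2f\n",
                100 * x$level, lab[1], x$ci["x50", 1], x$ci["x50", 2],
                lab[2], x$ci["x95", 1], x$ci["x95", 2]))
  }
  if (x$separation)
    cat("  warning: complete or quasi-complete separation detected\n")
  invisible(x)
}

#' @export
coef.ogive_fit <- function(object, ...) {
  c(x50 = object$x50, x95 = object$x95, pmax = object$pmax)
}

#' @export
predict.ogive_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) stop("supply covariate values in 'newdata'")
       else if (is.data.frame(newdata)) newdata$x
       else newdata
  maturity_prob(x, object$x50, object$x95, object$pmax)
}

#' @export
plot.ogive_fit <- function(x, ...,
                           xlab = if (x$scale == "length")
                             "Total length (cm)" else "Age (years)",
                           ylab = "Proportion mature") {
  rng <- c(x$x50 - 2 * (x$x95 - x$x50), x$x95 + 2 * (x$x95 - x$x50))
  xx <- seq(max(rng[1], 1e-6), rng[2], length.out = 200)
  graphics::plot(xx, maturity_prob(xx, x$x50, x$x95, x$pmax), type = "l",
                 lwd = 2, ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::points(x$x50, x$pmax / 2, pch = 19)
  graphics::abline(h = c(0.5, 0.95) * x$pmax, lty = 3, col = "grey")
  invisible(x)
}
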