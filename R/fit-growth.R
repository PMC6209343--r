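#' Append hypothetical age-zero animals
#'
#' One remedy for samples missing small young-of-year animals: append
#' `n_add` hypothetical records of age 0 and length `L0_value` so the fitted
#' curve is anchored near the known length-at-birth.
#'
#' @param data Data frame with numeric columns `age` and `length`.
#' @param L0_value Length-at-birth in cm assigned to the appended records.
#' @param n_add Number of records to append (default 4).
#' @return `data` with `n_add` rows of `(age = 0, length = L0_value)`
#'   appended; original rows untouched.
#' @export
augment_with_zero_age <- function(data, L0_value, n_add = 4L) {
  stopifnot(is.data.frame(data), all(c("age", "length") %in% names(data)))
  n_add <- as.integer(n_add)
  if (n_add < 0) stop("'n_add' must be >= 0")
  if (!is.numeric(L0_value) || L0_value <= 0)
    stop("'L0_value' must be a positive length (cm)")
  if (n_add == 0L) return(data)
  extra <- data[rep(NA_integer_, n_add), , drop = FALSE]
  extra$age <- 0
  extra$length <- L0_value
  if ("specimen_id" %in% names(extra))
    extra$specimen_id <- sprintf("HYP%02d", seq_len(n_add))
  rownames(extra) <- NULL
  out <- rbind(data, extra)
  rownames(out) <- NULL
  out
}

# default multi-start grid bracketing plausible estimates
start_grid <- function(data, spec) {
  maxL <- max(data$length)
  minL <- min(data$length)
  linf <- maxL * c(1, 1.1, 1.3)
  coeff <- c(0.3, 1, 3)
  if (spec$strategy == "two_param_fixed_L0") {
    g <- expand.grid(Linf = linf, coeff = coeff)
  } else {
    g <- expand.grid(Linf = linf, coeff = coeff,
                     L0 = c(0.8 * minL, minL))
  }
  g
}

fit_formula <- function(family, fixed_L0 = NULL) {
  rhs <- switch(family,
    vb       = "L0 + (Linf - L0) * (1 - exp(-coeff * age))",
    logistic = "(Linf * L0 * exp(coeff * age)) / (Linf + L0 * (exp(coeff * age) - 1))",
    gompertz = "Linf * exp(log(L0 / Linf) * exp(-coeff * age))")
  if (!is.null(fixed_L0))
    rhs <- gsub("\\bL0\\b", format(fixed_L0, digits = 15), rhs)
  stats::as.formula(paste("length ~", rhs))
}

#' Fit a growth model to length-at-age data
#'
#' Fits one growth-family/strategy combination by nonlinear least squares
#' (Levenberg–Marquardt, multi-start). Among converged starts the solution
#' with the lowest residual sum of squares wins (ties broken by fewest
#' iterations). Standard errors come from the curvature of the objective at
#' the optimum; for the fixed-`L0` strategy, `L0` is held constant and has
#' no standard error. The small-sample AICc is computed from
#' `AIC = n log(RSS/n) + 2k` with `k` = estimated parameters + 1 for the
#' error variance.
#'
#' @param data Data frame with numeric columns `age` (years, >= 0) and
#'   `length` (cm TL, > 0). A `group` attribute or `group_label` argument
#'   labels the fit.
#' @param spec A [model_spec]; alternatively pass `family`/`strategy`
#'   shortcuts.
#' @param family,strategy,fixed_L0_value,n_hypothetical Convenience
#'   arguments forwarded to [model_spec] when `spec` is missing.
#' @param starts Optional data frame of start values (columns `Linf`,
#'   `coeff`, and `L0` for three-parameter strategies); defaults to a grid
#'   bracketing the data.
#' @param group_label Label stored with the fit (e.g. `"female"`).
#' @param max_iter,tol Optimizer iteration cap and convergence tolerance.
#' @return An object of class `growth_fit` with components `spec`, `params`
#'   (a [growth_params]), `estimates`, `se`, `vcov`, `rss`, `rse`, `n`,
#'   `p_est`, `k_aic`, `aic`, `aicc`, `data` (post-augmentation),
#'   `data_original`, `boundary` (logical flag), `group_label`.
#' @examples
#' d <- data.frame(age = seq(0.25, 4.5, by = 0.25))
#' d$length <- predict_length(growth_params("vb", 26, 58, 1.98), d$age)
#' fit_growth(d, family = "vb", strategy = "two_param_fixed_L0",
#'            fixed_L0_value = 26)
#' @export
fit_growth <- function(data, spec = NULL,
                       family = c("vb", "logistic", "gompertz"),
                       strategy = c("three_param", "two_param_fixed_L0",
                                    "three_param_augmented"),
                       fixed_L0_value = 26, n_hypothetical = 4L,
                       starts = NULL, group_label = "combined",
                       max_iter = 200L, tol = 1e-10) {
  if (is.null(spec))
    spec <- model_spec(match.arg(family), match.arg(strategy),
                       fixed_L0_value, n_hypothetical)
  if (!inherits(spec, "model_spec")) stop("'spec' must be a model_spec")
  stopifnot(is.data.frame(data), all(c("age", "length") %in% names(data)))
  if (anyNA(data$age) || anyNA(data$length))
    stop("length-at-age data must not contain missing values")
  if (any(data$age < 0) || any(data$length <= 0))
    stop("ages must be >= 0 and lengths > 0")
  data_original <- data
  if (spec$strategy == "three_param_augmented")
    data <- augment_with_zero_age(data, spec$fixed_L0_value,
                                  spec$n_hypothetical)
  p_est <- parameter_count(spec)
  if (nrow(data) <= p_est)
    stop("need more records than estimated parameters")
  if (diff(range(data$age)) <= 0) stop("ages must span a positive range")

  fixed_L0 <- if (spec$strategy == "two_param_fixed_L0")
    spec$fixed_L0_value else NULL
  form <- fit_formula(spec$family, fixed_L0)
  if (is.null(starts)) starts <- start_grid(data, spec)

  lower <- c(Linf = 1e-3, coeff = 1e-4, L0 = 1e-3)[names(starts)]
  upper <- c(Linf = 10 * max(data$length), coeff = 100,
             L0 = max(data$length))[names(starts)]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = data, start = st,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = tol, ptol = tol))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    it <- fit$convInfo$finIter
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && it < best$it)) {
      best <- list(fit = fit, rss = rss, it = it)
    }
  }
  if (is.null(best))
    stop(sprintf("no start converged for %s / %s",
                 spec$family, spec$strategy))

  fit <- best$fit
  est <- stats::coef(fit)
  n <- nrow(data)
  rss <- best$rss
  rse <- sqrt(rss / (n - p_est))
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, p_est, p_est, dimnames = list(names(est), names(est)))
  })
  se <- sqrt(pmax(diag(vc), 0))
  boundary <- any(abs(est - upper[names(est)]) < 1e-6 * upper[names(est)]) ||
    any(abs(est - lower[names(est)]) < 1e-8)
  if (boundary)
    warning(sprintf("estimate at a search bound for %s / %s",
                    spec$family, spec$strategy))

  L0_hat <- if (is.null(fixed_L0)) unname(est["L0"]) else fixed_L0
  params <- growth_params(spec$family, L0 = L0_hat,
                          Linf = unname(est["Linf"]),
                          coeff = unname(est["coeff"]))
  k_aic <- p_est + 1L
  # a numerically perfect fit (zero-noise data) has likelihood -> Inf
  aic <- if (rss > 0) aic_rss(rss, n, p_est) else -Inf
  aicc_val <- if (is.finite(aic)) aicc(aic, n, k_aic) else aic
  structure(list(spec = spec, params = params,
                 estimates = est, se = se, vcov = vc,
                 rss = rss, rse = rse, n = n, p_est = p_est,
                 k_aic = k_aic, aic = aic, aicc = aicc_val,
                 data = data, data_original = data_original,
                 boundary = boundary, group_label = group_label,
                 iterations = best$it),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s growth fit (%s), group: %s\n",
              growth_family_label(x$spec$family), x$spec$strategy,
              x$group_label))
  est <- x$estimates
  cat("  ", paste(sprintf("%s = %.2f (SE %.2f)", names(est), est, x$se),
                  collapse = ", "), "\n", sep = "")
  if (x$spec$strategy == "two_param_fixed_L0")
    cat(sprintf("  L0 fixed at %.1f cm\n", x$spec$fixed_L0_value))
  cat(sprintf("  n = %d, RSE = %.2f cm, AICc = %.2f\n", x$n, x$rse, x$aicc))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$estimates, `Std. Error` = object$se)
  structure(list(fit = object, coefficients = tab),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$estimates

#' @export
vcov.growth_fit <- function(object, ...) object$vcov

#' @export
fitted.growth_fit <- function(object, ...) {
  predict_length(object$params, object$data$age)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$data$length - fitted(object)
}

#' @export
logLik.growth_fit <- function(object, ...) {
  n <- object$n
  ll <- -n / 2 * (log(2 * pi * object$rss / n) + 1)
  structure(ll, df = object$k_aic, nobs = n, class = "logLik")
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age
         else if (is.data.frame(newdata)) newdata$age
         else newdata
  predict_length(object$params, age)
}

#' @export
plot.growth_fit <- function(x, ...,
                            xlab = "Age (years)", ylab = "Total length (cm)") {
  d <- x$data
  graphics::plot(d$age, d$length, xlab = xlab, ylab = ylab,
                 pch = 21, bg = "grey", ...)
  tt <- seq(0, max(d$age) * 1.05, length.out = 200)
  graphics::lines(tt, predict_length(x$params, tt), lwd = 2)
  invisible(x)
}

#' Case-resampling bootstrap confidence intervals for a growth fit
#'
#' Resamples the original records with replacement (hypothetical age-zero
#' animals from the augmented strategy are re-appended, not resampled),
#' refits from the point estimates, and forms percentile intervals.
#' Replicates that fail to converge are dropped and counted; more than 20%
#' failures raises a warning and more than 50% an error.
#'
#' @param fit A [fit_growth] result.
#' @param B Number of bootstrap replicates (>= 100). Default 1000.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param level Interval level. Default 0.95.
#' @return An object of class `growth_boot`: list with `ci` (matrix of
#'   lower/upper bounds per estimated parameter), `se` (bootstrap SDs),
#'   `replicates`, `B`, `B_effective`, `n_failed`, `level`, `seed`.
#' @export
bootstrap_ci <- function(fit, B = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "growth_fit"))
  B <- as.integer(B)
  if (B < 100L) stop("'B' must be >= 100")
  spec <- fit$spec
  d0 <- fit$data_original
  st <- as.data.frame(as.list(fit$estimates))
  reps <- matrix(NA_real_, B, length(fit$estimates),
                 dimnames = list(NULL, names(fit$estimates)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- matrix(sample.int(nrow(d0), nrow(d0) * B, replace = TRUE), nrow = B)
  for (b in seq_len(B)) {
    db <- d0[idx[b, ], , drop = FALSE]
    fb <- tryCatch(
      suppressWarnings(fit_growth(db, spec = spec, starts = st,
                                  group_label = fit$group_label)),
      error = function(e) NULL)
    if (!is.null(fb)) reps[b, ] <- fb$estimates
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.5 * B)
    stop("more than half of bootstrap replicates failed to converge")
  if (n_failed > 0.2 * B)
    warning(n_failed, " of ", B, " bootstrap replicates failed to converge")
  reps_ok <- reps[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- t(apply(reps_ok, 2L, stats::quantile, probs = c(alpha, 1 - alpha)))
  colnames(ci) <- c("lower", "upper")
  structure(list(ci = ci, se = apply(reps_ok, 2L, stats::sd),
                 replicates = reps_ok, B = B, B_effective = sum(ok),
                 n_failed = n_failed, level = level, seed = seed,
                 estimates = fit$estimates),
            class = "growth_boot")
}

#' @export
print.growth_boot <- function(x, ...) {
  cat(sprintf("Bootstrap percentile intervals (%.0f%%, B = %d, %d failed)\n",
              100 * x$level, x$B, x$n_failed))
  tab <- cbind(Estimate = x$estimates, x$ci, `Boot SE` = x$se)
  print(round(tab, 3))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
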