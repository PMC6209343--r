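#' AIC from a residual sum of squares
#'
#' For a Gaussian least-squares fit, `AIC = n log(sigma^2) + 2k` with the
#' maximum-likelihood variance `sigma^2 = RSS / n` and
#' `k = p_est + 1` (estimated curve parameters plus the error variance).
#' Additive constants of the Gaussian likelihood are dropped; only
#' differences between models on the same data are meaningful.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param p_est Number of estimated curve parameters.
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n, p_est) {
  if (any(rss <= 0) || any(n <= 0)) stop("'rss' and 'n' must be positive")
  n * log(rss / n) + 2 * (p_est + 1)
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k + 1) / (n - k - 1)`, the bias correction recommended
#' when `n / k` is small (here, samples under ~200).
#'
#' @param aic AIC value.
#' @param n Number of observations.
#' @param k Total parameter count including the error variance.
#' @return The AICc value.
#' @export
aicc <- function(aic, n, k) {
  if (any(n - k - 1 <= 0))
    stop("AICc undefined: need n > k + 1")
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc differences, Akaike weights and support classes
#'
#' Ranks candidate models on the same data: `delta_i = AICc_i - min(AICc)`
#' and `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. Deltas of 0–2
#' indicate the strongest support, 2–10 less support, and > 10 the least.
#'
#' @param aicc_values Numeric vector of AICc values (>= 2, all finite).
#' @return Data frame with columns `aicc`, `delta`, `weight`,
#'   `support_class`.
#' @examples
#' delta_and_weights(c(1193.71, 1213.08, 1203.61))
#' @export
delta_and_weights <- function(aicc_values) {
  if (length(aicc_values) < 2L || any(!is.finite(aicc_values)))
    stop("need at least two finite AICc values")
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  support <- cut(delta, breaks = c(-Inf, 2, 10, Inf),
                 labels = c("strong", "less", "least"))
  data.frame(aicc = aicc_values, delta = delta, weight = w,
             support_class = support)
}

#' Model-comparison table
#'
#' Builds the machine-readable analogue of a printed multi-model summary
#' table from growth fits of the same data: sample size, AICc, delta,
#' Akaike weight, support class, parameter estimates with standard errors,
#' and residual standard error, sorted by delta.
#'
#' @param fits List of [fit_growth] results on the same data/group.
#' @return An object of class `comparison_table` (a data frame).
#' @export
comparison_report <- function(fits) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "growth_fit")))
  ns <- vapply(fits, function(f) f$n, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all fits in one table must share the same data")
  av <- vapply(fits, function(f) f$aicc, numeric(1))
  dw <- if (length(av) >= 2L) delta_and_weights(av) else
    data.frame(aicc = av, delta = 0, weight = 1,
               support_class = factor("strong",
                                      levels = c("strong", "less", "least")))
  fmt <- function(f, what) {
    i <- match(what, names(f$estimates))
    if (is.na(i)) NA_character_
    else sprintf("%.2f±%.2f", f$estimates[i], f$se[i])
  }
  tab <- data.frame(
    group = vapply(fits, function(f) f$group_label, character(1)),
    model = vapply(fits, function(f)
      paste0(growth_family_label(f$spec$family),
             if (f$spec$strategy == "two_param_fixed_L0") " (2p)" else ""),
      character(1)),
    family = vapply(fits, function(f) f$spec$family, character(1)),
    strategy = vapply(fits, function(f) f$spec$strategy, character(1)),
    n = ns,
    aicc = dw$aicc, delta = dw$delta, weight = dw$weight,
    support_class = dw$support_class,
    L0 = vapply(fits, fmt, character(1), "L0"),
    Linf = vapply(fits, fmt, character(1), "Linf"),
    coeff = vapply(fits, fmt, character(1), "coeff"),
    rse = vapply(fits, function(f) f$rse, numeric(1)))
  tab <- tab[order(tab$delta), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("comparison_table", "data.frame"),
            fits = fits)
}

#' @export
print.comparison_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$aicc <- sprintf("%.2f", y$aicc)
  y$delta <- sprintf("%.2f", y$delta)
  y$weight <- sprintf("%.2f", y$weight)
  y$rse <- sprintf("%.2f", y$rse)
  y$family <- y$strategy <- NULL
  print(y, right = FALSE)
  invisible(x)
}

#' Likelihood-ratio test for differences in growth between groups
#'
#' Kimura's test: the same model specification is fitted to the pooled data
#' (a common curve) and to each group separately. With Gaussian residuals
#' the statistic is `X^2 = N log(RSS_common / RSS_separate)`, where
#' `RSS_separate` is the summed group RSS and `N` the total sample size;
#' degrees of freedom are `(groups - 1) * p` for `p` estimated curve
#' parameters, and the p-value is the upper chi-square tail.
#'
#' @param data_by_group Named list of data frames (columns `age`,
#'   `length`), one per group.
#' @param spec A [model_spec] fitted to every group and to the pool.
#' @param ... Passed to [fit_growth] (e.g. `starts`).
#' @return An object of class `kimura_lrt`: list with `chi2`, `df`, `p`,
#'   `rss_common`, `rss_separate`, `n_total`, `fit_common`, `fits_group`.
#' @export
kimura_lrt <- function(data_by_group, spec, ...) {
  stopifnot(is.list(data_by_group), length(data_by_group) >= 2L,
            inherits(spec, "model_spec"))
  if (is.null(names(data_by_group)))
    names(data_by_group) <- paste0("group", seq_along(data_by_group))
  pooled <- do.call(rbind, lapply(data_by_group, function(d)
    d[, c("age", "length"), drop = FALSE]))
  rownames(pooled) <- NULL
  fit_common <- fit_growth(pooled, spec = spec, group_label = "pooled", ...)
  fits_group <- lapply(names(data_by_group), function(g)
    fit_growth(data_by_group[[g]], spec = spec, group_label = g, ...))
  names(fits_group) <- names(data_by_group)
  # augmented strategy adds hypothetical records per fit; use the fitted n
  n_total <- fit_common$n
  rss_common <- fit_common$rss
  rss_separate <- sum(vapply(fits_group, function(f) f$rss, numeric(1)))
  # a numerically perfect separate (or common) fit makes the RSS ratio
  # degenerate; treat RSS below working precision of the data scale as zero
  tiny <- 1e-12 * sum(pooled$length^2)
  chi2 <- if (rss_separate <= tiny) {
    if (rss_common <= tiny) 0 else Inf
  } else max(0, n_total * log(rss_common / rss_separate))
  df <- (length(data_by_group) - 1L) * parameter_count(spec)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 rss_common = rss_common, rss_separate = rss_separate,
                 n_total = n_total, fit_common = fit_common,
                 fits_group = fits_group, spec = spec),
            class = "kimura_lrt")
}

#' @export
print.kimura_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test for common vs separate %s curves\n",
              growth_family_label(x$spec$family)))
  cat(sprintf("  groups: %s\n", paste(names(x$fits_group), collapse = ", ")))
  cat(sprintf("  X^2 = %.2f, df = %d, p = %s\n", x$chi2, x$df,
              format.pval(x$p, digits = 3)))
  invisible(x)
}
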