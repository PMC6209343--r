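#' Fixed length-at-birth by the midpoint rule
#'
#' When length-at-birth cannot be observed in the sampled population, a
#' plausible range is assembled from embryo sizes and published estimates
#' and its midpoint is used as the fixed `L0`.
#'
#' @param low,high Bounds of the plausible length-at-birth range, cm
#'   (`0 < low < high`).
#' @return `(low + high) / 2`.
#' @examples
#' choose_fixed_L0(22, 30) # 26
#' @export
choose_fixed_L0 <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stop("need 0 < low < high")
  (low + high) / 2
}

#' Run the full age–growth–maturity analysis
#'
#' End-to-end pipeline over a specimen table: partial ageing, reader
#' precision, growth fits for all three families under each of the three
#' fitting strategies and for each grouping (combined, female, male),
#' comparison tables with AICc ranking, a likelihood-ratio test for sex
#' differences, maturity ogives on the length and age scales per sex, and
#' plot-ready data series. Specimens without a consensus band count are
#' excluded from growth fitting and accounted for in the manifest.
#'
#' @param specimens Specimen data frame (see [read_specimens]).
#' @param fixed_L0 Fixed length-at-birth, cm; default the midpoint of
#'   `L0_bounds`.
#' @param L0_bounds Plausible length-at-birth range for the midpoint rule.
#' @param n_hypothetical Age-zero animals appended by the augmented
#'   strategy.
#' @param birth_month_day,days_per_year Partial-age convention.
#' @param tolerance Agreement tolerance (years) for PA.
#' @param lrt_strategy Strategy of the comparison table whose AICc-best
#'   family is carried into the likelihood-ratio test. Default
#'   `"three_param"`.
#' @param bootstrap_B Bootstrap replicates for growth and ogive intervals
#'   (0 = skip; they dominate run time).
#' @param seed Root seed for all bootstrap resampling.
#' @return An object of class `growth_analysis`: list with `specimens`
#'   (aged, with exclusion flags), `precision` ([precision_report]),
#'   `tables` (strategy -> group -> [comparison_report]), `lrt`
#'   ([kimura_lrt]), `ogives` (sex -> scale -> [fit_ogive]), `bootstraps`
#'   (when requested), `plot_data`, and `manifest`.
#' @export
run_full_analysis <- function(specimens,
                              fixed_L0 = NULL, L0_bounds = c(22, 30),
                              n_hypothetical = 4L,
                              birth_month_day = "01-15", days_per_year = 365,
                              tolerance = 1L,
                              lrt_strategy = "three_param",
                              bootstrap_B = 0L, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  d <- stage("validate", validate_specimens(specimens))
  if (is.null(fixed_L0)) fixed_L0 <- choose_fixed_L0(L0_bounds[1], L0_bounds[2])

  d <- stage("ageing", {
    d$partial_age <- ifelse(is.na(d$consensus_band_count), NA_real_,
      assign_partial_age(d$consensus_band_count, d$capture_date,
                         birth_month_day, days_per_year))
    d$excluded <- is.na(d$partial_age)
    d
  })

  precision <- stage("precision",
    precision_report(d$band_count_r1, d$band_count_r2, tolerance))

  used <- d[!d$excluded, , drop = FALSE]
  groups <- list(combined = used,
                 female = used[used$sex == "F", , drop = FALSE],
                 male = used[used$sex == "M", , drop = FALSE])
  strategies <- c("three_param", "three_param_augmented", "two_param_fixed_L0")
  families <- c("vb", "logistic", "gompertz")

  tables <- stage("growth", {
    lapply(stats::setNames(strategies, strategies), function(strat)
      lapply(stats::setNames(names(groups), names(groups)), function(gname) {
        g <- groups[[gname]]
        gd <- data.frame(age = g$partial_age, length = g$total_length_cm,
                         specimen_id = g$specimen_id)
        fits <- lapply(families, function(fam)
          fit_growth(gd, spec = model_spec(fam, strat, fixed_L0,
                                           n_hypothetical),
                     group_label = gname))
        comparison_report(fits)
      }))
  })

  lrt <- stage("lrt", {
    best <- tables[[lrt_strategy]]$combined
    fam <- best$family[which.min(best$delta)]
    by_sex <- lapply(groups[c("female", "male")], function(g)
      data.frame(age = g$partial_age, length = g$total_length_cm))
    kimura_lrt(by_sex, model_spec(fam, lrt_strategy, fixed_L0,
                                  n_hypothetical))
  })

  ogives <- stage("maturity", {
    lapply(list(female = "F", male = "M"), function(s) {
      ds <- d[d$sex == s, , drop = FALSE]
      mat <- binarize_stage(ds$maturity_stage, ds$sex)
      list(
        length = fit_ogive(ds$total_length_cm, mat, scale = "length",
                           boot_B = bootstrap_B, boot_seed = seed),
        age = {
          # a capture on the birth anniversary gives partial age exactly 0,
          # outside the ogive's positive-covariate domain
          dm <- ds[!is.na(ds$partial_age) & ds$partial_age > 0, , drop = FALSE]
          fit_ogive(dm$partial_age,
                    binarize_stage(dm$maturity_stage, dm$sex),
                    scale = "age", boot_B = bootstrap_B,
                    boot_seed = seed + 1L)
        })
    })
  })

  bootstraps <- NULL
  if (bootstrap_B > 0L) {
    bootstraps <- stage("bootstrap", {
      best2p <- tables$two_param_fixed_L0
      lapply(stats::setNames(names(best2p), names(best2p)), function(gname) {
        tab <- best2p[[gname]]
        fit <- attr(tab, "fits")[[which.min(tab$delta)]]
        bootstrap_ci(fit, B = bootstrap_B, seed = seed + 2L)
      })
    })
  }

  plot_data <- stage("plot_data", {
    curves <- do.call(rbind, lapply(c("female", "male"), function(gname) {
      tab <- tables$two_param_fixed_L0[[gname]]
      fit <- attr(tab, "fits")[[which.min(tab$delta)]]
      tt <- seq(0, max(fit$data$age), length.out = 100)
      data.frame(group = gname, age = tt,
                 length = predict_length(fit$params, tt))
    }))
    og <- do.call(rbind, lapply(c("female", "male"), function(s)
      do.call(rbind, lapply(c("length", "age"), function(sc) {
        o <- ogives[[s]][[sc]]
        xx <- seq(max(0.05, o$x50 - 3 * (o$x95 - o$x50)),
                  o$x95 + 2 * (o$x95 - o$x50), length.out = 100)
        data.frame(sex = s, scale = sc, x = xx,
                   p = maturity_prob(xx, o$x50, o$x95, o$pmax))
      }))))
    list(age_class_histogram = as.data.frame(
           table(class = used$consensus_band_count, sex = used$sex)),
         growth_curves = curves,
         ogive_curves = og)
  })

  manifest <- list(
    config = list(fixed_L0 = fixed_L0, L0_bounds = L0_bounds,
                  n_hypothetical = n_hypothetical,
                  birth_month_day = birth_month_day,
                  days_per_year = days_per_year, tolerance = tolerance,
                  lrt_strategy = lrt_strategy,
                  bootstrap_B = bootstrap_B, seed = seed),
    package_version = as.character(utils::packageVersion("sharpnose")),
    n_input = nrow(d),
    n_used = nrow(used),
    n_excluded = sum(d$excluded),
    excluded_ids = d$specimen_id[d$excluded],
    exclusion_reason = if (any(d$excluded)) "missing consensus band count"
                       else character(0))

  structure(list(specimens = d, precision = precision, tables = tables,
                 lrt = lrt, ogives = ogives, bootstraps = bootstraps,
                 plot_data = plot_data, manifest = manifest),
            class = "growth_analysis")
}

#' @export
print.growth_analysis <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Age-growth-maturity analysis: %d specimens (%d used, %d excluded)\n",
              m$n_input, m$n_used, m$n_excluded))
  cat("\n"); print(x$precision)
  cat("\nTwo-parameter (fixed L0) comparison, sexes combined:\n")
  print(x$tables$two_param_fixed_L0$combined)
  cat("\n"); print(x$lrt)
  cat("\n"); print(x$ogives$female$length)
  print(x$ogives$male$length)
  invisible(x)
}
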