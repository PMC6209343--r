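#' Candidate growth functions
#'
#' Three length-at-age functions commonly used in elasmobranch age-and-growth
#' studies, all parameterized by length-at-birth `L0`, asymptotic length
#' `Linf` and a per-year growth-completion coefficient, so that every family
#' satisfies `L(0) = L0` and `L(t) -> Linf` as `t -> Inf`:
#'
#' * von Bertalanffy (`"vb"`):
#'   `L(t) = L0 + (Linf - L0) * (1 - exp(-k t))`
#' * logistic (`"logistic"`):
#'   `L(t) = Linf * L0 * exp(g t) / (Linf + L0 * (exp(g t) - 1))`
#' * Gompertz (`"gompertz"`):
#'   `L(t) = Linf * exp(log(L0 / Linf) * exp(-g t))`
#'
#' @param family One of `"vb"`, `"logistic"`, `"gompertz"`.
#' @param L0 Length-at-birth, cm TL. Must satisfy `0 < L0 < Linf`.
#' @param Linf Asymptotic length, cm TL.
#' @param coeff Growth-completion rate, per year (`k` for von Bertalanffy,
#'   `g` for the sigmoid families). Must be positive.
#'
#' @return An object of class `growth_params`: a list with elements
#'   `family`, `L0`, `Linf`, `coeff`.
#' @examples
#' p <- growth_params("vb", L0 = 26, Linf = 55.95, coeff = 1.27)
#' predict_length(p, age = 1) # 47.54 cm
#' @export
growth_params <- function(family = c("vb", "logistic", "gompertz"),
                          L0, Linf, coeff) {
  family <- match.arg(family)
  stopifnot(is.numeric(L0), is.numeric(Linf), is.numeric(coeff),
            length(L0) == 1L, length(Linf) == 1L, length(coeff) == 1L)
  if (!is.finite(Linf) || Linf <= 0)
    stop("'Linf' must be a positive, finite length (cm)")
  if (!is.finite(L0) || L0 <= 0 || L0 >= Linf)
    stop("'L0' must satisfy 0 < L0 < Linf")
  if (!is.finite(coeff) || coeff <= 0)
    stop("growth coefficient must be positive")
  structure(list(family = family, L0 = L0, Linf = Linf, coeff = coeff),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  lab <- growth_family_label(x$family)
  cat(sprintf("%s growth parameters: L0 = %.2f cm, Linf = %.2f cm, %s = %.3f /yr\n",
              lab, x$L0, x$Linf, coeff_name(x$family), x$coeff))
  invisible(x)
}

growth_family_label <- function(family) {
  c(vb = "von Bertalanffy", logistic = "Logistic", gompertz = "Gompertz")[[family]]
}

coeff_name <- function(family) {
  c(vb = "k", logistic = "g(log)", gompertz = "g(gom)")[[family]]
}

# length-at-age kernels; vectorized over t
growth_curve <- function(family, t, L0, Linf, coeff) {
  switch(family,
    vb       = L0 + (Linf - L0) * (1 - exp(-coeff * t)),
    logistic = (Linf * L0 * exp(coeff * t)) / (Linf + L0 * (exp(coeff * t) - 1)),
    gompertz = Linf * exp(log(L0 / Linf) * exp(-coeff * t)),
    stop("unknown growth family: ", family)
  )
}

#' Predicted length at age
#'
#' Evaluates a growth function at one or more ages.
#'
#' @param params A [growth_params] object.
#' @param age Ages in years; non-negative.
#' @return Predicted total lengths, cm TL.
#' @export
predict_length <- function(params, age) {
  if (!inherits(params, "growth_params"))
    stop("'params' must be a growth_params object")
  if (any(!is.finite(age)) || any(age < 0))
    stop("'age' must be finite and non-negative")
  growth_curve(params$family, age, params$L0, params$Linf, params$coeff)
}

#' Growth model specification
#'
#' Pairs a growth-function family with one of three fitting strategies used
#' when small, young-of-year animals are missing from the sample:
#'
#' * `"three_param"` — estimate `L0`, `Linf` and the growth coefficient.
#' * `"two_param_fixed_L0"` — hold `L0` at a known length-at-birth and
#'   estimate only `Linf` and the coefficient.
#' * `"three_param_augmented"` — append `n_hypothetical` hypothetical
#'   age-zero animals of length `fixed_L0_value` to the sample, then fit the
#'   three-parameter model.
#'
#' @param family Growth family, as in [growth_params].
#' @param strategy Fitting strategy (see Details).
#' @param fixed_L0_value Length-at-birth in cm used by the fixed-`L0` and
#'   augmented strategies. Default 26.
#' @param n_hypothetical Number of hypothetical age-zero animals appended by
#'   the augmented strategy. Default 4.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("vb", "two_param_fixed_L0", fixed_L0_value = 26)
#' @export
model_spec <- function(family = c("vb", "logistic", "gompertz"),
                       strategy = c("three_param", "two_param_fixed_L0",
                                    "three_param_augmented"),
                       fixed_L0_value = 26, n_hypothetical = 4L) {
  family <- match.arg(family)
  strategy <- match.arg(strategy)
  if (strategy != "three_param") {
    if (!is.numeric(fixed_L0_value) || length(fixed_L0_value) != 1L ||
        !is.finite(fixed_L0_value) || fixed_L0_value <= 0)
      stop("'fixed_L0_value' must be a positive length (cm) for strategy ",
           strategy)
  }
  n_hypothetical <- as.integer(n_hypothetical)
  if (strategy == "three_param_augmented" && n_hypothetical < 0)
    stop("'n_hypothetical' must be >= 0")
  structure(list(family = family, strategy = strategy,
                 fixed_L0_value = fixed_L0_value,
                 n_hypothetical = n_hypothetical),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s, %s (%d estimated parameters)\n",
              growth_family_label(x$family), x$strategy, parameter_count(x)))
  invisible(x)
}

#' Number of estimated parameters for a model specification
#'
#' Three for the three-parameter and zero-age-augmented strategies
#' (augmentation changes the data, not the parameter space); two when
#' length-at-birth is fixed.
#'
#' @param spec A [model_spec] object.
#' @return Integer parameter count (excludes the error variance).
#' @export
parameter_count <- function(spec) {
  if (!inherits(spec, "model_spec")) stop("'spec' must be a model_spec")
  if (spec$strategy == "two_param_fixed_L0") 2L else 3L
}
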