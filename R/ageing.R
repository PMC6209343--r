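#' Partial decimal ages from band-pair counts
#'
#' For a seasonally reproducing species with a known single pupping pulse,
#' the integer band-pair count can be refined into a decimal age: the count
#' plus the fraction of a year elapsed between the most recent birth
#' anniversary (on or before the capture date) and capture. The elapsed
#' fraction is the calendar-day difference divided by a fixed
#' `days_per_year` (365 by default, including in leap years).
#'
#' @param band_count Integer band-pair counts (age classes); `NA` allowed —
#'   the result is `NA` for those records.
#' @param capture_date Capture dates (`Date` or ISO-8601 strings).
#' @param birth_month_day Assumed birth date within the year, `"MM-DD"`.
#'   Default `"01-15"` (mid-January pupping pulse).
#' @param days_per_year Days used to convert the elapsed span to a year
#'   fraction. Default 365.
#' @return Partial ages in years; each value lies in
#'   `[band_count, band_count + 1)`.
#' @examples
#' assign_partial_age(1, as.Date("2015-08-30")) # 1.62
#' assign_partial_age(2, as.Date("2015-01-15")) # 2.00
#' @export
assign_partial_age <- function(band_count, capture_date,
                               birth_month_day = "01-15",
                               days_per_year = 365) {
  capture_date <- as.Date(capture_date)
  if (length(band_count) != length(capture_date)) {
    n <- max(length(band_count), length(capture_date))
    band_count <- rep_len(band_count, n)
    capture_date <- rep_len(capture_date, n)
  }
  if (any(is.na(capture_date)))
    stop("capture_date contains missing or unparseable dates")
  if (!is.numeric(days_per_year) || days_per_year <= 0)
    stop("'days_per_year' must be positive")
  bad <- !is.na(band_count) & (band_count < 0 | band_count != floor(band_count))
  if (any(bad))
    stop("band counts must be non-negative integers")

  anniv <- birth_anniversary(capture_date, birth_month_day)
  frac <- as.numeric(capture_date - anniv) / days_per_year
  # spans longer than days_per_year (leap years) would break the
  # [count, count + 1) contract; cap just below 1
  frac <- pmin(frac, 1 - 1e-9)
  band_count + frac
}

# most recent occurrence of birth_month_day on or before each date
birth_anniversary <- function(dates, birth_month_day = "01-15") {
  if (!grepl("^[0-1][0-9]-[0-3][0-9]$", birth_month_day))
    stop("'birth_month_day' must be an \"MM-DD\" string")
  yr <- as.integer(format(dates, "%Y"))
  anniv <- as.Date(paste0(yr, "-", birth_month_day))
  if (any(is.na(anniv))) stop("invalid 'birth_month_day': ", birth_month_day)
  before <- dates < anniv
  if (any(before))
    anniv[before] <- as.Date(paste0(yr[before] - 1L, "-", birth_month_day))
  anniv
}

#' Consensus band counts from two readers
#'
#' Where the two readers agree, the consensus is their shared count. Where
#' they differ, the consensus must come from an explicit, user-supplied
#' resolution table (the outcome of the readers jointly re-examining the
#' section); disagreements with no resolution entry are flagged excluded —
#' never silently dropped and never resolved by an automatic rule.
#'
#' @param records Data frame with columns `specimen_id`, `band_count_r1`,
#'   `band_count_r2`.
#' @param resolution Optional data frame with columns `specimen_id` and
#'   `consensus` giving the jointly agreed count for specimens whose reads
#'   differ. An entry that matches neither read is an error.
#' @return `records` with columns `consensus_band_count` (integer, `NA`
#'   when unresolved) and `excluded` (logical) added. The number of
#'   excluded records is attached as attribute `"n_excluded"` and reported
#'   via [message()].
#' @export
consensus_ages <- function(records, resolution = NULL) {
  stopifnot(is.data.frame(records),
            all(c("specimen_id", "band_count_r1", "band_count_r2")
                %in% names(records)))
  r1 <- records$band_count_r1
  r2 <- records$band_count_r2
  consensus <- ifelse(!is.na(r1) & !is.na(r2) & r1 == r2, r1, NA_integer_)
  disagree <- !is.na(r1) & !is.na(r2) & r1 != r2
  if (!is.null(resolution)) {
    stopifnot(is.data.frame(resolution),
              all(c("specimen_id", "consensus") %in% names(resolution)))
    idx <- match(records$specimen_id, resolution$specimen_id)
    has <- !is.na(idx) & disagree
    res <- resolution$consensus[idx[has]]
    conflict <- res != r1[has] & res != r2[has]
    if (any(conflict))
      stop("resolution entry matches neither read for specimen(s): ",
           paste(records$specimen_id[has][conflict], collapse = ", "))
    consensus[has] <- res
  }
  records$consensus_band_count <- as.integer(consensus)
  records$excluded <- is.na(consensus)
  n_excl <- sum(records$excluded)
  if (n_excl > 0)
    message(n_excl, " specimen(s) excluded: unresolved reader disagreement")
  attr(records, "n_excluded") <- n_excl
  records
}

# coerce reads to an n x R matrix and drop fish with a zero mean read
# (division guard for APE / CV)
read_matrix <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) < 2L) stop("need at least two reads per specimen")
  storage.mode(m) <- "double"
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Average percent error between readers
#'
#' Beamish–Fournier index of ageing precision. For fish `j` with `R` reads
#' `x_ij` and mean `m_j`, the per-fish error is
#' `100 / R * sum_i |x_ij - m_j| / m_j`; APE is its mean across fish. Fish
#' whose mean read is zero are excluded (division guard).
#'
#' @param counts Matrix or data frame of age reads, one row per fish, one
#'   column per reader (two or more).
#' @return APE in percent.
#' @examples
#' average_percent_error(cbind(1, 2)) # 33.33
#' @export
average_percent_error <- function(counts) {
  m <- read_matrix(counts)
  means <- rowMeans(m)
  keep <- means > 0
  if (!any(keep)) stop("no fish with a positive mean read")
  per_fish <- rowMeans(abs(m[keep, , drop = FALSE] - means[keep]) / means[keep])
  mean(per_fish) * 100
}

#' Chang's coefficient of variation between readers
#'
#' Per fish, the sample standard deviation of the reads (denominator
#' `R - 1`) divided by their mean, expressed in percent; the index is the
#' mean over fish. Fish with a zero mean read are excluded.
#'
#' @inheritParams average_percent_error
#' @return CV in percent.
#' @export
chang_cv <- function(counts) {
  m <- read_matrix(counts)
  means <- rowMeans(m)
  keep <- means > 0
  if (!any(keep)) stop("no fish with a positive mean read")
  sds <- apply(m[keep, , drop = FALSE], 1L, stats::sd)
  mean(sds / means[keep]) * 100
}

#' Percent agreement between two readers
#'
#' Share of fish whose two reads differ by at most `tolerance` years
#' (PA +/- `tolerance`).
#'
#' @param counts Two-column matrix or data frame of reads.
#' @param tolerance Non-negative integer tolerance in years. Default 1.
#' @return Agreement in percent.
#' @export
percent_agreement <- function(counts, tolerance = 1L) {
  m <- read_matrix(counts)
  if (ncol(m) != 2L) stop("percent agreement is defined for two readers")
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  mean(abs(m[, 1L] - m[, 2L]) <= tolerance) * 100
}

#' Cross-tabulate two readers' age estimates
#'
#' Square contingency table of reader-1 by reader-2 counts over the shared
#' range of age classes, the data behind an age-bias plot and input to
#' [bowker_symmetry()].
#'
#' @param r1,r2 Integer age reads of the same specimens.
#' @return A square `table` indexed by age class.
#' @export
age_crosstab <- function(r1, r2) {
  ok <- !is.na(r1) & !is.na(r2)
  r1 <- r1[ok]; r2 <- r2[ok]
  lev <- seq(min(r1, r2), max(r1, r2))
  table(factor(r1, levels = lev), factor(r2, levels = lev),
        dnn = c("reader1", "reader2"))
}

#' Bowker's test of symmetry
#'
#' Tests for systematic bias between two readers. Over unordered
#' off-diagonal cell pairs `(i, j)` with `n_ij + n_ji > 0`,
#' `X^2 = sum (n_ij - n_ji)^2 / (n_ij + n_ji)`; the degrees of freedom
#' count only those non-empty pairs, and the p-value is the upper
#' chi-square tail. With no non-empty pair the statistic is 0 and the
#' p-value `NA`.
#'
#' @param crosstab Square matrix or table of paired age reads, e.g. from
#'   [age_crosstab()].
#' @return An object of class `htest`.
#' @export
bowker_symmetry <- function(crosstab) {
  m <- as.matrix(unclass(crosstab))
  if (nrow(m) != ncol(m)) stop("'crosstab' must be square")
  if (any(m < 0)) stop("'crosstab' cells must be non-negative counts")
  k <- nrow(m)
  chi2 <- 0
  df <- 0L
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        tot <- m[i, j] + m[j, i]
        if (tot > 0) {
          chi2 <- chi2 + (m[i, j] - m[j, i])^2 / tot
          df <- df + 1L
        }
      }
    }
  }
  p <- if (df > 0L) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(list(statistic = c("X-squared" = chi2),
                 parameter = c(df = df),
                 p.value = p,
                 method = "Bowker's test of symmetry",
                 data.name = deparse(substitute(crosstab))),
            class = "htest")
}

#' Between-reader precision report
#'
#' Bundles the standard ageing precision and bias statistics for a set of
#' doubly-read specimens: APE, Chang's CV, percent agreement at a stated
#' tolerance, and Bowker's symmetry test.
#'
#' @param r1,r2 Integer age reads of the same specimens (missing pairs are
#'   dropped).
#' @param tolerance Agreement tolerance in years for PA. Default 1.
#' @return An object of class `precision_report`: list with `ape_percent`,
#'   `cv_percent`, `pa_percent`, `pa_tolerance`, `bowker` (an `htest`),
#'   `crosstab`, `n`.
#' @export
precision_report <- function(r1, r2, tolerance = 1L) {
  ok <- !is.na(r1) & !is.na(r2)
  m <- cbind(r1 = r1[ok], r2 = r2[ok])
  tab <- age_crosstab(m[, 1L], m[, 2L])
  structure(list(ape_percent = average_percent_error(m),
                 cv_percent = chang_cv(m),
                 pa_percent = percent_agreement(m, tolerance),
                 pa_tolerance = as.integer(tolerance),
                 bowker = bowker_symmetry(tab),
                 crosstab = tab,
                 n = nrow(m)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Between-reader ageing precision (n =", x$n, "doubly-read fish)\n")
  cat(sprintf("  APE:        %5.1f %%\n", x$ape_percent))
  cat(sprintf("  Chang's CV: %5.1f %%\n", x$cv_percent))
  cat(sprintf("  PA +/- %d:   %5.1f %%\n", x$pa_tolerance, x$pa_percent))
  b <- x$bowker
  cat(sprintf("  Bowker's symmetry: X^2 = %.2f, df = %d, p = %s\n",
              b$statistic, b$parameter,
              if (is.na(b$p.value)) "NA" else format.pval(b$p.value, digits = 3)))
  invisible(x)
}
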