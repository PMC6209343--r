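specimen_columns <- c("specimen_id", "sex", "total_length_cm", "capture_date",
                      "band_count_r1", "band_count_r2",
                      "consensus_band_count", "maturity_stage")

#' Read a specimen table from CSV
#'
#' Reads and validates the one-row-per-shark specimen schema: UTF-8 CSV
#' with a header and the columns `specimen_id`, `sex` (F/M),
#' `total_length_cm`, `capture_date` (ISO 8601), `band_count_r1`,
#' `band_count_r2`, `consensus_band_count`, `maturity_stage`. Extra
#' columns are preserved.
#'
#' @param path Path to the CSV file.
#' @return A validated specimen data frame with `capture_date` as `Date`.
#' @export
read_specimens <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(specimen_id = "character",
                                      maturity_stage = "character"),
                       encoding = "UTF-8")
  validate_specimens(d)
}

#' Write a specimen table to CSV
#'
#' @param specimens Specimen data frame (see [read_specimens] for schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  d <- specimens
  d$capture_date <- format(as.Date(d$capture_date), "%Y-%m-%d")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a specimen table
#'
#' Checks the specimen schema and record invariants: positive lengths,
#' integer non-negative band counts, parseable dates, sex codes F/M, and
#' stage codes consistent with sex.
#'
#' @param specimens Data frame to validate.
#' @return The data frame, with `capture_date` coerced to `Date`.
#' @export
validate_specimens <- function(specimens) {
  missing_cols <- setdiff(specimen_columns, names(specimens))
  if (length(missing_cols))
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- specimens
  d$capture_date <- as.Date(d$capture_date)
  if (anyNA(d$capture_date)) stop("unparseable capture_date values")
  if (!all(d$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  if (any(!is.finite(d$total_length_cm) | d$total_length_cm <= 0))
    stop("total_length_cm must be positive")
  for (col in c("band_count_r1", "band_count_r2", "consensus_band_count")) {
    v <- d[[col]]
    bad <- !is.na(v) & (v < 0 | v != floor(v))
    if (any(bad)) stop(col, " must be non-negative integers")
  }
  invisible(binarize_stage(d$maturity_stage, d$sex)) # errors on bad codes
  d
}
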