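#' Read a concentration-sample table from CSV
#'
#' Expected columns: `sample_id`, `element`, and `concentration_ug_per_kg`
#' (or `concentration`, taken in the same units). Any further columns
#' (`province`, `region`, `source`, ...) are kept as free-form stratum labels.
#' Concentrations are in ug/kg dry weight.
#'
#' Rows with a missing, non-numeric or negative concentration are rejected
#' with an error naming the offending row number(s); a duplicated
#' (`sample_id`, `element`) pair is a hard error because it would make the
#' dataset ambiguous.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A `data.frame` of validated samples with a canonical
#'   `concentration_ug_per_kg` column.
#' @seealso [write_samples()] for the inverse operation.
#' @export
read_samples <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_samples(raw, what = basename(path))
}

#' Write a concentration-sample table to CSV
#'
#' @param samples A sample `data.frame` as returned by [read_samples()] or
#'   [generate_samples()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a concentration-sample table
#'
#' @param samples A `data.frame` with at least `sample_id`, `element` and a
#'   concentration column.
#' @param what Label used in error messages (e.g. a file name).
#' @return The validated table with numeric `concentration_ug_per_kg`.
#' @export
validate_samples <- function(samples, what = "samples") {
  stopifnot(is.data.frame(samples))
  if (!is.null(samples$concentration) &&
      is.null(samples$concentration_ug_per_kg)) {
    names(samples)[names(samples) == "concentration"] <-
      "concentration_ug_per_kg"
  }
  need <- c("sample_id", "element", "concentration_ug_per_kg")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    stop(what, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  conc <- suppressWarnings(as.numeric(samples$concentration_ug_per_kg))
  bad <- which(is.na(conc) | conc < 0)
  if (length(bad) > 0) {
    stop(what, ": invalid concentration (non-numeric or negative) in row",
         if (length(bad) > 1) "s" else "", " ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(samples$sample_id, samples$element, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key), c("sample_id", "element"), drop = FALSE]
    stop(what, ": duplicate (sample_id, element) pair(s): ",
         paste(unique(paste0(dup$sample_id, "/", dup$element)),
               collapse = ", "), call. = FALSE)
  }
  samples$concentration_ug_per_kg <- conc
  samples
}
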