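#' Tab-separated read/write in the package dialect
#'
#' Plain TSV with a header row, `.`-decimal, empty fields for missing
#' values, no quoting and no row names — the on-disk form of every tabular
#' output (event tables, eigen series, long analysis tables).
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path)
  read.table(path, sep = "\t", header = TRUE, na.strings = "",
             stringsAsFactors = FALSE)

#' Validate an event table
#'
#' Checks the invariants every consumer relies on: strictly increasing
#' onsets, positive RTs on responded trials, and
#' `response_onset_s = onset_s + rt_s`. The first offending row is named.
#'
#' @param events event table.
#' @return `events`, invisibly, if valid.
#' @export
validate_events <- function(events) {
  need <- c("trial_index", "onset_s", "condition", "correct", "rt_s",
            "response_onset_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table missing columns: ", paste(miss, collapse = ", "))
  bad <- which(diff(events$onset_s) <= 0)
  if (length(bad)) stop("onsets not strictly increasing at row ", bad[1] + 1)
  bad <- which(!is.na(events$rt_s) & events$rt_s <= 0)
  if (length(bad)) stop("non-positive rt_s at row ", bad[1])
  bad <- which(abs(events$response_onset_s - events$onset_s - events$rt_s) > 1e-9)
  if (length(bad)) stop("response_onset_s != onset_s + rt_s at row ", bad[1])
  invisible(events)
}
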