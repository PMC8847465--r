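# Mutation event tables: one row per substitution or collapsed indel event.
# Coordinates are 1-based inclusive alignment columns within the region.

EVENT_COLUMNS <- c("locus_id", "region_kind", "subregion", "start", "end",
                   "kind", "multiplicity", "category",
                   "state_or", "state_on", "state_indica", "state_japonica",
                   "derived_state", "coding_effect", "aa_change_count")

#' An empty mutation-event table
#' @return Zero-row data frame with the canonical event columns.
#' @export
empty_events <- function() {
  data.frame(
    locus_id = character(0), region_kind = character(0),
    subregion = character(0),
    start = integer(0), end = integer(0),
    kind = character(0), multiplicity = integer(0), category = character(0),
    state_or = character(0), state_on = character(0),
    state_indica = character(0), state_japonica = character(0),
    derived_state = character(0), coding_effect = character(0),
    aa_change_count = integer(0),
    stringsAsFactors = FALSE
  )
}

normalize_events <- function(df) {
  for (col in setdiff(EVENT_COLUMNS, names(df))) {
    df[[col]] <- if (col %in% c("start", "end", "multiplicity", "aa_change_count")) {
      NA_integer_
    } else NA_character_
  }
  df <- df[, EVENT_COLUMNS, drop = FALSE]
  df[order(df$locus_id, df$region_kind, df$start, df$end), , drop = FALSE]
}

#' Write a mutation-event table as TSV
#'
#' Rows are sorted by locus, region and position; column order is stable so
#' that the table round-trips through [read_event_table()].
#'
#' @param events Event data frame.
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
write_event_table <- function(events, out_path) {
  events <- normalize_events(events)
  ok <- tryCatch({
    utils::write.table(events, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ggm_stop(paste0("cannot write ", out_path), "ggm_io_error")
  invisible(out_path)
}

#' Read back a mutation-event table written by [write_event_table()]
#' @param path TSV path.
#' @return Event data frame.
#' @export
read_event_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            locus_id = "character", region_kind = "character",
                            subregion = "character",
                            start = "integer", end = "integer",
                            kind = "character", multiplicity = "integer",
                            category = "character",
                            state_or = "character", state_on = "character",
                            state_indica = "character",
                            state_japonica = "character",
                            derived_state = "character",
                            coding_effect = "character",
                            aa_change_count = "integer"),
                          na.strings = "", stringsAsFactors = FALSE)
  normalize_events(df)
}
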