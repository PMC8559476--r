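#' Evoked dataset container
#'
#' In-memory container for a subject's standard and deviant event-related
#' fields with channel geometry and free-form metadata. On disk the
#' container is a directory of delimited matrices (`standard.tsv`,
#' `deviant.tsv`: channels x time; `times.tsv`; `channels.tsv`) with a
#' `meta.json` sidecar holding condition labels and provenance.
#'
#' @param standard,deviant matrices, channels x time.
#' @param times time axis (s).
#' @param channels data frame of channel names/positions (defaults to the
#'   synthetic 102-magnetometer layout).
#' @param meta named list of metadata (subject, group, condition, snr, ...).
#' @return object of class `"evoked_dataset"`.
#' @export
evoked_dataset <- function(standard, deviant, times, channels = NULL,
                           meta = list()) {
  stopifnot(ncol(standard) == length(times), ncol(deviant) == length(times),
            nrow(standard) == nrow(deviant))
  structure(list(standard = standard, deviant = deviant, times = times,
                 channels = channels, meta = meta),
            class = "evoked_dataset")
}

#' @export
print.evoked_dataset <- function(x, ...) {
  cat(sprintf("<evoked_dataset> %d channels x %d samples (%.0f-%.0f ms)\n",
              nrow(x$standard), length(x$times),
              1000 * min(x$times), 1000 * max(x$times)))
  if (length(x$meta)) {
    flat <- x$meta[vapply(x$meta, function(v) is.atomic(v) && length(v) == 1, TRUE)]
    if (length(flat))
      cat("  ", paste(names(flat), unlist(flat), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read and write evoked datasets
#'
#' @param x an `evoked_dataset`.
#' @param path directory to write to / read from.
#' @return `write_evoked` returns `path` invisibly; `read_evoked` returns
#'   an `evoked_dataset`.
#' @export
write_evoked <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) utils::write.table(
    m, file.path(path, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  wm(x$standard, "standard.tsv")
  wm(x$deviant, "deviant.tsv")
  wm(matrix(x$times, ncol = 1), "times.tsv")
  if (!is.null(x$channels))
    utils::write.table(x$channels, file.path(path, "channels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_evoked
#' @export
read_evoked <- function(path) {
  rm_ <- function(f) as.matrix(utils::read.table(file.path(path, f), sep = "\t"))
  ch_file <- file.path(path, "channels.tsv")
  evoked_dataset(
    standard = unname(rm_("standard.tsv")),
    deviant = unname(rm_("deviant.tsv")),
    times = drop(rm_("times.tsv")),
    channels = if (file.exists(ch_file))
      utils::read.delim(ch_file, stringsAsFactors = FALSE) else NULL,
    meta = jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  )
}

#' Read and write paradigm event tables
#'
#' Event tables are TSV files with the note-event schema: `onset_ms`,
#' `duration_ms`, `midi`, `cents_offset`, `feature`, `note_index`,
#' `melody_id`, `block`, `condition`.
#'
#' @param events event table (data frame).
#' @param path TSV file path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
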