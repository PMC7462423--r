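#' Read a spike table
#'
#' Reads a delimited text file of spike events into a [SpikeRecording-class].
#' The file must have a header with columns `neuron_id` (integer) and
#' `spike_time_s` (seconds, decimal); tab or comma delimiters are
#' auto-detected. An optional metadata comment line `# duration_s: <x>`
#' before the header fixes the recording duration; otherwise the duration is
#' the maximum spike time rounded up to the next whole second. Unsorted
#' times are sorted on read.
#'
#' @param path Path to the spike table.
#' @return A [SpikeRecording-class].
#' @seealso [writeSpikeTable()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeSpikeTable(SpikeRecording(list(`1` = c(0.1, 0.25), `2` = 0.2), 1), f)
#' readSpikeTable(f)
#' @export
readSpikeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_duration <- NULL
  label <- basename(path)
  meta <- grep("^#", lines, value = TRUE)
  m <- regmatches(meta, regexec("duration_s:\\s*([0-9.eE+-]+)", meta))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) meta_duration <- as.numeric(m[hit][[1]][2])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) stop("no header line found in ", path)
  delim <- if (grepl("\t", body[1])) "\t" else ","
  header <- strsplit(body[1], delim, fixed = TRUE)[[1]]
  ic <- match("neuron_id", header)
  tc <- match("spike_time_s", header)
  if (is.na(ic) || is.na(tc))
    stop("header must contain columns neuron_id and spike_time_s")
  rows <- body[-1]
  if (length(rows) == 0L) {
    return(SpikeRecording(list(), duration = if (is.null(meta_duration)) 0 else meta_duration,
                          label = label))
  }
  parts <- strsplit(rows, delim, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < max(ic, tc))
  if (length(bad))
    stop("malformed row at line ", bad[1] + length(lines) - length(rows), " of ", path)
  ids <- suppressWarnings(as.integer(vapply(parts, `[[`, "", ic)))
  tms <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", tc)))
  if (anyNA(ids) || anyNA(tms)) {
    bad <- which(is.na(ids) | is.na(tms))[1]
    stop("malformed row at line ", bad + length(lines) - length(rows), " of ", path)
  }
  if (any(tms < 0)) stop("negative spike time in ", path)
  spikes <- split(tms, ids)
  spikes <- spikes[order(as.integer(names(spikes)))]
  SpikeRecording(spikes, duration = meta_duration, label = label)
}

#' Write a spike table
#'
#' Writes a [SpikeRecording-class] as tab-delimited text with a
#' `# duration_s:` metadata line, a `neuron_id`/`spike_time_s` header, and
#' one row per spike. [readSpikeTable()] on the result reproduces the input.
#'
#' @param recording A [SpikeRecording-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeSpikeTable <- function(recording, path) {
  stopifnot(is(recording, "SpikeRecording"))
  validObject(recording)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s: %s", format(recording@duration, digits = 15)), con)
  writeLines("neuron_id\tspike_time_s", con)
  if (nNeurons(recording) > 0) {
    ids <- rep(names(recording@spikes), lengths(recording@spikes))
    tms <- unlist(recording@spikes, use.names = FALSE)
    if (length(tms))
      writeLines(paste(ids, format(tms, digits = 15, trim = TRUE, scientific = FALSE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Per-neuron firing-rate summary
#'
#' @param recording A [SpikeRecording-class] with positive duration.
#' @return data.frame with columns `neuron_id`, `n_spikes`, `rate_hz`
#'   (spikes per second, `n_spikes / duration`).
#' @examples
#' rateSummary(SpikeRecording(list(`1` = c(0.1, 0.25), `2` = 0.2), 1))
#' @export
rateSummary <- function(recording) {
  stopifnot(is(recording, "SpikeRecording"))
  if (recording@duration <= 0) stop("duration must be positive")
  n <- lengths(recording@spikes)
  data.frame(neuron_id = as.integer(names(recording@spikes)),
             n_spikes = as.integer(n),
             rate_hz = as.numeric(n) / recording@duration,
             row.names = NULL)
}
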