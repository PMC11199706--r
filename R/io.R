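#' Write and read two-channel recordings as delimited text
#'
#' The trace is written as tab-separated columns \code{time_s},
#' \code{signal}, \code{control}. A sidecar file \code{<path>.meta} holds
#' \code{key: value} lines (sampling rate, seed and any ground-truth scalars
#' present in the recording), and the event schedule, when present, goes to
#' \code{<path>.events} via \code{\link{write_schedule}}.
#'
#' @param rec a \code{\link{two_channel_recording}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "two_channel_recording"))
  utils::write.table(
    data.frame(time_s = rec$t, signal = rec$signal, control = rec$control),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(rate = rec$rate, unlist(rec$meta))
  writeLines(paste0(names(meta), ": ", meta), paste0(path, ".meta"))
  if (!is.null(rec$events)) write_schedule(rec$events, paste0(path, ".events"))
  invisible(path)
}

#' @rdname write_recording
#' @param events_path optional schedule file; defaults to
#'   \code{<path>.events} when that file exists.
#' @export
read_recording <- function(path, events_path = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- read_keyvalue(paste0(path, ".meta"))
  rate <- as.numeric(meta[["rate"]])
  if (is.null(events_path) && file.exists(paste0(path, ".events")))
    events_path <- paste0(path, ".events")
  events <- if (!is.null(events_path)) read_schedule(events_path) else NULL
  two_channel_recording(df$time_s, df$signal, df$control, rate,
                        events = events,
                        meta = meta[setdiff(names(meta), "rate")])
}

#' Write and read event schedules as delimited text
#'
#' Columns \code{time_s}, \code{label}, \code{duration_s}; session length
#' and variant are carried in a \code{# key: value} comment header.
#'
#' @param schedule an \code{\link{event_schedule}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# session_length: ", schedule$session_length),
               paste0("# variant: ", schedule$variant)), con)
  utils::write.table(schedule$events, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- grep("^#", readLines(path), value = TRUE)
  kv <- read_keyvalue(textConnection(sub("^#\\s*", "", hdr)))
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  event_schedule(ev, session_length = as.numeric(kv[["session_length"]]),
                 variant = kv[["variant"]])
}

#' Write and read dose-response tables as delimited text
#'
#' Columns \code{concentration_M}, \code{response}, \code{replicate_id}.
#'
#' @param table a \code{\link{dose_response_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dose_table <- function(table, path) {
  utils::write.table(
    data.frame(concentration_M = table$concentration,
               response = table$response,
               replicate_id = table$replicate_id),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_table
#' @export
read_dose_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  dose_response_table(df$concentration_M, df$response, df$replicate_id)
}

#' Write and read pixel stacks as TIFF
#'
#' The pixels x frames matrix is stored as a single-plane TIFF image
#' (32-bit float), the natural layout for a line scan; the reference
#' channel, when present, goes to \code{<path>.ref.tif}.
#'
#' @param stack a \code{\link{pixel_stack}}.
#' @param path output file path (.tif).
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "pixel_stack"))
  scale <- max(stack$data, 1)
  tiff::writeTIFF(stack$data / scale, path, bits.per.sample = 32L)
  meta <- c(rate = stack$rate, scale = scale)
  writeLines(paste0(names(meta), ": ", meta), paste0(path, ".meta"))
  if (!is.null(stack$reference)) {
    rscale <- max(stack$reference, 1)
    tiff::writeTIFF(stack$reference / rscale, paste0(path, ".ref.tif"),
                    bits.per.sample = 32L)
    writeLines(paste0("scale: ", rscale), paste0(path, ".ref.tif.meta"))
  }
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- read_keyvalue(paste0(path, ".meta"))
  dat <- tiff::readTIFF(path) * as.numeric(meta[["scale"]])
  ref <- NULL
  if (file.exists(paste0(path, ".ref.tif"))) {
    rmeta <- read_keyvalue(paste0(path, ".ref.tif.meta"))
    ref <- tiff::readTIFF(paste0(path, ".ref.tif")) *
      as.numeric(rmeta[["scale"]])
  }
  pixel_stack(dat, rate = as.numeric(meta[["rate"]]), reference = ref)
}

#' Write a processed trace with its provenance sidecar
#'
#' Trace as tab-separated \code{time_s}, \code{value}; provenance (variant,
#' unit, ordered steps and parameters) as \code{key: value} lines in
#' \code{<path>.prov}.
#'
#' @param trace a \code{\link{processed_trace}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_processed_trace <- function(trace, path) {
  stopifnot(inherits(trace, "processed_trace"))
  utils::write.table(data.frame(time_s = trace$t, value = trace$value),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  lines <- c(paste0("variant: ", trace$variant),
             paste0("unit: ", trace$unit))
  for (st in trace$provenance) {
    ps <- if (length(st$params))
      paste(names(st$params),
            vapply(st$params, function(p) paste(format(p), collapse = ","),
                   character(1)),
            sep = "=", collapse = "; ")
    else ""
    lines <- c(lines, paste0("step: ", st$step,
                             if (nzchar(ps)) paste0(" [", ps, "]") else ""))
  }
  writeLines(lines, paste0(path, ".prov"))
  invisible(path)
}

# key: value reader used for all sidecar metadata files
read_keyvalue <- function(con) {
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), trimws(keys))
}
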