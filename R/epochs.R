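#' Extract event-aligned epochs from a processed trace
#'
#' Cuts windows surrounding event onsets out of a processed trace, aligned
#' on a common sample grid relative to onset. When \code{zscore_per_epoch}
#' each row is standardized by its own window mean and SD (rows with zero
#' variance are excluded with a warning). Events whose window would exceed
#' the recording bounds are excluded and counted.
#'
#' @param trace a \code{\link{processed_trace}} (or list with \code{t},
#'   \code{value}).
#' @param events an \code{\link{event_schedule}}, a data.frame with
#'   \code{time_s} (and optionally \code{label}), or a numeric vector of
#'   onset times.
#' @param window length-2 vector \code{c(pre, post)} in seconds, both >= 0.
#' @param zscore_per_epoch standardize each row by its own mean/SD.
#' @param label optional label filter applied to \code{events}.
#' @return list of class \code{epoch_matrix}: \code{data} (events x samples),
#'   \code{t_rel} (s relative to onset), \code{zscored},
#'   \code{event_label}, \code{n_excluded_bounds}, \code{n_excluded_sd}.
#' @export
extract_epochs <- function(trace, events, window, zscore_per_epoch = TRUE,
                           label = NULL) {
  stopifnot(length(window) == 2, all(window >= 0))
  onsets <- if (inherits(events, "event_schedule")) {
    ev <- events$events
    if (!is.null(label)) ev <- ev[ev$label == label, , drop = FALSE]
    ev$time_s
  } else if (is.data.frame(events)) {
    ev <- events
    if (!is.null(label)) ev <- ev[ev$label == label, , drop = FALSE]
    ev$time_s
  } else as.numeric(events)
  t <- trace$t
  v <- trace$value
  rate <- 1 / stats::median(diff(t))
  npre <- round(window[1] * rate)
  npost <- round(window[2] * rate)
  if (npre + npost < 2) stop("window too narrow at this sampling rate")
  # half-open window [-pre, post): (pre + post) * rate samples per row
  t_rel <- (seq(-npre, npost - 1L)) / rate
  rows <- list()
  n_oob <- 0L
  for (on in onsets) {
    i0 <- which.min(abs(t - on))
    lo <- i0 - npre
    hi <- i0 + npost - 1L
    if (lo < 1 || hi > length(v)) { n_oob <- n_oob + 1L; next }
    rows[[length(rows) + 1L]] <- v[lo:hi]
  }
  if (length(rows) == 0)
    stop("no events with a full window inside the recording")
  mat <- do.call(rbind, rows)
  n_sd <- 0L
  if (zscore_per_epoch) {
    sds <- apply(mat, 1, stats::sd)
    bad <- !is.finite(sds) | sds == 0
    if (any(bad)) {
      warning(sum(bad), " epoch(s) with zero variance excluded")
      n_sd <- sum(bad)
      mat <- mat[!bad, , drop = FALSE]
      if (nrow(mat) == 0) stop("all epochs had zero variance")
      sds <- sds[!bad]
    }
    mat <- (mat - rowMeans(mat)) / sds
  }
  structure(list(data = mat, t_rel = t_rel, zscored = zscore_per_epoch,
                 event_label = if (is.null(label)) "" else label,
                 window = window, n_excluded_bounds = n_oob,
                 n_excluded_sd = n_sd),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("Epoch matrix%s: %d events x %d samples (%.1f s pre, %.1f s post)%s\n",
              if (nzchar(x$event_label)) paste0(" [", x$event_label, "]")
              else "", nrow(x$data), ncol(x$data), x$window[1], x$window[2],
              if (x$zscored) ", per-epoch z-scored" else ""))
  if (x$n_excluded_bounds > 0)
    cat(sprintf("  %d event(s) excluded (window out of bounds)\n",
                x$n_excluded_bounds))
  invisible(x)
}

#' Average event-aligned epochs
#'
#' @param epochs an \code{\link{epoch_matrix}}.
#' @return list: \code{t_rel}, \code{mean}, \code{sem}, \code{n}.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  n <- nrow(epochs$data)
  list(t_rel = epochs$t_rel, mean = colMeans(epochs$data),
       sem = apply(epochs$data, 2, stats::sd) / sqrt(n), n = n)
}

#' Binned area under the curve around an event
#'
#' Trapezoidal AUC over consecutive fixed-width bins anchored at the event
#' onset (time 0) and extending both before (negative start times) and
#' after it. Bin edges snap to the nearest aligned sample and each bin
#' integrates from its start edge sample to its end edge sample, so the sum
#' of contiguous bins equals the trapezoidal integral over their union
#' exactly. The AUC is signed: negative deflections give negative area.
#'
#' @param values aligned series (e.g. the mean trace of an
#'   \code{\link{epoch_matrix}}).
#' @param t_rel time vector relative to the event onset (s), same length.
#' @param bin_width bin width (s), default 5.
#' @return data.frame of class \code{auc_bins}: \code{start}, \code{end},
#'   \code{auc} (value units x s), \code{partial} flag.
#' @export
auc_bins <- function(values, t_rel, bin_width = 5) {
  stopifnot(length(values) == length(t_rel), bin_width > 0)
  if (max(t_rel) - min(t_rel) < bin_width)
    stop("series shorter than one bin")
  edges <- seq(floor(min(t_rel) / bin_width) * bin_width,
               ceiling(max(t_rel) / bin_width) * bin_width, by = bin_width)
  edges <- edges[edges >= min(t_rel) - bin_width & edges <= max(t_rel) + bin_width]
  eidx <- vapply(edges, function(e) which.min(abs(t_rel - e)), integer(1))
  eidx[1] <- 1L
  eidx[length(eidx)] <- length(t_rel)
  eidx <- unique(eidx)
  if (length(eidx) < 2) stop("series shorter than one bin")
  trapz <- function(i, j) {
    tt <- t_rel[i:j]; vv <- values[i:j]
    sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
  }
  out <- data.frame(
    start = t_rel[eidx[-length(eidx)]],
    end = t_rel[eidx[-1]],
    auc = vapply(seq_len(length(eidx) - 1L),
                 function(k) trapz(eidx[k], eidx[k + 1L]), numeric(1)))
  dt <- stats::median(diff(t_rel))
  out$partial <- abs((out$end - out$start) - bin_width) > dt
  class(out) <- c("auc_bins", "data.frame")
  attr(out, "bin_width") <- bin_width
  out
}

#' Mean of a processed trace over a time window
#'
#' Summary statistic for post-injection quantification, e.g. the mean
#' fluorescence 20-25 min after a drug injection. Batch mode aggregates
#' per-recording means for downstream group statistics.
#'
#' @param trace a \code{\link{processed_trace}} (or list with \code{t},
#'   \code{value}), or a list of them in batch mode.
#' @param window length-2 vector (start, end) in seconds.
#' @return single mean for one trace; for a list of traces, a data.frame
#'   with one row per recording plus grand mean and SEM as attributes.
#' @export
summarize_window <- function(trace, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  one <- function(tr) {
    idx <- window_idx(tr$t, window)
    if (length(idx) == 0) stop("window contains no samples")
    mean(tr$value[idx])
  }
  if (!is.null(trace$t)) return(one(trace))
  means <- vapply(trace, one, numeric(1))
  out <- data.frame(recording = seq_along(means), mean = means)
  attr(out, "grand_mean") <- mean(means)
  attr(out, "sem") <- stats::sd(means) / sqrt(length(means))
  out
}

#' Count labeled events inside a window
#'
#' @param schedule an \code{\link{event_schedule}} or a data.frame with
#'   \code{time_s} and \code{label}.
#' @param label event label to count.
#' @param window optional length-2 vector (s); NULL counts the whole
#'   session.
#' @return integer count of events with onset inside the window.
#' @export
count_events <- function(schedule, label, window = NULL) {
  ev <- if (inherits(schedule, "event_schedule")) schedule$events
        else schedule
  hits <- ev[ev$label == label, , drop = FALSE]
  if (!is.null(window))
    hits <- hits[hits$time_s >= window[1] & hits$time_s <= window[2], ,
                 drop = FALSE]
  nrow(hits)
}
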