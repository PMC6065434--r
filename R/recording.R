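#' Construct a subject recording
#'
#' Container for one subject's source-space time series: a numeric time x
#' channels matrix plus its sampling rate. All downstream stages (embedding,
#' sign flipping, spectra) operate on lists of these objects.
#'
#' @param data Numeric matrix, time points in rows, channels in columns.
#' @param fs Sampling rate in Hz.
#' @param subject_id Identifier for the subject (character or integer).
#' @param channel_labels Optional character vector, one label per channel.
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(data, fs, subject_id = "s1", channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording data must be finite with no missing values")
  if (is.null(channel_labels))
    channel_labels <- if (!is.null(colnames(data))) colnames(data)
      else paste0("ch", seq_len(ncol(data)))
  if (length(channel_labels) != ncol(data))
    stop("`channel_labels` length must equal the number of channels")
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, subject_id = subject_id,
         channel_labels = channel_labels),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> subject %s: %d samples x %d channels @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$data) / x$fs))
  invisible(x)
}

#' Standardize a recording channel-wise
#'
#' Centres each channel to mean zero and scales it to unit variance,
#' independently per subject. Run before time-delay embedding so that all
#' channels contribute equally to the PCA of the embedded space.
#'
#' @param x A `meg_recording` or a list of them.
#' @param ... Unused.
#' @return Same shape as the input, with each channel standardized.
#' @export
standardize <- function(x, ...) UseMethod("standardize")

#' @export
standardize.meg_recording <- function(x, ...) {
  sds <- apply(x$data, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- x$channel_labels[sds == 0]
    stop(sprintf("constant channel(s) cannot be standardized: %s",
                 paste(bad, collapse = ", ")))
  }
  x$data <- scale(x$data)
  attr(x$data, "scaled:center") <- NULL
  attr(x$data, "scaled:scale") <- NULL
  colnames(x$data) <- x$channel_labels
  x
}

#' @export
standardize.list <- function(x, ...) lapply(x, standardize)

# internal: validate a homogeneous list of recordings
check_recordings <- function(recordings) {
  if (inherits(recordings, "meg_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L)
  ok <- vapply(recordings, inherits, logical(1L), "meg_recording")
  if (!all(ok)) stop("expected a list of `meg_recording` objects")
  ncs <- vapply(recordings, function(r) ncol(r$data), integer(1L))
  if (length(unique(ncs)) != 1L)
    stop("all recordings must have the same number of channels")
  fss <- vapply(recordings, function(r) r$fs, numeric(1L))
  if (length(unique(fss)) != 1L)
    stop("all recordings must share one sampling rate")
  recordings
}
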