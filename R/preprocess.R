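#' Construct and validate a multichannel MEG recording
#'
#' @param data channels x samples numeric matrix (finite).
#' @param sampling_rate sampling rate in Hz.
#' @param array the \code{sensor_array} the data were recorded with.
#' @param subject_id,group labels carried through the pipeline.
#' @param moved flag set when head movement exceeded the 5-mm exclusion
#'   limit; flagged recordings are refused by \code{\link{read_recording}}.
#' @return Object of class \code{sensor_recording}.
#' @export
sensor_recording <- function(data, sampling_rate, array, subject_id = "s01",
                             group = "unknown", moved = FALSE) {
  data <- as.matrix(data)
  if (!all(is.finite(data)))
    stop_megdmn("recording contains non-finite samples",
                class = "megdmn_validity_error")
  if (sampling_rate <= 0)
    stop_megdmn("sampling_rate must be positive", class = "megdmn_config_error")
  if (nrow(data) != array$n_channels)
    stop_megdmn("data has %d rows but the array has %d channels",
                nrow(data), array$n_channels, class = "megdmn_validity_error")
  structure(list(data = data, sampling_rate = sampling_rate, array = array,
                 subject_id = subject_id, group = group, moved = moved),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s (%s): %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sampling_rate))
  invisible(x)
}

#' Band-stop (notch) filter for power-line interference
#'
#' Zero-phase Butterworth band-stop around \code{line_freq} (default 50 Hz).
#' The notch attenuates the line component by more than 40 dB while leaving
#' the pass-band (10 Hz away from the line) essentially untouched.
#'
#' @param rec a \code{sensor_recording}.
#' @param line_freq line frequency in Hz; must be below Nyquist.
#' @param width half-width of the stop band in Hz.
#' @return The filtered \code{sensor_recording}.
#' @export
notch_filter <- function(rec, line_freq = 50, width = 5) {
  fs <- rec$sampling_rate
  if (line_freq >= fs / 2)
    stop_megdmn("line frequency %g Hz is not below Nyquist (%g Hz)",
                line_freq, fs / 2, class = "megdmn_config_error")
  rec$data <- zerophase_butter(rec$data, fs,
                               c(line_freq - width, line_freq + width),
                               "stop", order = 4,
                               padlen = round(3 * fs / (2 * width)))
  rec
}

#' Segment a recording into consecutive fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' \code{epoch_length} seconds (default 500 ms); a trailing remainder
#' shorter than one epoch is discarded. All epochs start flagged "ok".
#'
#' @param rec a \code{sensor_recording}.
#' @param epoch_length epoch length in seconds.
#' @return Object of class \code{epoch_set}: \code{epochs} (list of
#'   channels x samples_per_epoch matrices, time ordered), \code{status}
#'   (per-epoch code: ok/spike/artifact/unselected), plus sampling and
#'   geometry metadata.
#' @export
segment_epochs <- function(rec, epoch_length = 0.5) {
  spe <- round(epoch_length * rec$sampling_rate)
  n <- ncol(rec$data)
  if (n < spe)
    stop_megdmn("recording (%d samples) shorter than one %g-s epoch",
                n, epoch_length, class = "megdmn_input_error")
  k <- floor(n / spe)
  eps <- lapply(seq_len(k), function(i)
    rec$data[, ((i - 1) * spe + 1):(i * spe), drop = FALSE])
  structure(list(epochs = eps, status = rep("ok", k),
                 epoch_length = epoch_length,
                 sampling_rate = rec$sampling_rate, array = rec$array,
                 subject_id = rec$subject_id, group = rec$group),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs x %g s (%s)\n", x$subject_id,
              length(x$epochs), x$epoch_length,
              paste(sprintf("%s:%d", names(table(x$status)), table(x$status)),
                    collapse = ", ")))
  invisible(x)
}

#' Flag epochs containing spike-like transients
#'
#' A deterministic surrogate for visual spike screening: per channel, a
#' median/MAD baseline is computed across all epochs; an epoch is flagged
#' "spike" if any sample on any channel deviates from its channel median by
#' more than \code{z_threshold} robust standard deviations. With the default
#' threshold of 6, injected bursts at 10x the background RMS are flagged
#' while Gaussian background is essentially never flagged. The MAD scale is
#' floored at machine epsilon times the channel range so constant channels
#' are never flagged.
#'
#' @param eps an \code{epoch_set} (at least 4 epochs).
#' @param z_threshold robust-z rejection threshold.
#' @return The \code{epoch_set} with updated status codes.
#' @export
flag_spike_epochs <- function(eps, z_threshold = 6) {
  if (length(eps$epochs) < 4)
    stop_megdmn("need at least 4 epochs for a robust baseline (got %d)",
                length(eps$epochs), class = "megdmn_input_error")
  all_data <- do.call(cbind, eps$epochs)
  mm <- .cpp_row_median_mad(all_data)
  med <- as.numeric(mm$median)
  sc <- 1.4826 * as.numeric(mm$mad)                   # MAD-based SD
  rng <- matrixranges(all_data)
  sc <- pmax(sc, .Machine$double.eps * rng)
  for (i in seq_along(eps$epochs)) {
    if (eps$status[i] != "ok") next
    dev <- abs(eps$epochs[[i]] - med)
    if (any(dev > z_threshold * sc)) eps$status[i] <- "spike"
  }
  eps
}

#' Randomly select a fixed number of clean epochs
#'
#' Retains exactly \code{k} epochs flagged "ok", sampled uniformly without
#' replacement with the given seed; the retained epochs keep their original
#' time order, the rest are marked "unselected". When exactly \code{k} clean
#' epochs exist they are all retained and no randomness is consumed.
#'
#' @param eps an \code{epoch_set} after rejection.
#' @param k number of clean epochs to keep (default 40).
#' @param seed integer seed for the subsample.
#' @return The \code{epoch_set} with non-retained clean epochs marked
#'   "unselected".
#' @export
select_clean_epochs <- function(eps, k = 40, seed = 1) {
  ok <- which(eps$status == "ok")
  if (length(ok) < k)
    stop_megdmn("only %d clean epochs available, %d required (deficit %d)",
                length(ok), k, k - length(ok),
                class = "megdmn_data_sufficiency_error")
  if (length(ok) > k) {
    keep <- with_seed(seed, sort(sample(ok, k)))
    eps$status[setdiff(ok, keep)] <- "unselected"
  }
  eps
}

# Matrices of the retained ("ok") epochs.
clean_epochs <- function(eps) eps$epochs[eps$status == "ok"]

# Per-row range width without apply() overhead.
matrixranges <- function(m) {
  apply(m, 1, function(r) diff(range(r)))
}
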