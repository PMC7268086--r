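#' Frequency band specification
#'
#' Canonical analysis bands are alpha (8-13 Hz), beta (14-30 Hz) and gamma
#' (31-80 Hz); \code{dmn_bands()} returns all three.
#'
#' @param name band label.
#' @param low,high band edges in Hz, 0 < low < high.
#' @return Object of class \code{band_spec}.
#' @export
band_spec <- function(name, low, high) {
  if (!(low > 0 && high > low))
    stop_megdmn("need 0 < low < high for band '%s'", name,
                class = "megdmn_config_error")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @rdname band_spec
#' @export
dmn_bands <- function() {
  list(alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 14, 30),
       gamma = band_spec("gamma", 31, 80))
}

# Zero-phase Butterworth filtering of a channels x samples matrix.
# type "pass" or "stop" with edges w = c(low, high) in Hz.
zerophase_butter <- function(X, fs, w, type, order = 4, padlen = NULL) {
  ny <- fs / 2
  if (any(w >= ny) || any(w <= 0))
    stop_megdmn("filter edges (%s Hz) must lie inside (0, Nyquist = %g Hz)",
                paste(w, collapse = ", "), ny, class = "megdmn_config_error")
  flt <- signal::butter(order, w / ny, type = type)
  if (is.null(padlen)) padlen <- round(3 * fs / min(w))
  padlen <- max(1L, min(as.integer(padlen), ncol(X) - 1L))
  out <- .cpp_filtfilt_rows(as.numeric(flt$b), as.numeric(flt$a), X, padlen)
  dimnames(out) <- dimnames(X)
  out
}
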