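#' Downsample a multichannel recording
#'
#' Anti-alias lowpass filtering followed by rate reduction. Integer ratios
#' use a high-order zero-phase FIR lowpass (cutoff 0.8 x Nyquist of the
#' target rate) and decimation; non-integer rational ratios fall back to
#' polyphase resampling ([signal::resample()]).
#'
#' @param x channels x samples numeric matrix (or a vector), or an
#'   `epoched_recording` (each epoch downsampled).
#' @param fs input sampling rate (Hz); ignored for `epoched_recording`.
#' @param target_fs output sampling rate (Hz), must not exceed `fs`.
#' @return matrix (or recording) at `target_fs`; the recording's `fs` field
#'   is updated.
#' @export
downsample <- function(x, fs, target_fs) {
  if (inherits(x, "epoched_recording")) {
    eps <- lapply(seq_len(dim(x$data)[3]), function(e)
      downsample(x$data[, , e, drop = FALSE][, , 1], x$fs, target_fs))
    x$data <- array(unlist(eps), dim = c(dim(eps[[1]]), length(eps)),
                    dimnames = list(x$montage$labels, NULL, NULL))
    x$fs <- target_fs
    return(x)
  }
  if (is.vector(x)) return(drop(downsample(matrix(x, 1), fs, target_fs)))
  if (target_fs > fs) stop("target_fs (", target_fs,
                           ") exceeds input rate (", fs, ")")
  if (target_fs == fs) return(x)
  q <- fs / target_fs
  if (abs(q - round(q)) < 1e-9) {
    q <- round(q)
    # anti-alias: zero-phase FIR lowpass at 0.8 of the target Nyquist
    ord <- 10 * q
    if (ord %% 2 == 1) ord <- ord + 1
    h <- signal::fir1(ord, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
    y <- t(apply(x, 1, function(ch) signal::filtfilt(h, ch)))
    y[, seq(1, ncol(x), by = q), drop = FALSE]
  } else {
    frac <- rational_approx(target_fs / fs)
    t(apply(x, 1, function(ch) signal::resample(ch, frac[1], frac[2])))
  }
}

rational_approx <- function(r, max_den = 1000) {
  best <- c(1, 1); err <- Inf
  for (den in seq_len(max_den)) {
    num <- round(r * den)
    if (num >= 1 && abs(num / den - r) < err) {
      err <- abs(num / den - r); best <- c(num, den)
      if (err < 1e-12) break
    }
  }
  best
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels. Requires at least
#' two channels.
#'
#' @param x channels x samples matrix, or an `epoched_recording`.
#' @return same shape, with zero column means.
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "epoched_recording")) {
    for (e in seq_len(dim(x$data)[3]))
      x$data[, , e] <- common_average_reference(x$data[, , e])
    return(x)
  }
  if (!is.matrix(x) || nrow(x) < 2)
    stop("common average reference needs >= 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) FIR design applied forward and backward
#' ([signal::filtfilt()]), giving zero group delay. Filter order is
#' `3 * fs / f_low`, rounded up to even.
#'
#' @param x numeric vector, channels x samples matrix, or an
#'   `epoched_recording` (each epoch filtered).
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high < fs/2`.
#' @param fs sampling rate (Hz).
#' @return filtered data, same shape.
#' @export
bandpass_fir_zero_phase <- function(x, f_low, f_high, fs) {
  if (inherits(x, "epoched_recording")) {
    for (e in seq_len(dim(x$data)[3]))
      x$data[, , e] <- bandpass_fir_zero_phase(x$data[, , e],
                                               f_low, f_high, x$fs)
    return(x)
  }
  if (!(f_low > 0 && f_low < f_high && f_high < fs / 2))
    stop("invalid band edges: need 0 < f_low < f_high < fs/2 (got ",
         f_low, "-", f_high, " Hz at fs = ", fs, ")")
  ord <- ceiling(3 * fs / f_low)
  if (ord %% 2 == 1) ord <- ord + 1
  h <- signal::fir1(ord, c(f_low, f_high) / (fs / 2), type = "pass")
  if (is.vector(x)) return(signal::filtfilt(h, x))
  t(apply(x, 1, function(ch) signal::filtfilt(h, ch)))
}

#' Extract non-overlapping fixed-length epochs
#'
#' Cuts `n_epochs` epochs of `epoch_len` seconds from continuous data at
#' the given onsets. Onsets default to contiguous non-overlapping epochs
#' from the start. Overlapping requests or epochs running past the end of
#' the data are rejected.
#'
#' @param x channels x samples matrix of continuous data.
#' @param fs sampling rate (Hz).
#' @param epoch_len epoch length in seconds.
#' @param n_epochs number of epochs.
#' @param onsets optional integer sample indices (1-based) of epoch starts;
#'   length `n_epochs`.
#' @param montage optional [montage_spec] attached to the result.
#' @param condition optional condition metadata list.
#' @return an `epoched_recording`.
#' @export
extract_epochs <- function(x, fs, epoch_len, n_epochs, onsets = NULL,
                           montage = NULL, condition = list()) {
  stopifnot(is.matrix(x), n_epochs >= 1)
  n <- round(epoch_len * fs)
  if (is.null(onsets)) onsets <- seq(1, by = n, length.out = n_epochs)
  if (length(onsets) != n_epochs)
    stop("need exactly one onset per epoch")
  onsets <- as.integer(onsets)
  ends <- onsets + n - 1L
  short <- ends > ncol(x)
  if (any(short))
    stop("insufficient data: ", sum(short), " epoch(s) run past the end ",
         "by up to ", max(ends) - ncol(x), " sample(s)")
  o <- order(onsets)
  if (any(onsets[o][-1] < ends[o][-length(o)] + 1L))
    stop("epochs overlap; onsets must be at least ", n, " samples apart")
  data <- array(0, dim = c(nrow(x), n, n_epochs))
  for (e in seq_len(n_epochs))
    data[, , e] <- x[, onsets[e]:ends[e], drop = FALSE]
  if (!is.null(montage)) dimnames(data)[[1]] <- montage$labels
  structure(list(data = data, fs = fs, montage = montage,
                 condition = condition, group = NA_character_),
            class = "epoched_recording")
}

#' Epoch onsets within repeated stimulus presentations
#'
#' For a stimulus presented `n_presentations` times for
#' `presentation_len` seconds each (presentations assumed contiguous),
#' returns onsets of the first `epochs_per_presentation` epochs of each
#' presentation, starting `edge_guard` seconds after each presentation
#' onset (edge guard keeps filter/Hilbert edge artifacts out of epochs).
#'
#' @param fs sampling rate (Hz).
#' @param presentation_len presentation length (s).
#' @param n_presentations number of presentations.
#' @param epoch_len epoch length (s).
#' @param epochs_per_presentation epochs to cut from each presentation.
#' @param edge_guard guard interval after each presentation onset (s).
#' @return integer vector of 1-based sample onsets.
#' @export
presentation_onsets <- function(fs, presentation_len = 30,
                                n_presentations = 5, epoch_len = 4,
                                epochs_per_presentation = 4,
                                edge_guard = 0.5) {
  need <- edge_guard + epochs_per_presentation * epoch_len
  if (need > presentation_len)
    stop("epochs (", need, " s) do not fit in a ", presentation_len,
         " s presentation")
  unlist(lapply(seq_len(n_presentations) - 1L, function(p) {
    start <- p * presentation_len + edge_guard
    round(start * fs) + 1L + round(fs * epoch_len) * (
      seq_len(epochs_per_presentation) - 1L)
  }))
}
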