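#' EEG frequency band table
#'
#' The six analysis sub-bands: delta (2-4 Hz), theta (4-8 Hz), alpha_low
#' (8-10 Hz), alpha_high (10-13 Hz), beta (13-30 Hz), gamma (30-40 Hz).
#'
#' @param names optional subset of band names to return.
#' @return data.frame with columns `band`, `f_low`, `f_high`.
#' @export
eeg_bands <- function(names = NULL) {
  tab <- data.frame(
    band  = c("delta", "theta", "alpha_low", "alpha_high", "beta", "gamma"),
    f_low = c(2, 4, 8, 10, 13, 30),
    f_high = c(4, 8, 10, 13, 30, 40),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    bad <- setdiff(names, tab$band)
    if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "))
    tab <- tab[match(names, tab$band), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Ganzfeld flicker target frequencies (Hz)
#' @return numeric vector of the eight target frequencies.
#' @export
ganzfeld_frequencies <- function() c(8, 10, 12, 14, 16, 20, 22, 24)

#' Ganzfeld mood-induction conditions
#' @return character vector of the three soundscape conditions.
#' @export
ganzfeld_moods <- function() c("neutral", "serenity", "anxiety")
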