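#' Instantaneous phase via the analytic signal
#'
#' Builds the discrete analytic signal `z = x + i*HT(x)` in the frequency
#' domain (positive frequencies doubled, negative zeroed) and returns its
#' argument. Input should be narrowband (use
#' [bandpass_fir_zero_phase()] first); the amplitude envelope is discarded.
#'
#' @param x numeric vector (one epoch of one channel), channels x samples
#'   matrix, or channels x samples x epochs array.
#' @return phases in `(-pi, pi]`, same shape as `x`.
#' @export
hilbert_phase <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    out <- x
    for (e in seq_len(dim(x)[3])) out[, , e] <- hilbert_phase(x[, , e])
    return(out)
  }
  if (is.matrix(x)) return(t(apply(x, 1, hilbert_phase)))
  if (all(x == 0)) stop("phase undefined for an all-zero signal")
  n <- length(x)
  if (n < 64) stop("need at least 64 samples for a stable phase estimate")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  Arg(z)
}

#' Phase-locking value of two phase series
#'
#' `PLV = |mean(exp(i * (phi1 - phi2)))|`: the mean resultant length of the
#' phase difference. 0 means unsynchronized phases, 1 perfect locking.
#'
#' @param phi1,phi2 numeric phase vectors (radians) of equal length.
#' @return scalar in `[0, 1]`.
#' @export
compute_plv <- function(phi1, phi2) {
  if (length(phi1) != length(phi2))
    stop("phase series lengths differ (", length(phi1), " vs ",
         length(phi2), ")")
  Mod(mean(exp(1i * (phi1 - phi2))))
}

# all-pairs PLV for one epoch of phases (channels x samples)
plv_matrix_epoch <- function(phi) {
  Z <- exp(1i * t(phi))                    # samples x channels
  P <- Mod(crossprod(Conj(Z), Z)) / nrow(Z)
  diag(P) <- 0
  dimnames(P) <- list(rownames(phi), rownames(phi))
  P
}

#' Band phases of an epoched recording
#'
#' Either the ground-truth generator phases (`source = "phases"`, only for
#' recordings created with `return_phases = TRUE`) or phases estimated from
#' the waveforms by zero-phase band filtering followed by [hilbert_phase()]
#' (`source = "signal"`).
#'
#' @param rec an `epoched_recording`.
#' @param band band name (see [eeg_bands()]).
#' @param source `"signal"` or `"phases"`.
#' @return channels x samples x epochs array of phases.
#' @export
band_phases <- function(rec, band, source = c("signal", "phases")) {
  source <- match.arg(source)
  if (source == "phases") {
    if (is.null(rec$phases[[band]]))
      stop("recording carries no ground-truth phases for band '", band, "'")
    return(rec$phases[[band]])
  }
  b <- eeg_bands(band)
  filt <- bandpass_fir_zero_phase(rec, b$f_low, b$f_high, rec$fs)
  hilbert_phase(filt$data)
}

#' Epoch-averaged PLV matrix
#'
#' PLV is computed per epoch and arithmetically averaged across epochs.
#'
#' @param x channels x samples x epochs phase array, or an
#'   `epoched_recording` (phases obtained via [band_phases()]).
#' @param band band name, required when `x` is a recording.
#' @param source phase source when `x` is a recording, see [band_phases()].
#' @return an object of class `plv_matrix`: list with `values` (symmetric
#'   channels x channels matrix in `[0,1]`, zero diagonal), `band`,
#'   `condition`, `n_epochs_averaged`.
#' @export
epoch_averaged_plv <- function(x, band = NULL,
                               source = c("signal", "phases")) {
  condition <- NULL
  if (inherits(x, "epoched_recording")) {
    if (is.null(band)) stop("band must be given for a recording")
    condition <- x$condition
    x <- band_phases(x, band, source)
  }
  stopifnot(length(dim(x)) == 3)
  E <- dim(x)[3]
  P <- plv_matrix_epoch(x[, , 1])
  if (E > 1) for (e in 2:E) P <- P + plv_matrix_epoch(x[, , e])
  structure(list(values = P / E, band = band, condition = condition,
                 n_epochs_averaged = E),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat("<plv_matrix> ", nrow(x$values), " channels, ",
      x$n_epochs_averaged, " epochs averaged",
      if (!is.null(x$band)) paste0(", band ", x$band), "\n", sep = "")
  cat("  mean off-diagonal PLV: ",
      round(mean(x$values[upper.tri(x$values)]), 4), "\n", sep = "")
  invisible(x)
}

#' Surrogate-based pruning of a PLV matrix
#'
#' Builds `M` surrogate PLV values per channel pair by randomly permuting
#' the time samples of the second channel's phase series (one fresh
#' permutation per surrogate per epoch; the first channel is left intact),
#' averaging across epochs exactly as the observed statistic. The empirical
#' one-sided p-value is `(1 + #{PLV_surr >= PLV_obs}) / (M + 1)`; entries
#' with `p >= alpha` are set to zero, the rest keep their observed value
#' (never rescaled).
#'
#' @param plv a `plv_matrix` (or plain symmetric matrix) of observed
#'   epoch-averaged PLV.
#' @param phases channels x samples x epochs phase array used for the
#'   observed PLV.
#' @param M number of surrogates (>= 20, and `1/(M+1) < alpha`).
#' @param alpha one-sided significance level in `(0, 0.5)`.
#' @param seed integer seed for the permutation stream.
#' @return a `plv_matrix` with pruned `values` and extra fields
#'   `p_surrogate` (symmetric matrix of empirical p-values) and `M`.
#' @export
surrogate_prune <- function(plv, phases, M = 100, alpha = 0.05,
                            seed = 1L) {
  obs <- if (inherits(plv, "plv_matrix")) plv$values else plv
  stopifnot(length(dim(phases)) == 3, nrow(obs) == dim(phases)[1])
  if (M < 20) stop("need at least 20 surrogates")
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must be in (0, 0.5)")
  if (1 / (M + 1) >= alpha)
    stop("M = ", M, " surrogates cannot resolve alpha = ", alpha,
         " (minimum attainable p is 1/(M+1))")
  C <- dim(phases)[1]; N <- dim(phases)[2]; E <- dim(phases)[3]
  set.seed(derive_seed(seed, "surrogate"))
  Zs <- lapply(seq_len(E), function(e) exp(1i * t(phases[, , e])))
  count_ge <- matrix(0L, C, C)
  for (m in seq_len(M)) {
    S <- matrix(0, C, C)
    for (e in seq_len(E)) {
      perm <- sample.int(N)
      # entry (i, j): channel i intact, channel j's phase permuted
      S <- S + Mod(crossprod(Conj(Zs[[e]]), Zs[[e]][perm, , drop = FALSE])) / N
    }
    S <- S / E
    count_ge <- count_ge + (S >= obs)
  }
  # one surrogate matrix per permutation is asymmetric; use the upper
  # triangle (j > i permuted) and mirror
  cnt <- count_ge
  cnt[lower.tri(cnt)] <- t(count_ge)[lower.tri(cnt)]
  p <- (1 + cnt) / (M + 1)
  diag(p) <- 1
  pruned <- obs
  pruned[p >= alpha] <- 0
  dimnames(p) <- dimnames(obs)
  out <- if (inherits(plv, "plv_matrix")) plv else
    structure(list(values = obs, band = NULL, condition = NULL,
                   n_epochs_averaged = E), class = "plv_matrix")
  out$values <- pruned
  out$p_surrogate <- p
  out$M <- M
  out$alpha <- alpha
  out
}

#' Long-format edge table of a PLV matrix
#'
#' @param plv a `plv_matrix` (ideally after [surrogate_prune()]).
#' @return data.frame with columns `channel_i`, `channel_j`, `plv`, and
#'   `p_surrogate` when available.
#' @export
edge_table <- function(plv) {
  v <- plv$values
  labs <- rownames(v)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(v)))
  ut <- which(upper.tri(v), arr.ind = TRUE)
  out <- data.frame(channel_i = labs[ut[, 1]], channel_j = labs[ut[, 2]],
                    plv = v[ut], stringsAsFactors = FALSE)
  if (!is.null(plv$p_surrogate)) out$p_surrogate <- plv$p_surrogate[ut]
  out
}
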