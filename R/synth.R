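#' Coupling plan for synthetic phase-coupled EEG
#'
#' Describes the ground-truth pairwise phase coupling used by the generator.
#' Coupling is parameterized as a symmetric channel-by-channel matrix of von
#' Mises concentrations `kappa`: the instantaneous phase difference of a
#' channel pair is (in population) von Mises distributed with that
#' concentration, so its expected phase-locking value is
#' `I1(kappa)/I0(kappa)` (see [vm_mean_resultant()]).
#'
#' By default the matrix follows a block (community) structure over the
#' montage's region sets: pairs within a region set share `kappa_within`,
#' all remaining pairs share `kappa_between`. Group effects are
#' multiplicative modifiers applied to region blocks: the HS-like group has
#' reduced coupling in the bilateral temporal/frontotemporal block and
#' increased coupling in the occipital/parieto-occipital block.
#'
#' @param montage a [montage_spec].
#' @param kappa_within von Mises concentration for within-region pairs.
#' @param kappa_between concentration for all other pairs.
#' @param kappa optional explicit symmetric non-negative concentration
#'   matrix (zero diagonal) overriding the block construction; either a
#'   single matrix used for every band or a named list per band.
#' @param bands character vector of band names the plan covers.
#' @param group_effect named list per group of multiplicative block
#'   modifiers, keyed by region-block name (`temporal_frontotemporal`
#'   covers the union of the left and right sets). Defaults: HS-like 0.6 on
#'   temporal/frontotemporal and 1.4 on occipital/parieto-occipital; LS-like
#'   1 everywhere.
#' @param subject_sd standard deviation of the per-subject log-normal
#'   multiplier applied to the whole concentration matrix (between-subject
#'   variability).
#' @param snr_db broadband signal-to-noise ratio of the 1/f background
#'   noise, in dB (0 dB = equal power).
#' @param seed integer root seed for the plan.
#' @return an object of class `coupling_plan`.
#' @export
coupling_plan <- function(montage,
                          kappa_within = 2,
                          kappa_between = 0.4,
                          kappa = NULL,
                          bands = eeg_bands()$band,
                          group_effect = list(
                            HS = list(temporal_frontotemporal = 0.6,
                                      occipital_parieto_occipital = 1.4),
                            LS = list()),
                          subject_sd = 0.2,
                          snr_db = 0,
                          seed = 1L) {
  stopifnot(inherits(montage, "montage_spec"))
  C <- length(montage$labels)
  if (is.null(kappa)) {
    K <- matrix(kappa_between, C, C,
                dimnames = list(montage$labels, montage$labels))
    for (set in montage$region_sets) {
      idx <- match(set, montage$labels)
      K[idx, idx] <- kappa_within
    }
    diag(K) <- 0
    kappa <- K
  }
  if (is.matrix(kappa)) {
    kappa <- stats::setNames(rep(list(kappa), length(bands)), bands)
  }
  for (b in names(kappa)) validate_kappa(kappa[[b]], C)
  for (g in names(group_effect)) {
    if (any(unlist(group_effect[[g]]) < 0))
      stop("group_effect multipliers must be non-negative")
  }
  structure(list(montage = montage, kappa = kappa, bands = bands,
                 group_effect = group_effect, subject_sd = subject_sd,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "coupling_plan")
}

validate_kappa <- function(K, C) {
  if (!is.matrix(K) || nrow(K) != C || ncol(K) != C)
    stop("kappa must be a ", C, "x", C, " matrix")
  if (!isTRUE(all.equal(K, t(K), tolerance = 1e-12)))
    stop("kappa must be symmetric")
  if (any(K < 0)) stop("kappa must be non-negative")
  if (any(diag(K) != 0)) stop("kappa must have a zero diagonal")
  invisible(TRUE)
}

# union of channels for a named region block; "temporal_frontotemporal"
# covers both hemispheres' sets
region_block_channels <- function(montage, block) {
  rs <- montage$region_sets
  if (block %in% names(rs)) return(rs[[block]])
  hits <- grep(paste0("^", block), names(rs), value = TRUE)
  if (!length(hits)) stop("unknown region block: ", block)
  unique(unlist(rs[hits]))
}

# group- and subject-adjusted concentration matrix for one band
kappa_for_group <- function(plan, band, group, subject_multiplier = 1) {
  K <- plan$kappa[[band]]
  if (is.null(K)) stop("coupling plan has no kappa for band '", band, "'")
  eff <- plan$group_effect[[group]]
  if (!is.null(eff)) {
    for (block in names(eff)) {
      ch <- region_block_channels(plan$montage, block)
      idx <- match(ch, plan$montage$labels)
      K[idx, idx] <- K[idx, idx] * eff[[block]]
    }
    diag(K) <- 0
  }
  K * subject_multiplier
}

# Partition channels into communities: each channel joins the first region
# set containing it; channels outside every region set become singletons.
montage_communities <- function(montage) {
  C <- length(montage$labels)
  comm <- rep(NA_integer_, C)
  k <- 0L
  for (set in montage$region_sets) {
    k <- k + 1L
    idx <- match(set, montage$labels)
    comm[idx[is.na(comm[idx])]] <- k
  }
  for (i in which(is.na(comm))) { k <- k + 1L; comm[i] <- k }
  comm
}

# Hierarchical block solution of the pairwise coupling targets.
#
# Phase model: theta_c = phi_global + eta_{community(c)} + eps_c, with
# independent per-sample von Mises jitters. The population PLV of a pair is
#   same community:      rho_i * rho_j
#   different community: rho_i * rho_j * rref_{r(i)} * rref_{r(j)}
# so we solve for log rho (per channel) and log rref (per community) in
# minimum-norm least squares over all pairs with a nonzero target
# A(kappa_ij) = I1/I0. Exact for block-homogeneous targets with
# kappa_between <= kappa_within; otherwise the best block-level compromise.
# Channels with no nonzero-target pair get rho = 0 (uniform jitter).
solve_block_coupling <- function(K, comm) {
  C <- nrow(K)
  R <- vm_mean_resultant(K)
  nr <- max(comm)
  ut <- which(upper.tri(K) & R > 1e-12, arr.ind = TRUE)
  if (nrow(ut) == 0)
    return(list(rho_ch = numeric(C), rho_comm = rep(1 - 1e-9, nr)))
  X <- matrix(0, nrow(ut), C + nr)
  for (q in seq_len(nrow(ut))) {
    i <- ut[q, 1]; j <- ut[q, 2]
    X[q, i] <- X[q, i] + 1
    X[q, j] <- X[q, j] + 1
    if (comm[i] != comm[j]) {
      X[q, C + comm[i]] <- X[q, C + comm[i]] + 1
      X[q, C + comm[j]] <- X[q, C + comm[j]] + 1
    }
  }
  y <- log(R[ut])
  used <- colSums(X != 0) > 0
  sol <- MASS::ginv(X[, used, drop = FALSE]) %*% y
  lv <- rep(-Inf, C + nr)
  lv[used] <- sol
  lv[C + which(!used[(C + 1):(C + nr)])] <- 0   # unused community refs
  list(rho_ch = exp(pmin(lv[seq_len(C)], log(1 - 1e-9))),
       rho_comm = exp(pmin(lv[(C + 1):(C + nr)], log(1 - 1e-9))))
}

#' Generate one synthetic subject
#'
#' For each band, every channel's instantaneous phase is a shared band
#' oscillation plus community-level plus channel-level independent
#' per-sample von Mises jitter, with concentrations solved so that the
#' phase difference of coupled pairs attains the plan's pairwise `kappa`
#' targets (population pair PLV = `I1(kappa)/I0(kappa)`; exact for
#' block-homogeneous targets, least-squares compromise otherwise). The waveform is the sum of the band cosines plus
#' 1/f-shaped Gaussian background noise at the plan's SNR. Deterministic
#' under a fixed seed.
#'
#' @param plan a [coupling_plan].
#' @param montage a [montage_spec]; defaults to the plan's montage.
#' @param fs sampling rate in Hz (>= 128 and > twice the highest band edge).
#' @param n_epochs number of non-overlapping epochs (>= 1).
#' @param epoch_len epoch length in seconds.
#' @param group group label, one of the names of the plan's `group_effect`
#'   (conventionally `"LS"`/`"HS"`), or `NA` for no group effect.
#' @param condition list with elements `mood` and `target_frequency`.
#' @param seed integer seed.
#' @param bands data.frame as [eeg_bands()], restricted to the plan's bands.
#' @param subject_multiplier optional fixed whole-matrix concentration
#'   multiplier; if `NULL`, drawn log-normally with `plan$subject_sd`.
#' @param return_phases if `TRUE`, attach the ground-truth band phases
#'   (list per band of channels x samples x epochs arrays) — memory-heavy,
#'   intended for parameter-recovery checks.
#' @return an object of class `epoched_recording`: list with `data`
#'   (channels x samples x epochs), `fs`, `montage`, `condition`, `group`,
#'   and optionally `phases`.
#' @export
generate_subject <- function(plan, montage = plan$montage, fs = 256,
                             n_epochs = 20, epoch_len = 4,
                             group = "LS",
                             condition = list(mood = "neutral",
                                              target_frequency = 10),
                             seed = plan$seed,
                             bands = eeg_bands(plan$bands),
                             subject_multiplier = NULL,
                             return_phases = FALSE) {
  stopifnot(inherits(plan, "coupling_plan"), n_epochs >= 1, epoch_len > 0)
  if (fs < 128) stop("fs must be >= 128 Hz")
  if (fs <= 2 * max(bands$f_high))
    stop("fs = ", fs, " Hz is too low for the ", max(bands$f_high),
         " Hz band edge (need fs > ", 2 * max(bands$f_high), ")")
  C <- length(montage$labels)
  n <- round(epoch_len * fs)
  set.seed(derive_seed(seed, "subject"))
  if (is.null(subject_multiplier))
    subject_multiplier <- exp(stats::rnorm(1, 0, plan$subject_sd))
  tt <- (seq_len(n) - 1) / fs
  data <- array(0, dim = c(C, n, n_epochs),
                dimnames = list(montage$labels, NULL, NULL))
  phases <- if (return_phases)
    stats::setNames(vector("list", nrow(bands)), bands$band) else NULL
  comm <- montage_communities(montage)
  for (bi in seq_len(nrow(bands))) {
    band <- bands$band[bi]
    K <- kappa_for_group(plan, band, group, subject_multiplier)
    sol <- solve_block_coupling(K, comm)
    kap_ch <- vm_concentration(sol$rho_ch)
    kap_comm <- vm_concentration(sol$rho_comm)
    fc <- (bands$f_low[bi] + bands$f_high[bi]) / 2
    ph <- if (return_phases) array(NA_real_, dim = c(C, n, n_epochs),
                                   dimnames = list(montage$labels, NULL, NULL))
    for (e in seq_len(n_epochs)) {
      ref <- 2 * pi * fc * tt + stats::runif(1, -pi, pi)
      eta <- lapply(seq_len(max(comm)), function(r)
        rvonmises(n, 0, kap_comm[r]))
      for (ci in seq_len(C)) {
        eps <- rvonmises(n, 0, kap_ch[ci])
        theta <- ref + eta[[comm[ci]]] + eps
        data[ci, , e] <- data[ci, , e] + cos(theta)
        if (return_phases) ph[ci, , e] <- wrap_angle(theta)
      }
    }
    if (return_phases) phases[[band]] <- ph
  }
  # 1/f-shaped background noise at the configured SNR
  sig_pow <- mean(data^2)
  noise_sd <- sqrt(sig_pow / 10^(plan$snr_db / 10))
  if (noise_sd > 0) {
    for (e in seq_len(n_epochs)) {
      for (ci in seq_len(C)) {
        w <- one_over_f_noise(n, fs)
        data[ci, , e] <- data[ci, , e] + noise_sd * w
      }
    }
  }
  structure(list(data = data, fs = fs, montage = montage,
                 condition = condition, group = group,
                 subject_multiplier = subject_multiplier,
                 phases = phases),
            class = "epoched_recording")
}

# unit-variance Gaussian noise with ~1/f amplitude spectrum above 1 Hz
one_over_f_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)            # two-sided frequency axis
  scale <- 1 / sqrt(pmax(f, 1))   # flat below 1 Hz
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_recording> ", d[1], " channels x ", d[2], " samples x ",
      d[3], " epochs @ ", x$fs, " Hz\n", sep = "")
  cat("  group: ", x$group, "; mood: ", x$condition$mood,
      "; target frequency: ", x$condition$target_frequency, " Hz\n", sep = "")
  invisible(x)
}

#' Cohort design table
#'
#' Enumerates subjects x condition cells with reproducible per-cell seeds
#' and per-subject coupling multipliers derived from the cohort seed.
#'
#' @param n_ls,n_hs number of LS-like and HS-like subjects (>= 2 each).
#' @param moods mood conditions to include.
#' @param target_frequencies flicker target frequencies (Hz) to include.
#' @param seed cohort root seed.
#' @param subject_sd between-subject log-normal multiplier SD.
#' @return data.frame with one row per subject x condition cell.
#' @export
cohort_design <- function(n_ls, n_hs,
                          moods = ganzfeld_moods(),
                          target_frequencies = ganzfeld_frequencies(),
                          seed = 1L, subject_sd = 0.2) {
  stopifnot(n_ls >= 2, n_hs >= 2)
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n_ls + n_hs)),
    group = rep(c("LS", "HS"), c(n_ls, n_hs)),
    stringsAsFactors = FALSE)
  subjects$multiplier <- vapply(seq_len(nrow(subjects)), function(i) {
    set.seed(derive_seed(seed, "multiplier", i))
    exp(stats::rnorm(1, 0, subject_sd))
  }, numeric(1))
  cells <- expand.grid(mood = moods, target_frequency = target_frequencies,
                       stringsAsFactors = FALSE)
  des <- merge(subjects, cells, by = NULL)
  des$cell_seed <- mapply(function(s, m, f) derive_seed(seed, s, m, f * 10),
                          des$subject, des$mood, des$target_frequency)
  des[order(des$subject, des$mood, des$target_frequency), ]
}

#' Generate a full synthetic cohort
#'
#' Materializes one [generate_subject()] recording per row of the cohort
#' design (subject x mood x target frequency). HS-like subjects receive the
#' plan's reduced temporal/frontotemporal and increased
#' occipital/parieto-occipital coupling. Use sparingly at full scale; the
#' pipeline streams subjects instead of materializing them.
#'
#' @inheritParams cohort_design
#' @param plan a [coupling_plan].
#' @param fs,n_epochs,epoch_len,return_phases forwarded to
#'   [generate_subject()].
#' @param design optional precomputed [cohort_design()] table.
#' @return list with `design` (data.frame) and `recordings` (list of
#'   `epoched_recording`, parallel to the design rows).
#' @export
generate_cohort <- function(n_ls, n_hs, plan,
                            moods = "neutral",
                            target_frequencies = 10,
                            fs = 256, n_epochs = 20, epoch_len = 4,
                            seed = plan$seed,
                            return_phases = FALSE,
                            design = NULL) {
  if (is.null(design))
    design <- cohort_design(n_ls, n_hs, moods, target_frequencies,
                            seed = seed, subject_sd = plan$subject_sd)
  recs <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    rec <- generate_subject(
      plan, fs = fs, n_epochs = n_epochs, epoch_len = epoch_len,
      group = row$group,
      condition = list(mood = row$mood,
                       target_frequency = row$target_frequency),
      seed = row$cell_seed, subject_multiplier = row$multiplier,
      return_phases = return_phases)
    rec$subject <- row$subject
    rec
  })
  list(design = design, recordings = recs)
}
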