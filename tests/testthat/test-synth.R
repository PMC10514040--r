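test_that("coupling_plan validates the concentration matrix", {
  m <- montage_spec(c("a", "b", "c"))
  K <- matrix(0, 3, 3)
  K[1, 2] <- 1            # asymmetric
  expect_error(coupling_plan(m, kappa = K), "symmetric")
  K <- matrix(-1, 3, 3); diag(K) <- 0
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  expect_error(coupling_plan(m, kappa = K), "non-negative")
  K <- diag(3)
  expect_error(coupling_plan(m, kappa = K), "diagonal")
  expect_error(coupling_plan(m, group_effect = list(HS = list(
    occipital_parieto_occipital = -0.5))), "non-negative")
})

test_that("sampling rate preconditions are enforced", {
  plan <- pair_plan(1)
  expect_error(generate_subject(plan, fs = 100), "128")
  high <- data.frame(band = "alpha_low", f_low = 55, f_high = 70)
  expect_error(generate_subject(plan, fs = 130, bands = high), "too low")
})

test_that("identical seeds give bit-identical recordings", {
  plan <- pair_plan(2)
  r1 <- generate_subject(plan, n_epochs = 2, epoch_len = 1, seed = 9,
                         bands = eeg_bands("alpha_low"))
  r2 <- generate_subject(plan, n_epochs = 2, epoch_len = 1, seed = 9,
                         bands = eeg_bands("alpha_low"))
  expect_identical(r1$data, r2$data)
  r3 <- generate_subject(plan, n_epochs = 2, epoch_len = 1, seed = 10,
                         bands = eeg_bands("alpha_low"))
  expect_false(identical(r1$data, r3$data))
})

test_that("extreme coupling limits give PLV near 1 and near 0", {
  expect_gt(pair_plv(1e6, n_epochs = 5, seed = 3), 1 - 1e-3)
  # independent uniform phases: single 1024-sample epochs over 50 seeds
  v <- vapply(1:50, function(s) pair_plv(0, n_epochs = 1, seed = s),
              numeric(1))
  expect_lt(mean(v), 0.1)
})

test_that("pairwise coupling recovers the Bessel-ratio PLV", {
  plv2 <- pair_plv(2, n_epochs = 100, seed = 21)
  expect_lt(abs(plv2 - vm_mean_resultant(2)), 0.02)
})

test_that("measured PLV is monotone in the coupling concentration", {
  kappas <- c(0, 0.5, 1, 2, 5)
  plvs <- vapply(kappas, function(k) pair_plv(k, n_epochs = 20, seed = 5),
                 numeric(1))
  expect_true(all(diff(plvs) > 0))
  # and tracks the theoretical curve
  expect_lt(max(abs(plvs[-1] - vm_mean_resultant(kappas[-1]))), 0.05)
})

test_that("cohort design enumerates subjects x condition cells", {
  d <- cohort_design(29, 14)     # 3 moods x 8 target frequencies
  expect_equal(nrow(d), 43 * 24)
  expect_equal(length(unique(d$subject)), 43)
  expect_equal(sum(d$group == "HS") / 24, 14)
  expect_equal(length(unique(d$cell_seed)), 43 * 24)
  # one multiplier per subject, shared across that subject's cells
  expect_equal(length(unique(d$multiplier)), 43)
  expect_error(cohort_design(1, 5), "n_ls >= 2")
})

test_that("group effects place block differences with the right sign", {
  m <- demo_montage()
  plan <- coupling_plan(m, bands = "theta", subject_sd = 0.05)
  co <- generate_cohort(5, 5, plan, moods = "anxiety", return_phases = TRUE,
                        target_frequencies = 10, n_epochs = 6,
                        seed = 31)
  block_mean <- function(rec, chans) {
    P <- epoch_averaged_plv(band_phases(rec, "theta", "phases"))$values
    idx <- match(chans, rownames(P))
    mean(P[idx, idx][upper.tri(P[idx, idx])])
  }
  tl <- m$region_sets$temporal_frontotemporal_left
  oc <- m$region_sets$occipital_parieto_occipital
  groups <- vapply(co$recordings, `[[`, "", "group")
  tmp <- vapply(co$recordings, block_mean, numeric(1), chans = tl)
  occ <- vapply(co$recordings, block_mean, numeric(1), chans = oc)
  expect_gt(mean(tmp[groups == "LS"]), mean(tmp[groups == "HS"]))
  expect_lt(mean(occ[groups == "LS"]), mean(occ[groups == "HS"]))
})

test_that("unit effect modifiers make the groups exchangeable", {
  m <- demo_montage()
  plan <- coupling_plan(m, bands = "theta", subject_sd = 0.1,
                        group_effect = list(HS = list(), LS = list()))
  co <- generate_cohort(6, 6, plan, moods = "neutral", return_phases = TRUE,
                        target_frequencies = 10, n_epochs = 4, seed = 17)
  groups <- vapply(co$recordings, `[[`, "", "group")
  # per-recording mean within-temporal PLV should not separate the groups
  tl <- m$region_sets$temporal_frontotemporal_left
  v <- vapply(co$recordings, function(r) {
    P <- epoch_averaged_plv(band_phases(r, "theta", "phases"))$values
    idx <- match(tl, rownames(P))
    mean(P[idx, idx][upper.tri(P[idx, idx])])
  }, numeric(1))
  w <- welch_t(v[groups == "HS"], v[groups == "LS"])
  expect_gt(w$p, 0.01)
})

test_that("generate_subject returns phases only on request", {
  plan <- pair_plan(1)
  r <- generate_subject(plan, n_epochs = 1, epoch_len = 1, seed = 1,
                        bands = eeg_bands("alpha_low"))
  expect_null(r$phases)
  r <- generate_subject(plan, n_epochs = 1, epoch_len = 1, seed = 1,
                        bands = eeg_bands("alpha_low"),
                        return_phases = TRUE)
  expect_equal(dim(r$phases$alpha_low), c(2, 256, 1))
  expect_true(all(r$phases$alpha_low > -pi & r$phases$alpha_low <= pi))
})
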