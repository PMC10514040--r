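# ganznet

Weighted EEG functional-network analysis under flicker Ganzfeld
stimulation, with a ground-truth synthetic generator.

## The problem

Under Ganzfeld conditions (a homogeneous visual field with random light
flicker plus mood-inducing soundscapes), people high in positive schizotypy
(HS) show altered cortical synchrony relative to low-schizotypy (LS)
individuals. Characterizing and classifying these states requires a full
connectivity pipeline: narrowband phase estimation, phase-locking value
(PLV) networks, a surrogate null to prune spurious edges, weighted
graph-theory summaries, two-group statistics, and classification that
respects a 29-vs-14 class imbalance. `ganznet` implements that pipeline in
R — and, because such EEG is rarely shareable, ships a synthetic
multichannel generator whose pairwise phase coupling is known exactly, so
every stage can be validated against ground truth.

## The core model

For channels *i*, *j* with instantaneous phases
φᵢ, φⱼ (argument of the analytic signal of the band-filtered waveform):

    PLV(i,j) = | (1/N) Σₖ exp( i·(φᵢ(tₖ) − φⱼ(tₖ)) ) |  ∈ [0, 1]

computed per 4-s epoch, averaged over the 20 epochs of each condition cell
(mood × flicker frequency), in six bands (delta 2–4 … gamma 30–40 Hz).
Edges failing a phase-permutation surrogate test (M = 100, α = 0.05,
p = (1 + #{PLV_surr ≥ PLV_obs})/(M+1)) are zeroed. Networks are
proportionally thresholded over densities 0.01–0.50; node strength,
Onnela's weighted clustering coefficient, and weighted global efficiency
are computed at each density, with features taken at density 0.08. Group
contrasts use Welch's *t* (sign convention HS − LS) with
Benjamini–Hochberg FDR across edges; classification uses leave-one-out
cross-validation with Welch-*t* feature ranking refit inside each training
fold and five classifiers (CART, KNN, LDA, linear SVM, RUSBoost — boosting
with per-round random undersampling of the majority class).

The generator plants coupling as von Mises phase jitter on a hierarchical
block structure (global carrier → region community → channel). A pair with
coupling concentration κ has population PLV I₁(κ)/I₀(κ), so parameter
recovery is checkable against a closed form. HS-like subjects get reduced
temporal/frontotemporal and increased occipital/parieto-occipital coupling.

## Worked example

```r
library(ganznet)

# A coupled channel pair: kappa = 2 should give PLV ~ I1(2)/I0(2) = 0.698
plan <- coupling_plan(montage_spec(c("T7", "T8")),
                      kappa = matrix(c(0, 2, 2, 0), 2),
                      bands = "alpha_low", subject_sd = 0)
rec <- generate_subject(plan, n_epochs = 20, seed = 42,
                        bands = eeg_bands("alpha_low"),
                        subject_multiplier = 1, return_phases = TRUE)
plv <- epoch_averaged_plv(rec, "alpha_low", source = "phases")
print(plv)
#> <plv_matrix> 2 channels, 20 epochs averaged, band alpha_low
#>   mean off-diagonal PLV: 0.6999
```

The measured PLV (0.700) sits on the theoretical Bessel-ratio curve
(0.698). A desk-scale cohort through the whole pipeline:

```r
cfg <- pipeline_config(out_dir = file.path(tempdir(), "demo-run"),
                       montage = "demo", bands = "theta",
                       moods = "anxiety", target_frequencies = 10,
                       n_ls = 10, n_hs = 6, n_epochs = 8,
                       densities = seq(0.02, 0.4, 0.02),
                       surrogate_M = 20, n_features = 8,
                       classifiers = c("lda", "rusboost"), seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
res$classification
#>      mood classifier accuracy sensitivity specificity   f1 tp fn tn fp
#> 1 anxiety        lda    93.75         100          90 0.92  6  0  9  1
#> 2 anxiety   rusboost   100.00         100         100 1.00  6  0 10  0

head(subset(res$node_stats, significant & metric == "strength",
            select = c(feature, t, p)), 5)
#>  feature         t            p
#>      PO4  6.628422 4.558154e-05
#>      POz  6.189375 1.026984e-04
#>       Oz  3.593914 5.004006e-03
#>      FC5 -3.212727 6.580501e-03
#>      PO3  2.970758 1.465613e-02
```

The node-level table shows the planted effects recovered with the right
signs: occipital/parieto-occipital channels (PO4, POz, Oz, PO3) have
positive *t* (HS-like coupling increased there), while the frontotemporal
channel FC5 is negative (LS-like higher), matching the generator's group
effects. Accuracy, sensitivity and specificity are percentages truncated
to two decimals with HS as the positive class; the confusion counts
(tp/fn/tn/fp) they derive from are alongside.

`run_pipeline()` writes delimited tables under `out_dir/`
(`graphs/`, `stats/`, `classification/`) plus `config.yaml` and a
`provenance.json` carrying the config hash and seed. A thin CLI wrapping
the same functions lives at `inst/cli/ganznet.R`
(`simulate | connect | graph | stats | classify | run-all`).

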