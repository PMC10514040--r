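---
title: "Phase-locking brain networks under Ganzfeld stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking brain networks under Ganzfeld stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Ganzfeld stimulation — a homogeneous visual field with random light flicker,
combined with mood-inducing soundscapes — alters cortical dynamics and can
induce pseudo-hallucinatory imagery, most readily in people high in positive
schizotypy. `ganznet` implements the full analysis chain used to compare
weighted EEG functional networks between high-schizotypy (HS) and
low-schizotypy (LS) groups under such stimulation, and to classify the two
groups from graph-derived features. Because raw EEG of this kind is rarely
shareable, the package pairs the analysis chain with a synthetic multichannel
generator whose pairwise phase coupling is known exactly, so every stage is
testable against ground truth.

The pipeline is: band-limited phase estimation → phase-locking value (PLV)
connectivity → surrogate-based edge pruning → proportional density
thresholding → weighted graph metrics → group statistics → leave-one-out
cross-validated (LOO-CV) classification.

## Connectivity model

For two narrowband signals $x_1(t), x_2(t)$, instantaneous phases
$\varphi_1, \varphi_2$ are the arguments of the analytic signals
$z_i = x_i + \mathrm{i}\,\mathrm{HT}(x_i)$ (FFT construction: positive
frequencies doubled, negative zeroed). Phase locking over $N$ samples is

$$\mathrm{PLV} = \Bigl|\tfrac1N \sum_{k=0}^{N-1}
  e^{\mathrm{i}\,(\varphi_1(t_k)-\varphi_2(t_k))}\Bigr| \in [0, 1],$$

computed per 4-s epoch and averaged over the 20 epochs of a condition cell
(one mood × one flicker target frequency), in six bands: delta (2–4 Hz),
theta (4–8), alpha-low (8–10), alpha-high (10–13), beta (13–30), gamma
(30–40).

**Surrogate pruning.** Each pair's observed PLV is compared against $M$
surrogates built by randomly permuting the time samples of the *second*
channel's phase series (one fresh permutation per surrogate per epoch, the
first channel left intact), averaged across epochs exactly like the observed
statistic, so the null and the observed value are exchangeable. With
empirical one-sided $p = (1 + \#\{\mathrm{PLV}_{surr} \ge
\mathrm{PLV}_{obs}\})/(M+1)$, entries with $p \ge \alpha$ are zeroed and the
rest keep their observed value. Defaults $M = 100$, $\alpha = 0.05$; the
smallest attainable $p$ is $1/(M+1)$, so $M$ must satisfy $1/(M+1) <
\alpha$. A full random permutation (not a circular shift) is used — the
stronger reading of "shuffling" — and no multiplicity correction is applied
at this stage (FDR control enters only in the group statistics).

## Graph metrics

Pruned PLV matrices are thresholded proportionally: the top
$\mathrm{round}(d \cdot N(N-1)/2)$ edges by weight are retained with their
values (never rescaled), for densities $d = 0.01, \dots, 0.50$; features for
classification come from the fixed $d = 0.08$ level. Rounding is
half-away-from-zero (the dominant brain-connectivity convention); ties at
the cut break by stable $(i, j)$ index order.

At each density:

* **strength** $s_i = \sum_j W_{ij}$ (weighted degree);
* **clustering** (Onnela): $t_i = \tfrac12 \sum_{j,h} (\hat W_{ij} \hat
  W_{jh} \hat W_{ih})^{1/3}$ with $\hat W = W / \max W$, and
  $CC_i = 2 t_i / (k_i (k_i - 1))$, zero when degree $k_i < 2$. The
  max-normalization keeps $CC \in [0,1]$. The network-mean CC is a separate
  reducer; the per-node values are the primary output because channel-wise
  significance maps need them;
* **global efficiency** $GE = \tfrac{1}{N(N-1)} \sum_{i \ne j}
  1/d^w(i,j)$ with edge lengths $1/\hat W_{ij}$ and Dijkstra shortest
  paths; unreachable pairs contribute zero. On max-normalized weights every
  edge length is $\ge 1$, so $GE \in [0, 1]$ and is invariant to uniform
  weight scaling. Whether to normalize is config-exposed
  (`global_efficiency(..., normalize =)`); normalized is the default.

## Group statistics

All two-group contrasts use Welch's $t$ with the fixed sign convention
HS − LS (negative $t$ ⇒ LS higher). Three families:

* **edge level**, on pruned but unthresholded PLV, FDR-corrected
  (Benjamini–Hochberg, $q = 0.05$) across edges within each band × mood ×
  target-frequency family;
* **node level** (strength and CC at density 0.08), reported at raw
  $p < 0.05$ with the $p < 0.001$ subset exported separately as the
  strict table; $q$-values are attached for optional FDR use, since
  whether the original nodal maps were corrected is ambiguous;
* **global level** (GE per density).

A one-sample Kolmogorov–Smirnov normality screen (sample standardized by
its own moments — conservative, as the parameters are estimated) is
available; it warns but does not gate the $t$-tests, since no nonparametric
fallback branch is defined for this design. Demographics-style summaries
use a two-group ANOVA $F$ computed from (mean, SD, $n$) — the square of the
pooled $t$, $df = (1, n_1 + n_2 - 2)$ — and a Pearson chi-square without
continuity correction for 2 × 2 tables.

## Classification

Per mood condition, features are per-channel CC and strength plus
whole-brain GE for every band × target frequency at density 0.08
(64 × 96 + 48 = 6192 columns at full scale), named
`{metric}.{channel|GLOBAL}.{band}.{freq}`. Under LOO-CV, features are
ranked by $|t|$ (Welch) *inside each training fold* — the held-out subject
can never influence selection — and the top $k$ (default 10; in practice
this choice is made by trial and error, so $k$ is config-exposed) feed five
classifiers: CART, KNN ($K = 5$, Euclidean, training-fold z-scoring), LDA
(pooled covariance with a shrinkage fallback when singular), linear SVM
(unit cost), and RUSBoost. A global-selection mode exists behind a flag for
comparison only.

**RUSBoost** is AdaBoost.M1 where each round's training set is rebalanced
by randomly undersampling the majority class down to the minority count,
drawing without replacement with probabilities proportional to the current
boosting weights. Defaults: 100 rounds, depth-3 CART weak learners,
learning rate 0.1. With undersampling disabled it reduces to plain
AdaBoost.M1 (tested against an independent reference implementation).

HS — the minority group — is the positive class, so sensitivity is HS
detection. Reported percentages are *truncated* (not rounded) to two
decimals: $41/43 \to 95.34$, $13/14 \to 92.85$, $28/29 \to 96.55$; the same
truncation applied to $F_1 = 26/28 = 0.9286$ yields the reported-style
$0.92$. The proportions themselves are returned alongside.

## The synthetic generator

The generator is first-class, tested code — it defines the study
conditions for every downstream check.

**Phase model.** Per band, channel $c$'s phase is

$$\theta_c(t) = \phi(t) + \eta_{r(c)}(t) + \varepsilon_c(t),$$

a shared band carrier (center-frequency sinusoidal phase with a random
start per epoch), plus community-level and channel-level independent
per-sample von Mises jitters ($r(c)$ = region community of $c$). With
$\rho = I_1(\kappa)/I_0(\kappa)$ the von Mises mean resultant, the
population PLV of a pair is $\rho_i \rho_j$ (same community) or $\rho_i
\rho_j \rho_{r(i)} \rho_{r(j)}$ (different communities). The jitter
concentrations are solved from the target pairwise matrix $\kappa_{ij}$ in
minimum-norm least squares on the log scale, which is *exact* for
block-homogeneous targets with between-block coupling no stronger than
within-block (an arbitrary pairwise matrix is jointly infeasible — the
attainable set is the two-level product structure — so recovery checks are
stated at block level). A pair with target $\kappa$ then has measured
epoch-averaged PLV converging to $I_1(\kappa)/I_0(\kappa)$, the
Bessel-ratio curve, which the test suite verifies within 0.05 over
$\kappa \in \{0.5, 1, 2, 5\}$ along with the exact limits
($\kappa \to \infty \Rightarrow$ PLV $\to 1$; $\kappa = 0 \Rightarrow$
PLV $\to 0$).

**Waveforms.** Each channel's signal sums the band cosines plus
1/f-shaped Gaussian noise at a configurable SNR (default 0 dB — equal
broadband power, a realistic EEG-like spectrum that leaves phase targets
untouched at the phase level). Recordings can be exported to EDF (16-bit)
or delimited matrices with JSON sidecars.

**A deliberate limitation.** Per-sample iid jitter is spectrally broadband.
A narrow band filter therefore removes most of the jitter power and the
waveform route (filter → Hilbert → PLV) saturates toward 1 for coupled
pairs, compressing — though preserving the order of — coupling differences.
For this reason the pipeline consumes the generator's ground-truth phases
by default (`phase_source = "phases"`), while the waveform route — the one
used for recorded data — is validated on its own contracts (filter
response, zero group delay, Hilbert phase accuracy, cross-format
round-trips). Quantitative κ-recovery is asserted at the phase level, where
the von Mises model is defined. Slowly varying jitter would survive
filtering but would cut the effective samples per epoch and bias PLV
upward at low coupling; the iid choice keeps the estimator regime clean
and is stated here once rather than tuned per test.

**Default coupling conditions.** Within-region $\kappa = 2$ (pair PLV
$\approx 0.70$, strong but not saturated narrowband synchrony),
between-region $\kappa = 0.4$ (PLV $\approx 0.20$ background). The HS-like
group multiplies the bilateral temporal/frontotemporal block by 0.6
(reduced coupling) and the occipital/parieto-occipital block by 1.4
(increased), matching the reported direction of group differences; LS-like
is baseline. Between-subject variability is a log-normal whole-matrix
multiplier (SD 0.2 on the log scale, ≈ ±20 % coupling spread). Under these
defaults the full pipeline separates 29 + 14 synthetic subjects at ≥ 90 %
LOO accuracy, which is the documented intent of the effect sizes, and the
planted signs are recovered in the designated regions — both verified by
the acceptance suite, not assumed.

**Cohort geometry.** The full design is 29 LS + 14 HS × 3 moods × 8
flicker target frequencies (8–16 Hz in 2-Hz steps; 20, 22, 24 Hz) × 20
non-overlapping 4-s epochs at 256 Hz on the 64-channel BioSemi 10-10
montage. Seeds fan out deterministically per subject × cell via an
exact-integer polynomial hash, so identical seeds give bit-identical
recordings and pipeline reruns are byte-identical.

## Preprocessing chain

For recorded (or exported) waveforms: downsampling with anti-alias
filtering (zero-phase FIR at 0.8 × target Nyquist for integer ratios,
e.g. 2048 → 256 Hz; polyphase resampling otherwise), common average
reference, and a windowed-sinc (Hamming) zero-phase FIR band filter of
order $3 f_s / f_{low}$ rounded to even, applied forward–backward. Band
filtering precedes epoching so Hilbert edge artifacts stay outside the
epochs; with repeated 30-s presentations, onsets start 0.5 s after each
presentation onset and take the first four 4-s epochs of each of the five
presentations (the deterministic, onset-locked reading of "20 epochs per
condition"; which 20 of the possible epochs the original design used is
not specified).

## Desk-scale problem sizes

The test suite and the acceptance script exercise the pipeline end-to-end
at reduced size: a 16-channel montage subset that still covers all region
sets, one mood × two target frequencies × two bands, 10 epochs, $M = 20$
surrogates, density grid 0.02–0.40. These are the package's documented
demonstration sizes; the full study design remains the configuration
default (`pipeline_config()` with no arguments). The acceptance script
(`scripts/acceptance.R`) recomputes, from scratch at each run: the
demographics statistics from printed summaries, the confusion-matrix
arithmetic, the 64-channel density-0.08 edge count, the κ → Bessel-ratio
recovery error, the surrogate type-I retention rate, and the synthetic
cohort's classification and sign-recovery results.

## What passing tests do and do not show

The generator emulates group-structured narrowband phase coupling with
realistic 1/f background spectra and between-subject variability. It does
**not** model volume conduction or a leadfield (no spurious zero-lag
inflation), ocular/muscle artifacts, nonstationarity within epochs,
frequency-dependent coupling delays, or button-press behavior. Passing
recovery tests therefore demonstrates the correctness of the estimation
chain — not that real Ganzfeld EEG satisfies the model. Performance
figures on synthetic cohorts characterize the harness under planted,
well-separated effects and are not comparable to accuracies on real
cohorts. Limitations worth keeping in mind: PLV on common-referenced data
is sensitive to the reference choice; proportional thresholding at a fixed
density remains a field-wide open question; and the KS normality screen is
conservative because its parameters are estimated from the sample.
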