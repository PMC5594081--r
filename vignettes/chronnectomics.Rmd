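---
title: "Chronnectomics of dynamic EEG connectivity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronnectomics of dynamic EEG connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronnect)
```

This vignette is the package's own account of the science it implements:
what each stage models, which parameters matter and why they default as
they do, what the synthetic generators do and do not emulate, and where the
design was genuinely open.

## The pipeline in one paragraph

Resting-state EEG is a superposition of band-limited rhythms whose
interactions reconfigure on a sub-second scale. The package tracks those
reconfigurations by estimating, in every sliding window and for every
sensor pair, the coupling strength of 36 candidate interaction types — 8
within-band phase couplings and 28 phase-to-amplitude cross-frequency
couplings — and keeping only the *dominant* one that survives a surrogate
test. The result is a pair of tensors (strength and mode label), the
integrated dynamic functional connectivity graph (IDFCG). Each windowed
graph is reduced to a sparse backbone by orthogonal-MST filtering, and
summarized by a nodal global-efficiency profile; the sequence of profiles
is vector-quantized into a small alphabet of network microstates. The
symbolic dynamics of the microstate sequence and of the per-pair mode
labels yield the chronnectomic features that feed age regression and
group classification.

## Coupling estimation

**Estimator.** The imaginary phase-locking value
$\mathrm{iPLV} = \lvert \mathrm{Im}\, \langle e^{i(\varphi_a - \varphi_b)}
\rangle \rvert = \lvert \langle \sin(\varphi_a - \varphi_b) \rangle \rvert$
discards zero-lag synchrony, the component most contaminated by volume
conduction. The identity with $\langle\sin\Delta\varphi\rangle$ lets the
whole windowed computation run in real arithmetic through one sparse
window-summation matrix.

**Phase-to-amplitude coupling.** For a band pair (low, high), the high
band's amplitude envelope is band-filtered within the low band and its
analytic phase extracted (`cfc_phase`); iPLV between that phase and a
low-band phase quantifies PAC. Both directions (slow phase from sensor A
vs. envelope from B, and vice versa) are evaluated; the larger iPLV
represents the pair and the direction is recorded. Because the pair
statistic is a maximum over two directions, its surrogate null is the
maximum over the same two directions of the shifted surrogates — using the
single-direction null would inflate the false-positive rate of the 28 PAC
modes by up to a factor of two.

**Surrogates.** Null statistics come from circular time shifts of the
second series by uniformly random offsets of at least one slowest-band
cycle, with $p = (1 + \#\{\text{surrogate} \ge \text{observed}\})/(n_{surr}
+ 1)$; the floor is $1/(n_{surr}+1)$. Offsets are drawn once per sensor
pair from a stream derived from the master seed and the same shifted
series is scored in every window, which makes the computation deterministic
and an order of magnitude cheaper than per-window shifting at no cost in
validity. With the default $n_{surr} = 200$ and $\alpha = 0.05$
(uncorrected, per mode) the per-mode false-positive rate on uncoupled
pairs is calibrated (the acceptance suite measures it); note that with 36
modes per pair the *dominant label* of a null pair is nonzero in roughly
$1 - 0.95^{36} \approx 84\%$ of windows — a structural consequence of
picking a maximum over 36 tests, which is why a Bonferroni option exists.
Bonferroni over 36 modes requires $p < 0.05/36 \approx 0.0014$ and hence
$n_{surr} \ge 719$; with the default 200 surrogates it cannot fire, so
raise `n_surr` to 1000 when using it.

**Window scheme.** Window width defaults to 2.5 s with a 20 ms step. The
width is a tractability compromise: it holds ten cycles of a 4 Hz rhythm,
and about six cycles of the 2.25 Hz centre of the δ band, the slowest
analyzed. Windows are placed wholly outside the per-band filter transient
margins (`ceil(fs / f_lo)` samples per edge). Mode labels are 1–8 for
within-band couplings in band order and 9–36 for cross-frequency pairs in
low-band-major lexicographic order, ending at (γ₁, γ₂) = 36; the mapping is
exported by `coupling_mode_table()` and configurable through its band
table.

## Preprocessing

Line noise is removed with a 3rd-order Butterworth band-stop applied
forward–backward; all band filters are 3rd-order Butterworth applied the
same way, so the magnitude response is effectively 6th order and the phase
response is exactly zero (a time-shifted input yields the identically
shifted output — a property the tests assert). Attenuation is measured on
interior samples; the forward–backward transient occupies the marked edge
margins.

The artifact screen computes kurtosis and skewness in 1 s windows per
component and z-scores them against the pooled distribution over **all**
components' windows; a component is rejected when more than 30% of its
windows exceed |z| > 2 on either moment. Pooling is load-bearing: within a
single sample at most 25% of points can lie beyond two empirical standard
deviations, so a per-component reference could never reach the 30%
criterion. On 1,000 simulated Gaussian components the flag rate stays
under 5%. The decomposition feeding the rule is pluggable (any object with
`components`/`mixing`/`center`); the default is whitened PCA retaining 95%
of variance, and reconstruction back-projects the surviving components to
full sensor space, since the downstream graphs are defined over sensors.

## Topological filtering

OMST extracts successive minimum spanning trees on edge lengths $1/w$ over
the edges unused by previous rounds, accumulating their union; after round
$m$ the quality function $J(m) = GE - Cost$ is evaluated and the union at
the maximizing round retained. Statistically non-significant edges (mode
label 0) are removed *before* OMST — statistical then topological
filtering, in that order. Rounds continue to $\lfloor (N-1)/2 \rfloor$ by
default with early stop after two consecutive decreases of $J$; the
acceptance suite verifies the selection against exhaustive search over all
rounds with brute-force shortest paths. On disconnected significant
graphs the MST step yields a spanning forest per component and unreachable
pairs contribute zero efficiency — the standard convention.

## Microstates

The NMTS matrix (windows × sensors, nonnegative) is factorized as
$X \approx V W^\top$ by multiplicative updates (tolerance $10^{-6}$, 500
iterations, best of 5 restarts; the first restart uses a deterministic
sign-fixed SVD-based nonnegative initialization, which also makes the
reduction equivariant to channel permutations). The neural gas fits $k$
codevectors in the reduced space with rank-based soft-max updates,
neighbourhood $\lambda$ decaying from $k/2$ to 0.01 and learning rate from
0.5 to 0.005 over 100 passes. $k$ is the smallest candidate whose
vector-quantized reconstruction (each window replaced by its codevector,
back-projected through $W$) has Frobenius error ratio below 4%; if no
candidate qualifies the largest is used with a warning — short noisy
recordings (as in the README example) routinely sit above 4%, and the
warning is the honest signal of that. The NNMF rank $r$ (default 8) and
$k$ are independent knobs. Seriation orders prototypes along a
nearest-neighbour chain started at the highest-occupancy prototype, so
neighbouring symbols are similar network states. Cohort analyses fit one
codebook on the concatenated NMTS of all subjects so that symbols are
comparable across subjects; per-subject fitting is also available.

## Chronnectomic features

All Markov quantities use log base 2 (bits). The trajectory-entropy matrix
follows the Ekroot–Cover construction
$H = K - K' + H_\Delta$, $K = (I - P + A)^{-1}(H^* - H_\Delta)$ with every
row of $A$ equal to the stationary distribution, $H^*_{ij} = H(P_i)$ and
$(H_\Delta)_{ii} = H(X)/\mu_i$. A variant flag implements the transposed
$A$ ($A_{ij} = \mu_i$); algebraically the difference cancels in $K - K'$
and both yield the same $H$, which the tests confirm — the flag exists for
transparency. The return-trajectory identity $H_{ii} = H(X)/\mu_i$ is
asserted to $10^{-9}$ over 1,000 random chains, and the off-diagonal is
checked against both an analytic geometric-dwell oracle and a Monte-Carlo
first-passage path-entropy estimate. States never visited in a sequence
are dropped before modeling, and rows left without outgoing transitions
(e.g. the final symbol) are pruned iteratively; a reducible empirical
chain is restricted to its largest recurrent communicating class with a
warning.

The complexity index counts distinct words up to length 7 (default) and is
z-scored against 1,000 random shuffles; a constant sequence has zero
shuffle spread and returns $Z = 0$ with a warning. The flexibility index
counts a change to or from label 0 as a change — losing or gaining a
significant coupling is a network reconfiguration. Sample entropy uses
$m = 2$, $r = 0.2\,\mathrm{SD}$, Chebyshev distance with self-matches
excluded; a constant series returns 0 and a matchless series $+\infty$
with a warning. The assembled vector is
$1 + k^2 + N^2 + 36 + 1 + k^2 + 1$ named entries — 4,263 at $k = 8$,
$N = 64$.

## Prediction

For age regression, the pairwise distance-correlation matrix of features
is clustered by iterated dominant-set extraction (replicator dynamics from
a near-uniform profile with a tiny deterministic index tilt, which
prevents exactly symmetric similarity blocks from pinning the dynamics on
an unstable mixed fixed point), one representative per cluster is chosen
by correlation with age, and a linear SVR ($C = 1$, $\varepsilon = 0.1$)
is fitted. For classification, Laplacian scores on the label graph are
thresholded at mean + 2.5 SD of 200 label-shuffled recomputations, and an
ELM (100 sigmoid hidden units, input weights uniform on $[-1, 1]$, ridge
$10^{-6}$) classifies. Feature selection runs *inside* every leave-one-out
fold by default; the cohort-level (selection-first) variant is available
as `nested = FALSE` but leaks selection information, which the null
calibrations in the acceptance suite make visible: with nested selection a
shuffled-age cohort yields $R^2 \le 0.1$ and shuffled labels classify
within binomial chance bounds. Reported $R^2$ is the squared correlation
between predicted and true ages, alongside the least-squares line of
predicted on true.

## Synthetic data: what it emulates, and what it does not

`gen_coupled_eeg` realizes within-band couplings as a *shared
phase-diffusing oscillator* (linear phase ramp at the band centre plus a
Gaussian random walk, 0.1 rad/sample) observed in both channels with a
phase lag (default π/2, where the imaginary PLV is maximal), and PAC as
the slow oscillator's phase modulating a fast carrier's amplitude with the
same lag convention. Phase diffusion is essential for surrogate validity:
a pure sinusoid stays phase-locked to its own circular shifts, so shifted
surrogates of deterministic signals would not decorrelate. Background is
$1/f$ noise scaled to the requested SNR (default 10 dB). Epochs tile the
recording, enabling piecewise-stationary state switching. The generator
does **not** emulate volume conduction, realistic head geometry, ocular or
cardiac artifact morphology, or non-stationary spectra — so passing
planted-recovery tests demonstrates estimator correctness, not robustness
to every property of real scalp EEG. `gen_feature_cohort` plants linear
age loadings plus correlated nuisance blocks and pure noise;
`gen_markov_sequence` realizes arbitrary finite chains.

## Problem sizes and numerical choices

The validation battery runs at desk scale, chosen once: planted-coupling
recovery uses 8 channels, 25 s at 160 Hz, 2.5 s windows stepped 125 ms
(181 windows), 200 surrogates; brute-force graph oracles use $N \le 8$;
Monte-Carlo trajectory entropy uses $10^6$ first-passage paths; cohort
recovery uses 40 subjects. Ties in the dominant mode break to the lowest
label; ties in seriation and representative selection break to the lowest
index; surrogate comparisons use a $10^{-12}$ slack so exact ties count
as exceedances (conservative). All randomness flows from explicit seeds;
every pipeline output carries the configuration hash and seed.

## Known limitations

- The printed window count of the motivating 64-sensor analyses cannot be
  reconstructed from any single (width, step) pair at 160 Hz; width is
  therefore an explicit configuration value, defaulting to 2.5 s.
- EDF support covers the standard 16-bit format with a single sampling
  rate across signals; EDF+ annotations are not parsed.
- Infomax ICA is not bundled; the artifact rule accepts any external
  decomposition honouring the `components`/`mixing`/`center` contract.
- At uncorrected α the dominant-label tensor of null data is dense by
  construction (see above); interpret mode *labels* jointly with their
  strengths, or use the Bonferroni option with ≥ 1000 surrogates.
- Outputs persist as CSV/JSON; no HDF5 container is written.
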