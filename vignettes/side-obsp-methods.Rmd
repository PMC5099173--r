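---
title: "Decomposing multichannel biosignals with oblique subspace projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing multichannel biosignals with oblique subspace projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(sideobsp)
```

## The problem

Bedside monitoring produces many synchronously sampled channels: a
near-infrared spectroscopy (NIRS) tissue-oxygenation index (TOI) together
with systemic variables such as mean arterial blood pressure (MABP),
arterial oxygen saturation (SaO~2~), heart rate, end-tidal CO~2~, or
extracorporeal-support pump flow. The output channel reflects *all* of
them at once. Clinical questions, however, are usually about one pathway at
a time — e.g. "how does TOI respond to blood pressure, once the effect of a
desaturation is removed?" (the basis of cerebral-autoregulation assessment
with NIRS).

`sideobsp` answers this by decomposing the output additively,

$$y[n] \;=\; \sum_{i=1}^{d}\; \underbrace{\sum_{m=0}^{p-1} s_i[n-m]\,h_i[m]}_{\hat y_i[n]} \;+\; \varepsilon[n],$$

one finite impulse response $h_i$ (and hence one partial contribution
$\hat y_i$) per input channel. The difficulty is that physiological inputs
are *correlated*: their signal subspaces are oblique to each other, and
ordinary per-input least squares assigns shared dynamics to whichever
regressor it fits, contaminating every component.

## Oblique projections on a block-Hankel design

Stacking $p$ delayed copies of each input gives the block design
$A = [A_1, \dots, A_d] \in \mathbb{R}^{(N-p)\times dp}$ (delay 0 first in
each block; the first $p$ output samples are dropped so that every row is a
complete convolution window — no zero padding, no boundary artifacts). For
input $k$, write $A_{(k)}$ for the remaining blocks and

$$Q_{(k)} = I - A_{(k)}\bigl(A_{(k)}^{\top}A_{(k)}\bigr)^{+}A_{(k)}^{\top},$$

the orthogonal projector onto the null space of $A_{(k)}^{\top}$. Solving
the *projected* regression $Q_{(k)}y = Q_{(k)}A_k h_k + \eta$ is equivalent
to applying the oblique projector
$P_{k.(k)} = A_k (A_k^\top Q_{(k)} A_k)^{+} A_k^\top Q_{(k)}$, which maps
$y$ onto $\mathrm{span}(A_k)$ *along* $\mathrm{span}(A_{(k)})$: whatever the
other inputs can explain is removed before $h_k$ is estimated, so shared
dynamics land in the right component even under strong input correlation.
When the blocks happen to be orthogonal this reduces to the familiar
orthogonal projection, and the package's tests exercise that limit
explicitly.

The solver never materializes the $(N-p)\times(N-p)$ projectors: $Q_{(k)}$
is applied implicitly as the residual of a least-squares fit against
$A_{(k)}$ (an SVD basis, rank-aware). The explicit projectors are exposed
through `oblique_projector()` for teaching and testing, where every identity
($Q = Q^\top = Q^2$, $P^2 = P$, $PA_k = A_k$, $PA_{(k)} = 0$, and the
asymmetry $P \ne P^\top$ on correlated blocks) is asserted numerically.

Smoothness is imposed with a Tikhonov penalty built from the first
difference operator $\Gamma \in \mathbb{R}^{(p-1)\times p}$
($\Gamma_{i,i} = -1$, $\Gamma_{i,i+1} = 1$):

$$\hat h_k = \bigl(A_k^\top Q_{(k)} A_k + \gamma\, \Gamma^\top\Gamma\bigr)^{+} A_k^\top Q_{(k)}\, y .$$

Physiological impulse responses are smooth, so penalizing tap-to-tap
differences (not tap magnitudes, as ridge would) is the natural prior;
constant responses are not penalized at all.

## Conventions and numerical choices

* **Taps and trimming.** `block_hankel()` uses delays $0,\dots,p-1$; row $r$
  corresponds to output time $p + r$. An impulse-response vector of $p$ taps
  multiplied onto the block reproduces the causal convolution exactly, which
  the tests assert against a naive convolution sum.
* **Centering.** Inputs and output are mean-centered by default
  (`center = TRUE`): the model describes deviations, and uncentered
  channels would load a collinear constant subspace into every block.
  Optional unit-variance scaling (`scale = TRUE`) is undone on the
  returned impulse responses.
* **Pseudoinverse.** All $(\cdot)^{+}$ are SVD pseudoinverses with the
  cutoff $\max(\mathrm{dim})\cdot\varepsilon\cdot\sigma_{\max}$, centralized
  in `obsp_control()`.
* **Ill-posed projections.** If $\mathrm{rank}([A_k\ A_{(k)}]) <
  \mathrm{rank}(A_k) + \mathrm{rank}(A_{(k)})$ (the target subspace leaks
  into the reference subspace — e.g. the output supplied as its own input,
  or constant channels whose delays are collinear), the projection is
  ill-defined. The package warns (condition class `sideobsp_ill_posed`),
  names the offending channel, and proceeds with the pseudoinverse /
  regularized solution rather than aborting, since the Tikhonov term
  mitigates exactly this degeneracy.
* **Overdetermination.** `build_design()` requires $N - p > dp$ and reports
  the minimum record length otherwise.

## Choosing $p$ and $\gamma$ by cross-validation

`cross_validate()` treats the reference-block projection as a fixed
preprocessing of the record: $Q_{(k)}y$ and $Q_{(k)}A_k$ are computed once
from all rows, and the regularized fit is cross-validated over
**contiguous, non-overlapping time blocks** of the projected regression —
shuffled folds would break the serial dependence of physiological signals.
The fold error is the validation prediction error

$$e = \frac{1}{N_v}\,\bigl\|(Q_{(k)}y)_v - (Q_{(k)}A_k)_v\,h_k\bigr\|_2^2,$$

summed over blocks and averaged over folds.

Two design points deserve a note, because the obvious alternatives fail:

* *Why a full-record projection rather than per-fold validation
  projectors?* A validation fold of $(N-p)/K$ rows supports a complement
  projector of rank $N_v - \mathrm{rank}(A_{(k),v})$. At the benchmark's
  own configuration ($d = 3$, $p = 50$, $N = 1024$, 10 folds) a fold has
  ~97 rows against $(d-1)p = 100$ reference columns, so a per-fold
  projector is identically zero and the validation mismatch term vanishes
  identically. Projecting once on the full record keeps it informative for
  any fold count.
* *Why no smoothness term in the selection criterion?* The penalty already
  acts inside every fit; re-adding $\|\Gamma h\|^2$ to the model-choice
  criterion double-counts it and biases the choice, in a direction that
  depends on an arbitrary weighting: weighted $1/p$ it decreases in $p$
  (on noise-free data every order at or above the truth fits exactly, so
  order selection would always prefer the largest candidate); weighted
  $\gamma/p$ it grows linearly in $\gamma$ and swamps the few-percent
  prediction gains that regularization actually delivers, so $\gamma = 0$
  would always win. Selecting on prediction error alone is consistent for
  both knobs: noise-free order selection is exact, and under benchmark
  noise the error curve has a genuine interior minimum in $\gamma$.

Ties (measured relative to $\max(\text{best}, \operatorname{var} y)$, so
machine-zero errors compare as equal) are broken towards the smallest
$\gamma$, then the smallest $p$ — less bias, fewer parameters. The default
$\gamma$ grid is 13 log-spaced points over $10^{-6}\dots10^{3}$ scaled by
$\operatorname{tr}(A_k^\top Q_{(k)} A_k)/p$, so it tracks the scale of the
normal-equation matrix. A single global $\gamma$ is shared by all blocks.

The truncation-based order heuristic (how much impulse-response mass sits
in the last 10% of taps) is deliberately *not* used for automatic order
selection; it is exposed post hoc as `tail_mass()` — order selection
belongs to cross-validation or prior knowledge.

## The synthetic benchmark

`generate_benchmark()` reproduces a controlled version of the problem with
full ground truth, and is the basis of nearly every test:

* $N = 1024$ samples; three pseudo-random binary inputs band-limited to
  0–0.3 half-cycles/sample. The PRBS generator takes the sign of
  band-limited Gaussian noise; because a hard limiter spreads power into
  harmonics, the pre-limiter filter sits at a third of the nominal band
  edge, which keeps ≥90% of the two-level signal's power inside the band
  (a periodogram property asserted by tests, not an exact construction).
* Input correlation $\rho = 0.5$ induced by mixing a fourth reference PRBS
  into each input as $\rho\,z(x_4) + \sqrt{1-\rho^2}\,z(x_i)$ after
  standardization. The $\sqrt{1-\rho^2}$ weight is what actually delivers
  the target correlation for independent standardized signals; mixing
  without the square root would not.
* Three subsystems: a 3rd-order low-pass Butterworth at 0.15
  half-cycles/sample and two 3rd-order band-passes (0.1–0.2 and
  0.05–0.15). The *generative* ground truth is the impulse response of each
  filter truncated to 50 taps — the analysis model's order. The band-pass
  responses only fall below $10^{-6}$ of their peak after roughly 250–320
  taps, with tails beyond tap 50 still ~6% of peak, so a 50-tap
  moving-average analysis of the *recursive* filters could never be exact;
  defining the truth as the 50-tap truncation keeps the benchmark
  self-consistent and makes exact recovery a meaningful check.
  `subsystem_filters()` still exposes the full $10^{-6}$-truncated FIRs.
* The low-passed reference signal is mixed into the output at correlation
  0.3 *before* measurement noise is added; the mixing rescales the clean
  output by $\sqrt{1-0.3^2}$, so the stored ground-truth components are
  recorded after that scaling and the identity
  `y == rowSums(true_components) + contamination + noise_y` holds exactly.
* Measurement noise is zero-mean *uniform*, scaled so the realized SNR of
  the drawn realization is exactly 4 dB on the output and on every input.

What the benchmark does **not** emulate: nonstationarity, nonlinearity
(autoregulation is not linear), measurement dropouts, and inputs whose
subspaces genuinely overlap. Passing its tests therefore says the algebra
and the estimator are right, not that every clinical record will decompose
cleanly.

`generate_physio_scenario()` complements it with a trend-monitoring
flavour: a slowly drifting pressure channel (band-limited random walk plus
a slow oscillation), a saturation channel with step desaturations
(fast drop, exponential recovery), known smooth 15-tap responses (DC gains
0.3 %TOI/mmHg and 0.5 %TOI/%SaO~2~), 1/3 Hz sampling, and 20 dB output
noise. Its headline check: after decomposition, the pressure component's
deviation from its ground truth around a desaturation stays below 10% of
the injected step response — the step stays out of the pressure pathway.

## Quantifying residual coupling

`coupling_table()` asks, for every (input, component) pair, how much the
input's past predicts the component. Two estimators share one contract
(non-negative; zero in expectation for independent stationary signals;
increasing in linear coupling strength; invariant to affine rescaling):

* `"infotransfer"` — reduction in corrected conditional entropy of the
  (uniformly quantized) component when the input's past is added to the
  component's own past; embedding length 2 and 6 levels by default. The
  correction substitutes the marginal entropy for conditioning patterns
  seen once, compensating the downward bias of sparse counts.
* `"linear"` — the fraction of component variance explained by the input
  at lags $0\dots L$; deterministic and fast, the right choice for
  reproducible automated checks (set `embedding` to the model order to
  cover the whole impulse response).

Significance is judged against circular time-shift surrogates of the input
(199 shifts, at least 50 samples, preserving marginals and
autocorrelation). For a whole table, per-entry 5% tests would flag *some*
entry in about a quarter of tables by chance alone, so `coupling_table()`
defaults to a Bonferroni family-wise 5% threshold across its $d^2$ entries;
`coupling_significance()` for a single pair keeps the plain 95th
percentile.

One honest caveat, demonstrated by the package's own tests: when inputs are
correlated by construction ($\rho = 0.5$ through a shared reference), the
measured inputs are *genuinely* statistically coupled to every component —
including the ground-truth components. A calibrated surrogate test
therefore flags occasional off-diagonal entries no matter how good the
decomposition is; what distinguishes a good decomposition is the *size* of
the off-diagonal couplings (an order of magnitude below the diagonal here,
and systematically smaller than those of naive per-input OLS components),
not their exact zeroness. Expecting an all-zero off-diagonal significance
pattern in every realization would be asking the estimator to be blind to
real dependence.

## Problem sizes used by the automated checks

The test-suite and the acceptance script regenerate everything from seeds:
100 random projector designs (up to 200 rows, 4 blocks, order 15); the
$N = 1024$ benchmark for recovery, decoupling (100 seeds), band-width
comparison (100 replicates at the cross-validated $\gamma$), and coupling
patterns (20 seeds, 199 surrogates); 20 cross-validation seeds; and one
two-event physiological record of 2400 samples. These sizes give stable
pass/fail behaviour for the stochastic checks while keeping a full run in
the minutes range.

## Limitations

* The model is linear and time-invariant over the analyzed segment;
  nonstationary records should be windowed (the CLI processes one file per
  run — segment first, then decompose).
* Any input *not* measured is implicitly treated as orthogonal to the
  measured ones; its influence lands in the residual (or, worse, in
  correlated components). Inspect `glance()$r_squared` and the residual.
* Impulse responses longer than the chosen order alias into the estimate;
  check `tail_mass()`.
* The coupling table is a diagnostic, not a causal analysis.
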