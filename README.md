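# sideobsp

Decompose a measured output signal into the additive partial contributions
of its (correlated) input channels.

The motivating setting is hemodynamic monitoring with near-infrared
spectroscopy (NIRS): a tissue-oxygenation index (TOI) reflects mean
arterial blood pressure (MABP), arterial oxygen saturation (SaO₂), heart
rate, CO₂, pump flow — all at once, and all correlated with each other.
Assessing one pathway (for example cerebral autoregulation, the TOI⟷MABP
relation) requires first removing the others: a sudden desaturation must
not masquerade as a pressure response. `sideobsp` does this separation for
any synchronously sampled multichannel record, not just NIRS.

## The model

Each input channel $s_i$ drives the output through an unknown finite
impulse response $h_i$ of $p$ taps:

$$y[n] = \sum_{i=1}^{d} \hat y_i[n] + \varepsilon[n], \qquad
  \hat y_i[n] = \sum_{m=0}^{p-1} s_i[n-m]\, h_i[m].$$

Stacking delayed copies of each input gives a block design
$A = [A_1,\dots,A_d]$. For input $k$ the other blocks $A_{(k)}$ are
projected out with the orthogonal projector $Q_{(k)}$ onto
$\mathrm{Null}(A_{(k)}^\top)$, and the impulse response is estimated from
the projected, Tikhonov-regularized regression

$$\hat h_k = \bigl(A_k^\top Q_{(k)} A_k + \gamma\,\Gamma^\top\Gamma\bigr)^{+}
             A_k^\top Q_{(k)}\, y,$$

with $\Gamma$ the first-difference operator (physiological responses are
smooth). This is equivalent to applying the *oblique* projector onto
$\mathrm{span}(A_k)$ along $\mathrm{span}(A_{(k)})$ — so dynamics shared by
correlated inputs are assigned to the right component, where ordinary
per-input least squares leaks them everywhere. The order $p$ and the
regularization constant $\gamma$ can be chosen by blocked (contiguous-fold)
cross-validation.

The package also ships synthetic generators with full ground truth (a
correlated-input filter-bank benchmark and a desaturation-event
physiological scenario), an information-transfer coupling diagnostic with
surrogate-null significance, frequency-response reporting, broom-style
`tidy()`/`glance()` and `autoplot()` methods, and a small CLI.

## Worked example

Generate the standard benchmark (three band-limited binary inputs,
correlated at ρ = 0.5 through a shared reference, filtered through known
low-/band-pass subsystems, 4 dB uniform noise on all channels) and
decompose it, letting cross-validation pick γ:

```r
library(sideobsp)

bench <- generate_benchmark(seed = 42)
fit <- side_obsp(bench$data, target = "y", order = 50, gamma = "auto")
fit
#> <side_obsp> y ~ x1 + x2 + x3
#>   order p = 50, gamma = 208, n = 974 rows, R^2 = 0.6980
glance(fit)
#> # A tibble: 1 × 6
#>   order gamma     n r_squared residual_rms tail_mass_max
#>   <int> <dbl> <int>     <dbl>        <dbl>         <dbl>
#> 1    50  208.   974     0.698        0.787        0.0494
```

At 4 dB SNR roughly 70% of the output variance is explained — about what
the noise level permits — and `tail_mass_max` ≈ 0.05 says the estimated
responses have decayed within the 50-tap window. How well does each
component track *its own* input and no other?

```r
coupling_table(bench$data[c("x1", "x2", "x3")], fit,
               method = "linear", embedding = 50L)
#> <coupling_matrix> linear estimator (inputs x components)
#>       x1    x2    x3
#> x1 1.000 0.053 0.113
#> x2 0.072 1.000 0.051
#> x3 0.103 0.071 1.000
```

Each component is fully predictable from its own input (diagonal 1.000,
as it must be — a component lies in its input's lag span) and an order of
magnitude less coupled to the others; the small off-diagonal values are
the genuine residue of the ρ = 0.5 input correlation, not leakage.
`tidy(fit)`, `autoplot(fit)`, `plot_impulse_responses(fit, bench$true_h)`
and `frequency_response(fit)` expose the components, impulse responses and
subsystem gains; `write_results(fit, dir = "out")` writes them as CSV with
a reproducibility manifest.

The same pipeline runs from a shell:

```sh
exec/sideobsp simulate  --scenario benchmark --seed 42 --out sim
exec/sideobsp decompose --input sim/signals.csv --target y \
                        --order 50 --gamma auto --out fit
exec/sideobsp evaluate  --input sim/signals.csv --components fit --out eval
```

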