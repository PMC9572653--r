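# flimmixer

Fluorescence-lifetime estimation from time-correlated single-photon
counting (TCSPC) histograms, for FLIM practitioners and methods developers.
The package simulates realistic decay histograms, trains a compact
MLP-Mixer neural network to regress **amplitude-weighted average
lifetimes**, and benchmarks it head-to-head against classical estimators —
all from a single seeded configuration, with no external data.

## The problem and the model

A TCSPC histogram follows

    y(t) = IRF(t) * A Σᵢ αᵢ exp(−t/τᵢ) + ε(t),   Σᵢ αᵢ = 1,

a multiexponential decay convolved with the instrument response function
(IRF, modelled as a Gaussian pulse) and corrupted by Poisson counting noise
ε. The target quantity is the amplitude-weighted average lifetime
**τ_A = Σᵢ αᵢτᵢ**, the standard readout for FRET and quenching studies.
With 100–10,000 photons per pixel (20–40 dB under the shot-noise convention
SNR = 10·log₁₀Y), per-pixel curve fitting is slow and noisy; the package's
mixer network — patch embedding, one token-mixing/channel-mixing MLP block
with skip connections, and a three-layer regression head, ~30k parameters —
maps a peak-normalized histogram directly to τ_A in a single forward pass.

Estimators provided:

| Function | Method |
|---|---|
| `train_mixer()` / `predict_lifetime()` | MLP-Mixer regressor (compiled forward/backward, Adam, early stopping) |
| `fit_nlsm()` | Levenberg–Marquardt nonlinear least squares on the convolved model |
| `fit_vpm()` | variable projection (lifetimes nonlinear, amplitudes by non-negative LS) |
| `fit_cmm()` | center-of-mass first moment (intensity-weighted, fit-free) |

Around them: a seeded decay simulator (`generate_dataset()`), benchmark
drivers (`run_mono_benchmark()`, `run_bi_benchmark()`), SSIM for lifetime
maps (`ssim()`), and per-pixel image inference on TIFF stacks
(`read_stack()`, `mask_low_counts()`, `predict_image()`). A thin CLI lives
at `inst/scripts/flim-mixer`.

## A worked example

Simulate one biexponential decay at 34 dB and estimate its lifetime:

```r
library(flimmixer)
axis  <- time_axis()                       # 256 bins x 0.039 ns
irf   <- irf_spec(fwhm = 167)              # Gaussian IRF, 167 ps FWHM
model <- decay_model(alpha = c(0.3, 0.7), tau = c(0.8, 3.0))
amplitude_weighted_lifetime(model)
#> [1] 2.34

clean <- synthesize_clean(model, irf, axis)
h <- sample_histogram(clean, counts_from_snr_db(34), axis, seed = 42)
h$total_counts
#> [1] 2518

round(c(nlsm = fit_nlsm(h, irf, n_components = 2)$tau_a,
        vpm  = fit_vpm(h, irf, n_components = 2)$tau_a,
        cmm  = fit_cmm(h, t0 = 0.1 * axis$window)), 3)
#>  nlsm   vpm   cmm
#> 1.930 1.930 2.289
```

The true τ_A is 2.34 ns. At ~2,500 photons the two-component least-squares
fits land 0.41 ns low — a single noisy replicate is genuinely hard — and
the center-of-mass value is not comparable (it estimates the
intensity-weighted lifetime, here 2.77 ns, pulled down by window
truncation). A mixer trained on 10,000 simulated signals (about three
minutes on one CPU core) reads the same histogram as:

```r
ds  <- generate_dataset(dataset_spec(10000, seed = 101))
fit <- train_mixer(ds, train_config(max_epochs = 500, seed = 202))
round(predict_lifetime(fit$network, h$counts), 3)
#> [1] 2.121
```

Benchmarked over hundreds of replicates (`run_bi_benchmark()`), the
mixer's *mean* estimate tracks the truth to well under the reported 0.037
relative bias at α = 0.2, while the per-replicate spread of all methods
reflects the Poisson information limit — see the methods vignette
(`vignettes/flim-mixer-methods.Rmd`) for the full analysis, including why
validation MSE cannot reach arbitrarily small values at these photon
budgets.

Per-pixel imaging works the same way end to end:

```r
ph  <- simulate_phantom(list(decay_model(1, 1), decay_model(1, 3)),
                        h = 32, w = 32, counts = 2500, seed = 7)
map <- predict_image(fit$network, ph$stack,
                     mask = mask_low_counts(ph$stack, 0.1))
write_lifetime_map(map, "phantom")   # float TIFF + PNG + CSV summary
```

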