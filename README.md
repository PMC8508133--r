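# smres — single-molecule residence times from time-lapse imaging

`smres` estimates how long DNA-binding proteins stay bound to chromatin in
living cells from single-molecule microscopy data. It was built around the
residence-time analysis of RBPJ-family transcription factors (RBPJ, its
DNA-binding mutant, and the pancreatic paralog RBPJL), whose long-lived
chromatin binding lasts minutes — far longer than a fluorophore survives
continuous illumination.

## The method

A tracked molecule disappears either by dissociating (rate `k`) or by
photobleaching. Time-lapse illumination disentangles the two: the camera
integration time `t_int` (50 ms) is fixed while the dark period varies,
giving acquisition conditions with frame cycle times `tau` from 0.1 s to
14 s. Bleaching accrues only while the laser is on, so each binding state
loses tracked molecules at the effective rate

    k_eff(tau) = k + a / tau,      a = k_b * t_int  (bleach number, 1/frame)

Per condition, bound-track durations are assembled into fluorescence
survival-time distributions. A global fit across all conditions infers a
dissociation-rate *event spectrum* — non-negative weights `w_i` on a fixed
log-spaced grid of rates `k_i` — together with the shared bleach number
`a`, by non-negative least squares on the duration histograms (an inverse
Laplace transformation; the forward model also accounts for the finite
movie duration and the frame-capture probability). Dividing event weights
by their rates and renormalizing yields the *state spectrum* `s_i`, the
probability of finding a molecule in state `i` at a random instant. The
fit is repeated 499 times on 80% subsets of the tracks; the slowest
cluster of the merged resampled spectrum gives the long-lived binding
time `1/k_slow` with a resampling standard deviation.

The package also contains the upstream imaging stages (Gaussian-PSF movie
rendering, SNR-threshold spot detection, nearest-neighbour track linking
with gap closing, confinement-based bound/unbound classification) and a
kinetic simulator, so the entire chain is testable end to end by parameter
recovery — the original imaging data are not publicly deposited.

## Worked example

```r
library(smres)

# simulate a small RBPJL-like experiment and analyze it end to end
rep <- recovery_study("RBPJL", seed = 1, n_resamples = 60)
print(rep)
#> Residence-time pipeline report
#>   bound/total molecules per condition:
#>     0.1 s tl: 969/1093
#>     0.4 s tl: 923/1100
#>     3.2 s tl: 856/1132
#>     14 s tl: 502/942
#>   bleach number: 0.05059 /frame
#>   slowest-cluster binding time: 413 s (±36 s, mean ± s.d. from resampling)
#>   recovery: truth 465 s, estimate 413 s +/- 36 s -> FAIL
```

Reading the output: per condition, `bound/total` counts the tracks that
passed the confinement and minimum-length criteria versus all simulated
molecules (the same reporting convention as the imaging experiment). The
bleach number recovered (0.051/frame) matches the simulation truth
(`k_b = 1 /s` at 50 ms integration, i.e. 0.05/frame). The binding time 413 s
estimates the simulated ground truth of 465 s; the `recovery` line compares
the two at ±1 resampling s.d. — at this reduced data volume and with the
subsampling spread understating full-sample variability, an estimate
1.4 s.d. away is unremarkable (the published spread for the analogous
quantity is 256 s on 910 s). `plot(rep$fit)` overlays the fitted model
survival curves on the empirical distributions, one per cycle time;
`plot_spectrum(rep$fit)` draws the state spectrum.

A thin command-line interface over the same functions lives at
`inst/cli/smres.R` (`simulate`, `detect`, `track`, `survive`, `grid`,
`run-all`).

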