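# axonmap

Quantitative mapping of long-range axonal projections and of the synaptic
populations they form. `axonmap` is an R package for three linked analyses
common in functional connectomics of descending (e.g. corticocollicular)
pathways:

1. **Semi-automatic 3D axon tracing** of fluorophore-labelled axons in
   calibrated confocal stacks, and axonal density in µm of axon per µm³ of
   tissue. Tracing has two stages: *seed generation* (maximum-intensity
   projection → user-thresholded binarization → exact Euclidean distance
   transform → windowed local maxima → brightest-z selection) and
   *vectorial tracking* — at each node the Hessian of the Gaussian-smoothed
   volume is eigen-decomposed; a point is tubular when
   `λ2 ≈ λ3 ≪ 0, λ1 ≈ 0` (eigenvalues by ascending magnitude), the march
   advances along the minor eigenvector, and a medial correction in the
   normal plane keeps nodes on the axon's centerline.
2. **Sum-of-Gaussians decomposition** of all-point histograms of synapse
   sizes (mGRASP puncta surface areas, µm²) or quantal amplitudes (mEPSC
   peaks, pA): Freedman–Diaconis binning (`2·IQR/n^{1/3}`), bounded
   least-squares fitting of
   `y = y0 + Σ A/(w√(π/2))·exp(−2(x−xc)²/w²)` with 1–4 components,
   χ²- and adjusted-r²-guided selection of the component count, component
   area fractions, and small/medium/large classification at the component
   density crossings.
3. **mEPSC analysis**: passive membrane properties (`Cm = Q/ΔV`,
   `Gm = Iss/ΔV`, `Rs = ΔV/Ip`, with the >30% series-resistance exclusion
   rule), deterministic event detection, per-event peak amplitude, 10–90%
   rise time, amplitude-weighted bi-exponential decay, instantaneous
   frequency, and the regression of event frequency on optical stimulation
   rate with 5%/95% confidence limits.

Ground-truthed synthetic generators (tubular image phantoms with analytic
centerlines, Gaussian-mixture samples, Poisson trains of bi-exponential
synaptic events) back every pipeline with exact oracles; the methods
vignette (`vignettes/axonmap-methods.Rmd`) documents the models,
parameters and numerical choices.

## Worked example

Trace a noisy helical axon phantom (peak SNR ≈ 5) and recover its density:

```r
library(axonmap)

spec <- phantom_spec(
  shape = c(72L, 72L, 72L), voxel_size = c(0.5, 0.4, 0.4),
  curves = list(curve_helix(center = c(14.4, 14.4, 7.9),
                            radius_um = 7.5, pitch_um = 10, turns = 2,
                            width_px = 3, peak = 0.9)),
  background = 0.05, noise_sd = 0.17, seed = 42)
ph <- make_phantom(spec)
ph$total_length
#> [1] 96.34989

pars <- benchmark_trace_params(noise_sd = 0.17)
traces <- trace_all(ph$stack, pars$seed, pars$tracer, verbose = TRUE)
#> trace_all: 88 seeds, 30 suppressed, 1 traces emitted
traces[[1]]
#> <axon_trace: 235 nodes, 96.15 um, seed 1>
axon_density(traces, ph$stack)
#> [1] 0.0032201
```

The single emitted trace recovers 96.15 of 96.35 µm of analytic arc
length, and the density (0.00322 µm/µm³) matches ground truth
(length/volume = 0.0032266) to 0.2%. The 88 seeds collapse to one trace
because voxels claimed by the first trace suppress redundant seeds on the
same axon.

Decompose a synapse-size distribution into small/medium/large populations
(here sampled from known fractions 0.31/0.41/0.28):

```r
x <- sample_mixture(mixture_spec(c(0.31, 0.41, 0.28), c(0.15, 0.45, 0.95),
                                 c(0.1, 0.15, 0.3), n = 5000, seed = 7))
fit <- select_model(build_histogram(x))
fit
#> <mixture_fit: k = 3, chi^2 = 0.02476, adj r^2 = 0.9952, converged>
#>           A         w        xc  fraction
#> 1 0.3017999 0.1029581 0.1462337 0.3071897
#> 2 0.4104166 0.1557391 0.4511214 0.4177462
#> 3 0.2702379 0.3010585 0.9563945 0.2750640
fit$trail
#>   k chi_square adjusted_r2 converged accepted
#> 1 1    5.65391     0.26945      TRUE     TRUE
#> 2 2    0.91403     0.85828      TRUE     TRUE
#> 3 3    0.02476     0.99520      TRUE     TRUE
#> 4 4    0.00559     0.99856      TRUE    FALSE
size_cutoffs(fit)
#> [1] 0.2690 0.6476
```

Three components are selected (the probed fourth is rejected because it
barely moves the adjusted r²); the recovered area fractions
30.7/41.8/27.5% match the generating 31/41/28%, and the two cutoffs define
the small/medium/large classes for `classify_sizes()`.

## Command line

A thin CLI over the same functions ships in `inst/cli/axonmap`:

```sh
axonmap simulate phantom --spec phantom.yaml --out stack.tif --seed 2
axonmap seeds  --in stack.tif --voxel 0.5,0.4,0.4 --lower 0.2 --upper 1 --out seeds.tsv
axonmap trace  --in stack.tif --voxel 0.5,0.4,0.4 --lower 0.2 --upper 1 \
               --sigma 2 --min-intensity 0.1 --out traces/
axonmap density --in traces/ --stack stack.tif --voxel 0.5,0.4,0.4
axonmap fitmix --in areas.tsv --out fit.json --cutoffs --classify
axonmap events --in trace.tsv --rate 20000 --threshold -8 --out events.tsv
```

Options can also live in a YAML `--config` file; flags override it. Exit
codes: 0 success, 1 user/parameter error, 2 internal error.

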