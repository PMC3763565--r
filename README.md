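# arpeggio

Spectral compression and deconvolution of ChIP-seq signals.

Comparing a new ChIP-seq experiment against thousands of public ones is
hard at genome resolution: coverage vectors are huge, noisy, and tied to
one genome build. `arpeggio` compresses each experiment into the
pair-count autocorrelation of its deduplicated 5' read starts,

R(τ) = #{ read pairs on the same strand and chromosome separated by exactly τ bp },  0 ≤ τ < W (default 8192),

and works in the Fourier domain of that profile (its *spectral density*,
a fixed 8192-element vector). The measured signal is modelled as the true
IP signal convolved with technical variability; deconvolving the ChIP
autocorrelation by a spectrally matched control's,

R̃_Z = F⁻¹[ F(R_chip) / F(R_control) ],

yields the **Arpeggio profile**, a genome-aggregated signature of
protein–chromatin interaction geometry: isolated factors give a sharp
decaying pulse, phased nucleosome arrays a damped ~190-bp oscillation,
polymerases a slow-shouldered pulse, and controls a pure impulse. The
same machinery recovers the **full fragment-length distribution** from
single-end reads (deconvolving the opposing-strand cross-correlation by
the same-strand autocorrelation), quantifies nucleosome-spacing
strictness (the α ratio), and embeds collections of experiments by the
leading six principal components of their spectra for clustering
(Davies–Bouldin), classification (1-NN balanced accuracy) and ranking
(AUC) against biological annotations. A seeded simulator with full
ground truth covers four interaction regimes for testing.

Intended users: computational epigenomics groups organizing or querying
collections of ChIP-seq experiments, and anyone needing fragment-length
or nucleosome-spacing estimates from single-end archives.

## Worked example

Simulate a phased nucleosome array with a matched background control,
deconvolve, and read off the repeat length:

```r
library(arpeggio)

cfg  <- simulation_config("periodic_array", n_events = 200, array_size = 10,
                          repeat_length = 190, positional_jitter_sd = 5,
                          n_reads = 200000, seed = 7)
pair <- simulate_matched_pair(cfg)

chip <- autocorrelation(pair$chip$starts)      # pair counts, W = 8192
ctrl <- autocorrelation(pair$control$starts)
ap   <- deconvolve(chip, ctrl)

profile_local_maxima(ap)[1:2]
#> [1] 187 377
alpha_ratio(spectral_density(ap))
#> [1] 15.50959
```

The first two positive-lag maxima of the Arpeggio profile sit at the
nucleosome repeat length and its second harmonic (187 and 377 bp here,
within ±5 bp of the simulated 190/380), and α ≈ 15.5 ≫ 1 says the
spacing is strict — an isolated-factor simulation gives α ≈ 1.

Fragment lengths from single-end reads alone:

```r
cfg <- simulation_config("isolated_factor", n_events = 500,
                         fragment_model = list(type = "fixed", mean = 250, sd = 0),
                         n_reads = 20000, background_fraction = 0, seed = 11)
sim <- simulate_experiment(cfg)
fld <- fragment_length_distribution(
  cross_correlation(sim$starts),
  autocorrelation(sim$starts, strands = "plus"))
fld
#> fragment_length_distribution 'sim': mode 251 bp, mean 270.5 bp (25.88% mass clipped)
```

Every fragment was 250 bp; the recovered pmf mode lands within ±2 bp of
it. For point-source libraries like this one the *mode* is the reliable
estimand (fragment starts and lengths are coupled, so the distribution's
shape is only partially identifiable — the inflated mean reflects that);
see the methods vignette (`vignettes/arpeggio-methods.Rmd`) for the
identifiability analysis and the boundary-anchored geometry in which the
full shape is recovered to KS ≤ 0.05.

## Command line

A thin Rscript wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "arpeggio.R", package = "arpeggio"))')
Rscript $CLI simulate --config sim.json --out-prefix run1
Rscript $CLI autocorr --starts run1.starts.tsv --max-lag 8192 --out run1.auto.tsv
Rscript $CLI profile  --chip run1.auto.tsv --control ctrl.auto.tsv --out run1.arpeggio.tsv
```

Subcommands: `ingest simulate autocorr xcorr profile fraglen alpha
match-control mds db-index knn auc jaccard`. Every output gets a
`.manifest.json` (command, parameters, input digests, seed, version) so
runs are reproducible.

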