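# streamdyn

Decoding and dynamical-system modelling of rapid visual streams.

When oriented stimuli are flashed every 250 ms, sensor-level brain
recordings can carry the traces of several successive stimuli at once.
`streamdyn` implements the full computational chain for studying this
multiplexing on synthetic data:

* a discrete-time simulator for hierarchical networks of observable (`x`)
  and hidden (`y`) units, `z(t+1) = f(Σ_u w(z,u) · u(t))`, with recurrent,
  feedforward and feedback connections and four monotone activation
  functions;
* a complexity-ordered grid search over the `3^12 = 531,441`
  connection-sign architectures of such networks, asking for the minimal
  number of connections that yields onset and offset traveling waves with
  increasing maintenance across levels;
* a synthetic generator for rapid-serial-visual-presentation EEG: 672
  8-item sequences per subject, orientations uniform on `[0, π)`, evoked
  responses superposed additively and projected onto 32 noisy virtual
  sensors;
* per-time-sample linear decoding of the circular stimulus angle
  (`W_t = (X_t'X_t)^{-1} X_t'Y` on targets `(δ, sin 2θ, cos 2θ)`, angular
  score `π/2 − |α − α̂|`, chance 0), grouped cross-validation by sequence,
  Haufe pattern transforms `P = Σ_X W Σ_Ŷ^{-1}`, temporal generalization
  matrices, per-position and encoding analyses;
* second-level group statistics: Wilcoxon signed-rank tests and a
  cluster-based sign-flip permutation test with family-wise error control.

The headline modelling result the package reproduces: among all
hierarchical two-role networks, no model with three or fewer connections
generates the observed traveling-wave phenomenology, and exactly **two
four-connection architectures** do — an *updating hierarchy* of local
negative feedback loops, and a hierarchy whose observable units are leaf
nodes. In both, hidden units maintain stimulus content while observable
units only signal its updates.

## Worked example

```r
library(streamdyn)

## simulate one synthetic subject (36 sequences) and decode it
net <- updatingHierarchy()          # hidden units maintain, x units update
design <- sampleDesign(nTrials = 36, nSubjects = 1, seed = 1)
epochs <- simulateSubjectEpochs(design, net, subject = 1, seed = 5,
                                noiseSd = 1, window = c(-0.1, 0.9))
scores <- crossvalDecode(epochs, K = 5, seed = 3)
round(max(scores$angleScore), 3)
#> [1] 1.261
scores$time[which.max(scores$angleScore)]
#> [1] 0.004
round(max(scores$deltaR, na.rm = TRUE), 3)
#> [1] 0.496
```

The peak angular score of about 1.26 radians (chance 0, ceiling `π/2 ≈
1.571`) occurs one sample after stimulus onset — the synthetic hierarchy
has no conduction delay, so its first level responds immediately — and
decodability persists for several hundred milliseconds as the wave climbs
the hierarchy. With the sensor noise turned off the peak reaches the
ceiling exactly. The orientation change δ decodes with a peak Pearson
correlation of about 0.50 at this noise level.

```r
## which architectures generate the traveling-wave phenomenology?
sr <- searchMinComplexity(maxK = 4)   # ~2 minutes on one CPU
sr
#> SearchResult: k_min = 4, 2 valid architecture(s)
#>   models covered: 3.43117e+07 (simulated: 1.01909e+07)
attr(sr$architectures, "epiphenomenalX")
#> [1]  TRUE FALSE
```

The search covers every model of complexity 1–4 over an 8-value weight
grid and 16 activation pairs, finds nothing below four connections, and
returns the two valid four-connection architectures, one of which has
leaf-node (epiphenomenal) observable units.

## Package layout

* `R/`, `src/` — S4 classes (`NetworkSpec`, `StepInput`,
  `SimulationTrace`, `SensorEpochs`, `TGMatrix`), the scalar and compiled
  batch simulators, the search, generator, decoding and statistics layers,
  and a staged, manifest-hashed pipeline (`runPipeline()`).
* `vignettes/streamdyn-methods.Rmd` — the models, the validity criteria
  and their interpretation, the generator's assumptions, and numerical
  choices.
* `tests/testthat/` — unit, property and end-to-end tests, including
  independent scalar oracles for the simulator and the regression algebra.
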