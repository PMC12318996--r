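# hyperleaf

Non-destructive detection of abiotic stress in plant leaves from
visible/near-infrared (VNIR) hyperspectral imagery and FTIR
microspectroscopy — for plant-phenotyping and chemometrics researchers who
want an auditable, fully seeded reimplementation of this workflow on
synthetic data with known ground truth.

The package covers the whole pipeline:

* **Synthetic data with ground truth** — class-structured leaf reflectance
  (chlorophyll troughs, green peak, red edge, NIR water band; stress encoded
  as monotone trough-depth scaling plus a ≤ 5 nm red-edge shift), simulated
  ten-leaf hyperspectral boards with exact masks, and FTIR perturbation
  series with a planted band-response order.
* **Ingest** — ENVI cube I/O (bit-exact round trips), leaf segmentation by
  single-band thresholding (reflectance at 655 nm < 0.6, 8-connected
  components), per-leaf mean spectra, band retention to 425–965 nm
  (256 bands).
* **Chemometrics** — PCA with explained-variance reporting and a NIPALS
  PLS-DA baseline classifier.
* **SE-LSTM classifier** — a squeeze-and-excitation channel attention block

  `s = σ(W₂ relu(W₁ x + b₁) + b₂)`, `x' = s ⊙ x`

  feeding a stacked LSTM (standard gates
  `fₜ = σ(W_fx xₜ + W_fh hₜ₋₁ + b_f)`, …,
  `cₜ = fₜ ⊙ cₜ₋₁ + iₜ ⊙ gₜ`, `hₜ = oₜ ⊙ tanh(cₜ)`)
  one band per time step, plus a softmax head over the 0/10/100 mg/L
  classes; trained by BPTT with SGD/Adam/RMSprop, with the paper-style
  tuning protocol (3 layer-counts × 4 widths; 3 optimizers × 5 learning
  rates) and the accuracy / loss / overfitting-coefficient report.
* **Wavelength selection** — SPA, GA, binary PSO, and BOSS, all
  seed-deterministic with fitness traces, plus simplified models on the
  selected bands.
* **Explanation** — exact (coalition-enumeration) and sampled interventional
  Shapley values over bands or band groups, global importance ranking, and
  per-class beeswarm tables.
* **2DCOS** — transmission→absorbance (Beer–Lambert), rubberband/ALS
  baseline correction, synchronous/asynchronous correlation maps
  (`Φ = ỸᵀỸ/(m−1)`, `Ψ = Ỹᵀ N Ỹ/(m−1)` with the Hilbert–Noda matrix), auto
  peaks, and Noda's rules for sequencing band responses.

See `vignettes/hyperleaf-methods.Rmd` for the models, assumptions, and
design decisions.

## Worked example

Simulate a ten-leaf board, segment it, extract mean spectra, and train the
SE-LSTM on the seeded 900 × 256 benchmark:

```r
library(hyperleaf)

profiles <- make_class_profiles(profile_config())
board <- simulate_cube(ten_leaf_layout(), profiles, seed = 1)
mask <- segment_leaves(board$cube, band_nm = 655, threshold = 0.6)
mask
#> Leaf mask: 10 region(s); threshold 0.60 at 655.8 nm

spectra <- simulate_spectra(profiles, n_per_class = 300, seed = 7,
                            polymers = "PET")
pca <- spectral_pca(spectra, k = 3)
pca
#> Spectral PCA: 3 component(s), rank 256
#>   explained: 87.9% 9.0% 0.5%  (cumulative 97.4%)

fit <- selstm(spectra, config = selstm_config(n_layers = 2, units = 32,
                                              epochs = 30, seed = 11))
fit
#> SE-LSTM: 2 layer(s) x 32 units, 256 bands -> 3 classes
#>   Adam, lr 0.01, 30 epochs (final training loss 0.0582)
#>   calibration 97.94% / prediction 91.85% (overfit 6.08 pp)
```

The mask reports exactly the ten planted leaves; three principal components
carry ~97 % of the spectral variance (leaf-to-leaf brightness dominates,
then the stress-related shape contrasts); the classifier reaches ~92 %
held-out accuracy on the three concentration classes with a ~6-point
calibration–prediction gap (the "overfitting coefficient").

Wavelength selection and attribution run the same way:

```r
sel <- ga_select(spectra, seed = 1)           # or spa/pso/boss_select()
simp <- fit_simplified_model(spectra, subset = sel, kind = "plsda")
shap <- shapley_attribute(function(M) predict(simp$fit, M, type = "prob"),
                          spectra$X[1:20, ], groups = band_groups(256, 16))
head(global_importance(shap))
```

A thin command-line wrapper drives the same stages:

```sh
Rscript inst/cli/hyperleaf.R simulate --seed 42 --out runs/demo
Rscript inst/cli/hyperleaf.R segment cube=runs/demo/board.img --out runs/demo
```

Every stage writes a manifest with seeds, parameters, and MD5 hashes so
deterministic stages can be re-run and verified bitwise.

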