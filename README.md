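# anchorFS

Joint feature selection across multiple data modalities with anchor
graphs, row-sparse regression and learned per-feature simplex weights.

## The problem

Biomarker studies of neurodegenerative disease routinely describe the
same subjects through several tabular feature blocks — for example ~93
regional volumes from MRI, ~93 regional uptake values from PET and a
handful of CSF biomarkers — with only a couple of hundred subjects.
Selecting the features that jointly predict a clinical label must
respect three things at once: whole-feature (row) sparsity, the fact
that modalities differ in usefulness, and the local similarity
structure among subjects, all without ever forming an n × n similarity
matrix.

## The model

With per-modality blocks `X_v ∈ R^{n×d_v}`, one-hot labels
`Y ∈ R^{k×n}`, weights `W_v ∈ R^{d_v×k}`, a shared bias `b` and a
nonnegative feature-weight vector `θ` (summing to 1 over all
d = Σ d_v features), anchorFS minimizes

```
Σ_v ‖ W_vᵀ Θ_v X_vᵀ + b 1ᵀ − Y ‖_F²
  + α Σ_v ‖ W_v ‖_{2,1}
  + β Σ_v tr( W_vᵀ X_vᵀ (I − B_v B_vᵀ) X_v W_v )
      s.t.  θ ≥ 0,  θᵀ1 = 1
```

* the `ℓ2,1` norm removes whole features by zeroing rows of `W_v`;
* `B_v = Z_v Δ_v^{-1/2}` comes from a per-modality **anchor graph**: a
  k-sparse row-stochastic affinity `Z_v` between the n samples and m ≪ n
  anchor points, whose implied sample similarity `Z Δ⁻¹ Zᵀ` is
  row-stochastic, so the graph Laplacian is simply `I − B Bᵀ` and the
  smoothness penalty costs O(nm) instead of O(n²);
* `θ` is learned on the probability simplex; its within-modality sums
  are the modality importances.

Optimization alternates a closed-form bias update, iteratively
reweighted closed-form solves for each `W_v`, and an augmented
Lagrangian method for the simplex-constrained quadratic program in `θ`.
The recorded objective is non-increasing at every sweep and iteration
stops when `|obj(t+1) − obj(t)| / obj(t) ≤ 1e-5`.

## Worked example

```r
library(anchorFS)

sim <- simulateMultiModal(nSamples = 200, modalityDims = c(93, 93, 3),
                          nInformative = c(10, 10, 1), effectSize = 1.5,
                          modalityStrength = c(0.4, 0.4, 0.2), seed = 1)
fit <- agfsFit(sim$dataset, agfsParams(seed = 1))
fit
#> AGFSModel: 3 modalities, d = 189 features, 2 classes
#>   6 sweeps, converged; final objective 42.39579
#>   modality importance: modality1 0.664, modality2 0.336, modality3 0.000

rk <- rankFeatures(fit, nSelect = 10)
head(as.data.frame(rk), 3)
#>   rank index modality withinIndex feature     score
#> 1    1    13        1          13  m1_f13 0.2012931
#> 2    2     4        1           4   m1_f4 0.1465741
#> 3    3    21        1          21  m1_f21 0.1338789
```

The fit converges in 6 sweeps and 9 of the 10 top-ranked features lie
in the generator's planted support for this seed (feature 13 of
modality 1 is a planted one); across 20 seeds the mean top-10
precision is 0.955, and a zero-effect control sits at the
21/189 ≈ 0.111 chance level. A 10-fold stratified cross-validation
with a linear SVM on the selected features is available through
`crossValidate()`, and `gridSearch()` sweeps the usual
`{1e-3, …, 1e3}` grid for α and β.

A command-line front end with `simulate`, `build-graph`, `fit`,
`select`, `evaluate` and `grid` subcommands is installed at
`system.file("scripts", "agfs.R", package = "anchorFS")`.

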