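# nirparity

Estimating the parity status of wild mosquitoes — parous (has laid eggs)
versus nulliparous — from near-infrared spectra. Parity is the field
entomologist's proxy for mosquito age and potential infectiousness, and
the reference method (ovary dissection) is slow and limited to a few
experts. `nirparity` implements a complete chemometric alternative for
the R user: window each absorbance spectrum to the standard
1851-dimensional feature space, compress it to 10 features with a
stepwise (stacked) autoencoder, classify with a one-hidden-layer
ten-neuron feed-forward network trained by Levenberg–Marquardt least
squares, and evaluate with ten-repeat Monte-Carlo 75/25
cross-validation, confusion-matrix metrics, ROC/AUC, and cross-cohort
independent testing.

## The method in brief

A spectrum is windowed to 500–2350 nm (1851 points at 1 nm), min–max
scaled per wavelength on training data, and passed through greedily
trained autoencoder steps 1851 → 256 → 64 → 10. The classifier scores

    s(x) = σ( W₂ σ(W₁x + b₁) + b₂ ),   label = 1  iff  s > 0.5,

and is trained by Levenberg–Marquardt on the squared residuals
e = y − s: each iteration solves (JᵀJ + μI)δ = Jᵀe, accepting a step
(and relaxing μ) only when the SSE decreases. Evaluation reports, with
parous as the positive class,

    sensitivity = TP/P,  specificity = TN/N,
    accuracy = (TP+TN)/(P+N),  precision = TP/(TP+FP),

plus the trapezoidal AUC of the threshold-swept ROC curve, aggregated
as mean ± sd over ten random 75/25 splits. A synthetic spectra
generator (smooth continuum + Gaussian absorption bands + tunable
band-localized class effect, imbalance, noise, and cohort shift) makes
the whole pipeline testable without field data.

## Worked example

```r
library(nirparity)

# an imbalanced labeled cohort: 60 parous vs 140 nulliparous, with a
# subtle band-localized parity effect
cfg <- synthetic_config(n_parous = 60, n_nulliparous = 140,
                        effect_size = 1, seed = 42)
ds <- preprocess(generate_spectra(cfg))   # window to 1851 features
print(ds)
#> spectral_dataset: 200 samples x 1851 wavelengths (500-2350 nm)
#>   labels: 140 nulliparous (0), 60 parous (1)
#>   cohort(s): synthetic

res <- monte_carlo_cv(ds,
  pipeline_config(step_dims = c(64, 10), ae = ae_config(epochs = 80)),
  repeats = 10, seed = 1)
print(res)
#> Monte-Carlo cross-validation: 10 repeats (encoded-ann pipeline)
#>   accuracy      92.2 +/- 6.2 %
#>   sensitivity   79.1 +/- 19.3 %
#>   specificity   97.9 +/- 2.0 %
#>   precision     94.8 +/- 5.2 %
#>   auc           96.1 +/- 4.8 %

print(res$per_repeat[[10]]$confusion)
#>              actual
#> estimate      nulliparous parous
#>   nulliparous          34      3
#>   parous                0     13
```

Read it as a field result: on held-out quarters the model calls 92% of
mosquitoes correctly; specificity (nulliparous recall) is high while
sensitivity swings more across repeats because only ~15 parous insects
land in each test quarter — exactly the imbalance penalty that
motivates compressing 1851 wavelengths to 10 codes before training.
The final-repeat confusion matrix shows the absolute counts behind
those percentages.

Real data come in as CSV — one row per mosquito; `id`, `label`
(0/1 or nulliparous/parous), optional `cohort`, then one column per
wavelength named in nm — via `read_spectra()`. Trained pipelines
persist with `save_bundle()`/`load_bundle()`, and
`cross_cohort_eval()` tests a model trained on one collection site
against another.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/nirparity.R simulate --preset muleba-imbalance --seed 2 --out runs/
Rscript inst/cli/nirparity.R preprocess --in runs/muleba-imbalance.csv \
    --out runs/windowed.csv
Rscript inst/cli/nirparity.R evaluate --in runs/windowed.csv \
    --report-out runs/report.json --repeats 10 --seed 2
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's core computation from
scratch against the installed package: it generates the separable
synthetic preset, windows it to 1851 features, runs the
autoencoder + ANN pipeline under ten-repeat Monte-Carlo
cross-validation, prints the summary, and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

See the methods vignette
(`vignettes/parity-pipeline-methods.Rmd`) for the model, its
assumptions, the synthetic generator's design and limits, and every
numerical choice (tolerances, tie rules, stopping criteria); function
reference via roxygen comments in `R/`.
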