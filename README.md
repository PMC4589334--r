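# hairpincs

Classify protein sequence fragments as **beta-hairpin** or
**non-hairpin** supersecondary structure from backbone NMR chemical
shifts alone.

Beta-hairpins — two antiparallel strands joined by a tight turn — are
among the most common supersecondary motifs, and recognising them early
helps fold assignment when no structure is available. Chemical shifts
are cheap, early-available experimental observables that are exquisitely
sensitive to local conformation, which makes them a natural alternative
to the sequence-composition features traditionally used for motif
prediction. This package implements, end to end, a shift-based hairpin
classifier: fragment averaging of six nuclei, a two-class quadratic
discriminant with an "error-allowed-scope" correction, ANOVA feature
screening, a cross-validation/ablation harness, and a synthetic
generator so the whole pipeline is testable without any external
database.

## The model

A fragment of length *l* with assigned shifts for the six backbone
nuclei *m* ∈ {C, Cα, Cβ, HN, Hα, N} is reduced to the six-vector of
per-nucleus averages

> t_m = (1/l) Σ_j CS_mj,

one mean ppm value per nucleus. Each class *v* (hairpin, non-hairpin)
is modelled on the training set by a Gaussian with mean μ_v, covariance
Σ_v (maximum-likelihood divisor p_v, the class count) and prior
proportional to p_v. A test vector **t** is scored per class with

> η_v = ln p_v − δ_v/2 − ½ ln |Σ_v|,  δ_v = (t − μ_v)ᵀ Σ_v⁻¹ (t − μ_v),

and assigned to the class with the larger η (a quadratic discriminant:
η_v is the Bayes log-posterior up to a class-independent constant). At
evaluation time, a misclassified sample may be re-counted as correct
when the *error-allowed-scope* coefficient

> R = (η_corr − η_wro) / η_corr

(η_corr: score of the true class; η_wro: score of the wrongly predicted
class) satisfies R < 0.2 — the conventional protocol threshold.
Performance is summarised by sensitivity, specificity, accuracy and the
Matthews correlation coefficient from three-fold cross-validation, and
per-nucleus importance by leave-one-nucleus-out ablation.

## Worked example

```r
library(hairpincs)

# a synthetic benchmark at the curated-study conditions:
# 157 hairpin / 75 non-hairpin fragments, lengths 7-38 / 8-40
data <- generate_dataset(default_config(separation = 2.5, seed = 1))$dataset

# are the per-nucleus averages discriminative at all?
anova_by_nucleus(build_feature_matrix(data))[, c("feature", "f_value", "p_value")]
#>   feature  f_value      p_value
#> 1       C 62.97463 9.143182e-14
#> 2      CA 55.04521 2.258504e-12
#> 3      CB 42.90737 3.713437e-10
#> 4      HN 75.28996 7.512941e-16
#> 5      HA 54.57731 2.737203e-12
#> 6       N 56.44238 1.274715e-12

# three-fold cross-validation with the R < 0.2 correction
cross_validate(data, "cs6", k = 3, seed = 11, r_max = 0.2)
#> <cs_cv> cs6 features, k = 3, r_max = 0.2, epsilon = 0
#>   averaged raw:       Sn=95.5% Sp=76.0% Acc=89.2% MCC=0.749
#>   averaged corrected: Sn=98.7% Sp=89.3% Acc=95.7% MCC=0.901
#>   pooled corrected:   Sn=98.7% Sp=89.3% Acc=95.7% MCC=0.901
```

All six F-statistics are large with p ≪ 0.05: each nucleus's fragment
average separates the two classes on its own. Raw three-fold accuracy
(89%) sits just under the configuration's Bayes bound (~90%, from
`bayes_error_mc()`); the error-allowed-scope correction then forgives
near-miss errors and lifts the protocol metrics into the mid-90s.

A fitted model can be saved, reloaded, and applied to new fragments:

```r
model <- qda_fit(build_feature_matrix(data))
write_qda_model(model, "hairpin_model.json")
predict(model, build_feature_matrix(new_data))
```

The same workflow is scriptable from a shell via the installed CLI
(`simulate`, `validate`, `anova`, `train`, `predict`, `crossval`,
`ablate`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hairpincs.R", package = "hairpincs"))')
Rscript "$CLI" simulate --seed 1 --out fragments.tsv
Rscript "$CLI" crossval --in fragments.tsv --features cs6 --k 3 \
    --r-max 0.2 --seed 1 --out cv.json
```

Input data are plain TSV fragment tables (one row per residue, columns
`protein_id fragment_id class pos aa cs_C cs_CA cs_CB cs_HN cs_HA cs_N`,
missing shifts as `NA`), so any curated shift set can be converted in.

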