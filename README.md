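# fcaffinity

Structure-based prediction of Fc/FcRn binding affinity for engineered
antibody Fc variants.

The binding of an IgG's Fc portion to the neonatal Fc receptor (FcRn) in
acidified endosomes rescues the antibody from catabolism and sets its
serum half-life; Fc mutations that tune the dissociation constant KD of
this interaction are a mainstay of antibody engineering. `fcaffinity`
implements the full in silico loop for this problem, aimed at antibody
engineers and computational structural biologists:

1. **Model** each variant (mutation strings in EU numbering, e.g.
   `M252Y/S254T/T256E`) on a reference Fc/FcRn co-complex by deterministic
   template side-chain replacement with a chi1/chi2 clash scan.
2. **Featurize** the interface: per-residue accessible and buried surface
   area (Shrake–Rupley quadrature) and atomic solvation energy at 21 Fc
   and 24 receptor-side positions, plus 12 complex-level counts (hydrogen
   bonds at 3.5 Å, salt bridges at 4.0 Å, Cα contacts, paired hydrophilic
   residues, β2-microglobulin–Fc contact atoms, ...) — 147 features in
   total.
3. **Curate** measured affinities: records assayed at pH 6.0 are
   harmonized to pH 7.0 by the wild-type KD ratio
   `round(8.8e-5 / 1.3e-6) = 68`, responses become `log10(KD)`,
   effective-signature duplicates (variants differing only at positions
   invisible to the features) are removed, and the two learning sets are
   built: FLS (pH 7 SPR only) and SLS (FLS plus harmonized pH 6 records).
4. **Learn**: standardization, four regressors — ordinary least squares
   (MLR), RBF support-vector regression (SVR, C = 1, ε = 0.1), random
   forest (RFR, depth 10), and a (20, 2)-unit tanh multi-layer perceptron
   (MLP, L2 α = 20, full-batch BFGS) — with importance-based iterative
   feature elimination, correlation pruning at |r| ≥ 0.9, 10-fold
   cross-validation (R², MAE, MSE on log10 KD) and a shuffled-label
   control.
5. **Screen** in silico random libraries (mut3/mut5 with 3/5 random
   mutations at the 21 interface positions; mut8 with 6–8 mutations drawn
   from an allowlist of not-too-destabilizing singles) and summarize
   predicted log KD distributions.

Because curated patent-derived affinity panels are proprietary and not
publicly deposited, the package ships a first-class synthetic-data module: toy
complexes with planted, exactly countable interface geometry, a synthetic
reference complex, and variant tables drawn from a known generative truth
— so every stage is testable against exact oracles. See the methods
vignette (`vignettes/fc-affinity-methods.Rmd`) for the model, parameter
and design details.

## Worked example

```r
library(fcaffinity)

ref     <- make_reference_complex()          # synthetic Fc/FcRn/B2M complex
catalog <- default_catalog(ref)              # 147 interface features

# a synthetic affinity study: 200 variants, known truth, sigma = 0.15
gen  <- make_variant_table(synthetic_truth(n = 200, sigma = 0.15, seed = 1),
                           reference = ref, catalog = catalog)
sets <- build_learning_sets(gen$table)
#> harmonize_ph: excluding 3 non-binder record(s)
sets$SLS
#> curated_set SLS: 200 records (5 duplicates removed, 3 non-binders excluded)

# 10-fold cross-validation and shuffled-label control, random forest
cross_validate(gen$truth$features, gen$truth$y_true, "RFR", k = 10, seed = 1)
#> cv_report RFR (k=10, seed=1): R2=0.635 MAE=0.574 MSE=0.693
shuffled_control(gen$truth$features, gen$truth$y_true, "RFR", k = 10, seed = 1)
#> cv_report RFR (k=10, seed=1): R2=-0.191 MAE=1.082 MSE=2.140

# end-to-end prediction for new variants (log10 KD at pH 7.0)
pipe <- train_pipeline(gen$truth$features, gen$truth$y_true, ref, catalog,
                       algorithm = "MLR")
round(predict_variants(pipe, c("M252W/M428K/N434W",
                               "T256E/N286H/K288E/V308P/L309D/N434Y/Y436K")), 3)
#> [1]  -8.139 -10.747

# screen a random 3-mutation library
lib <- random_library(50, 3, ref, seed = 1)
distribution_summary(list(mut3 = predict_variants(pipe, lib)))
#>   library  n      mean       sd       min       max
#> 1    mut3 50 -6.996029 1.268906 -9.552253 -2.920515
```

The cross-validated R² of 0.635 says the forest recovers most of the
planted signal at this noise level; the shuffled control collapsing below
zero (with MAE roughly the response spread) confirms the fit is not an
artifact of the pipeline. Predictions are on the log10 KD scale — more
negative means tighter binding — and the library summary shows the spread
of predicted affinities a 3-mutation random library would explore.

Real structures work the same way: read a co-complex with
`read_complex(pdb_text, chain_map = c(FC = "A", FCRN_ALPHA = "B",
B2M = "C"))`, apply EU-numbering offsets with `eu_renumber()`, and point
`default_catalog()` / `variant_features()` at it. Chain roles and
numbering offsets are always declared, never inferred.

A thin command-line wrapper over the same functions is available at
`inst/exec/fcaffinity-cli.R` (subcommands `cv`, `predict`, `library`).

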