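# exdriver

Expression-informed prioritization of cancer driver mutations.

Tumors accumulate many somatic mutations, but only a minority — the
drivers — confer a growth advantage. Because of inter-tumor heterogeneity,
many real drivers recur in only a handful of patients, where frequency-based
callers cannot separate them from passengers. `exdriver` ranks individual
mutant alleles (gene + protein change, e.g. `PIK3CA:E545K`) by a different
signal: whether carrying the allele is associated with systematic variation
in genome-wide expression, with per-variant functional impact scores (GERP
conservation, SIFT tolerance) acting as a soft prior.

## The model

For each gene *j* (centered expression `y_j`) and standardized binary
mutation columns `x_k`, an intercept-free linear model
`y_j = Σ_k β_jk x_k + ε_j` is fitted by an adaptively weighted lasso,
one gene at a time:

    min over β:  (1/2n)‖y_j − Xβ‖² + λ1j Σ_k δ_k |β_k| + λ2j Σ_i w_i²

Each allele's penalty scale `δ_k = sigmoid(−Σ_i w_i f̃_ki)` is a sigmoid of
its impact-oriented, standardized functional impact scores weighted by
non-negative feature weights `w`, so predicted-damaging variants are easier
to select. Fitting alternates per-gene 10-fold cross-validation for `λ1j`,
warm-started coordinate descent (compiled, covariance updates) and a
projected-gradient update of `w`, starting from the uniform prior
(`w = 0`, `δ = 0.5`).

The **driver score** of an allele is the number of genes with a nonzero
fitted coefficient. Significance comes from a permutation null: the sample
order of the whole expression matrix is shuffled (preserving gene–gene
correlation), the model is refitted with an identical configuration, and
empirical p-values are computed with add-one smoothing against the pooled
null scores.

The package also implements the surrounding analyses: Mann–Whitney
differential expression with BH adjustment, hypergeometric gene-set
enrichment from GMT files, a mutation-frequency baseline, ROC/confusion
evaluation, an integrative prognostic score `IPS_s = x_s' B y_s` with exact
1-D k-means consensus clustering (cophenetic selection of k) and log-rank
survival comparison, plus a synthetic-data generator with planted sparse
mutation→expression effects that makes the whole pipeline testable without
any external data.

## Worked example

```r
library(exdriver)

# a synthetic cohort: 200 samples, 200 genes, 50 recurrent alleles,
# 5 true drivers each regulating 30 genes
ds  <- simulate_dataset(simulation_config(seed = 1))
fis <- build_feature_table(ds$features)   # impute, orient, standardize
fit <- exdriver(ds$expression, ds$mutations, fis, seed = 1)
print(fit)
#> Expression-association driver mutation model
#>   samples: 200   genes: 200   alleles: 50
#>   penalty mode: oriented   outer iterations: 4 (converged)
#>   nonzero associations: 956 (9.56% of 10000)
#>   mean variance explained: 32.7%

null <- permutation_null(fit, n_perm = 100, seed = 1)
tab  <- driver_score_table(fit, null)
head(tab, 6)
#>          allele   gene protein_change score    p_value   q_value   call
#> 3  MUT003:K422H MUT003          K422H    49 0.00019996 0.0019996 driver
#> 2  MUT002:K136N MUT002          K136N    46 0.00019996 0.0019996 driver
#> 1  MUT001:R893D MUT001          R893D    45 0.00019996 0.0019996 driver
#> 4  MUT004:C611K MUT004          C611K    43 0.00019996 0.0019996 driver
#> 5  MUT005:A701H MUT005          A701H    42 0.00019996 0.0019996 driver
#> 15 MUT015:Q461C MUT015          Q461C    22 0.01639672 0.0819836 driver

roc_auc(driver_scores(fit), ds$true_driver)
#> [1] 1
```

The five planted drivers (`MUT001`–`MUT005`) occupy the top five ranks:
their scores count the genes whose expression each allele is associated
with (each truly regulates 30, plus a few incidental associations), the
p-values locate those scores in the pooled permutation null, and the
perfect AUC says the score separates drivers from passengers completely in
this cohort. Downstream, `prognostic_score(fit)` gives one scalar per
patient and `ips_survival()` stratifies the cohort and tests survival
separation (here the simulated hazards depend strongly on the score, so
consensus clustering favors a fine 5-way stratification and the log-rank
separation is extreme):

```r
sv <- ips_survival(prognostic_score(fit), ds$clinical, seed = 1)
sv$stratification$k        #> [1] 5
sv$logrank$p_value         #> [1] 1.153476e-47
```

A command-line front end wrapping the same functions ships under
`inst/cli/` (subcommands `simulate`, `fit`, `score`, `deg`, `enrich`,
`ips`, `survive`, `evaluate`).

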