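# translatome

Tools for identifying mRNAs whose translation depends on an RNA helicase
(or any perturbed initiation factor) from polysome-profiling RNA-seq, and
for characterising what distinguishes their 5′UTRs.

## The problem

Knocking down a translation-initiation helicase such as eIF4A1 shifts the
mRNAs that need it from polysomes (many ribosomes) into subpolysomal pools
(few or none). Polysome profiling + RNA-seq measures each transcript's
abundance in both fractions under control and knockdown conditions, with
transcript quantifiers reporting a posterior mean *y* and posterior SD *s*
of log expression per transcript and sample. The analytical question is a
difference of differences: does the knockdown-vs-control log-fold change
differ between the polysomal and subpolysomal fractions?

## The model

For each transcript, observations follow a measurement-error regression

    y_i ~ Normal(x_i' beta, s_i^2 + sigma^2)

with the quantifier's `s_i` treated as known and `sigma` a shared residual
SD. Two nested designs are compared:

* **M0**: intercept + condition + fraction (parallel log-fold changes);
* **M1**: M0 + an interaction column that is 1 exactly for
  (knockdown, polysomal) samples, whose coefficient `delta` is
  `(poly_KD − poly_ctrl) − (subpoly_KD − subpoly_ctrl)`.

Coefficients get zero-centred normal priors (vague on the intercept) and
`sigma` a half-normal prior; `beta` is integrated in closed form given
`sigma` and the `sigma` integral is evaluated by Simpson quadrature on a
log-spaced grid, giving a deterministic log marginal likelihood for each
model. The Bayes factor `BF = exp(logML1 − logML0)` is converted to a
posterior probability `P1 = p·BF / (p·BF + 1 − p)` with prior complex-model
probability `p = 0.1`, and transcripts with `P1 ≥ 0.2` (a deliberately
liberal threshold) are classified **dependent** (`delta < 0`, lost from
polysomes) or **independent** (`delta > 0`). `P1 × sign(−delta)` provides a
ranking metric for preranked gene-set enrichment.

Companion modules compute 5′UTR features — G/C content, minimum folding
energy, length, upstream AUGs, G-quadruplex potential
(`GG N1–7 GG N1–7 GG N1–7 GG` or the GGG-tract analogue), paired GGAGG
elements (`GGAGG N4–10 GGAGG`) and arbitrary IUPAC motifs — and compare
classes by two-sample Kolmogorov–Smirnov and Fisher's exact tests. A
synthetic-data generator with known ground truth makes the whole pipeline
testable offline.

## Worked example

```r
library(translatome)

sim <- simulate_expression(sim_config(n_transcripts = 200,
                                      frac_interaction = 0.2,
                                      delta_scale = 2, sigma_bio = 0.1,
                                      seed = 42))
res <- run_model_selection(sim$expression, sim$design)
head(res[, c("transcript_id", "log_bf", "post_prob", "delta_hat", "class")], 5)
#>   transcript_id log_bf post_prob delta_hat        class
#> 1       TX00001   7.37    0.9943    -1.853    dependent
#> 2       TX00002  -1.34    0.0283    -0.149 unclassified
#> 3       TX00003  -1.04    0.0379     0.184 unclassified
#> 4       TX00004  -1.45    0.0253     0.107 unclassified
#> 5       TX00005  13.34    1.0000     2.090  independent
table(res$class)
#>    dependent  independent unclassified
#>           21           23          156
```

TX00001 has strong evidence for the interaction model (posterior
probability 0.994) with a negative shift of −1.85 natural-log units — it
leaves polysomes on knockdown, i.e. it is helicase-dependent. The 40
planted interaction transcripts are recovered as 21 dependent + 23
independent (two borderline nulls cross the liberal 0.2 threshold).

Published motif frequencies can be turned back into testable tables:

```r
tab <- reconstruct_table(62, 156, 35, 49)  # GGC-repeat motif, % by class
tab
#>        with without
#> group1   97      59
#> group2   17      32
fisher_exact(tab)
#> [1] 0.000928
```

and UTR sequences into feature vectors:

```r
utr_features(c(NM_0001 = "GGAGGCGGCGGCGGCGAAAAGGAGGATG"))
#>    utr_id    gc length dG n_uaug has_ggc_motif has_gagg_motif
#> 1 NM_0001 0.714     28 -5      1          TRUE           TRUE
#>   has_urich_motif has_g4 has_paired_ggagg
#> 1           FALSE   TRUE            FALSE
```

`run_pipeline()` chains everything (simulate or load → select → classify →
collapse to genes → UTR features → enrichment report) and writes TSV/FASTA/
`.rnk`/JSON artifacts plus a manifest; `inst/cli/translatome.R` exposes the
same steps as shell subcommands (`simulate`, `select`, `features`,
`enrich`, `validate`, `run`).

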