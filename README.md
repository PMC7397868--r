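# ricactivity

Estimation of in vivo poly(A)+ RNA-binding activities from RNA
interactome capture (RIC) proteomics, with whole-cell-extract (WCE)
normalization.

## The problem

RIC couples in vivo UV crosslinking with oligo(dT) capture of
poly(A)+ RNA–protein adducts and quantitative mass spectrometry. The
raw pull-down signal of a protein confounds two things: how much of
the protein there is, and how much of it is actually bound to RNA.
Normalizing each protein's pull-down intensity to its WCE intensity
separates the two: the **RIC/WCE ratio** (a log2 fold change) estimates
the fraction of the cellular protein pool engaged with poly(A)+ RNA,
up to a protein-specific UV-crosslinkability factor. Ratios of this
kind let you rank RNA-binding proteins by binding activity, locate the
RNA-contacting subunits inside large complexes, and — by comparing a
mutant against wild type — detect RNP remodeling as coherent **shift
coefficients** of whole complexes.

This package implements that analysis workflow for protein-level
label-free MS intensity tables:

* **Preprocessing** — left-censored missing values imputed at a fixed
  background (18 log2 units), per-sample median centering, batch
  merging (`impute_background`, `median_normalize`, `merge_batches`).
* **Enrichment statistics** — paired RIC−WCE (or unpaired CL vs noCL)
  log2 fold changes, an empirical-Bayes moderated t-test, BH and
  Bonferroni adjustment, and volcano-plot population flags
  (`enrichment_table`). The moderated test shrinks each protein's
  variance toward a scaled inverse-chi-square prior
  (d0, s0²) fitted by moment matching on log variances:
  s̃² = (d0·s0² + d·s²)/(d0 + d), t = mean/(s̃/√n) on d0 + d df.
* **Comparative RIC** — per-genotype ratio moments, second-order
  Taylor uncertainty propagation, global rescaling over crosslinked
  proteins, exact-moment pseudo-replicates, and moderated testing of
  mutant−WT shifts (`compare_ric`, `taylor_propagate`,
  `empirical_mvn`, `rescale_shifts`).
* **Domain classification** — per-Pfam-domain classes of nonclassical
  RNA-binding domains (`classical_like` / `substoichiometric` /
  `adaptive` / `unclassified`), high/low-activity protein sets
  (RIC/WCE ratio >4 or <0.25 at p < 0.01), and descriptive GO-term
  fractions (`classify_domains`, `select_sets`, `term_fractions`).
* **Binding assays** — fluorescence anisotropy
  r = (I∥ − G·I⊥)/(I∥ + 2G·I⊥) and four-parameter logistic fits
  y = ymin + (ymax − ymin)/(1 + (x/Kd)^(−n)) for Kd estimation
  (`anisotropy`, `fit_4pl`, `predict_4pl`).
* **Synthetic data** — a generator with known ground truth (abundance,
  bound fraction φ, crosslink efficiency κ, complex membership,
  mutant effects, left-censoring, complex-shared noise) so every stage
  is testable without deposited data (`generate_experiment`,
  `generate_mutant_pair`, `generate_titration`,
  `generate_annotation_fixture`).

## Worked example

```r
library(ricactivity)

sim <- generate_experiment(sim_config(n_proteins = 1000), seed = 42)
sim$table
#> intensity_table: 1000 proteins x 15 samples
#> samples per fraction/batch:
#>        B1 B2
#>   noCL  3  0
#>   RIC   3  3
#>   WCE   3  3
#> 4026 missing cells, 0 imputed

tab <- median_normalize(impute_background(sim$table))
enr <- enrichment_table(tab, mode = "wce")
attr(enr, "prior")
#> variance prior: d0 = 8.866736, s0^2 = 0.3364883 (fit on 996 variances)

solid <- enr[enr$population == "both", ]
head(solid[order(-solid$mean_log2fc), c("protein_id", "mean_log2fc",
                                        "ratio_sd", "t_mod", "p", "q_fdr")], 5)
#>     protein_id mean_log2fc  ratio_sd    t_mod            p        q_fdr
#> 914     P00917    6.292596 0.7292379 24.16335 9.879930e-13 3.280137e-11
#> 905     P00908    6.081049 1.1325109 18.09502 4.848140e-11 4.311382e-10
#> 353     P00354    5.870123 0.4082345 27.40681 1.781718e-13 1.998910e-11
#> 947     P00950    5.754175 0.8400160 20.56833 8.711027e-12 1.221998e-10
#> 961     P00964    5.700952 0.3531803 27.37934 1.806244e-13 1.998910e-11

length(select_sets(enr)$enriched)   # >4-fold enrichment at p < 0.01
#> [1] 396

curve <- generate_titration(list(ymin = 0.05, ymax = 0.25, kd = 47, n = 1),
                            noise_sd = 0.004, seed = 1)
fit_4pl(curve$concentration_nM, curve$anisotropy)
#> 4PL fit: Kd = 45.5 nM (SE 3.03), Hill n = 1.02, ymin = 0.0516,
#> ymax = 0.248, RSS = 0.000118
```

Reading the output: `mean_log2fc` is the RIC/WCE ratio (log2; +6 means
the protein is captured ~64-fold above its abundance expectation),
`ratio_sd` its replicate SD, `t_mod`/`p`/`q_fdr` the moderated test
against zero. The `population` flag records where a protein was
actually observed before imputation — ratios for `ric_only`/`wce_only`
proteins rest on imputed background values and should be read with
care. The 4PL fit recovers the planted Kd of 47 nM from a noisy
13-point titration.

A command-line front end over the same functions is installed at
`exec/ric-activity` with subcommands
`enrich | compare | classify | simulate | fitbind`.

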