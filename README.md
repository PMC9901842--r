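# triomix

Case–control multi-omics analysis for small clinical cohorts: label-free
proteome quantification, metabolome differential analysis, a
stratification-controlled association scan, and integration of the three
molecular layers into a pathway "connective" graph. The package grew out
of serum-based schizophrenia biomarker work, but every stage is generic:
it takes feature-by-sample matrices (and a VCF for genotypes) and a
case/control labelling.

## What it computes

**Proteome.** Proteins identified by more than one unique peptide
(`ni(p) > 1`) are quantified semi-quantitatively by the normalized
spectral abundance factor, per sample:

    NSAF_i = (SpC_i / L_i) / Σ_j (SpC_j / L_j)

where `SpC` is the spectral count and `L` the protein length. Group
differences are tested with a two-sided Wilcoxon rank-sum test and
Benjamini–Hochberg FDR control; a protein is called significant when its
detection frequency reaches 0.85 in at least one group, its linear fold
change lies outside (0.5, 2), and the adjusted p-value clears the chosen
cut-off (0.05 for discovery, 0.01 for a validated panel). Absolute
concentrations come from a 48-protein spike-in standard spanning five
orders of magnitude: ordinary least squares of mean `log10(LFQ)` on
`log10(concentration)`, inverted per sample, with a validation rule that
additionally requires the measured concentration to be significantly
nonzero (mean exceeding twice its standard error) in at least one group.

**Metabolome.** Drug-like / non-endogenous features are removed against
an exclusion list, features must be detected more than once in each
group, and the same Wilcoxon/BH machinery is applied with the
`|log2FC| > 1`, adjusted `p < 0.05` gates. A label-permutation test of
the group-mean difference of log intensities guards against inflated
false positives.

**Multivariate.** PCA and a from-first-principles sparse PLS-DA
(soft-thresholded PLS2 with exact per-component feature counts, mixOmics
conventions) with 0.95 confidence ellipses from the chi-square quantile.

**GWAS stage.** Variant QC (≤2% missingness, MAF ≥ 5%, minor-allele
counts ≥ 10 in cases and in controls), genotype PCA with
`sqrt(2p(1−p))` standardization, exclusion of cases beyond 3 control
SDs on PC1/PC2, per-variant logistic regression of case status on allele
dosage plus 5 PC covariates (Wald test; Firth-penalized fallback under
separation), and nomination of the top-100 candidates with a soft
`p < 1e-5` flag.

**Integration.** Significant proteins (gene symbols), metabolites (KEGG
compound IDs) and nominated SNPs (via their mapped gene) are joined to
pathway membership sets (GMT). Each element shared by `k ≥ 2` pathways
contributes one layer-coloured edge per pathway pair; an element unique
to one pathway contributes a self-loop. Node centrality is the incident
edge count, hubs are counted above thresholds 10 and 20, and degree
assortativity is Newman's r over non-loop edges.

A synthetic tri-omics generator (planted effect sizes, structural
left-censoring, Balding–Nichols population structure, medication-like
contaminants) makes the whole pipeline testable end to end without any
external data.

## Worked example

```r
library(triomix)

cfg <- synthetic_config(seed = 1)          # 49 cases vs 50 controls
proteome <- generate_proteome(cfg)
keep <- proteome$features$unique_peptides > 1
nsaf <- compute_nsaf(proteome$spc[keep, ], proteome$features$length[keep])
res <- differential_test(nsaf, proteome$groups, alpha = 0.01)
head(res[order(res$p_adj), c("feature_id", "log2fc", "p_adj", "significant")], 5)
#>     feature_id    log2fc        p_adj significant
#> 199      P0218 -2.764166 5.190691e-17        TRUE
#> 14       P0015 -2.843873 5.646735e-16        TRUE
#> 60       P0064  2.582217 5.646735e-16        TRUE
#> 86       P0094  2.599221 5.646735e-16        TRUE
#> 177      P0195  2.522921 5.646735e-16        TRUE
sum(res$significant)
#> [1] 20
```

The generator planted 20 regulated proteins at |log2FC| = 2.5; the
differential test recovers them (and nothing else) at FDR 0.01.

Integration on the packaged pathway fixture:

```r
gmt <- read_gmt(system.file("extdata", "table3.gmt", package = "triomix"))
els <- read.delim(system.file("extdata", "table3_elements.tsv", package = "triomix"))
rep <- intersection_report(map_elements(els, gmt))
rep$report[rep$report$n_layers == 3, c("pathway", "proteome", "metabolome")]
#>     pathway proteome           metabolome
#> 4  hsa04080      PLG C00547;C00780;C03758
#> 16 hsa04977     APOB               C05443
summarize_graph(build_graph(map_elements(els, gmt)))[c("size", "n_nodes")]
#> $size
#> [1] 60
#> $n_nodes
#> [1] 17
```

Exactly two pathways — neuroactive ligand–receptor interaction
(hsa04080) and vitamin digestion and absorption (hsa04977) — are reached
by all three omics layers.

The full pipeline (simulate → proteome → metabolome → projection → GWAS
→ integration) runs from one configuration object:

```r
run <- run_pipeline(pipeline_config(synthetic_config(seed = 1)), "run1")
```

and writes stage TSVs, a GraphML connective graph and a provenance
manifest into the run directory; identical config and seed give
byte-identical outputs.

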