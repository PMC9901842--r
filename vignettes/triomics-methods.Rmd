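---
title: "Methods: tri-omics quantification, association and pathway integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-omics quantification, association and pathway integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomix)
```

# Scope and design

`triomix` implements a small-cohort case–control multi-omics workflow:
semi-quantitative and absolute protein quantification, metabolite
cleaning and differential analysis, supervised projection, a
PCA-stratified association scan, and integration of the three layers
into a pathway multigraph. Raw mass-spectrometry processing (peak
picking, peptide identification), genotype imputation and live
pathway-database queries are deliberately out of scope: the package
starts from protein/metabolite feature matrices, a GT-only VCF and
GMT-style pathway membership.

This vignette records the models, the tunable parameters and the
numerical decisions, so a reader can judge what the defaults assume and
what passing tests do — and do not — demonstrate.

# Proteome quantification

## NSAF and filtering

For sample $s$, protein $i$ of length $L_i$ (residues) with spectral
count $\mathrm{SpC}_{is}$:

$$\mathrm{NSAF}_{is} = \frac{\mathrm{SpC}_{is}/L_i}{\sum_j \mathrm{SpC}_{js}/L_j}$$

so each sample column sums to one and a zero count stays a zero NSAF.
Samples with no counts at all are an error (a failed injection should be
confronted, not silently dropped). Upstream of quantification, only
proteins with more than one unique peptide are retained (`unicity_filter`);
the boundary is strict: exactly one unique peptide is dropped, two are
kept.

## Group summaries, imputation, fold change

Group means of zero (a protein never detected in one group) are replaced
by half the smallest nonzero value of that feature anywhere in the data
before the fold change is formed. Half-minimum is the standard
left-censoring surrogate; it is deliberately feature-specific, so an
abundant protein missing from one group is imputed at an abundant
protein's detection floor, not a global one. Features that are zero
everywhere cannot be rescued and are removed with a warning. The fold
change is `log2(case/control)` of the group summaries; the summary is the
mean by default with a median option — the validated concentration panel
this package mirrors prints means, and the mean is what reproduces its
fold-change arithmetic.

## Differential testing

Per feature: a two-sided Wilcoxon rank-sum test (exact enumeration for
small tie-free groups, normal approximation with tie correction
otherwise — the behaviour of `stats::wilcox.test`, which the test suite
checks against a full-enumeration oracle), then Benjamini–Hochberg
adjustment across **all** tested features as one family (no strata are
defined, so none are invented). Significance requires all three gates:

* detection frequency ≥ 0.85 in at least one group,
* linear fold change strictly outside (0.5, 2) (equivalently
  |log2FC| > 1; the boundary itself does not pass),
* adjusted p below `alpha` — 0.05 for a discovery pass, 0.01 for the
  validated panel.

## Spike-in calibration and the validation rule

The calibration model is ordinary least squares of replicate-averaged
$\log_{10}(\mathrm{LFQ})$ on $\log_{10}(\text{known concentration})$
over the 48-protein standard (replicates averaged in log space; standard
proteins never detected are excluded; fewer than three usable points is
an error). Concentration estimates invert the line; zero signal is a
non-detect, and estimates outside the standard's concentration range are
flagged extrapolated rather than silently trusted.

A panel protein is *validated* when its adjusted p is below 0.01 **and**
its measured concentration is significantly nonzero in at least one
group. "Significantly nonzero" is implemented, by default, as the group
mean exceeding twice its standard error ($2\,\mathrm{SD}/\sqrt{n}$).
The literal alternative — mean exceeding twice the per-sample SD — is
available via `se_of_mean = FALSE`, but it is a far stricter gate that
rejects well-measured analytes whose biological between-subject spread
is wide relative to the mean (a low-abundance protein measured precisely
in every subject but varying 3-fold between subjects would fail it
despite being unambiguously quantified). The standard-error reading is
the one consistent with published validated panels of this design; the
scope of the rule (case group, control group, or either) is exposed as a
flag with "either" as default.

# Metabolome analysis

Cleaning order: contaminant exclusion first (drug-like and
non-endogenous compounds matched by feature, KEGG or HMDB identifier
against an exclusion list, with an audit trail), then the frequency
rule — detected on more than one occasion in *each* group, read as at
least two nonzero observations per group and configurable — then
differential testing with the proteome machinery at metabolome defaults
(adjusted p < 0.05, |log2FC| > 1).

The permutation check uses the difference of group means of log
intensity (zeros imputed at half the feature minimum) as its statistic —
no statistic is canonical here, and the mean difference on the log scale
matches the direction of the rank test used for inference. The
two-sided p is $(1 + \#\{|T^\pi| \ge |T|\})/(1 + n_\pi)$; the default
$n_\pi = 499$ resolves $\alpha = 0.05$ with granularity 0.002, and the
implementation refuses an $n_\pi$ too coarse for the requested level.

# Projections

PCA is the singular value decomposition of the column-centred (optionally
unit-scaled, constant features dropped from scaling) matrix; explained
variance fractions are squared singular values over their sum.

Sparse PLS-DA is written from first principles: the class factor becomes
a one-hot indicator matrix whose columns are centred and scaled (class
sizes thereby weight the fit), and per component the feature weight
vector of the cross-covariance matrix $M = X^\top Y$ is iterated with
soft-thresholding calibrated so that **exactly** `keepX` features keep a
nonzero loading, followed by regression deflation of both blocks on the
component scores. With `keepX` equal to the feature count the procedure
is dense PLS-DA; the test suite verifies equality against an
independently written dense NIPALS oracle and against `mixOmics` on
random instances. Defaults: 2 components, `keepX = 50` per component
(no keepX is canonical for this design; 50 is a conventional panel size
for a few-hundred-feature matrix and is fully configurable), unit-variance
scaling. Explained variance for (s)PLS-DA is reported as the fraction of
X-variance captured by each component — the convention under which
projection plots annotate components with percentages.

Confidence ellipses use the per-group sample mean and covariance scaled
by $\chi^2_{0.95}(2)$; a singular covariance yields a degenerate ellipse
that is flagged, not an error.

# Association stage

QC removes variants failing, in order: missingness > 2%, minor-allele
frequency below 5% (the boundary is kept — "higher than 5%" is read
inclusively at the printed precision, and the semantics are
configurable), and minor-allele counts below 10 in controls
($C_U$) or cases ($C_A$); each removed variant is attributed to the
first rule it fails so the QC report sums exactly to the number removed.
$C_U$/$C_A$ are interpreted as minor-allele counts per phenotype group.

Genotype PCA mean-imputes missing calls per variant, centres at $2p$ and
standardizes by $\sqrt{2p(1-p)}$ (the smartpca convention), dropping
monomorphic variants. Cases beyond 3 control SDs on either of the first
two PCs are excluded; controls never are. The scan then fits, per
variant, a maximum-likelihood logistic regression of case status on
allele dosage plus the first five PCs (complete cases per variant) and
reports the Wald p of the dosage term — the plink convention. Separated
or non-convergent fits fall back to a Firth-style Jeffreys-penalized fit
and are flagged; degenerate variants (no dosage variance after
missingness) are flagged and excluded from nomination. Candidates are
the top-100 by ascending p with ties broken by (chromosome, position);
a soft $p < 10^{-5}$ flag marks near-threshold hits, since in a cohort
of this size genome-wide significance is not expected — nomination, not
declaration, is the stage's output.

# Integration

Element mapping joins proteins (gene symbol) and metabolites (KEGG
compound ID) directly, and SNPs through their mapped gene, onto GMT
pathway sets; unmapped elements are kept with an empty set and logged.
Graph construction: an element in $k \ge 2$ pathways contributes
$\binom{k}{2}$ labelled multiedges (one per unordered pathway pair,
coloured by omics layer); an element in exactly one pathway contributes
a self-loop — a visible marker of pathway-specific evidence rather than
a discarded row. The edge count therefore obeys
$\sum_e \binom{k_e}{2} + [k_e = 1]$, which is property-tested.

Summaries: centrality is the count of incident non-loop edge endpoints
(multiplicity counted); whether a self-loop adds 0 or 2 is configurable
because "edges attached to the node" is genuinely ambiguous for loops —
the default excludes loops so that centrality ranks cross-pathway
connectivity. Hub counts are taken strictly above thresholds 10 and 20.
Degree assortativity is Newman's r, the Pearson correlation of endpoint
centralities over non-loop edges; it is reported as undefined (with a
flag) when all endpoint degrees are equal. "Graph size" is the edge
count, with the node count reported alongside. Term refinement collapses
terms with pairwise Jaccard similarity strictly above 0.7 by transitive
closure (connected components), representing each cluster by its largest
set with a lexicographic tie-break — greedy single-linkage is the
simplest deterministic reading of a bare similarity threshold.

The packaged fixture (`inst/extdata/table3.gmt`,
`table3_elements.tsv`) transcribes a published three-layer
pathway-assignment table; one internally inconsistent row (a receptor
gene printed in the protein column of the estrogen-signalling pathway
while its SNP is annotated elsewhere with a different gene) is encoded
as a gwas-layer pairing, the only reading under which the table's
printed conclusion — exactly two pathways reached by all three layers —
holds. The stand-in concentration rows for the four proteins that failed
panel validation are synthetic (the originals are not printed) and are
shipped as `table1_failures_synthetic.tsv`.

# The synthetic-data generator

The generator exists so every downstream stage can be tested against a
known truth. Its defaults are the study conditions the pipeline targets:
49 cases vs 50 controls, 250 detected proteins with 20 planted effects
of |log2FC| = 2.5 (80% up, 20% down), 1,200 metabolite features of which
226 are medication-like contaminants, 12 planted metabolite effects at
the magnitudes of a published serum panel (−3.26 … +3.61), and 500
variants with 5 causal loci at odds ratio 3 over two subpopulations at
Balding–Nichols divergence 0.1.

Model choices:

* **Counts and intensities share one latent truth.** Per protein and
  sample a log-normal latent abundance (log-scale SD 0.5 within groups,
  1.2 between proteins) drives both a Poisson spectral count and an LFQ
  intensity (latent × protein-specific response factor). This gives
  integer counts for NSAF and a continuous channel for calibration that
  are consistent with each other.
* **Zeros are structural, not MCAR.** Entries whose latent abundance
  falls below the `missing_rate` quantile of the latent matrix are
  censored in both channels. Left-censoring is an assumption — the
  true missingness mechanism of label-free proteomics is not printed
  anywhere — but it is the assumption under which the half-minimum
  imputation downstream is actually exercised; the count scale is set
  high enough that Poisson zeros above the detection threshold are
  rare, so the realized zero fraction tracks `missing_rate` to within
  1%.
* **Contaminants are presence/absence artefacts.** Medication-derived
  features are detected in 85% of case samples and 5% of controls,
  which is what makes exclusion-by-identity (not by statistics) the
  correct first step.
* **Genotypes.** Ancestral allele frequencies are uniform on
  (0.1, 0.9); subpopulation frequencies are Beta-diverged with the
  Fst-like parameter; case status follows a centred logistic model on
  the causal dosages and cohorts are sampled retrospectively from a 6×
  pool. Linkage disequilibrium is not simulated.
* **Seeding.** One master seed fans out to fixed per-generator
  substreams, so any layer can be regenerated independently and every
  generator is byte-reproducible.

What passing tests show — and what they do not: the suite demonstrates
that the statistical machinery is correct (against enumeration,
closed-form and independent-implementation oracles) and that under the
generator's assumptions the pipeline recovers planted truths at the
expected rates. It does not show that real spectral counts are Poisson
around a log-normal, that real missingness is pure left-censoring, or
that real genotype panels are LD-free; conclusions about power on real
data should be read with those simplifications in mind. In particular,
the association stage at the default cohort size (99 subjects) is
underpowered by design — it nominates candidates rather than declaring
hits, and planted causal variants can be lost at QC when call
missingness sits near the 2% rule, mirroring how small-cohort scans
behave in practice.

# Problem sizes and runtime

Simulation-backed checks run at sizes chosen to make Monte-Carlo error
small relative to the asserted margins while keeping the default suite
around ten seconds: calibration recovery over 100 simulated standards,
logistic type-I calibration over 100 permuted-phenotype seeds
(60 samples × 40 variants each), permutation-p uniformity over 100 seeds
at 499 permutations, sPLS-DA/dense equivalence over 50 random instances,
and candidate-recovery power at 500 samples × 500 variants over 3 seeds.
The acceptance script's end-to-end run uses the full default
configuration and completes in a few seconds.

# Known limitations

* Peptide-to-protein inference, match-between-runs and isoform handling
  are upstream of this package.
* The permutation statistic and the exact reading of several published
  thresholds (the frequency rule's "more than one occasion", the 2×SD
  validation rule, the MAF boundary) are ambiguous in their source;
  each interpretation is documented above and configurable.
* Assortativity and hub counts depend on the self-loop convention;
  production-scale graph figures from other toolchains may count loops
  differently.
* The generator does not emulate chromatographic drift, mass-error
  structure, batch effects or LD; effect-size recovery rates on
  synthetic data are upper bounds for real data.
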