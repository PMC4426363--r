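# imprintr

Detection of parent-of-origin (PO) expression bias from allele-specific
RNA-seq in reciprocal F1-hybrid designs.

## The problem

Genomic imprinting makes some genes express preferentially from one
parental allele. In an F1 hybrid between two inbred mouse strains
(e.g. CAST/EiJ × C57BL/6J), reads overlapping strain-distinguishing SNPs
can be assigned to the parental allele that produced them, so allelic
expression is directly measurable. A single cross cannot distinguish a
*parent-of-origin* effect from a *strain* effect (the Cast allele might
simply be a stronger promoter). The reciprocal-cross design resolves
this: in CB lines the Cast allele is maternal, in BC lines it is
paternal, so a maternally imprinted gene favors Cast in CB but B6 in BC,
while a strain-biased gene favors the same strain in both.

`imprintr` implements this analysis end to end for anyone working with
allelic count data from reciprocal hybrid crosses:

* **pseudogenome construction** — substitute strain SNPs into the
  reference to build the in-silico alternate-strain genome
  (`build_pseudogenome()`);
* **read allele assignment** — label each uniquely mapping read `B6`,
  `CAST`, `NO_SNP` or `CONFLICT` from the SNP bases it covers
  (`assign_read_allele()`);
* **annotation** — one longest exemplar per gene
  (`select_longest_exemplar()`) plus de novo transcription units from
  strand-matched read clustering with a ±5 kb rule
  (`find_novel_units()`);
* **counting & normalisation** — gene-body allelic counts by midpoint
  containment (`count_allelic()`), CPM, the >1-CPM-in-every-line
  eligibility filter, and RPKM (`cpm()`, `filter_expressed()`,
  `rpkm()`);
* **testing & classification** — per-gene negative-binomial GLM
  likelihood-ratio tests of Cast-vs-B6 imbalance in each cross group,
  Benjamini–Hochberg adjustment within group, and the dual-FDR
  reciprocal classification (`imprint_test()`);
* **synthetic data** — a truth-labelled generator of the six-line
  reciprocal experiment, down to read level (`simulation_config()`,
  `make_truth()`, `simulate_allele_counts()`, `simulate_reads()`).

## The model

For gene *g* in one cross group, with allelic counts
*y<sub>sa</sub>* (sample *s*, allele *a* ∈ {B6, Cast}) and
sample-by-allele column library sizes *N<sub>sa</sub>*:

*y<sub>sa</sub>* ~ NB(*μ<sub>sa</sub>*, *φ<sub>g</sub>*),  
log *μ<sub>sa</sub>* = log *N<sub>sa</sub>* + *β₀* + *β₁* · 1[*a* = Cast],

with variance *μ* + *φμ²*. The null *β₁* = 0 is rejected by a 1-df
likelihood-ratio test; *φ<sub>g</sub>* is estimated by a Cox–Reid
adjusted profile likelihood (common value plus per-gene shrinkage).
P-values are BH-adjusted within each cross group. A gene with FDR ≤ 0.05
in **both** groups is classified from the two fold-change directions:
maternal-allele-up in both crosses → `MATERNAL`, paternal-up in both →
`PATERNAL`, same-strain-up in both → `STRAIN_B6`/`STRAIN_CAST`.

## Worked example

```r
library(imprintr)

cfg    <- simulation_config(n_genes = 2000, theta_imprinted = 0.9, seed = 11)
truth  <- make_truth(cfg)             # 5% maternal, 5% paternal, 2% strain
design <- cross_design(3, 3)          # CB.1-3 (Cast mother), BC.1-3 (B6 mother)
counts <- simulate_allele_counts(truth, design, cfg)

fit <- imprint_test(counts, design)   # dispersion estimated from the data
summary(fit)
```

```
eligible genes tested: 2000
PO-biased (FDR <= 0.05 in both crosses): 192 (95 maternal, 97 paternal)
strain-biased: 17 B6, 27 Cast
common dispersion: CB 0.1059, BC 0.1005
top biased genes:
 gene_id       fdr_cb       fdr_bc bias_class
  G01317 5.427441e-17 1.077271e-16   MATERNAL
  G01636 2.047195e-16 1.531051e-19  STRAIN_B6
  ...
```

The simulation planted 95 maternal, 97 paternal and 44 strain-biased
genes (seed 11), and the fit recovers exactly those tallies: every
imprinted gene is called with the correct parental direction, the
strain-biased genes are kept out of the PO classes by the reciprocal
rule, and the generating dispersion (φ = 0.1) is recovered by the
common Cox–Reid estimate in both groups. `plot(fit)` shows the
percent-maternal scatter across the two cross directions; `coef(fit)`
returns the per-group Cast-vs-B6 log-fold-changes.

The package also ships transcriptions of the published per-gene allelic
result tables for six mouse trophoblast stem cell lines
(`load_reference_table("T2")` — 32 known imprinted genes,
`"T3"` — 17 candidate imprinted genes, `"T4"` — miRNA host genes), with
every printed percent-maternal cell reproducible from its raw count pair
(`verify_fixture_percentages()`).

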