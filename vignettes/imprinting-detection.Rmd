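---
title: "Detecting parent-of-origin expression bias in reciprocal F1-hybrid RNA-seq"
author: "imprintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parent-of-origin expression bias in reciprocal F1-hybrid RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
```

## The design and the confounder it removes

An F1 hybrid between two inbred strains carries one chromosome set from
each parent, distinguishable wherever the strains differ by a SNP. A read
that uniquely maps over such informative SNPs can be assigned to the
parental allele that produced it, which turns bulk RNA-seq into an
allele-resolved expression assay. The catch is that a single cross
confounds two very different phenomena: a gene may favor one allele
because of *which parent* contributed it (genomic imprinting) or because
of *which strain* it came from (cis-regulatory strain differences). The
reciprocal-cross design separates them. With CB lines (Cast mother × B6
father) and BC lines (B6 mother × Cast father), a maternally imprinted
gene favors the Cast allele in CB but the B6 allele in BC; a strain
effect favors the same strain in both. `imprintr` implements the whole
path from reads to that classification, plus a generator of synthetic
experiments with known truth.

## Allele assignment and counting

Reads arrive as intervals with the bases they show at informative SNP
positions (the simulator writes this dialect; for real data the
equivalent information comes out of an allele-aware alignment). A read is
labelled `B6` only if *every* covered SNP shows the B6 allele, `CAST`
only if every one shows the Cast allele. Mixed or unmatched bases give
`CONFLICT` — such a read supports neither haplotype cleanly (the usual
cause is a sequencing error at the SNP) and is discarded, which is the
deliberate analogue of a read failing to align uniquely to exactly one of
the two strain genomes. Reads covering no SNP are `NO_SNP` and
uninformative. Assignment is strand-blind because base observations are
reference-oriented.

Counting is gene-body based: a labelled read increments a gene when the
read's midpoint falls inside the gene's `[start, end]` span — introns
included — and the strands match (the library is stranded). Midpoint
containment was chosen over overlap counting so a read straddling a gene
boundary is attributed to exactly one side, making counts additive and
order-invariant. Known genes are represented by their longest exemplar
transcript (ties: smaller start, then lexicographic id), which fixes one
counting interval per gene.

## Novel transcription units

Transcription outside annotated genes is recovered by clustering:
reads that overlap no same-strand known gene body extended by 5 kb per
side are single-linkage merged per chromosome and strand whenever their
intervals lie within 5 kb of each other (inter-interval gap, boundary
inclusive: a 5,000-nt gap merges, 5,001 splits). Each cluster becomes a
unit spanning its reads. Two readings of "within ±5 kb" were possible —
nearest-end distance or midpoint distance; we use the nearest-end gap as
the simplest one, and both radii are arguments. Antisense reads inside a
known gene survive the filter (they fail the strand match), so antisense
units over annotated genes are discoverable. The default minimum support
is a single read — the reference tables report units down to a handful
of reads — but `min_reads` exists because real discovery needs noise
suppression.

## The statistical model

Within one cross group each gene contributes six observations (three
lines × two alleles). We model counts as negative binomial with
variance μ + φμ² and fit the log-linear model

    log mu = log N + b0 + b1 * [allele = Cast]

where N is the *column* library size — the total of that sample-by-allele
column over all genes. Offsetting by allele-column totals makes the test
a comparison of allele compositions rather than raw depths; it assumes,
as any composition-normalised analysis does, that the columns are
dominated by unbiased genes. The `b1 = 0` null is tested by a 1-df
likelihood-ratio test (Fisher scoring with per-gene step-halving,
convergence at a relative log-likelihood change below 1e-10, 100
iteration cap; non-converged genes are reported untested). At φ = 0 the
model collapses to Poisson, which gives a closed-form check:
b6 = (10,10,10) vs cast = (20,20,20) with equal offsets must yield
2·[30·ln(10/15) + 60·ln(20/15)] ≈ 10.194.

Genes enter testing only if their summed allelic CPM exceeds 1 in every
line (strict inequality, per the eligibility rule the reference analysis
used); per-line eligibility sums the two allele CPMs, each normalised by
its own column. All-zero genes are `NOT_TESTED`; genes silent on one
allele remain testable because the offset model tolerates a boundary fit
(the fold-change estimate diverges but the likelihood, and hence the
LRT, converges).

### Dispersion

The dispersion φ is estimated per cross group on a log-spaced grid
(10⁻⁴ to 10, 41 points) by the Cox–Reid adjusted profile likelihood
APL(φ) = ℓ(β̂; φ) − ½ log det(XᵀWX), which corrects the profile
likelihood for estimating the two mean parameters. The common value
maximizes the mean APL over genes; per-gene ("shrunken") values maximize
APL_g + (n₀/n)·C(φ), where C is the common curve and n₀ = 10
pseudo-observations against the gene's n = 6 — with so few replicates
per-gene likelihoods are shallow, and this weighting pulls unstable
estimates toward the common value while letting strongly informative
genes deviate. The scheme is validated by recovery (φ = 0 data pins the
estimate at the grid floor; φ = 0.2 truth is recovered within
[0.15, 0.25] at 2,000 genes) and by type-I calibration: with the true φ
supplied, the LRT rejects 5.0% of 10,000 null genes at p < 0.05 and the
p-value distribution is KS-uniform. Exact reproduction of any particular
production GLM framework's dispersion shrinkage is a non-goal; agreement
of the LRT itself with an independent NB GLM implementation at fixed φ
is asserted in the test suite.

The default design has no line-blocking term: the question is a group
comparison of allele columns, and with three replicates a pairing factor
costs more degrees of freedom than it buys. (The allele columns of one
line share library conditions, so residual line effects inflate φ
slightly rather than bias b1.)

### Classification

P-values are BH-adjusted *within* each cross group (the two tests are
separate families; pooling would let one strong group buy discoveries in
the other). A gene is called only when FDR ≤ 0.05 in both groups — the
dual-FDR rule — and then classified from the two directions: Cast-up in
CB with B6-up in BC is `MATERNAL` (the maternal strain differs between
crosses), the mirror is `PATERNAL`, same-strain-up in both is
`STRAIN_CAST`/`STRAIN_B6`. The rule is structurally immune to strain
effects masquerading as imprinting, and the package asserts the
corresponding symmetry: relabeling strains and crosses simultaneously
leaves PO calls fixed and swaps the strain classes. Alpha defaults to
0.05 (inclusive) and is an argument.

## What the simulator emulates — and what it does not

`simulation_config()` defaults describe the reference experiment at desk
scale: 2,000 genes; 3 + 3 reciprocal lines; 5% maternal and 5% paternal
genes with bias strength drawn Beta(57, 3) (mean 0.95, matching the
strong biases known imprinted genes show; the recovery analyses in the
test suite fix θ = 0.9, a milder and therefore more demanding setting);
1% + 1% strain-biased genes at θ = 0.9; NB dispersion φ = 0.1, a typical
between-replicate value for cell-line RNA-seq; per-gene abundance
log-uniform on 50–500 informative reads per million; library sizes
log-uniform on 0.5–2 million informative reads, mimicking unequal depth
(real raw depths are tens of millions, of which SNP-overlapping unique
reads are a small fraction — the scale is chosen so the suite runs in
seconds, and the vignette's statements hold at that scale). Counts are
drawn NB(μ, φ) with maternal mean N·m·θ/10⁶ per gene and sample, mapped
to B6/Cast by the sample's cross.

The read-level generator places uniform 100-nt reads within gene bodies
on the gene's strand, draws each read's parental haplotype
Bernoulli(θ), and writes the haplotype's allele at every covered SNP.
Hidden "novel" models emit reads but are withheld from the known
annotation, exercising unit discovery. Not simulated: sequencing errors
(hence no `CONFLICT` reads), splicing (irrelevant to gene-body
counting), PCR duplicates, mapping bias, or overlapping genes. Passing
tests therefore demonstrate the statistical machinery and bookkeeping
are correct under the generative model — not that real-data artifacts
like reference bias are absent; for real data those must be handled
upstream at alignment.

## Numerical choices and degenerate inputs

* Printed-percentage comparisons round half away from zero to one
  decimal (a 56.25 must print 56.3); `round_half_away()` is exported
  because base `round()` is half-even.
* Percent maternal of a (0, 0) count pair is undefined and reported
  missing rather than zero.
* The BH step is `stats::p.adjust` behind a validating wrapper (range
  checks, NA passthrough); the suite checks it against a brute-force
  min-over-suffix oracle rather than trusting either implementation.
* Grid argmaxima for φ are refined by quadratic interpolation on the
  log scale; φ is floored at the grid minimum, effectively 0.
* The clustering boundary is inclusive at exactly `gap_bp`; exemplar
  ties break by start then id, so all outputs are permutation-invariant
  to input order.
* Counts of zero across one allele give a divergent but valid boundary
  fit (see above); counts of zero across both alleles give
  `NOT_TESTED`.

## Known limitations

Reads are consumed as pre-extracted SNP observations (the TSV dialect);
BAM/MD-tag extraction is upstream of this package. Multi-allelic sites
and indels are out of scope. RPKM for known genes uses the exemplar
gene-body length, an approximation to exon-level RPKM; for novel units
the unit span is the defined denominator. The composition assumption
behind column-libsize offsets fails on tiny gene panels with one-sided
bias (the test suite constructs symmetric panels for exactly this
reason); at genome scale the assumption is mild. X-linked analysis —
where imprinted X inactivation makes the story different — is outside
the model.

## A complete run

```{r example, eval = FALSE}
cfg    <- simulation_config(n_genes = 2000, theta_imprinted = 0.9, seed = 11)
truth  <- make_truth(cfg)
design <- cross_design(3, 3)
counts <- simulate_allele_counts(truth, design, cfg)

fit <- imprint_test(counts, design)
summary(fit)
plot(fit)

# compare calls with the generative truth
table(truth = truth$bias_class, called = fit$results$bias_class)
```

At these settings the fit recovers every planted imprinted gene with its
correct parental direction and admits no strain-biased gene into the PO
classes; the common dispersion estimates land on the generating φ = 0.1
in both groups.
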