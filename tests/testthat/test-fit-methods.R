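test_that("imprint_test returns a well-formed fit with working methods", {
  cfg <- simulation_config(n_genes = 300, theta_imprinted = 0.95, seed = 31)
  tr <- make_truth(cfg)
  des <- cross_design(3, 3)
  cnt <- simulate_allele_counts(tr, des, cfg)
  fit <- imprint_test(cnt, des, dispersion = 0.1)

  expect_s3_class(fit, "imprint_fit")
  r <- fit$results
  expect_equal(nrow(r), 300)
  expect_true(all(c("p_cb", "p_bc", "fdr_cb", "fdr_bc", "dir_cb", "dir_bc",
                    "bias_class") %in% names(r)))
  # FDR dominates p pointwise within each group
  ok <- !is.na(r$p_cb)
  expect_true(all(r$fdr_cb[ok] >= r$p_cb[ok] - 1e-12))
  expect_true(all(r$fdr_bc[!is.na(r$p_bc)] >= r$p_bc[!is.na(r$p_bc)] - 1e-12))
  # percent maternal bounded
  pct <- as.matrix(r[grep("^pct_", names(r))])
  expect_true(all(pct >= 0 & pct <= 100, na.rm = TRUE))

  expect_output(print(fit), "Reciprocal-cross")
  s <- summary(fit)
  expect_s3_class(s, "summary.imprint_fit")
  expect_output(print(s), "PO-biased")
  cf <- coef(fit)
  expect_equal(dim(cf), c(300, 2))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()

  # class tallies agree between summary and results
  expect_equal(s$class_summary$counts[["MATERNAL"]],
               sum(r$bias_class == "MATERNAL"))
})

test_that("genes with no counts are NOT_TESTED; filtering controls eligibility", {
  b6 <- matrix(c(0, 50, 60, 0, 55, 65, 0, 52, 62,
                 0, 48, 58, 0, 51, 61, 0, 49, 59), 3, 6,
               dimnames = list(c("dead", "gA", "gB"),
                               c("CB.1", "CB.2", "CB.3", "BC.1", "BC.2", "BC.3")))
  cast <- matrix(50, 3, 6, dimnames = dimnames(b6))
  cast["dead", ] <- 0
  cnt <- allele_counts(b6, cast)
  fit <- imprint_test(cnt, cross_design(3, 3), dispersion = 0.05,
                      filter = FALSE)
  expect_equal(fit$results$bias_class[fit$results$gene_id == "dead"],
               "NOT_TESTED")
  expect_true(all(fit$results$bias_class[fit$results$gene_id != "dead"] !=
                    "NOT_TESTED"))
})

test_that("classification is invariant under simultaneous strain and cross relabeling", {
  set.seed(17)
  n <- 1000
  fdr_cb <- runif(n)^2
  fdr_bc <- runif(n)^2
  dir_cb <- sample(c(-1, 1), n, replace = TRUE)
  dir_bc <- sample(c(-1, 1), n, replace = TRUE)
  base <- classify_bias(fdr_cb, fdr_bc, dir_cb, dir_bc)
  # swap strains (both directions flip sign) and crosses (cb/bc swap)
  flipped <- classify_bias(fdr_bc, fdr_cb, -dir_bc, -dir_cb)
  expect_identical(flipped[base == "MATERNAL"],
                   base[base == "MATERNAL"])
  expect_identical(flipped[base == "PATERNAL"],
                   base[base == "PATERNAL"])
  expect_true(all(flipped[base == "STRAIN_B6"] == "STRAIN_CAST"))
  expect_true(all(flipped[base == "STRAIN_CAST"] == "STRAIN_B6"))
  expect_identical(flipped[base == "NOT_SIG"], base[base == "NOT_SIG"])
})

test_that("the relabeling symmetry holds end to end on simulated counts", {
  cfg <- simulation_config(n_genes = 400, theta_imprinted = 0.9, seed = 41,
                           library_sizes = rep(1e6, 6))
  tr <- make_truth(cfg)
  des <- cross_design(3, 3)
  cnt <- simulate_allele_counts(tr, des, cfg)
  fit <- imprint_test(cnt, des, dispersion = 0.1)

  # swap strain labels (b6 <-> cast matrices) and cross labels of samples
  swapped <- allele_counts(cnt$cast, cnt$b6)
  des2 <- des
  des2$cross <- ifelse(des$cross == "CB", "BC", "CB")
  des2$maternal_strain <- ifelse(des2$cross == "CB", "CAST", "B6")
  fit2 <- imprint_test(swapped, des2, dispersion = 0.1)

  a <- fit$results$bias_class
  b <- fit2$results$bias_class
  expect_identical(b[a == "MATERNAL"], rep("MATERNAL", sum(a == "MATERNAL")))
  expect_identical(b[a == "PATERNAL"], rep("PATERNAL", sum(a == "PATERNAL")))
  expect_identical(b[a == "STRAIN_B6"],
                   rep("STRAIN_CAST", sum(a == "STRAIN_B6")))
})

test_that("read-level simulation feeds the pipeline back to the truth", {
  # simulate reads, assign alleles, count, test: marginals and maternal
  # fractions must match the generative truth within sampling error
  genome <- sim_genome(c(chr1 = 3e5), seed = 61)
  snps <- sim_snps(genome, density = 1 / 25, seed = 62)
  gm <- sim_gene_models(genome, n_genes = 8, gene_length = c(4000, 8000),
                        seed = 63)
  cfg <- simulation_config(n_genes = 8, mean_expr = 600, dispersion = 0,
                           theta_imprinted = 0.9,
                           library_sizes = rep(1e6, 6), seed = 64)
  tr <- make_truth(cfg)
  tr$gene_id <- gm$gene_id
  # symmetric class mix so the allele-column library sizes stay balanced
  # (library sizes are column sums; on a handful of genes a one-sided mix
  # would push the offsets themselves, as it would in any GLM with
  # composition-skewed columns)
  tr$bias_class <- rep(c("MATERNAL", "PATERNAL", "BIALLELIC", "BIALLELIC"), 2)
  tr$theta <- ifelse(tr$bias_class == "MATERNAL", 0.9,
                     ifelse(tr$bias_class == "PATERNAL", 0.1, 0.5))
  des <- cross_design(3, 3)
  reads <- simulate_reads(tr, genome, snps, gm, des, cfg)
  lab <- assign_read_allele(reads, snps)
  expect_false(any(lab == "CONFLICT"))  # no sequencing errors simulated
  cnt <- count_allelic(lab, reads, gm, samples = des$sample)

  # per-gene informative totals scale with the expected read count times the
  # per-read probability of covering a SNP (read placement is uniform)
  expected <- 600  # reads per sample per gene at libsize 1e6
  inf_frac <- mean(lab != "NO_SNP")
  tot <- rowMeans(cnt$b6 + cnt$cast)
  expect_true(all(abs(tot - expected * inf_frac) < 6 * sqrt(expected)))

  # maternal fraction of informative reads tracks theta per gene
  for (g in seq_len(nrow(gm))) {
    mat <- sum(cnt$cast[g, 1:3]) + sum(cnt$b6[g, 4:6])
    pat <- sum(cnt$b6[g, 1:3]) + sum(cnt$cast[g, 4:6])
    expect_lt(abs(percent_maternal(mat, pat) - 100 * tr$theta[g]), 3)
  }

  # and the fit recovers the imprinted genes and leaves the balanced ones
  fit <- imprint_test(cnt, des, dispersion = "common")
  got <- fit$results$bias_class
  expect_identical(got[tr$bias_class == "MATERNAL"],
                   rep("MATERNAL", sum(tr$bias_class == "MATERNAL")))
  expect_identical(got[tr$bias_class == "PATERNAL"],
                   rep("PATERNAL", sum(tr$bias_class == "PATERNAL")))
  expect_true(all(got[tr$bias_class == "BIALLELIC"] %in%
                    c("NOT_SIG", "NOT_TESTED")))
})
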