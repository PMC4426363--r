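test_that("truth tables honour the configured class mix and are reproducible", {
  cfg <- simulation_config(n_genes = 100, seed = 7,
                           class_fractions = c(MATERNAL = 0, PATERNAL = 0,
                                               STRAIN_B6 = 0, STRAIN_CAST = 0,
                                               BIALLELIC = 1))
  tr <- make_truth(cfg)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$bias_class == "BIALLELIC"))
  expect_true(all(tr$theta == 0.5))

  # determinism: same seed, bit-identical
  expect_identical(make_truth(cfg), make_truth(cfg))

  # class draw is multinomial: MATERNAL tally inside the central 99% interval
  cfg2 <- simulation_config(n_genes = 10000, seed = 7)
  tr2 <- make_truth(cfg2)
  n_mat <- sum(tr2$bias_class == "MATERNAL")
  interval <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(n_mat, interval[1])
  expect_lte(n_mat, interval[2])
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(class_fractions = c(MATERNAL = 0.5,
                                                     PATERNAL = 0.5,
                                                     STRAIN_B6 = 0.1,
                                                     STRAIN_CAST = 0,
                                                     BIALLELIC = 0)),
               "sum to 1")
  expect_error(simulation_config(n_cb = 0), "replicate")
  expect_error(simulation_config(dispersion = -1), "dispersion")
})

test_that("allelic count means follow theta, the cross mapping, and library size", {
  # degenerate case: fully maternal gene, Poisson noise, CB sample
  # (Cast mother) must put every read on the Cast allele
  cfg <- simulation_config(n_genes = 50, theta_imprinted = 1, dispersion = 0,
                           class_fractions = c(MATERNAL = 1, PATERNAL = 0,
                                               STRAIN_B6 = 0, STRAIN_CAST = 0,
                                               BIALLELIC = 0),
                           library_sizes = rep(1e6, 6), seed = 3)
  tr <- make_truth(cfg)
  cnt <- simulate_allele_counts(tr, cross_design(3, 3), cfg)
  expect_true(all(cnt$b6[, c("CB.1", "CB.2", "CB.3")] == 0))
  expect_true(all(cnt$cast[, c("BC.1", "BC.2", "BC.3")] == 0))

  # Poisson moment check: phi = 0, theta = 0.5, mean_expr 200, libsize 1e6
  # -> each allele count is Poisson(100); mean over genes within 3 SE
  cfg2 <- simulation_config(n_genes = 10000, dispersion = 0, mean_expr = 200,
                            class_fractions = c(MATERNAL = 0, PATERNAL = 0,
                                                STRAIN_B6 = 0, STRAIN_CAST = 0,
                                                BIALLELIC = 1),
                            library_sizes = rep(1e6, 2), seed = 4)
  tr2 <- make_truth(cfg2)
  cnt2 <- simulate_allele_counts(tr2, cross_design(1, 1), cfg2)
  se <- sqrt(100 / 10000)
  for (m in list(cnt2$b6, cnt2$cast)) {
    expect_lt(abs(mean(m[, 1]) - 100), 3 * se)
  }

  # strain-biased gene: favored allele higher in BOTH cross directions
  cfg3 <- simulation_config(n_genes = 200, theta_strain = 0.9, dispersion = 0.05,
                            class_fractions = c(MATERNAL = 0, PATERNAL = 0,
                                                STRAIN_B6 = 0, STRAIN_CAST = 1,
                                                BIALLELIC = 0),
                            library_sizes = rep(1e6, 6), seed = 5)
  tr3 <- make_truth(cfg3)
  cnt3 <- simulate_allele_counts(tr3, cross_design(3, 3), cfg3)
  for (s in colnames(cnt3$b6)) {
    expect_gt(mean(cnt3$cast[, s]), mean(cnt3$b6[, s]))
  }
})

test_that("count simulation is seed-deterministic and rejects bad input", {
  cfg <- simulation_config(n_genes = 20, seed = 9)
  tr <- make_truth(cfg)
  d <- cross_design(2, 2)
  expect_identical(simulate_allele_counts(tr, d, cfg),
                   simulate_allele_counts(tr, d, cfg))
  expect_error(simulate_allele_counts(tr[0, ], d, cfg), "empty")
  bad <- d[d$cross == "CB", ]
  expect_error(simulate_allele_counts(tr, bad, cfg), "CB and one BC")
})

test_that("simulated reads carry haplotype-consistent SNP bases", {
  genome <- sim_genome(c(chr1 = 60000), seed = 1)
  snps <- sim_snps(genome, density = 1 / 40, seed = 2)
  gm <- sim_gene_models(genome, n_genes = 3, gene_length = c(2000, 4000),
                        seed = 3)
  cfg <- simulation_config(n_genes = 3, mean_expr = 300, dispersion = 0,
                           library_sizes = rep(1e6, 2), seed = 4,
                           class_fractions = c(MATERNAL = 1, PATERNAL = 0,
                                               STRAIN_B6 = 0, STRAIN_CAST = 0,
                                               BIALLELIC = 0),
                           theta_imprinted = 1)
  tr <- make_truth(cfg)
  tr$gene_id <- gm$gene_id
  reads <- simulate_reads(tr, genome, snps, gm, cross_design(1, 1), cfg)
  expect_gt(nrow(reads), 0)

  # theta = 1: every read is maternal; BC sample (B6 mother) reads must be
  # drawn from the B6 haplotype and carry B6 alleles at covered SNPs
  bc <- reads[reads$sample == "BC.1", ]
  expect_true(all(bc$origin_allele == "B6"))
  lab <- assign_read_allele(bc, snps)
  expect_true(all(lab %in% c("B6", "NO_SNP")))

  # CB sample: maternal is Cast
  cb <- reads[reads$sample == "CB.1", ]
  lab_cb <- assign_read_allele(cb, snps)
  expect_true(all(lab_cb %in% c("CAST", "NO_SNP")))

  # determinism
  expect_identical(reads, simulate_reads(tr, genome, snps, gm,
                                         cross_design(1, 1), cfg))
})

test_that("a gene body without SNPs warns and emits only SNP-free reads", {
  genome <- sim_genome(c(chr1 = 60000), seed = 1)
  gm <- sim_gene_models(genome, n_genes = 2, seed = 3)
  # place all SNPs inside the first gene only
  snps <- data.frame(chrom = "chr1",
                     pos = seq(gm$start[1], gm$end[1], by = 97))
  ref <- strsplit(as.character(genome[["chr1"]]), "")[[1]]
  snps$b6_allele <- ref[snps$pos]
  snps$cast_allele <- ifelse(snps$b6_allele == "A", "C", "A")
  cfg <- simulation_config(n_genes = 2, mean_expr = 100, dispersion = 0,
                           library_sizes = rep(1e6, 2), seed = 5)
  tr <- make_truth(cfg)
  tr$gene_id <- gm$gene_id
  expect_warning(
    reads <- simulate_reads(tr, genome, snps, gm, cross_design(1, 1), cfg),
    "no informative SNP")
  bare <- reads[grepl(gm$gene_id[2], reads$read_id), ]
  expect_true(all(bare$snp_obs == ""))
})
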