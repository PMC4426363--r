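#' Configuration for the synthetic reciprocal-cross experiment
#'
#' Bundles every tunable of the generator emulating a six-line reciprocal
#' F1-hybrid experiment (three CB lines, Cast mother; three BC lines, B6
#' mother). Defaults give a 2,000-gene experiment with 5% maternally and 5%
#' paternally imprinted genes, 1% + 1% strain-biased genes, NB dispersion
#' 0.1, and unequal library depths drawn log-uniformly from 0.5-2 million
#' informative reads.
#'
#' @param n_genes number of simulated genes.
#' @param class_fractions named proportions over
#'   `MATERNAL, PATERNAL, STRAIN_B6, STRAIN_CAST, BIALLELIC`; must sum to 1.
#' @param theta_imprinted maternal expression fraction of the favored allele
#'   for imprinted genes: a single number, or a `function(n)` drawing n
#'   values (default Beta with mean 0.95, emulating the strong biases real
#'   imprinted genes show).
#' @param theta_strain favored-strain expression fraction for strain-biased
#'   genes (number or `function(n)`).
#' @param mean_expr expected informative reads per million library reads per
#'   gene: number or `function(n)` (default log-uniform on [50, 500]).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param library_sizes optional vector of per-sample informative-read
#'   totals; if `NULL`, drawn log-uniformly from `[0.5e6, 2e6]`.
#' @param n_cb,n_bc replicate counts per cross direction (each >= 1).
#' @param read_length simulated read length in nt.
#' @param snp_free_frac fraction of simulated reads forced to overlap no SNP.
#' @param seed RNG seed; every generator consumes it deterministically.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              class_fractions = c(MATERNAL = 0.05,
                                                  PATERNAL = 0.05,
                                                  STRAIN_B6 = 0.01,
                                                  STRAIN_CAST = 0.01,
                                                  BIALLELIC = 0.88),
                              theta_imprinted = function(n) stats::rbeta(n, 57, 3),
                              theta_strain = 0.9,
                              mean_expr = function(n) exp(stats::runif(n, log(50), log(500))),
                              dispersion = 0.1,
                              library_sizes = NULL,
                              n_cb = 3, n_bc = 3,
                              read_length = 100,
                              snp_free_frac = 0,
                              seed = 1L) {
  classes <- c("MATERNAL", "PATERNAL", "STRAIN_B6", "STRAIN_CAST", "BIALLELIC")
  if (!all(classes %in% names(class_fractions)))
    stopf("class_fractions must name all of: %s", paste(classes, collapse = ", "))
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stopf("class fractions must be non-negative and sum to 1 (got %.12f)",
          sum(class_fractions))
  if (!is_count1(n_genes) || n_genes < 1) stopf("n_genes must be a positive integer")
  if (n_cb < 1 || n_bc < 1) stopf("replicate counts must be >= 1")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 class_fractions = class_fractions,
                 theta_imprinted = theta_imprinted,
                 theta_strain = theta_strain,
                 mean_expr = mean_expr,
                 dispersion = dispersion,
                 library_sizes = library_sizes,
                 n_cb = as.integer(n_cb), n_bc = as.integer(n_bc),
                 read_length = as.integer(read_length),
                 snp_free_frac = snp_free_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

draw_par <- function(par, n) {
  if (is.function(par)) par(n) else rep_len(par, n)
}

#' Sample-to-cross design table
#'
#' @param n_cb,n_bc replicate counts for the CB (Cast mother x B6 father) and
#'   BC (B6 mother x Cast father) cross directions.
#' @return data.frame with `sample`, `cross` ("CB"/"BC") and the derived
#'   `maternal_strain` ("CAST" for CB, "B6" for BC).
#' @export
cross_design <- function(n_cb = 3, n_bc = 3) {
  stopifnot(n_cb >= 1, n_bc >= 1)
  s <- c(paste0("CB.", seq_len(n_cb)), paste0("BC.", seq_len(n_bc)))
  g <- rep(c("CB", "BC"), c(n_cb, n_bc))
  data.frame(sample = s, cross = g,
             maternal_strain = ifelse(g == "CB", "CAST", "B6"),
             stringsAsFactors = FALSE)
}

#' Draw the per-gene generative truth table
#'
#' Assigns each simulated gene a bias class, a bias strength theta (the
#' maternal expression fraction, or the favored-strain fraction for strain
#' classes; biallelic genes have theta = 0.5 by definition), an expected
#' informative-read abundance, and an NB dispersion.
#'
#' @param config a [simulation_config()].
#' @return data.frame of class `simulation_truth`: `gene_id`, `bias_class`,
#'   `theta`, `mean_expr`, `dispersion`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  cls <- sample(names(config$class_fractions), n, replace = TRUE,
                prob = config$class_fractions)
  bias <- draw_par(config$theta_imprinted, n)
  strain_bias <- draw_par(config$theta_strain, n)
  theta <- rep(0.5, n)
  theta[cls == "MATERNAL"] <- bias[cls == "MATERNAL"]
  theta[cls == "PATERNAL"] <- 1 - bias[cls == "PATERNAL"]
  theta[cls %in% c("STRAIN_B6", "STRAIN_CAST")] <-
    strain_bias[cls %in% c("STRAIN_B6", "STRAIN_CAST")]
  theta <- pmin(pmax(theta, 0), 1)
  out <- data.frame(gene_id = sprintf("G%05d", seq_len(n)),
                    bias_class = cls,
                    theta = theta,
                    mean_expr = draw_par(config$mean_expr, n),
                    dispersion = config$dispersion,
                    stringsAsFactors = FALSE)
  class(out) <- c("simulation_truth", "data.frame")
  out
}

## expected (maternal, paternal) -> (b6, cast) mean mapping for one sample
.allele_means <- function(truth, cross, libsize) {
  base <- libsize * truth$mean_expr / 1e6
  th <- truth$theta
  cls <- truth$bias_class
  po <- cls %in% c("MATERNAL", "PATERNAL", "BIALLELIC")
  b6 <- cast <- numeric(nrow(truth))
  # parent-of-origin classes: theta is the maternal fraction
  mat <- base * th; pat <- base * (1 - th)
  if (cross == "CB") { cast[po] <- mat[po]; b6[po] <- pat[po] }
  else               { b6[po] <- mat[po]; cast[po] <- pat[po] }
  # strain classes: theta is the favored-strain fraction, cross-independent
  sb6 <- cls == "STRAIN_B6"; sca <- cls == "STRAIN_CAST"
  b6[sb6] <- base[sb6] * th[sb6];      cast[sb6] <- base[sb6] * (1 - th[sb6])
  cast[sca] <- base[sca] * th[sca];    b6[sca] <- base[sca] * (1 - th[sca])
  list(b6 = b6, cast = cast)
}

#' Simulate the allelic count matrix directly from the truth table
#'
#' For gene g in sample s, the maternal-allele mean is
#' `libsize_s * mean_expr_g * theta_g / 1e6` and the paternal mean uses
#' `1 - theta_g`; strain-biased genes put theta on the favored strain allele
#' instead, independent of cross direction. Each allelic count is drawn
#' NB(mean, phi) (Poisson when phi = 0), and maternal/paternal are mapped to
#' B6/Cast via the sample's cross group.
#'
#' @param truth a [make_truth()] table.
#' @param design a [cross_design()] table with at least one sample per cross.
#' @param config the [simulation_config()] (supplies library sizes, phi,
#'   seed).
#' @return an [allele_counts] object with attribute `library_sizes` (the
#'   per-sample informative-read totals used).
#' @export
simulate_allele_counts <- function(truth, design, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truth) || nrow(truth) == 0L) stopf("empty truth table")
  if (!all(c("CB", "BC") %in% design$cross))
    stopf("design needs at least one CB and one BC sample")
  set.seed(config$seed + 1L)
  ns <- nrow(design)
  lib <- config$library_sizes %||%
    exp(stats::runif(ns, log(0.5e6), log(2e6)))
  lib <- rep_len(lib, ns)
  phi <- config$dispersion
  draw <- function(mu) {
    if (phi <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
  }
  b6 <- cast <- matrix(0L, nrow(truth), ns,
                       dimnames = list(truth$gene_id, design$sample))
  for (j in seq_len(ns)) {
    mm <- .allele_means(truth, design$cross[j], lib[j])
    b6[, j] <- draw(mm$b6)
    cast[, j] <- draw(mm$cast)
  }
  out <- allele_counts(b6, cast)
  attr(out, "library_sizes") <- stats::setNames(lib, design$sample)
  out
}

#' Simulate a random genome
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed RNG seed.
#' @return a [Biostrings::DNAStringSet].
#' @export
sim_genome <- function(chrom_lengths = c(chr1 = 2e5), seed = 1L) {
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_lengths)))
}

#' Simulate informative strain-distinguishing SNPs
#'
#' @param genome a `DNAStringSet`.
#' @param density expected SNPs per bp (default 1/150, roughly the density of
#'   informative Cast/B6 variants in transcribed regions).
#' @param seed RNG seed.
#' @return SNP data.frame (`chrom`, `pos`, `b6_allele`, `cast_allele`) with
#'   the B6 allele equal to the reference base.
#' @export
sim_snps <- function(genome, density = 1 / 150, seed = 2L) {
  set.seed(seed)
  out <- lapply(names(genome), function(chr) {
    L <- Biostrings::width(genome[chr])
    n <- max(1L, stats::rbinom(1, L, density))
    pos <- sort(sample.int(L, n))
    refbase <- strsplit(toupper(as.character(genome[[chr]])), "")[[1]][pos]
    alt <- vapply(refbase, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    data.frame(chrom = chr, pos = pos, b6_allele = refbase,
               cast_allele = unname(alt), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate gene models, optionally with hidden novel units
#'
#' Places non-overlapping gene bodies along each chromosome, separated by
#' more than 2 x 5 kb so that known-gene flanks never absorb the reads of a
#' hidden novel unit. `n_novel` of the models are flagged `origin = "novel"`:
#' they emit reads but are withheld from the "known" annotation handed to
#' [find_novel_units()].
#'
#' @param genome a `DNAStringSet`.
#' @param n_genes total models to place (known + novel).
#' @param n_novel how many of them are hidden novel units.
#' @param gene_length range (min, max) of gene-body lengths in bp.
#' @param spacing_bp minimum gap between neighbouring models (default 12000,
#'   comfortably beyond the 5 kb clustering/exclusion radii).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `origin`,
#'   `length_bp`.
#' @export
sim_gene_models <- function(genome, n_genes = 20, n_novel = 0,
                            gene_length = c(1000, 5000),
                            spacing_bp = 12000, seed = 3L) {
  set.seed(seed)
  stopifnot(n_novel <= n_genes)
  lens <- Biostrings::width(genome)
  chroms <- rep(names(genome), length.out = n_genes)
  per_chrom <- table(chroms)
  rows <- list()
  for (chr in names(per_chrom)) {
    k <- per_chrom[[chr]]
    L <- lens[match(chr, names(genome))]
    slot <- L %/% k
    if (slot < max(gene_length) + spacing_bp)
      stopf("chromosome %s too short for %d models at the requested spacing", chr, k)
    for (i in seq_len(k)) {
      gl <- sample(seq(gene_length[1], gene_length[2]), 1)
      lo <- (i - 1) * slot + spacing_bp %/% 2
      start <- lo + sample.int(max(1L, slot - gl - spacing_bp), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start = start, end = start + gl - 1L,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  origin <- rep("known", n_genes)
  if (n_novel > 0) origin[sample.int(n_genes, n_novel)] <- "novel"
  out$origin <- origin
  id <- character(n_genes)
  id[origin == "known"] <- sprintf("G%05d", seq_len(sum(origin == "known")))
  id[origin == "novel"] <- sprintf("NOV%03d", seq_len(sum(origin == "novel")))
  out <- data.frame(gene_id = id, out, stringsAsFactors = FALSE)
  out$length_bp <- out$end - out$start + 1L
  out
}

#' Simulate read-level data over gene bodies
#'
#' Reads are placed uniformly within each gene body on the gene's strand,
#' drawn from the maternal or paternal haplotype with the gene's theta, and
#' carry the strain allele base at every SNP they cover, consistent with the
#' drawn parental origin. A configurable fraction of reads is forced to
#' overlap no SNP. Genes whose body contains no informative SNP emit
#' SNP-free reads only, with a warning.
#'
#' @param truth a [make_truth()]-style table with one row per `gene_id` in
#'   `gene_models` (novel units included).
#' @param genome a `DNAStringSet` (defines chromosome bounds).
#' @param snps SNP table.
#' @param gene_models models from [sim_gene_models()].
#' @param design a [cross_design()] table.
#' @param config a [simulation_config()] (read length, SNP-free fraction,
#'   library sizes, seed).
#' @return data.frame of reads: `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `snp_obs` (semicolon-joined `pos:base`), `sample`, and the simulation
#'   truth column `origin_allele` ("B6"/"CAST").
#' @export
simulate_reads <- function(truth, genome, snps, gene_models, design, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truth) || nrow(truth) == 0L) stopf("empty truth table")
  miss <- setdiff(gene_models$gene_id, truth$gene_id)
  if (length(miss)) stopf("truth table lacks rows for: %s", paste(miss, collapse = ", "))
  set.seed(config$seed + 2L)
  ns <- nrow(design)
  lib <- rep_len(config$library_sizes %||%
                   exp(stats::runif(ns, log(0.5e6), log(2e6))), ns)
  rl <- config$read_length
  snps_by_chr <- split(snps, snps$chrom)
  no_snp <- vapply(seq_len(nrow(gene_models)), function(g) {
    sc <- snps_by_chr[[gene_models$chrom[g]]]
    is.null(sc) || !any(sc$pos >= gene_models$start[g] & sc$pos <= gene_models$end[g])
  }, TRUE)
  if (any(no_snp) && config$snp_free_frac < 1)
    warnf("gene(s) with no informative SNP emit SNP-free reads only: %s",
          paste(gene_models$gene_id[no_snp], collapse = ", "))
  rows <- vector("list", 0)
  for (j in seq_len(ns)) {
    cross <- design$cross[j]
    for (g in seq_len(nrow(gene_models))) {
      gm <- gene_models[g, ]
      tr <- truth[match(gm$gene_id, truth$gene_id), ]
      mm <- .allele_means(tr, cross, lib[j])
      n_reads <- stats::rpois(1, mm$b6 + mm$cast)
      if (n_reads == 0L) next
      p_b6 <- mm$b6 / (mm$b6 + mm$cast)
      hap <- ifelse(stats::runif(n_reads) < p_b6, "B6", "CAST")
      span <- max(1L, gm$end - gm$start + 1L - rl + 1L)
      st <- gm$start + sample.int(span, n_reads, replace = TRUE) - 1L
      en <- pmin(st + rl - 1L, gm$end)
      sc <- snps_by_chr[[gm$chrom]]
      gene_snps <- if (is.null(sc)) integer(0) else
        which(sc$pos >= gm$start & sc$pos <= gm$end)
      force_free <- stats::runif(n_reads) < config$snp_free_frac
      obs <- character(n_reads)
      for (i in seq_len(n_reads)) {
        if (length(gene_snps) == 0L) next
        if (force_free[i]) {
          for (try in 1:50) {
            cover <- sc$pos[gene_snps] >= st[i] & sc$pos[gene_snps] <= en[i]
            if (!any(cover)) break
            st[i] <- gm$start + sample.int(span, 1) - 1L
            en[i] <- min(st[i] + rl - 1L, gm$end)
          }
        }
        cover <- gene_snps[sc$pos[gene_snps] >= st[i] & sc$pos[gene_snps] <= en[i]]
        if (length(cover) == 0L) next
        base <- if (hap[i] == "B6") sc$b6_allele[cover] else sc$cast_allele[cover]
        obs[i] <- paste(sc$pos[cover], base, sep = ":", collapse = ";")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("%s_%s_r%05d", design$sample[j], gm$gene_id,
                          seq_len(n_reads)),
        chrom = gm$chrom, start = st, end = en, strand = gm$strand,
        snp_obs = obs, sample = design$sample[j], origin_allele = hap,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      snp_obs = character(), sample = character(),
                      origin_allele = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
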