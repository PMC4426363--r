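## File-format adapters. Sequences go through Biostrings, intervals through
## rtracklayer/GenomicRanges, VCF parsing through VariantAnnotation; the
## small TSV dialects of the simulator are plain tab tables.

#' Read / write genomes as FASTA
#' @param path file path.
#' @return [read_fasta()]: a `DNAStringSet` named by chromosome.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param genome a `DNAStringSet`.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read and write informative SNP tables
#'
#' The TSV dialect has columns `chrom`, `pos` (1-based), `b6_allele`,
#' `cast_allele`. The VCF dialect stores the B6 allele as REF and the Cast
#' allele as ALT; [write_snp_vcf()] emits a minimal single-sample-free VCF,
#' [read_snp_vcf()] accepts any VCF of biallelic SNVs.
#'
#' @param path file path.
#' @return SNP data.frame.
#' @export
read_snps_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_snps(x)
}

#' @rdname read_snps_tsv
#' @param snps SNP data.frame.
#' @export
write_snps_tsv <- function(snps, path) {
  utils::write.table(validate_snps(snps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_snps_tsv
#' @export
read_snp_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  alt1 <- vapply(seq_along(alt), function(i) as.character(alt[[i]][1]), "")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    b6_allele = as.character(VariantAnnotation::ref(v)),
                    cast_allele = alt1, stringsAsFactors = FALSE)
  keep <- nchar(out$b6_allele) == 1 & nchar(out$cast_allele) == 1
  validate_snps(out[keep, ])
}

#' @rdname read_snps_tsv
#' @export
write_snp_vcf <- function(snps, path) {
  snps <- validate_snps(snps)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=imprintr",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  snps$chrom, snps$pos,
                  paste0("snp", seq_len(nrow(snps))),
                  snps$b6_allele, snps$cast_allele)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write gene models as BED6
#'
#' BED is half-open 0-based on disk; in memory all coordinates are 1-based
#' inclusive. BED12 input is accepted (blocks ignored; the gene body span is
#' used).
#'
#' @param path file path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `length_bp`.
#' @export
read_models_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = g$name %||% paste0("feature", seq_along(g)),
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             length_bp = GenomicRanges::width(g),
             stringsAsFactors = FALSE)
}

#' @rdname read_models_bed
#' @param models data.frame with `gene_id`/`unit_id`, `chrom`, `start`,
#'   `end`, `strand`; an `n_reads` column (novel units) is written to the
#'   BED score field.
#' @export
write_models_bed <- function(models, path) {
  name <- models$gene_id %||% models$unit_id
  g <- GenomicRanges::GRanges(models$chrom,
                              IRanges::IRanges(models$start, models$end),
                              strand = models$strand)
  g$name <- name
  g$score <- models$n_reads %||% rep(0L, nrow(models))
  rtracklayer::export(g, path, format = "BED")
  invisible(path)
}

#' Read and write the simulator's read dialect
#'
#' TSV with `read_id`, `chrom`, `start`, `end` (1-based inclusive), `strand`,
#' `snp_obs` (semicolon-joined `pos:base`, empty when the read covers no
#' SNP), `sample`, and optionally the simulation truth column
#' `origin_allele`.
#'
#' @param path file path.
#' @return data.frame of reads.
#' @export
read_reads_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(snp_obs = "character"))
  x$snp_obs[is.na(x$snp_obs)] <- ""
  x
}

#' @rdname read_reads_tsv
#' @param reads read data.frame.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write allelic count tables
#'
#' TSV with `gene_id` then `<sample>_b6` / `<sample>_cast` column pairs.
#'
#' @param path file path.
#' @return an [allele_counts] object.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(names(x)[1] == "gene_id")
  cols <- names(x)[-1]
  b6c <- grep("_b6$", cols, value = TRUE)
  samples <- sub("_b6$", "", b6c)
  stopifnot(all(paste0(samples, "_cast") %in% cols))
  b6 <- as.matrix(x[paste0(samples, "_b6")])
  cast <- as.matrix(x[paste0(samples, "_cast")])
  dimnames(b6) <- dimnames(cast) <- list(x$gene_id, samples)
  allele_counts(b6, cast)
}

#' @rdname read_counts_tsv
#' @param counts an [allele_counts] object.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  s <- colnames(counts$b6)
  out <- data.frame(gene_id = rownames(counts$b6), stringsAsFactors = FALSE)
  for (i in seq_along(s)) {
    out[[paste0(s[i], "_b6")]] <- counts$b6[, i]
    out[[paste0(s[i], "_cast")]] <- counts$cast[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-cross design table
#'
#' TSV with columns `sample` and `cross` ("CB"/"BC"); the maternal strain is
#' derived (CB: Cast mother, BC: B6 mother).
#'
#' @param path file path.
#' @return design data.frame as from [cross_design()].
#' @export
read_design_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "cross") %in% names(x)),
            all(x$cross %in% c("CB", "BC")))
  x$maternal_strain <- ifelse(x$cross == "CB", "CAST", "B6")
  x
}
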