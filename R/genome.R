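#' Build an in-silico alternate-strain pseudogenome by SNP substitution
#'
#' Substitutes the Cast allele into the reference (B6) sequence at every
#' informative SNP position, producing the alternate-strain genome used for
#' allele-aware read handling. Every SNP's B6 allele must match the reference
#' base at its position; a mismatch signals the wrong genome build and is an
#' error.
#'
#' @param ref a [Biostrings::DNAStringSet] (or named character vector of
#'   sequences) keyed by chromosome name.
#' @param snps SNP table: data.frame with columns `chrom`, `pos` (1-based),
#'   `b6_allele`, `cast_allele` (single differing bases).
#' @return a `DNAStringSet` identical to `ref` except that each SNP position
#'   carries the Cast allele; sequence lengths are unchanged.
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "AATT"))
#' snps <- data.frame(chrom = "chr1", pos = 2, b6_allele = "A", cast_allele = "G")
#' as.character(build_pseudogenome(ref, snps))  # "AGTT"
build_pseudogenome <- function(ref, snps) {
  if (!methods::is(ref, "DNAStringSet")) ref <- Biostrings::DNAStringSet(ref)
  snps <- validate_snps(snps)
  seqs <- toupper(as.character(ref))
  if (nrow(snps) == 0L) {
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(ref)
    return(out)
  }
  missing_chr <- setdiff(unique(snps$chrom), names(ref))
  if (length(missing_chr))
    stopf("SNP chromosome(s) absent from reference: %s",
          paste(missing_chr, collapse = ", "))
  for (chr in unique(snps$chrom)) {
    s <- snps[snps$chrom == chr, ]
    ch <- strsplit(seqs[[chr]], "", fixed = TRUE)[[1]]
    if (any(s$pos < 1 | s$pos > length(ch)))
      stopf("SNP position out of range on %s", chr)
    bad <- ch[s$pos] != s$b6_allele
    if (any(bad)) {
      i <- which(bad)[1]
      stopf("reference mismatch at %s:%d (reference %s, SNP table B6 allele %s); wrong genome build?",
            chr, s$pos[i], ch[s$pos[i]], s$b6_allele[i])
    }
    ch[s$pos] <- s$cast_allele
    seqs[[chr]] <- paste(ch, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(ref)
  out
}

validate_snps <- function(snps) {
  req <- c("chrom", "pos", "b6_allele", "cast_allele")
  if (!all(req %in% names(snps)))
    stopf("SNP table needs columns: %s", paste(req, collapse = ", "))
  snps$chrom <- as.character(snps$chrom)
  snps$b6_allele <- toupper(as.character(snps$b6_allele))
  snps$cast_allele <- toupper(as.character(snps$cast_allele))
  if (any(nchar(snps$b6_allele) != 1L) || any(nchar(snps$cast_allele) != 1L))
    stopf("alleles must be single bases")
  if (any(snps$b6_allele == snps$cast_allele))
    stopf("b6 and cast alleles must differ at every SNP")
  if (anyDuplicated(snps[c("chrom", "pos")]))
    stopf("duplicated (chrom, pos) in SNP table")
  snps
}

#' Assign reads to parental alleles from the SNP bases they cover
#'
#' Each uniquely mapping read is labelled by comparing its observed bases at
#' informative SNP positions with the two strain alleles: `B6` if every
#' covered SNP matches the B6 allele, `CAST` if every one matches the Cast
#' allele, `NO_SNP` if the read covers no SNP, and `CONFLICT` if the observed
#' bases mix strains or match neither (such reads cannot support either
#' haplotype and are discarded downstream). Assignment ignores strand: bases
#' are reference-oriented.
#'
#' @param reads read table as produced by [simulate_reads()] or
#'   [read_reads_tsv()]: data.frame with at least `read_id` and `snp_obs`
#'   (semicolon-joined `pos:base` observations, `""` for none) and `chrom`.
#' @param snps SNP table (see [build_pseudogenome()]).
#' @return character vector of labels, one per read, named by `read_id`.
#' @export
assign_read_allele <- function(reads, snps) {
  snps <- validate_snps(snps)
  key <- paste0(snps$chrom, ":", snps$pos)
  b6 <- stats::setNames(snps$b6_allele, key)
  ca <- stats::setNames(snps$cast_allele, key)
  obs <- parse_snp_obs(reads$snp_obs)
  n_obs <- lengths(obs) / 2L
  lab <- rep("NO_SNP", nrow(reads))
  idx <- which(n_obs > 0)
  for (i in idx) {
    o <- obs[[i]]
    m <- length(o) / 2L
    pos <- o[seq_len(m)]
    base <- toupper(o[m + seq_len(m)])
    k <- paste0(reads$chrom[i], ":", pos)
    if (anyNA(match(k, key)))
      stopf("read %s observes position(s) absent from the SNP table: %s",
            reads$read_id[i], paste(k[is.na(match(k, key))], collapse = ", "))
    is_b6 <- base == unname(b6[k])
    is_ca <- base == unname(ca[k])
    lab[i] <- if (all(is_b6)) "B6"
      else if (all(is_ca)) "CAST"
      else "CONFLICT"
  }
  stats::setNames(lab, reads$read_id)
}

## "101:A;205:G" -> c("101","205","A","G"); "" -> character(0)
parse_snp_obs <- function(x) {
  x <- as.character(x)
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    c(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  })
}
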