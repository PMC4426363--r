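#' Select the longest exemplar transcript per gene
#'
#' Collapses a transcript table to one counting model per gene: the transcript
#' maximizing gene-body length. Ties are broken by smaller start, then by
#' lexicographically smaller transcript id.
#'
#' @param transcripts data.frame with columns `gene_id`, `tx_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `strand`.
#' @return data.frame of one row per gene (columns as input plus `length_bp`),
#'   ordered by gene_id.
#' @export
select_longest_exemplar <- function(transcripts) {
  req <- c("gene_id", "tx_id", "chrom", "start", "end", "strand")
  stopifnot(all(req %in% names(transcripts)))
  tx <- transcripts
  empty <- is.na(tx$gene_id) | !nzchar(as.character(tx$gene_id))
  if (any(empty)) {
    warnf("dropping %d transcript(s) without a parent gene id", sum(empty))
    tx <- tx[!empty, ]
  }
  if (nrow(tx) == 0L) return(tx)
  tx$length_bp <- tx$end - tx$start + 1L
  ord <- order(tx$gene_id, -tx$length_bp, tx$start, as.character(tx$tx_id))
  tx <- tx[ord, ]
  out <- tx[!duplicated(tx$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Discover novel transcription units by strand-matched read clustering
#'
#' Reads that overlap no same-strand known gene body (extended by `flank_bp`
#' on each side) are single-linkage clustered per chromosome and strand:
#' reads whose intervals lie within `gap_bp` of each other (inter-interval
#' gap, nearest ends) merge into one unit spanning from the smallest start to
#' the largest end. Antisense reads inside a known gene's span are retained,
#' so antisense units over known genes remain discoverable.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param known data.frame of known gene models (`chrom`, `start`, `end`,
#'   `strand`); may be empty.
#' @param gap_bp maximum inter-read gap merged into one unit (default 5000).
#' @param flank_bp exclusion flank around known gene bodies (default 5000).
#' @param min_reads minimum supporting reads per reported unit (default 1).
#' @return data.frame of units: `unit_id` ("TU1"... per chrom/strand order),
#'   `chrom`, `start`, `end`, `strand`, `n_reads`.
#' @export
find_novel_units <- function(reads, known, gap_bp = 5000, flank_bp = 5000,
                             min_reads = 1) {
  empty <- data.frame(unit_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_reads = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(reads) || nrow(reads) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start, reads$end),
                               strand = reads$strand)
  if (!is.null(known) && nrow(known) > 0L) {
    kg <- GenomicRanges::GRanges(known$chrom,
                                 IRanges::IRanges(pmax(1L, known$start - flank_bp),
                                                  known$end + flank_bp),
                                 strand = known$strand)
    hit <- IRanges::overlapsAny(gr, kg, ignore.strand = FALSE)
    gr <- gr[!hit]
  }
  if (length(gr) == 0L) return(empty)
  # single-linkage with inter-interval gap <= gap_bp; reduce() merges ranges
  # separated by a gap strictly smaller than min.gapwidth
  units <- GenomicRanges::reduce(gr, min.gapwidth = gap_bp + 1L,
                                 ignore.strand = FALSE)
  n <- GenomicRanges::countOverlaps(units, gr, ignore.strand = FALSE)
  keep <- n >= min_reads
  units <- units[keep]; n <- n[keep]
  if (length(units) == 0L) return(empty)
  # order by chrom, strand, start for stable TU numbering
  o <- order(as.character(GenomicRanges::seqnames(units)),
             as.character(GenomicRanges::strand(units)),
             GenomicRanges::start(units))
  units <- units[o]; n <- n[o]
  data.frame(unit_id = paste0("TU", seq_along(units)),
             chrom = as.character(GenomicRanges::seqnames(units)),
             start = GenomicRanges::start(units),
             end = GenomicRanges::end(units),
             strand = as.character(GenomicRanges::strand(units)),
             n_reads = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Combine known exemplars and novel units into one counting model table
#'
#' @param known data.frame of exemplar gene models (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param novel data.frame from [find_novel_units()]; may be `NULL`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `origin` ("known"/"novel"), `length_bp`.
#' @export
combine_models <- function(known, novel = NULL) {
  k <- data.frame(gene_id = as.character(known$gene_id),
                  chrom = as.character(known$chrom),
                  start = as.integer(known$start), end = as.integer(known$end),
                  strand = as.character(known$strand),
                  origin = "known", stringsAsFactors = FALSE)
  if (!is.null(novel) && nrow(novel) > 0L) {
    nv <- data.frame(gene_id = as.character(novel$unit_id),
                     chrom = as.character(novel$chrom),
                     start = as.integer(novel$start), end = as.integer(novel$end),
                     strand = as.character(novel$strand),
                     origin = "novel", stringsAsFactors = FALSE)
    k <- rbind(k, nv)
  }
  k$length_bp <- k$end - k$start + 1L
  k
}
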