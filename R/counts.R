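#' Allelic count table container
#'
#' Gene-by-sample matrix of (B6, Cast) read-count pairs. Internally two
#' integer matrices with shared dimnames; the column library size of each
#' sample-by-allele column is its column sum over all genes.
#'
#' @param b6,cast non-negative integer matrices (genes x samples) with
#'   identical dimnames.
#' @return an object of class `allele_counts`.
#' @export
allele_counts <- function(b6, cast) {
  b6 <- as.matrix(b6); cast <- as.matrix(cast)
  stopifnot(identical(dim(b6), dim(cast)),
            !is.null(rownames(b6)), !is.null(colnames(b6)))
  if (is.null(rownames(cast))) dimnames(cast) <- dimnames(b6)
  stopifnot(identical(dimnames(b6), dimnames(cast)))
  if (any(b6 < 0) || any(cast < 0)) stopf("allelic counts must be non-negative")
  structure(list(b6 = b6, cast = cast), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d genes x %d samples\n",
              nrow(x$b6), ncol(x$b6)))
  cat("samples:", paste(colnames(x$b6), collapse = ", "), "\n")
  cat("allele-column library sizes:\n")
  print(allele_libsizes(x))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$b6)

#' Library sizes of the sample-by-allele columns
#'
#' @param counts an [allele_counts] object.
#' @return named numeric vector over columns `<sample>_b6`, `<sample>_cast`.
#' @export
allele_libsizes <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  s <- colnames(counts$b6)
  stats::setNames(c(rbind(colSums(counts$b6), colSums(counts$cast))),
                  c(rbind(paste0(s, "_b6"), paste0(s, "_cast"))))
}

#' Count allelic reads per gene body
#'
#' A read labelled `B6` or `CAST` increments the corresponding allele count of
#' every same-strand model whose gene body (`[start, end]`, introns included)
#' contains the read's interval midpoint. `NO_SNP` and `CONFLICT` reads
#' contribute nothing.
#'
#' @param assignments named character vector of labels from
#'   [assign_read_allele()], aligned with `reads` (matched by `read_id`).
#' @param reads read table with `read_id`, `chrom`, `start`, `end`, `strand`
#'   and a `sample` column naming the library each read came from.
#' @param models counting models from [combine_models()] (needs `gene_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param samples optional character vector fixing the sample (column) order;
#'   defaults to the sorted unique `reads$sample`.
#' @return an [allele_counts] object (genes x samples).
#' @export
count_allelic <- function(assignments, reads, models, samples = NULL) {
  stopifnot(all(c("read_id", "chrom", "start", "end", "strand", "sample")
                %in% names(reads)))
  lab <- assignments[match(reads$read_id, names(assignments))]
  if (anyNA(lab)) stopf("assignments missing for %d read(s)", sum(is.na(lab)))
  samples <- samples %||% sort(unique(as.character(reads$sample)))
  genes <- as.character(models$gene_id)
  b6 <- matrix(0L, length(genes), length(samples),
               dimnames = list(genes, samples))
  cast <- b6
  keep <- lab %in% c("B6", "CAST")
  r <- reads[keep, ]; lab <- lab[keep]
  if (nrow(r) > 0L) {
    mid <- (r$start + r$end) %/% 2L
    pts <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(mid, mid),
                                  strand = r$strand)
    mg <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(models$start, models$end),
                                 strand = models$strand)
    ov <- GenomicRanges::findOverlaps(pts, mg, ignore.strand = FALSE)
    qi <- S4Vectors::queryHits(ov); mi <- S4Vectors::subjectHits(ov)
    si <- match(as.character(r$sample[qi]), samples)
    is_b6 <- lab[qi] == "B6"
    inc <- function(M, sel) {
      if (!any(sel)) return(M)
      t <- table(factor(mi[sel], levels = seq_along(genes)),
                 factor(si[sel], levels = seq_along(samples)))
      M + matrix(as.integer(t), nrow(M), ncol(M))
    }
    b6 <- inc(b6, is_b6)
    cast <- inc(cast, !is_b6)
  }
  allele_counts(b6, cast)
}

#' Counts per million
#'
#' @param count non-negative count(s).
#' @param column_libsize positive library size of the count's column.
#' @return `count * 1e6 / column_libsize`.
#' @export
#' @examples
#' cpm(37, 250000)  # 148
cpm <- function(count, column_libsize) {
  if (any(column_libsize <= 0)) stopf("library size must be positive")
  count * 1e6 / column_libsize
}

#' Filter to genes eligible for allelic testing
#'
#' A gene is eligible iff, in every sample, the sum of its B6 and Cast CPM
#' values (each normalized by its own sample-by-allele column library size)
#' is strictly greater than `threshold`.
#'
#' @param counts an [allele_counts] object.
#' @param threshold CPM threshold (default 1; strict "more than").
#' @return character vector of eligible gene ids.
#' @export
filter_expressed <- function(counts, threshold = 1.0) {
  stopifnot(inherits(counts, "allele_counts"), ncol(counts$b6) >= 1)
  lb <- colSums(counts$b6); lc <- colSums(counts$cast)
  if (any(lb <= 0) || any(lc <= 0))
    stopf("every sample-by-allele column must have a positive library size")
  tot <- sweep(counts$b6, 2, lb / 1e6, "/") + sweep(counts$cast, 2, lc / 1e6, "/")
  rownames(counts$b6)[apply(tot > threshold, 1, all)]
}

#' Reads per kilobase per million aligned reads
#'
#' @param count read count(s) for the feature.
#' @param length_bp feature length in bp (> 0); gene-body length for known
#'   exemplars, unit span for novel transcription units.
#' @param total_aligned total aligned reads in the library (> 0).
#' @return `count * 1e9 / (length_bp * total_aligned)`.
#' @export
#' @examples
#' rpkm(250, 2500, 2e6)  # 50
rpkm <- function(count, length_bp, total_aligned) {
  if (any(length_bp <= 0)) stopf("feature length must be positive")
  if (any(total_aligned <= 0)) stopf("total aligned reads must be positive")
  count * 1e9 / (length_bp * total_aligned)
}
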