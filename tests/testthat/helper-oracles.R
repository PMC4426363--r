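# Independent brute-force oracles used to validate the fast-path
# implementations. These deliberately share no code with the package
# internals: all-pairs transitive closure, per-read scans, sort-based
# step-up.

# single-linkage clustering of read intervals by transitive closure of the
# pairwise "inter-interval gap <= gap_bp" relation, after removing reads
# that intersect a same-strand, flank-extended known gene body
oracle_novel_units <- function(reads, known, gap_bp = 5000, flank_bp = 5000,
                               min_reads = 1) {
  keep <- rep(TRUE, nrow(reads))
  if (!is.null(known) && nrow(known) > 0) {
    for (i in seq_len(nrow(reads))) {
      for (k in seq_len(nrow(known))) {
        if (reads$chrom[i] == known$chrom[k] &&
            reads$strand[i] == known$strand[k] &&
            reads$start[i] <= known$end[k] + flank_bp &&
            reads$end[i] >= known$start[k] - flank_bp) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  r <- reads[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), n_reads = integer()))
  }
  gap_ok <- function(i, j) {
    r$chrom[i] == r$chrom[j] && r$strand[i] == r$strand[j] &&
      max(r$start[i], r$start[j]) - min(r$end[i], r$end[j]) - 1 <= gap_bp
  }
  comp <- seq_len(nrow(r))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(r))) {
      for (j in seq_len(nrow(r))) {
        if (comp[i] != comp[j] && gap_ok(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cid) {
    m <- r[comp == cid, , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               strand = m$strand[1], n_reads = nrow(m),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_reads >= min_reads, , drop = FALSE]
  out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

# per-read containment scan: a B6/CAST read increments every same-strand
# model containing its midpoint
oracle_count_allelic <- function(assignments, reads, models, samples) {
  b6 <- matrix(0L, nrow(models), length(samples),
               dimnames = list(models$gene_id, samples))
  cast <- b6
  for (i in seq_len(nrow(reads))) {
    lab <- assignments[[reads$read_id[i]]]
    if (!(lab %in% c("B6", "CAST"))) next
    mid <- (reads$start[i] + reads$end[i]) %/% 2
    for (k in seq_len(nrow(models))) {
      if (models$chrom[k] == reads$chrom[i] &&
          models$strand[k] == reads$strand[i] &&
          models$start[k] <= mid && mid <= models$end[k]) {
        j <- match(reads$sample[i], samples)
        if (lab == "B6") b6[k, j] <- b6[k, j] + 1L else cast[k, j] <- cast[k, j] + 1L
      }
    }
  }
  list(b6 = b6, cast = cast)
}

# sort-based min-over-suffix step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# random reads on a toy genome for clustering/counting properties
random_reads <- function(n, chroms = c("chr1", "chr2"), max_pos = 2e5,
                         len_range = c(50, 150)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(read_id = paste0("r", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
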