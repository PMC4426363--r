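#' Load a packaged reference table
#'
#' The package ships transcriptions of the published per-gene allelic results
#' for mouse trophoblast stem cell lines: `"T2"` — known imprinted genes with
#' significant parent-of-origin bias (32 rows); `"T3"` — candidate imprinted
#' genes (17 rows); `"T4"` — imprinted host genes of annotated microRNAs
#' (static reference, no computation). For T2/T3 each of the six lines
#' (CB.1-3, BC.1-3) contributes a printed percent-maternal value and the raw
#' (maternal, paternal) SNP-overlapping read-count pair behind it.
#'
#' @param table `"T2"`, `"T3"` or `"T4"`.
#' @return data.frame; T2/T3 carry attribute `samples` with the six line
#'   short names (`cb1`...`bc3`).
#' @export
load_reference_table <- function(table = c("T2", "T3", "T4")) {
  table <- match.arg(table)
  f <- c(T2 = "table2_known_imprinted.tsv",
         T3 = "table3_candidate_imprinted.tsv",
         T4 = "table4_mirna_hosts.tsv")[[table]]
  path <- system.file("extdata", f, package = "imprintr", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (table %in% c("T2", "T3")) {
    x$cbp <- as.numeric(x$cbp)
    x$bcp <- as.numeric(x$bcp)
    attr(x, "samples") <- c("cb1", "cb2", "cb3", "bc1", "bc2", "bc3")
    n_expect <- if (table == "T2") 32L else 17L
    stopifnot(nrow(x) == n_expect)
  }
  x
}

#' Tally classified genes
#'
#' @param results data.frame with a `bias_class` column (e.g.
#'   `imprint_test()$results`).
#' @return list of class `class_summary`: `counts` (named tally over all six
#'   classes), `n_eligible` (tested genes: everything except NOT_TESTED),
#'   `n_maternal`, `n_paternal`, and `n_po_biased` (= maternal + paternal).
#' @export
summarize_classes <- function(results) {
  lv <- c("MATERNAL", "PATERNAL", "STRAIN_B6", "STRAIN_CAST",
          "NOT_SIG", "NOT_TESTED")
  cls <- if (is.data.frame(results)) results$bias_class else results
  counts <- table(factor(cls, levels = lv))
  out <- list(counts = stats::setNames(as.integer(counts), lv),
              n_eligible = sum(counts) - counts[["NOT_TESTED"]],
              n_maternal = counts[["MATERNAL"]],
              n_paternal = counts[["PATERNAL"]])
  out$n_po_biased <- out$n_maternal + out$n_paternal
  class(out) <- "class_summary"
  out
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("eligible: %d; PO-biased: %d (%d maternal + %d paternal)\n",
              x$n_eligible, x$n_po_biased, x$n_maternal, x$n_paternal))
  print(x$counts)
  invisible(x)
}

#' Mean and median of a set of RPKM values
#'
#' @param values non-empty numeric vector.
#' @return list `mean`, `median` (even n: midpoint of the central pair).
#' @export
#' @examples
#' rpkm_summary(c(1, 2, 3, 4))  # mean 2.5, median 2.5
rpkm_summary <- function(values) {
  if (length(values) == 0L || all(is.na(values))) stopf("empty RPKM vector")
  list(mean = mean(values), median = stats::median(values))
}

#' Recompute and check the printed percent-maternal values of a fixture
#'
#' For every line-by-gene cell of a T2/T3 table, recomputes
#' `100 * maternal / (maternal + paternal)` from the printed count pair,
#' rounds half away from zero to one decimal, and compares with the printed
#' percentage. Cells with zero total counts are skipped and listed.
#'
#' @param fixture a table from [load_reference_table()] (`"T2"` or `"T3"`).
#' @param tolerance maximum accepted |printed - recomputed| after rounding
#'   (default 0.1).
#' @return data.frame of problem cells (`gene`, `sample`, `printed`,
#'   `recomputed`, `reason` in `"discrepant"`/`"zero_total"`); zero rows when
#'   every cell checks out.
#' @export
verify_fixture_percentages <- function(fixture, tolerance = 0.1) {
  samples <- attr(fixture, "samples")
  if (is.null(samples)) stopf("not a T2/T3 fixture (no samples attribute)")
  rows <- list()
  for (s in samples) {
    m <- fixture[[paste0(s, "_mat")]]
    p <- fixture[[paste0(s, "_pat")]]
    printed <- fixture[[paste0(s, "_pct")]]
    rec <- round_half_away(percent_maternal(m, p), 1)
    zero <- (m + p) == 0
    bad <- !zero & abs(rec - printed) > tolerance
    idx <- which(bad | zero)
    for (i in idx) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = fixture$gene[i], sample = s, printed = printed[i],
        recomputed = rec[i],
        reason = if (zero[i]) "zero_total" else "discrepant",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(), sample = character(),
                      printed = numeric(), recomputed = numeric(),
                      reason = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Fraction of measurements agreeing in direction of allelic bias
#'
#' Two percent-maternal measurements agree when both fall on the same side
#' of 50%; a value of exactly 50% is concordant with anything. Keys are
#' matched by name.
#'
#' @param a,b named numeric vectors of percent-maternal values (names are
#'   gene-by-sample keys).
#' @return fraction of shared keys agreeing in direction.
#' @export
direction_concordance <- function(a, b) {
  keys <- intersect(names(a), names(b))
  if (length(keys) == 0L) stopf("no shared keys between the two tables")
  x <- a[keys]; y <- b[keys]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stopf("no shared non-missing values")
  agree <- (x[ok] - 50) * (y[ok] - 50) >= 0  # 50 itself matches either side
  mean(agree)
}
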