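#' Percent of allele-specific reads from the maternal allele
#'
#' @param maternal,paternal non-negative counts of reads supporting the
#'   maternally and paternally inherited allele (vectors recycle).
#' @return `100 * maternal / (maternal + paternal)`; `NA` where both counts
#'   are zero (undefined).
#' @export
#' @examples
#' percent_maternal(2508, 119)  # 95.47...
percent_maternal <- function(maternal, paternal) {
  if (any(maternal < 0, na.rm = TRUE) || any(paternal < 0, na.rm = TRUE))
    stopf("counts must be non-negative")
  tot <- maternal + paternal
  out <- 100 * maternal / tot
  out[tot == 0] <- NA_real_
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: with m tested p-values sorted ascending,
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, mapped back to input
#' order. Missing values are excluded from m and returned missing.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs allowed).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Classify a gene's allelic bias from the reciprocal-cross test pair
#'
#' A gene is called only when its FDR is at or below `alpha` in **both**
#' cross directions. The direction pattern then separates parent-of-origin
#' from strain effects: the Cast allele up in CB (Cast mother) together with
#' the B6 allele up in BC (B6 mother) means the maternal allele is favored in
#' both crosses (MATERNAL); the mirror pattern is PATERNAL; the same strain
#' up in both crosses is a strain-of-origin bias (STRAIN_CAST / STRAIN_B6).
#'
#' @param fdr_cb,fdr_bc BH-adjusted values per cross group (vectors recycle).
#' @param dir_cb,dir_bc sign of the Cast-vs-B6 log-fold-change per group
#'   (+1 Cast up, -1 B6 up).
#' @param alpha FDR threshold (default 0.05, inclusive).
#' @param tested logical; genes filtered out upstream get `NOT_TESTED`.
#' @return character vector over `MATERNAL, PATERNAL, STRAIN_B6,
#'   STRAIN_CAST, NOT_SIG, NOT_TESTED`.
#' @export
classify_bias <- function(fdr_cb, fdr_bc, dir_cb, dir_bc, alpha = 0.05,
                          tested = TRUE) {
  n <- max(length(fdr_cb), length(fdr_bc), length(dir_cb), length(dir_bc),
           length(tested))
  fdr_cb <- rep_len(fdr_cb, n); fdr_bc <- rep_len(fdr_bc, n)
  dir_cb <- rep_len(dir_cb, n); dir_bc <- rep_len(dir_bc, n)
  tested <- rep_len(tested, n)
  out <- rep("NOT_SIG", n)
  out[!tested | is.na(fdr_cb) | is.na(fdr_bc)] <- "NOT_TESTED"
  sig <- out == "NOT_SIG" & fdr_cb <= alpha & fdr_bc <= alpha
  if (any(sig & (dir_cb == 0 | dir_bc == 0)))
    stopf("zero direction with significant FDR: inconsistent inputs")
  out[sig & dir_cb > 0 & dir_bc < 0] <- "MATERNAL"
  out[sig & dir_cb < 0 & dir_bc > 0] <- "PATERNAL"
  out[sig & dir_cb > 0 & dir_bc > 0] <- "STRAIN_CAST"
  out[sig & dir_cb < 0 & dir_bc < 0] <- "STRAIN_B6"
  out
}

## observation layout for one cross group: columns c(<samples>_b6, <samples>_cast)
.group_obs <- function(counts, design, group) {
  s <- design$sample[design$cross == group]
  if (length(s) == 0L) stopf("no samples in cross group %s", group)
  Y <- cbind(counts$b6[, s, drop = FALSE], counts$cast[, s, drop = FALSE])
  libs <- allele_libsizes(counts)
  off <- log(c(libs[paste0(s, "_b6")], libs[paste0(s, "_cast")]))
  list(Y = Y, offset = off, allele = rep(c(0, 1), each = length(s)),
       samples = s)
}

#' Estimate NB dispersion for one cross group
#'
#' Common dispersion maximizes the sum over genes of the Cox-Reid adjusted
#' profile likelihood on a log-spaced phi grid; per-gene ("shrunken")
#' dispersions maximize the gene's own adjusted profile likelihood plus a
#' common-curve prior weighted as `prior_n` pseudo-observations, pulling
#' noisy per-gene estimates toward the common value.
#'
#' @param counts an [allele_counts] object (full table; library-size offsets
#'   come from its allele-column sums).
#' @param design a [cross_design()] table.
#' @param group `"CB"` or `"BC"`.
#' @param method `"shrunken"` (default), `"common"`, or `"fixed"`.
#' @param phi dispersion used when `method = "fixed"` (also the only mode
#'   available with a single sample in the group).
#' @param prior_n prior weight of the common curve, in observations
#'   (default 10).
#' @param grid log-spaced candidate phi values.
#' @return data.frame `gene_id`, `phi`, `method`, with attribute
#'   `common_phi`. All-zero genes get `NA` (dispersion undefined;
#'   downstream they are NOT_TESTED).
#' @export
estimate_dispersion <- function(counts, design, group = c("CB", "BC"),
                                method = c("shrunken", "common", "fixed"),
                                phi = NULL, prior_n = 10,
                                grid = 10^seq(-4, 1, length.out = 41)) {
  group <- match.arg(group)
  method <- match.arg(method)
  ob <- .group_obs(counts, design, group)
  genes <- rownames(counts$b6)
  nz <- rowSums(ob$Y) > 0
  out <- data.frame(gene_id = genes, phi = NA_real_, method = NA_character_,
                    stringsAsFactors = FALSE)
  if (method == "fixed") {
    if (is.null(phi) || phi < 0) stopf("fixed method needs phi >= 0")
    out$phi[nz] <- phi
    out$method[nz] <- "fixed"
    attr(out, "common_phi") <- phi
    return(out)
  }
  if (length(ob$samples) < 2L)
    stopf("dispersion estimation needs >= 2 samples per group; use method = \"fixed\"")
  A <- apl_grid(ob$Y, ob$allele, ob$offset, grid)
  lg <- log10(grid)
  common_curve <- colMeans(A[nz, , drop = FALSE])
  common_phi <- max(0, 10^argmax_quad(lg, common_curve))
  if (method == "common") {
    out$phi[nz] <- common_phi
    out$method[nz] <- "common"
  } else {
    # weighted objective: APL_g + (prior_n / n_obs) * common curve, so the
    # prior counts as prior_n pseudo-observations against the gene's own n_obs
    w <- prior_n / ncol(ob$Y)
    for (i in which(nz)) {
      out$phi[i] <- max(0, 10^argmax_quad(lg, A[i, ] + w * common_curve))
    }
    out$method[nz] <- "shrunken"
  }
  attr(out, "common_phi") <- common_phi
  out
}

#' Test for parent-of-origin and strain expression bias
#'
#' The central fitting function. For each eligible gene it fits, separately
#' in the CB and BC cross groups, the NB log-linear model
#' `log mu = log(libsize) + b0 + b1 * [allele == Cast]` and tests `b1 = 0`
#' with a 1-df likelihood-ratio test ([nb_glm_lrt()]); p-values are
#' BH-adjusted within each group and genes significant in both groups are
#' classified by the direction pattern ([classify_bias()]).
#'
#' Genes are eligible when their summed allelic CPM exceeds `cpm_threshold`
#' in every sample ([filter_expressed()]); others are reported `NOT_TESTED`.
#'
#' @param counts an [allele_counts] object (genes x samples).
#' @param design a [cross_design()] table covering the count columns.
#' @param alpha dual-group FDR threshold for calling bias (default 0.05).
#' @param dispersion `"shrunken"`, `"common"`, or a fixed numeric phi used
#'   for every gene in both groups.
#' @param cpm_threshold eligibility threshold (strictly greater-than).
#' @param filter logical; set `FALSE` to test every gene with nonzero counts.
#' @return an object of class `imprint_fit`; see [summary.imprint_fit()].
#'   Its `$results` data.frame has one row per gene: per-sample percent
#'   maternal (`pct_<sample>`), `p_cb`, `p_bc`, `fdr_cb`, `fdr_bc`,
#'   `dir_cb`, `dir_bc`, `lfc_cb`, `lfc_bc`, `bias_class`.
#' @export
imprint_test <- function(counts, design, alpha = 0.05,
                         dispersion = "shrunken", cpm_threshold = 1,
                         filter = TRUE) {
  stopifnot(inherits(counts, "allele_counts"))
  stopifnot(all(design$sample %in% colnames(counts$b6)))
  genes <- rownames(counts$b6)
  eligible <- if (filter) filter_expressed(counts, cpm_threshold) else
    genes[rowSums(counts$b6 + counts$cast) > 0]
  res <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  # per-sample percent maternal (maternal allele resolved by cross group)
  for (j in seq_len(nrow(design))) {
    s <- design$sample[j]
    m <- if (design$cross[j] == "CB") counts$cast[, s] else counts$b6[, s]
    p <- if (design$cross[j] == "CB") counts$b6[, s] else counts$cast[, s]
    res[[paste0("pct_", s)]] <- percent_maternal(m, p)
  }
  disp <- list()
  for (g in c("CB", "BC")) {
    ob <- .group_obs(counts, design, g)
    if (is.character(dispersion)) {
      d <- estimate_dispersion(counts, design, g, method = dispersion)
    } else {
      d <- estimate_dispersion(counts, design, g, method = "fixed",
                               phi = dispersion)
    }
    disp[[g]] <- d
    phig <- d$phi
    tested_g <- genes %in% eligible & !is.na(phig) & rowSums(ob$Y) > 0
    p <- dir <- lfc <- rep(NA_real_, length(genes))
    idx <- which(tested_g)
    if (length(idx)) {
      ph <- phig[idx]
      full <- nb_fit_vec(ob$Y[idx, , drop = FALSE], ob$allele, ob$offset, ph,
                         two_group = TRUE)
      null <- nb_fit_vec(ob$Y[idx, , drop = FALSE], ob$allele, ob$offset, ph,
                         two_group = FALSE)
      stat <- pmax(0, 2 * (full$loglik - null$loglik))
      p[idx] <- stats::pchisq(stat, 1, lower.tail = FALSE)
      lfc[idx] <- full$b1
      dir[idx] <- ifelse(abs(full$b1) < 1e-12, 0, sign(full$b1))
    }
    gl <- tolower(g)
    res[[paste0("p_", gl)]] <- p
    res[[paste0("fdr_", gl)]] <- bh_adjust(p)
    res[[paste0("dir_", gl)]] <- dir
    res[[paste0("lfc_", gl)]] <- lfc
  }
  res$bias_class <- classify_bias(res$fdr_cb, res$fdr_bc, res$dir_cb,
                                  res$dir_bc, alpha = alpha,
                                  tested = genes %in% eligible &
                                    !is.na(res$p_cb) & !is.na(res$p_bc))
  structure(list(results = res, counts = counts, design = design,
                 dispersion = disp, alpha = alpha,
                 eligible = eligible, call = match.call()),
            class = "imprint_fit")
}

#' @export
print.imprint_fit <- function(x, ...) {
  cat("Reciprocal-cross allelic imbalance fit (NB GLM LRT)\n")
  cat(sprintf("  %d genes, %d samples (%d CB + %d BC); alpha = %g\n",
              nrow(x$results), nrow(x$design),
              sum(x$design$cross == "CB"), sum(x$design$cross == "BC"),
              x$alpha))
  cat(sprintf("  eligible after CPM filter: %d\n", length(x$eligible)))
  tb <- table(factor(x$results$bias_class,
                     levels = c("MATERNAL", "PATERNAL", "STRAIN_B6",
                                "STRAIN_CAST", "NOT_SIG", "NOT_TESTED")))
  print(tb)
  invisible(x)
}

#' Summarize an imprint_fit
#'
#' @param object an `imprint_fit`.
#' @param ... unused.
#' @return a list of class `summary.imprint_fit`: the class tally
#'   ([summarize_classes()]), common dispersions per group, and the
#'   significant-gene table sorted by the larger of the two FDRs.
#' @export
summary.imprint_fit <- function(object, ...) {
  sm <- summarize_classes(object$results)
  sig <- object$results[object$results$bias_class %in%
                          c("MATERNAL", "PATERNAL", "STRAIN_B6", "STRAIN_CAST"), ]
  sig <- sig[order(pmax(sig$fdr_cb, sig$fdr_bc)), ]
  structure(list(class_summary = sm,
                 common_phi = lapply(object$dispersion, attr, "common_phi"),
                 significant = sig, alpha = object$alpha),
            class = "summary.imprint_fit")
}

#' @export
print.summary.imprint_fit <- function(x, ...) {
  s <- x$class_summary
  cat(sprintf("eligible genes tested: %d\n", s$n_eligible))
  cat(sprintf("PO-biased (FDR <= %g in both crosses): %d (%d maternal, %d paternal)\n",
              x$alpha, s$n_po_biased, s$n_maternal, s$n_paternal))
  cat(sprintf("strain-biased: %d B6, %d Cast\n",
              s$counts[["STRAIN_B6"]], s$counts[["STRAIN_CAST"]]))
  cat(sprintf("common dispersion: CB %.4g, BC %.4g\n",
              x$common_phi$CB %||% NA, x$common_phi$BC %||% NA))
  if (nrow(x$significant)) {
    cat("top biased genes:\n")
    cols <- c("gene_id", "fdr_cb", "fdr_bc", "bias_class")
    print(utils::head(x$significant[cols], 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.imprint_fit <- function(object, ...) {
  cbind(lfc_cb = object$results$lfc_cb, lfc_bc = object$results$lfc_bc) |>
    `rownames<-`(object$results$gene_id)
}

#' Scatter of percent-maternal expression across the reciprocal crosses
#'
#' Plots each tested gene's mean percent maternal in the CB lines against
#' that in the BC lines, coloured by bias class. Parent-of-origin-biased
#' genes fall along the diagonal corners (high/high maternal, low/low),
#' strain-biased genes in the anti-diagonal corners.
#'
#' @param x an `imprint_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.imprint_fit <- function(x, ...) {
  r <- x$results
  pc <- rowMeans(r[, paste0("pct_", x$design$sample[x$design$cross == "CB"]),
                   drop = FALSE], na.rm = TRUE)
  pb <- rowMeans(r[, paste0("pct_", x$design$sample[x$design$cross == "BC"]),
                   drop = FALSE], na.rm = TRUE)
  cls <- factor(r$bias_class, levels = c("BIALLELIC", "NOT_SIG", "NOT_TESTED",
                                         "MATERNAL", "PATERNAL",
                                         "STRAIN_B6", "STRAIN_CAST"))
  pal <- c(NOT_SIG = "grey60", NOT_TESTED = "grey85", MATERNAL = "#c2185b",
           PATERNAL = "#1565c0", STRAIN_B6 = "#2e7d32", STRAIN_CAST = "#ef6c00",
           BIALLELIC = "grey60")
  graphics::plot(pc, pb, col = pal[as.character(r$bias_class)], pch = 16,
                 cex = 0.6, xlab = "% maternal, CB lines (Cast mother)",
                 ylab = "% maternal, BC lines (B6 mother)", ...)
  graphics::abline(h = 50, v = 50, lty = 3, col = "grey40")
  keep <- names(pal)[names(pal) %in% unique(r$bias_class)]
  graphics::legend("topleft", legend = keep, col = pal[keep], pch = 16,
                   cex = 0.7, bty = "n")
  invisible(NULL)
}
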