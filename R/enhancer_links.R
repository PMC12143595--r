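# Link induced enhancer TSSs to distal genes through provided
# enhancer-to-gene association pairs, with distance and significance
# filters.

#' Build enhancer-TSS-to-gene links
#'
#' Pairs are coordinate-anchored enhancer regions associated with a gene
#' (0-based `chrom`/`start`/`end` plus `gene_id`); a CTSS peak joins a pair
#' when its summit lies inside the pair region. Distance is measured from
#' the CTSS summit to the annotated gene TSS; links closer than
#' `min_distance` (promoter-proximal) are removed. Pairs referencing unknown
#' genes are dropped with a warning; cross-chromosome pairs are dropped.
#'
#' @param ctss_peaks Stranded `GRanges` with metadata `summit`, `log2fc`,
#'   `padj` and logical `bound` (overlaps a binding site).
#' @param pairs data.frame of enhancer-gene associations.
#' @param gene_table data.frame with `gene_id`, `chrom`, `tss_pos` (0-based),
#'   `log2fc`, `padj`.
#' @param min_distance Minimum summit-to-gene-TSS distance (default 2500).
#' @return data.table of links: peak index/coordinates, gene, distance,
#'   `bound`, TSS and gene differential statistics.
#' @export
build_links <- function(ctss_peaks, pairs, gene_table, min_distance = 2500L) {
  pr <- as.data.table(pairs)
  gt <- as.data.table(gene_table)
  unknown <- setdiff(pr$gene_id, gt$gene_id)
  if (length(unknown)) {
    warning("dropping ", length(unknown), " pair(s) referencing unknown gene(s)")
    pr <- pr[!gene_id %in% unknown]
  }
  empty <- data.table(peak = integer(), chrom = character(), summit = integer(),
                      gene_id = character(), distance = integer(),
                      bound = logical(), tss_log2fc = numeric(),
                      tss_padj = numeric(), gene_log2fc = numeric(),
                      gene_padj = numeric())
  if (nrow(pr) == 0L || length(ctss_peaks) == 0L) return(empty)
  pk <- data.table(
    peak = seq_along(ctss_peaks),
    chrom = as.character(GenomicRanges::seqnames(ctss_peaks)),
    summit = S4Vectors::mcols(ctss_peaks)$summit,
    bound = S4Vectors::mcols(ctss_peaks)$bound,
    tss_log2fc = S4Vectors::mcols(ctss_peaks)$log2fc,
    tss_padj = S4Vectors::mcols(ctss_peaks)$padj
  )
  pr <- pr[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), gene_id = as.character(gene_id))]
  hits <- pk[pr, on = .(chrom, summit >= start, summit < end),
             .(peak = x.peak, chrom = x.chrom, summit = x.summit,
               bound = x.bound, tss_log2fc = x.tss_log2fc,
               tss_padj = x.tss_padj, gene_id = i.gene_id),
             allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) return(empty)
  hits <- merge(hits, gt[, .(gene_id, gene_chrom = chrom, tss_pos,
                             gene_log2fc = log2fc, gene_padj = padj)],
                by = "gene_id")
  hits <- hits[chrom == gene_chrom]
  hits[, distance := abs(summit - tss_pos)]
  hits <- hits[distance >= min_distance]
  hits[, c("gene_chrom", "tss_pos") := NULL]
  setcolorder(hits, c("peak", "chrom", "summit", "gene_id", "distance",
                      "bound", "tss_log2fc", "tss_padj", "gene_log2fc",
                      "gene_padj"))
  hits[order(peak, gene_id)][]
}

#' Candidate genes under bound-enhancer regulation
#'
#' A gene is a candidate iff it has at least one link whose enhancer TSS is
#' bound and significantly upregulated (TSS log2FC > `tss_fc`, FDR <
#' `tss_fdr`) and whose gene is significantly upregulated (gene log2FC >
#' `gene_fc`, FDR < `gene_fdr`). All inequalities strict; genes are
#' deduplicated. Loosening any threshold never removes a candidate.
#'
#' @param links Output of [build_links()].
#' @param tss_fc,tss_fdr,gene_fc,gene_fdr Thresholds (defaults 1, 0.1, 0.5,
#'   0.05).
#' @return Sorted character vector of candidate gene ids.
#' @export
candidate_genes <- function(links, tss_fc = 1, tss_fdr = 0.1,
                            gene_fc = 0.5, gene_fdr = 0.05) {
  lk <- as.data.table(links)
  hit <- lk[bound & tss_log2fc > tss_fc & tss_padj < tss_fdr &
              gene_log2fc > gene_fc & gene_padj < gene_fdr]
  sort(unique(hit$gene_id))
}

#' Rank correlation between TSS and gene expression changes
#'
#' Spearman correlation (average-rank ties, two-sided p via the normal
#' approximation) between enhancer-TSS log2FC and linked-gene log2FC,
#' optionally restricted to bound TSSs. Constant input yields an undefined
#' (NA) correlation, flagged in the result.
#'
#' @param links Output of [build_links()].
#' @param subset `"all"` or `"bound"`.
#' @return List with `rho`, `p`, `n`, `defined`.
#' @export
change_correlation <- function(links, subset = c("all", "bound")) {
  subset <- match.arg(subset)
  lk <- as.data.table(links)
  if (subset == "bound") lk <- lk[bound == TRUE]
  if (nrow(lk) < 3L) stop("change_correlation requires >= 3 link pairs")
  x <- lk$tss_log2fc; y <- lk$gene_log2fc
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = nrow(lk), defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(lk), defined = TRUE)
}
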