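# Region quantification and a simplified negative-binomial Wald test with
# Benjamini-Hochberg correction. Deliberately minimal compared with a full
# count-model framework: no dispersion trend, no fold-change shrinkage
# priors, no outlier filtering.

#' Region x sample count matrix
#'
#' @param regions `GRanges` of quantified regions.
#' @param counts Integer matrix, regions x samples.
#' @param condition Character vector per sample, values `control`/`treated`.
#' @param sample_id Optional sample labels.
#' @param strandness Counting convention used: `"none"` or `"reverse"`.
#' @return A `region_counts` object.
#' @export
region_counts <- function(regions, counts, condition,
                          sample_id = NULL, strandness = "none") {
  counts <- as.matrix(counts)
  if (length(regions) != nrow(counts)) stop("regions/counts dimension mismatch")
  if (ncol(counts) != length(condition)) stop("condition length != n samples")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (!all(condition %in% c("control", "treated"))) {
    stop("condition values must be 'control' or 'treated'")
  }
  if (is.null(sample_id)) {
    sample_id <- paste0(condition, "_", stats::ave(seq_along(condition),
                                                   condition, FUN = seq_along))
  }
  colnames(counts) <- sample_id
  structure(list(regions = regions, counts = counts,
                 samples = data.table(sample_id = sample_id,
                                      condition = condition),
                 strandness = strandness),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("region_counts: %d regions x %d samples (%s strandness)\n",
              nrow(x$counts), ncol(x$counts), x$strandness))
  invisible(x)
}

#' Count reads or fragments over regions
#'
#' A read is assigned to every region it overlaps (multi-assignment), so
#' overlapping regions each receive the read. Modes:
#' \describe{
#'   \item{`none`}{any-overlap fragment counting, strand ignored.}
#'   \item{`sense`}{5' read position inside the region, read strand equal to
#'     region strand (reads in transcript orientation).}
#'   \item{`reverse`}{5' read position inside the region, read strand
#'     opposite to the region strand (reverse-stranded libraries).}
#' }
#'
#' @param reads Named list of read/fragment tables (one per sample); each a
#'   `GRanges` or a 0-based `chrom/start/end/strand` data.frame.
#' @param regions `GRanges` of regions.
#' @param condition Condition label per sample.
#' @param strandness `"none"`, `"sense"` or `"reverse"`.
#' @return A [region_counts] object.
#' @export
count_regions <- function(reads, regions, condition,
                          strandness = c("none", "sense", "reverse")) {
  strandness <- match.arg(strandness)
  reg_strand <- as.character(BiocGenerics::strand(regions))
  count_one <- function(x) {
    dt <- as_frag_dt(x)
    if (strandness == "none") {
      gr <- GenomicRanges::GRanges(dt$chrom,
                                   IRanges::IRanges(dt$start + 1L, dt$end))
      return(GenomicRanges::countOverlaps(regions, gr, ignore.strand = TRUE))
    }
    if (any(!dt$strand %in% c("+", "-"))) {
      stop("stranded counting requires stranded reads")
    }
    pos5 <- ifelse(dt$strand == "+", dt$start, dt$end - 1L)
    gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(pos5 + 1L, pos5 + 1L),
                                 strand = dt$strand)
    hits <- GenomicRanges::findOverlaps(regions, gr, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    rs <- reg_strand[q]
    ss <- as.character(BiocGenerics::strand(gr))[S4Vectors::subjectHits(hits)]
    keep <- if (strandness == "sense") rs == "*" | rs == ss else
      rs == "*" | rs != ss
    tabulate(q[keep], nbins = length(regions))
  }
  counts <- vapply(reads, count_one, numeric(length(regions)))
  storage.mode(counts) <- "integer"
  region_counts(regions, counts, condition,
                sample_id = names(reads), strandness = strandness)
}

#' Median-of-ratios library size factors
#'
#' Per-sample scale factors computed from the median ratio to the per-region
#' geometric mean, using regions with all-positive counts; falls back to
#' total-count scaling (with a message) when no such region exists. Factors
#' are rescaled so their geometric mean is 1.
#'
#' @param counts Count matrix or [region_counts].
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "region_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    logg <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2L,
                function(col) exp(median(log(col) - logg)))
  } else {
    message("size_factors: no region with all-positive counts; ",
            "falling back to total-count scaling")
    sf <- colSums(counts)
  }
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial Wald test
#'
#' Counts are normalized by [size_factors()] (or supplied factors).
#' log2FC = log2((mean normalized treated + c) / (mean normalized control +
#' c)) with pseudocount c = 0.5. Per-region dispersion is estimated by
#' method of moments on normalized counts, floored at 0 and shrunk halfway
#' toward the across-region median. The Wald statistic divides log2FC by its
#' delta-method standard error under NB variance (var = mu + a mu^2);
#' two-sided p from a t reference whose degrees of freedom are the residual
#' df inflated by the dispersion shrinkage,
#' `(n_t + n_c - 2) / (1 - shrink_weight)^2` (small-sample correction over
#' the asymptotic normal).
#'
#' @param rc A [region_counts].
#' @param factors Optional precomputed size factors.
#' @param pseudocount Pseudocount on normalized condition means.
#' @param shrink_weight Weight on the across-region median dispersion.
#' @return data.table with columns `log2fc`, `pvalue`, `padj`, `base_mean`,
#'   `class` plus region coordinates (`padj` via [bh_adjust()], `class` via
#'   [classify_differential()] at default thresholds).
#' @export
nb_diff <- function(rc, factors = NULL, pseudocount = 0.5, shrink_weight = 0.5) {
  stopifnot(inherits(rc, "region_counts"))
  cond <- rc$samples$condition
  n_t <- sum(cond == "treated"); n_c <- sum(cond == "control")
  if (n_t < 2L || n_c < 2L) {
    stop("nb_diff requires >= 2 replicates per condition; ",
         "use descriptive summaries for unreplicated designs")
  }
  if (is.null(factors)) factors <- size_factors(rc)
  norm <- sweep(rc$counts, 2L, factors, "/")
  xt <- norm[, cond == "treated", drop = FALSE]
  xc <- norm[, cond == "control", drop = FALSE]
  mu_t <- rowMeans(xt); mu_c <- rowMeans(xc)
  # method-of-moments dispersion pooled over conditions, floored at 0
  mom <- function(x, mu) (apply(x, 1L, var) - mu) / pmax(mu, 1e-8)^2
  disp <- pmax((mom(xt, mu_t) + mom(xc, mu_c)) / 2, 0)
  disp[!is.finite(disp)] <- 0
  disp <- (1 - shrink_weight) * disp + shrink_weight * median(disp)
  log2fc <- log2((mu_t + pseudocount) / (mu_c + pseudocount))
  var_t <- (mu_t + disp * mu_t^2) / n_t
  var_c <- (mu_c + disp * mu_c^2) / n_c
  se <- sqrt(var_t / (mu_t + pseudocount)^2 + var_c / (mu_c + pseudocount)^2) /
    log(2)
  wald <- ifelse(se > 0, log2fc / se, 0)
  # residual df per region, inflated for the shrinkage toward the
  # across-region median (whose own sampling error is negligible): shrinking
  # with weight w scales the dispersion-estimator variance by (1 - w)^2
  df_eff <- (n_t + n_c - 2L) / (1 - shrink_weight)^2
  pvalue <- 2 * stats::pt(-abs(wald), df = df_eff)
  res <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rc$regions)),
    start = BiocGenerics::start(rc$regions) - 1L,
    end = BiocGenerics::end(rc$regions),
    base_mean = (mu_t + mu_c) / 2,
    log2fc = log2fc, pvalue = pvalue
  )
  res[, padj := bh_adjust(pvalue)]
  res[, class := classify_differential(log2fc, padj)]
  res[]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values; monotone in p-rank, all in \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values along `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify differential results
#'
#' `increased` iff log2FC > fc_cut and FDR < fdr_cut; `decreased` iff
#' log2FC < -fc_cut and FDR < fdr_cut; otherwise `unchanged`. Inequalities
#' are strict.
#'
#' @param log2fc,fdr Numeric vectors.
#' @param fc_cut,fdr_cut Thresholds (defaults 1 and 0.1).
#' @return Character vector of class labels.
#' @export
classify_differential <- function(log2fc, fdr, fc_cut = 1, fdr_cut = 0.1) {
  out <- rep("unchanged", length(log2fc))
  out[log2fc > fc_cut & fdr < fdr_cut] <- "increased"
  out[log2fc < -fc_cut & fdr < fdr_cut] <- "decreased"
  out
}
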