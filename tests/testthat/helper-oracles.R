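# Brute-force oracles, independent of the package's implementation paths.
# All interval arguments are plain data.frames in 0-based half-open
# coordinates.

# per-base membership test for any-overlap
bf_overlaps_any <- function(q, subjects) {
  qb <- seq(q$start, q$end - 1L)
  for (i in seq_len(nrow(subjects))) {
    if (subjects$chrom[i] != q$chrom) next
    sb <- seq(subjects$start[i], subjects$end[i] - 1L)
    if (length(intersect(qb, sb)) > 0) return(TRUE)
  }
  FALSE
}

# merge via covered-base components: two covered bases belong to one merged
# interval iff at most max_gap uncovered bases separate them
bf_merge <- function(df, max_gap) {
  bases <- sort(unique(unlist(mapply(function(s, e) seq(s, e - 1L),
                                     df$start, df$end, SIMPLIFY = FALSE))))
  brk <- which(diff(bases) > max_gap + 1L)
  starts <- bases[c(1L, brk + 1L)]
  ends <- bases[c(brk, length(bases))] + 1L
  data.frame(start = starts, end = ends)
}

# total (read, region) any-overlap incidences by double loop
bf_incidences <- function(reads, regions) {
  total <- 0L
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(regions))) {
      if (reads$chrom[i] == regions$chrom[j] &&
          reads$start[i] < regions$end[j] &&
          regions$start[j] < reads$end[i]) {
        total <- total + 1L
      }
    }
  }
  total
}

# step-up BH from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- running
  }
  q
}

# average ranks and Spearman rho from first principles
bf_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}
bf_spearman <- function(x, y) {
  rx <- bf_rank(x); ry <- bf_rank(y)
  a <- rx - mean(rx); b <- ry - mean(ry)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# exhaustive argmax summit over a coverage map (leftmost tie)
bf_summit <- function(pos, score, lo, hi) {
  keep <- pos >= lo & pos < hi
  if (!any(keep)) return(NULL)
  p <- pos[keep]; s <- score[keep]
  list(summit = min(p[s == max(s)]), total = sum(s))
}

# build a GRanges from 0-based half-open vectors
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

rand_intervals <- function(n, max_pos = 10000L, max_len = 300L, chrom = "chr1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# small, fast simulator configuration shared across tests; dots override
small_config <- function(seed = 1L, ...) {
  defaults <- list(n_chroms = 1L, chrom_length = 4e5, n_sites = 80L,
                   depth = 3e4, chip_depth = 5e5, n_replicates = 2L,
                   n_genes = 20L, n_linked_genes = 5L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
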