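# CTSS positional density around response-element centers: per-region
# normalized density profiles, a windowed offset-enrichment histogram, and
# mode detection on the profile.

#' CTSS density profile around RE centers
#'
#' For each region (RE center +/- `half_width`, 401 positions by default)
#' the per-position 5'-read counts are divided by the region's in-window
#' total; regions with total reads below `min_reads` are dropped; the
#' surviving regions' normalized vectors are averaged per offset, separately
#' per stratum. Each contributing vector sums to 1, hence so does the mean.
#' CTSS strands are pooled.
#'
#' @param track A [signal_track()] of 5' coverage.
#' @param centers RE centers: data.frame with 0-based `chrom`/`pos`, or a
#'   `GRanges` (start used).
#' @param min_reads Minimum in-window read total per region (default 5).
#' @param strata Optional per-center stratum labels (e.g. collapsed
#'   chromatin state); `NULL` means a single stratum `"all"`.
#' @param condition Condition label recorded in the output.
#' @param half_width Window half-width (default 200).
#' @return A `density_profile` data.table: offset, density, n_regions,
#'   stratum, condition.
#' @export
density_profile <- function(track, centers, min_reads = 5L, strata = NULL,
                            condition = "all", half_width = 200L) {
  if (methods::is(centers, "GRanges")) {
    centers <- data.table(
      chrom = as.character(GenomicRanges::seqnames(centers)),
      pos = BiocGenerics::start(centers) - 1L)
  }
  ce <- as.data.table(centers)[, .(chrom = as.character(chrom),
                                   pos = as.integer(pos))]
  n <- nrow(ce)
  if (is.null(strata)) strata <- rep("all", n)
  if (length(strata) != n) stop("strata must align with centers")
  tr <- as.data.table(track)[, .(score = sum(score)), by = .(chrom, pos)]
  W <- as.integer(half_width)
  offs <- seq.int(-W, W)
  grid <- data.table(
    id = rep(seq_len(n), each = length(offs)),
    chrom = rep(ce$chrom, each = length(offs)),
    offset = rep(offs, times = n),
    stratum = rep(as.character(strata), each = length(offs))
  )
  grid[, pos := rep(ce$pos, each = length(offs)) + offset]
  grid[tr, score := i.score, on = .(chrom, pos)]
  grid[is.na(score), score := 0]
  grid[, total := sum(score), by = id]
  keep <- grid[total >= min_reads]
  if (nrow(keep) == 0L) {
    message("density_profile: no region passes the read threshold")
    out <- data.table(offset = integer(), density = numeric(),
                      n_regions = integer(), stratum = character(),
                      condition = character())
  } else {
    keep[, norm := score / total]
    out <- keep[, .(density = sum(norm) / uniqueN(id),
                    n_regions = uniqueN(id)),
                keyby = .(stratum, offset)]
    out[, condition := condition]
    setcolorder(out, c("offset", "density", "n_regions", "stratum", "condition"))
  }
  setattr(out, "class", c("density_profile", class(out)))
  out[]
}

#' Windowed offset-enrichment histogram
#'
#' Bins RE-center-to-CTSS offsets into contiguous windows of width
#' `ceiling(span / window)` across the +/- span/2 axis. Enrichment is the
#' observed bin fraction over the uniform expectation (proportional to the
#' number of valid offsets each bin covers); the expectation-weighted mean
#' enrichment is exactly 1 and bin fractions sum to 1.
#'
#' @param ctss Either a [signal_track()] (scores used as weights) or a
#'   data.frame with 0-based `chrom`/`pos`.
#' @param centers RE centers as in [density_profile()].
#' @param span Axis length in positions (default 401, i.e. +/- 200).
#' @param window Number of windows (default 19).
#' @return data.table: bin, offset_start, offset_end, fraction, expected,
#'   enrichment.
#' @export
offset_histogram <- function(ctss, centers, span = 401L, window = 19L) {
  if (methods::is(centers, "GRanges")) {
    centers <- data.table(
      chrom = as.character(GenomicRanges::seqnames(centers)),
      pos = BiocGenerics::start(centers) - 1L)
  }
  ce <- as.data.table(centers)[, .(chrom = as.character(chrom),
                                   pos = as.integer(pos))]
  ct <- as.data.table(ctss)
  if (!"score" %in% names(ct)) ct[, score := 1]
  ct <- ct[, .(score = sum(score)), by = .(chrom, pos)]
  half <- (as.integer(span) - 1L) %/% 2L
  ce[, `:=`(lo = pos - half, hi = pos + half, cpos = pos)]
  hits <- ct[ce, on = .(chrom, pos >= lo, pos <= hi),
             .(offset = x.pos - i.cpos, score = x.score),
             allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) stop("offset_histogram: no CTSS within span of any center")
  width <- ceiling(span / window)
  nbins <- ceiling(span / width)
  hits[, bin := pmin(((offset + half) %/% width) + 1L, nbins)]
  total <- sum(hits$score)
  obs <- hits[, .(fraction = sum(score) / total), keyby = bin]
  out <- data.table(bin = seq_len(nbins))
  out[, offset_start := -half + (bin - 1L) * width]
  out[, offset_end := pmin(offset_start + width - 1L, half)]
  out[, expected := (offset_end - offset_start + 1L) / span]
  out[obs, fraction := i.fraction, on = "bin"]
  out[is.na(fraction), fraction := 0]
  out[, enrichment := fraction / expected]
  out[]
}

#' Detect modal initiation offsets in a density profile
#'
#' Smooths the profile with a centered moving average of length
#' `smooth_bw`, finds local maxima (plateaus report their center), and
#' greedily keeps the top `n_modes` by height subject to a minimum
#' separation. Invariant under profile rescaling. Returns the offsets sorted
#' by height; if fewer maxima exist than requested, returns what exists with
#' attribute `incomplete = TRUE`.
#'
#' @param profile A [density_profile()] (single stratum/condition) or any
#'   table with `offset` and `density` columns.
#' @param n_modes Number of modes to report (default 2).
#' @param smooth_bw Moving-average window length (default 5).
#' @param min_sep Minimum separation between reported modes in bp.
#' @return Numeric offsets sorted by decreasing height, with attribute
#'   `heights` (and `incomplete` when applicable).
#' @export
peak_offsets <- function(profile, n_modes = 2L, smooth_bw = 5L, min_sep = 20L) {
  pr <- as.data.table(profile)
  if (nrow(pr) == 0L) stop("empty profile")
  if ("stratum" %in% names(pr) && length(unique(pr$stratum)) > 1L) {
    stop("profile holds multiple strata; filter to one before mode calling")
  }
  pr <- pr[order(offset)]
  v <- pr$density
  # moving average with edge replication
  k <- max(1L, as.integer(smooth_bw))
  halfk <- k %/% 2L
  padded <- c(rep(v[1L], halfk), v, rep(v[length(v)], halfk))
  sm <- as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2L))
  sm <- sm[(halfk + 1L):(halfk + length(v))]
  # plateau-aware local maxima
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nv <- length(r$values)
  prev <- c(-Inf, r$values[-nv])
  nxt <- c(r$values[-1L], -Inf)
  is_max <- r$values > prev & r$values > nxt
  cand_idx <- as.integer(floor((starts[is_max] + ends[is_max]) / 2))
  cand <- data.table(offset = pr$offset[cand_idx], height = sm[cand_idx])
  cand <- cand[order(-height, offset)]
  picked <- cand[0]
  for (i in seq_len(nrow(cand))) {
    if (nrow(picked) == 0L || all(abs(cand$offset[i] - picked$offset) >= min_sep)) {
      picked <- rbind(picked, cand[i])
    }
    if (nrow(picked) == n_modes) break
  }
  out <- picked$offset
  attr(out, "heights") <- picked$height
  if (length(out) < n_modes) attr(out, "incomplete") <- TRUE
  out
}
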