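# Core interval engine: BED/bedGraph I/O, overlap/merge/extend arithmetic,
# strand-aware 5' coverage tracks and CTSS summit calling.
#
# Convention fixed at the I/O boundary: files are 0-based half-open (BED);
# in-memory interval collections are GRanges (1-based closed). Single-base
# positions (CTSS, track entries) are 0-based throughout.

#' Read a BED3/BED6 file into a GRanges
#'
#' Tab-separated, headerless BED. Three columns give chrom/start/end; six add
#' name, score and strand (`.` maps to `*`). Coordinates are converted from
#' the file's 0-based half-open convention to 1-based closed `GRanges`.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`; for BED6 input with metadata columns `name` and
#'   `score`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\ts1\t0\t+", f)
#' read_bed(f)
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf >= 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  }
  ncol <- min(nf)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncol))), ncol = ncol, byrow = TRUE)
  ok_int <- function(x) grepl("^-?[0-9]+$", x)
  bad <- which(!(ok_int(m[, 2L]) & ok_int(m[, 3L])))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  }
  start0 <- as.integer(m[, 2L])
  end0 <- as.integer(m[, 3L])
  bad <- which(start0 < 0L | start0 >= end0)
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": requires 0 <= start < end")
  }
  if (ncol >= 6L) {
    str <- m[, 6L]
    bad <- which(!str %in% c("+", "-", "."))
    if (length(bad)) {
      stop("malformed BED line ", bad[1L], ": invalid strand '", str[bad[1L]], "'")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = m[, 1L],
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = ifelse(str == ".", "*", str)
    )
    S4Vectors::mcols(gr)$name <- m[, 4L]
    S4Vectors::mcols(gr)$score <- as.numeric(m[, 5L])
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = m[, 1L],
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
    )
  }
  gr
}

#' Write a GRanges as BED
#'
#' Writes BED6 when the input carries any of name/score/strand information,
#' BED3 otherwise. Output is sorted by (chrom, start, end) and 0-based
#' half-open; `write_bed(read_bed(x))` reproduces a sorted BED6 file
#' byte-for-byte.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param bed6 Force BED6 output (default: auto-detect).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, bed6 = NULL) {
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
  mc <- S4Vectors::mcols(gr)
  has_meta <- any(dt$strand != "*") || any(c("name", "score") %in% colnames(mc))
  if (is.null(bed6)) bed6 <- has_meta
  if (bed6) {
    dt[, name := if ("name" %in% colnames(mc)) as.character(mc$name) else "."]
    dt[, score := if ("score" %in% colnames(mc)) mc$score else 0]
    dt[, strand := ifelse(strand == "*", ".", strand)]
    out <- dt[order(chrom, start, end), .(chrom, start, end, name, score, strand)]
  } else {
    out <- dt[order(chrom, start, end), .(chrom, start, end)]
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Test each query interval for overlap with any subject interval
#'
#' Half-open adjacency does not count: intervals sharing only a boundary do
#' not overlap. Strand is ignored unless `match_strand = TRUE`, in which case
#' `*` still matches either strand (GRanges semantics).
#'
#' @param query,subjects `GRanges`.
#' @param match_strand Require strand compatibility (default `FALSE`).
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subjects, match_strand = FALSE) {
  if (length(subjects) == 0L) {
    return(rep(FALSE, length(query)))
  }
  IRanges::overlapsAny(query, subjects, ignore.strand = !match_strand)
}

#' Merge intervals lying within a maximum gap of each other
#'
#' Two intervals with `gap <= max_gap` intervening bases end up in one merged
#' interval (gap 0 means book-ended). Merging is per strand unless
#' `ignore_strand = TRUE`. Output is sorted and disjoint; the operation is
#' idempotent.
#'
#' @param x A `GRanges`.
#' @param max_gap Maximum allowed gap in bases (>= 0).
#' @param ignore_strand Merge across strands (default `FALSE`).
#' @return Merged, sorted `GRanges`.
#' @export
merge_within <- function(x, max_gap, ignore_strand = FALSE) {
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single nonnegative number")
  }
  GenomicRanges::reduce(x, min.gapwidth = max_gap + 1L, ignore.strand = ignore_strand)
}

#' Extend intervals upstream/downstream
#'
#' With `strand_aware = TRUE`, "upstream" is against the direction of
#' transcription, so minus-strand intervals extend their end coordinate.
#' Results are clipped at position 0 (file convention).
#'
#' @param x A `GRanges`.
#' @param upstream,downstream Nonnegative extensions in bases.
#' @param strand_aware Mirror extensions on the minus strand (default `TRUE`).
#' @return A `GRanges` with the same metadata columns.
#' @export
extend_intervals <- function(x, upstream = 0L, downstream = 0L, strand_aware = TRUE) {
  if (upstream < 0 || downstream < 0) stop("extensions must be >= 0")
  minus <- strand_aware & as.character(BiocGenerics::strand(x)) == "-"
  up <- ifelse(minus, downstream, upstream)
  dn <- ifelse(minus, upstream, downstream)
  new_start <- pmax(1L, BiocGenerics::start(x) - as.integer(up))
  new_end <- BiocGenerics::end(x) + as.integer(dn)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(x),
    ranges = IRanges::IRanges(start = new_start, end = new_end),
    strand = BiocGenerics::strand(x)
  )
  S4Vectors::mcols(out) <- S4Vectors::mcols(x)
  out
}

# ---- fragment / read normalization ------------------------------------------

# Normalize reads/fragments to a data.table with 0-based half-open
# chrom/start/end/strand columns. Accepts GRanges or any data.frame already in
# file convention.
as_frag_dt <- function(x) {
  if (methods::is(x, "GRanges")) {
    dt <- data.table(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = BiocGenerics::start(x) - 1L,
      end = BiocGenerics::end(x),
      strand = as.character(BiocGenerics::strand(x))
    )
  } else {
    dt <- as.data.table(x)
    if (!all(c("chrom", "start", "end") %in% names(dt))) {
      stop("fragment table requires chrom/start/end columns")
    }
    if (!"strand" %in% names(dt)) dt[, strand := "*"]
    dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), strand = as.character(strand))]
  }
  if (any(dt$start < 0L | dt$start >= dt$end)) {
    stop("fragments must satisfy 0 <= start < end")
  }
  dt
}

# ---- signal tracks ----------------------------------------------------------

#' Construct a sparse per-base signal track
#'
#' A signal track stores strictly positive per-base values sparsely
#' (absent = 0), optionally partitioned by strand. Positions are 0-based.
#'
#' @param chrom,pos,strand,score Parallel vectors; `strand` defaults to `*`.
#' @return A `signal_track` (a keyed `data.table`).
#' @export
signal_track <- function(chrom = character(), pos = integer(),
                         strand = rep("*", length(pos)), score = numeric()) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), score = as.numeric(score))
  dt <- dt[score != 0]
  if (any(dt$score < 0)) stop("signal track values must be nonnegative")
  dt <- dt[, .(score = sum(score)), by = .(chrom, strand, pos)]
  setkey(dt, chrom, strand, pos)
  setattr(dt, "class", c("signal_track", class(dt)))
  dt[]
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d positions, mass %.6g, strands {%s}\n",
              nrow(x), sum(x$score), paste(unique(x$strand), collapse = ",")))
  NextMethod()
}

#' Total mass of a signal track
#'
#' @param track A `signal_track`.
#' @param strand Optional strand filter (`"+"`, `"-"` or `"*"`).
#' @return Numeric scalar.
#' @export
track_mass <- function(track, strand = NULL) {
  if (is.null(strand)) return(sum(track$score))
  sum(track$score[track$strand == strand])
}

#' Per-strand 5'-end coverage from stranded reads
#'
#' Each plus-strand read contributes one count at its start, each minus-strand
#' read one count at `end - 1` (its 5' base under half-open coordinates).
#' Per-strand mass equals the per-strand read count.
#'
#' @param reads Stranded reads: a `GRanges` or a data.frame with 0-based
#'   half-open `chrom/start/end/strand`.
#' @return A `signal_track` partitioned by strand.
#' @export
five_prime_coverage <- function(reads) {
  dt <- as_frag_dt(reads)
  if (any(!dt$strand %in% c("+", "-"))) {
    stop("5' coverage requires stranded reads (+ or -)")
  }
  dt[, pos := ifelse(strand == "+", start, end - 1L)]
  signal_track(dt$chrom, dt$pos, dt$strand, rep(1, nrow(dt)))
}

#' Call CTSS summits inside merged peak intervals
#'
#' For every peak, the summit is the position of maximum 5'-coverage within
#' the peak on the peak's strand; ties resolve to the genomically leftmost
#' position. Peaks without any coverage are dropped (with a message).
#'
#' @param track A `signal_track` of 5' coverage.
#' @param peaks Disjoint stranded `GRanges` peaks.
#' @return `peaks` subset to covered peaks, with metadata columns `summit`
#'   (0-based position) and `total_count` (in-peak mass).
#' @export
call_ctss <- function(track, peaks) {
  if (length(peaks) == 0L) return(peaks)
  pk <- data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    strand = as.character(BiocGenerics::strand(peaks)),
    ps = BiocGenerics::start(peaks) - 1L,
    pe = BiocGenerics::end(peaks),
    id = seq_along(peaks)
  )
  tr <- as.data.table(track)
  hits <- tr[pk, on = .(chrom, strand, pos >= ps, pos < pe),
             .(id = i.id, pos = x.pos, score = x.score),
             allow.cartesian = TRUE, nomatch = NULL]
  n_covered <- length(unique(hits$id))
  if (n_covered < length(peaks)) {
    message("call_ctss: dropped ", length(peaks) - n_covered,
            " zero-coverage peak(s)")
  }
  if (nrow(hits) == 0L) return(peaks[0])
  stats <- hits[order(id, -score, pos),
                .(summit = pos[1L], total_count = sum(score)), by = id]
  out <- peaks[stats$id]
  S4Vectors::mcols(out)$summit <- stats$summit
  S4Vectors::mcols(out)$total_count <- stats$total_count
  out
}

# ---- bedGraph ---------------------------------------------------------------

#' Write a signal track as bedGraph
#'
#' Four 0-based half-open columns (chrom, start, end, value); consecutive
#' equal-valued positions are run-length compressed. Stranded tracks must be
#' written one strand at a time.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @param strand Strand to export for stranded tracks.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = NULL) {
  dt <- as.data.table(track)
  if (!is.null(strand)) dt <- dt[dt$strand == strand]
  if (length(unique(dt$strand)) > 1L) {
    stop("track has multiple strands; pass strand = to select one")
  }
  dt <- dt[order(chrom, pos)]
  if (nrow(dt) == 0L) {
    fwrite(data.table(), path, sep = "\t", col.names = FALSE)
    return(invisible(path))
  }
  dt[, run := cumsum(c(1L, as.integer(
    chrom[-1L] != chrom[-.N] | pos[-1L] != pos[-.N] + 1L | score[-1L] != score[-.N]
  )))]
  out <- dt[, .(chrom = chrom[1L], start = pos[1L], end = pos[.N] + 1L,
                value = score[1L]), by = run][, run := NULL]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a signal track
#'
#' @param path Path to a 4-column bedGraph.
#' @param strand Strand to assign to all entries (default `*`).
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, strand = "*") {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  if (nrow(dt) == 0L) return(signal_track())
  idx <- rep(seq_len(nrow(dt)), dt$end - dt$start)
  off <- sequence(dt$end - dt$start) - 1L
  signal_track(dt$chrom[idx], dt$start[idx] + off,
               rep(strand, length(idx)), dt$value[idx])
}
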