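test_that("BED6 parsing maps fields losslessly and round-trips byte-identically", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\ts1\t0\t+", f)
  gr <- read_bed(f)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr1")
  expect_equal(BiocGenerics::start(gr) - 1L, 100L)
  expect_equal(BiocGenerics::end(gr), 200L)
  expect_equal(as.character(BiocGenerics::strand(gr)), "+")
  expect_equal(S4Vectors::mcols(gr)$name, "s1")

  # empty file -> empty collection
  writeLines(character(), f)
  expect_length(read_bed(f), 0L)

  # 50-record sorted BED6 fixture round-trips byte-for-byte
  set.seed(11)
  x <- rand_intervals(50, max_pos = 50000)
  gr <- gr0(sample(c("chr1", "chr2"), 50, TRUE), x$start, x$end,
            sample(c("+", "-"), 50, TRUE))
  S4Vectors::mcols(gr)$name <- sprintf("r%02d", 1:50)
  S4Vectors::mcols(gr)$score <- sample(0:1000, 50, TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(gr, f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed BED lines raise errors naming the line number", {
  f <- tempfile()
  writeLines(c("chr1\t10\t20", "chr1\tten\t20"), f)
  expect_error(read_bed(f), "line 2.*non-integer")
  writeLines(c("chr1\t30\t25"), f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t10\t20\tx\t0\tz"), f)
  expect_error(read_bed(f), "strand")
})

test_that("overlap testing uses half-open semantics and handles empty subjects", {
  q <- gr0("chr1", 100, 200)
  expect_true(overlaps_any(q, gr0("chr1", 199, 300)))   # 1-base overlap
  expect_false(overlaps_any(q, gr0("chr1", 200, 300)))  # adjacency
  expect_false(overlaps_any(q, GenomicRanges::GRanges()))
})

test_that("merge_within bridges gaps up to max_gap and is idempotent", {
  x <- gr0("chr1", c(0, 55), c(10, 60))
  m <- merge_within(x, 50)                   # gap 45 merges
  expect_equal(BiocGenerics::start(m) - 1L, 0L)
  expect_equal(BiocGenerics::end(m), 60L)
  x2 <- gr0("chr1", c(0, 61), c(10, 70))     # gap 51 does not
  expect_length(merge_within(x2, 50), 2L)
  set.seed(3)
  y <- with(rand_intervals(30), gr0("chr1", start, end))
  expect_identical(merge_within(merge_within(y, 25), 25), merge_within(y, 25))
  expect_error(merge_within(y, -1), "nonnegative")
})

test_that("interval extension is strand-aware and clips at the origin", {
  p <- extend_intervals(gr0("chr1", 500, 510, "+"), upstream = 200)
  expect_equal(c(BiocGenerics::start(p) - 1L, BiocGenerics::end(p)), c(300L, 510L))
  m <- extend_intervals(gr0("chr1", 500, 510, "-"), upstream = 200)
  expect_equal(c(BiocGenerics::start(m) - 1L, BiocGenerics::end(m)), c(500L, 710L))
  e <- extend_intervals(gr0("chr1", 50, 60, "+"), upstream = 200)
  expect_equal(BiocGenerics::start(e) - 1L, 0L)
  expect_error(extend_intervals(p, upstream = -5), ">= 0")
})

test_that("5' coverage follows strand conventions and conserves read counts", {
  plus <- data.frame(chrom = "chr1", start = 100, end = 150, strand = "+")
  tr <- five_prime_coverage(plus)
  expect_equal(tr$pos, 100L)
  minus <- data.frame(chrom = "chr1", start = 100, end = 150, strand = "-")
  tr <- five_prime_coverage(minus)
  expect_equal(tr$pos, 149L)
  expect_error(five_prime_coverage(data.frame(chrom = "chr1", start = 1,
                                              end = 5, strand = "*")),
               "stranded")
  set.seed(5)
  n <- 10000L
  reads <- data.frame(chrom = "chr1",
                      start = sample.int(1e5, n, TRUE),
                      strand = sample(c("+", "-"), n, TRUE))
  reads$end <- reads$start + 30L
  tr <- five_prime_coverage(reads)
  expect_equal(track_mass(tr, "+"), sum(reads$strand == "+"))
  expect_equal(track_mass(tr, "-"), sum(reads$strand == "-"))
})

test_that("CTSS summits are in-peak argmax positions with leftmost ties", {
  tr <- signal_track(rep("chr1", 3), c(100, 101, 102), rep("+", 3), c(5, 9, 3))
  pk <- call_ctss(tr, gr0("chr1", 95, 110, "+"))
  expect_equal(S4Vectors::mcols(pk)$summit, 101L)
  expect_equal(S4Vectors::mcols(pk)$total_count, 17)

  tr2 <- signal_track(rep("chr1", 2), c(100, 102), rep("+", 2), c(5, 5))
  pk2 <- call_ctss(tr2, gr0("chr1", 95, 110, "+"))
  expect_equal(S4Vectors::mcols(pk2)$summit, 100L)

  expect_message(
    dropped <- call_ctss(tr, gr0("chr1", c(95, 500), c(110, 600), "+")),
    "zero-coverage")
  expect_length(dropped, 1L)

  # exhaustive scan over random peaks, plus order invariance
  set.seed(8)
  pos <- sort(sample.int(5000, 400))
  sc <- sample.int(20, 400, TRUE)
  tr3 <- signal_track(rep("chr1", 400), pos, rep("+", 400), sc)
  pstart <- seq(0, 4900, by = 49)[1:100]
  peaks <- gr0("chr1", pstart, pstart + 45, "+")
  called <- call_ctss(tr3, peaks)
  idx <- match(paste(BiocGenerics::start(called), BiocGenerics::end(called)),
               paste(BiocGenerics::start(peaks), BiocGenerics::end(peaks)))
  for (i in seq_along(called)) {
    o <- bf_summit(pos, sc, pstart[idx[i]], pstart[idx[i]] + 45)
    expect_equal(S4Vectors::mcols(called)$summit[i], o$summit)
    expect_equal(S4Vectors::mcols(called)$total_count[i], o$total)
    expect_true(S4Vectors::mcols(called)$summit[i] >=
                  BiocGenerics::start(called)[i] - 1L)
    expect_true(S4Vectors::mcols(called)$summit[i] < BiocGenerics::end(called)[i])
  }
  perm <- sample(length(peaks))
  called_perm <- call_ctss(tr3, peaks[perm])
  expect_equal(sort(S4Vectors::mcols(called_perm)$summit),
               sort(S4Vectors::mcols(called)$summit))
})

test_that("bedGraph round-trips a sparse track through run-length form", {
  tr <- signal_track(rep("chr1", 5), c(10, 11, 12, 20, 21), rep("*", 5),
                     c(2, 2, 3, 1, 1))
  f <- tempfile()
  write_bedgraph(tr, f)
  lines <- readLines(f)
  expect_equal(lines[1], "chr1\t10\t12\t2")
  back <- read_bedgraph(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))
})
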