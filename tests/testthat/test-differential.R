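test_that("region counting assigns reads to every overlapped region", {
  regions <- gr0("chr1", c(100, 150), c(200, 250))
  frags <- data.frame(chrom = "chr1", start = c(120, 160), end = c(180, 190),
                      strand = "*")
  rc <- count_regions(list(s1 = frags), regions, "control", "none")
  expect_equal(unname(rc$counts[, 1]), c(2L, 2L))  # both fragments hit both regions
})

test_that("stranded 5' counting follows sense and reverse conventions", {
  region_plus <- gr0("chr1", 100, 200, "+")
  read_minus <- data.frame(chrom = "chr1", start = 120, end = 150, strand = "-")
  rc_rev <- count_regions(list(s = read_minus), region_plus, "control", "reverse")
  expect_equal(unname(rc_rev$counts[, 1]), 1L)     # opposite strand counts
  rc_sense <- count_regions(list(s = read_minus), region_plus, "control", "sense")
  expect_equal(unname(rc_sense$counts[, 1]), 0L)
  unstranded <- data.frame(chrom = "chr1", start = 120, end = 150, strand = "*")
  expect_error(count_regions(list(s = unstranded), region_plus, "control",
                             "reverse"),
               "stranded")
})

test_that("counting matches the brute-force incidence oracle and is order-invariant", {
  set.seed(21)
  for (i in 1:30) {
    reads <- rand_intervals(12, max_pos = 2000, max_len = 120)
    regions_df <- rand_intervals(6, max_pos = 2000, max_len = 250)
    regions <- gr0(regions_df$chrom, regions_df$start, regions_df$end)
    reads$strand <- "*"
    rc <- count_regions(list(a = reads), regions, "control", "none")
    expect_equal(sum(rc$counts), bf_incidences(reads, regions_df))
    perm <- reads[sample(nrow(reads)), ]
    rc2 <- count_regions(list(a = perm), regions, "control", "none")
    expect_identical(rc$counts, rc2$counts)
  }
})

test_that("size factors are symmetric, scale-equivariant and match hand computation", {
  m <- matrix(rep(c(10L, 40L, 7L, 100L, 25L), 4), ncol = 4)
  expect_equal(size_factors(m), rep(1, 4))

  m2 <- m; m2[, 3] <- m2[, 3] * 2L
  sf1 <- size_factors(m); sf2 <- size_factors(m2)
  expect_equal(sf2[3] / sf2[1], 2 * sf1[3] / sf1[1], tolerance = 1e-12)
  expect_equal(exp(mean(log(sf2))), 1, tolerance = 1e-12)

  # direct median-of-ratios hand computation on a 5x4 matrix
  set.seed(2)
  m3 <- matrix(rpois(20, 50) + 1L, ncol = 4)
  ref <- exp(rowMeans(log(m3)))
  hand <- apply(m3, 2, function(col) median(col / ref))
  hand <- hand / exp(mean(log(hand)))
  expect_equal(size_factors(m3), hand, tolerance = 1e-12)

  expect_error(size_factors(matrix(0L, 3, 2)), "all-zero")
})

test_that("NB test is symmetric under equal means and requires replication", {
  cnt <- matrix(rep(c(50L, 200L, 10L, 80L), 4), ncol = 4)
  rc <- region_counts(gr0("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350)),
                      cnt, c("control", "control", "treated", "treated"))
  res <- nb_diff(rc)
  expect_equal(res$log2fc, rep(0, 4))
  expect_true(all(res$pvalue == 1))

  rc1 <- region_counts(gr0("chr1", 0, 50), matrix(c(5L, 9L), 1),
                       c("control", "treated"))
  expect_error(nb_diff(rc1), "2 replicates")
})

test_that("spiked effects are recovered by the NB test at moderate depth", {
  set.seed(31)
  n <- 300L; mu <- rep(500, n); spiked <- 1:20
  mu_t <- mu; mu_t[spiked] <- mu[spiked] * 4
  cnt <- cbind(vapply(1:4, function(j) rnbinom(n, mu = mu, size = 20), numeric(n)),
               vapply(1:4, function(j) rnbinom(n, mu = mu_t, size = 20), numeric(n)))
  storage.mode(cnt) <- "integer"
  rc <- region_counts(gr0("chr1", seq_len(n) * 500, seq_len(n) * 500 + 100),
                      cnt, rep(c("control", "treated"), each = 4))
  res <- nb_diff(rc)
  expect_lt(abs(mean(res$log2fc[spiked]) - 2), 0.3)
  expect_true(all(res$padj[spiked] < 0.1))
  expect_lt(abs(mean(res$log2fc[-spiked])), 0.1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)                      # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))                  # hand step-up
  set.seed(7)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))            # monotone in p-rank
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential classification applies strict thresholds", {
  expect_equal(classify_differential(1.2, 0.05), "increased")
  expect_equal(classify_differential(1.2, 0.2), "unchanged")
  expect_equal(classify_differential(-1.0, 0.01), "unchanged")  # boundary strict
  expect_equal(classify_differential(-1.4, 0.02), "decreased")
  expect_equal(classify_differential(c(2, 0, -2), c(0.01, 0.01, 0.01)),
               c("increased", "unchanged", "decreased"))
})
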