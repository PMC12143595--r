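test_that("mono-nucleosome filtering is exact at the stated boundaries", {
  frags <- data.frame(chrom = "chr1", start = c(0, 0, 0, 0, 0),
                      end = c(179, 180, 200, 240, 241))
  tr <- mono_occupancy(frags)
  # 179 and 241 excluded; 180, 200, 240 retained
  expect_equal(track_mass(tr), 1e6)  # 3 fragments, CPM scale
  tr_single <- mono_occupancy(data.frame(chrom = "chr1", start = 100, end = 300))
  expect_equal(nrow(tr_single), 200L)
  expect_true(all(abs(tr_single$score - 1e6 / 200) < 1e-9))
  expect_equal(range(tr_single$pos), c(100L, 299L))
  expect_message(mono_occupancy(data.frame(chrom = "chr1", start = 0, end = 50)),
                 "no fragments")
})

test_that("mass is conserved before CPM scaling", {
  set.seed(61)
  n <- 500L
  start <- sample.int(1e5, n)
  frags <- data.frame(chrom = "chr1", start = start,
                      end = start + sample(120:300, n, TRUE))
  kept <- sum(frags$end - frags$start >= 180 & frags$end - frags$start <= 240)
  tr <- mono_occupancy(frags)
  expect_equal(track_mass(tr) * kept / 1e6, kept, tolerance = 1e-6)
})

test_that("anchored profiles spike at the anchor and mirror on strand flip", {
  tr <- signal_track("chr1", 1000L, "*", 5)
  p <- anchored_profile(tr, data.frame(chrom = "chr1", pos = 1000, strand = "+"),
                        half_width = 50)
  expect_equal(p$mean[p$offset == 0], 5)
  expect_equal(sum(p$mean), 5)

  tr2 <- signal_track(c("chr1", "chr1"), c(990L, 1020L), c("*", "*"), c(2, 7))
  plus <- anchored_profile(tr2, data.frame(chrom = "chr1", pos = 1000,
                                           strand = "+"), 50)
  minus <- anchored_profile(tr2, data.frame(chrom = "chr1", pos = 1000,
                                            strand = "-"), 50)
  expect_equal(plus$mean, rev(minus$mean))
})

test_that("anchored profiles equal the brute-force window average and are linear", {
  set.seed(62)
  pos <- sample.int(5000, 300)
  sc <- runif(300, 0, 4)
  tr <- signal_track(rep("chr1", 300), pos, rep("*", 300), sc)
  anchors <- data.frame(chrom = "chr1", pos = sample(500:4500, 7), strand = "+")
  W <- 100L
  p <- anchored_profile(tr, anchors, W)
  dense <- numeric(6001); names(dense) <- 0:6000
  agg <- tapply(sc, pos, sum)
  dense[as.integer(names(agg)) + 1L] <- agg
  manual <- sapply(-W:W, function(o) mean(dense[anchors$pos + o + 1L]))
  expect_equal(p$mean, unname(manual))

  tr_b <- signal_track(rep("chr1", 300), pos, rep("*", 300), sc * 3)
  p_b <- anchored_profile(tr_b, anchors, W)
  expect_equal(p_b$mean, 3 * p$mean, tolerance = 1e-12)
})

test_that("eviction and shift scores respond to construction", {
  offs <- -300:300
  set.seed(63)
  base <- 1 + 0.8 * cos(2 * pi * offs / 190) + 0.05 * rnorm(length(offs))
  mk <- function(v) {
    structure(data.table::data.table(offset = offs, mean = v),
              class = c("occupancy_profile", "data.table", "data.frame"))
  }
  same <- eviction_shift(mk(base), mk(base))
  expect_equal(same$eviction, 0)
  expect_equal(same$shift, 0L)

  gone <- base; gone[abs(offs) <= 73] <- 0
  ev <- eviction_shift(mk(base), mk(gone))
  expect_gt(ev$eviction, 0)

  # flanks translated 30 bp away from the center on both sides
  shifted <- base
  right <- which(offs > 73); left <- which(offs < -73)
  shifted[right] <- base[pmax(right - 30L, min(right))]
  shifted[left] <- base[pmin(left + 30L, max(left))]
  sh <- eviction_shift(mk(base), mk(shifted))
  expect_true(sh$shift_defined)
  expect_lte(abs(sh$shift - 30L), 2L)

  flat <- mk(rep(2, length(offs)))
  und <- eviction_shift(flat, flat)
  expect_false(und$shift_defined)
})

test_that("simulated opened sites show eviction while closed sites do not", {
  sim <- simulate_multiome(small_config(seed = 71, n_sites = 120L, depth = 6e4))
  mono_c <- mono_occupancy(data.table::rbindlist(sim$fragments$atac$control))
  mono_t <- mono_occupancy(data.table::rbindlist(sim$fragments$atac$treated))
  grp <- function(sel) {
    anchors <- data.frame(chrom = sim$truth$chrom[sel],
                          pos = sim$truth$center[sel], strand = "*")
    eviction_shift(anchored_profile(mono_c, anchors, 400),
                   anchored_profile(mono_t, anchors, 400))
  }
  opened <- which(!sim$truth$open_control & sim$truth$open_treated)
  closed <- which(!sim$truth$open_control & !sim$truth$open_treated)
  expect_gt(grp(opened)$eviction, 0)
  expect_lt(abs(grp(closed)$eviction), grp(opened)$eviction / 3)
})
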