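test_that("accessibility transitions cover the four condition combinations", {
  sites <- gr0("chr1", c(100, 500, 900, 1300), c(200, 600, 1000, 1400))
  pk_c <- gr0("chr1", c(120, 920), c(180, 980))    # open at sites 1, 3
  pk_t <- gr0("chr1", c(120, 520), c(180, 580))    # open at sites 1, 2
  expect_equal(classify_accessibility(sites, pk_c, pk_t),
               c("constitutively_open", "opened", "putatively_closed",
                 "constitutively_closed"))
})

test_that("transition labels partition any random site set", {
  set.seed(14)
  for (i in 1:10) {
    sites_df <- rand_intervals(40, max_pos = 20000, max_len = 300)
    sites <- gr0(sites_df$chrom, sites_df$start, sites_df$end)
    pk_c <- with(rand_intervals(15, 20000, 400), gr0("chr1", start, end))
    pk_t <- with(rand_intervals(15, 20000, 400), gr0("chr1", start, end))
    lab <- classify_accessibility(sites, pk_c, pk_t)
    expect_length(lab, 40L)
    expect_true(all(lab %in% c("constitutively_open", "opened",
                               "constitutively_closed", "putatively_closed")))
  }
})

test_that("18-state labels collapse to the four-state scheme", {
  expect_equal(collapse_state("TssBiv"), "promoter")
  expect_equal(collapse_state("EnhWk"), "enhancer")
  expect_equal(collapse_state(c("Tx", "TxWk")), rep("transcription", 2))
  expect_equal(collapse_state(c("Het", "ZNF/Rpts", "ReprPCWk")),
               rep("quiescent", 3))
  expect_equal(collapse_state("UnknownState"), "n/a")
  # all 18 members map to their own state
  expect_equal(collapse_state(c("TssA", "TssFlnk", "TssFlnkD", "TssFlnkU")),
               rep("promoter", 4))
  expect_equal(collapse_state(c("EnhA1", "EnhA2", "EnhBiv", "EnhG1", "EnhG2")),
               rep("enhancer", 5))
  expect_equal(collapse_state(c("Quies", "ReprPC")), rep("quiescent", 2))
})

test_that("sites inherit the collapsed state of their dominant segment", {
  sites <- gr0("chr1", c(100, 500), c(200, 600))
  states <- gr0("chr1", c(0, 150, 700), c(150, 400, 800))
  S4Vectors::mcols(states)$name <- c("TssA", "EnhA1", "Quies")
  # site 1 overlaps TssA by 50 and EnhA1 by 50 -> tie resolves to first sorted
  expect_equal(assign_state(sites, states), c("promoter", "n/a"))
})

test_that("TSS status applies the induced threshold with induced dominance", {
  site <- gr0("chr1", 1000, 1400)
  pk <- function(s, e, strand, lfc) {
    g <- gr0("chr1", s, e, strand)
    S4Vectors::mcols(g)$log2fc <- lfc
    g
  }
  expect_equal(tss_status(site, pk(1100, 1120, "+", 0.8)), "induced")
  expect_equal(tss_status(site, pk(1100, 1120, "+", 0.2)), "uninduced")
  expect_equal(tss_status(site, pk(5000, 5020, "+", 2)), "none")
  both <- c(pk(1100, 1120, "+", 0.2), pk(1200, 1220, "+", 0.9))
  expect_equal(tss_status(site, both), "induced")
  # 200 bp upstream extension (strand-aware) creates the overlap on +
  expect_equal(tss_status(site, pk(1450, 1470, "+", 1)), "induced")
  expect_equal(tss_status(site, pk(1450, 1470, "-", 1)), "none")
})

test_that("RE status distinguishes canonical, noncanonical and absent elements", {
  expect_equal(re_status("two_half_sites_no_spacer"), "canonical")
  expect_equal(re_status(c("spacer1_half_sites", "three_quarter_sites",
                           "single_half_site")),
               rep("noncanonical", 3))
  expect_equal(re_status("none"), "none")
  expect_error(re_status("quintuple_sites"), "unknown RE subtype")
})

test_that("layer summaries normalize and are invariant to site order", {
  df <- data.frame(acc = rep(c("open", "closed"), c(3, 7)),
                   st = rep(c("promoter", "quiescent"), 5))
  s <- summarize_layers(df)
  expect_equal(s$total, 10L)
  expect_equal(sum(s$axis$acc$count), 10L)
  expect_equal(sum(s$axis$acc$fraction), 1)
  expect_true(abs(sum(s$axis$st$percent) - 100) <= 1)
  s2 <- summarize_layers(df[sample(10), , drop = FALSE])
  expect_equal(s$axis$acc[order(level)], s2$axis$acc[order(level)])
  expect_equal(as.vector(s$pairs[["acc:st"]]), as.vector(s2$pairs[["acc:st"]]))
  s0 <- summarize_layers(df[0, , drop = FALSE])
  expect_equal(s0$total, 0L)
})

test_that("sigmoid fit recovers noise-free parameters and beats a line on sigmoid data", {
  set.seed(51)
  x <- 10^runif(80, -1, 3)
  truth <- c(a = 0.3, b = 2.8, x0 = 1.2, k = 0.3)
  f <- function(lx) truth["a"] + (truth["b"] - truth["a"]) /
    (1 + exp(-(lx - truth["x0"]) / truth["k"]))
  fit0 <- fit_occupancy_response(x, f(log10(x)))
  expect_true(fit0$converged)
  expect_lt(abs(fit0$params["x0"] - truth["x0"]), 1e-3)
  expect_gt(fit0$r2, 0.999)

  y <- f(log10(x)) + rnorm(80, sd = 0.25)
  fit1 <- fit_occupancy_response(x, y)
  lin <- summary(lm(y ~ log10(x)))$r.squared
  expect_gte(fit1$r2, lin)
  expect_gt(fit1$rho, 0.5)

  flat <- fit_occupancy_response(x, rep(1.5, 80))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$rho))

  expect_error(fit_occupancy_response(x[1:5], y[1:5]), ">= 10")
})

test_that("occupancy is reported in CPM over the site interval", {
  sites <- gr0("chr1", c(100, 1000), c(300, 1200))
  frags <- data.frame(chrom = "chr1",
                      start = c(rep(150, 30), rep(1050, 10), rep(5000, 60)),
                      end = c(rep(250, 30), rep(1150, 10), rep(5100, 60)))
  occ <- compute_occupancy(sites, frags)
  expect_equal(occ, c(30, 10) / 100 * 1e6)
})
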