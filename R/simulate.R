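# Ground-truthed multi-omics simulator.
#
# Emulates the signal structure the downstream analysis assumes: binding
# sites with log-normal occupancy, response-element classes, chromatin
# states, nucleosome-depleted regions flanked by positioned nucleosomes at
# open sites, condition-dependent fragment/5'-read counts with
# negative-binomial replicate noise, and CAGE initiation offsets
# concentrated at 0 and +50 bp from RE centers.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_multiome()]. Defaults
#' define the package's reference study conditions: 500 sites on 2 x 1 Mb
#' chromosomes, 4 replicates per condition, 1e5 fragments per library,
#' RE-class frequencies matching the recurrent-binding-site annotation
#' (canonical 0.699 / noncanonical 0.179 / none 0.122), and a TSS initiation
#' offset mixture with modes at 0 and +50 bp (sd 5).
#'
#' @param n_chroms,chrom_length Genome shape.
#' @param n_sites Number of binding sites.
#' @param site_width Width of each site interval (bp).
#' @param re_class_probs Probabilities over canonical/noncanonical/none.
#' @param state_probs Probabilities over the four collapsed chromatin states.
#' @param occupancy_meanlog,occupancy_sdlog Log-normal law for site occupancy
#'   (CPM units).
#' @param open_fraction_baseline Overall fraction of sites open in the
#'   control condition (state-dependent shifts applied around it).
#' @param opening_midpoint,opening_slope Logistic law (in log10 occupancy)
#'   for the probability that a closed site opens under treatment.
#' @param effect_access_opened,effect_access_open True accessibility log2FC
#'   at sites that open, and at constitutively open sites.
#' @param effect_h3k4me1,effect_h3k27ac Maximal histone-mark log2FC.
#' @param cage_sigmoid Named vector (a, b, x0, k): true CAGE log2FC as a
#'   sigmoid of log10 occupancy.
#' @param tss_offset_centers,tss_offset_weights,tss_offset_sd Gaussian
#'   mixture of initiation offsets from the RE center (bp).
#' @param n_background_tss Number of stable (condition-independent)
#'   housekeeping TSSs; these anchor the CAGE peak landscape so library
#'   normalization is not driven by the induced sites, as in real data where
#'   the vast majority of TSSs do not respond to treatment.
#' @param nb_dispersion Negative-binomial dispersion (variance = mu + a*mu^2).
#' @param n_replicates Replicates per condition (all assays).
#' @param depth Expected fragments per library.
#' @param chip_depth Expected fragments in the binding (ChIP-like) library;
#'   deeper than the per-condition assays so occupancy (CPM) is measurable
#'   per site.
#' @param background_frac Fraction of each library that is uniform background.
#' @param n_genes,n_linked_genes Size of the gene table and the number of
#'   genes wired to induced bound enhancers.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 1e6,
                       n_sites = 500L,
                       site_width = 400L,
                       re_class_probs = c(canonical = 0.699, noncanonical = 0.179,
                                          none = 0.122),
                       state_probs = c(promoter = 0.15, enhancer = 0.25,
                                       transcription = 0.25, quiescent = 0.35),
                       occupancy_meanlog = log(5),
                       occupancy_sdlog = 1,
                       open_fraction_baseline = 0.27,
                       opening_midpoint = log10(8),
                       opening_slope = 2.5,
                       effect_access_opened = 4,
                       effect_access_open = 0.7,
                       effect_h3k4me1 = 1.5,
                       effect_h3k27ac = 1.5,
                       cage_sigmoid = c(a = 0, b = 4, x0 = log10(8), k = 0.25),
                       tss_offset_centers = c(0, 50),
                       tss_offset_weights = c(0.5, 0.5),
                       tss_offset_sd = 5,
                       n_background_tss = 300L,
                       nb_dispersion = 0.05,
                       n_replicates = 4L,
                       depth = 1e5,
                       chip_depth = 2e6,
                       background_frac = 0.3,
                       n_genes = 60L,
                       n_linked_genes = 12L,
                       seed = 1L) {
  cfg <- as.list(environment())
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be nonnegative and sum to 1")
    }
  }
  check_probs(cfg$re_class_probs, "re_class_probs")
  check_probs(cfg$state_probs, "state_probs")
  check_probs(cfg$tss_offset_weights, "tss_offset_weights")
  if (cfg$depth < 1 || cfg$n_replicates < 1) {
    stop("depth and n_replicates must be >= 1")
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (length(cfg$tss_offset_centers) != length(cfg$tss_offset_weights)) {
    stop("tss_offset_centers and tss_offset_weights lengths differ")
  }
  cfg$null_effects <- FALSE
  structure(cfg, class = "sim_config")
}

# NB draw parameterized by mean and dispersion (variance = mu + disp*mu^2);
# dispersion 0 degenerates to Poisson.
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Members of each collapsed chromatin state in the 18-state segmentation.
.STATE18 <- list(
  promoter = c("TssA", "TssBiv", "TssFlnk", "TssFlnkD", "TssFlnkU"),
  enhancer = c("EnhA1", "EnhA2", "EnhBiv", "EnhG1", "EnhG2", "EnhWk"),
  transcription = c("Tx", "TxWk"),
  quiescent = c("Het", "Quies", "ReprPC", "ReprPCWk", "ZNF/Rpts")
)

.NONCANONICAL_SUBTYPES <- c("three_quarter_sites", "spacer1_half_sites",
                            "single_half_site")

sample_offsets <- function(n, centers, weights, sd) {
  comp <- sample.int(length(centers), n, replace = TRUE, prob = weights)
  round(rnorm(n, mean = centers[comp], sd = sd))
}

# Uniform background fragments over the genome.
background_frags <- function(n, chroms, chrom_length, len_min, len_max,
                             stranded = FALSE) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample.int(len_max - len_min + 1L, n, replace = TRUE) + len_min - 1L
  start <- floor(runif(n, 0, chrom_length - len_max - 1))
  data.table(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len),
             strand = if (stranded) sample(c("+", "-"), n, replace = TRUE) else "*")
}

# Expand per-site fragment counts into fragments centered near `center` with
# Gaussian positional jitter and uniform integer lengths in [len_min, len_max].
site_frags <- function(counts, chrom, center, pos_sd, len_min, len_max,
                       chrom_length, stranded = FALSE) {
  idx <- rep(seq_along(counts), counts)
  n <- length(idx)
  if (n == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  len <- sample.int(len_max - len_min + 1L, n, replace = TRUE) + len_min - 1L
  ctr <- center[idx] + rnorm(n, sd = pos_sd)
  start <- pmax(0L, pmin(as.integer(round(ctr - len / 2)),
                         as.integer(chrom_length - len_max - 1L)))
  data.table(chrom = chrom[idx], start = start, end = start + len,
             strand = if (stranded) sample(c("+", "-"), n, replace = TRUE) else "*")
}

#' Simulate a ground-truthed multi-omics dataset
#'
#' Generates binding sites with graded occupancy, RE classes and chromatin
#' states; condition-dependent ATAC (sub-nucleosomal < 120 bp and
#' mono-nucleosome 180-240 bp fragment classes, nucleosome-depleted regions
#' with positioned flanking nucleosomes at open sites), H3K4me1/H3K27ac
#' CUT&Tag-like fragments, stranded CAGE 5' reads with initiation offsets
#' from the configured mixture, one binding (ChIP-like) library, an
#' 18-state segmentation, enhancer-gene pairs and a gene differential table.
#' Replicate counts are negative-binomial around condition means. Open/closed
#' ground truth is defined by simulated nucleosome eviction, independent of
#' any classifier rule. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `truth` (per-site data.table), `sites`
#'   (GRanges), `states` (GRanges, 18-state labels in `name`), `fragments`
#'   (nested list assay -> condition -> replicate data.tables), `cage`
#'   (condition -> replicate stranded read tables), `chip` (one fragment
#'   table), `pairs`, `genes`, and `config`.
#' @export
simulate_multiome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  L <- cfg$chrom_length
  nS <- cfg$n_sites
  null <- isTRUE(cfg$null_effects)

  # --- site placement: non-overlapping slots, >= 2 kb apart -----------------
  slot_pitch <- max(cfg$site_width + 2100L, 2500L)
  slots <- data.table(
    chrom = rep(chroms, each = floor((L - 4000) / slot_pitch)),
    pos = rep(seq(2000L, by = slot_pitch,
                  length.out = floor((L - 4000) / slot_pitch)),
              times = cfg$n_chroms)
  )
  if (nS > nrow(slots)) stop("n_sites too large for genome size")
  picked <- slots[sort(sample.int(nrow(slots), nS))]
  start0 <- picked$pos + sample.int(500L, nS, replace = TRUE)
  truth <- data.table(
    site_id = sprintf("site_%04d", seq_len(nS)),
    chrom = picked$chrom,
    start = start0,
    end = start0 + cfg$site_width,
    center = start0 + as.integer(cfg$site_width / 2)
  )

  # --- annotations and occupancy -------------------------------------------
  truth[, re_class := sample(names(cfg$re_class_probs), nS, replace = TRUE,
                             prob = cfg$re_class_probs)]
  truth[, re_subtype := fifelse(
    re_class == "canonical", "two_half_sites_no_spacer",
    fifelse(re_class == "none", "none",
            sample(.NONCANONICAL_SUBTYPES, nS, replace = TRUE)))]
  truth[, re_center := fifelse(re_class == "none", NA_integer_, center)]
  truth[, state := sample(names(cfg$state_probs), nS, replace = TRUE,
                          prob = cfg$state_probs)]
  truth[, state18 := vapply(state, function(s) sample(.STATE18[[s]], 1L), "")]
  truth[, occupancy := rlnorm(nS, cfg$occupancy_meanlog, cfg$occupancy_sdlog)]
  log_occ <- log10(truth$occupancy)

  # --- openness ground truth (defines nucleosome architecture) --------------
  state_shift <- c(promoter = 2, enhancer = 1, transcription = -1, quiescent = -2)
  p_open <- plogis(qlogis(cfg$open_fraction_baseline) +
                     state_shift[truth$state] +
                     0.5 * (log_occ - mean(log_occ)))
  truth[, open_control := runif(nS) < p_open]
  p_gain <- plogis(cfg$opening_slope * (log_occ - cfg$opening_midpoint))
  truth[, open_treated := open_control | (!null & runif(nS) < p_gain)]

  # --- true per-assay effects ----------------------------------------------
  sg <- cfg$cage_sigmoid
  truth[, lfc_access := fifelse(open_control & open_treated, cfg$effect_access_open,
                        fifelse(!open_control & open_treated, cfg$effect_access_opened, 0))]
  hist_scale <- plogis(2 * (log_occ - cfg$opening_midpoint))
  truth[, lfc_h3k4me1 := cfg$effect_h3k4me1 * hist_scale]
  truth[, lfc_h3k27ac := cfg$effect_h3k27ac * hist_scale]
  truth[, lfc_cage := sg[["a"]] + (sg[["b"]] - sg[["a"]]) /
          (1 + exp(-(log_occ - sg[["x0"]]) / sg[["k"]]))]
  if (null) truth[, c("lfc_access", "lfc_h3k4me1", "lfc_h3k27ac", "lfc_cage") := 0]

  reps <- seq_len(cfg$n_replicates)
  conds <- c("control", "treated")
  disp <- cfg$nb_dispersion
  sig_depth <- cfg$depth * (1 - cfg$background_frac)
  bg_n <- cfg$depth * cfg$background_frac

  # --- ATAC: sub-nucleosomal + mono-nucleosome fragments --------------------
  # short-fragment mean scales with openness; closed-site leak fixes the true
  # accessibility log2FC at the configured effect sizes
  m_short_open <- 0.45 * sig_depth / nS
  atac <- list()
  for (cond in conds) {
    open_now <- if (cond == "treated") truth$open_treated else truth$open_control
    leak <- 2^(-cfg$effect_access_opened)
    short_mu <- m_short_open * ifelse(open_now, 1, leak)
    # constitutively open sites gain accessibility under treatment
    if (cond == "treated" && !null) {
      both <- truth$open_control & truth$open_treated
      short_mu[both] <- short_mu[both] * 2^cfg$effect_access_open
    }
    # nucleosome dyads: open sites have an NDR with flanking nucleosomes,
    # closed sites carry nucleosomes tight around the RE
    dyads_open <- c(-165L, 165L, -330L, 330L)
    dyads_closed <- c(-95L, 95L, -285L, 285L)
    m_mono <- 0.40 * sig_depth / (nS * 4L)
    for (r in reps) {
      short <- site_frags(rnb(nS, short_mu, disp), truth$chrom, truth$center,
                          pos_sd = 50, len_min = 40L, len_max = 110L, chrom_length = L)
      mono_parts <- lapply(seq_len(4L), function(d) {
        dy <- ifelse(open_now, dyads_open[d], dyads_closed[d])
        site_frags(rnb(nS, rep(m_mono, nS), disp), truth$chrom,
                   truth$center + dy, pos_sd = 15, len_min = 180L,
                   len_max = 240L, chrom_length = L)
      })
      bg <- background_frags(rpois(1L, bg_n), chroms, L, 40L, 240L)
      atac[[cond]][[r]] <- rbindlist(c(list(short), mono_parts, list(bg)))
    }
  }

  # --- histone marks (CUT&Tag-like, fragments > 120 bp) ---------------------
  hist_assays <- list(h3k4me1 = truth$lfc_h3k4me1, h3k27ac = truth$lfc_h3k27ac)
  base_level <- c(promoter = 1, enhancer = 0.8, transcription = 0.25,
                  quiescent = 0.1)[truth$state]
  marks <- list()
  for (a in names(hist_assays)) {
    ctrl_mu <- 0.9 * sig_depth / nS * base_level
    for (cond in conds) {
      mu <- if (cond == "treated") ctrl_mu * 2^hist_assays[[a]] else ctrl_mu
      for (r in reps) {
        sig <- site_frags(rnb(nS, mu, disp), truth$chrom, truth$center,
                          pos_sd = 200, len_min = 150L, len_max = 500L,
                          chrom_length = L)
        bg <- background_frags(rpois(1L, bg_n), chroms, L, 150L, 500L)
        marks[[a]][[cond]][[r]] <- rbindlist(list(sig, bg))
      }
    }
  }

  # --- CAGE: stranded 5' reads anchored at RE centers -----------------------
  anchor <- fifelse(is.na(truth$re_center), truth$center, truth$re_center)
  ctrl_act <- ifelse(truth$state == "promoter", 1, 0.05)
  m_cage_ctrl <- 0.9 * sig_depth / nS * ctrl_act
  # stable housekeeping TSSs, placed clear of binding sites; identical means
  # in both conditions so they anchor library normalization
  n_bg_tss <- cfg$n_background_tss
  bg_tss <- data.table(chrom = character(), pos = integer(), strand = character())
  while (nrow(bg_tss) < n_bg_tss) {
    need <- n_bg_tss - nrow(bg_tss)
    ch <- sample(chroms, need, replace = TRUE)
    p <- as.integer(floor(runif(need, 1000, L - 1000)))
    ok <- vapply(seq_len(need), function(j) {
      same <- truth$chrom == ch[j]
      !any(same) || min(abs(truth$center[same] - p[j])) >= 600L
    }, logical(1L))
    bg_tss <- rbind(bg_tss, data.table(chrom = ch[ok], pos = p[ok],
                                       strand = sample(c("+", "-"), sum(ok),
                                                       replace = TRUE)))
  }
  bg_tss_mu <- if (n_bg_tss > 0) 0.35 * sig_depth / n_bg_tss else 0
  cage_reads <- function(chrom, pos5, str) {
    out <- data.table(chrom = chrom,
                      start = ifelse(str == "+", pos5, pos5 - 29L),
                      end = ifelse(str == "+", pos5 + 30L, pos5 + 1L),
                      strand = str)
    out[, start := pmax(0L, as.integer(start))]
    out
  }
  cage <- list()
  for (cond in conds) {
    mu <- if (cond == "treated") m_cage_ctrl * 2^truth$lfc_cage else m_cage_ctrl
    for (r in reps) {
      counts <- rnb(nS, mu, disp)
      idx <- rep(seq_len(nS), counts)
      off <- sample_offsets(length(idx), cfg$tss_offset_centers,
                            cfg$tss_offset_weights, cfg$tss_offset_sd)
      pos5 <- pmax(0L, pmin(anchor[idx] + off, as.integer(L - 100L)))
      sig <- cage_reads(truth$chrom[idx], pos5,
                        sample(c("+", "-"), length(idx), replace = TRUE))
      bidx <- rep(seq_len(nrow(bg_tss)), rnb(nrow(bg_tss), bg_tss_mu, disp))
      hk <- cage_reads(bg_tss$chrom[bidx],
                       bg_tss$pos[bidx] + as.integer(round(rnorm(length(bidx), sd = 3))),
                       bg_tss$strand[bidx])
      bg <- background_frags(rpois(1L, 0.3 * bg_n), chroms, L, 30L, 30L,
                             stranded = TRUE)
      cage[[cond]][[r]] <- rbindlist(list(sig, hk, bg))
    }
  }

  # --- binding signal (single ChIP-like library) ----------------------------
  chip_mu <- truth$occupancy * cfg$chip_depth / 1e6
  chip <- rbindlist(list(
    site_frags(rnb(nS, chip_mu, disp), truth$chrom, truth$center,
               pos_sd = 60, len_min = 150L, len_max = 300L, chrom_length = L),
    background_frags(rpois(1L, 0.05 * cfg$chip_depth), chroms, L, 150L, 300L)
  ))

  # --- 18-state segmentation: site-local labels over Quies background -------
  seg_site <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start + 1L - 500L, truth$end + 500L))
  S4Vectors::mcols(seg_site)$name <- truth$state18
  gaps <- GenomicRanges::gaps(GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start + 1L - 500L, truth$end + 500L),
    seqlengths = setNames(rep(L, cfg$n_chroms), chroms)))
  gaps <- gaps[as.character(BiocGenerics::strand(gaps)) == "*"]
  S4Vectors::mcols(gaps)$name <- "Quies"
  states <- BiocGenerics::sort(c(seg_site, gaps))

  # --- genes, links and the gene differential table -------------------------
  cand <- which(truth$re_class != "none" & truth$lfc_cage > 1.5 &
                  truth$open_treated)
  k <- min(cfg$n_linked_genes, length(cand))
  linked_sites <- if (k > 0) sort(sample(cand, k)) else integer()
  truth[, linked_gene := NA_character_]
  genes <- data.table(
    gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
    chrom = sample(chroms, cfg$n_genes, replace = TRUE),
    tss_pos = as.integer(floor(runif(cfg$n_genes, 1000, L - 1000))),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    log2fc = rnorm(cfg$n_genes, 0, 0.3),
    padj = runif(cfg$n_genes, 0.2, 1)
  )
  pairs <- data.table(chrom = character(), start = integer(), end = integer(),
                      gene_id = character())
  if (k > 0) {
    for (j in seq_len(k)) {
      s <- linked_sites[j]
      g <- j  # first k genes get wired
      dist <- sample(5000:50000, 1L)
      # mirror near the chromosome end so the wired distance is preserved
      gpos <- if (truth$center[s] + dist <= L - 1000) truth$center[s] + dist
              else truth$center[s] - dist
      genes[g, `:=`(chrom = truth$chrom[s],
                    tss_pos = as.integer(gpos),
                    log2fc = if (null) rnorm(1, 0, 0.3) else rnorm(1, 1.5, 0.2),
                    padj = if (null) runif(1, 0.2, 1) else runif(1, 0, 0.01))]
      truth[s, linked_gene := genes$gene_id[g]]
      pairs <- rbind(pairs, data.table(chrom = truth$chrom[s],
                                       start = truth$start[s] - 100L,
                                       end = truth$end[s] + 100L,
                                       gene_id = genes$gene_id[g]))
    }
    # decoy pairs: unbound background regions and one promoter-proximal pair
    decoys <- setdiff(seq_len(nS), linked_sites)
    decoys <- decoys[sample.int(length(decoys), min(5L, length(decoys)))]
    pairs <- rbind(pairs, data.table(chrom = truth$chrom[decoys],
                                     start = truth$start[decoys] - 100L,
                                     end = truth$end[decoys] + 100L,
                                     gene_id = sample(genes$gene_id[-seq_len(k)],
                                                      length(decoys), replace = TRUE)))
  }

  sites <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start + 1L, truth$end))
  S4Vectors::mcols(sites)$name <- truth$site_id
  S4Vectors::mcols(sites)$occupancy <- truth$occupancy
  S4Vectors::mcols(sites)$re_class <- truth$re_class
  S4Vectors::mcols(sites)$re_subtype <- truth$re_subtype
  S4Vectors::mcols(sites)$re_center <- truth$re_center

  list(truth = truth[], sites = sites, states = states,
       fragments = list(atac = atac, h3k4me1 = marks$h3k4me1,
                        h3k27ac = marks$h3k27ac),
       cage = cage, chip = chip, pairs = pairs[], genes = genes[],
       config = cfg)
}

#' Simulate under the null (no treatment effect)
#'
#' `level = "fragments"` returns a full [simulate_multiome()] dataset in
#' which the two condition means are identical at every site (all true
#' log2FCs zero; only replicate noise differs). `level = "counts"` directly
#' returns a null [region_counts] matrix (log-normal region means, NB
#' replicate noise, mild library-size variation), the fast path for
#' calibration studies of the differential test.
#'
#' @param config A [sim_config()].
#' @param level `"fragments"` or `"counts"`.
#' @param n_regions Number of regions for `level = "counts"`.
#' @param mean_log,mean_sdlog Log-normal law of region means for the counts
#'   level.
#' @return A simulation list, or a `region_counts` object.
#' @export
simulate_null <- function(config = sim_config(), level = c("fragments", "counts"),
                          n_regions = 2000L, mean_log = log(50), mean_sdlog = 1) {
  level <- match.arg(level)
  if (level == "fragments") {
    cfg <- config
    cfg$null_effects <- TRUE
    return(simulate_multiome(cfg))
  }
  set.seed(config$seed)
  mu <- rlnorm(n_regions, mean_log, mean_sdlog)
  n_rep <- config$n_replicates
  sf <- runif(2L * n_rep, 0.7, 1.3)
  counts <- vapply(seq_len(2L * n_rep), function(j) {
    rnb(n_regions, mu * sf[j], config$nb_dispersion)
  }, numeric(n_regions))
  storage.mode(counts) <- "integer"
  regions <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = seq_len(n_regions) * 1000L, width = 500L))
  region_counts(regions, counts,
                condition = rep(c("control", "treated"), each = n_rep))
}

#' Write a simulated dataset to disk
#'
#' Writes the standard text formats the pipeline reads: sites as BED6
#' (score = occupancy), RE annotations and truth as TSV, the segmentation as
#' BED (name = 18-state label), fragments and CAGE reads as BED per
#' assay/condition/replicate, pairs/genes as TSV and the config as YAML.
#'
#' @param sim Output of [simulate_multiome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_bed(sim$sites, p("sites.bed"))
  fwrite(sim$truth[, .(site_id, re_class, re_subtype, re_center)],
         p("sites_re.tsv"), sep = "\t")
  write_bed(sim$states, p("states.bed"), bed6 = TRUE)
  fwrite(sim$truth, p("truth.tsv"), sep = "\t")
  frag_bed <- function(dt, path) {
    fwrite(dt[order(chrom, start, end),
              .(chrom, start, end, name = ".", score = 0L,
                strand = ifelse(strand == "*", ".", strand))],
           path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  for (assay in names(sim$fragments)) {
    for (cond in names(sim$fragments[[assay]])) {
      for (r in seq_along(sim$fragments[[assay]][[cond]])) {
        frag_bed(sim$fragments[[assay]][[cond]][[r]],
                 p(sprintf("%s_%s_rep%d.bed", assay, cond, r)))
      }
    }
  }
  for (cond in names(sim$cage)) {
    for (r in seq_along(sim$cage[[cond]])) {
      frag_bed(sim$cage[[cond]][[r]], p(sprintf("cage_%s_rep%d.bed", cond, r)))
    }
  }
  frag_bed(sim$chip, p("chip.bed"))
  fwrite(sim$pairs, p("pairs.tsv"), sep = "\t")
  fwrite(sim$genes, p("genes.tsv"), sep = "\t")
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
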