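# Configuration-driven end-to-end orchestration over a simulated (or
# equivalently formatted) dataset directory, plus the simple threshold peak
# caller used on synthetic tracks.

#' Per-base fragment coverage track
#'
#' Counts, at every base, the fragments covering it (optionally restricted
#' to a fragment-length range). Unstranded.
#'
#' @param fragments `GRanges` or 0-based fragment table.
#' @param size_range Optional inclusive length bounds.
#' @return A [signal_track()].
#' @export
fragment_coverage <- function(fragments, size_range = NULL) {
  dt <- as_frag_dt(fragments)
  if (!is.null(size_range)) {
    len <- dt$end - dt$start
    dt <- dt[len >= size_range[1L] & len <= size_range[2L]]
  }
  if (nrow(dt) == 0L) return(signal_track())
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
  cov <- IRanges::coverage(gr)
  parts <- lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    v <- S4Vectors::runValue(r); l <- S4Vectors::runLength(r)
    starts1 <- cumsum(c(1L, l))[seq_along(l)]
    keep <- which(v > 0)
    if (length(keep) == 0L) return(NULL)
    data.table(chrom = ch,
               pos = rep(starts1[keep], l[keep]) + sequence(l[keep]) - 2L,
               score = rep(v[keep], l[keep]))
  })
  all <- rbindlist(parts)
  signal_track(all$chrom, all$pos, rep("*", nrow(all)), all$score)
}

#' Simple threshold peak caller
#'
#' Positions with track value >= `min_height` are grouped into runs; runs
#' separated by at most `max_gap` below-threshold bases are bridged; runs
#' shorter than `min_length` are dropped. Intended for synthetic tracks --
#' it does not model local background.
#'
#' @param track A [signal_track()].
#' @param min_height Positive height threshold.
#' @param min_length Minimum peak length in bp (default 50).
#' @param max_gap Maximum bridged gap in bp (default 100).
#' @param per_strand Call separately per strand (stranded tracks).
#' @return `GRanges` of peaks (stranded when `per_strand`).
#' @export
call_peaks_simple <- function(track, min_height, min_length = 50L,
                              max_gap = 100L, per_strand = FALSE) {
  if (length(min_height) != 1L || is.na(min_height) || min_height <= 0) {
    stop("min_height must be a single positive number")
  }
  dt <- as.data.table(track)
  if (!per_strand) dt <- dt[, .(score = sum(score)), by = .(chrom, pos)][, strand := "*"]
  dt <- dt[score >= min_height][order(chrom, strand, pos)]
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  dt[, brk := c(1L, as.integer(chrom[-1L] != chrom[-.N] |
                                 strand[-1L] != strand[-.N] |
                                 pos[-1L] - pos[-.N] - 1L > max_gap))]
  dt[, run := cumsum(brk)]
  pk <- dt[, .(chrom = chrom[1L], strand = strand[1L],
               start = pos[1L], end = pos[.N] + 1L), by = run]
  pk <- pk[end - start >= min_length]
  GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end),
                         strand = pk$strand)
}

#' Pipeline configuration
#'
#' Collects input location, thresholds and seed, and validates that every
#' required input file exists (fail-fast, before any computation).
#'
#' @param data_dir Directory written by [write_dataset()] (or equivalently
#'   formatted data).
#' @param outdir Output directory.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stage-level randomness (the analysis stages themselves are
#'   deterministic).
#' @param fc_cut,fdr_cut Differential classification thresholds.
#' @param tss_induced_cut TSS-status log2FC threshold.
#' @param tss_extension Upstream TSS extension (bp).
#' @param min_reads Density-profile region read threshold.
#' @param link_min_distance Enhancer-gene minimum distance (bp).
#' @param atac_fe Fold enrichment over mean coverage for accessibility peaks.
#' @param cage_min_height Absolute 5'-coverage threshold for CTSS peaks.
#' @param ctss_merge_gap CTSS peak merge distance (bp).
#' @param profile_half_width Nucleosome profile half-width (bp).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, outdir, seed = 1L,
                            fc_cut = 1, fdr_cut = 0.1,
                            tss_induced_cut = 0.5, tss_extension = 200L,
                            min_reads = 5L, link_min_distance = 2500L,
                            atac_fe = 5, cage_min_height = 5,
                            ctss_merge_gap = 50L, profile_half_width = 500L) {
  cfg <- as.list(environment())
  required <- c("sites.bed", "sites_re.tsv", "states.bed", "chip.bed",
                "pairs.tsv", "genes.tsv")
  for (f in required) {
    path <- file.path(data_dir, f)
    if (!file.exists(path)) stop("missing pipeline input: ", path)
  }
  for (assay in c("atac", "h3k4me1", "h3k27ac", "cage")) {
    for (cond in c("control", "treated")) {
      n <- length(Sys.glob(file.path(data_dir, sprintf("%s_%s_rep*.bed", assay, cond))))
      if (n < 2L) {
        stop("missing pipeline input: need >= 2 '", assay, "' replicates for ",
             cond, " in ", data_dir)
      }
    }
  }
  if (fdr_cut <= 0 || fdr_cut > 1) stop("fdr_cut must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

read_frag_set <- function(data_dir, assay) {
  out <- list(); cond_v <- character()
  for (cond in c("control", "treated")) {
    files <- sort(Sys.glob(file.path(data_dir, sprintf("%s_%s_rep*.bed", assay, cond))))
    for (f in files) {
      dt <- fread(f, header = FALSE, sep = "\t")
      setnames(dt, seq_len(min(6L, ncol(dt))),
               head(c("chrom", "start", "end", "name", "score", "strand"), ncol(dt)))
      if (!"strand" %in% names(dt)) dt[, strand := "*"]
      dt[strand == ".", strand := "*"]
      nm <- sub("\\.bed$", "", basename(f))
      out[[nm]] <- dt[, .(chrom, start, end, strand)]
      cond_v[nm] <- cond
    }
  }
  list(reads = out, condition = unname(cond_v))
}

pool_frags <- function(fragset, cond) {
  rbindlist(fragset$reads[fragset$condition == cond])
}

#' Run the full layered analysis
#'
#' Executes the stages in dependency order: load inputs; accessibility peak
#' calling per condition (sub-nucleosomal fragments); per-assay region
#' counting and NB differential testing at binding sites; CTSS peak calling,
#' merging, summit calling and differential testing; layer classification
#' (accessibility transition, collapsed state, TSS status, RE status);
#' occupancy-response sigmoid fit; mono-nucleosome profiles with
#' eviction/shift scores per transition group; CTSS density profiles and
#' initiation-mode detection; enhancer-gene linking. Writes the site-layer
#' table, profile tables, link/candidate tables, a summary JSON and a run
#' manifest to `config$outdir`; identical config + seed reproduces the
#' outputs byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[stage %s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  dd <- config$data_dir
  set.seed(config$seed)

  # ---- inputs ---------------------------------------------------------------
  inputs <- stage("load", {
    sites <- read_bed(file.path(dd, "sites.bed"))
    re <- fread(file.path(dd, "sites_re.tsv"))
    re <- re[match(S4Vectors::mcols(sites)$name, re$site_id)]
    list(sites = sites, re = re,
         states = read_bed(file.path(dd, "states.bed")),
         atac = read_frag_set(dd, "atac"),
         h3k4me1 = read_frag_set(dd, "h3k4me1"),
         h3k27ac = read_frag_set(dd, "h3k27ac"),
         cage = read_frag_set(dd, "cage"),
         chip = fread(file.path(dd, "chip.bed"),
                      col.names = c("chrom", "start", "end", "name", "score",
                                    "strand"))[, .(chrom, start, end, strand = "*")],
         pairs = fread(file.path(dd, "pairs.tsv")),
         genes = fread(file.path(dd, "genes.tsv")))
  })
  sites <- inputs$sites
  n_sites <- length(sites)
  message(sprintf("[stage load] %d sites, %d segmentation intervals",
                  n_sites, length(inputs$states)))

  # ---- accessibility peaks per condition -----------------------------------
  peaks <- stage("atac_peaks", {
    lapply(c(control = "control", treated = "treated"), function(cond) {
      frags <- pool_frags(inputs$atac, cond)
      tr <- fragment_coverage(frags, size_range = c(1L, 119L))
      genome_size <- sum(tapply(tr$pos, tr$chrom, max))
      call_peaks_simple(tr, min_height = config$atac_fe * track_mass(tr) / genome_size,
                        min_length = 50L, max_gap = 100L)
    })
  })

  # ---- per-assay differential at binding sites -----------------------------
  diffs <- stage("differential", {
    lapply(list(atac = inputs$atac, h3k4me1 = inputs$h3k4me1,
                h3k27ac = inputs$h3k27ac), function(fs) {
      nb_diff(count_regions(fs$reads, sites, fs$condition, "none"))
    })
  })

  # ---- CTSS peaks and differential -----------------------------------------
  ctss <- stage("ctss", {
    pooled <- five_prime_coverage(rbindlist(inputs$cage$reads))
    raw <- call_peaks_simple(pooled, min_height = config$cage_min_height,
                             min_length = 1L, max_gap = 25L, per_strand = TRUE)
    merged <- merge_within(raw, config$ctss_merge_gap)
    pk <- call_ctss(pooled, merged)
    rc <- count_regions(inputs$cage$reads, pk, inputs$cage$condition, "sense")
    res <- nb_diff(rc)
    S4Vectors::mcols(pk)$log2fc <- res$log2fc
    S4Vectors::mcols(pk)$padj <- res$padj
    S4Vectors::mcols(pk)$bound <- overlaps_any(pk, sites)
    list(track = pooled, peaks = pk, diff = res)
  })
  message(sprintf("[stage ctss] %d peaks (%d bound)",
                  length(ctss$peaks), sum(S4Vectors::mcols(ctss$peaks)$bound)))

  # ---- site layers ----------------------------------------------------------
  layers <- stage("layers", {
    occupancy <- compute_occupancy(sites, inputs$chip)
    dt <- data.table(
      site_id = S4Vectors::mcols(sites)$name,
      accessibility = classify_accessibility(sites, peaks$control, peaks$treated),
      state = assign_state(sites, inputs$states),
      tss = tss_status(sites, ctss$peaks, extension = config$tss_extension,
                       induced_cut = config$tss_induced_cut),
      re = re_status(inputs$re$re_subtype),
      occupancy = occupancy
    )
    for (a in names(diffs)) {
      dt[, paste0(a, "_log2fc") := diffs[[a]]$log2fc]
      dt[, paste0(a, "_padj") := diffs[[a]]$padj]
    }
    dt
  })
  summary_layers <- summarize_layers(layers[, .(accessibility, state, tss, re)])

  # ---- occupancy -> transcription sigmoid ----------------------------------
  sigmoid <- stage("sigmoid", {
    cage_site <- nb_diff(count_regions(inputs$cage$reads, sites,
                                       inputs$cage$condition, "sense"))
    layers[, cage_log2fc := cage_site$log2fc]
    layers[, cage_padj := cage_site$padj]
    fit_occupancy_response(layers$occupancy, cage_site$log2fc)
  })

  # ---- nucleosome profiles per transition group ----------------------------
  nuc <- stage("nucleosome", {
    mono <- lapply(c(control = "control", treated = "treated"), function(cond) {
      mono_occupancy(pool_frags(inputs$atac, cond))
    })
    has_re <- !is.na(inputs$re$re_center)
    groups <- c("opened", "constitutively_open", "constitutively_closed")
    prof <- list(); scores <- list()
    for (g in groups) {
      sel <- which(layers$accessibility == g & has_re)
      if (length(sel) < 5L) next
      anchors <- data.table(chrom = as.character(GenomicRanges::seqnames(sites))[sel],
                            pos = inputs$re$re_center[sel], strand = "*")
      pc <- anchored_profile(mono$control, anchors, config$profile_half_width)
      pt <- anchored_profile(mono$treated, anchors, config$profile_half_width)
      prof[[g]] <- data.table(group = g, offset = pc$offset,
                              mean_control = pc$mean, mean_treated = pt$mean,
                              n_anchors = attr(pc, "n_anchors"))
      scores[[g]] <- eviction_shift(pc, pt)
    }
    list(profiles = rbindlist(prof), scores = scores)
  })

  # ---- CTSS density around canonical REs -----------------------------------
  dens <- stage("density", {
    canonical <- which(inputs$re$re_class == "canonical")
    centers <- data.table(chrom = as.character(GenomicRanges::seqnames(sites))[canonical],
                          pos = inputs$re$re_center[canonical])
    strata <- layers$state[canonical]
    out <- list()
    for (cond in c("control", "treated")) {
      tr <- five_prime_coverage(pool_frags(inputs$cage, cond))
      out[[paste0(cond, "_all")]] <- density_profile(
        tr, centers, min_reads = config$min_reads, condition = cond)
      out[[paste0(cond, "_states")]] <- density_profile(
        tr, centers, min_reads = config$min_reads, strata = strata,
        condition = cond)
    }
    modes <- if (nrow(out$treated_all) > 0) {
      peak_offsets(out$treated_all)
    } else numeric()
    list(profiles = rbindlist(out), modes = modes)
  })

  # ---- enhancer-gene linking ------------------------------------------------
  links <- stage("links", {
    lk <- build_links(ctss$peaks, inputs$pairs, inputs$genes,
                      min_distance = config$link_min_distance)
    cand <- candidate_genes(lk, tss_fc = config$fc_cut, tss_fdr = config$fdr_cut)
    corr <- if (nrow(lk) >= 3L) change_correlation(lk, "all") else NULL
    corr_bound <- if (sum(lk$bound) >= 3L) change_correlation(lk, "bound") else NULL
    list(links = lk, candidates = cand, corr = corr, corr_bound = corr_bound)
  })

  # ---- outputs --------------------------------------------------------------
  axis_counts <- lapply(summary_layers$axis, function(tab) {
    setNames(as.list(tab$count), tab$level)
  })
  axis_pct <- lapply(summary_layers$axis, function(tab) {
    setNames(as.list(tab$percent), tab$level)
  })
  summary <- list(
    n_sites = n_sites,
    layer_counts = axis_counts,
    layer_percent = axis_pct,
    n_ctss_peaks = length(ctss$peaks),
    n_ctss_bound = sum(S4Vectors::mcols(ctss$peaks)$bound),
    sigmoid = list(params = as.list(sigmoid$params), r2 = sigmoid$r2,
                   rho = sigmoid$rho, rho_p = sigmoid$rho_p,
                   converged = sigmoid$converged),
    nucleosome = lapply(nuc$scores, function(s) {
      list(eviction = s$eviction, shift = s$shift)
    }),
    ctss_modes = as.numeric(dens$modes),
    n_links = nrow(links$links),
    candidates = links$candidates,
    link_correlation = links$corr,
    link_correlation_bound = links$corr_bound
  )
  o <- function(...) file.path(config$outdir, ...)
  fwrite(layers, o("site_layers.tsv"), sep = "\t")
  if (nrow(nuc$profiles) > 0) fwrite(nuc$profiles, o("nuc_profiles.tsv"), sep = "\t")
  fwrite(dens$profiles, o("density_profiles.tsv"), sep = "\t")
  fwrite(links$links, o("links.tsv"), sep = "\t")
  writeLines(links$candidates, o("candidate_genes.txt"))
  write_bed(ctss$peaks, o("ctss_peaks.bed"))
  jsonlite::write_json(summary, o("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  cfg_plain <- unclass(config)
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  saveRDS(cfg_plain, tmp, version = 2)
  manifest <- list(
    package = "chromlayers",
    version = as.character(utils::packageVersion("chromlayers")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = unname(tools::md5sum(tmp))
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  message(sprintf("[pipeline] done in %.1fs", proc.time()[["elapsed"]] - t_all))
  invisible(list(layers = layers, summary = summary, summary_layers = summary_layers,
                 peaks = peaks, ctss = ctss, diffs = diffs, sigmoid = sigmoid,
                 nucleosome = nuc, density = dens, links = links,
                 config = config))
}
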