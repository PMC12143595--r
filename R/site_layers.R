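# Layered classification of binding sites: accessibility transition,
# collapsed chromatin state, transcription-initiation status,
# response-element class; summaries and the occupancy-to-transcription
# sigmoidal response model.

#' Accessibility transition between conditions
#'
#' Assesses the presence (open) or absence (closed) of an accessibility peak
#' at each site in the control and the treated condition:
#' open/open -> `constitutively_open`, closed/open -> `opened`,
#' closed/closed -> `constitutively_closed`, open/closed ->
#' `putatively_closed`. The last label is retained rather than dropped --
#' such calls typically behave like false positives, and interpretation is
#' left to the report.
#'
#' @param sites `GRanges` of binding sites.
#' @param peaks_control,peaks_treated Peak `GRanges` per condition.
#' @return Character vector of transition labels along `sites`.
#' @export
classify_accessibility <- function(sites, peaks_control, peaks_treated) {
  open_c <- overlaps_any(sites, peaks_control)
  open_t <- overlaps_any(sites, peaks_treated)
  out <- rep("constitutively_closed", length(sites))
  out[open_c & open_t] <- "constitutively_open"
  out[!open_c & open_t] <- "opened"
  out[open_c & !open_t] <- "putatively_closed"
  out
}

#' Collapse 18-state chromatin labels to four states
#'
#' promoter = TssA, TssBiv, TssFlnk, TssFlnkD, TssFlnkU; enhancer = EnhA1,
#' EnhA2, EnhBiv, EnhG1, EnhG2, EnhWk; transcription = Tx, TxWk; quiescent =
#' Het, Quies, ReprPC, ReprPCWk, ZNF/Rpts. Any other label maps to `n/a`.
#'
#' @param state18 Character vector of segmentation labels.
#' @return Character vector of collapsed states.
#' @export
collapse_state <- function(state18) {
  map <- unlist(lapply(names(.STATE18), function(s) {
    setNames(rep(s, length(.STATE18[[s]])), .STATE18[[s]])
  }))
  out <- unname(map[state18])
  out[is.na(out)] <- "n/a"
  out
}

#' Assign each site its local collapsed chromatin state
#'
#' Picks the segmentation interval with the largest overlap with the site
#' (ties: first in sorted order) and collapses its label with
#' [collapse_state()]; sites with no overlapping segment get `n/a`.
#'
#' @param sites `GRanges` of binding sites.
#' @param states Segmentation `GRanges` with labels in the `name` column.
#' @return Character vector of collapsed states along `sites`.
#' @export
assign_state <- function(sites, states) {
  hits <- GenomicRanges::findOverlaps(sites, states, ignore.strand = TRUE)
  if (length(hits) == 0L) return(rep("n/a", length(sites)))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(sites)[q], IRanges::ranges(states)[s]))
  dt <- data.table(q = q, label = S4Vectors::mcols(states)$name[s], ov = ov)
  best <- dt[order(q, -ov)][, .SD[1L], by = q]
  out <- rep("n/a", length(sites))
  out[best$q] <- collapse_state(best$label)
  out
}

#' Transcription-initiation status of binding sites
#'
#' A site overlapping no (upstream-extended) CTSS peak is `none`; if any
#' overlapping peak has log2FC above `induced_cut` the site is `induced`
#' (the induced label dominates when several TSSs overlap); otherwise
#' `uninduced`. Peaks are extended upstream (strand-aware) before the
#' overlap test.
#'
#' @param sites `GRanges` of binding sites.
#' @param ctss_peaks Stranded `GRanges` with a `log2fc` metadata column.
#' @param extension Upstream extension in bp (default 200).
#' @param induced_cut log2FC threshold (default 0.5, strict).
#' @return Character vector in `{induced, uninduced, none}` along `sites`.
#' @export
tss_status <- function(sites, ctss_peaks, extension = 200L, induced_cut = 0.5) {
  if (length(ctss_peaks) == 0L) return(rep("none", length(sites)))
  ext <- extend_intervals(ctss_peaks, upstream = extension, downstream = 0L,
                          strand_aware = TRUE)
  hits <- GenomicRanges::findOverlaps(sites, ext, ignore.strand = TRUE)
  out <- rep("none", length(sites))
  if (length(hits) == 0L) return(out)
  lfc <- S4Vectors::mcols(ctss_peaks)$log2fc[S4Vectors::subjectHits(hits)]
  dt <- data.table(q = S4Vectors::queryHits(hits), lfc = lfc)
  st <- dt[, .(status = if (any(lfc > induced_cut)) "induced" else "uninduced"),
           by = q]
  out[st$q] <- st$status
  out
}

#' Response-element status of binding sites
#'
#' `canonical` iff the annotated subtype is two decameric half-sites without
#' a spacer; the other annotated subtypes (three quarter-sites, 1-bp-spaced
#' half-sites, single half-site) are `noncanonical`; absent annotation is
#' `none`. Annotation provenance is an input, not computed from sequence.
#'
#' @param subtype Character vector of RE subtype labels.
#' @return Character vector in `{canonical, noncanonical, none}`.
#' @export
re_status <- function(subtype) {
  known <- c("two_half_sites_no_spacer", .NONCANONICAL_SUBTYPES, "none")
  bad <- setdiff(unique(subtype), known)
  if (length(bad)) stop("unknown RE subtype label(s): ", paste(bad, collapse = ", "))
  fifelse(subtype == "two_half_sites_no_spacer", "canonical",
          fifelse(subtype == "none", "none", "noncanonical"))
}

#' Summarize classification layers
#'
#' Counts, raw fractions and whole-percent-rounded percentages per axis, and
#' pairwise contingency tables between axes. Invariant under site
#' reordering; per-axis counts always sum to the total.
#'
#' @param layers data.frame/data.table, one row per site, one column per
#'   classification axis (any columns may be passed via `axes`).
#' @param axes Columns to summarize (default: all columns).
#' @return A `layer_summary`: list with `total`, `axis` (per-axis tables)
#'   and `pairs` (named contingency tables).
#' @export
summarize_layers <- function(layers, axes = names(layers)) {
  layers <- as.data.table(layers)[, axes, with = FALSE]
  total <- nrow(layers)
  axis <- lapply(axes, function(a) {
    tab <- layers[, .(count = .N), by = a]
    setnames(tab, a, "level")
    tab[, fraction := if (total > 0) count / total else 0]
    tab[, percent := round(100 * fraction)]
    tab[order(-count)][]
  })
  names(axis) <- axes
  pairs <- list()
  if (length(axes) >= 2L) {
    cmb <- utils::combn(axes, 2L, simplify = FALSE)
    pairs <- lapply(cmb, function(ab) {
      table(layers[[ab[1L]]], layers[[ab[2L]]], dnn = ab)
    })
    names(pairs) <- vapply(cmb, paste, "", collapse = ":")
  }
  structure(list(total = total, axis = axis, pairs = pairs),
            class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat("layer_summary:", x$total, "sites\n")
  for (a in names(x$axis)) {
    cat("--", a, "--\n")
    print(x$axis[[a]])
  }
  invisible(x)
}

#' Fraction of sites within a stratum that carry a given label
#'
#' Convenience accessor on a [summarize_layers()] pair table, e.g. the
#' fraction of `opened` sites lying in transcribed or quiescent chromatin.
#'
#' @param summary A `layer_summary`.
#' @param pair Name of the pair table (`"axisA:axisB"`).
#' @param row_levels Levels of the first axis defining the stratum.
#' @param col_levels Levels of the second axis defining the numerator.
#' @return List with `count`, `denominator` and `fraction`.
#' @export
pair_fraction <- function(summary, pair, row_levels, col_levels) {
  tab <- summary$pairs[[pair]]
  if (is.null(tab)) stop("no pair table '", pair, "'")
  rows <- intersect(row_levels, rownames(tab))
  cols <- intersect(col_levels, colnames(tab))
  denom <- sum(tab[rows, , drop = FALSE])
  num <- sum(tab[rows, cols, drop = FALSE])
  list(count = num, denominator = denom,
       fraction = if (denom > 0) num / denom else NA_real_)
}

#' Site occupancy in counts-per-million
#'
#' Binding-signal reads overlapping the site interval, per million library
#' reads. The window is the site interval itself.
#'
#' @param sites `GRanges` of binding sites.
#' @param binding_reads Binding-signal fragments (`GRanges` or 0-based
#'   table).
#' @return Numeric CPM vector along `sites`.
#' @export
compute_occupancy <- function(sites, binding_reads) {
  dt <- as_frag_dt(binding_reads)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
  GenomicRanges::countOverlaps(sites, gr, ignore.strand = TRUE) / nrow(dt) * 1e6
}

#' Sigmoidal occupancy-to-transcription response fit
#'
#' Least-squares fit of `y = a + (b - a) / (1 + exp(-(log10(x) - x0) / k))`
#' relating site occupancy (CPM) to the local change in transcription
#' initiation (log2FC), with a multi-start grid (`x0` over data quantiles,
#' `k` over 0.1/0.3/1). `x0` estimates the occupancy threshold for
#' productive binding. Reports r-squared and the two-sided Spearman rank
#' correlation. Falls back to a linear fit (flagged) if no sigmoid start
#' converges; constant input yields a degenerate flag with undefined rho.
#'
#' @param occupancy Positive occupancy values (CPM).
#' @param delta_tss Local transcription change per site (log2FC).
#' @return An `occupancy_fit` list: `params` (a, b, x0, k), `r2`, `rho`,
#'   `rho_p`, `fitted`, flags `converged`, `fallback`, `degenerate`, and `n`.
#' @export
fit_occupancy_response <- function(occupancy, delta_tss) {
  keep <- is.finite(occupancy) & is.finite(delta_tss) & occupancy > 0
  x <- occupancy[keep]; y <- delta_tss[keep]
  if (length(x) < 10L) stop("need >= 10 paired observations with occupancy > 0")
  lx <- log10(x)
  if (sd(y) == 0 || sd(lx) == 0) {
    return(structure(list(params = c(a = NA, b = NA, x0 = NA, k = NA),
                          r2 = NA_real_, rho = NA_real_, rho_p = NA_real_,
                          fitted = rep(mean(y), length(y)), converged = FALSE,
                          fallback = FALSE, degenerate = TRUE, n = length(x)),
                     class = "occupancy_fit"))
  }
  ct <- suppressWarnings(cor.test(lx, y, method = "spearman", exact = FALSE))
  dat <- data.frame(lx = lx, y = y)
  tss <- sum((y - mean(y))^2)
  best <- NULL
  for (x0_start in unname(quantile(lx, c(0.25, 0.5, 0.75)))) {
    for (k_start in c(0.1, 0.3, 1)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ a + (b - a) / (1 + exp(-(lx - x0) / k)), data = dat,
          start = list(a = unname(quantile(y, 0.05)),
                       b = unname(quantile(y, 0.95)),
                       x0 = x0_start, k = k_start),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    lin <- lm(y ~ lx, data = dat)
    return(structure(list(
      params = c(a = unname(coef(lin)[1L]), b = unname(coef(lin)[2L]),
                 x0 = NA, k = NA),
      r2 = summary(lin)$r.squared, rho = unname(ct$estimate),
      rho_p = ct$p.value, fitted = unname(predict(lin)), converged = FALSE,
      fallback = TRUE, degenerate = FALSE, n = length(x)),
      class = "occupancy_fit"))
  }
  cf <- coef(best$fit)
  structure(list(params = c(a = unname(cf["a"]), b = unname(cf["b"]),
                            x0 = unname(cf["x0"]), k = unname(cf["k"])),
                 r2 = 1 - best$rss / tss, rho = unname(ct$estimate),
                 rho_p = ct$p.value, fitted = unname(predict(best$fit)),
                 converged = TRUE, fallback = FALSE, degenerate = FALSE,
                 n = length(x)),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("occupancy_fit: degenerate (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf(
      "occupancy_fit: a=%.3g b=%.3g x0=%.3g k=%.3g | r2=%.3f rho=%.3f (p=%.3g) n=%d%s\n",
      x$params["a"], x$params["b"], x$params["x0"], x$params["k"],
      x$r2, x$rho, x$rho_p, x$n, if (x$fallback) " [linear fallback]" else ""))
  }
  invisible(x)
}
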