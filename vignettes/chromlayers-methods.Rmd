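---
title: "chromlayers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromlayers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Pioneer transcription factors can engage nucleosome-occupied (closed)
chromatin and initiate its opening, but at any given moment most binding
sites of such a factor show no overt regulatory output. `chromlayers`
implements an integrative analysis that dissects this heterogeneity into
*layers* measured by different assays at the same set of binding sites:

1. **Accessibility transition** — is an accessibility (ATAC-type) peak
   present at the site in the control and/or the treated condition?
   Sites are labelled `constitutively_open`, `opened`,
   `constitutively_closed` or `putatively_closed`.
2. **Chromatin state** — the local 18-state segmentation label, collapsed
   to promoter / enhancer / transcription / quiescent.
3. **Transcription-initiation status** — does the site overlap a CAGE-derived
   TSS, and was that TSS induced (log2FC > 0.5) by the treatment?
4. **Response-element (RE) class** — canonical (two decameric half-sites
   without spacer), noncanonical (three quarter-sites, 1-bp-spaced
   half-sites, single half-site) or absent. RE annotations are inputs; the
   package does not call motifs from sequence.

Around the classification sit four quantitative analyses: a simplified
negative-binomial differential test for region counts, fragment-size-resolved
nucleosome occupancy profiling with eviction/shift scoring, a CTSS
positional-density analysis around canonical RE centers, and
distance-filtered enhancer-to-gene linking. Everything is exercised
end-to-end on a ground-truthed simulator, so the whole pipeline is testable
without external data.

# Coordinate and I/O conventions

One convention is fixed at the boundary: files (BED, bedGraph, TSV) are
0-based half-open; in-memory interval collections are `GRanges` (1-based
closed) and all readers normalize on entry. Adjacent intervals never count
as overlapping. Single-base quantities — CTSS positions, track entries,
summits — are 0-based everywhere. Signal tracks (`signal_track`) store
strictly positive per-base values sparsely, optionally split by strand;
5′-end coverage places a plus-strand read's count at its start and a
minus-strand read's count at `end - 1`.

# The differential test

Genome-scale analyses of this kind typically hand differential testing to a
full count-model framework. `chromlayers` deliberately uses a compact,
documented negative-binomial Wald test instead (`nb_diff`): the package's
contribution is the downstream integration, and what matters for it is
calibration and recovery on ground-truthed data, not coefficient-level
equality with any specific tool:

* **Normalization**: median-of-ratios size factors (`size_factors`), with a
  total-count fallback when no region has all-positive counts. Factors are
  rescaled to geometric mean 1; only their ratios matter downstream.
* **Effect size**: `log2FC = log2((mean_t + c)/(mean_c + c))` on normalized
  condition means, pseudocount `c = 0.5` (config-exposed). The pseudocount
  stabilizes empty regions and biases large effects by < 0.01 at counts
  above ~50.
* **Dispersion**: per-region method-of-moments on normalized counts
  (`alpha = (s² − μ)/μ²`), floored at 0 and shrunk halfway toward the
  across-region median (`shrink_weight = 0.5`).
* **Inference**: Wald statistic from the delta-method standard error under
  NB variance (`var = μ + αμ²`), referred to a t distribution with
  `(n_t + n_c − 2)/(1 − shrink_weight)²` degrees of freedom. The inflation
  reflects that shrinking the dispersion toward an essentially exact target
  with weight `w` scales the estimator's sampling variance by `(1 − w)²`;
  with 4 + 4 replicates and the default weight this gives 24 df. The plain
  normal reference is anticonservative at this sample size, the plain
  6-df t overcorrects; the inflated-df reference holds the empirical
  type-I error at the nominal 5% level in the package's null simulations
  (2000 regions, 4 vs 4, 20 seeds — the sizes used by the test suite).
* **Multiple testing**: Benjamini–Hochberg step-up (`bh_adjust`, a validated
  wrapper over the standard implementation, cross-checked in the tests
  against a from-scratch step-up oracle).
* **Classification**: `increased`/`decreased` require `|log2FC| > 1` *and*
  `FDR < 0.1`, strict inequalities, both config-exposed.

Out of scope by design: dispersion trend fitting, log-fold-change shrinkage
priors, outlier filtering and independent filtering.

Reads are assigned to **every** region they overlap (multi-assignment).
CAGE counting uses the 5′ position with strand matching; both a `sense`
convention (reads in transcript orientation, used for the simulated data)
and a `reverse` convention (for reverse-stranded libraries, where a read is
assigned when its strand is opposite to the feature's) are available.

# Nucleosome profiling

`mono_occupancy` keeps fragments of 180–240 bp (inclusive bounds —
mono-nucleosome-sized), spreads each fragment's unit mass uniformly over its
span and scales the track to counts-per-million fragment mass. Uniform
spreading (rather than midpoint placement) was chosen because it yields
smoother profiles at desk-scale depth; the alternative is config-reachable
by prefiltering fragments to their midpoints. Sub-nucleosomal fragments
(< 120 bp) drive the accessibility analysis instead.

`anchored_profile` averages ±W windows (default 500 bp) around anchor
positions, mirroring minus-strand anchors; windows are zero-padded at
profile edges and still count toward the mean, and the operation is linear
in the track. `eviction_shift` contrasts two conditions:

* **eviction** = mean occupancy within ±73 bp of the anchor in control
  minus treated (positive = loss under treatment). 73 bp is about half the
  DNA wrapped around one nucleosome, matching the spatial scale on which
  initiation offsets are interpreted.
* **shift** = the lag (±100 bp) maximizing the flank cross-correlation
  between the two profiles, computed separately on the left and right
  flanks with "away from the anchor" as the positive direction and
  averaged. Zero-variance flanks leave the shift undefined (flagged).
  Ties resolve to the smallest absolute lag.

No nucleosome calling, dyad modeling or transposase-bias correction is
attempted; a background-normalization step as used by dedicated nucleosome
tools is replaced by CPM scaling plus the explicit control−treated contrast.

# CTSS density and initiation modes

`density_profile` takes canonical RE centers, extracts ±200 bp (401
positions), drops regions with fewer than 5 in-window reads (`min_reads`),
divides each surviving region's per-position counts by that region's total,
and averages across regions — so every contributing vector and the mean
vector sum to 1, and the profile is invariant to per-region sequencing
depth. Profiles are computed per condition and, optionally, per collapsed
chromatin state. The window is anchored at the RE **center** (the
200-bp extension from a ~20-bp element is ambiguous between center and
edges; center ±200 matches the axis on which the modes are interpreted, and
the anchor is config-exposed). CTSS strands are pooled; a strand-split mode
exists for diagnostics.

`offset_histogram` is the package's simplified positional-enrichment layer:
RE-to-CTSS offsets are binned into `ceiling(span/window)`-wide windows
(span 401, 19 windows by default), and enrichment is the observed bin
fraction over the uniform expectation; the expectation-weighted mean
enrichment is exactly 1. It replaces k-mer-based positional enrichment
because sequence-level scanning is out of scope and the histogram serves
the same corroborating role.

`peak_offsets` smooths a profile with a centered moving average (default
length 5), finds local maxima (plateaus report their center position — the
smoothing of a single delta produces a plateau whose center is the delta)
and greedily keeps the top modes by height with a minimum separation of
20 bp.

# The occupancy→transcription response

`fit_occupancy_response` fits

    y = a + (b − a) / (1 + exp(−(log10 x − x0) / k))

relating site occupancy `x` (CPM of binding-signal reads over the site
interval, the window being the site itself) to the local change in
transcription initiation `y` (log2FC of CAGE counts at the site). `x0`
estimates the occupancy threshold above which binding becomes productive.
Fitting is least squares via Levenberg–Marquardt with a multi-start grid
(`x0` over the 25/50/75% quantiles of `log10 x`, `k` over {0.1, 0.3, 1});
the best-RSS start wins. If no start converges, a linear fit in `log10 x`
is returned and flagged; constant input returns a degenerate flag with the
rank correlation reported as undefined. Alongside the fit the function
reports r² and the two-sided Spearman correlation (average ranks, normal
approximation). The fit runs on all sites with a measured local change;
a stratified subset can be selected upstream by the caller.

# Enhancer–gene linking

Enhancer-to-gene association pairs are inputs (as coordinate-anchored
regions with a gene id, the shape in which public chromatin-interaction
links are distributed). A CTSS peak joins a pair when its **summit** falls
inside the pair region — the summit is single-base and deterministic,
whereas peak edges depend on merging parameters. Distance is measured from
summit to annotated gene TSS and links below 2.5 kb are removed as
promoter-proximal. A gene becomes a candidate when at least one of its
links has a bound, significantly induced enhancer TSS (log2FC > 1,
FDR < 0.1) and the gene itself is significantly upregulated (log2FC > 0.5,
FDR < 0.05); all inequalities strict, a gene reachable through several
enhancers is counted once, and per-link evidence is retained. Loosening
any threshold can only grow the candidate set.

# The simulator: what it emulates, and what it does not

`simulate_multiome` generates, per seed, a complete dataset: binding sites
with log-normal occupancy (CPM units), RE classes at the frequencies of the
recurrent-binding-site annotation the analysis is designed around
(canonical 0.699, noncanonical 0.179, none 0.122), collapsed chromatin
states, an 18-state segmentation with site-local labels over a quiescent
background, per-condition ATAC fragments in two size classes
(sub-nucleosomal < 120 bp at open sites; 180–240 bp mono-nucleosome
fragments around positioned dyads), histone-mark fragments (> 120 bp),
stranded CAGE 5′ reads whose offsets from the RE center follow a
two-component Gaussian mixture (centers 0 and +50 bp, sd 5), one deep
binding-signal library, enhancer–gene pairs and a gene-level differential
table. Replicate counts are negative-binomial with a mean–dispersion
parameterization (`var = μ + αμ²`, one α per assay run, default 0.05).
Background is uniform Poisson fragment rain — the neutral choice in the
absence of any stated noise model.

Design points worth calling out:

* **Openness is mechanistic, not label-copied.** Whether a site is open in
  a condition is drawn first (state- and occupancy-dependent around an
  overall baseline of 0.27), and openness then *causes* the nucleosome
  architecture: open sites get a nucleosome-depleted region with flanking
  dyads at ±165/±330 bp, closed sites carry dyads tight around the RE at
  ±95/±285 bp. The accessibility classifier is therefore genuinely tested
  against an independent ground truth, not against its own rule.
* **Closed-site accessibility effect.** The true accessibility log2FC at
  sites that open defaults to 4: regions that gain a peak go from
  essentially background to full peak signal, and a leak of 2⁻⁴ of the
  open-site rate keeps the configured effect exact while staying below any
  reasonable peak-calling threshold. (With a much smaller effect the "closed"
  state would itself be half a peak, which is not what peak-gain means.)
* **Stable housekeeping TSSs.** CAGE reads include ~300 condition-stable
  TSSs placed clear of binding sites. Real TSS landscapes are dominated by
  non-responding promoters, and without them median-of-ratios normalization
  of CTSS-peak counts would absorb the induction signal (the median peak
  would itself be induced).
* **Occupancy→transcription coupling.** The true CAGE log2FC per site is a
  sigmoid of log10 occupancy (defaults a = 0, b = 4, x0 = log10 8,
  k = 0.25), so the response-model stage has a recoverable ground truth.
* **Effect sizes** for histone marks (default max 1.5, scaled by a logistic
  in occupancy) are config-exposed; no source states them, so they are
  fixed once at values a practitioner would call moderate-to-strong and are
  not tuned thereafter.
* **The gene table is simulated directly** (gene-level modeling is outside
  the analysis scope; only the linking logic is tested). Wired genes are
  placed 5–50 kb from an induced bound enhancer site, mirrored away from
  chromosome ends so the wired distance survives the 2.5-kb filter.

What the generator does **not** emulate — and hence what green tests do not
show about real data: no sequences (no motif content, no mappability or GC
effects), no transposase sequence bias, no fragment-length/chromatin-state
interactions beyond the two size classes, no peak-shape heterogeneity, no
between-replicate batch structure beyond NB dispersion, and no
chromosome-scale covariance. Agreement numbers (e.g. the accessibility
classifier's recovery) are upper bounds that real data will not reach.

`simulate_null` produces either the full dataset with every treatment
effect zeroed (`level = "fragments"`), or a direct NB region-count null
(`level = "counts"`: log-normal region means, mild library-size variation)
— the fast path used for calibration studies, where fragment-level
simulation would add nothing but runtime.

# Pipeline, determinism and problem sizes

`run_pipeline` executes load → accessibility peak calling (simple threshold
caller on sub-nucleosomal coverage, height = 5× mean coverage, min length
50 bp, max gap 100 bp) → per-assay differential at sites → CTSS peak
calling (absolute height 5 on pooled 5′ coverage, per strand), merging
within 50 bp, summit calling, differential → layer classification →
sigmoid fit → nucleosome profiles and eviction/shift per transition group →
density profiles and mode detection → linking, then writes tables, a
summary JSON and a manifest (package version, seed, config echo and hash).
All analysis stages are deterministic given their inputs; the single RNG
seed enters only through simulation, so identical config + seed reproduces
every output byte-for-byte — which the test suite asserts.

The reference conditions used throughout the tests and the acceptance
script are 500 sites on 2 × 1 Mb chromosomes, 4 + 4 replicates, 1e5
fragments per library and a 2e6-fragment binding library; unit tests use
a smaller 80-site, 1-chromosome configuration. These sizes were chosen so
the full suite exercises every stage at depths where the statistical
behavior (calibration, recovery) is measurable.

# Known limitations

* The simple peak caller has no local background model; it exists so the
  synthetic path is self-contained. Peak calling on real data should be
  done upstream with a dedicated caller, and the pipeline consumed from its
  outputs.
* The NB test's df inflation is derived for shrinkage toward a
  high-precision target; with very few regions the median dispersion is
  itself noisy and the test will drift anticonservative.
* `putatively_closed` (open → closed) labels are retained and flagged
  rather than interpreted; in practice they behave like false-positive peak
  calls and carry a high background.
* Blacklist filtering, alignment, deduplication and other read-level
  preprocessing are assumed done upstream; the package starts from
  fragment/read intervals in BED form.
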