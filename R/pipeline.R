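# Orchestration: a validated configuration object holding every numeric
# threshold of the analysis, a per-group peak pooling helper, the occupancy
# matrix builder, and a one-shot end-to-end run on a synthetic cohort.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated,
#' echoable object.  Unknown keys are rejected.
#'
#' @param stitch_distance Enhancer stitching gap in bases (default 12500).
#' @param tss_exclusion Promoter half-width for peak exclusion (default
#'   3000).
#' @param proximal_window Gene-target proximity window (default 50000).
#' @param min_overlap Consensus support threshold in samples (default 2).
#' @param cooperative_k Enhancers per gene defining cooperativity (default
#'   5).
#' @param motif_q Motif-hit q-value cutoff (default 0.1).
#' @param enrich_q TF-enrichment q-value cutoff (default 0.1).
#' @param min_expr Expressed-gene mean threshold (default 0).
#' @param k_clusters Clusters to cut the sample dendrogram at (default 2).
#' @param seed Master seed (default 1).
#' @param ... Unknown keys: an error.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(stitch_distance = 12500, tss_exclusion = 3000,
                            proximal_window = 50000, min_overlap = 2,
                            cooperative_k = 5, motif_q = 0.1, enrich_q = 0.1,
                            min_expr = 0, k_clusters = 2, seed = 1, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(sprintf("unknown configuration key: %s", names(extra)[1]))
  }
  cfg <- list(stitch_distance = stitch_distance, tss_exclusion = tss_exclusion,
              proximal_window = proximal_window, min_overlap = min_overlap,
              cooperative_k = cooperative_k, motif_q = motif_q,
              enrich_q = enrich_q, min_expr = min_expr,
              k_clusters = k_clusters, seed = seed)
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && !is.na(x), TRUE)
  if (!all(num)) abort(sprintf("configuration value '%s' must be a single number",
                               names(cfg)[which(!num)[1]]))
  if (any(unlist(cfg[c("stitch_distance", "tss_exclusion", "proximal_window",
                       "min_expr")]) < 0)) {
    abort("distances and thresholds must be non-negative")
  }
  if (min_overlap < 1 || cooperative_k < 1 || k_clusters < 1) {
    abort("min_overlap, cooperative_k and k_clusters must be >= 1")
  }
  if (motif_q <= 0 || motif_q > 1 || enrich_q <= 0 || enrich_q > 1) {
    abort("q-value cutoffs must lie in (0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

#' Pool per-sample peaks into group-level scored peaks
#'
#' Merges all samples' peaks into consensus footprints (support >=
#' `min_overlap` samples) and averages the ChIP and input densities of the
#' contributing sample peaks, giving one scored peak set per group for SE
#' calling.
#'
#' @param peaks Tibble with sample_id, chrom, start, end, chip_density,
#'   input_density.
#' @param min_overlap Consensus support threshold (default 2).
#' @return Tibble chrom, start, end, support, chip_density, input_density.
#' @export
pool_peaks <- function(peaks, min_overlap = 2) {
  cons <- consensus_peaks(peaks, min_overlap = min_overlap)
  if (!nrow(cons)) return(mutate(cons, chip_density = double(),
                                 input_density = double()))
  hits <- GenomicRanges::findOverlaps(
    as_granges(cons[c("chrom", "start", "end")]),
    as_granges(peaks[c("chrom", "start", "end")]))
  dens <- tibble(region = S4Vectors::queryHits(hits),
                 chip = peaks$chip_density[S4Vectors::subjectHits(hits)],
                 input = peaks$input_density[S4Vectors::subjectHits(hits)]) |>
    group_by(.data$region) |>
    summarise(chip_density = mean(.data$chip),
              input_density = mean(.data$input), .groups = "drop")
  cons$chip_density <- 0
  cons$input_density <- 0
  cons$chip_density[dens$region] <- dens$chip_density
  cons$input_density[dens$region] <- dens$input_density
  select(cons, "chrom", "start", "end", "support", "chip_density",
         "input_density")
}

#' Element-by-sample occupancy matrix
#'
#' For each consensus element and sample, the total input-normalized signal
#' (`max(0, chip - input) * length`) of the sample's peaks overlapping the
#' element; 0 where the sample has no peak.
#'
#' @param consensus Consensus elements (chrom, start, end).
#' @param peaks Per-sample peaks with densities.
#' @return Numeric matrix, elements x samples.
#' @export
build_occupancy <- function(consensus, peaks) {
  samples <- sort(unique(peaks$sample_id))
  m <- matrix(0, nrow(consensus), length(samples),
              dimnames = list(NULL, samples))
  if (!nrow(consensus) || !nrow(peaks)) return(m)
  hits <- GenomicRanges::findOverlaps(
    as_granges(consensus[c("chrom", "start", "end")]),
    as_granges(peaks[c("chrom", "start", "end")]))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  sig <- pmax(0, peaks$chip_density[s] - peaks$input_density[s]) *
    (peaks$end[s] - peaks$start[s])
  for (i in seq_along(q)) {
    j <- match(peaks$sample_id[s[i]], samples)
    m[q[i], j] <- m[q[i], j] + sig[i]
  }
  m
}

#' Run the full analysis end-to-end on a synthetic cohort
#'
#' Simulates a cohort, then runs every stage: per-group consensus,
#' group-exclusive sets, peak annotation, per-group SE calling on pooled
#' peaks, target mapping, cooperative-gene classification, regulon
#' over-representation, motif scanning of the DM SE regions against a
#' shuffled background with TF enrichment, the expression hierarchy, sample
#' clustering on the occupancy matrix, and the clinical association tests.
#' Re-running with the same configuration reproduces every result.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built [synthetic_cohort()]; by default one is
#'   simulated from `config$seed`.
#' @return A list of stage results plus a `manifest` echoing the
#'   configuration, seed and package version.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- synthetic_cohort(seed = config$seed)
  peaks <- cohort$peaks
  genes <- cohort$annotation
  pt <- filter(peaks, .data$group == "pt")
  dm <- filter(peaks, .data$group == "dm")

  cons_pt <- consensus_peaks(pt, min_overlap = config$min_overlap)
  cons_dm <- consensus_peaks(dm, min_overlap = config$min_overlap)
  excl <- exclusive_sets(cons_pt, cons_dm)
  annotated_dm <- annotate_peaks(cons_dm, genes,
                                 tss_window = config$tss_exclusion)

  secfg <- se_call_config(stitch_distance = config$stitch_distance,
                          tss_exclusion = config$tss_exclusion,
                          proximal_window = config$proximal_window)
  pooled_dm <- pool_peaks(dm, min_overlap = config$min_overlap)
  pooled_pt <- pool_peaks(pt, min_overlap = config$min_overlap)
  se_dm <- call_superenhancers(pooled_dm, genes, secfg)
  se_pt <- call_superenhancers(pooled_pt, genes, secfg)

  assoc <- map_targets(tidy(se_dm), genes,
                       proximal_window = config$proximal_window)
  counts <- count_res_per_gene(assoc, select(tidy(se_dm), "element_id",
                                             "is_super"))
  coop <- classify_cooperative(counts, k = config$cooperative_k)
  se_target_genes <- sort(unique(
    assoc$gene_id[assoc$element_id %in%
                    tidy(se_dm)$element_id[tidy(se_dm)$is_super]]))

  regulon_res <- regulon_overrepresentation(
    se_target_genes, cohort$regulons, universe = genes$gene_id,
    q_threshold = config$enrich_q)

  enrichment <- NULL
  if (!is.null(cohort$genome)) {
    se_regions <- tidy(se_dm) |>
      filter(.data$is_super) |>
      select(region_id = "element_id", "chrom", "start", "end")
    bg_regions <- shuffle_background(se_regions, cohort$chrom_sizes,
                                     seed = config$seed)
    hits <- bind_rows(
      scan_regions(cohort$genome, se_regions, cohort$pwms,
                   q_threshold = config$motif_q),
      scan_regions(cohort$genome, bg_regions, cohort$pwms,
                   q_threshold = config$motif_q))
    enrichment <- tf_enrichment(se_regions, bg_regions, hits,
                                tfs = names(cohort$pwms),
                                q_threshold = config$enrich_q)
  }

  expressed <- expressed_filter(cohort$expression, min_mean = config$min_expr)
  hierarchy <- expression_hierarchy(
    filter(cohort$expression, .data$gene_id %in% expressed),
    se_genes = cohort$truth$se_genes,
    coop_genes = cohort$truth$cooperative_genes,
    classical_genes = cohort$truth$classical_genes,
    samples = filter(cohort$truth$cluster_labels,
                     .data$group == "dm")$sample_id)

  occupancy <- build_occupancy(
    consensus_peaks(peaks, min_overlap = config$min_overlap), peaks)
  clustering <- cluster_samples(occupancy, k = config$k_clusters)
  clinical <- clinical_association(
    cohort$clinical,
    setNames(cohort$truth$cluster_labels$cluster,
             cohort$truth$cluster_labels$sample_id))

  list(
    cohort = cohort,
    consensus = list(pt = cons_pt, dm = cons_dm),
    exclusive = excl,
    annotated_dm = annotated_dm,
    annotation_summary = annotation_summary(annotated_dm),
    se_call = list(pt = se_pt, dm = se_dm),
    associations = assoc,
    gene_counts = counts,
    cooperative = coop,
    regulon = regulon_res,
    enrichment = enrichment,
    hierarchy = hierarchy,
    clustering = clustering,
    clinical = clinical,
    manifest = list(config = unclass(config), seed = config$seed,
                    package_version = as.character(utils::packageVersion("sescape")),
                    n_samples = n_distinct(peaks$sample_id))
  )
}
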