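# Genomic interval algebra: BED I/O, merging, consensus occupancy across
# samples, group-exclusive sets, and feature-class annotation of peaks.
# Coordinates are 0-based half-open throughout (the BED dialect).

bed_peak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                   "chip_density", "input_density")

#' Read peaks from a BED6+2 file
#'
#' Expects eight tab-separated columns: chrom, start, end, name, score,
#' strand, chip_density, input_density.  Coordinates are 0-based half-open.
#' Signal densities are per-base, input-normalized units (>= 0).
#'
#' @param path Path to a BED6+2 file (no header).
#' @param chrom_sizes Optional tibble with columns `chrom`, `size`; when
#'   supplied, records on unknown chromosomes or running past the end are
#'   rejected.
#' @return A tibble with the eight BED6+2 columns.
#' @seealso [write_bed()]
#' @export
read_peaks <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines))
  if (!length(keep)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character(),
                  chip_density = double(), input_density = double()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8)) {
    i <- which(nf != 8)[1]
    abort(sprintf("malformed BED6+2 record at line %d: expected 8 fields, got %d",
                  keep[i], nf[i]))
  }
  m <- matrix(unlist(fields), ncol = 8, byrow = TRUE)
  suppressWarnings({
    start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
    score <- as.double(m[, 5])
    chip <- as.double(m[, 7]); input <- as.double(m[, 8])
  })
  bad <- which(is.na(start) | is.na(end) | is.na(chip) | is.na(input) |
                 start < 0 | start >= end)
  if (length(bad)) {
    abort(sprintf("malformed BED6+2 record at line %d: need 0 <= start < end and numeric signal",
                  keep[bad[1]]))
  }
  if (any(!(m[, 6] %in% c("+", "-", ".")))) {
    i <- which(!(m[, 6] %in% c("+", "-", ".")))[1]
    abort(sprintf("malformed BED6+2 record at line %d: strand must be +, - or .", keep[i]))
  }
  if (any(chip < 0 | input < 0)) {
    i <- which(chip < 0 | input < 0)[1]
    abort(sprintf("malformed BED6+2 record at line %d: negative signal density", keep[i]))
  }
  out <- tibble(chrom = m[, 1], start = start, end = end, name = m[, 4],
                score = score, strand = m[, 6],
                chip_density = chip, input_density = input)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(out$chrom, chrom_sizes$chrom)
    if (length(unknown)) {
      abort(sprintf("unknown chromosome in %s: %s", path, unknown[1]))
    }
    sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
    over <- which(out$end > sz[out$chrom])
    if (length(over)) {
      abort(sprintf("record at line %d extends past the chromosome end", keep[over[1]]))
    }
  }
  out
}

#' Write intervals or peaks to a BED file
#'
#' Writes whichever of the canonical BED6+2 columns are present, in canonical
#' order, tab-separated with no header.  `read_peaks(write_bed(x))` is an
#' exact round trip for BED6+2 tibbles.
#'
#' @param x Tibble with at least chrom, start, end.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(bed_peak_cols, names(x))
  m <- do.call(cbind, lapply(x[cols], function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE, digits = 15)
    else as.character(col)
  }))
  writeLines(if (is.null(m)) character() else apply(m, 1, paste, collapse = "\t"),
             path)
  invisible(path)
}

#' Merge intervals within a gap
#'
#' Any two intervals on the same chromosome separated by at most `gap` bases
#' (end-to-start, half-open) end up in the same merged output interval.  The
#' output is disjoint and sorted.
#'
#' @param x Tibble with chrom, start, end.
#' @param gap Maximum separation, in bases, at which intervals still merge
#'   (default 0: only touching or overlapping intervals merge).
#' @return Tibble of merged intervals (chrom, start, end), sorted.
#' @export
merge_intervals <- function(x, gap = 0) {
  check_intervals(x)
  stopifnot(gap >= 0)
  if (!nrow(x)) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(as_granges(x[c("chrom", "start", "end")]),
                              min.gapwidth = gap + 1)
  granges_to_tbl(GenomicRanges::sort(gr)) |> arrange(.data$chrom, .data$start)
}

#' Consensus peakset across samples
#'
#' Merges every sample's peaks into candidate regions (gap 0) and keeps the
#' regions detected -- with at least one overlapping base -- in at least
#' `min_overlap` distinct samples.  The merged footprint is reported.
#'
#' @param peaks Tibble of peaks from all samples with a `sample_id` column
#'   (plus chrom, start, end).
#' @param min_overlap Minimum number of supporting samples (default 2).
#' @return Tibble chrom, start, end, support, member_samples (list-column of
#'   sorted sample ids).
#' @export
consensus_peaks <- function(peaks, min_overlap = 2) {
  stopifnot(min_overlap >= 1)
  if (!"sample_id" %in% names(peaks)) abort("peaks must carry a sample_id column")
  if (!nrow(peaks) || !n_distinct(peaks$sample_id)) abort("no samples supplied")
  check_intervals(peaks, "peaks")
  cand <- merge_intervals(peaks, gap = 0)
  hits <- GenomicRanges::findOverlaps(as_granges(cand), as_granges(peaks))
  support_tbl <- tibble(
    region = S4Vectors::queryHits(hits),
    sample_id = peaks$sample_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
  agg <- support_tbl |>
    group_by(.data$region) |>
    summarise(support = n(),
              member_samples = list(sort(unique(.data$sample_id))),
              .groups = "drop")
  cand$support <- 0L
  cand$support[agg$region] <- agg$support
  cand$member_samples <- rep(list(character()), nrow(cand))
  cand$member_samples[agg$region] <- agg$member_samples
  cand |> filter(.data$support >= min_overlap)
}

#' Split two consensus sets into exclusive and shared elements
#'
#' An element of A is exclusive when it shares zero bases with every element
#' of B (and symmetrically).  The shared component carries both sides with a
#' `source` column, so the three sets partition the union of A and B by
#' overlap status.
#'
#' @param a,b Tibbles of intervals (chrom, start, end, ...), same genome.
#' @return Named list `a_only`, `b_only`, `shared`.
#' @export
exclusive_sets <- function(a, b) {
  check_intervals(a, "a"); check_intervals(b, "b")
  ga <- as_granges(a[c("chrom", "start", "end")])
  gb <- as_granges(b[c("chrom", "start", "end")])
  a_hit <- GenomicRanges::countOverlaps(ga, gb) > 0
  b_hit <- GenomicRanges::countOverlaps(gb, ga) > 0
  shared <- bind_rows(
    if (any(a_hit)) mutate(a[a_hit, , drop = FALSE], source = "a") else NULL,
    if (any(b_hit)) mutate(b[b_hit, , drop = FALSE], source = "b") else NULL
  )
  if (is.null(shared)) shared <- mutate(a[0, , drop = FALSE], source = character())
  list(a_only = a[!a_hit, , drop = FALSE],
       b_only = b[!b_hit, , drop = FALSE],
       shared = shared)
}

# spans of each feature class for one gene table, as 0-based half-open tibbles
gene_feature_spans <- function(genes, downstream_window) {
  plus <- genes$strand == "+"
  utr5 <- tibble(chrom = genes$chrom,
                 start = if_else(plus, genes$start, genes$end - genes$utr5),
                 end = if_else(plus, genes$start + genes$utr5, genes$end))
  utr3 <- tibble(chrom = genes$chrom,
                 start = if_else(plus, genes$end - genes$utr3, genes$start),
                 end = if_else(plus, genes$end, genes$start + genes$utr3))
  exon_starts <- lapply(strsplit(genes$exon_starts, ","), as.integer)
  exon_sizes <- lapply(strsplit(genes$exon_sizes, ","), as.integer)
  exons <- tibble(chrom = rep(genes$chrom, lengths(exon_starts)),
                  start = unlist(exon_starts),
                  end = unlist(exon_starts) + unlist(exon_sizes))
  body <- genes[c("chrom", "start", "end")]
  down <- tibble(chrom = genes$chrom,
                 start = if_else(plus, genes$end, genes$start - downstream_window),
                 end = if_else(plus, genes$end + downstream_window, genes$start))
  down <- filter(down, .data$start < .data$end)
  list(utr5 = filter(utr5, .data$start < .data$end),
       utr3 = filter(utr3, .data$start < .data$end),
       exon = exons, body = body, down = down)
}

#' Annotate peaks with genomic feature classes
#'
#' Assigns exactly one feature class per peak, decided by the peak midpoint
#' with precedence TSS > 5'UTR > 3'UTR > Exon > Intron > Downstream >
#' DistalIntergenic.  A midpoint within `tss_window` bases of any TSS is
#' promoter-class; "Downstream" covers midpoints within `downstream_window`
#' bases past a gene end (strand-aware).  The nearest gene is the one with
#' the smallest |midpoint - TSS| (ties broken by gene id).
#'
#' @param peaks Tibble of peaks (chrom, start, end, ...).
#' @param genes Gene models as produced by [make_annotation()]: gene_id,
#'   chrom, start, end, strand, tss, exon_starts, exon_sizes, utr5, utr3.
#' @param tss_window Promoter half-width in bases (default 3000).
#' @param downstream_window Bases past the gene end still called Downstream
#'   (default 300).
#' @return The peaks with `feature_class`, `nearest_gene` and
#'   `distance_to_tss` (signed, positive downstream of the TSS) appended.
#' @export
annotate_peaks <- function(peaks, genes, tss_window = 3000,
                           downstream_window = 300) {
  check_intervals(peaks, "peaks")
  classes <- c("TSS", "5'UTR", "3'UTR", "Exon", "Intron", "Downstream",
               "DistalIntergenic")
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- mutate(peaks, feature_class = "DistalIntergenic",
                nearest_gene = NA_character_, distance_to_tss = NA_integer_)
  if (!nrow(genes) || !nrow(peaks)) {
    out$feature_class <- factor(out$feature_class, levels = classes)
    return(out)
  }
  midgr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  hit_any <- function(span_tbl) {
    if (!nrow(span_tbl)) return(rep(FALSE, nrow(peaks)))
    GenomicRanges::countOverlaps(midgr, as_granges(span_tbl)) > 0
  }
  spans <- gene_feature_spans(genes, downstream_window)
  tss_spans <- tibble(chrom = genes$chrom,
                      start = pmax(0L, genes$tss - tss_window),
                      end = genes$tss + tss_window + 1L)
  cls <- rep("DistalIntergenic", nrow(peaks))
  in_body <- hit_any(spans$body)
  cls[hit_any(spans$down)] <- "Downstream"
  cls[in_body] <- "Intron"
  cls[in_body & hit_any(spans$exon)] <- "Exon"
  cls[hit_any(spans$utr3)] <- "3'UTR"
  cls[hit_any(spans$utr5)] <- "5'UTR"
  cls[hit_any(tss_spans)] <- "TSS"
  # nearest gene by |midpoint - TSS| on the same chromosome, ties by gene id
  genes_sorted <- arrange(genes, .data$gene_id)
  near <- map(seq_len(nrow(peaks)), function(i) {
    g <- genes_sorted[genes_sorted$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(list(NA_character_, NA_integer_))
    d <- abs(mid[i] - g$tss)
    j <- which.min(d) # first minimum = lexicographically smallest gene id
    signed <- if (g$strand[j] == "+") mid[i] - g$tss[j] else g$tss[j] - mid[i]
    list(g$gene_id[j], as.integer(signed))
  })
  out$feature_class <- factor(cls, levels = classes)
  out$nearest_gene <- map_chr(near, 1)
  out$distance_to_tss <- map_int(near, 2)
  out
}

#' Per-class percentages of an annotated peak set
#'
#' @param annotated Output of [annotate_peaks()].
#' @param digits Decimal places for the percentage (default 1).
#' @return Tibble feature_class, n, pct; percentages are computed with
#'   [format_pct()] and sum to ~100.
#' @export
annotation_summary <- function(annotated, digits = 1) {
  annotated |>
    count(.data$feature_class, .drop = FALSE) |>
    mutate(pct = format_pct(.data$n, sum(.data$n), digits = digits))
}
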