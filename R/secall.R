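# ROSE-style super-enhancer calling: promoter exclusion, 12.5 kb stitching,
# input-normalized signal ranking, tangent-slope-1 cutoff on the rescaled
# ranked-signal curve, and element-to-gene target mapping.

#' Configuration for super-enhancer calling
#'
#' @param stitch_distance Peaks separated by at most this many bases are
#'   stitched into one candidate element (default 12500).
#' @param tss_exclusion Half-width of the promoter window; a peak fully
#'   contained in TSS +/- this window is dropped before stitching
#'   (default 3000).
#' @param proximal_window A gene is a proximal target when its TSS lies
#'   within this many bases of the element boundary (default 50000).
#' @return A validated list of class `se_call_config`.
#' @export
se_call_config <- function(stitch_distance = 12500, tss_exclusion = 3000,
                           proximal_window = 50000) {
  stopifnot(stitch_distance >= 0, tss_exclusion >= 0, proximal_window >= 0)
  structure(list(stitch_distance = stitch_distance,
                 tss_exclusion = tss_exclusion,
                 proximal_window = proximal_window),
            class = "se_call_config")
}

#' Remove promoter-contained peaks
#'
#' A peak is removed iff its full span lies within `[TSS - w, TSS + w]` of
#' any gene; peaks merely straddling the window edge are retained.  Applied
#' to constituent peaks before stitching.
#'
#' @param peaks Tibble of peaks.
#' @param genes Gene models with `tss`.
#' @param tss_exclusion Window half-width `w` in bases (default 3000).
#' @return The retained peaks.
#' @export
exclude_tss_peaks <- function(peaks, genes, tss_exclusion = 3000) {
  stopifnot(tss_exclusion >= 0)
  check_intervals(peaks, "peaks")
  if (!nrow(peaks) || !nrow(genes)) return(peaks)
  win <- tibble(chrom = genes$chrom,
                start = pmax(0L, genes$tss - as.integer(tss_exclusion)),
                end = genes$tss + as.integer(tss_exclusion))
  contained <- GenomicRanges::countOverlaps(
    as_granges(peaks[c("chrom", "start", "end")]),
    as_granges(win), type = "within") > 0
  peaks[!contained, , drop = FALSE]
}

#' Stitch peaks into candidate regulatory elements
#'
#' Equivalent to [merge_intervals()] at `gap = stitch_distance`, but records
#' the constituent peaks of every element.  Each input peak belongs to
#' exactly one element.
#'
#' @param peaks Tibble of peaks (with signal densities if the elements are
#'   to be scored).
#' @param stitch_distance Stitching gap in bases (default 12500).
#' @return Tibble of elements: element_id, chrom, start, end,
#'   n_constituents, constituents (list-column of peak tibbles).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  check_intervals(peaks, "peaks")
  if (!nrow(peaks)) {
    return(tibble(element_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_constituents = integer(), constituents = list()))
  }
  els <- merge_intervals(peaks, gap = stitch_distance)
  hits <- GenomicRanges::findOverlaps(as_granges(peaks[c("chrom", "start", "end")]),
                                      as_granges(els))
  idx <- S4Vectors::subjectHits(hits) # one element per peak by construction
  constituents <- map(seq_len(nrow(els)), function(i) {
    k <- S4Vectors::queryHits(hits)[idx == i]
    arrange(peaks[k, , drop = FALSE], .data$start)
  })
  els |>
    mutate(element_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
           n_constituents = map_int(constituents, nrow),
           constituents = constituents) |>
    select("element_id", "chrom", "start", "end", "n_constituents", "constituents")
}

#' Score stitched elements by input-normalized signal
#'
#' Element signal is the sum over constituent peaks of
#' `max(0, chip_density - input_density) * peak_length`; input in excess of
#' ChIP is floored at zero per constituent so that negative-input regions
#' cannot cancel genuine signal elsewhere in the element.
#'
#' @param elements Output of [stitch_peaks()] whose constituents carry
#'   `chip_density` and `input_density`.
#' @return `elements` with a `signal` column appended.
#' @export
score_elements <- function(elements) {
  sig <- map_dbl(elements$constituents, function(p) {
    if (!nrow(p)) return(0)
    sum(pmax(0, p$chip_density - p$input_density) * (p$end - p$start))
  })
  mutate(elements, signal = sig)
}

#' Ranked-signal cutoff separating super-enhancers from classical enhancers
#'
#' Sorts the signals ascending and rescales rank and signal to the unit
#' square.  The threshold is the original signal at the point where the
#' unit-slope line is tangent to the rescaled curve (the point of maximal
#' depth below the diagonal, where the discrete neighbor-difference slope
#' crosses 1 from below); elements with signal strictly above the threshold
#' are super-enhancers.  If the discrete slope never strictly exceeds 1 --
#' a linear ramp, or all-equal signals -- there are no super-enhancers.
#' The partition is invariant to rescaling every signal by a positive
#' constant.
#'
#' @param signals Numeric vector of element signals (length >= 2).
#' @return The threshold signal (elements with `signal > threshold` are
#'   super-enhancers).
#' @export
se_cutoff <- function(signals) {
  stopifnot(length(signals) >= 2, all(signals >= 0))
  y <- sort(signals)
  n <- length(y)
  rng <- y[n] - y[1]
  if (rng == 0) return(y[n]) # degenerate flat curve: no supers by convention
  ys <- (y - y[1]) / rng
  xs <- (seq_len(n) - 1) / (n - 1)
  slope <- diff(ys) / diff(xs)
  # strict crossing, with a relative tolerance so an exactly linear ramp
  # (slope 1 everywhere up to floating error) yields no super-enhancers
  if (!any(slope > 1 + 1e-9)) return(y[n])
  y[which.min(ys - xs)]
}

#' Call super-enhancers and classical enhancers from peaks
#'
#' The full pipeline: promoter exclusion, stitching, input-normalized
#' scoring, ranking (rank 1 = highest signal, ties broken by genomic
#' coordinate), and the ranked-signal cutoff.  SE count plus ENH count
#' equals the element count.
#'
#' @param peaks Tibble of peaks with `chip_density`, `input_density`.
#' @param genes Gene models (for promoter exclusion); may be empty.
#' @param config An [se_call_config()].
#' @return An object of class `se_call`: list with `elements` (the ranked
#'   table with `is_super`), `threshold`, and `config`.  Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
call_superenhancers <- function(peaks, genes, config = se_call_config()) {
  stopifnot(inherits(config, "se_call_config"))
  kept <- exclude_tss_peaks(peaks, genes, config$tss_exclusion)
  if (!nrow(kept)) {
    warn("no peaks remain after promoter exclusion; returning an empty call")
    els <- score_elements(stitch_peaks(kept, config$stitch_distance)) |>
      mutate(rank = integer(), is_super = logical())
    return(structure(list(elements = els, threshold = NA_real_, config = config),
                     class = "se_call"))
  }
  els <- stitch_peaks(kept, config$stitch_distance) |> score_elements()
  ord <- order(-els$signal, els$chrom, els$start)
  els <- els[ord, , drop = FALSE] |> mutate(rank = row_number())
  thr <- if (nrow(els) >= 2) se_cutoff(els$signal) else els$signal
  els <- mutate(els, is_super = .data$signal > thr)
  structure(list(elements = els, threshold = thr, config = config),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("SE call: %d elements (%d super, %d classical), threshold %.4g\n",
              nrow(x$elements), sum(x$elements$is_super),
              sum(!x$elements$is_super), x$threshold))
  invisible(x)
}

#' @rdname call_superenhancers
#' @param x,object An `se_call`.
#' @param ... Unused.
#' @method tidy se_call
#' @export
tidy.se_call <- function(x, ...) {
  select(x$elements, "element_id", "chrom", "start", "end",
         "n_constituents", "signal", "rank", "is_super")
}

#' @rdname call_superenhancers
#' @method glance se_call
#' @export
glance.se_call <- function(x, ...) {
  tibble(n_elements = nrow(x$elements),
         n_super = sum(x$elements$is_super),
         n_enhancer = sum(!x$elements$is_super),
         threshold = x$threshold,
         total_signal = sum(x$elements$signal))
}

#' @rdname call_superenhancers
#' @method autoplot se_call
#' @export
autoplot.se_call <- function(object, ...) {
  d <- tidy(object) |> mutate(asc_rank = rank(.data$signal, ties.method = "first"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$asc_rank, y = .data$signal,
                                  colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "elements ranked by signal",
                  y = "input-normalized signal",
                  colour = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' Map stitched elements to putative target genes
#'
#' Reports the union of three relations per element: `overlapping` (the gene
#' body overlaps the element), `proximal` (the TSS lies within
#' `proximal_window` bases of the element boundary), and `closest` (the
#' single gene with minimal TSS-to-element distance, ties broken by gene
#' id).  One row per (element, gene, relation).
#'
#' @param elements Tibble with element_id, chrom, start, end.
#' @param genes Gene models with `tss`.
#' @param proximal_window Proximity window in bases (default 50000).
#' @return Tibble element_id, gene_id, relation.
#' @export
map_targets <- function(elements, genes, proximal_window = 50000) {
  empty <- tibble(element_id = character(), gene_id = character(),
                  relation = character())
  if (!nrow(elements) || !nrow(genes)) return(empty)
  check_intervals(elements, "elements")
  rows <- map(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    g <- genes[genes$chrom == el$chrom, , drop = FALSE]
    if (!nrow(g)) return(empty)
    dist <- if_else(g$tss < el$start, el$start - g$tss,
                    if_else(g$tss >= el$end, g$tss - (el$end - 1L), 0L))
    overlapping <- g$start < el$end & g$end > el$start
    proximal <- dist <= proximal_window
    closest_id <- g$gene_id[order(dist, g$gene_id)][1]
    bind_rows(
      tibble(element_id = el$element_id, gene_id = g$gene_id[overlapping],
             relation = "overlapping"),
      tibble(element_id = el$element_id, gene_id = g$gene_id[proximal],
             relation = "proximal"),
      tibble(element_id = el$element_id, gene_id = closest_id,
             relation = "closest")
    )
  })
  list_rbind(rows)
}
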