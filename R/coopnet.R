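# Classify genes by the number of converging classical enhancers, identify
# cooperative (>= k enhancers) target genes, and compute group-specific
# regulatory-element sets.

#' Count distinct regulatory elements per gene
#'
#' A gene's count is the number of DISTINCT elements linked to it by any
#' relation: an element reaching a gene as both `overlapping` and `closest`
#' counts once.  Super-enhancers and classical enhancers are counted
#' separately.
#'
#' @param associations Element-to-gene associations from [map_targets()]
#'   (element_id, gene_id, relation).
#' @param element_labels Tibble element_id, is_super; every associated
#'   element must be labelled.
#' @return Tibble gene_id, n_enhancers, n_superenhancers.
#' @export
count_res_per_gene <- function(associations, element_labels) {
  if (!nrow(associations)) {
    return(tibble(gene_id = character(), n_enhancers = integer(),
                  n_superenhancers = integer()))
  }
  unknown <- setdiff(associations$element_id, element_labels$element_id)
  if (length(unknown)) {
    abort(sprintf("association references an unlabelled element: %s", unknown[1]))
  }
  associations |>
    distinct(.data$gene_id, .data$element_id) |>
    left_join(element_labels, by = "element_id") |>
    group_by(.data$gene_id) |>
    summarise(n_enhancers = sum(!.data$is_super),
              n_superenhancers = sum(.data$is_super),
              .groups = "drop")
}

#' Classify genes by enhancer convergence
#'
#' Partitions enhancer-associated genes into `single` (exactly 1 classical
#' enhancer), `multi` (2 to k-1) and `cooperative` (>= k); genes reached
#' only by super-enhancers are classed `none`.
#'
#' @param counts Output of [count_res_per_gene()].
#' @param k Cooperativity threshold (default 5, i.e. five or more elements).
#' @return List with `counts` (input plus a `class` column),
#'   `cooperative_genes` (character vector) and `histogram` (class, n).
#' @export
classify_cooperative <- function(counts, k = 5) {
  stopifnot(k >= 1)
  lev <- c("none", "single", "multi", "cooperative")
  counts <- mutate(counts, class = factor(
    dplyr::case_when(
      .data$n_enhancers >= k ~ "cooperative",
      .data$n_enhancers >= 2 ~ "multi",
      .data$n_enhancers == 1 ~ "single",
      TRUE ~ "none"
    ), levels = lev))
  list(counts = counts,
       cooperative_genes = sort(counts$gene_id[counts$class == "cooperative"]),
       histogram = count(counts, .data$class, .drop = FALSE))
}

#' Group-specific regulatory elements
#'
#' Elements of A with zero-base overlap against every element of B.  When
#' both sets carry an `is_super` column the comparison is class-matched
#' (SE vs SE, ENH vs ENH), mirroring how SE-specific and ENH-specific
#' counts are reported separately.
#'
#' @param elements_a,elements_b Element tibbles (chrom, start, end,
#'   optionally is_super).
#' @return The A-specific rows of `elements_a`.
#' @export
group_specific <- function(elements_a, elements_b) {
  check_intervals(elements_a, "elements_a")
  check_intervals(elements_b, "elements_b")
  if (!nrow(elements_a)) return(elements_a)
  classed <- "is_super" %in% names(elements_a) && "is_super" %in% names(elements_b)
  specific <- function(a, b) {
    if (!nrow(a)) return(a)
    if (!nrow(b)) return(a)
    hit <- GenomicRanges::countOverlaps(
      as_granges(a[c("chrom", "start", "end")]),
      as_granges(b[c("chrom", "start", "end")])) > 0
    a[!hit, , drop = FALSE]
  }
  if (!classed) return(specific(elements_a, elements_b))
  bind_rows(
    specific(elements_a[elements_a$is_super, , drop = FALSE],
             elements_b[elements_b$is_super, , drop = FALSE]),
    specific(elements_a[!elements_a$is_super, , drop = FALSE],
             elements_b[!elements_b$is_super, , drop = FALSE])
  )
}

#' Regions of elements converging on cooperative genes
#'
#' The union of element intervals associated with any cooperative gene,
#' deduplicated (an element shared between two cooperative genes appears
#' once).
#'
#' @param cooperative_genes Character vector of gene ids.
#' @param associations Output of [map_targets()].
#' @param elements Element tibble with element_id, chrom, start, end.
#' @return Deduplicated tibble element_id, chrom, start, end.
#' @export
cooperative_regions <- function(cooperative_genes, associations, elements) {
  if (!length(cooperative_genes)) abort("cooperative gene set is empty")
  ids <- associations |>
    filter(.data$gene_id %in% cooperative_genes) |>
    distinct(.data$element_id)
  elements |>
    inner_join(ids, by = "element_id") |>
    distinct(.data$element_id, .keep_all = TRUE) |>
    select("element_id", "chrom", "start", "end") |>
    arrange(.data$chrom, .data$start)
}

#' Specificity summary with printed-share percentages
#'
#' Formats "n of N (pct%)" rows for group-specific element sets the way
#' cohort studies print them, using [format_pct()].
#'
#' @param n_specific,n_total Named or unnamed counts (same length).
#' @param label Optional labels (e.g. element classes).
#' @return Tibble label, n_specific, n_total, pct.
#' @export
specificity_summary <- function(n_specific, n_total,
                                label = names(n_specific) %||% as.character(seq_along(n_specific))) {
  stopifnot(length(n_specific) == length(n_total))
  tibble(label = label, n_specific = as.integer(n_specific),
         n_total = as.integer(n_total),
         pct = format_pct(n_specific, n_total))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
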