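# Closing statistics: expression hierarchy across regulatory-element classes
# (pairwise Wilcoxon + BH), clinical 2x2 Fisher exact tests, expressed-gene
# filtering, and correlation-based unsupervised sample clustering.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The minimum-likelihood two-sided convention: the p-value sums the
#' hypergeometric probabilities of every table with the same margins whose
#' probability does not exceed that of the observed table.  Rows are the
#' feature levels, columns the sample clusters.
#'
#' @param a,b,c,d Cell counts (row-wise: a,b / c,d), or pass a 2x2 matrix
#'   as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(6, 2, 1, 6) # 0.041
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
    stopifnot(all(dim(m) == c(2, 2)))
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(m < 0) || any(is.na(m))) abort("counts must be non-negative")
  stats::fisher.test(m)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties (both sizes <= 25);
#' otherwise the normal approximation with midranks, tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  exact <- length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Filter to expressed genes
#'
#' A gene is retained iff its mean normalized abundance across the selected
#' samples exceeds `min_mean`.  With the default threshold of 0 on a
#' non-negative matrix this keeps any gene with at least one positive
#' value.
#'
#' @param expr Tibble: `gene_id` plus one numeric column per sample.
#' @param samples Sample columns to average over (default: all).
#' @param min_mean Expression threshold (default 0).
#' @return Character vector of retained gene ids.
#' @export
expressed_filter <- function(expr, samples = NULL, min_mean = 0) {
  all_samples <- setdiff(names(expr), "gene_id")
  if (is.null(samples)) samples <- all_samples
  unknown <- setdiff(samples, all_samples)
  if (length(unknown)) abort(sprintf("unknown sample: %s", unknown[1]))
  m <- as.matrix(expr[samples])
  expr$gene_id[rowMeans(m) > min_mean]
}

#' Expression hierarchy across regulatory-element classes
#'
#' Assigns each gene to one class with precedence SE > cooperative >
#' classical (a gene targeted by both an SE and classical enhancers counts
#' as SE-class), averages expression per gene over the selected samples,
#' runs the three pairwise two-sided Wilcoxon tests, BH-adjusts across the
#' three, and flags whether the class means are ordered
#' SE > cooperative > classical.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param se_genes,coop_genes,classical_genes Gene-id vectors per class.
#' @param samples Samples to average over (default all).
#' @param precedence Apply the SE > cooperative > classical precedence to
#'   overlapping sets (default TRUE); with FALSE overlapping membership is
#'   an error.
#' @return Object of class `hierarchy_result`: gene_means, class_means,
#'   tests (pair, p_value, q_value), ordered.  Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
expression_hierarchy <- function(expr, se_genes, coop_genes, classical_genes,
                                 samples = NULL, precedence = TRUE) {
  if (precedence) {
    coop_genes <- setdiff(coop_genes, se_genes)
    classical_genes <- setdiff(classical_genes, union(se_genes, coop_genes))
  } else if (length(intersect(se_genes, coop_genes)) ||
             length(intersect(se_genes, classical_genes)) ||
             length(intersect(coop_genes, classical_genes))) {
    abort("gene classes overlap; set precedence = TRUE to resolve")
  }
  all_samples <- setdiff(names(expr), "gene_id")
  if (is.null(samples)) samples <- all_samples
  means <- tibble(gene_id = expr$gene_id,
                  mean_expr = rowMeans(as.matrix(expr[samples])))
  sets <- list(SE = se_genes, cooperative = coop_genes,
               classical = classical_genes)
  gene_means <- list_rbind(imap(sets, function(g, cls) {
    filter(means, .data$gene_id %in% g) |> mutate(class = cls)
  }))
  n_per <- table(factor(gene_means$class, levels = names(sets)))
  if (any(n_per == 0)) {
    abort(sprintf("class '%s' has no genes in the expression matrix",
                  names(n_per)[which(n_per == 0)[1]]))
  }
  vals <- split(gene_means$mean_expr, gene_means$class)
  pairs <- list(c("SE", "cooperative"), c("SE", "classical"),
                c("cooperative", "classical"))
  tests <- tibble(
    pair = map_chr(pairs, paste, collapse = " vs "),
    p_value = map_dbl(pairs, function(pr) wilcoxon_rank_sum(vals[[pr[1]]], vals[[pr[2]]]))
  )
  tests$q_value <- benjamini_hochberg(tests$p_value)
  cm <- vapply(vals[names(sets)], mean, 0)
  structure(list(gene_means = as_tibble(gene_means),
                 class_means = cm,
                 tests = tests,
                 ordered = cm[["SE"]] > cm[["cooperative"]] &&
                   cm[["cooperative"]] > cm[["classical"]]),
            class = "hierarchy_result")
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat(sprintf("Expression hierarchy: SE %.3g, cooperative %.3g, classical %.3g (%sordered)\n",
              x$class_means[["SE"]], x$class_means[["cooperative"]],
              x$class_means[["classical"]], if (x$ordered) "" else "NOT "))
  print(x$tests)
  invisible(x)
}

#' @rdname expression_hierarchy
#' @param x,object A `hierarchy_result`.
#' @param ... Unused.
#' @method tidy hierarchy_result
#' @export
tidy.hierarchy_result <- function(x, ...) x$tests

#' @rdname expression_hierarchy
#' @method glance hierarchy_result
#' @export
glance.hierarchy_result <- function(x, ...) {
  tibble(mean_se = x$class_means[["SE"]],
         mean_cooperative = x$class_means[["cooperative"]],
         mean_classical = x$class_means[["classical"]],
         ordered = x$ordered,
         max_q = max(x$tests$q_value))
}

#' @rdname expression_hierarchy
#' @method autoplot hierarchy_result
#' @export
autoplot.hierarchy_result <- function(object, ...) {
  d <- mutate(object$gene_means,
              class = factor(.data$class, levels = c("SE", "cooperative", "classical")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$mean_expr)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "regulatory-element class",
                  y = "mean normalized expression") +
    ggplot2::theme_minimal()
}

#' Unsupervised clustering of samples on the occupancy matrix
#'
#' log2(x + 1)-transforms the element-by-sample signal matrix, computes
#' 1 - Pearson correlation between samples, clusters with average-linkage
#' hierarchical clustering, and cuts the tree at `k`.
#'
#' @param mat Numeric matrix (elements x samples) or tibble with an
#'   `element_id` column.
#' @param k Number of clusters (default 2).
#' @return Object of class `sample_clustering`: labels (tibble sample,
#'   cluster), hclust, order (sample names in dendrogram order).
#' @export
cluster_samples <- function(mat, k = 2) {
  if (is.data.frame(mat)) {
    ids <- setdiff(names(mat), "element_id")
    mat <- as.matrix(mat[ids])
  }
  if (ncol(mat) < k) abort("need at least k samples")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  m <- log2(mat + 1)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("sample '%s' has constant signal; correlation undefined",
                  colnames(m)[which(sds == 0)[1]]))
  }
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, k = k)
  structure(list(labels = tibble(sample = names(labels), cluster = unname(labels)),
                 hclust = hc, order = colnames(m)[hc$order], k = k),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("Sample clustering: %d samples in %d clusters\n",
              nrow(x$labels), x$k))
  print(table(x$labels$cluster))
  invisible(x)
}

#' @rdname cluster_samples
#' @param x A `sample_clustering`.
#' @param ... Unused.
#' @method tidy sample_clustering
#' @export
tidy.sample_clustering <- function(x, ...) x$labels

#' Clinical feature association with sample clusters
#'
#' Builds one 2x2 table per binary clinical feature (rows = feature levels,
#' columns = clusters, both in sorted order) and tests it with the
#' two-sided Fisher exact test.  A feature constant across samples is
#' flagged degenerate with p = 1; features with more than two levels are an
#' error (dichotomize first).
#'
#' @param clinical Tibble: `sample_id` plus feature columns
#'   (character/factor, two levels).
#' @param cluster_labels Tibble sample, cluster (two clusters), or a named
#'   vector.
#' @param features Feature columns to test (default: all non-id character
#'   or factor columns).
#' @return Tibble feature, level_1, level_2, a, b, c, d, p_value,
#'   degenerate.
#' @export
clinical_association <- function(clinical, cluster_labels, features = NULL) {
  if (!is.data.frame(cluster_labels)) {
    cluster_labels <- tibble(sample = names(cluster_labels),
                             cluster = unname(cluster_labels))
  }
  dat <- clinical |>
    select(-dplyr::any_of("cluster")) |> # labels come from cluster_labels
    inner_join(cluster_labels, by = c(sample_id = "sample"))
  clusters <- sort(unique(dat$cluster))
  if (length(clusters) != 2) abort("exactly two clusters are required")
  if (is.null(features)) {
    features <- names(clinical)[vapply(clinical, function(col)
      is.character(col) || is.factor(col), TRUE)]
    features <- setdiff(features, "sample_id")
  }
  list_rbind(map(features, function(f) {
    v <- as.character(dat[[f]])
    lev <- sort(unique(v))
    if (length(lev) > 2) {
      abort(sprintf("feature '%s' has %d levels; dichotomize it first",
                    f, length(lev)))
    }
    if (length(lev) < 2) {
      return(tibble(feature = f, level_1 = lev[1], level_2 = NA_character_,
                    a = sum(dat$cluster == clusters[1]),
                    b = sum(dat$cluster == clusters[2]),
                    c = 0L, d = 0L, p_value = 1, degenerate = TRUE))
    }
    a <- sum(v == lev[1] & dat$cluster == clusters[1])
    b <- sum(v == lev[1] & dat$cluster == clusters[2])
    cc <- sum(v == lev[2] & dat$cluster == clusters[1])
    dd <- sum(v == lev[2] & dat$cluster == clusters[2])
    tibble(feature = f, level_1 = lev[1], level_2 = lev[2],
           a = a, b = b, c = cc, d = dd,
           p_value = fisher_exact_two_sided(a, b, cc, dd),
           degenerate = FALSE)
  }))
}
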