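# Independent brute-force oracles used to cross-check the fast
# implementations.  These deliberately avoid the code paths they verify:
# quadratic loops, per-base counting, and exhaustive enumeration.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           max_len = 300) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(max_pos, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_len, n, replace = TRUE))
}

# transitive closure on the gap graph: intervals are connected when their
# separation on the same chromosome is <= gap; each component spans
# [min start, max end]
oracle_merge <- function(x, gap = 0) {
  if (!nrow(x)) return(tibble::tibble(chrom = character(), start = integer(),
                                      end = integer()))
  out <- lapply(split(x, x$chrom), function(d) {
    n <- nrow(d)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      sep <- max(d$start[i], d$start[j]) - min(d$end[i], d$end[j])
      adj[i, j] <- sep <= gap
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    do.call(rbind, lapply(unique(comp), function(cp) {
      data.frame(chrom = d$chrom[1],
                 start = min(d$start[comp == cp]),
                 end = max(d$end[comp == cp]))
    }))
  })
  dplyr::arrange(tibble::as_tibble(do.call(rbind, out)), chrom, start)
}

# per-base counting consensus: candidate regions from the union coverage,
# support = samples contributing at least one covered base
oracle_consensus <- function(peaks, min_overlap = 2) {
  res <- lapply(split(peaks, peaks$chrom), function(d) {
    L <- max(d$end) + 1L
    cov_any <- logical(L)
    for (i in seq_len(nrow(d))) cov_any[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(cov_any)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    regions <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
    regions$support <- vapply(seq_len(nrow(regions)), function(k) {
      length(unique(d$sample_id[d$start < regions$end[k] &
                                  d$end > regions$start[k]]))
    }, 0L)
    regions$chrom <- d$chrom[1]
    regions
  })
  out <- tibble::as_tibble(do.call(rbind, res))
  dplyr::arrange(out[out$support >= min_overlap,
                     c("chrom", "start", "end", "support")], chrom, start)
}

oracle_exclusive <- function(a, b) {
  hit_a <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, TRUE)
  hit_b <- vapply(seq_len(nrow(b)), function(i) {
    any(a$chrom == b$chrom[i] & a$start < b$end[i] & a$end > b$start[i])
  }, TRUE)
  list(a_only = a[!hit_a, ], b_only = b[!hit_b, ],
       shared_a = a[hit_a, ], shared_b = b[hit_b, ])
}

# exhaustive per-gene feature classification at the peak midpoint
oracle_annotate <- function(peaks, genes, tss_window = 3000,
                            downstream_window = 300) {
  vapply(seq_len(nrow(peaks)), function(i) {
    m <- (peaks$start[i] + peaks$end[i]) %/% 2
    cls <- "DistalIntergenic"
    in_any <- function(test) {
      any(vapply(seq_len(nrow(genes)), function(g) {
        genes$chrom[g] == peaks$chrom[i] && test(genes[g, ])
      }, TRUE))
    }
    exon_hit <- in_any(function(g) {
      es <- as.integer(strsplit(g$exon_starts, ",")[[1]])
      sz <- as.integer(strsplit(g$exon_sizes, ",")[[1]])
      any(m >= es & m < es + sz)
    })
    body_hit <- in_any(function(g) m >= g$start && m < g$end)
    down_hit <- in_any(function(g) {
      if (g$strand == "+") m >= g$end && m < g$end + downstream_window
      else m >= g$start - downstream_window && m < g$start
    })
    utr5_hit <- in_any(function(g) {
      if (g$strand == "+") m >= g$start && m < g$start + g$utr5
      else m >= g$end - g$utr5 && m < g$end
    })
    utr3_hit <- in_any(function(g) {
      if (g$strand == "+") m >= g$end - g$utr3 && m < g$end
      else m >= g$start && m < g$start + g$utr3
    })
    tss_hit <- in_any(function(g) abs(m - g$tss) <= tss_window)
    if (down_hit) cls <- "Downstream"
    if (body_hit) cls <- "Intron"
    if (body_hit && exon_hit) cls <- "Exon"
    if (utr3_hit) cls <- "3'UTR"
    if (utr5_hit) cls <- "5'UTR"
    if (tss_hit) cls <- "TSS"
    cls
  }, "")
}

oracle_map_targets <- function(elements, genes, proximal_window = 50000) {
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    g <- genes[genes$chrom == elements$chrom[i], ]
    if (!nrow(g)) next
    d <- vapply(seq_len(nrow(g)), function(j) {
      if (g$tss[j] < elements$start[i]) as.numeric(elements$start[i] - g$tss[j])
      else if (g$tss[j] >= elements$end[i]) as.numeric(g$tss[j] - (elements$end[i] - 1))
      else 0
    }, 0)
    for (j in seq_len(nrow(g))) {
      if (g$start[j] < elements$end[i] && g$end[j] > elements$start[i]) {
        rows[[length(rows) + 1]] <- data.frame(
          element_id = elements$element_id[i], gene_id = g$gene_id[j],
          relation = "overlapping")
      }
      if (d[j] <= proximal_window) {
        rows[[length(rows) + 1]] <- data.frame(
          element_id = elements$element_id[i], gene_id = g$gene_id[j],
          relation = "proximal")
      }
    }
    best <- g$gene_id[order(d, g$gene_id)][1]
    rows[[length(rows) + 1]] <- data.frame(
      element_id = elements$element_id[i], gene_id = best,
      relation = "closest")
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# minimum-likelihood two-sided Fisher p by enumerating all tables with the
# observed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# enumerate all 4^w windows: integerized score distribution under the
# i.i.d. background (independent of the DP convolution it checks)
oracle_score_distribution <- function(int_scores, background) {
  w <- ncol(int_scores)
  grids <- do.call(expand.grid, rep(list(1:4), w))
  scores <- apply(grids, 1, function(bases) {
    sum(int_scores[cbind(bases, seq_len(w))])
  })
  probs <- apply(grids, 1, function(bases) prod(background[bases]))
  agg <- tapply(probs, scores, sum)
  tibble::tibble(score = as.integer(names(agg)), prob = as.numeric(agg))
}

# score every window of one sequence with nested loops
oracle_window_scores <- function(s, log_odds) {
  w <- ncol(log_odds)
  base_idx <- c(A = 1, C = 2, G = 3, T = 4)
  chars <- strsplit(s, "")[[1]]
  vapply(seq_len(nchar(s) - w + 1), function(i) {
    sum(vapply(seq_len(w), function(j) log_odds[base_idx[[chars[i + j - 1]]], j], 0))
  }, 0)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# small, fast synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 1, sequence = FALSE) {
  synthetic_cohort(
    seed = seed, n_pt = 6, n_dm = 6,
    config = cohort_config(n_se = 4, n_coop_genes = 4,
                           n_classical_genes = 6, n_extra_pt = 4),
    n_chrom = 2, chrom_len = 1500000, n_genes = 24,
    sequence = sequence)
}

f1_score <- function(called, truth) {
  tp <- length(intersect(called, truth))
  if (!length(called) || !length(truth) || !tp) return(0)
  p <- tp / length(called); r <- tp / length(truth)
  2 * p * r / (p + r)
}
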