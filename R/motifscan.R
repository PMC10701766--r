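# Two-step upstream-TF inference: regulon over-representation on target gene
# lists, then PWM scanning of regulatory-element sequence with exact p-values
# from an integerized dynamic-programming score distribution, a constrained
# shuffled-background null, and chi-squared binding-difference ranking.

DNA_BASES <- c("A", "C", "G", "T")

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min over j >= rank(i) of m * p_(j) / j`,
#' capped at 1 and order-preserving.
#'
#' @param p Numeric p-values in (0, 1].
#' @return q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Regulon over-representation test for upstream TFs
#'
#' For every TF in the regulon library, the hypergeometric upper-tail
#' probability of observing at least the seen overlap between the TF's
#' regulon and the target gene list, given the universe; BH-adjusted across
#' TFs.
#'
#' @param target_genes Character vector of target gene ids.
#' @param regulons Tibble tf, target (one row per regulon edge).
#' @param universe Character vector of all considered genes.
#' @param q_threshold Selection cutoff on the BH q-value (default 0.1).
#' @return Tibble tf, n_overlap, n_regulon, n_targets, p_value, q_value,
#'   selected; sorted by p.
#' @export
regulon_overrepresentation <- function(target_genes, regulons, universe,
                                       q_threshold = 0.1) {
  if (!length(universe)) abort("universe must be non-empty")
  universe <- unique(universe)
  targets <- intersect(unique(target_genes), universe)
  res <- regulons |>
    filter(.data$target %in% universe) |>
    distinct(.data$tf, .data$target) |>
    group_by(.data$tf) |>
    summarise(n_overlap = sum(.data$target %in% targets),
              n_regulon = n(), .groups = "drop") |>
    mutate(n_targets = length(targets),
           p_value = phyper(.data$n_overlap - 1, .data$n_regulon,
                            length(universe) - .data$n_regulon,
                            length(targets), lower.tail = FALSE),
           q_value = benjamini_hochberg(.data$p_value),
           selected = .data$q_value < q_threshold) |>
    arrange(.data$p_value)
  res
}

#' Build a position weight matrix from counts
#'
#' Probabilities are `(count + pseudocount) / (column_total + 4 *
#' pseudocount)`; log-odds are `log2(prob / background)`.
#'
#' @param counts 4 x width numeric matrix of base counts, rows A, C, G, T.
#' @param pseudocount Added to every cell (default 0.5).
#' @param background Base frequencies (A, C, G, T); default flat.
#' @param tf Name attached to the motif.
#' @return An object of class `pwm`: list with tf, width, probs, log_odds,
#'   background, consensus.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.5,
                            background = rep(0.25, 4), tf = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 4, all(counts >= 0),
            length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  if (any(colSums(counts) == 0)) abort("PWM has an all-zero position")
  rownames(counts) <- DNA_BASES
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  log_odds <- log2(probs / background)
  structure(list(tf = tf, width = ncol(counts), probs = probs,
                 log_odds = log_odds, background = background,
                 consensus = paste(DNA_BASES[apply(probs, 2, which.max)],
                                   collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: width %d, consensus %s\n", x$tf, x$width, x$consensus))
  invisible(x)
}

#' Read / write JASPAR-style PWM count matrices
#'
#' The plain-text format: a `>id name` header followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @param path File path.
#' @return `read_jaspar()`: a named list of 4 x width count matrices.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no JASPAR records found")
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) != 4) abort(sprintf("JASPAR record %d: expected 4 base rows", i))
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = parts[1], counts = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES)) abort(sprintf("JASPAR record %d: rows must be A,C,G,T", i))
    m <- do.call(rbind, lapply(DNA_BASES, function(b) rows[[which(bases == b)]]$counts))
    rownames(m) <- DNA_BASES
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]]
    out[[tail(name, 1)]] <- m
  }
  out
}

#' @rdname read_jaspar
#' @param counts_list Named list of 4 x width count matrices.
#' @export
write_jaspar <- function(counts_list, path) {
  lines <- unlist(imap(counts_list, function(m, nm) {
    c(paste0(">", nm, " ", nm),
      vapply(seq_len(4), function(r) {
        sprintf("%s [ %s ]", DNA_BASES[r], paste(m[r, ], collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Exact null distribution of PWM window scores
#'
#' Integerizes per-position log-odds at the given granularity and convolves
#' them by dynamic programming over positions, yielding the exact
#' probability of every achievable (integerized) window score under an
#' i.i.d. background.  The tail `P(score >= s)` is the scanner's p-value.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param background Base frequencies for the null (default: the PWM's own
#'   background).
#' @param granularity Score discretization step (default 1e-3; rounding
#'   error is at most granularity/2 per position).
#' @return Object of class `score_distribution`: int_scores (4 x width),
#'   support (integer scores), prob, tail, granularity.  `as_tibble()` gives
#'   score, prob, p_value.
#' @export
score_distribution <- function(pwm, background = pwm$background,
                               granularity = 1e-3) {
  stopifnot(inherits(pwm, "pwm"), granularity > 0)
  int_scores <- round(pwm$log_odds / granularity)
  cur_lo <- 0L
  cur <- 1 # P(sum of zero positions = 0) = 1
  for (j in seq_len(pwm$width)) {
    s <- int_scores[, j]
    new_lo <- cur_lo + min(s)
    new_hi <- cur_lo + length(cur) - 1 + max(s)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- cur_lo + s[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_lo <- as.integer(new_lo)
  }
  support <- seq.int(cur_lo, cur_lo + length(cur) - 1)
  keep <- cur > 0
  tail_all <- rev(cumsum(rev(cur)))
  structure(list(int_scores = int_scores,
                 support = support[keep], prob = cur[keep],
                 tail = tail_all[keep],
                 full_lo = cur_lo, full_tail = tail_all,
                 granularity = granularity),
            class = "score_distribution")
}

#' @exportS3Method tibble::as_tibble
as_tibble.score_distribution <- function(x, ...) {
  tibble(score = x$support * x$granularity, prob = x$prob, p_value = x$tail)
}

# p-value lookup for integerized window scores
score_pvalue <- function(dist, int_score) {
  idx <- int_score - dist$full_lo + 1
  idx <- pmin(pmax(idx, 1), length(dist$full_tail))
  p <- dist$full_tail[idx]
  # scores above the achievable maximum are impossible under the same
  # integerization; below the minimum the tail is 1
  p[int_score > dist$full_lo + length(dist$full_tail) - 1] <- NA_real_
  p[int_score < dist$full_lo] <- 1
  # guard against floating-point drift in the cumulated tail
  pmin(pmax(p, .Machine$double.xmin), 1)
}

seq_to_codes <- function(s) {
  x <- utf8ToInt(toupper(s))
  codes <- rep(NA_integer_, 128)
  codes[utf8ToInt("A")] <- 1L; codes[utf8ToInt("C")] <- 2L
  codes[utf8ToInt("G")] <- 3L; codes[utf8ToInt("T")] <- 4L
  codes[x]
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# integerized window scores along one strand of one sequence; NA where the
# window contains a non-ACGT base
window_scores <- function(codes, int_scores) {
  w <- ncol(int_scores)
  L <- length(codes)
  if (L < w) return(integer(0))
  nwin <- L - w + 1
  sc <- numeric(nwin)
  for (j in seq_len(w)) {
    sc <- sc + int_scores[codes[j:(j + nwin - 1)], j]
  }
  unname(sc)
}

#' Scan sequences with a PWM
#'
#' Scores every window on both strands, assigns each window the exact tail
#' p-value from [score_distribution()], BH-adjusts across all scanned
#' windows of this PWM (both strands, all sequences), and keeps hits with
#' `q < q_threshold`.  Windows containing N are skipped; sequences shorter
#' than the motif yield no windows.  Coordinates are 0-based half-open
#' within each sequence; minus-strand hits are reported on the forward
#' coordinate system.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param pwm A [pwm_from_counts()] object.
#' @param background Null base frequencies (default: the PWM's).
#' @param q_threshold BH q-value cutoff for retained hits (default 0.1).
#' @param dist Optional precomputed [score_distribution()].
#' @return Tibble seqname, start, end, strand, tf, score, p_value, q_value.
#' @export
scan_pwm <- function(sequences, pwm, background = pwm$background,
                     q_threshold = 0.1, dist = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) names(sequences) <- as.character(seq_along(sequences))
  if (is.null(dist)) dist <- score_distribution(pwm, background)
  w <- pwm$width
  rows <- imap(sequences, function(s, nm) {
    L <- nchar(s)
    if (L < w) return(NULL)
    fwd <- window_scores(seq_to_codes(s), dist$int_scores)
    rev <- window_scores(seq_to_codes(revcomp_chr(s)), dist$int_scores)
    bind_rows(
      tibble(seqname = nm, start = seq_along(fwd) - 1L, strand = "+", int = fwd),
      # window i on the reverse complement starts at L - (i-1) - w forward
      tibble(seqname = nm, start = L - seq_along(rev) - w + 1L, strand = "-",
             int = rev)
    )
  })
  hits <- list_rbind(rows)
  if (is.null(hits) || !nrow(hits)) {
    return(tibble(seqname = character(), start = integer(), end = integer(),
                  strand = character(), tf = character(), score = double(),
                  p_value = double(), q_value = double()))
  }
  hits <- filter(hits, !is.na(.data$int))
  hits <- mutate(hits, p_value = score_pvalue(dist, .data$int))
  hits$q_value <- benjamini_hochberg(hits$p_value)
  hits |>
    filter(.data$q_value < q_threshold) |>
    mutate(end = .data$start + w, tf = pwm$tf,
           score = .data$int * dist$granularity) |>
    select("seqname", "start", "end", "strand", "tf", "score",
           "p_value", "q_value") |>
    arrange(.data$seqname, .data$start, .data$strand)
}

#' Scan genomic regions with one or more PWMs
#'
#' Extracts each region's sequence from the genome, scans it with
#' [scan_pwm()] and lifts hit coordinates back to the genome.  The null base
#' frequencies default to the zero-order composition of the supplied
#' genome.
#'
#' @param genome A `DNAStringSet` (names = chromosomes).
#' @param regions Tibble with region_id, chrom, start, end.
#' @param pwms A single `pwm` or list of them.
#' @param q_threshold BH q-value cutoff per PWM (default 0.1).
#' @param background Optional base frequencies; default estimated from the
#'   genome.
#' @return Tibble region_id, chrom, start, end, strand, tf, score, p_value,
#'   q_value (genomic coordinates).
#' @export
scan_regions <- function(genome, regions, pwms, q_threshold = 0.1,
                         background = NULL) {
  check_intervals(regions, "regions")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions,
                      region_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end))
  }
  if (is.null(background)) background <- genome_base_frequencies(genome)
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    regions$start[i] + 1L, regions$end[i]))
  }, "")
  names(seqs) <- regions$region_id
  hits <- list_rbind(map(pwms, function(p) {
    d <- score_distribution(p, background)
    scan_pwm(seqs, p, background = background, q_threshold = q_threshold,
             dist = d)
  }))
  if (is.null(hits) || !nrow(hits)) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  tf = character(), score = double(), p_value = double(),
                  q_value = double()))
  }
  hits |>
    rename(region_id = "seqname") |>
    left_join(select(regions, "region_id", "chrom", region_start = "start"),
              by = "region_id") |>
    mutate(start = .data$start + .data$region_start,
           end = .data$end + .data$region_start) |>
    select("region_id", "chrom", "start", "end", "strand", "tf", "score",
           "p_value", "q_value")
}

#' Zero-order base composition of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Length-4 frequency vector (A, C, G, T), normalized over ACGT.
#' @export
genome_base_frequencies <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(genome, DNA_BASES))
  as.numeric(counts / sum(counts))
}

#' Shuffled background regions on the same chromosomes
#'
#' For each input region (in order), places one background region of the
#' same length on the same chromosome, uniformly over the placement space
#' that remains valid: a background region may overlap neither any excluded
#' region (the input regions themselves by default) nor a previously placed
#' background region.  Sampling is exact over the valid start positions, so
#' a single remaining slot is found deterministically; an error names the
#' chromosome when no valid start exists.
#'
#' @param regions Tibble region_id, chrom, start, end.
#' @param chrom_sizes Tibble chrom, size.
#' @param excluded Regions background may not touch (default: `regions`).
#' @param seed Integer seed for reproducible placement.
#' @return Tibble region_id, chrom, start, end mirroring the input order,
#'   with `region_id` suffixed `_bg`.
#' @export
shuffle_background <- function(regions, chrom_sizes, excluded = regions,
                               seed = 1) {
  check_intervals(regions, "regions")
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions,
                      region_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end))
  }
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  unknown <- setdiff(regions$chrom, names(sizes))
  if (length(unknown)) abort(sprintf("unknown chromosome: %s", unknown[1]))
  # mutable per-chromosome exclusion lists (start, end tibbles)
  excl <- split(excluded[c("start", "end")], excluded$chrom)
  with_child_seed(seed, 101, {
    placed <- vector("list", nrow(regions))
    for (i in seq_len(nrow(regions))) {
      chrom <- regions$chrom[i]
      len <- regions$end[i] - regions$start[i]
      L <- sizes[[chrom]]
      ex <- excl[[chrom]]
      # free gaps between merged exclusions, clipped to the chromosome
      if (!is.null(ex) && nrow(ex)) {
        m <- merge_intervals(tibble(chrom = chrom, start = ex$start, end = ex$end))
        gap_start <- c(0, m$end)
        gap_end <- c(m$start, L)
      } else {
        gap_start <- 0; gap_end <- L
      }
      ok <- gap_end - gap_start >= len
      starts_per_gap <- (gap_end - gap_start - len + 1)[ok]
      total <- sum(starts_per_gap)
      if (total <= 0) {
        abort(sprintf("no valid background placement left on %s for a %d bp region",
                      chrom, len))
      }
      u <- sample.int(total, 1)
      g <- which(cumsum(starts_per_gap) >= u)[1]
      offset <- u - c(0, cumsum(starts_per_gap))[g] - 1
      s <- gap_start[ok][g] + offset
      placed[[i]] <- tibble(region_id = paste0(regions$region_id[i], "_bg"),
                            chrom = chrom, start = as.integer(s),
                            end = as.integer(s + len))
      excl[[chrom]] <- bind_rows(ex, tibble(start = as.integer(s),
                                            end = as.integer(s + len)))
    }
    list_rbind(placed)
  })
}

#' TF enrichment in regulatory elements versus background
#'
#' A region is "bound" by a TF when at least one retained motif hit (either
#' strand) falls in it.  Per TF, a 2x2 bound/unbound x RE/background table
#' is tested with the Pearson chi-squared statistic (no continuity
#' correction), BH-adjusted across TFs.  The binding difference is
#' `pct_re_bound - pct_bg_bound` in percentage points; a TF is selected iff
#' `q < q_threshold` and the difference is positive (enrichment in the
#' analyzed regions, not depletion).  Output is ranked by descending
#' binding difference.
#'
#' @param re_regions,bg_regions Tibbles with region_id.
#' @param hits Motif hits carrying `region_id` and `tf` (e.g. from
#'   [scan_regions()] run on both arms).
#' @param tfs TFs to report (default: those present in `hits`).
#' @param q_threshold Selection cutoff (default 0.1).
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A `tf_enrichment` tibble: tf, n_re_bound, n_bg_bound,
#'   pct_re_bound, pct_bg_bound, binding_difference, chi2_stat, p_value,
#'   q_value, selected.
#' @export
tf_enrichment <- function(re_regions, bg_regions, hits,
                          tfs = NULL, q_threshold = 0.1, correct = FALSE) {
  n_re <- nrow(re_regions); n_bg <- nrow(bg_regions)
  if (!n_re || !n_bg) abort("both region arms must be non-empty")
  if (is.null(tfs)) tfs <- sort(unique(hits$tf))
  if (!length(tfs)) abort("no TFs to test")
  res <- list_rbind(map(tfs, function(tf) {
    h <- hits[hits$tf == tf, , drop = FALSE]
    b_re <- n_distinct(intersect(h$region_id, re_regions$region_id))
    b_bg <- n_distinct(intersect(h$region_id, bg_regions$region_id))
    tibble(tf = tf, n_re_bound = b_re, n_bg_bound = b_bg)
  }))
  res <- res |>
    mutate(pct_re_bound = 100 * .data$n_re_bound / n_re,
           pct_bg_bound = 100 * .data$n_bg_bound / n_bg,
           binding_difference = .data$pct_re_bound - .data$pct_bg_bound)
  stat <- map_dbl(seq_len(nrow(res)), function(i) {
    pearson_chi2(res$n_re_bound[i], n_re - res$n_re_bound[i],
                 res$n_bg_bound[i], n_bg - res$n_bg_bound[i],
                 correct = correct)
  })
  res <- res |>
    mutate(chi2_stat = stat,
           p_value = pchisq(stat, df = 1, lower.tail = FALSE),
           q_value = benjamini_hochberg(.data$p_value),
           selected = .data$q_value < q_threshold & .data$binding_difference > 0) |>
    arrange(desc(.data$binding_difference))
  class(res) <- c("tf_enrichment", class(res))
  res
}

# Pearson chi-squared on a 2x2 (a,b // c,d); degenerate margins give 0
pearson_chi2 <- function(a, b, c, d, correct = FALSE) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  n * dev^2 / (r1 * r2 * c1 * c2)
}

#' @exportS3Method generics::tidy
tidy.tf_enrichment <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.tf_enrichment <- function(x, ...) {
  tibble(n_tf = nrow(x), n_selected = sum(x$selected),
         top_tf = if (nrow(x)) x$tf[1] else NA_character_,
         top_binding_difference = if (nrow(x)) x$binding_difference[1] else NA_real_)
}

#' @exportS3Method ggplot2::autoplot
autoplot.tf_enrichment <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(tf = factor(.data$tf, levels = rev(.data$tf)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$binding_difference, y = .data$tf,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "binding difference (percentage points)", y = NULL,
                  fill = "selected (q < 0.1, enriched)") +
    ggplot2::theme_minimal()
}
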