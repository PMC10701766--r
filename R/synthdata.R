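# Fully synthetic cohort generator: genome, gene annotation, per-sample peak
# calls with input-normalized signal, planted super-enhancer clusters and
# cooperative-enhancer wiring, motif instances written into SE sequence, an
# expression matrix with an ordered class hierarchy, and a clinical table
# associated with sample groups.  Every ground-truth object is recoverable
# from the emitted tables alone.  All generators are pure functions of
# (config, seed): child RNG streams are derived from the master seed by
# fixed offsets, so outputs are reproducible byte for byte.

#' Generate a random genome
#'
#' I.i.d. sequence at the stated GC content (A and T share `(1 - gc)/2`
#' each, C and G share `gc/2`).
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_len Length of each chromosome in bases.
#' @param gc GC fraction in (0, 1).
#' @param seed Master seed.
#' @return List: `genome` (a `DNAStringSet` named chr1..chrN) and
#'   `chrom_sizes` (tibble chrom, size).
#' @export
make_genome <- function(n_chrom, chrom_len, gc = 0.41, seed = 1) {
  if (n_chrom < 1 || chrom_len <= 0) abort("n_chrom >= 1 and chrom_len > 0 required")
  stopifnot(gc > 0, gc < 1)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_child_seed(seed, 1, {
    vapply(seq_len(n_chrom), function(i) {
      paste(DNA_BASES[sample.int(4, chrom_len, replace = TRUE, prob = probs)],
            collapse = "")
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  list(genome = Biostrings::DNAStringSet(seqs),
       chrom_sizes = tibble(chrom = names(seqs),
                            size = as.integer(rep(chrom_len, n_chrom))))
}

#' Generate gene models
#'
#' Places `n_genes` genes across the chromosomes (proportionally to size)
#' with at least `min_spacing` bases between consecutive gene starts, a
#' random strand, `n_exons` exons with intervening introns, and fixed UTR
#' lengths clipped into the terminal exons.  The TSS is the first
#' transcribed base (gene start on +, gene end - 1 on -).  Coordinates are
#' 0-based half-open.
#'
#' @param chrom_sizes Tibble chrom, size.
#' @param n_genes Number of genes (0 gives a valid empty annotation).
#' @param min_spacing Minimum distance between consecutive gene starts on a
#'   chromosome (default 2000).
#' @param gene_length_range Min/max gene length in bases.
#' @param n_exons Exons per gene (default 3).
#' @param utr5,utr3 UTR lengths in bases.
#' @param seed Master seed.
#' @return Tibble gene_id, chrom, start, end, strand, tss, n_exons,
#'   exon_starts, exon_sizes (comma strings, absolute 0-based), utr5, utr3.
#' @export
make_annotation <- function(chrom_sizes, n_genes, min_spacing = 2000,
                            gene_length_range = c(2000, 10000), n_exons = 3,
                            utr5 = 200, utr3 = 300, seed = 1) {
  stopifnot(n_genes >= 0, min_spacing >= 0, n_exons >= 1)
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  tss = integer(), n_exons = integer(),
                  exon_starts = character(), exon_sizes = character(),
                  utr5 = integer(), utr3 = integer())
  if (n_genes == 0) return(empty)
  max_len <- gene_length_range[2]
  # apportion genes to chromosomes proportionally to size
  share <- chrom_sizes$size / sum(chrom_sizes$size)
  n_per <- floor(share * n_genes)
  rem <- n_genes - sum(n_per)
  if (rem > 0) n_per[order(-share)[seq_len(rem)]] <- n_per[order(-share)[seq_len(rem)]] + 1
  slack <- chrom_sizes$size - max_len - n_per * min_spacing
  if (any(slack < 0 & n_per > 0)) {
    abort(sprintf("cannot place %d genes with %d bp spacing: chromosome %s is too short",
                  n_genes, min_spacing,
                  chrom_sizes$chrom[which(slack < 0 & n_per > 0)[1]]))
  }
  with_child_seed(seed, 2, {
    rows <- map(seq_len(nrow(chrom_sizes)), function(ci) {
      nc <- n_per[ci]
      if (nc == 0) return(NULL)
      # sorted uniform draws over the slack, shifted apart by min_spacing:
      # consecutive starts then differ by at least min_spacing
      u <- sort(sample.int(slack[ci] + 1, nc, replace = TRUE) - 1L)
      starts <- u + (seq_len(nc) - 1L) * min_spacing
      lens <- sample.int(gene_length_range[2] - gene_length_range[1] + 1, nc,
                         replace = TRUE) + gene_length_range[1] - 1L
      strand <- sample(c("+", "-"), nc, replace = TRUE)
      tibble(chrom = chrom_sizes$chrom[ci], start = as.integer(starts),
             end = as.integer(starts + lens), strand = strand)
    })
    genes <- list_rbind(rows) |> arrange(.data$chrom, .data$start)
    # alternate exon/intron blocks of roughly equal size; the last exon
    # absorbs the remainder
    exon_info <- pmap(list(genes$start, genes$end), function(s, e) {
      len <- e - s
      units <- 2L * n_exons - 1L
      block <- len %/% units
      starts <- s + (seq_len(n_exons) - 1L) * 2L * block
      sizes <- rep(block, n_exons)
      sizes[n_exons] <- (e - starts[n_exons])
      list(starts = starts, sizes = sizes)
    })
    ne <- n_exons; u5 <- utr5; u3 <- utr3
    genes |>
      mutate(gene_id = sprintf("g%04d", row_number()),
             tss = if_else(.data$strand == "+", .data$start, .data$end - 1L),
             n_exons = as.integer(.env$ne),
             exon_starts = map_chr(exon_info, ~ paste(.x$starts, collapse = ",")),
             exon_sizes = map_chr(exon_info, ~ paste(.x$sizes, collapse = ",")),
             utr5 = as.integer(pmin(.env$u5, map_int(exon_info, ~ as.integer(.x$sizes[1])))),
             utr3 = as.integer(pmin(.env$u3, map_int(exon_info, ~ as.integer(.x$sizes[.env$ne]))))) |>
      select(all_of(names(empty)))
  })
}

#' Configuration of the planted cohort ground truth
#'
#' Defaults emulate the study design the generator stands in for: dense
#' super-enhancer clusters near driver genes, genes wired to five dispersed
#' classical enhancers (cooperative genes), singleton classical enhancers,
#' a ~10:1 SE-to-enhancer signal ratio, lognormal signal, and a per-sample
#' Bernoulli detection probability of 0.8 within an element's group (with
#' two samples per group always forced, so group-specific elements appear
#' in at least two samples of their group and none of the other).
#'
#' @param n_se Planted super-enhancers (default 8).
#' @param n_coop_genes Genes wired to `coop_n_enh` dispersed enhancers
#'   (default 10).
#' @param n_classical_genes Genes with a single classical enhancer
#'   (default 20).
#' @param n_extra_pt PT-only singleton enhancers, so both exclusivity
#'   directions are populated and the PT group has an occupancy signature
#'   of its own (default 30; in the emulated design the primary-tumor
#'   group has more exclusive peaks than the metastasis group).
#' @param se_n_constituents,se_constituent_width,se_gap SE cluster geometry
#'   (4 peaks of 1500 bp, 4 kb apart: within one 12.5 kb stitching reach).
#' @param enh_width Classical enhancer peak width (default 1000).
#' @param coop_n_enh Enhancers per cooperative gene (default 5), each
#'   placed more than 12.5 kb from its nearest co-targeting enhancer.
#' @param signal_ratio Target ratio of mean SE element signal to mean
#'   classical-enhancer element signal (default 10).
#' @param enh_chip_mean,input_mean Mean ChIP / input per-base densities for
#'   a classical enhancer (arbitrary normalized units).
#' @param sdlog,input_sdlog,sample_sdlog Lognormal spread of the element
#'   base signal, the input, and the per-sample multiplicative noise.
#' @param detect_prob Per-sample element detection probability within the
#'   element's group (default 0.8).
#' @param frac_specific Fraction of SE / cooperative / classical elements
#'   that are DM-specific rather than shared (default 0.5).
#' @param jitter Per-sample coordinate jitter in bases (default 100).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_se = 8, n_coop_genes = 10, n_classical_genes = 20,
                          n_extra_pt = 30, se_n_constituents = 4,
                          se_constituent_width = 1500, se_gap = 4000,
                          enh_width = 1000, coop_n_enh = 5,
                          signal_ratio = 10, enh_chip_mean = 3,
                          input_mean = 0.5, sdlog = 0.25, input_sdlog = 0.2,
                          sample_sdlog = 0.15, detect_prob = 0.8,
                          frac_specific = 0.5, jitter = 100) {
  cfg <- as.list(environment())
  if (frac_specific < 0 || frac_specific > 1) abort("frac_specific must lie in [0, 1]")
  if (detect_prob < 0 || detect_prob > 1) abort("detect_prob must lie in [0, 1]")
  if (signal_ratio <= 0) abort("signal_ratio must be positive")
  if (enh_chip_mean <= input_mean) abort("enhancer ChIP mean must exceed the input mean")
  if (se_n_constituents < 3) abort("a planted SE needs at least 3 constituents")
  if ((se_constituent_width + se_gap) > 12500) {
    abort("SE constituent spacing exceeds the 12.5 kb stitching reach")
  }
  structure(cfg, class = "cohort_config")
}

# offsets of planted elements relative to the target TSS (bases)
se_offset <- 8000
coop_offsets <- function(n) {
  half <- ceiling(n / 2)
  c(-rev(seq_len(half)) * 16000, seq_len(n - half) * 16000)
}
boundary_margin <- 55000

#' Generate a synthetic cohort of per-sample peak calls with planted truth
#'
#' Chooses disjoint target genes (pairwise well separated, away from
#' chromosome ends), plants one element set per role -- SE clusters,
#' cooperative enhancer groups, singleton classical enhancers, PT-only
#' enhancers -- assigns each element a group status (shared / dm / pt), and
#' emits per-sample peaks: membership is Bernoulli within the group with
#' two samples per group forced, coordinates are jittered per sample, and
#' densities are lognormal with the SE class calibrated to
#' `signal_ratio` times the classical-enhancer element signal.
#'
#' @param chrom_sizes Tibble chrom, size.
#' @param annotation Gene models from [make_annotation()]; target genes
#'   need 55 kb clearance from chromosome ends and 112 kb pairwise TSS
#'   separation to be eligible (enough that planted elements of adjacent
#'   target genes can never stitch or swap closest-gene assignments).
#' @param n_pt,n_dm Samples per group (defaults 17 and 12).
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @return List: `peaks` (tibble sample_id, group, chrom, start, end, name,
#'   score, strand, chip_density, input_density) and `truth` (planted_se,
#'   elements, se_genes, cooperative_genes, classical_genes,
#'   cluster_labels, config echo, seed).
#' @export
make_cohort <- function(chrom_sizes, annotation, n_pt = 17, n_dm = 12,
                        config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"), n_pt >= 2, n_dm >= 2)
  cfg <- config
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  with_child_seed(seed, 3, {
    # eligible target genes: clear of chromosome ends, >= 120 kb apart
    cand <- annotation[sample.int(nrow(annotation)), , drop = FALSE]
    cand <- cand[cand$tss >= boundary_margin &
                   cand$tss <= sizes[cand$chrom] - boundary_margin, , drop = FALSE]
    chosen <- integer()
    for (i in seq_len(nrow(cand))) {
      if (!length(chosen) ||
          all(cand$chrom[chosen] != cand$chrom[i] |
                abs(cand$tss[chosen] - cand$tss[i]) >= 112000)) {
        chosen <- c(chosen, i)
      }
    }
    need <- cfg$n_se + cfg$n_coop_genes + cfg$n_classical_genes + cfg$n_extra_pt
    if (length(chosen) < need) {
      abort(sprintf("annotation supports only %d well-separated target genes; %d needed",
                    length(chosen), need))
    }
    tg <- cand[chosen[seq_len(need)], , drop = FALSE]
    role <- rep(c("se", "coop", "classical", "pt_extra"),
                c(cfg$n_se, cfg$n_coop_genes, cfg$n_classical_genes, cfg$n_extra_pt))

    # group status per element set
    pick_specific <- function(n, frac, specific_to) {
      k <- round(frac * n)
      status <- rep("shared", n)
      if (k > 0) status[sample.int(n, k)] <- specific_to
      status
    }

    # SE signal calibration: per-constituent net density such that the mean
    # SE element signal is signal_ratio times the mean enhancer signal
    enh_net <- cfg$enh_chip_mean - cfg$input_mean
    se_net <- cfg$signal_ratio * enh_net * cfg$enh_width /
      (cfg$se_n_constituents * cfg$se_constituent_width)
    se_chip_mean <- se_net + cfg$input_mean
    lmean <- function(m, s) log(m) - s^2 / 2

    # constituent-level table of planted peaks (one row per constituent)
    make_constituents <- function(gi, key, type, group) {
      g <- tg[gi, ]
      if (type == "se") {
        step <- cfg$se_constituent_width + cfg$se_gap
        starts <- g$tss + se_offset + (seq_len(cfg$se_n_constituents) - 1L) * step
        widths <- rep(cfg$se_constituent_width, cfg$se_n_constituents)
        chip <- rlnorm(length(starts), lmean(se_chip_mean, cfg$sdlog), cfg$sdlog)
      } else if (type == "coop") {
        off <- coop_offsets(cfg$coop_n_enh) +
          round(runif(cfg$coop_n_enh, -1000, 1000))
        starts <- g$tss + off
        widths <- rep(cfg$enh_width, cfg$coop_n_enh)
        chip <- rlnorm(length(starts), lmean(cfg$enh_chip_mean, cfg$sdlog), cfg$sdlog)
      } else {
        starts <- g$tss + 20000L + round(runif(1, -2000, 2000))
        widths <- cfg$enh_width
        chip <- rlnorm(1, lmean(cfg$enh_chip_mean, cfg$sdlog), cfg$sdlog)
      }
      tibble(element_key = if (type == "coop") {
        sprintf("%s_e%d", key, seq_along(starts))
      } else if (type == "se") {
        key
      } else key,
      constituent = seq_along(starts),
      type = type, gene_id = g$gene_id, group = group,
      chrom = g$chrom, start = as.integer(starts),
      end = as.integer(starts + widths), base_chip = chip)
    }

    se_idx <- which(role == "se"); coop_idx <- which(role == "coop")
    cls_idx <- which(role == "classical"); pt_idx <- which(role == "pt_extra")
    se_status <- pick_specific(length(se_idx), cfg$frac_specific, "dm")
    coop_status <- pick_specific(length(coop_idx), cfg$frac_specific, "dm")
    cls_status <- pick_specific(length(cls_idx), cfg$frac_specific, "dm")
    constituents <- bind_rows(
      list_rbind(map(seq_along(se_idx), function(i)
        make_constituents(se_idx[i], sprintf("se%02d", i), "se", se_status[i]))),
      list_rbind(map(seq_along(coop_idx), function(i)
        make_constituents(coop_idx[i], sprintf("coop%02d", i), "coop", coop_status[i]))),
      list_rbind(map(seq_along(cls_idx), function(i)
        make_constituents(cls_idx[i], sprintf("cls%02d", i), "classical", cls_status[i]))),
      list_rbind(map(seq_along(pt_idx), function(i)
        make_constituents(pt_idx[i], sprintf("ptx%02d", i), "pt_extra", "pt")))
    )

    samples <- tibble(
      sample_id = c(sprintf("pt_%02d", seq_len(n_pt)),
                    sprintf("dm_%02d", seq_len(n_dm))),
      group = rep(c("pt", "dm"), c(n_pt, n_dm))
    )
    group_samples <- split(samples$sample_id, samples$group)

    # per-element sample membership: two forced samples per eligible group,
    # the rest Bernoulli(detect_prob)
    element_keys <- unique(constituents$element_key)
    el_group <- constituents$group[match(element_keys, constituents$element_key)]
    membership <- list_rbind(map(seq_along(element_keys), function(i) {
      gs <- if (el_group[i] == "shared") c("pt", "dm") else el_group[i]
      list_rbind(map(gs, function(g) {
        ids <- group_samples[[g]]
        forced <- sample(ids, 2)
        keep <- unique(c(forced, ids[runif(length(ids)) < cfg$detect_prob]))
        tibble(element_key = element_keys[i], sample_id = keep)
      }))
    }))

    peaks <- membership |>
      inner_join(rename(constituents, element_group = "group"),
                 by = "element_key", relationship = "many-to-many") |>
      inner_join(samples, by = "sample_id")
    n <- nrow(peaks)
    jit1 <- as.integer(round(runif(n, -cfg$jitter, cfg$jitter)))
    jit2 <- as.integer(round(runif(n, -cfg$jitter, cfg$jitter)))
    peaks <- peaks |>
      mutate(start = pmax(0L, .data$start + jit1),
             end = .data$end + jit2,
             chip_density = .data$base_chip *
               rlnorm(n, lmean(1, cfg$sample_sdlog), cfg$sample_sdlog),
             input_density = rlnorm(n, lmean(cfg$input_mean, cfg$input_sdlog),
                                    cfg$input_sdlog),
             name = sprintf("%s_c%d_%s", .data$element_key, .data$constituent,
                            .data$sample_id),
             score = round(.data$chip_density, 3), strand = ".") |>
      select("sample_id", "group", "chrom", "start", "end", "name", "score",
             "strand", "chip_density", "input_density") |>
      arrange(.data$sample_id, .data$chrom, .data$start)

    planted_se <- constituents |>
      filter(.data$type == "se") |>
      group_by(.data$element_key, .data$gene_id, .data$group, .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      select("element_key", "chrom", "start", "end", "gene_id", "group")
    elements <- constituents |>
      group_by(.data$element_key, .data$type, .data$gene_id, .data$group,
               .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
    truth <- list(
      planted_se = planted_se,
      elements = elements,
      se_genes = sort(unique(tg$gene_id[role == "se"])),
      cooperative_genes = sort(unique(tg$gene_id[role == "coop"])),
      classical_genes = sort(unique(tg$gene_id[role == "classical"])),
      cluster_labels = mutate(samples, cluster = if_else(.data$group == "pt", 1L, 2L)),
      config = unclass(cfg), seed = seed
    )
    list(peaks = peaks, truth = truth)
  })
}

#' Plant motif instances into super-enhancer sequence
#'
#' Writes consensus-sequence instances of the supplied PWMs into the
#' planted SE spans at `rate_in_se` instances per kb (Poisson), and into
#' the rest of the genome at `rate_elsewhere` per kb, on a random strand.
#' Overlapping draws are dropped (first kept); every applied insertion is
#' logged.  A PWM wider than a target span is skipped with a warning.
#'
#' @param genome A `DNAStringSet`.
#' @param se_regions Tibble chrom, start, end of planted SE spans.
#' @param pwms A `pwm` or list of `pwm` objects to plant.
#' @param rate_in_se Instances per kb inside SE spans (default 0.8).
#' @param rate_elsewhere Instances per kb elsewhere (default 0); must not
#'   exceed `rate_in_se`.
#' @param seed Master seed.
#' @return List: `genome` (mutated copy) and `log` (tibble chrom, start,
#'   end, strand, tf, in_se).
#' @export
plant_motifs <- function(genome, se_regions, pwms, rate_in_se = 0.8,
                         rate_elsewhere = 0, seed = 1) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(pwms)) {
    return(list(genome = genome,
                log = tibble(chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             tf = character(), in_se = logical())))
  }
  stopifnot(rate_elsewhere >= 0, rate_in_se > rate_elsewhere)
  chrom_sizes <- tibble(chrom = names(genome),
                        size = Biostrings::width(genome))
  outside <- list_rbind(map(seq_len(nrow(chrom_sizes)), function(i) {
    ch <- chrom_sizes$chrom[i]
    se_ch <- merge_intervals(filter(se_regions, .data$chrom == ch))
    tibble(chrom = ch,
           start = c(0L, se_ch$end),
           end = c(se_ch$start, chrom_sizes$size[i])) |>
      filter(.data$start < .data$end)
  }))
  with_child_seed(seed, 4, {
    draw <- function(spans, rate, in_se) {
      list_rbind(map(seq_len(nrow(spans)), function(i) {
        span_len <- spans$end[i] - spans$start[i]
        list_rbind(map(pwms, function(p) {
          if (p$width > span_len) {
            warn(sprintf("PWM %s (width %d) wider than a %d bp span; skipped",
                         p$tf, p$width, span_len))
            return(NULL)
          }
          n <- rpois(1, rate * span_len / 1000)
          if (!n) return(NULL)
          s <- spans$start[i] + sample.int(span_len - p$width + 1, n,
                                           replace = TRUE) - 1L
          strand <- sample(c("+", "-"), n, replace = TRUE)
          tibble(chrom = spans$chrom[i], start = as.integer(s),
                 end = as.integer(s + p$width), strand = strand,
                 tf = p$tf, in_se = in_se,
                 seqstr = if_else(strand == "+", p$consensus,
                                  revcomp_chr(p$consensus)))
        }))
      }))
    }
    ins <- bind_rows(draw(se_regions, rate_in_se, TRUE),
                     if (rate_elsewhere > 0) draw(outside, rate_elsewhere, FALSE))
    if (is.null(ins) || !nrow(ins)) {
      return(list(genome = genome,
                  log = tibble(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               tf = character(), in_se = logical())))
    }
    # drop overlapping insertions (keep the earliest-drawn per conflict)
    ins <- ins[order(ins$chrom, ins$start), , drop = FALSE]
    keep <- unlist(map(split(seq_len(nrow(ins)), ins$chrom), function(ix) {
      last_end <- -1L; ok <- logical(length(ix))
      for (j in seq_along(ix)) {
        if (ins$start[ix[j]] >= last_end) {
          ok[j] <- TRUE; last_end <- ins$end[ix[j]]
        }
      }
      ix[ok]
    }))
    ins <- ins[sort(keep), , drop = FALSE]
    out <- genome
    for (ch in unique(ins$chrom)) {
      sub <- ins[ins$chrom == ch, , drop = FALSE]
      out[[ch]] <- Biostrings::replaceAt(
        out[[ch]],
        IRanges::IRanges(sub$start + 1L, sub$end),
        as.character(sub$seqstr))
    }
    list(genome = out, log = select(ins, -"seqstr"))
  })
}

#' Generate an expression matrix with an ordered class hierarchy
#'
#' Log-normal values: each gene's expression is `2^N(mu, sigma)` with `mu`
#' set by its planted class (SE target > cooperative target > classical
#' target > unplanted baseline).  The generator's contract is the
#' hierarchy: unordered class means are rejected.
#'
#' @param annotation Gene models.
#' @param truth Truth list from [make_cohort()].
#' @param effect Named class means in log2 units, strictly ordered
#'   `se > cooperative > classical` (default 8, 6, 4).
#' @param baseline Mean for unplanted genes (default 2).
#' @param sigma Log2-scale spread (>= 0; 0 gives exact class means).
#' @param samples Sample ids (default: the cohort's).
#' @param seed Master seed.
#' @return Tibble `gene_id` + one numeric column per sample.
#' @export
make_expression <- function(annotation, truth,
                            effect = c(se = 8, cooperative = 6, classical = 4),
                            baseline = 2, sigma = 1, samples = NULL, seed = 1) {
  stopifnot(sigma >= 0)
  if (!(effect[["se"]] > effect[["cooperative"]] &&
        effect[["cooperative"]] > effect[["classical"]])) {
    abort("class means must be strictly ordered se > cooperative > classical")
  }
  if (is.null(samples)) samples <- truth$cluster_labels$sample_id
  mu <- rep(baseline, nrow(annotation))
  mu[annotation$gene_id %in% truth$classical_genes] <- effect[["classical"]]
  mu[annotation$gene_id %in% truth$cooperative_genes] <- effect[["cooperative"]]
  mu[annotation$gene_id %in% truth$se_genes] <- effect[["se"]]
  with_child_seed(seed, 5, {
    m <- matrix(2^rnorm(nrow(annotation) * length(samples),
                        mean = rep(mu, times = length(samples)), sd = sigma),
                nrow = nrow(annotation))
    colnames(m) <- samples
    dplyr::bind_cols(tibble(gene_id = annotation$gene_id), as_tibble(m))
  })
}

#' Generate a clinical table associated with sample clusters
#'
#' Binary histopathology features (vertical growth, Clark invasion level,
#' Breslow tumor thickness) drawn with cluster-dependent probabilities: the
#' second cluster's odds of the aggressive level are `odds` times the
#' first's.  `odds = 1` makes every feature independent of the cluster;
#' `odds = Inf` separates the 2x2 table perfectly.  A mitotic count
#' (Poisson, higher rate in the second cluster) is included as a
#' non-binary covariate.
#'
#' @param cluster_labels Tibble sample_id (or sample), cluster -- exactly
#'   two distinct labels -- or a named vector.
#' @param odds Association odds ratio (>= 1; may be `Inf`).
#' @param p_baseline First-cluster probability of the aggressive level
#'   (default 0.2).
#' @param seed Master seed.
#' @return Tibble sample_id, cluster, vertical_growth, invasion_level,
#'   tumor_thickness, mitoses.
#' @export
make_clinical <- function(cluster_labels, odds = 6, p_baseline = 0.2, seed = 1) {
  if (!is.data.frame(cluster_labels)) {
    cluster_labels <- tibble(sample_id = names(cluster_labels),
                             cluster = unname(cluster_labels))
  }
  if ("sample" %in% names(cluster_labels) && !"sample_id" %in% names(cluster_labels)) {
    cluster_labels <- rename(cluster_labels, sample_id = "sample")
  }
  stopifnot(odds >= 1, p_baseline > 0, p_baseline < 1)
  lev <- sort(unique(cluster_labels$cluster))
  if (length(lev) != 2) {
    abort(sprintf("expected exactly 2 cluster labels, got %d", length(lev)))
  }
  second <- cluster_labels$cluster == lev[2]
  if (is.infinite(odds)) {
    p <- if_else(second, 1, 0)
  } else {
    o2 <- odds * p_baseline / (1 - p_baseline)
    p <- if_else(second, o2 / (1 + o2), p_baseline)
  }
  levels2 <- list(
    vertical_growth = c("Absent", "Present"),
    invasion_level = c("Clark IV", "Clark V"),
    tumor_thickness = c("Breslow <= 4 mm", "Breslow > 4 mm")
  )
  with_child_seed(seed, 6, {
    out <- tibble(sample_id = cluster_labels$sample_id,
                  cluster = cluster_labels$cluster)
    for (f in names(levels2)) {
      out[[f]] <- levels2[[f]][1 + rbinom(nrow(out), 1, p)]
    }
    out$mitoses <- rpois(nrow(out), if_else(second, 5, 2))
    out
  })
}

#' Deterministic synthetic PWM set
#'
#' Generates `n` informative PWMs (count 97 on a random consensus base, 1
#' elsewhere per position); the first is designated the driver TF planted
#' into SE sequence.
#'
#' @param n Number of PWMs (default 3).
#' @param width Motif width (default 10).
#' @param seed Master seed.
#' @return Named list of `pwm` objects (`tf1` .. `tfN`).
#' @export
synth_pwms <- function(n = 3, width = 10, seed = 1) {
  with_child_seed(seed, 7, {
    pwms <- map(seq_len(n), function(i) {
      cons <- sample.int(4, width, replace = TRUE)
      counts <- matrix(1, 4, width)
      counts[cbind(cons, seq_len(width))] <- 97
      pwm_from_counts(counts, tf = sprintf("tf%d", i))
    })
    setNames(pwms, map_chr(pwms, "tf"))
  })
}

#' Synthetic regulon library
#'
#' The driver TF's regulon is the planted SE target genes plus noise genes;
#' decoy TFs get random regulons of the same size.
#'
#' @param truth Truth list from [make_cohort()].
#' @param annotation Gene models (the universe).
#' @param tfs TF names; the first is the driver.
#' @param noise_frac Fraction of the driver regulon drawn at random
#'   (default 0.3).
#' @param seed Master seed.
#' @return Tibble tf, target.
#' @export
make_regulons <- function(truth, annotation, tfs, noise_frac = 0.3, seed = 1) {
  with_child_seed(seed, 8, {
    universe <- annotation$gene_id
    core <- truth$se_genes
    n_noise <- max(1, round(noise_frac * length(core) / (1 - noise_frac)))
    driver <- unique(c(core, sample(setdiff(universe, core), n_noise)))
    decoys <- map(tfs[-1], function(tf) {
      tibble(tf = tf, target = sample(universe, length(driver)))
    })
    bind_rows(tibble(tf = tfs[1], target = driver), list_rbind(decoys)) |>
      distinct()
  })
}

#' One-shot synthetic cohort
#'
#' Chains the generators under a single master seed: genome (4 x 2.6 Mb at
#' GC 0.41), spaced gene models, per-sample peaks with planted truth, a
#' driver PWM planted into SE sequence plus decoys, regulons, expression
#' with the ordered hierarchy, and the clinical table.
#'
#' @param seed Master seed (default 1).
#' @param n_pt,n_dm Samples per group (defaults 17 and 12, the cohort
#'   retained after quality filtering in the emulated design).
#' @param config A [cohort_config()].
#' @param n_chrom,chrom_len,gc,n_genes,gene_spacing Genome and annotation
#'   scale.
#' @param sequence Generate genome sequence and plant motifs (default
#'   TRUE); FALSE skips the sequence-level components for speed when only
#'   peak-level truth is needed.
#' @param clinical_odds Odds ratio of the clinical association (default 6).
#' @return List: genome, chrom_sizes, annotation, peaks, truth, pwms,
#'   driver_tf, motif_log, expression, clinical, regulons, seed.
#' @export
synthetic_cohort <- function(seed = 1, n_pt = 17, n_dm = 12,
                             config = cohort_config(), n_chrom = 4,
                             chrom_len = 2600000, gc = 0.41, n_genes = 80,
                             gene_spacing = 120000, sequence = TRUE,
                             clinical_odds = 6) {
  chrom_sizes <- tibble(chrom = paste0("chr", seq_len(n_chrom)),
                        size = as.integer(rep(chrom_len, n_chrom)))
  annotation <- make_annotation(chrom_sizes, n_genes = n_genes,
                                min_spacing = gene_spacing,
                                gene_length_range = c(2000, 6000), seed = seed)
  cohort <- make_cohort(chrom_sizes, annotation, n_pt = n_pt, n_dm = n_dm,
                        config = config, seed = seed)
  pwms <- synth_pwms(3, width = 10, seed = seed)
  out <- list(chrom_sizes = chrom_sizes, annotation = annotation,
              peaks = cohort$peaks, truth = cohort$truth, pwms = pwms,
              driver_tf = pwms[[1]]$tf, seed = seed)
  out$truth$driver_tfs <- pwms[[1]]$tf
  if (sequence) {
    g <- make_genome(n_chrom, chrom_len, gc = gc, seed = seed)
    planted <- plant_motifs(g$genome, cohort$truth$planted_se, pwms[[1]],
                            rate_in_se = 0.8, rate_elsewhere = 0, seed = seed)
    out$genome <- planted$genome
    out$motif_log <- planted$log
  }
  out$expression <- make_expression(annotation, cohort$truth, seed = seed)
  out$clinical <- make_clinical(cohort$truth$cluster_labels, odds = clinical_odds,
                                seed = seed)
  out$regulons <- make_regulons(cohort$truth, annotation,
                                tfs = names(pwms), seed = seed)
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the on-disk dialects: genome FASTA, two-column chrom.sizes, one
#' BED6+2 peak file per sample, gene models TSV, expression TSV, clinical
#' TSV, JASPAR-style PWM text, regulon TSV, and the planted truth as JSON.
#' Identical seeds give byte-identical files.
#'
#' @param cohort A [synthetic_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  if (!is.null(cohort$genome)) {
    Biostrings::writeXStringSet(cohort$genome, fp("genome.fa"))
  }
  readr::write_tsv(cohort$chrom_sizes, fp("chrom.sizes"), col_names = FALSE)
  readr::write_tsv(cohort$annotation, fp("genes.tsv"))
  for (s in unique(cohort$peaks$sample_id)) {
    write_bed(filter(cohort$peaks, .data$sample_id == s),
              fp(paste0(s, "_peaks.bed")))
  }
  readr::write_tsv(cohort$expression, fp("expression.tsv"))
  readr::write_tsv(cohort$clinical, fp("clinical.tsv"))
  readr::write_tsv(cohort$regulons, fp("regulons.tsv"))
  write_jaspar(map(cohort$pwms, function(p) {
    round(p$probs * 100) # count-scale echo of the generating model
  }), fp("pwms.jaspar"))
  truth <- cohort$truth
  truth$config <- truth$config[!vapply(truth$config, is.function, TRUE)]
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
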