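test_that("genome generator honors length, GC and determinism contracts", {
  g <- make_genome(1, 1000000, gc = 0.5, seed = 7)
  expect_equal(Biostrings::width(g$genome), 1000000)
  expect_equal(g$chrom_sizes$size, 1000000L)

  a <- make_genome(2, 500000, gc = 0.41, seed = 1)
  b <- make_genome(2, 500000, gc = 0.41, seed = 1)
  expect_identical(as.character(a$genome), as.character(b$genome))

  g6 <- make_genome(1, 1000000, gc = 0.6, seed = 3)
  n_gc <- sum(Biostrings::letterFrequency(g6$genome, c("G", "C")))
  expect_lt(abs(n_gc - 600000), 3 * sqrt(1e6 * 0.6 * 0.4))

  expect_error(make_genome(0, 1000), "n_chrom")
  expect_error(make_genome(1, -5), "chrom_len")
})

test_that("annotation generator respects bounds, spacing and feasibility", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"),
                          size = c(1000000L, 1000000L))
  empty <- make_annotation(sizes, 0)
  expect_equal(nrow(empty), 0)

  genes <- make_annotation(sizes, 200, min_spacing = 2000, seed = 4)
  expect_equal(nrow(genes), 200)
  expect_true(all(genes$start >= 0))
  expect_true(all(genes$end <= 1000000))
  expect_true(all(genes$strand %in% c("+", "-")))
  expect_equal(genes$tss,
               ifelse(genes$strand == "+", genes$start, genes$end - 1L))
  by_chrom <- split(genes, genes$chrom)
  for (d in by_chrom) expect_true(all(diff(sort(d$start)) >= 2000))
  # exons lie inside the gene body
  es <- lapply(strsplit(genes$exon_starts, ","), as.integer)
  sz <- lapply(strsplit(genes$exon_sizes, ","), as.integer)
  expect_true(all(unlist(es) >= rep(genes$start, lengths(es))))
  expect_true(all(unlist(Map(`+`, es, sz)) <= rep(genes$end, lengths(es))))

  expect_error(make_annotation(sizes, 500, min_spacing = 5000), "too short")
})

test_that("cohort generator plants recoverable group-specific elements", {
  co <- small_cohort(seed = 11)
  peaks <- co$peaks
  truth <- co$truth
  expect_equal(dplyr::n_distinct(peaks$sample_id), 12)

  # SE invariants: >= 3 constituents within stitching reach, present in
  # >= 2 samples of the element's group and 0 of the other when specific
  for (i in seq_len(nrow(truth$planted_se))) {
    se <- truth$planted_se[i, ]
    in_span <- peaks[peaks$chrom == se$chrom & peaks$start < se$end &
                       peaks$end > se$start, ]
    per_sample <- split(in_span, in_span$sample_id)
    expect_true(all(vapply(per_sample, nrow, 0L) >= 3))
    n_dm <- dplyr::n_distinct(in_span$sample_id[in_span$group == "dm"])
    n_pt <- dplyr::n_distinct(in_span$sample_id[in_span$group == "pt"])
    expect_gte(n_dm, 2)
    if (se$group == "dm") expect_equal(n_pt, 0) else expect_gte(n_pt, 2)
  }

  # cooperative wiring: planted enhancers of one gene never stitch together
  coop_els <- truth$elements[truth$elements$type == "coop", ]
  for (g in unique(coop_els$gene_id)) {
    d <- dplyr::arrange(coop_els[coop_els$gene_id == g, ], start)
    expect_equal(nrow(d), 5)
    expect_true(all(d$start[-1] - d$end[-nrow(d)] > 12500))
  }

  # determinism: identical seed, identical output
  co2 <- small_cohort(seed = 11)
  expect_identical(co$peaks, co2$peaks)
  expect_identical(co$truth$elements, co2$truth$elements)

  expect_error(cohort_config(frac_specific = 1.4), "frac_specific")
  expect_error(cohort_config(se_gap = 20000), "stitching reach")
})

test_that("planted SE:ENH signal ratio is recovered from the emitted peaks", {
  cfg <- cohort_config(n_se = 10, n_coop_genes = 6, n_classical_genes = 14,
                       n_extra_pt = 6, signal_ratio = 10)
  co <- synthetic_cohort(seed = 21, config = cfg, sequence = FALSE)
  peaks <- dplyr::mutate(co$peaks,
                         element_key = sub("_c\\d+_.*$", "", name),
                         signal = pmax(0, chip_density - input_density) *
                           (end - start))
  el_signal <- peaks |>
    dplyr::group_by(element_key, sample_id) |>
    dplyr::summarise(signal = sum(signal), .groups = "drop_last") |>
    dplyr::summarise(signal = mean(signal), .groups = "drop")
  el_type <- co$truth$elements[c("element_key", "type")]
  el_signal <- dplyr::inner_join(el_signal, el_type, by = "element_key")
  ratio <- mean(el_signal$signal[el_signal$type == "se"]) /
    mean(el_signal$signal[el_signal$type == "classical"])
  expect_gte(ratio, 7)
  expect_lte(ratio, 13)
})

test_that("motif planting respects rates, logs and identity cases", {
  g <- make_genome(1, 200000, seed = 2)
  se <- tibble::tibble(chrom = "chr1", start = c(20000L, 60000L),
                       end = c(30000L, 70000L))
  pwm <- synth_pwms(1, width = 10, seed = 2)[[1]]

  planted <- plant_motifs(g$genome, se, pwm, rate_in_se = 1,
                          rate_elsewhere = 0, seed = 5)
  lg <- planted$log
  expect_true(all(lg$in_se))
  expect_true(all(lg$start >= 20000 & lg$end <= 30000 |
                    lg$start >= 60000 & lg$end <= 70000))
  # the logged instances are really in the sequence
  for (i in seq_len(nrow(lg))) {
    written <- as.character(Biostrings::subseq(planted$genome[[lg$chrom[i]]],
                                               lg$start[i] + 1, lg$end[i]))
    want <- if (lg$strand[i] == "+") pwm$consensus else revcomp(pwm$consensus)
    expect_equal(written, want)
  }

  # Poisson band: rate 2/kb over a 10 kb span
  one_se <- se[1, ]
  counts <- vapply(1:30, function(s) {
    nrow(plant_motifs(g$genome, one_se, pwm, rate_in_se = 2,
                      rate_elsewhere = 0, seed = s)$log)
  }, 0L)
  band <- qpois(c(0.005, 0.995), 20)
  expect_gte(min(counts), band[1] - 3) # overlap-dropping can shave a few
  expect_lte(max(counts), band[2])

  # empty PWM set: genome unchanged byte for byte
  same <- plant_motifs(g$genome, se, list(), rate_in_se = 1, seed = 1)
  expect_identical(as.character(same$genome), as.character(g$genome))
  expect_equal(nrow(same$log), 0)

  # PWM wider than the span: warned and skipped
  wide <- pwm_from_counts(matrix(1, 4, 50), tf = "wide")
  sliver <- tibble::tibble(chrom = "chr1", start = 0L, end = 20L)
  expect_warning(out <- plant_motifs(g$genome, sliver, wide, seed = 1),
                 "wider")
  expect_equal(nrow(out$log), 0)
})

test_that("expression generator enforces and recovers the class hierarchy", {
  co <- small_cohort(seed = 31)
  expr <- co$expression
  cls_mean <- function(genes) {
    mean(as.matrix(expr[expr$gene_id %in% genes, -1]))
  }
  m_se <- cls_mean(co$truth$se_genes)
  m_coop <- cls_mean(co$truth$cooperative_genes)
  m_cls <- cls_mean(co$truth$classical_genes)
  expect_gt(m_se, m_coop)
  expect_gt(m_coop, m_cls)

  # sigma = 0: exact class means on the log2 scale
  exact <- make_expression(co$annotation, co$truth, sigma = 0, seed = 1)
  expect_equal(unique(unlist(exact[exact$gene_id %in% co$truth$se_genes, -1])),
               2^8)
  # determinism
  expect_identical(make_expression(co$annotation, co$truth, seed = 9),
                   make_expression(co$annotation, co$truth, seed = 9))
  expect_error(
    make_expression(co$annotation, co$truth,
                    effect = c(se = 4, cooperative = 6, classical = 8)),
    "ordered")
})

test_that("clinical generator covers independence, separation and determinism", {
  labs <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                         cluster = rep(1:2, each = 15))
  sep <- make_clinical(labs, odds = Inf, seed = 3)
  tab <- table(sep$vertical_growth, sep$cluster)
  expect_equal(unname(tab["Absent", "1"]), 15)
  expect_equal(unname(tab["Present", "2"]), 15)
  expect_identical(make_clinical(labs, odds = 4, seed = 6),
                   make_clinical(labs, odds = 4, seed = 6))
  expect_error(make_clinical(labs, odds = 0.5), "odds")
  bad <- dplyr::mutate(labs, cluster = rep(1:3, each = 10))
  expect_error(make_clinical(bad), "2 cluster")
  expect_true(all(c("vertical_growth", "invasion_level", "tumor_thickness",
                    "mitoses") %in% names(sep)))
})

test_that("a written cohort is byte-reproducible and round-trips its truth", {
  co <- small_cohort(seed = 41, sequence = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(small_cohort(seed = 41, sequence = TRUE), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # the emitted files alone reproduce the in-memory objects
  sizes <- readr::read_tsv(file.path(d1, "chrom.sizes"),
                           col_names = c("chrom", "size"), show_col_types = FALSE)
  expect_equal(sizes$size, co$chrom_sizes$size)
  one <- read_peaks(file.path(d1, "dm_01_peaks.bed"), chrom_sizes = sizes)
  want <- dplyr::select(dplyr::filter(co$peaks, sample_id == "dm_01"),
                        -sample_id, -group)
  expect_equal(as.data.frame(one), as.data.frame(want))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$cooperative_genes, co$truth$cooperative_genes)
  expect_equal(truth$planted_se$start, co$truth$planted_se$start)
  pwms_back <- read_jaspar(file.path(d1, "pwms.jaspar"))
  expect_equal(names(pwms_back), names(co$pwms))
})
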