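test_that("Benjamini-Hochberg matches the hand-applied step-up formula", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  # hand computation: sorted p (0.005, 0.04, 0.2), m = 3:
  # q3 = 0.2, q2 = min(0.2, 3*0.04/2) = 0.06, q1 = min(0.06, 3*0.005) = 0.015
  expect_equal(benjamini_hochberg(c(0.2, 0.005, 0.04)),
               c(0.2, 0.015, 0.06))
  withr::with_seed(2, {
    p <- runif(50)
    q <- benjamini_hochberg(p)
    expect_true(all(diff(q[order(p)]) >= 0)) # monotone in p after sorting
    expect_true(all(q >= p))
    # order invariance
    perm <- sample.int(50)
    expect_equal(benjamini_hochberg(p[perm]), q[perm])
  })
  expect_error(benjamini_hochberg(c(0.5, 0)))
})

test_that("regulon over-representation equals the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  regulons <- tibble::tibble(
    tf = rep(c("tfA", "tfB"), c(5, 6)),
    target = c(universe[1:5], universe[10:15]))
  targets <- universe[1:6]
  got <- regulon_overrepresentation(targets, regulons, universe)
  pa <- got$p_value[got$tf == "tfA"]
  expect_equal(pa, oracle_hyper_tail(5, 5, 20, 6), tolerance = 1e-12)
  expect_true(got$selected[got$tf == "tfA"])
  # disjoint regulon: p = 1
  pb <- got$p_value[got$tf == "tfB"]
  expect_equal(pb, 1, tolerance = 1e-12)
  expect_equal(pb, oracle_hyper_tail(0, 6, 20, 6), tolerance = 1e-12)
  expect_error(regulon_overrepresentation(targets, regulons, character()),
               "universe")
})

test_that("PWM construction applies pseudocounts and flat-background identities", {
  counts <- matrix(c(100, 0, 0, 0,
                     0, 50, 50, 0,
                     25, 25, 25, 25,
                     0, 0, 0, 100), nrow = 4)
  p <- pwm_from_counts(counts, pseudocount = 0.5)
  expect_equal(unname(p$probs[1, 1]), 100.5 / 102)
  expect_equal(colSums(p$probs), rep(1, 4), tolerance = 1e-12)
  # flat counts against a flat background: log-odds are zero
  expect_equal(unname(p$log_odds[, 3]), rep(0, 4))
  expect_error(pwm_from_counts(matrix(0, 4, 4)), "all-zero")
})

test_that("JASPAR-style text round-trips count matrices", {
  withr::with_seed(14, {
    m1 <- matrix(as.numeric(sample.int(50, 24, replace = TRUE)), 4, 6,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
    m2 <- matrix(as.numeric(sample.int(50, 16, replace = TRUE)), 4, 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
    path <- withr::local_tempfile(fileext = ".jaspar")
    write_jaspar(list(MA1 = m1, MA2 = m2), path)
    back <- read_jaspar(path)
    expect_equal(back, list(MA1 = m1, MA2 = m2))
  })
})

test_that("exact score distribution matches enumeration and base cases", {
  bg <- c(0.3, 0.2, 0.2, 0.3)
  w1 <- pwm_from_counts(matrix(c(8, 1, 1, 2,
                                 1, 9, 1, 1,
                                 1, 1, 9, 1,
                                 2, 1, 1, 8), nrow = 4), tf = "w1")
  d4 <- score_distribution(w1, background = bg)
  expect_equal(sum(d4$prob), 1, tolerance = 1e-9)
  # enumeration over all 256 windows under the same integerization
  want <- oracle_score_distribution(d4$int_scores, bg)
  expect_equal(d4$support, want$score)
  expect_equal(d4$prob, want$prob, tolerance = 1e-12)
  # the tail at the maximum achievable score is P(consensus window) > 0
  expect_gt(d4$tail[length(d4$tail)], 0)
  expect_equal(d4$tail[length(d4$tail)],
               want$prob[which.max(want$score)], tolerance = 1e-12)
  tbl <- tibble::as_tibble(d4)
  expect_equal(sum(tbl$prob), 1, tolerance = 1e-9)
  expect_equal(tbl$p_value[1], 1, tolerance = 1e-9)
})

test_that("scanning finds a planted consensus and mirrors under reverse complement", {
  withr::with_seed(4, {
    pwm <- synth_pwms(1, width = 6, seed = 8)[[1]]
    flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
    s <- paste0(flank(25), pwm$consensus, flank(29))
    hits <- scan_pwm(c(seq1 = s), pwm, background = rep(0.25, 4),
                     q_threshold = 2)
    top <- hits[which.min(hits$p_value), ]
    expect_equal(top$start, 25L)
    expect_equal(top$strand, "+")
    expect_equal(top$end, 31L)

    # scanning the reverse complement flips strands and mirrors coordinates
    rc_hits <- scan_pwm(c(seq1 = revcomp(s)), pwm, background = rep(0.25, 4),
                        q_threshold = 2)
    L <- nchar(s)
    mirrored <- dplyr::arrange(
      dplyr::mutate(rc_hits, start = L - start - 6L,
                    strand = ifelse(strand == "+", "-", "+")),
      start, strand)
    expect_equal(
      as.data.frame(mirrored[c("start", "strand", "score", "p_value")]),
      as.data.frame(dplyr::arrange(hits, start, strand)[
        c("start", "strand", "score", "p_value")]))
  })
})

test_that("window scores and p-values match brute-force scoring of a toy sequence", {
  withr::with_seed(6, {
    pwm <- synth_pwms(1, width = 4, seed = 12)[[1]]
    bg <- rep(0.25, 4)
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    d <- score_distribution(pwm, background = bg)
    hits <- scan_pwm(c(x = s), pwm, background = bg, q_threshold = 2) |>
      dplyr::filter(strand == "+") |>
      dplyr::arrange(start)
    want_scores <- oracle_window_scores(s, pwm$log_odds)
    expect_equal(hits$score, want_scores, tolerance = 2.1e-3) # integerization
    # p-values are achievable tail values of the distribution
    expect_true(all(hits$p_value %in% c(d$tail, 1)))
    # integerized brute force: loop-scored windows against the enumerated
    # 4^w distribution
    ints <- round(pwm$log_odds / 1e-3)
    odist <- oracle_score_distribution(ints, bg)
    chars <- strsplit(s, "")[[1]]
    base_idx <- c(A = 1, C = 2, G = 3, T = 4)
    want_p <- vapply(seq_len(nchar(s) - 3), function(i) {
      sc <- sum(ints[cbind(base_idx[chars[i:(i + 3)]], 1:4)])
      sum(odist$prob[odist$score >= sc])
    }, 0)
    expect_equal(hits$p_value, want_p, tolerance = 1e-9)
  })
  # sequences shorter than the motif yield no windows and no error
  pwm <- synth_pwms(1, width = 8, seed = 1)[[1]]
  expect_equal(nrow(scan_pwm(c(tiny = "ACG"), pwm)), 0)
})

test_that("windows containing N are skipped", {
  pwm <- synth_pwms(1, width = 4, seed = 3)[[1]]
  s <- paste0("AAAA", "N", strrep("C", 10))
  hits <- scan_pwm(c(x = s), pwm, q_threshold = 2)
  # no retained window may cover the N at 0-based position 4
  expect_false(any(hits$start <= 4 & hits$end > 4))
})

test_that("shuffled background is same-chromosome, same-length, non-overlapping", {
  sizes <- tibble::tibble(chrom = "chr1", size = 1000000L)
  region <- tibble::tibble(region_id = "r1", chrom = "chr1",
                           start = 5000L, end = 6000L)
  bg <- shuffle_background(region, sizes, seed = 5)
  expect_equal(bg$chrom, "chr1")
  expect_equal(bg$end - bg$start, 1000L)
  expect_false(bg$start < region$end && bg$end > region$start)

  # a single remaining slot is found deterministically
  blocked <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 10000L), end = c(8999L, 1000000L))
  forced <- shuffle_background(region, sizes, excluded = blocked, seed = 5)
  expect_equal(forced$start, 8999L)
  expect_equal(forced$end, 9999L)

  # infeasible placement errors and names the chromosome
  full <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000000L)
  expect_error(shuffle_background(region, sizes, excluded = full), "chr1")

  # reproducible with a fixed seed; multiple regions never overlap
  many <- tibble::tibble(region_id = sprintf("r%d", 1:50), chrom = "chr1",
                         start = (0:49) * 2000L, end = (0:49) * 2000L + 500L)
  b1 <- shuffle_background(many, sizes, seed = 9)
  b2 <- shuffle_background(many, sizes, seed = 9)
  expect_identical(b1, b2)
  gr_bg <- GenomicRanges::GRanges(b1$chrom, IRanges::IRanges(b1$start + 1, b1$end))
  gr_re <- GenomicRanges::GRanges(many$chrom, IRanges::IRanges(many$start + 1, many$end))
  expect_equal(length(GenomicRanges::findOverlaps(gr_bg)), nrow(b1)) # self only
  expect_equal(length(GenomicRanges::findOverlaps(gr_bg, gr_re)), 0)
})

test_that("background placement is uniform over the valid space", {
  sizes <- tibble::tibble(chrom = "chr1", size = 100000L)
  region <- tibble::tibble(region_id = "r", chrom = "chr1",
                           start = 49000L, end = 50000L)
  starts <- vapply(1:500, function(s) {
    shuffle_background(region, sizes, seed = s)$start
  }, 0L)
  # valid starts: [0, 48000] and [50000, 99000]; fold into one axis
  u <- ifelse(starts < 49000, starts, starts - 2000L) / 97001
  gof <- suppressWarnings(stats::chisq.test(table(cut(u, breaks = seq(0, 1, 0.1)))))
  expect_gt(gof$p.value, 0.01)
})

test_that("chi-squared TF enrichment reproduces hand values and the direction filter", {
  re <- tibble::tibble(region_id = sprintf("re%02d", 1:100))
  bg <- tibble::tibble(region_id = sprintf("bg%02d", 1:100))
  hits <- dplyr::bind_rows(
    tibble::tibble(region_id = re$region_id[1:90], tf = "up"),
    tibble::tibble(region_id = bg$region_id[1:10], tf = "up"),
    tibble::tibble(region_id = re$region_id[1:10], tf = "down"),
    tibble::tibble(region_id = bg$region_id[1:90], tf = "down"),
    tibble::tibble(region_id = re$region_id[1:40], tf = "flat"),
    tibble::tibble(region_id = bg$region_id[1:40], tf = "flat"))
  got <- tf_enrichment(re, bg, hits)
  up <- got[got$tf == "up", ]
  expect_equal(up$chi2_stat, 128)  # 200*(90*90-10*10)^2 / 100^4
  expect_equal(up$binding_difference, 80)
  expect_true(up$selected)
  # equal bound fractions: chi2 = 0, p = 1, not selected
  flat <- got[got$tf == "flat", ]
  expect_equal(flat$chi2_stat, 0)
  expect_equal(flat$p_value, 1)
  expect_false(flat$selected)
  # significant depletion is NOT selected
  down <- got[got$tf == "down", ]
  expect_lt(down$q_value, 0.1)
  expect_false(down$selected)
  # ranked by descending binding difference
  expect_equal(got$tf, c("up", "flat", "down"))
  expect_error(tf_enrichment(re[0, ], bg, hits), "non-empty")
  expect_s3_class(autoplot(got), "ggplot")
  expect_equal(glance(got)$top_tf, "up")
})
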