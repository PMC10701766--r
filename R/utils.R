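# Internal helpers shared across modules.

# Run `code` under a child RNG stream derived from a master seed by a fixed
# offset, restoring the caller's RNG state afterwards.  Offsets are fixed per
# generator so adding a new generator does not perturb the streams of the
# existing ones.  Derived seeds stay below 2^31 - 1.
with_child_seed <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  child <- (abs(as.double(seed)) * 48271 + offset * 16807) %% 2147483647
  withr::with_seed(as.integer(child), code)
}

# Coerce a tibble with chrom/start/end (0-based half-open) to GRanges
# (1-based closed).  Extra columns are carried as mcols.
as_granges <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(x[extra])
  }
  gr
}

# Inverse of as_granges(): back to 0-based half-open tibble.
granges_to_tbl <- function(gr) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) out <- dplyr::bind_cols(out, as_tibble(as.data.frame(mc)))
  out
}

check_intervals <- function(x, what = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(sprintf("%s: invalid span (need 0 <= start < end) at row %d",
                  what, bad[1]))
  }
  invisible(x)
}

#' Format a printed share as a percentage
#'
#' The summary formatter used throughout the package to report shares the way
#' cohort papers print them: `round(100 * numerator / denominator, digits)`.
#'
#' @param numerator,denominator Non-negative counts.
#' @param digits Decimal places (default 1).
#' @return A numeric percentage on the 0--100 scale.
#' @examples
#' format_pct(14155, 20898) # 67.7
#' @export
format_pct <- function(numerator, denominator, digits = 1) {
  stopifnot(denominator > 0, numerator >= 0)
  round(100 * numerator / denominator, digits)
}
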