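#' Construct a merged, sorted interval set
#'
#' Overlapping and adjacent input intervals are merged and the set is sorted
#' so that downstream coverage arithmetic cannot be inflated by
#' self-overlapping input (BED files in the wild frequently are). All
#' features are treated as unstranded.
#'
#' @param x BED-style data frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or a GRanges.
#' @return An `interval_set` tibble (`chrom`, `start`, `end`) with attribute
#'   `total_coverage` (bp). Constructing from already-merged intervals is
#'   the identity.
#' @export
interval_set <- function(x) {
  if (methods::is(x, "GRanges")) x <- granges_to_bed(x)
  assert_bed_frame(x)
  if (nrow(x) == 0L) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  } else {
    gr <- GenomicRanges::reduce(bed_to_granges(x[, c("chrom", "start", "end")]))
    out <- granges_to_bed(GenomicRanges::sort(gr))
  }
  structure(out,
            total_coverage = sum(out$end - out$start),
            class = c("interval_set", class(out)))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("Interval set: %d intervals, %s bp total coverage\n",
              nrow(x), format(attr(x, "total_coverage"), big.mark = ",")))
  NextMethod()
}

#' Base-coverage overlap between two interval sets
#'
#' Reports the percentage of each set's base pairs falling inside the other,
#' the figure conventionally drawn in paired Venn diagrams of genomic
#' domains.
#'
#' @param A,B `interval_set` objects (data frames are coerced).
#' @return List with `pct_A_in_B`, `pct_B_in_A` (percentages in
#'   \[0, 100\], `NA` with a warning for an empty set) and `shared_bp`.
#' @export
base_coverage_overlap <- function(A, B) {
  A <- interval_set(A)
  B <- interval_set(B)
  cov_a <- attr(A, "total_coverage")
  cov_b <- attr(B, "total_coverage")
  shared <- if (nrow(A) == 0L || nrow(B) == 0L) 0 else {
    sum(GenomicRanges::width(GenomicRanges::intersect(
      bed_to_granges(A), bed_to_granges(B)
    )))
  }
  pct_a <- if (cov_a == 0) {
    rlang::warn("set A is empty; pct_A_in_B is undefined")
    NA_real_
  } else 100 * shared / cov_a
  pct_b <- if (cov_b == 0) {
    rlang::warn("set B is empty; pct_B_in_A is undefined")
    NA_real_
  } else 100 * shared / cov_b
  list(pct_A_in_B = pct_a, pct_B_in_A = pct_b, shared_bp = shared)
}

#' Fraction of peaks residing within a region set
#'
#' In `"midpoint"` mode (default) a peak counts when its centre base lies in
#' a region; `"any_overlap"` counts one or more shared base pairs. The
#' midpoint of a 0-based half-open peak \[start, end) is the base
#' `floor((start + end) / 2)`.
#'
#' @param peaks Non-empty BED-style data frame or `interval_set` of peaks.
#' @param regions Region set (e.g. called LADs).
#' @param mode `"midpoint"` or `"any_overlap"`.
#' @return List with `n_within`, `n_peaks`, `fraction`, `pct`.
#' @export
peak_fraction_within <- function(peaks, regions,
                                 mode = c("midpoint", "any_overlap")) {
  mode <- match.arg(mode)
  assert_bed_frame(peaks, "peaks")
  if (nrow(peaks) == 0L) rlang::abort("`peaks` is empty")
  regions <- interval_set(regions)
  region_gr <- bed_to_granges(regions)
  if (mode == "midpoint") {
    mid <- floor((peaks$start + peaks$end) / 2)
    q <- bed_to_granges(tibble::tibble(chrom = peaks$chrom, start = mid,
                                       end = mid + 1))
  } else {
    q <- bed_to_granges(peaks[, c("chrom", "start", "end")])
  }
  n_within <- sum(GenomicRanges::countOverlaps(q, region_gr, minoverlap = 1L) > 0)
  list(n_within = n_within, n_peaks = nrow(peaks),
       fraction = n_within / nrow(peaks),
       pct = 100 * n_within / nrow(peaks))
}
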