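#' Score, segment and call LADs in one step
#'
#' Convenience wrapper chaining [compute_damid_scores()],
#' [segment_scores()] and [call_lads()] with their defaults.
#'
#' @param fusion,control `bin_counts` for the Dam-fusion and Dam-only
#'   libraries.
#' @param normalize,mask,center Passed to [compute_damid_scores()].
#' @param alpha,n_perm,seed Passed to [segment_scores()].
#' @param min_lad,max_gap Passed to [call_lads()].
#' @return List with `scores`, `segments`, `lads`.
#' @export
damid_lad_pipeline <- function(fusion, control, normalize = TRUE,
                               mask = NULL, center = "mean",
                               alpha = 0.01, n_perm = 10000L, seed = 1L,
                               min_lad = 100000, max_gap = 10000) {
  scores <- compute_damid_scores(fusion, control, normalize = normalize,
                                 mask = mask, center = center)
  segments <- segment_scores(scores, alpha = alpha, n_perm = n_perm,
                             seed = seed)
  lads <- call_lads(segments, min_lad = min_lad, max_gap = max_gap)
  list(scores = scores, segments = segments, lads = lads)
}

#' Base-coverage Jaccard index of two interval sets
#'
#' Shared base pairs over union base pairs; 1 for identical sets, 0 for
#' disjoint ones. The standard summary for comparing called against truth
#' domains.
#'
#' @param A,B BED-style interval tables.
#' @return A number in \[0, 1\] (`NaN` when both sets are empty).
#' @export
interval_jaccard <- function(A, B) {
  A <- interval_set(A)
  B <- interval_set(B)
  if (nrow(A) == 0L && nrow(B) == 0L) return(NaN)
  ga <- bed_to_granges(A)
  gb <- bed_to_granges(B)
  shared <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  shared / uni
}
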