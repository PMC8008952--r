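# Boundary- and anchor-oriented average signal profiles ("metagene"-style
# plots around LAD boundaries or peak centres).

# Weighted per-bin means of a piecewise-constant track. bins: tibble with
# chrom, gstart, gend (0-based half-open), anchor, offset. Returns bins with
# a `value` column (base-weighted mean of the track over the bin; NA where
# the bin has no track coverage).
profile_bin_values <- function(track, bins) {
  keep <- bins$gend > bins$gstart
  bins <- bins[keep, , drop = FALSE]
  track <- track[!is.na(track$score), , drop = FALSE]
  bin_gr <- bed_to_granges(tibble::tibble(chrom = bins$chrom,
                                          start = bins$gstart,
                                          end = bins$gend))
  trk_gr <- bed_to_granges(as.data.frame(track)[, c("chrom", "start", "end", "score")])
  hits <- GenomicRanges::findOverlaps(bin_gr, trk_gr, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(GenomicRanges::pintersect(bin_gr[q], trk_gr[s]))
  sc <- trk_gr$score[s]
  num <- tapply(w * sc, q, sum)
  den <- tapply(w, q, sum)
  value <- rep(NA_real_, nrow(bins))
  value[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  bins$value <- value
  bins
}

profile_from_bins <- function(bins, offsets, n_anchors, orientation) {
  means <- vapply(offsets, function(o) {
    v <- bins$value[bins$offset == o & !is.na(bins$value)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ns <- vapply(offsets, function(o) {
    sum(bins$offset == o & !is.na(bins$value))
  }, integer(1))
  out <- tibble::tibble(offset = offsets, mean = means, n = ns)
  structure(out, n_anchors = n_anchors, orientation = orientation,
            class = c("signal_profile", class(out)))
}

#' Average signal profile across region boundaries, oriented outside-in
#'
#' Anchors a window at every boundary of every retained region (both ends
#' contribute) and averages the track within half-open offset bins
#' \[o, o + step) relative to the boundary. Right-hand boundaries are
#' mirrored so that positive offsets always point into the region and
#' negative offsets outside; the boundary sits at offset 0 on the inside
#' edge. Within a bin the track is averaged base-weighted; at each offset
#' the mean is taken over the anchors that have data there, so windows
#' running off a chromosome (or into unscored territory) simply contribute
#' fewer anchors.
#'
#' @param track Signal as a `damid_scores` tibble or any bedGraph-style
#'   table (`chrom`, `start`, `end`, `score`); `NA` scores are ignored.
#' @param regions BED-style regions (e.g. called LADs).
#' @param min_region Only regions at least this long (bp) anchor windows
#'   (default 100 kb, the conventional minimum LAD size).
#' @param flank Half-window width in bp on each side of the boundary.
#' @param step Offset bin width in bp.
#' @return A `signal_profile` tibble (`offset`, `mean`, `n`) with attributes
#'   `n_anchors` and `orientation = "outside_in"`.
#' @export
boundary_profile <- function(track, regions, min_region = 100000,
                             flank = 100000, step = 10000) {
  assert_bed_frame(track, "track")
  regions <- interval_set(regions)
  regions <- regions[regions$end - regions$start >= min_region, , drop = FALSE]
  if (nrow(regions) == 0L) {
    rlang::abort("no regions pass `min_region`; nothing to anchor")
  }
  offsets <- seq(-flank, flank - step, by = step)
  anchors <- dplyr::bind_rows(
    tibble::tibble(chrom = regions$chrom, pos = regions$start, sign = 1),
    tibble::tibble(chrom = regions$chrom, pos = regions$end, sign = -1)
  )
  bins <- dplyr::bind_rows(lapply(seq_len(nrow(anchors)), function(i) {
    p <- anchors$pos[i]
    if (anchors$sign[i] > 0) {
      gstart <- p + offsets
      gend <- p + offsets + step
    } else {
      gstart <- p - offsets - step
      gend <- p - offsets
    }
    tibble::tibble(chrom = anchors$chrom[i], gstart = pmax(gstart, 0),
                   gend = pmax(gend, 0), anchor = i, offset = offsets)
  }))
  bins <- profile_bin_values(track, bins)
  profile_from_bins(bins, offsets, nrow(anchors), "outside_in")
}

#' Average signal profile around point anchors
#'
#' Symmetric window \[-flank, +flank) around each anchor point, with no
#' orientation flip; averaging is as in [boundary_profile()].
#'
#' @param track Signal table (`chrom`, `start`, `end`, `score`).
#' @param anchors Data frame with `chrom` and `pos` (0-based base position,
#'   e.g. peak centres).
#' @param flank Half-window width in bp.
#' @param step Offset bin width in bp.
#' @return A `signal_profile` tibble (`offset`, `mean`, `n`).
#' @export
anchor_profile <- function(track, anchors, flank = 100000, step = 10000) {
  assert_bed_frame(track, "track")
  if (!is.data.frame(anchors) || !all(c("chrom", "pos") %in% names(anchors)) ||
      nrow(anchors) == 0L) {
    rlang::abort("`anchors` must be a non-empty data frame with chrom, pos")
  }
  offsets <- seq(-flank, flank - step, by = step)
  bins <- dplyr::bind_rows(lapply(seq_len(nrow(anchors)), function(i) {
    p <- anchors$pos[i]
    tibble::tibble(chrom = anchors$chrom[i],
                   gstart = pmax(p + offsets, 0),
                   gend = pmax(p + offsets + step, 0),
                   anchor = i, offset = offsets)
  }))
  bins <- profile_bin_values(track, bins)
  profile_from_bins(bins, offsets, nrow(anchors), "symmetric")
}
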