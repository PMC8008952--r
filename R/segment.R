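# Recursive binary segmentation of the per-fragment score track, in the
# spirit of circular binary segmentation: at each step the candidate split
# maximising the two-sample partial-sum statistic is accepted iff its
# permutation p-value is below alpha, and accepted splits are recursed.

# Interim checkpoints for early acceptance: after chk_n[i] permutations a
# split is declared significant if its exceedance count is <= chk_kmax[i],
# i.e. the conf-level upper confidence bound on the permutation p-value is
# already below alpha. Clear changepoints therefore stop after ~1000
# permutations instead of running all n_perm.
perm_checkpoints <- function(n_perm, alpha, conf = 0.999) {
  n <- c(500L, 1000L, 2000L, 5000L)
  n <- n[n < n_perm]
  kmax <- vapply(n, function(nn) {
    k <- -1L
    while (k + 1L < nn && qbeta(conf, k + 2, nn - (k + 1)) < alpha) {
      k <- k + 1L
    }
    k
  }, integer(1))
  keep <- kmax >= 0L
  list(n = n[keep], kmax = kmax[keep])
}

# Segment a numeric vector; returns matrix with columns lo, hi (1-based
# inclusive index ranges tiling seq_along(x)).
cbs_segment_vector <- function(x, alpha, n_perm, chk) {
  m <- length(x)
  if (m < 2L) return(cbind(lo = 1L, hi = m))
  segs <- list()
  stack <- list(c(1L, m))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rng[1]
    hi <- rng[2]
    if (hi - lo + 1L < 2L) {
      segs[[length(segs) + 1L]] <- rng
      next
    }
    res <- cbs_split_test(x[lo:hi], n_perm, alpha, chk$n, chk$kmax)
    if (isTRUE(res$significant) && res$index > 0L) {
      cut <- lo + res$index - 1L
      stack[[length(stack) + 1L]] <- c(cut + 1L, hi)
      stack[[length(stack) + 1L]] <- c(lo, cut)
    } else {
      segs[[length(segs) + 1L]] <- rng
    }
  }
  out <- do.call(rbind, segs)
  colnames(out) <- c("lo", "hi")
  out[order(out[, 1]), , drop = FALSE]
}

#' Partition a DamID score track into constant-mean segments
#'
#' Recursive binary changepoint segmentation per chromosome: at each step
#' the split maximising the two-sample partial-sum statistic is accepted if
#' its permutation p-value (up to `n_perm` seeded permutations, with
#' sequential early stopping in both directions) is below `alpha`, and
#' accepted splits are recursed until no further significant split exists.
#' Ties between equally good split points resolve to the leftmost.
#'
#' Missing fragments are skipped in all statistics; in the output they
#' inherit the enclosing segment, with a run of missing fragments between
#' two segments attached to the segment on its left. Segments therefore tile
#' every fragment of each chromosome that has at least one scored fragment.
#'
#' @param track A `damid_scores` tibble from [compute_damid_scores()].
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Maximum number of permutations per tested split.
#' @param seed Integer seed; the whole segmentation is deterministic given
#'   the seed and input.
#' @return A `segment_set` tibble: `chrom`, `first_frag`, `last_frag`
#'   (1-based fragment indices, inclusive), `start`, `end` (genomic, 0-based
#'   half-open), `mean_score` (arithmetic mean of member scored fragments),
#'   `n_scored`.
#' @export
segment_scores <- function(track, alpha = 0.01, n_perm = 10000L, seed = 1L) {
  stopifnot(all(c("chrom", "start", "end", "frag", "score") %in% names(track)))
  set.seed(seed)
  chk <- perm_checkpoints(n_perm, alpha)
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$frag), , drop = FALSE]
    idx <- which(!is.na(sub$score))
    if (length(idx) == 0L) {
      rlang::warn(sprintf("chromosome %s has no scored fragments; skipped", ch))
      next
    }
    x <- sub$score[idx]
    segs <- cbs_segment_vector(x, alpha, n_perm, chk)
    n <- nrow(segs)
    first_frag <- integer(n)
    last_frag <- integer(n)
    for (k in seq_len(n)) {
      first_frag[k] <- if (k == 1L) 1L else idx[segs[k, "lo"]]
      last_frag[k] <- if (k == n) nrow(sub) else idx[segs[k + 1L, "lo"]] - 1L
    }
    mean_score <- vapply(seq_len(n), function(k) {
      mean(x[segs[k, "lo"]:segs[k, "hi"]])
    }, numeric(1))
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = ch,
      first_frag = first_frag,
      last_frag = last_frag,
      start = sub$start[first_frag],
      end = sub$end[last_frag],
      mean_score = mean_score,
      n_scored = segs[, "hi"] - segs[, "lo"] + 1L
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    chrom = character(), first_frag = integer(), last_frag = integer(),
    start = integer(), end = integer(), mean_score = numeric(),
    n_scored = integer()
  )
  structure(res, class = c("segment_set", class(res)))
}

#' Classify LADs from a segmented score track
#'
#' Positive segments (mean score strictly greater than zero) are mapped to
#' genomic intervals; consecutive positive intervals separated by
#' non-positive spans shorter than `max_gap` are merged across the gap
#' (applied left to right, which reaches the fixpoint in one pass); merged
#' regions with genomic length at or above `min_lad` are emitted. LAD
#' boundaries always lie at outermost positive-segment edges, never inside a
#' gap.
#'
#' @param segments A `segment_set` from [segment_scores()].
#' @param min_lad Minimum LAD length in bp (inclusive; default 100 kb).
#' @param max_gap Maximum internal negative-span length in bp that may be
#'   absorbed (exclusive; default 10 kb).
#' @param zero_tol Numerical tolerance for "positive": segment means within
#'   `zero_tol` of zero count as zero-mean and are non-positive (centred
#'   score tracks leave means that are zero up to floating-point residue).
#' @return A `lad_set` tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `length`.
#' @export
call_lads <- function(segments, min_lad = 100000, max_gap = 10000,
                      zero_tol = 1e-9) {
  stopifnot(all(c("chrom", "start", "end", "mean_score") %in% names(segments)))
  assert_scalar_number(min_lad, "min_lad", min = 0)
  assert_scalar_number(max_gap, "max_gap", min = 0)
  out <- list()
  for (ch in unique(segments$chrom)) {
    pos <- segments[segments$chrom == ch &
                      !is.na(segments$mean_score) &
                      segments$mean_score > zero_tol, , drop = FALSE]
    if (nrow(pos) == 0L) next
    pos <- pos[order(pos$start), , drop = FALSE]
    starts <- pos$start[1]
    ends <- pos$end[1]
    for (k in seq_len(nrow(pos))[-1]) {
      gap <- pos$start[k] - ends[length(ends)]
      if (gap < max_gap) {
        ends[length(ends)] <- pos$end[k]
      } else {
        starts <- c(starts, pos$start[k])
        ends <- c(ends, pos$end[k])
      }
    }
    keep <- (ends - starts) >= min_lad
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = starts[keep], end = ends[keep],
        length = ends[keep] - starts[keep]
      )
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    length = numeric()
  )
  structure(res, class = c("lad_set", class(res)))
}
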