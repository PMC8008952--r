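#' Assign aligned reads to GATC fragments
#'
#' Counts, for each DpnI fragment, the aligned reads overlapping it by at
#' least one base. A read straddling a fragment boundary counts toward every
#' fragment it touches, so the column sum can exceed the library size; the
#' library size is the number of input reads.
#'
#' @param reads BED-style data frame of aligned reads (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param frags A `gatc_map` from [build_fragment_map()].
#' @return A `bin_counts` object: list with `map` (the fragment map),
#'   `counts` (one count per fragment, in map row order) and `library_size`.
#' @export
count_reads_per_fragment <- function(reads, frags) {
  assert_bed_frame(reads, "reads")
  stopifnot(inherits(frags, "gatc_map"))
  sl <- attr(frags, "seqlengths")
  bad_chrom <- !reads$chrom %in% names(sl)
  if (any(bad_chrom)) {
    i <- which(bad_chrom)[1]
    rlang::abort(sprintf(
      "read %d (%s:%d-%d) is on a chromosome absent from the fragment map",
      i, reads$chrom[i], reads$start[i], reads$end[i]
    ))
  }
  out_of_bounds <- reads$start < 0 | reads$end > sl[reads$chrom] |
    reads$end <= reads$start
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1]
    rlang::abort(sprintf(
      "read %d (%s:%d-%d) falls outside chromosome bounds",
      i, reads$chrom[i], reads$start[i], reads$end[i]
    ))
  }
  frag_gr <- bed_to_granges(as.data.frame(frags)[, c("chrom", "start", "end")])
  read_gr <- bed_to_granges(reads[, c("chrom", "start", "end")])
  counts <- GenomicRanges::countOverlaps(frag_gr, read_gr, minoverlap = 1L)
  structure(
    list(map = frags, counts = as.numeric(counts),
         library_size = nrow(reads)),
    class = "bin_counts"
  )
}

#' Construct fragment counts directly
#'
#' Used when per-fragment counts are produced elsewhere (e.g. by the
#' synthetic-data generators) rather than tallied from aligned reads.
#'
#' @param frags A `gatc_map`.
#' @param counts Numeric vector, one non-negative count per fragment.
#' @param library_size Total reads in the library; defaults to `sum(counts)`.
#' @return A `bin_counts` object.
#' @export
bin_counts <- function(frags, counts, library_size = sum(counts)) {
  stopifnot(inherits(frags, "gatc_map"))
  if (length(counts) != nrow(frags)) {
    rlang::abort("`counts` must have one entry per fragment")
  }
  if (any(counts < 0)) rlang::abort("`counts` must be non-negative")
  structure(
    list(map = frags, counts = as.numeric(counts),
         library_size = library_size),
    class = "bin_counts"
  )
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("<bin_counts: %d fragments, library size %s>\n",
              length(x$counts), format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Compute per-fragment DamID log2 scores
#'
#' Scores each GATC fragment as the log2 ratio of the Dam-fusion signal over
#' the Dam-only control. Fragments with zero reads in both samples, and
#' fragments overlapping the optional mask, are set to missing (never to an
#' accidental zero). A zero count in exactly one sample is replaced by the
#' 0.5 pseudocount before the ratio. With `normalize = TRUE` counts are
#' first scaled to reads per million by library size (the pseudocount is
#' applied after scaling, on the raw-zero side).
#'
#' By default scores are then centred on the genome-wide mean log-ratio
#' (`center = "mean"`), so that a positive score denotes above-average
#' fusion signal: the zero point of the raw ratio depends on the relative
#' read composition of the two libraries, which makes the sign of the raw
#' score arbitrary. Use `center = "none"` for the literal log2 ratio.
#'
#' @param fusion,control `bin_counts` for the Dam-fusion and Dam-only
#'   libraries, sharing one fragment map.
#' @param normalize Scale counts to reads per million before the ratio.
#' @param mask Optional BED-style data frame; fragments overlapping it are
#'   excluded (e.g. unalignable regions).
#' @param pseudocount Value substituted for a zero count (0.5).
#' @param center One of `"mean"`, `"median"`, `"none"`.
#' @return A `damid_scores` tibble with columns `chrom`, `start`, `end`,
#'   `frag`, `score` (`NA` = missing), and attributes `seqlengths`,
#'   `n_masked`.
#' @export
compute_damid_scores <- function(fusion, control, normalize = TRUE,
                                 mask = NULL, pseudocount = 0.5,
                                 center = c("mean", "median", "none")) {
  center <- match.arg(center)
  stopifnot(inherits(fusion, "bin_counts"), inherits(control, "bin_counts"))
  if (!identical(as.data.frame(fusion$map), as.data.frame(control$map))) {
    rlang::abort("fusion and control must share one fragment map")
  }
  if (fusion$library_size <= 0 || control$library_size <= 0) {
    rlang::abort("library sizes must be positive")
  }
  map <- fusion$map
  f_raw <- fusion$counts
  c_raw <- control$counts
  missing <- f_raw == 0 & c_raw == 0

  if (!is.null(mask)) {
    assert_bed_frame(mask, "mask")
    frag_gr <- bed_to_granges(as.data.frame(map)[, c("chrom", "start", "end")])
    mask_gr <- bed_to_granges(mask[, c("chrom", "start", "end")])
    masked <- GenomicRanges::countOverlaps(frag_gr, mask_gr) > 0
  } else {
    masked <- rep(FALSE, nrow(map))
  }

  f_val <- if (normalize) f_raw * 1e6 / fusion$library_size else f_raw
  c_val <- if (normalize) c_raw * 1e6 / control$library_size else c_raw
  f_val[f_raw == 0] <- pseudocount
  c_val[c_raw == 0] <- pseudocount

  score <- log2(f_val / c_val)
  score[missing | masked] <- NA_real_
  if (center != "none" && any(!is.na(score))) {
    mid <- if (center == "mean") mean(score, na.rm = TRUE)
           else median(score, na.rm = TRUE)
    score <- score - mid
  }

  out <- tibble::tibble(
    chrom = map$chrom, start = map$start, end = map$end, frag = map$frag,
    score = score
  )
  structure(out,
            seqlengths = attr(map, "seqlengths"),
            n_masked = sum(masked),
            class = c("damid_scores", class(out)))
}

#' Write a score track as bedGraph
#'
#' Missing fragments are omitted from the output, as bedGraph has no notion
#' of NA.
#'
#' @param scores A `damid_scores` tibble (or any table with `chrom`, `start`,
#'   `end`, `score`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(scores, path) {
  assert_bed_frame(scores, "scores")
  keep <- !is.na(scores$score)
  gr <- bed_to_granges(as.data.frame(scores)[keep, c("chrom", "start", "end", "score")])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `score` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  granges_to_bed(rtracklayer::import(path, format = "bedGraph"))
}
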