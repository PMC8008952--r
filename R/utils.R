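# Shared coordinate conventions: user-facing interval tables are BED-style,
# 0-based half-open [start, end). GRanges (1-based closed) are used internally
# for overlap arithmetic and converted at the boundary.

#' Convert a BED-style interval table to GRanges
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based half-open)
#'   and optionally further metadata columns, which are carried over.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
#' @noRd
bed_to_granges <- function(x, seqlengths = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(x[, extra, drop = FALSE])
  }
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' @noRd
granges_to_bed <- function(gr) {
  out <- tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(mc)))
  out
}

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    rlang::abort(sprintf("`%s` must be a single number >= %s", name, min))
  }
  invisible(x)
}

#' @noRd
assert_bed_frame <- function(x, name = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    rlang::abort(sprintf(
      "`%s` must be a data frame with columns chrom, start, end", name
    ))
  }
  if (any(x$end < x$start)) {
    rlang::abort(sprintf("`%s` contains intervals with end < start", name))
  }
  invisible(x)
}
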