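#' Construct a sequencing read
#'
#' A lightweight record holding a read identifier, its base string and
#' per-base Phred quality scores. These preprocessing helpers are provided
#' for completeness; the standard entry point of the LAD caller is aligned
#' reads in BED form (alignment itself is outside the package's scope).
#'
#' @param id Read identifier.
#' @param bases DNA string.
#' @param quals Integer vector of Phred scores, one per base, all >= 0.
#' @return An object of class `damid_read`.
#' @export
damid_read <- function(id, bases, quals) {
  if (nchar(bases) != length(quals)) {
    rlang::abort("`bases` and `quals` must have the same length")
  }
  if (length(quals) && any(quals < 0)) {
    rlang::abort("`quals` must be non-negative")
  }
  structure(list(id = id, bases = bases, quals = as.integer(quals)),
            class = "damid_read")
}

#' @export
print.damid_read <- function(x, ...) {
  cat(sprintf("<damid_read %s: %d bp>\n", x$id, nchar(x$bases)))
  invisible(x)
}

#' Quality-trim the 5' end of a read
#'
#' Removes the smallest 5' prefix such that the first sliding window of the
#' remainder has mean quality at or above the cutoff (window of 3 bases and
#' cutoff 30 by default). When fewer than `window` bases remain at a
#' candidate start, the mean over the remaining bases is used, so a short
#' read is returned as-is if its full-length mean passes. If no window
#' qualifies the empty read is returned.
#'
#' @param read A [damid_read()].
#' @param window Sliding window width in bases.
#' @param cutoff Minimum mean Phred score for the window.
#' @return A `damid_read` (possibly empty).
#' @export
trim_read_5prime <- function(read, window = 3L, cutoff = 30) {
  stopifnot(inherits(read, "damid_read"))
  if (window < 1L) rlang::abort("`window` must be >= 1")
  n <- length(read$quals)
  for (s in seq_len(n)) {
    w <- read$quals[s:min(s + window - 1L, n)]
    if (mean(w) >= cutoff) {
      return(damid_read(read$id, substr(read$bases, s, n), read$quals[s:n]))
    }
  }
  damid_read(read$id, "", integer(0))
}

#' Split a read at DamID adaptor-primer occurrences
#'
#' Partitions the read at every exact occurrence of the adaptor sequence,
#' removes the adaptor bases, and keeps only pieces longer than
#' `min_len - 1` bases (i.e. > 20 bp at the default), with matching quality
#' slices. A read without the adaptor is returned whole (if long enough).
#'
#' @param read A [damid_read()].
#' @param adaptor Adaptor-primer DNA string (exact matching, non-overlapping,
#'   left to right).
#' @param min_len Minimum retained piece length (pieces shorter than this are
#'   discarded).
#' @return List of `damid_read` pieces, possibly empty.
#' @export
split_on_adaptor <- function(read, adaptor, min_len = 21L) {
  stopifnot(inherits(read, "damid_read"))
  if (!is.character(adaptor) || !nzchar(adaptor)) {
    rlang::abort("`adaptor` must be a non-empty string")
  }
  hits <- gregexpr(adaptor, read$bases, fixed = TRUE)[[1]]
  starts <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  alen <- nchar(adaptor)
  piece_start <- 1L
  bounds <- list()
  for (h in starts) {
    if (h < piece_start) next # overlapping occurrence already consumed
    bounds[[length(bounds) + 1L]] <- c(piece_start, h - 1L)
    piece_start <- h + alen
  }
  bounds[[length(bounds) + 1L]] <- c(piece_start, nchar(read$bases))
  pieces <- list()
  for (k in seq_along(bounds)) {
    a <- bounds[[k]][1]
    b <- bounds[[k]][2]
    if (b - a + 1L >= min_len) {
      pieces[[length(pieces) + 1L]] <- damid_read(
        sprintf("%s/%d", read$id, k),
        substr(read$bases, a, b),
        read$quals[seq(a, b)]
      )
    }
  }
  pieces
}
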