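#' Scan a DNA sequence for GATC motifs
#'
#' Finds every occurrence of the DpnI recognition motif GATC in a DNA
#' sequence. Matching is case-insensitive (soft-masked genomes are common);
#' `N` (or any other ambiguity code) never matches, because DpnI recognises
#' the literal sequence.
#'
#' @param seq A single DNA string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return Sorted integer vector of 0-based motif start positions, so that
#'   `substr(seq, p + 1, p + 4) == "GATC"` for every returned `p`.
#' @examples
#' scan_gatc_sites("GGATCAAAGATCCC")
#' @export
scan_gatc_sites <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    rlang::abort("`seq` must be a single character string")
  }
  if (nchar(seq) == 0L) {
    rlang::abort("`seq` is empty: cannot scan an empty sequence")
  }
  bad <- gregexpr("[^ACGTNacgtn]", seq)[[1]]
  if (bad[1] != -1L) {
    rlang::abort(sprintf(
      "illegal character '%s' in sequence at position %d (1-based)",
      substr(seq, bad[1], bad[1]), bad[1]
    ))
  }
  subject <- Biostrings::DNAString(toupper(seq))
  hits <- Biostrings::matchPattern("GATC", subject, fixed = TRUE)
  as.integer(Biostrings::start(hits)) - 1L
}

#' Build the DpnI (GATC) restriction-fragment map of a genome
#'
#' Digests each chromosome in silico at every GATC motif and returns the
#' resulting fragments, which are the quantification bins for DamID. DpnI
#' cuts GA^TC, so the cut coordinate is motif start + 2 (0-based); any
#' consistent convention shifts all bins by at most 2 bp. Fragments tile each
#' chromosome exactly: a motif-free chromosome yields a single fragment, and
#' terminal sub-fragments at chromosome ends are retained as bins.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return A `gatc_map`: a tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open, BED convention) and `frag` (1-based index within the
#'   chromosome), with attributes `seqlengths` (named integer vector) and
#'   `cut_sites` (named list of 0-based cut positions per chromosome).
#' @examples
#' build_fragment_map(c(chrA = "GGATCAAAGATCCC"))
#' @export
build_fragment_map <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      any(!nzchar(names(genome)))) {
    rlang::abort("`genome` must be a named character vector or DNAStringSet")
  }
  if (anyDuplicated(names(genome))) {
    rlang::abort("chromosome names must be unique")
  }
  seqlengths <- setNames(nchar(genome), names(genome))
  pieces <- vector("list", length(genome))
  cut_sites <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    len <- seqlengths[[i]]
    cuts <- scan_gatc_sites(genome[[i]]) + 2L
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    pieces[[i]] <- tibble::tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      frag = seq_len(length(bounds) - 1L)
    )
    cut_sites[[i]] <- cuts
  }
  out <- dplyr::bind_rows(pieces)
  structure(
    out,
    seqlengths = seqlengths,
    cut_sites = setNames(cut_sites, names(genome)),
    class = c("gatc_map", class(out))
  )
}

#' @export
print.gatc_map <- function(x, ...) {
  sl <- attr(x, "seqlengths")
  cat(sprintf(
    "GATC fragment map: %d fragments on %d chromosome(s), %s bp total\n",
    nrow(x), length(sl), format(sum(as.numeric(sl)), big.mark = ",")
  ))
  NextMethod()
}

#' Coerce a BED-style fragment table to a `gatc_map`
#'
#' Reconstructs the fragment-map object from fragment intervals read back
#' from disk (e.g. a `fragments.bed` written by [write_bed3()]). The
#' fragments of each chromosome must tile it contiguously from 0.
#'
#' @param x Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return A `gatc_map` (see [build_fragment_map()]).
#' @export
as_gatc_map <- function(x) {
  assert_bed_frame(x, "fragments")
  x <- x[order(x$chrom, x$start), c("chrom", "start", "end"), drop = FALSE]
  pieces <- lapply(split(x, x$chrom), function(sub) {
    if (sub$start[1] != 0 ||
        any(sub$start[-1] != sub$end[-nrow(sub)])) {
      rlang::abort(sprintf(
        "fragments on %s do not tile the chromosome contiguously from 0",
        sub$chrom[1]))
    }
    sub$frag <- seq_len(nrow(sub))
    sub
  })
  out <- tibble::as_tibble(do.call(rbind, pieces))
  rownames(out) <- NULL
  seqlengths <- vapply(pieces, function(sub) max(sub$end), numeric(1))
  cuts <- lapply(pieces, function(sub) as.integer(sub$end[-nrow(sub)]))
  structure(out, seqlengths = setNames(as.integer(seqlengths), names(pieces)),
            cut_sites = cuts, class = c("gatc_map", class(out)))
}

#' Read a genome FASTA into the form expected by [build_fragment_map()]
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(as.character(ss), names(ss))
}

#' Write a fragment map (or any BED-style table) to a BED3 file
#'
#' @param x Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed3 <- function(x, path) {
  assert_bed_frame(x)
  gr <- bed_to_granges(x[, c("chrom", "start", "end")])
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as a BED-style tibble
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) plus any
#'   name/score columns present.
#' @export
read_bed <- function(path) {
  granges_to_bed(rtracklayer::import(path, format = "BED"))
}
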