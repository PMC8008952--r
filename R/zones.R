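#' Normalize protein symbols
#'
#' Uppercases and whitespace-strips symbols, then applies an optional
#' synonym table mapping aliases to canonical symbols. Interactome studies
#' mix species casing and aliases, so normalization must precede any set
#' comparison.
#'
#' @param symbols Character vector of raw symbols.
#' @param synonyms Optional data frame with columns `alias`, `canonical`.
#'   Aliases are matched after case/trim normalization. An alias mapped to
#'   two distinct canonical symbols is an error.
#' @return Character vector of normalized symbols (same length/order).
#'   Collisions (distinct inputs collapsing to one symbol) are reported with
#'   a message.
#' @export
normalize_symbols <- function(symbols, synonyms = NULL) {
  out <- toupper(trimws(symbols))
  if (!is.null(synonyms)) {
    stopifnot(all(c("alias", "canonical") %in% names(synonyms)))
    alias <- toupper(trimws(synonyms$alias))
    canonical <- toupper(trimws(synonyms$canonical))
    dup <- split(canonical, alias)
    bad <- names(dup)[vapply(dup, function(v) length(unique(v)) > 1L, logical(1))]
    if (length(bad)) {
      rlang::abort(sprintf(
        "synonym table maps alias '%s' to multiple canonical symbols", bad[1]))
    }
    lookup <- vapply(dup, function(v) v[1], character(1))
    hit <- out %in% names(lookup)
    out[hit] <- lookup[out[hit]]
  }
  collided <- duplicated(out) & !duplicated(symbols)
  if (any(collided)) {
    rlang::inform(sprintf(
      "%d distinct input symbol(s) collapsed onto an existing symbol after normalization",
      sum(collided)))
  }
  out
}

#' Build the meta-laminome from several published lamina interactomes
#'
#' A protein joins the meta-laminome when it appears in at least
#' `min_studies` of the supplied datasets (the conventional rule is 3 of 4).
#'
#' @param datasets Named list of character vectors (normalized protein
#'   symbols), one per study.
#' @param min_studies Minimum number of datasets a protein must appear in.
#' @return Sorted character vector of meta-laminome symbols.
#' @export
meta_laminome <- function(datasets, min_studies = 3L) {
  if (!is.list(datasets) || length(datasets) == 0L) {
    rlang::abort("`datasets` must be a non-empty list of symbol vectors")
  }
  if (min_studies > length(datasets)) {
    rlang::abort(sprintf(
      "min_studies (%d) exceeds the number of datasets (%d)",
      min_studies, length(datasets)))
  }
  tallies <- table(unlist(lapply(datasets, unique)))
  sort(names(tallies)[tallies >= min_studies])
}

#' Assign nuclear-periphery interface zones
#'
#' Partitions the protein universe into three interface zones plus a
#' remainder: zone 1 holds proteins restricted to the INM/lamina (in the
#' laminome or the bait interactome but not LAD-associated), zone 2 the
#' "middlemen" found both at the lamina and on LADs, zone 3 proteins
#' restricted to LADs, and `none` the rest of the universe.
#'
#' @param laminome,lap2b,ladome Character vectors of normalized symbols:
#'   the (meta-)laminome, the bait (LAP2beta) interactome, and the
#'   LAD-associated proteome.
#' @param universe Optional explicit universe; defaults to the union of the
#'   three sets.
#' @return A `zone_assignment` tibble with `symbol` and `zone` (factor with
#'   levels `1`, `2`, `3`, `none`); every universe protein gets exactly one
#'   label and the partition property is asserted on every run.
#' @export
assign_zones <- function(laminome, lap2b, ladome, universe = NULL) {
  laminome <- unique(laminome)
  lap2b <- unique(lap2b)
  ladome <- unique(ladome)
  if (is.null(universe)) universe <- union(union(laminome, lap2b), ladome)
  universe <- unique(universe)
  inm <- union(laminome, lap2b)
  zone <- rep("none", length(universe))
  zone[universe %in% setdiff(inm, ladome)] <- "1"
  zone[universe %in% intersect(ladome, inm)] <- "2"
  zone[universe %in% setdiff(ladome, inm)] <- "3"
  out <- tibble::tibble(
    symbol = universe,
    zone = factor(zone, levels = c("1", "2", "3", "none"))
  )
  stopifnot(sum(table(out$zone)) == length(universe))
  structure(out[order(out$zone, out$symbol), ],
            class = c("zone_assignment", class(out)))
}

#' Disjoint-region counts for a Venn diagram of up to four sets
#'
#' @param sets Named list of 2 to 4 character vectors (normalized symbols).
#' @return Tibble with one row per non-empty combination pattern:
#'   `region` (set names joined by `&`), `count`. Region counts sum to the
#'   size of the union.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rlang::abort("`sets` must be a named list")
  }
  k <- length(sets)
  if (k < 2L || k > 4L) {
    rlang::abort("venn_counts supports 2 to 4 sets; report a membership table instead")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(n) {
    utils::combn(names(sets), n, paste, collapse = "&")
  }))
  counts <- table(factor(patterns, levels = combos))
  tibble::tibble(region = names(counts), count = as.integer(counts))
}

#' Read a one-symbol-per-row dataset file
#'
#' @param path TSV/text file whose first column holds protein symbols
#'   (header optional; a first line named `symbol` is skipped).
#' @param synonyms Optional synonym table passed to [normalize_symbols()].
#' @return Character vector of unique normalized symbols.
#' @export
read_symbol_set <- function(path, synonyms = NULL) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) && tolower(trimws(raw[1])) == "symbol") raw <- raw[-1]
  unique(normalize_symbols(raw, synonyms))
}
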