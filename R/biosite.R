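#' Load a biotinylation-site table
#'
#' Reads a TSV with one row per biotinylated-peptide observation. Required
#' columns: `protein_id`, `site_pos` (1-based residue index), `residue`
#' (expected `K`, since the biotin transfer targets lysines), `condition`,
#' `replicate`, `abundance` (MS1 intensity, >= 0). Non-biotinylated
#' peptides are assumed to have been removed upstream; rows whose residue is
#' not lysine are flagged (and rejected under `strict = TRUE`).
#'
#' @param path Path to the TSV file.
#' @param strict Reject non-lysine residues with an error instead of a
#'   warning.
#' @return Tibble of typed site records.
#' @export
load_site_table <- function(path, strict = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("protein_id", "site_pos", "residue", "condition",
                "replicate", "abundance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    rlang::abort(sprintf("site table is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0L) {
    rlang::warn("site table has an empty data section")
    return(df)
  }
  df$site_pos <- as.integer(df$site_pos)
  df$replicate <- as.integer(df$replicate)
  df$abundance <- as.numeric(df$abundance)
  if (any(is.na(df$site_pos)) || any(df$site_pos < 1L)) {
    rlang::abort("`site_pos` must be a 1-based positive residue index")
  }
  if (any(is.na(df$abundance)) || any(df$abundance < 0)) {
    i <- which(is.na(df$abundance) | df$abundance < 0)[1]
    rlang::abort(sprintf("row %d has a negative or missing abundance", i))
  }
  non_k <- df$residue != "K"
  if (any(non_k)) {
    msg <- sprintf("%d row(s) carry a non-lysine residue (e.g. row %d: '%s')",
                   sum(non_k), which(non_k)[1], df$residue[which(non_k)[1]])
    if (strict) rlang::abort(msg) else rlang::warn(msg)
  }
  df
}

#' Aggregate biotinylation-site records to the protein level
#'
#' Per protein, condition and replicate, abundance is the sum over that
#' protein's site records; `n_sites` is the number of distinct biotinylated
#' positions observed for the protein across all conditions and replicates
#' (sites are identified by `(protein_id, site_pos)`, so peptides sharing a
#' site collapse).
#'
#' @param records Tibble of site records as from [load_site_table()].
#' @return Tibble with one row per (`protein_id`, `condition`, `replicate`):
#'   `protein_id`, `n_sites`, `condition`, `replicate`, `abundance`.
#' @export
summarize_proteins <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    rlang::abort("`records` must be a non-empty data frame of site records")
  }
  n_sites <- records |>
    dplyr::distinct(.data$protein_id, .data$site_pos) |>
    dplyr::count(.data$protein_id, name = "n_sites")
  records |>
    dplyr::group_by(.data$protein_id, .data$condition, .data$replicate) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::left_join(n_sites, by = "protein_id") |>
    dplyr::select("protein_id", "n_sites", "condition", "replicate",
                  "abundance") |>
    dplyr::arrange(.data$protein_id, .data$condition, .data$replicate)
}

#' Compute per-protein replicate ratios and enrichment calls
#'
#' For each protein, one ratio per replicate (numerator-condition abundance
#' over denominator-condition abundance) is computed and the ratios are then
#' averaged across replicates; a protein is called enriched when the mean
#' ratio exceeds the fold threshold. The default threshold of 2 matches a
#' bait-versus-tracer comparison; 1.6 is the conventional choice for a
#' +shield versus -shield comparison.
#'
#' A protein absent from the denominator in a replicate would give an
#' infinite ratio; instead the denominator is imputed as the smallest
#' positive abundance observed in that replicate of the denominator
#' condition (a floor), and the protein is flagged `imputed`. A protein with
#' no numerator-condition observation at all is excluded (with a message).
#' Proteins quantified in only a subset of replicates are averaged over the
#' available replicates, with `n_replicates` reported.
#'
#' @param summaries Protein-level table from [summarize_proteins()].
#' @param numerator_condition,denominator_condition Condition labels.
#' @param threshold Fold-change threshold; enriched iff mean ratio >
#'   threshold (strictly).
#' @param mean_type Average the per-replicate ratios arithmetically
#'   (default, "average ratio between replicates") or geometrically.
#' @param method `"ratio_of_replicates"` (default): one ratio per replicate,
#'   then the mean. `"ratio_of_means"`: average abundances across replicates
#'   per condition, then a single ratio.
#' @return Tibble with `protein_id`, `n_sites`, `n_replicates`,
#'   `mean_ratio`, `enriched`, `imputed`, plus one `ratio_<r>` column per
#'   replicate.
#' @export
compute_enrichment <- function(summaries, numerator_condition,
                               denominator_condition, threshold = 2,
                               mean_type = c("arithmetic", "geometric"),
                               method = c("ratio_of_replicates",
                                          "ratio_of_means")) {
  mean_type <- match.arg(mean_type)
  method <- match.arg(method)
  conds <- unique(summaries$condition)
  for (cond in c(numerator_condition, denominator_condition)) {
    if (!cond %in% conds) {
      rlang::abort(sprintf("condition '%s' not present in the summaries", cond))
    }
  }
  num <- summaries[summaries$condition == numerator_condition, , drop = FALSE]
  den <- summaries[summaries$condition == denominator_condition, , drop = FALSE]
  reps <- sort(intersect(unique(num$replicate), unique(den$replicate)))
  if (length(reps) == 0L) {
    rlang::abort("the two conditions share no replicate indices")
  }
  # replicate-wise imputation floor: smallest positive denominator abundance
  floor_by_rep <- vapply(reps, function(r) {
    v <- den$abundance[den$replicate == r & den$abundance > 0]
    if (length(v)) min(v) else NA_real_
  }, numeric(1))
  names(floor_by_rep) <- as.character(reps)

  proteins <- sort(unique(c(num$protein_id, den$protein_id)))
  absent_num <- setdiff(unique(den$protein_id), unique(num$protein_id))
  if (length(absent_num)) {
    rlang::inform(sprintf(
      "%d protein(s) absent from the numerator condition were excluded",
      length(absent_num)))
    proteins <- setdiff(proteins, absent_num)
  }

  n_sites_map <- summaries |>
    dplyr::distinct(.data$protein_id, .data$n_sites)

  rows <- lapply(proteins, function(p) {
    ratios <- setNames(rep(NA_real_, length(reps)), as.character(reps))
    imputed <- FALSE
    for (r in reps) {
      a_num <- num$abundance[num$protein_id == p & num$replicate == r]
      a_den <- den$abundance[den$protein_id == p & den$replicate == r]
      have_num <- length(a_num) == 1L && a_num > 0
      have_den <- length(a_den) == 1L && a_den > 0
      if (!have_num && !have_den) next
      if (!have_den) {
        a_den <- floor_by_rep[[as.character(r)]]
        imputed <- TRUE
      }
      if (!have_num) a_num <- 0
      ratios[[as.character(r)]] <- a_num / a_den
    }
    obs <- ratios[!is.na(ratios)]
    tibble::tibble(protein_id = p,
                   n_replicates = length(obs),
                   imputed = imputed,
                   !!!setNames(as.list(ratios), paste0("ratio_", reps)))
  })
  out <- dplyr::bind_rows(rows)
  ratio_cols <- paste0("ratio_", reps)
  ratio_mat <- as.matrix(out[, ratio_cols, drop = FALSE])
  if (method == "ratio_of_means") {
    mean_ratio <- vapply(proteins, function(p) {
      m_num <- mean(num$abundance[num$protein_id == p & num$replicate %in% reps])
      a_den <- den$abundance[den$protein_id == p & den$replicate %in% reps]
      m_den <- if (length(a_den) && sum(a_den) > 0) mean(a_den)
               else min(floor_by_rep, na.rm = TRUE)
      m_num / m_den
    }, numeric(1))
  } else if (mean_type == "arithmetic") {
    mean_ratio <- rowMeans(ratio_mat, na.rm = TRUE)
  } else {
    mean_ratio <- exp(rowMeans(log(ratio_mat), na.rm = TRUE))
  }
  out$mean_ratio <- as.numeric(mean_ratio)
  out$enriched <- !is.na(out$mean_ratio) & out$mean_ratio > threshold
  out <- dplyr::left_join(out, n_sites_map, by = "protein_id")
  dplyr::select(out, "protein_id", "n_sites", "n_replicates",
                dplyr::all_of(ratio_cols), "mean_ratio", "enriched",
                "imputed")
}

#' Rank proteins by degree of biotinylation
#'
#' The degree of biotinylation of a protein is the number of distinct
#' biotinylated lysines divided by the total number of lysines in its
#' sequence, a value in \[0, 1\] used to rank proteins from greatest to
#' least (a proxy for proximity and/or abundance relative to the bait).
#'
#' @param records Tibble of site records ([load_site_table()]).
#' @param proteome A [Biostrings::AAStringSet], or a named character vector
#'   of protein sequences, or a path to a protein FASTA.
#' @return Tibble `protein_id`, `biotinylated_lysines`, `total_lysines`,
#'   `degree`, sorted descending by degree with ties broken by
#'   `protein_id`. Proteins that could not be scored (absent from the
#'   proteome, zero lysines, or a site position that is out of range or not
#'   a lysine) are dropped from the ranking and reported in the `errors`
#'   attribute (a tibble of `protein_id`, `reason`), with a warning.
#' @export
degree_of_biotinylation <- function(records, proteome) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    proteome <- Biostrings::readAAStringSet(proteome)
  }
  if (methods::is(proteome, "AAStringSet")) {
    proteome <- setNames(as.character(proteome),
                         sub("\\s.*$", "", names(proteome)))
  }
  if (!is.character(proteome) || is.null(names(proteome))) {
    rlang::abort("`proteome` must be an AAStringSet, named character vector, or FASTA path")
  }
  sites <- dplyr::distinct(records, .data$protein_id, .data$site_pos)
  rows <- list()
  errors <- list()
  for (p in sort(unique(sites$protein_id))) {
    pos <- sites$site_pos[sites$protein_id == p]
    if (!p %in% names(proteome)) {
      errors[[p]] <- "absent from proteome FASTA"
      next
    }
    seq <- proteome[[p]]
    if (any(pos > nchar(seq))) {
      errors[[p]] <- "site position exceeds sequence length"
      next
    }
    res_at <- substring(seq, pos, pos)
    if (any(res_at != "K")) {
      errors[[p]] <- "site position is not a lysine in the sequence"
      next
    }
    total_k <- sum(Biostrings::letterFrequency(Biostrings::AAString(seq), "K"))
    if (total_k == 0L) {
      errors[[p]] <- "protein has zero lysines; degree undefined"
      next
    }
    rows[[p]] <- tibble::tibble(
      protein_id = p,
      biotinylated_lysines = length(unique(pos)),
      total_lysines = as.integer(total_k),
      degree = length(unique(pos)) / total_k
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- out[order(-out$degree, out$protein_id), , drop = FALSE]
  }
  err_tbl <- tibble::tibble(protein_id = names(errors),
                            reason = unlist(errors, use.names = FALSE))
  if (nrow(err_tbl)) {
    rlang::warn(sprintf("%d protein(s) could not be scored; see attr(, 'errors')",
                        nrow(err_tbl)))
  }
  attr(out, "errors") <- err_tbl
  out
}

#' Locate biotinylation sites within membrane-topology domains
#'
#' Labels every distinct site with the annotated topological domain
#' (lumenal, nucleoplasmic, cytoplasmic, transmembrane, ...) whose 1-based
#' inclusive residue range contains the site. Sites on proteins without any
#' annotation are labelled `"unannotated"`; annotated proteins' sites
#' falling in no domain are `"unassigned"`.
#'
#' @param records Tibble of site records.
#' @param annotations Tibble with `protein_id`, `start`, `end`, `label`
#'   (1-based inclusive residue ranges).
#' @param strict Error on a site beyond the annotated span of its protein
#'   (default); with `strict = FALSE` such sites get label `NA` and a
#'   warning.
#' @return Tibble `protein_id`, `site_pos`, `topology`.
#' @export
map_site_topology <- function(records, annotations, strict = TRUE) {
  stopifnot(all(c("protein_id", "start", "end", "label") %in% names(annotations)))
  # reject overlapping domain ranges per protein
  for (p in unique(annotations$protein_id)) {
    a <- annotations[annotations$protein_id == p, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1] <= a$end[-nrow(a)])) {
      rlang::abort(sprintf("overlapping domain ranges in annotation of %s", p))
    }
  }
  sites <- dplyr::distinct(records, .data$protein_id, .data$site_pos)
  topo <- character(nrow(sites))
  oob <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$protein_id[i]
    pos <- sites$site_pos[i]
    a <- annotations[annotations$protein_id == p, , drop = FALSE]
    if (nrow(a) == 0L) {
      topo[i] <- "unannotated"
      next
    }
    if (pos > max(a$end)) {
      oob[i] <- TRUE
      topo[i] <- NA_character_
      next
    }
    hit <- which(a$start <= pos & pos <= a$end)
    topo[i] <- if (length(hit)) a$label[hit[1]] else "unassigned"
  }
  if (any(oob)) {
    msg <- sprintf(
      "%d site(s) lie beyond the annotated span of their protein (e.g. %s:%d)",
      sum(oob), sites$protein_id[which(oob)[1]], sites$site_pos[which(oob)[1]])
    if (strict) rlang::abort(msg) else rlang::warn(msg)
  }
  tibble::tibble(protein_id = sites$protein_id, site_pos = sites$site_pos,
                 topology = topo)
}
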