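# Seeded synthetic-data generators. Every generator is a pure function of
# (config, seed): it calls set.seed internally (with a small fixed offset per
# generator so the stages draw independent streams) and regenerating with the
# same config is byte-identical. Defaults emulate a mouse-like scale-down:
# one 10 Mb chromosome, a GATC roughly every 250 bp, 15 planted LADs of
# 100-500 kb at 4-fold Dam-fusion enrichment and a mean depth of 10 reads
# per fragment.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by the `simulate_*`
#' generators. Any component can be overridden by passing a partial list;
#' unspecified entries keep their defaults.
#'
#' @param seed Integer seed (mandatory).
#' @param genome_length Chromosome length in bp.
#' @param gatc_rate Expected inserted GATC motifs per kb.
#' @param chrom Chromosome name used in all emitted files.
#' @param lads List: `n`, `size_range` (bp), `min_spacing` (bp).
#' @param damid List: `depth` (mean reads per fragment), `fold`
#'   (fusion enrichment inside LADs, > 1 unless simulating the null),
#'   `noise` (`"poisson"` or `"negative_binomial"`), `nb_dispersion`
#'   (variance/mean ratio for the negative binomial).
#' @param biosite List: `n_proteins`, `n_enriched`, `fold`, `lognormal_sd`,
#'   `n_replicates`, `sites_range`.
#' @param peaks List: `n`, `width_range` (bp), `target_overlap` in \[0, 1\].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       genome_length = 1e7,
                       gatc_rate = 4,
                       chrom = "chrSim",
                       lads = list(),
                       damid = list(),
                       biosite = list(),
                       peaks = list()) {
  if (missing(seed)) rlang::abort("`seed` is mandatory")
  assert_scalar_number(seed, "seed")
  cfg <- list(
    seed = as.integer(seed),
    genome_length = genome_length,
    gatc_rate = gatc_rate,
    chrom = chrom,
    lads = utils::modifyList(
      list(n = 15L, size_range = c(1e5, 5e5), min_spacing = 1e5), lads),
    damid = utils::modifyList(
      list(depth = 10, fold = 4, noise = "poisson", nb_dispersion = 2), damid),
    biosite = utils::modifyList(
      list(n_proteins = 500L, n_enriched = 50L, fold = 3,
           lognormal_sd = 0.2, n_replicates = 2L, sites_range = c(1L, 6L)),
      biosite),
    peaks = utils::modifyList(
      list(n = 500L, width_range = c(200, 1000), target_overlap = 0.8), peaks)
  )
  if (cfg$genome_length < 1000) rlang::abort("`genome_length` must be >= 1 kb")
  if (cfg$gatc_rate < 0) rlang::abort("`gatc_rate` must be >= 0")
  if (cfg$gatc_rate > 100) {
    rlang::abort("`gatc_rate` above 100/kb: motifs would overlap")
  }
  with(cfg$lads, {
    if (size_range[1] > size_range[2]) rlang::abort("lads$size_range min > max")
    if (n < 0 || min_spacing < 0) rlang::abort("lads counts must be >= 0")
  })
  if (cfg$damid$fold < 1) rlang::abort("damid$fold must be >= 1")
  if (!cfg$damid$noise %in% c("poisson", "negative_binomial")) {
    rlang::abort("damid$noise must be 'poisson' or 'negative_binomial'")
  }
  with(cfg$biosite, {
    if (n_enriched > n_proteins) rlang::abort("biosite$n_enriched > n_proteins")
    if (sites_range[1] > sites_range[2]) rlang::abort("biosite$sites_range min > max")
  })
  if (cfg$peaks$target_overlap < 0 || cfg$peaks$target_overlap > 1) {
    rlang::abort("peaks$target_overlap must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [sim_config()].
#' @return A validated `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Simulate a genome with controlled GATC structure
#'
#' Generates a uniform-random background sequence, scrubs it of accidental
#' GATC motifs (so that motif density is governed by `gatc_rate` rather than
#' the 1/256 background rate), then inserts GATC motifs at positions drawn
#' as a Poisson process at `gatc_rate` per kb (candidates closer than 4 bp
#' are thinned so motifs cannot overlap). The returned truth is a fresh scan
#' of the final sequence, so any motif accidentally created at an insertion
#' junction is included.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector, one chromosome) and
#'   `truth_gatc` (0-based motif start positions).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (iter in 1:10) {
    hits <- scan_gatc_sites(paste(s, collapse = ""))
    if (!length(hits)) break
    s[hits + 3L] <- "A" # GATC -> GAAC
  }
  n_ins <- rpois(1, L * config$gatc_rate / 1000)
  if (n_ins > 0) {
    pos <- sort(sample.int(L - 3L, min(n_ins, L - 3L)))
    if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 4L)]
    s[pos] <- "G"
    s[pos + 1L] <- "A"
    s[pos + 2L] <- "T"
    s[pos + 3L] <- "C"
  }
  seqstr <- paste(s, collapse = "")
  genome <- setNames(seqstr, config$chrom)
  list(genome = genome, truth_gatc = scan_gatc_sites(seqstr))
}

#' Plant ground-truth LADs
#'
#' Places `lads$n` non-overlapping intervals with sizes uniform in
#' `lads$size_range` and pairwise (and terminal) spacing of at least
#' `lads$min_spacing`, positions drawn by distributing the leftover space
#' randomly among the gaps.
#'
#' @param config A [sim_config()].
#' @return A `lad_set` tibble of truth intervals (sorted, disjoint).
#' @export
plant_lads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$lads$n
  L <- config$genome_length
  spacing <- config$lads$min_spacing
  sizes <- round(runif(n, config$lads$size_range[1], config$lads$size_range[2]))
  slack <- L - sum(sizes) - (n + 1) * spacing
  if (slack < 0) {
    rlang::abort(paste(
      "cannot place the requested LADs in the genome;",
      "reduce lads$n or the size range"))
  }
  w <- runif(n + 1)
  gaps <- spacing + slack * w / sum(w)
  starts <- numeric(n)
  cursor <- 0
  for (i in seq_len(n)) {
    cursor <- cursor + gaps[i]
    starts[i] <- round(cursor)
    cursor <- cursor + sizes[i]
  }
  out <- tibble::tibble(chrom = config$chrom, start = starts,
                        end = starts + sizes, length = sizes)
  structure(out, class = c("lad_set", class(out)))
}

#' Simulate DamID fragment counts over planted LADs
#'
#' The Dam-only control has mean `damid$depth` reads on every fragment; the
#' Dam-fusion library has mean `depth * fold` on fragments inside a truth
#' LAD (fragment membership by midpoint; fragments are small relative to
#' LADs, so boundary fragments are ambiguous under any rule) and `depth`
#' outside. Counts are drawn per fragment from the configured noise model.
#'
#' @param frags A `gatc_map` built from the simulated genome.
#' @param truth A `lad_set` of planted LADs.
#' @param config A [sim_config()].
#' @return List with `fusion` and `control` (`bin_counts`), and `in_lad`
#'   (logical truth membership per fragment).
#' @export
simulate_damid_counts <- function(frags, truth, config) {
  stopifnot(inherits(frags, "gatc_map"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  mid <- floor((frags$start + frags$end) / 2)
  mid_gr <- bed_to_granges(tibble::tibble(chrom = frags$chrom, start = mid,
                                          end = mid + 1))
  lad_gr <- bed_to_granges(truth[, c("chrom", "start", "end")])
  in_lad <- GenomicRanges::countOverlaps(mid_gr, lad_gr) > 0
  depth <- config$damid$depth
  mu_f <- ifelse(in_lad, depth * config$damid$fold, depth)
  mu_c <- rep(depth, nrow(frags))
  draw <- function(mu) {
    if (config$damid$noise == "poisson") {
      rpois(length(mu), mu)
    } else {
      d <- config$damid$nb_dispersion
      if (d <= 1) rlang::abort("nb_dispersion must be > 1")
      rnbinom(length(mu), mu = mu, size = mu / (d - 1))
    }
  }
  f <- draw(mu_f)
  cc <- draw(mu_c)
  list(fusion = bin_counts(frags, f),
       control = bin_counts(frags, cc),
       in_lad = in_lad)
}

#' Simulate a biotinylation-site table with planted enrichment
#'
#' Generates a lysine-bearing random proteome, assigns each protein random
#' lysine sites, and draws MS1 abundances: a per-site log-normal baseline,
#' multiplied in the numerator ("bait") condition by `biosite$fold` for the
#' planted-enriched subset, with independent multiplicative log-normal noise
#' (sd `lognormal_sd`) per replicate around the shared per-site mean.
#'
#' @param config A [sim_config()].
#' @return List with `sites` (tibble in the [load_site_table()] schema),
#'   `proteome` ([Biostrings::AAStringSet] containing every protein in the
#'   table), and `truth` (tibble `protein_id`, `enriched`).
#' @export
simulate_biosite_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  bs <- config$biosite
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ids <- sprintf("P%04d", seq_len(bs$n_proteins))
  enriched <- ids %in% sample(ids, bs$n_enriched)
  seqs <- character(bs$n_proteins)
  site_pos <- vector("list", bs$n_proteins)
  for (i in seq_len(bs$n_proteins)) {
    len <- sample(200:600, 1)
    aa <- sample(aa20, len, replace = TRUE)
    ns <- sample(seq(bs$sites_range[1], bs$sites_range[2]), 1)
    k_at <- which(aa == "K")
    if (length(k_at) < ns) {
      extra <- sample(setdiff(seq_len(len), k_at), ns - length(k_at))
      aa[extra] <- "K"
      k_at <- which(aa == "K")
    }
    site_pos[[i]] <- sort(sample(k_at, ns))
    seqs[i] <- paste(aa, collapse = "")
  }
  rows <- vector("list", bs$n_proteins)
  for (i in seq_len(bs$n_proteins)) {
    pos <- site_pos[[i]]
    base <- rlnorm(length(pos), meanlog = log(1e6), sdlog = 1)
    per <- list()
    for (cond in c("bait", "control")) {
      mu <- base * if (cond == "bait" && enriched[i]) bs$fold else 1
      for (r in seq_len(bs$n_replicates)) {
        per[[length(per) + 1L]] <- tibble::tibble(
          protein_id = ids[i], site_pos = pos, residue = "K",
          condition = cond, replicate = r,
          abundance = mu * rlnorm(length(pos), 0, bs$lognormal_sd)
        )
      }
    }
    rows[[i]] <- dplyr::bind_rows(per)
  }
  sites <- dplyr::bind_rows(rows)
  proteome <- Biostrings::AAStringSet(setNames(seqs, ids))
  list(sites = sites, proteome = proteome,
       truth = tibble::tibble(protein_id = ids, enriched = enriched))
}

# Draw one uniform base (0-based) from an interval set with total coverage w.
sample_base_in <- function(iv, cumw) {
  u <- floor(runif(1) * cumw[length(cumw)])
  idx <- findInterval(u, cumw) + 1L
  prev <- if (idx == 1L) 0 else cumw[idx - 1L]
  iv$start[idx] + (u - prev)
}

#' Simulate a peak set with a target midpoint-in-region fraction
#'
#' Each peak's midpoint is placed uniformly inside `regions` with
#' probability `peaks$target_overlap` and uniformly in the complement
#' otherwise; widths are uniform in `peaks$width_range`. The achieved
#' fraction is recomputed from the final peaks with the midpoint rule.
#'
#' @param regions BED-style region set on a single chromosome.
#' @param config A [sim_config()] (supplies `genome_length` and the `peaks`
#'   component).
#' @return List with `peaks` (sorted tibble `chrom`, `start`, `end`) and
#'   `achieved` (fraction of peak midpoints inside `regions`).
#' @export
simulate_peaks <- function(regions, config) {
  stopifnot(inherits(config, "sim_config"))
  regions <- interval_set(regions)
  if (nrow(regions) == 0L) rlang::abort("`regions` is empty")
  if (length(unique(regions$chrom)) != 1L) {
    rlang::abort("simulate_peaks expects regions on a single chromosome")
  }
  set.seed(config$seed + 4L)
  L <- config$genome_length
  chrom <- regions$chrom[1]
  gaps_start <- c(0, regions$end)
  gaps_end <- c(regions$start, L)
  outside <- tibble::tibble(chrom = chrom, start = gaps_start, end = gaps_end)
  outside <- outside[outside$end > outside$start, , drop = FALSE]
  target <- config$peaks$target_overlap
  if (nrow(outside) == 0L && target < 1) {
    rlang::abort("regions cover the whole chromosome; no outside space")
  }
  cum_in <- cumsum(regions$end - regions$start)
  cum_out <- cumsum(outside$end - outside$start)
  n <- config$peaks$n
  wr <- config$peaks$width_range
  starts <- numeric(n)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    w <- round(runif(1, wr[1], wr[2]))
    inside <- runif(1) < target
    for (try in 1:100) {
      m <- if (inside) sample_base_in(regions, cum_in)
           else sample_base_in(outside, cum_out)
      st <- m - floor(w / 2)
      if (st >= 0 && st + w <= L) break
      if (try == 100) rlang::abort("could not place a peak within bounds")
    }
    starts[i] <- st
    widths[i] <- w
  }
  peaks <- tibble::tibble(chrom = chrom, start = starts, end = starts + widths)
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  achieved <- peak_fraction_within(peaks, regions, mode = "midpoint")$fraction
  list(peaks = peaks, achieved = achieved)
}

#' Run every generator and write the files of a complete synthetic study
#'
#' Emits, under `outdir`: `genome.fa`, `fragments.bed`, `truth_lads.bed`,
#' `damid_counts.tsv` (fragment coordinates with fusion/control counts),
#' `sites.tsv`, `proteome.fa`, `truth_enrichment.tsv`, `peaks.bed` and
#' `peaks_summary.tsv` (achieved overlap fraction). Truth files sit beside
#' data files so downstream recovery checks can read them.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory objects.
#' @export
simulate_all <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(gen$genome), file.path(outdir, "genome.fa"))
  frags <- build_fragment_map(gen$genome)
  write_bed3(frags, file.path(outdir, "fragments.bed"))
  truth <- plant_lads(config)
  write_bed3(truth, file.path(outdir, "truth_lads.bed"))
  counts <- simulate_damid_counts(frags, truth, config)
  utils::write.table(
    data.frame(chrom = frags$chrom, start = frags$start, end = frags$end,
               fusion = counts$fusion$counts, control = counts$control$counts),
    file.path(outdir, "damid_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  bio <- simulate_biosite_table(config)
  utils::write.table(bio$sites, file.path(outdir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(bio$proteome, file.path(outdir, "proteome.fa"))
  utils::write.table(bio$truth, file.path(outdir, "truth_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- simulate_peaks(truth, config)
  write_bed3(pk$peaks, file.path(outdir, "peaks.bed"))
  utils::write.table(
    data.frame(n_peaks = nrow(pk$peaks), achieved_overlap = pk$achieved),
    file.path(outdir, "peaks_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = gen, frags = frags, truth_lads = truth,
                 counts = counts, biosite = bio, peaks = pk))
}
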