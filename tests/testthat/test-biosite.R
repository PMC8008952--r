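write_sites_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

demo_sites <- function() {
  tibble::tibble(
    protein_id = c("P1", "P1", "P1", "P2"),
    site_pos = c(10L, 22L, 10L, 5L),
    residue = "K",
    condition = c("bait", "bait", "bait", "bait"),
    replicate = c(1L, 1L, 1L, 1L),
    abundance = c(100, 50, 50, 10)
  )
}

test_that("site tables are parsed and validated", {
  p <- write_sites_tsv(demo_sites())
  rec <- load_site_table(p)
  expect_equal(nrow(rec), 4L)
  expect_type(rec$site_pos, "integer")

  bad <- demo_sites()[, -2]
  expect_error(load_site_table(write_sites_tsv(bad)), "site_pos")

  neg <- demo_sites()
  neg$abundance[2] <- -1
  expect_error(load_site_table(write_sites_tsv(neg)), "row 2")

  nonk <- demo_sites()
  nonk$residue[1] <- "R"
  expect_warning(load_site_table(write_sites_tsv(nonk)), "non-lysine")
  expect_error(load_site_table(write_sites_tsv(nonk), strict = TRUE),
               "non-lysine")

  empty <- demo_sites()[0, ]
  expect_warning(out <- load_site_table(write_sites_tsv(empty)), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("protein summaries count distinct sites and sum abundances", {
  s <- summarize_proteins(demo_sites())
  p1 <- s[s$protein_id == "P1", ]
  expect_equal(p1$n_sites, 2L)          # sites 10 and 22; repeated 10 collapses
  expect_equal(p1$abundance, 200)       # 100 + 50 + 50
  expect_equal(s$abundance[s$protein_id == "P2"], 10)
})

test_that("random-record summaries match a brute-force group-and-sum", {
  set.seed(21)
  rec <- tibble::tibble(
    protein_id = sample(paste0("P", 1:20), 200, replace = TRUE),
    site_pos = sample(1:50, 200, replace = TRUE),
    residue = "K",
    condition = sample(c("bait", "control"), 200, replace = TRUE),
    replicate = sample(1:2, 200, replace = TRUE),
    abundance = runif(200, 1, 1000)
  )
  s <- summarize_proteins(rec)
  for (i in sample(nrow(s), 25)) {
    sel <- rec$protein_id == s$protein_id[i] &
      rec$condition == s$condition[i] & rec$replicate == s$replicate[i]
    expect_equal(s$abundance[i], sum(rec$abundance[sel]))
  }
  # aggregation conservation per condition/replicate
  for (cond in c("bait", "control")) {
    for (r in 1:2) {
      expect_equal(
        sum(s$abundance[s$condition == cond & s$replicate == r]),
        sum(rec$abundance[rec$condition == cond & rec$replicate == r]))
    }
  }
})

enr_summaries <- function(num_ab, den_ab, protein = "P1") {
  dplyr::bind_rows(
    tibble::tibble(protein_id = protein, n_sites = 1L, condition = "bait",
                   replicate = seq_along(num_ab), abundance = num_ab),
    tibble::tibble(protein_id = protein, n_sites = 1L, condition = "control",
                   replicate = seq_along(den_ab), abundance = den_ab)
  )
}

test_that("enrichment is the mean of per-replicate ratios", {
  e <- compute_enrichment(enr_summaries(c(25, 19), c(10, 10)),
                          "bait", "control", threshold = 2)
  expect_equal(e$mean_ratio, mean(c(2.5, 1.9)))
  expect_true(e$enriched)

  e2 <- compute_enrichment(enr_summaries(c(15, 15), c(10, 10)),
                           "bait", "control", threshold = 1.6)
  expect_equal(e2$mean_ratio, 1.5)
  expect_false(e2$enriched) # 1.5 < 1.6

  # boundary is strict: mean ratio exactly at threshold is not enriched
  e3 <- compute_enrichment(enr_summaries(c(20, 20), c(10, 10)),
                           "bait", "control", threshold = 2)
  expect_false(e3$enriched)
})

test_that("zero denominators are imputed with the replicate floor", {
  s <- dplyr::bind_rows(
    enr_summaries(c(50, 50), c(0, 10), protein = "P1"),
    enr_summaries(c(30, 30), c(5, 20), protein = "P2")
  )
  e <- compute_enrichment(s, "bait", "control", threshold = 2)
  p1 <- e[e$protein_id == "P1", ]
  expect_true(p1$imputed)
  # replicate-1 floor is the smallest positive control abundance there (5)
  expect_equal(p1$ratio_1, 50 / 5)
  expect_false(e$imputed[e$protein_id == "P2"])
})

test_that("proteins absent from the numerator are excluded with a note", {
  s <- dplyr::bind_rows(
    enr_summaries(c(10, 10), c(5, 5), protein = "P1"),
    tibble::tibble(protein_id = "P3", n_sites = 1L, condition = "control",
                   replicate = 1:2, abundance = c(4, 4))
  )
  expect_message(e <- compute_enrichment(s, "bait", "control"), "excluded")
  expect_false("P3" %in% e$protein_id)
  expect_error(
    compute_enrichment(enr_summaries(10, 10), "bait", "missing"),
    "not present")
})

test_that("enriched sets are monotone in the threshold", {
  set.seed(13)
  s <- dplyr::bind_rows(lapply(1:40, function(i) {
    enr_summaries(runif(2, 1, 100), runif(2, 1, 50),
                  protein = sprintf("P%02d", i))
  }))
  prev <- NULL
  for (th in c(1.2, 1.6, 2, 3, 5)) {
    cur <- compute_enrichment(s, "bait", "control", threshold = th)
    called <- cur$protein_id[cur$enriched]
    if (!is.null(prev)) expect_true(all(called %in% prev))
    prev <- called
  }
})

test_that("degree of biotinylation counts lysines against the proteome", {
  proteome <- c(
    P1 = "KAKAKAKAKAKAKAKA",     # 8 lysines at odd positions
    P2 = "AAAA",                 # no lysines
    P3 = "KKKK"
  )
  rec <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P3"),
    site_pos = c(1L, 5L, 1L, 2L),
    residue = "K", condition = "bait", replicate = 1L, abundance = 1
  )
  expect_warning(deg <- degree_of_biotinylation(rec, proteome), "could not")
  p1 <- deg[deg$protein_id == "P1", ]
  expect_equal(p1$degree, 2 / 8)
  errs <- attr(deg, "errors")
  expect_true("P2" %in% errs$protein_id) # zero lysines -> error record
  # P1 and P3 tie at 0.25; ties break lexicographically by protein_id
  expect_equal(deg$protein_id, c("P1", "P3"))
  expect_true(all(deg$degree >= 0 & deg$degree <= 1))
})

test_that("degree integrity checks reject bad site positions", {
  rec <- tibble::tibble(protein_id = "P1", site_pos = 99L, residue = "K",
                        condition = "bait", replicate = 1L, abundance = 1)
  expect_warning(deg <- degree_of_biotinylation(rec, c(P1 = "KAKA")))
  expect_match(attr(deg, "errors")$reason, "exceeds")
  rec2 <- tibble::tibble(protein_id = "P1", site_pos = 2L, residue = "K",
                         condition = "bait", replicate = 1L, abundance = 1)
  expect_warning(deg2 <- degree_of_biotinylation(rec2, c(P1 = "KAKA")))
  expect_match(attr(deg2, "errors")$reason, "not a lysine")
  rec3 <- tibble::tibble(protein_id = "PX", site_pos = 1L, residue = "K",
                         condition = "bait", replicate = 1L, abundance = 1)
  expect_warning(deg3 <- degree_of_biotinylation(rec3, c(P1 = "KAKA")))
  expect_match(attr(deg3, "errors")$reason, "absent")
})

test_that("random degrees match per-sequence character counting", {
  set.seed(8)
  cfg <- sim_config(seed = 77, biosite = list(n_proteins = 30L, n_enriched = 3L))
  bio <- simulate_biosite_table(cfg)
  deg <- degree_of_biotinylation(bio$sites, bio$proteome)
  seqs <- setNames(as.character(bio$proteome), names(bio$proteome))
  for (i in sample(nrow(deg), 10)) {
    p <- deg$protein_id[i]
    expect_equal(deg$total_lysines[i],
                 unname(lengths(regmatches(seqs[p], gregexpr("K", seqs[p])))))
    expect_equal(
      deg$biotinylated_lysines[i],
      length(unique(bio$sites$site_pos[bio$sites$protein_id == p])))
  }
})

test_that("sites are located within topology domains", {
  ann <- tibble::tibble(
    protein_id = "P1",
    start = c(1L, 201L, 224L),
    end = c(200L, 223L, 300L),
    label = c("nucleoplasmic", "transmembrane", "lumenal")
  )
  rec <- function(pos) {
    tibble::tibble(protein_id = "P1", site_pos = pos, residue = "K",
                   condition = "bait", replicate = 1L, abundance = 1)
  }
  expect_equal(map_site_topology(rec(150L), ann)$topology, "nucleoplasmic")
  expect_equal(map_site_topology(rec(210L), ann)$topology, "transmembrane")
  expect_error(map_site_topology(rec(350L), ann), "beyond the annotated span")

  other <- rec(10L)
  other$protein_id <- "P9"
  expect_equal(map_site_topology(other, ann)$topology, "unannotated")

  gap_ann <- ann
  gap_ann$end[1] <- 100L
  expect_equal(map_site_topology(rec(150L), gap_ann)$topology, "unassigned")

  overlap <- ann
  overlap$start[2] <- 150L
  expect_error(map_site_topology(rec(150L), overlap), "overlapping")
})
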