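test_that("exact junction-spanning reads give a single zero-mismatch hit", {
  cfg <- sim_config(seed = 31L, n_genes = 5L)
  sim <- simulate_genome_and_models(cfg)
  L <- 40L
  db <- build_junction_db(sim$models, sim$genome, L)
  rec <- db[db$category == "scrambled", ][1, ]
  b <- rec$boundary_offset
  read <- substr(rec$sequence, b - L / 2 + 1L, b + L / 2)  # centered on boundary
  hits <- align_reads(c(r1 = read), setNames(db$sequence, db$junction_id),
                      align_settings(v = 1L))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$target_id, rec$junction_id)
  expect_equal(hits$mismatches, 0L)
  expect_lte(hits$offset, b - 15L)
  expect_gte(hits$offset + L, b + 15L)
})

test_that("-m 1 suppression drops reads matching two targets", {
  t1 <- random_dna(80)
  targets <- c(j1 = t1, j2 = paste0(substr(t1, 1, 60), random_dna(20)))
  read <- substr(t1, 5, 44)  # present in both targets
  none <- align_reads(c(r = read), targets,
                      align_settings(v = 0L, unique_only = TRUE))
  expect_equal(nrow(none), 0L)
  both <- align_reads(c(r = read), targets,
                      align_settings(v = 0L, unique_only = FALSE))
  expect_equal(sort(both$target_id), c("j1", "j2"))
})

test_that("reads with non-ACGTN characters are rejected by name", {
  expect_error(align_reads(c(bad = "ACGTRYACGTACGTACGTAC"),
                           c(t = random_dna(50)), align_settings(v = 0L)),
               "bad")
})

test_that("aligner equals the brute-force Hamming oracle on a settings grid", {
  set.seed(99)
  grid <- expand.grid(v = c(0L, 1L, 3L), unique_only = c(TRUE, FALSE),
                      both_strands = c(TRUE, FALSE))
  for (g in seq_len(nrow(grid))) {
    v <- grid$v[g]
    targets <- setNames(vapply(1:6, function(i) random_dna(sample(60:120, 1)),
                               character(1)), paste0("t", 1:6))
    reads <- character(0)
    for (r in 1:12) {
      tgt <- sample(targets, 1)
      o <- sample.int(nchar(tgt) - 35L, 1)
      planted <- mutate_dna(substr(tgt, o, o + 34L), sample(0:4, 1))
      if (runif(1) < 0.3) planted <- oracle_revcomp(planted)
      reads <- c(reads, planted)
    }
    reads <- c(reads, vapply(1:4, function(i) random_dna(35), character(1)))
    names(reads) <- paste0("r", seq_along(reads))
    got <- align_reads(reads, targets,
                       align_settings(v = v, unique_only = grid$unique_only[g],
                                      both_strands = grid$both_strands[g]))
    want <- oracle_align(as.list(reads), targets, v, grid$unique_only[g],
                         grid$both_strands[g])
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("settings row %d", g))
  }
})

test_that("trimming is applied before alignment and length checks", {
  tgt <- c(t = random_dna(100))
  core <- unname(substr(tgt, 11, 50))
  read <- paste0("AAA", core, "GG")  # 3 junk bases 5', 2 junk 3'
  st <- align_settings(v = 0L, trim5 = 3L, trim3 = 2L)
  hits <- align_reads(c(r = read), tgt, st)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 10L)
  expect_equal(trim_reads(c(r = read), st), c(r = core))
})

test_that("prefilter retains only reads failing genome and transcriptome", {
  cfg <- sim_config(seed = 41L, n_genes = 10L, circle_gene_fraction = 0.2,
                    circle_copies_fixed = 80, depth = 3)
  sim <- simulate_genome_and_models(cfg)
  pool <- simulate_pool(sim$truth)
  rd <- simulate_reads(pool, sim$genome, sim$models, cfg)
  tx <- spliced_transcripts(sim$genome, sim$models)
  keep <- prefilter_unaligned(rd$reads, sim$genome, tx, align_settings(v = 0L))
  prov <- rd$provenance
  linear_ids <- prov$read_id[prov$molecule == "linear"]
  expect_length(intersect(keep, linear_ids), 0L)
  # reads well across the back-splice junction fail both references
  circ_junc <- prov$read_id[prov$crosses_with_overhang]
  expect_true(all(circ_junc %in% keep))
})

test_that("junction read counting honors the boundary overhang rule", {
  cfg <- sim_config(seed = 31L, n_genes = 5L)
  sim <- simulate_genome_and_models(cfg)
  L <- 40L
  db <- build_junction_db(sim$models, sim$genome, L)
  rec <- db[db$category == "scrambled", ][2, ]
  b <- rec$boundary_offset
  reads <- c(r1 = substr(rec$sequence, b - 19L, b + 20L),
             r2 = substr(rec$sequence, b - 19L, b + 20L))
  hits <- align_reads(reads, setNames(db$sequence, db$junction_id),
                      align_settings(v = 1L))
  counts <- count_junction_reads(hits, db)
  expect_equal(counts$read_count[counts$junction_id == rec$junction_id], 2L)
  # full-length reads on a matched-L database always satisfy overhang <= 15
  expect_true(all(hits$offset <= b - 15L & hits$offset + L >= b + 15L))
  expect_error(count_junction_reads(hits, db, read_length = 50L),
               "does not match")
  bad <- hits
  bad$target_id[1] <- "nonexistent|1-1"
  expect_error(count_junction_reads(bad, db), "unknown junction_id")
})

test_that("each read is assigned to at most one junction", {
  cfg <- sim_config(seed = 51L, n_genes = 20L, circle_gene_fraction = 0.1,
                    circle_copies_fixed = 60, depth = 3)
  sim <- simulate_genome_and_models(cfg)
  pool <- simulate_pool(sim$truth)
  rd <- simulate_reads(pool, sim$genome, sim$models, cfg)
  db <- build_junction_db(sim$models, sim$genome, cfg$read_length)
  hits <- align_reads(rd$reads, setNames(db$sequence, db$junction_id),
                      align_settings(v = 1L, unique_only = FALSE))
  counts <- count_junction_reads(hits, db)
  asn <- attr(counts, "assignments")
  expect_equal(anyDuplicated(asn$read_id), 0L)
  expect_equal(sum(counts$read_count), nrow(asn))
})
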