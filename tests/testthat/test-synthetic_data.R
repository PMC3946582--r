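test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 17L, n_genes = 20L, circle_gene_fraction = 0.1)
  a <- simulate_genome_and_models(cfg)
  b <- simulate_genome_and_models(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)
  ra <- simulate_reads(simulate_pool(a$truth), a$genome, a$models, cfg)
  rb <- simulate_reads(simulate_pool(b$truth), b$genome, b$models, cfg)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$provenance, rb$provenance)
})

test_that("organism presets set the intron length scale", {
  cfg <- sim_config(seed = 19L, n_genes = 500L, organism = "pombe")
  sim <- simulate_genome_and_models(cfg)
  # intron lengths = gaps between genomically adjacent exons
  introns <- unlist(lapply(split(sim$models, sim$models$transcript_id),
                           function(m) {
                             m <- m[order(m$start), ]
                             if (nrow(m) < 2L) return(NULL)
                             m$start[-1L] - m$end[-nrow(m)]
                           }))
  expect_gt(length(introns), 1000L)
  expect_lt(abs(mean(introns) - 82) / 82, 0.10)
  expect_equal(sim_config(organism = "arabidopsis")$intron_length_mean, 158)
  expect_equal(sim_config(organism = "cerevisiae")$intron_length_mean, 148)
})

test_that("the configured fraction of genes carries planted circles", {
  cfg <- sim_config(seed = 23L, n_genes = 100L, circle_gene_fraction = 0.02)
  sim <- simulate_genome_and_models(cfg)
  tr <- sim$truth$circles
  expect_equal(nrow(tr), 2L)  # round(100 * 0.02)
  nex <- n_exons(sim$models)
  # contiguous internal runs j..i
  expect_true(all(tr$acceptor_index >= 2L))
  expect_true(all(tr$donor_index <= nex[tr$transcript_id] - 1L))
  expect_true(all(tr$donor_index >= tr$acceptor_index))
  exlen <- split(sim$models$end - sim$models$start, sim$models$transcript_id)
  for (k in seq_len(nrow(tr)))
    expect_equal(tr$circle_size[k],
                 sum(exlen[[tr$transcript_id[k]]][
                   tr$acceptor_index[k]:tr$donor_index[k]]))
})

test_that("condition scaling multiplies linear but not circle copies", {
  cfg <- sim_config(seed = 29L, n_genes = 25L, circle_gene_fraction = 0.08)
  sim <- simulate_genome_and_models(cfg)
  s <- 7315 / 40909  # starvation analogue of the mRNA-per-cell decrease
  p1 <- simulate_pool(sim$truth)
  p2 <- simulate_pool(sim$truth, condition = "starved", linear_scaling = s)
  expect_equal(sum(p2$linear$copies), s * sum(p1$linear$copies))
  expect_equal(p2$circles$copies, p1$circles$copies)
  # bookkeeping: pool ratio equals the planted ratio exactly
  expect_equal(sum(p1$circles$copies) / sum(p1$linear$copies),
               sum(sim$truth$circles$copies) / sum(sim$truth$linear_copies))
})

test_that("RNase R thinning follows binomial moments and edge cases", {
  cfg <- sim_config(seed = 31L, n_genes = 10L, circle_gene_fraction = 0.1,
                    rnaser_linear_survival = 2^-6)
  sim <- simulate_genome_and_models(cfg)
  pool <- simulate_pool(sim$truth)
  pool$linear$copies <- rep(64000, nrow(pool$linear))
  after <- apply_rnaser(pool, cfg)
  expect_equal(after$circles$copies, pool$circles$copies)  # survival 1
  depletion <- pool$linear$copies / after$linear$copies
  expect_true(all(depletion > 32))  # about 64-fold, never under 32
  expect_lt(abs(mean(after$linear$copies) - 1000) / 1000, 0.05)
  cfg0 <- sim_config(seed = 31L, rnaser_linear_survival = 0)
  gone <- apply_rnaser(pool, cfg0)
  expect_true(all(gone$linear$copies == 0))
})

test_that("error-free reads are exact substrings of their templates", {
  cfg <- sim_config(seed = 37L, n_genes = 15L, circle_gene_fraction = 0.1,
                    circle_copies_fixed = 40L, error_rate = 0)
  sim <- simulate_genome_and_models(cfg)
  pool <- simulate_pool(sim$truth)
  rd <- simulate_reads(pool, sim$genome, sim$models, cfg)
  expect_equal(nrow(rd$provenance), length(rd$reads))  # provenance conserved
  tx <- spliced_transcripts(sim$genome, sim$models)
  lin <- rd$provenance$molecule == "linear"
  some <- which(lin)[seq_len(min(50L, sum(lin)))]
  for (k in some)
    expect_true(grepl(rd$reads[[rd$provenance$read_id[k]]],
                      tx[[rd$provenance$transcript_id[k]]], fixed = TRUE))
})

test_that("junction-crossing read fraction matches the concatemer geometry", {
  cfg <- sim_config(seed = 41L, n_genes = 40L, circle_gene_fraction = 0.1,
                    circle_copies_fixed = 400L, depth = 4,
                    rolling_circle_laps = 3L)
  sim <- simulate_genome_and_models(cfg)
  pool <- simulate_pool(sim$truth)
  rd <- simulate_reads(pool, sim$genome, sim$models, cfg)
  prov <- rd$provenance[rd$provenance$molecule == "circle", ]
  L <- cfg$read_length
  for (k in seq_len(nrow(sim$truth$circles))) {
    cc <- sim$truth$circles[k, ]
    sub <- prov[prov$transcript_id == cc$transcript_id, ]
    if (nrow(sub) < 150L) next
    clen <- cc$circle_size
    tlen <- clen * cfg$rolling_circle_laps
    # starts are uniform on [0, tlen - L]; each of laps-1 interior
    # boundaries is crossed by L - 1 of those starts
    expected <- (cfg$rolling_circle_laps - 1L) *
      min(L - 1L, clen - 1L) / (tlen - L + 1L)
    observed <- mean(sub$crosses_backsplice)
    expect_lt(abs(observed - expected),
              3 * sqrt(expected * (1 - expected) / nrow(sub)) + 0.01)
  }
})

test_that("scrambled-junction reads vanish without planted circles", {
  cfg <- sim_config(seed = 43L, n_genes = 30L, circle_gene_fraction = 0,
                    error_rate = 0, depth = 2)
  sim <- simulate_genome_and_models(cfg)
  expect_equal(nrow(sim$truth$circles), 0L)
  pool <- simulate_pool(sim$truth)
  rd <- simulate_reads(pool, sim$genome, sim$models, cfg)
  db <- build_junction_db(sim$models, sim$genome, cfg$read_length)
  hits <- align_reads(rd$reads, setNames(db$sequence, db$junction_id),
                      align_settings(v = 1L))
  counts <- count_junction_reads(hits, db)
  cand <- call_circles(counts, db, sim$models)
  expect_equal(nrow(cand), 0L)
})

test_that("FASTQ output round-trips read sequences", {
  cfg <- sim_config(seed = 47L, n_genes = 5L)
  sim <- simulate_genome_and_models(cfg)
  rd <- simulate_reads(simulate_pool(sim$truth), sim$genome, sim$models, cfg)
  path <- tempfile(fileext = ".fastq")
  write_fastq(rd$reads, path)
  back <- read_fastq(path)
  expect_identical(back, rd$reads)
})
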