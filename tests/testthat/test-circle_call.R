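test_that("junction classification partitions the (i, j) grid", {
  expect_equal(classify_junction(2L, 3L), "canonical")
  expect_equal(classify_junction(3L, 6L), "skipping")
  expect_equal(classify_junction(7L, 6L), "scrambled")
  expect_equal(classify_junction(2L, 2L), "scrambled")
  grid <- expand.grid(i = 1:13, j = 1:13)
  cats <- classify_junction(grid$i, grid$j)
  expect_true(all(cats %in% c("canonical", "skipping", "scrambled")))
  expect_equal(sum(cats == "canonical"), 12L)           # j = i + 1
  expect_equal(sum(cats == "scrambled"), 13L * 14L / 2L) # j <= i
})

make_counts <- function(junction_id, read_count) {
  out <- data.frame(junction_id = junction_id, read_count = read_count,
                    stringsAsFactors = FALSE)
  attr(out, "assignments") <-
    data.frame(read_id = sprintf("r%03d", seq_len(sum(read_count))),
               junction_id = rep(junction_id, read_count),
               mismatches = 0L, stringsAsFactors = FALSE)
  out
}

toy_models <- function(exon_lengths, tid = "tx1", gid = "g1") {
  n <- length(exon_lengths)
  starts <- cumsum(c(0L, head(exon_lengths, -1L) + 50L))
  data.frame(transcript_id = tid, gene_id = gid, exon_index = seq_len(n),
             chrom = "c1", start = starts, end = starts + exon_lengths,
             strand = "+", stringsAsFactors = FALSE)
}

toy_db <- function(models) {
  nex <- max(models$exon_index)
  grid <- expand.grid(donor_index = seq_len(nex), acceptor_index = seq_len(nex))
  data.frame(
    junction_id = sprintf("%s|%d-%d", models$transcript_id[1],
                          grid$donor_index, grid$acceptor_index),
    transcript_id = models$transcript_id[1], gene_id = models$gene_id[1],
    donor_index = grid$donor_index, acceptor_index = grid$acceptor_index,
    category = classify_junction(grid$donor_index, grid$acceptor_index),
    boundary_offset = 35L, read_length = 50L, sequence = "N",
    stringsAsFactors = FALSE)
}

test_that("predicted circle size sums exon lengths j..i", {
  models <- toy_models(c(90L, 120L, 130L, 150L, 80L))
  db <- toy_db(models)
  counts <- make_counts(c("tx1|2-2", "tx1|3-2"), c(3L, 1L))
  cand <- call_circles(counts, db, models)
  expect_equal(cand$predicted_circle_size[cand$donor_index == 2], 120L)
  expect_equal(cand$predicted_circle_size[cand$donor_index == 3], 250L)
  expect_equal(cand$read_count, c(3L, 1L))  # sorted by descending count
  expect_equal(lengths(cand$supporting_read_ids), cand$read_count)
  expect_false(any(cand$single_exon_transcript))
  # single-read candidates are retained by default
  expect_true(1L %in% cand$read_count)
})

test_that("circle size is strand-invariant", {
  m_plus <- toy_models(c(100L, 150L, 120L))
  m_minus <- m_plus
  m_minus$strand <- "-"
  db <- toy_db(m_plus)
  counts <- make_counts("tx1|2-2", 2L)
  expect_equal(call_circles(counts, db, m_plus)$predicted_circle_size,
               call_circles(counts, toy_db(m_minus), m_minus)$predicted_circle_size)
})

test_that("skipping reciprocity requires the exact complementary skip", {
  models <- toy_models(rep(100L, 8L))
  db <- toy_db(models)
  # circle of exons 4..5 + a linear junction 3->6 skipping exactly 4 and 5
  counts <- make_counts(c("tx1|5-4", "tx1|3-6"), c(2L, 1L))
  cand <- call_circles(counts, db, models)
  skips <- call_skipping(counts, db)
  expect_equal(nrow(skips), 1L)
  expect_equal(c(skips$upstream_exon, skips$downstream_exon), c(3L, 6L))
  rep1 <- skipping_reciprocity(cand, skips)
  expect_true(rep1$reciprocal)
  # circle of exons 6..8 with only a skip of exon 2: not reciprocal
  counts2 <- make_counts(c("tx1|8-6", "tx1|1-3"), c(1L, 1L))
  rep2 <- skipping_reciprocity(call_circles(counts2, db, models),
                               call_skipping(counts2, db))
  expect_false(rep2$reciprocal)
  # no skip events at all
  rep3 <- skipping_reciprocity(cand, call_skipping(make_counts("tx1|5-4", 1L), db))
  expect_false(rep3$reciprocal)
})

test_that("planted circles are recovered and unplanted genes stay silent", {
  cfg <- sim_config(seed = 61L, n_genes = 60L, circle_gene_fraction = 0.05,
                    circle_copies_fixed = 100L, depth = 3, error_rate = 0)
  sim <- simulate_genome_and_models(cfg)
  pool <- simulate_pool(sim$truth)
  rd <- simulate_reads(pool, sim$genome, sim$models, cfg)
  db <- build_junction_db(sim$models, sim$genome, cfg$read_length)
  hits <- align_reads(rd$reads, setNames(db$sequence, db$junction_id),
                      align_settings(v = 1L, unique_only = TRUE))
  counts <- count_junction_reads(hits, db)
  cand <- call_circles(counts, db, sim$models)
  truth <- sim$truth$circles
  planted <- sprintf("%s|%d-%d", truth$transcript_id, truth$donor_index,
                     truth$acceptor_index)
  called <- sprintf("%s|%d-%d", cand$transcript_id, cand$donor_index,
                    cand$acceptor_index)
  covered <- truth$transcript_id %in%
    rd$provenance$transcript_id[rd$provenance$crosses_with_overhang]
  expect_true(all(covered))
  expect_true(all(planted %in% called))      # 100% recall
  expect_true(all(called %in% planted))      # no false scrambled candidates
  expect_equal(cand$predicted_circle_size[match(planted, called)],
               truth$circle_size)
})

test_that("a 1-exon transcript's self-junction is reported and flagged", {
  models <- toy_models(200L)
  db <- toy_db(models)
  cand <- call_circles(make_counts("tx1|1-1", 2L), db, models)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$single_exon_transcript)
  expect_equal(cand$predicted_circle_size, 200L)
})
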