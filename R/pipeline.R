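#' Built-in dataset profiles
#'
#' Per-organism alignment regimes: read length, 5'/3' trimming, mismatch
#' allowance `v`, unique-mapping suppression (`-m 1`, used for organisms
#' lacking extensive annotated alternative splicing), whether reads are
#' prefiltered against genome (and transcriptome) before the junction
#' database, and the first-N-exons cap on database construction.
#'
#' @return Named list of profiles; each a list with `name`,
#'   `read_length`, `trim5`, `trim3`, `v`, `unique_only`, `prefilter`,
#'   `prefilter_transcriptome`, `prefilter_v`, `max_exons` (NULL = no
#'   cap). `effective_length` = read_length - trim5 - trim3 is the L
#'   used for the junction database.
#' @export
make_profiles <- function() {
  prof <- function(name, read_length, trim5 = 0L, trim3 = 0L, v,
                   unique_only, prefilter = FALSE,
                   prefilter_transcriptome = FALSE, prefilter_v = v,
                   max_exons = NULL) {
    eff <- read_length - trim5 - trim3
    stopifnot(eff > 30L)
    list(name = name, read_length = as.integer(read_length),
         trim5 = as.integer(trim5), trim3 = as.integer(trim3),
         v = as.integer(v), unique_only = unique_only,
         prefilter = prefilter,
         prefilter_transcriptome = prefilter_transcriptome,
         prefilter_v = as.integer(prefilter_v),
         max_exons = max_exons, effective_length = as.integer(eff))
  }
  list(
    falciparum = prof("falciparum", 60L, v = 3L, unique_only = TRUE),
    pombe = prof("pombe", 50L, v = 1L, unique_only = TRUE),
    pombe_awan = prof("pombe_awan", 43L, trim5 = 3L, v = 1L,
                      unique_only = TRUE, prefilter = TRUE,
                      prefilter_transcriptome = FALSE, prefilter_v = 3L),
    arabidopsis = prof("arabidopsis", 100L, v = 3L, unique_only = FALSE,
                       prefilter = TRUE, prefilter_transcriptome = TRUE,
                       max_exons = 10L),
    dictyostelium = prof("dictyostelium", 150L, trim5 = 5L, trim3 = 5L,
                         v = 3L, unique_only = FALSE, prefilter = TRUE,
                         prefilter_transcriptome = TRUE),
    synthetic = prof("synthetic", 50L, v = 1L, unique_only = TRUE)
  )
}

#' Run the circle-discovery pipeline
#'
#' Orchestrates: (simulate or load inputs) -> build junction database ->
#' (prefilter) -> align -> count junction reads -> call circles and
#' skipping events -> expression rates (+ circles-per-cell when a
#' copy-number table is supplied). All stage tables are written as TSV
#' under `out_dir` along with a YAML manifest (config, config hash,
#' seed, per-stage read counts).
#'
#' @param config A list, or path to a YAML file, with entries:
#'   `out_dir`; `profile` (a [make_profiles()] name, or a custom profile
#'   list); `seed`; either `simulate` (a list of [sim_config()]
#'   arguments) or `inputs` (`genome_fasta`, `annotation`,
#'   `reads_fastq`); optionally `copy_table` (TSV path, see
#'   [read_copy_table()]) and `min_reads`.
#' @return Invisibly, a list with the principal stage results
#'   (`candidates`, `skips`, `counts`, `rates`, `estimates`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[backsplicer] ", ...)

  profile <- config$profile %||% "synthetic"
  if (is.character(profile)) {
    profiles <- make_profiles()
    if (!profile %in% names(profiles))
      stop("unknown profile '", profile, "'")
    profile <- profiles[[profile]]
  }
  seed <- as.integer(config$seed %||% 1L)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    sim_args$read_length <- profile$read_length
    cfg <- do.call(sim_config, sim_args)
    log_line("simulating genome and models (", cfg$n_genes, " genes, ",
             cfg$organism, " preset)")
    sim <- simulate_genome_and_models(cfg)
    genome <- sim$genome; models <- sim$models
    pool <- simulate_pool(sim$truth)
    rd <- simulate_reads(pool, genome, models, cfg)
    reads <- rd$reads
    utils::write.table(sim$truth$circles,
                       file.path(config$out_dir, "truth_circles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    inp <- config$inputs
    stopifnot(!is.null(inp$genome_fasta), !is.null(inp$annotation),
              !is.null(inp$reads_fastq))
    log_line("loading genome, annotation, reads")
    genome <- read_genome(inp$genome_fasta)
    models <- parse_annotation(inp$annotation,
                               feature_type = inp$feature_type %||% "exon",
                               id_attribute = inp$id_attribute)
    reads <- read_fastq(inp$reads_fastq)
  }
  n_input <- length(reads)
  log_line(n_input, " input reads")

  L <- profile$effective_length
  db <- build_junction_db(models, genome, L, max_exons = profile$max_exons)
  write_junction_fasta(db, file.path(config$out_dir, "junctions.fasta"))
  write_junction_manifest(db, file.path(config$out_dir, "junctions.tsv"))
  log_line(nrow(db), " junction records (L = ", L, ")")

  settings <- align_settings(v = profile$v, unique_only = profile$unique_only,
                             trim5 = profile$trim5, trim3 = profile$trim3)
  n_filtered <- n_input
  if (isTRUE(profile$prefilter)) {
    tx <- spliced_transcripts(genome, models)
    pre_settings <- align_settings(v = profile$prefilter_v,
                                   trim5 = profile$trim5,
                                   trim3 = profile$trim3)
    keep <- prefilter_unaligned(
      reads, genome,
      transcriptome = if (isTRUE(profile$prefilter_transcriptome)) tx,
      settings = pre_settings)
    reads <- reads[keep]
    n_filtered <- length(reads)
    log_line(n_filtered, " reads survive the genome/transcriptome prefilter")
  }

  targets <- stats::setNames(db$sequence, db$junction_id)
  hits <- if (length(reads)) align_reads(reads, targets, settings)
  else data.frame(read_id = character(), target_id = character(),
                  offset = integer(), strand = character(),
                  mismatches = integer())
  write_hits(hits, file.path(config$out_dir, "hits.tsv"))
  counts <- count_junction_reads(hits, db, read_length = L)
  log_line(nrow(hits), " hits; ", sum(counts$read_count),
           " junction-assigned reads")

  candidates <- call_circles(counts, db, models,
                             min_reads = config$min_reads %||% 1L)
  skips <- call_skipping(counts, db)
  candidates <- skipping_reciprocity(candidates, skips)
  write_candidates(candidates, file.path(config$out_dir, "circle_candidates.tsv"))
  utils::write.table(skips, file.path(config$out_dir, "skipping_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(nrow(candidates), " circle candidates, ", nrow(skips),
           " skipping events")

  rates <- expression_rates(counts, db, models)
  estimates <- NULL
  if (!is.null(config$copy_table)) {
    ct <- read_copy_table(config$copy_table)
    estimates <- do.call(rbind, lapply(seq_len(nrow(ct)), function(k) {
      r <- rates; r$condition <- ct$condition[k]
      estimate_circles_per_cell(list(r), ct[k, ])
    }))
    utils::write.table(estimates,
                       file.path(config$out_dir, "circles_per_cell.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("backsplicer")),
    seed = seed, profile = profile$name,
    config_md5 = unname(tools::md5sum(cfg_path)),
    reads_input = n_input, reads_after_prefilter = n_filtered,
    hits = nrow(hits), junction_assigned = sum(counts$read_count),
    candidates = nrow(candidates)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(candidates = candidates, skips = skips, counts = counts,
                 rates = rates, estimates = estimates, manifest = manifest,
                 db = db, out_dir = config$out_dir))
}
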