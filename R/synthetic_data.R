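#' Simulation configuration
#'
#' Captures the statistical structure of the emulated libraries: gene
#' architectures typical of intron-poor eukaryotes (2-13 exons, introns
#' of order 100 nt), a small fraction of multi-exon genes expressing
#' circles, skewed linear copy numbers, RNase R survival of linears vs
#' circles, and rolling-circle concatemeric cDNA from circular templates.
#'
#' Organism presets set the mean intron length: `cerevisiae` 148,
#' `pombe` 82, `dictyostelium` 142, `falciparum` 134, `arabidopsis`
#' 158 nt; intron lengths are gamma-distributed with a standard
#' deviation of half the mean (floored at 20 nt), exon lengths gamma
#' with mean 180 / sd 100 (floored at 30 nt).
#'
#' @param seed Integer seed; fully determines every generated object.
#' @param organism One of the presets above (sets the intron mean).
#' @param n_genes Number of genes (one transcript per gene).
#' @param exon_count_weights Weights over 1..13 exons; the default puts
#'   most mass on 2-9 exon genes.
#' @param exon_length_mean,exon_length_sd Exon length distribution (nt).
#' @param intron_length_mean Overrides the organism preset when given.
#' @param circle_gene_fraction Fraction of genes carrying a planted
#'   circle (default 0.02; the source organisms show roughly 1-3% of
#'   multi-intron genes with circle evidence).
#' @param linear_copy_meanlog,linear_copy_sdlog Lognormal per-gene linear
#'   copy numbers (default mean about 8 copies/cell-analogue).
#' @param circle_copy_ratio_range Planted circle copies as a fraction of
#'   the host gene's linear copies (circles are usually minor isoforms).
#' @param circle_copies_fixed When set, every planted circle gets this
#'   copy number instead of the ratio draw.
#' @param read_length Nominal read length L (single-end).
#' @param depth Expected reads per kilobase of template per molecule copy.
#' @param error_rate Per-base substitution rate (no indels; the aligner
#'   is ungapped).
#' @param rnaser_linear_survival Survival probability of a linear
#'   molecule under RNase R (default 2^-6, i.e. 64-fold depletion).
#' @param rnaser_circle_survival Survival of circles (default 1).
#' @param rolling_circle_laps Laps of rolling-circle reverse
#'   transcription per circular template (default 3).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       organism = c("pombe", "cerevisiae", "dictyostelium",
                                    "falciparum", "arabidopsis"),
                       n_genes = 100L,
                       exon_count_weights = c(0.08, 0.14, 0.16, 0.14, 0.12,
                                              0.10, 0.08, 0.06, 0.05, 0.03,
                                              0.02, 0.01, 0.01),
                       exon_length_mean = 180, exon_length_sd = 100,
                       intron_length_mean = NULL,
                       circle_gene_fraction = 0.02,
                       linear_copy_meanlog = log(5), linear_copy_sdlog = 1,
                       circle_copy_ratio_range = c(0.01, 0.1),
                       circle_copies_fixed = NULL,
                       read_length = 50L,
                       depth = 2,
                       error_rate = 0,
                       rnaser_linear_survival = 2^-6,
                       rnaser_circle_survival = 1,
                       rolling_circle_laps = 3L) {
  organism <- match.arg(organism)
  intron_means <- c(cerevisiae = 148, pombe = 82, dictyostelium = 142,
                    falciparum = 134, arabidopsis = 158)
  if (is.null(intron_length_mean)) intron_length_mean <- intron_means[[organism]]
  stopifnot(length(exon_count_weights) == 13L, all(exon_count_weights >= 0),
            sum(exon_count_weights) > 0,
            intron_length_mean > 0, exon_length_mean > 0,
            circle_gene_fraction >= 0, circle_gene_fraction <= 1,
            read_length > 30L, depth > 0, error_rate >= 0, error_rate < 1,
            rnaser_linear_survival >= 0, rnaser_linear_survival <= 1,
            rnaser_circle_survival >= 0, rnaser_circle_survival <= 1,
            rolling_circle_laps >= 1L)
  structure(list(
    seed = as.integer(seed), organism = organism, n_genes = as.integer(n_genes),
    exon_count_weights = exon_count_weights / sum(exon_count_weights),
    exon_length_mean = exon_length_mean, exon_length_sd = exon_length_sd,
    intron_length_mean = intron_length_mean,
    circle_gene_fraction = circle_gene_fraction,
    linear_copy_meanlog = linear_copy_meanlog,
    linear_copy_sdlog = linear_copy_sdlog,
    circle_copy_ratio_range = circle_copy_ratio_range,
    circle_copies_fixed = circle_copies_fixed,
    read_length = as.integer(read_length), depth = depth,
    error_rate = error_rate,
    rnaser_linear_survival = rnaser_linear_survival,
    rnaser_circle_survival = rnaser_circle_survival,
    rolling_circle_laps = as.integer(rolling_circle_laps)
  ), class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rgamma_floor <- function(n, mean, sd, floor) {
  shape <- (mean / sd)^2
  pmax(floor, round(stats::rgamma(n, shape = shape, rate = shape / mean)))
}

#' Simulate a genome, gene models, and ground truth
#'
#' One chromosome per gene (exons separated by short introns, flanked by
#' 100 nt spacers), a random strand, lognormal linear copy numbers, and
#' `round(n_genes * circle_gene_fraction)` planted circles. Planted
#' circles occupy a contiguous exon run j..i chosen among internal exons
#' of genes with at least 3 exons (so j >= 2 and i <= n - 1; a 3-exon
#' gene hosts a single-exon "2-2" circle).
#'
#' @param config [sim_config()].
#' @return `list(genome, models, truth)`: genome is a
#'   [Biostrings::DNAStringSet], models an exon table, truth a list with
#'   `linear_copies` (per transcript) and `circles`
#'   (`data.frame(transcript_id, gene_id, acceptor_index, donor_index,
#'   circle_size, copies)`).
#' @export
simulate_genome_and_models <- function(config) {
  set.seed(config$seed)
  spacer <- 100L
  chroms <- character(config$n_genes)
  rows <- vector("list", config$n_genes)
  nex_all <- sample(1:13, config$n_genes, replace = TRUE,
                    prob = config$exon_count_weights)
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene_%04d", g)
    tid <- sprintf("tx_%04d", g)
    n <- nex_all[g]
    elen <- .rgamma_floor(n, config$exon_length_mean, config$exon_length_sd, 30)
    ilen <- if (n > 1L)
      .rgamma_floor(n - 1L, config$intron_length_mean,
                    max(10, config$intron_length_mean / 2), 20)
    else integer(0)
    total <- spacer * 2L + sum(elen) + sum(ilen)
    chroms[g] <- .rand_dna(total)
    starts <- spacer + cumsum(c(0L, utils::head(elen, -1L) + ilen))
    # genomic order; transcript index depends on strand
    idx <- if (strands[g] == "+") seq_len(n) else rev(seq_len(n))
    rows[[g]] <- data.frame(
      transcript_id = tid, gene_id = gid, exon_index = idx,
      chrom = gid, start = starts, end = starts + elen,
      strand = strands[g], stringsAsFactors = FALSE
    )
  }
  genome <- Biostrings::DNAStringSet(chroms)
  names(genome) <- sprintf("gene_%04d", seq_len(config$n_genes))
  models <- do.call(rbind, rows)
  models <- models[order(models$transcript_id, models$exon_index), ]
  rownames(models) <- NULL

  copies <- round(stats::rlnorm(config$n_genes, config$linear_copy_meanlog,
                                config$linear_copy_sdlog)) + 1
  names(copies) <- sprintf("tx_%04d", seq_len(config$n_genes))

  n_circ <- round(config$n_genes * config$circle_gene_fraction)
  eligible <- which(nex_all >= 3L)
  if (n_circ > length(eligible))
    stop("not enough genes with >= 3 exons to plant ", n_circ, " circles")
  hosts <- sort(eligible[sample.int(length(eligible), n_circ)])
  circles <- lapply(hosts, function(g) {
    n <- nex_all[g]
    js <- 2:(n - 1L)
    j <- js[sample.int(length(js), 1L)]
    i <- min(n - 1L, j + sample.int(3L, 1L) - 1L)
    tid <- sprintf("tx_%04d", g)
    exlen <- with(rows[[g]], (end - start)[order(exon_index)])
    cop <- if (!is.null(config$circle_copies_fixed)) config$circle_copies_fixed
    else max(1, round(copies[[tid]] *
                        stats::runif(1, config$circle_copy_ratio_range[1L],
                                     config$circle_copy_ratio_range[2L])))
    data.frame(transcript_id = tid, gene_id = sprintf("gene_%04d", g),
               acceptor_index = j, donor_index = i,
               circle_size = sum(exlen[j:i]), copies = cop,
               stringsAsFactors = FALSE)
  })
  circles <- if (length(circles)) do.call(rbind, circles)
  else data.frame(transcript_id = character(), gene_id = character(),
                  acceptor_index = integer(), donor_index = integer(),
                  circle_size = integer(), copies = numeric())
  list(genome = genome, models = models,
       truth = list(linear_copies = copies, circles = circles))
}

#' Build a molecule pool from the ground truth
#'
#' Scales total linear copies by `linear_scaling` (e.g. the
#' exponential-to-starvation analogue scales by 7315/40909 = 0.179)
#' while circle copies are scaled independently by `circle_scaling`
#' (default 1: circles do not follow the bulk mRNA decrease).
#'
#' @param truth Truth list from [simulate_genome_and_models()].
#' @param condition Condition label.
#' @param linear_scaling Multiplier on every linear copy number.
#' @param circle_scaling Multiplier on every circle copy number.
#' @return `list(condition, linear, circles)` with copy numbers.
#' @export
simulate_pool <- function(truth, condition = "exponential",
                          linear_scaling = 1, circle_scaling = 1) {
  circles <- truth$circles
  circles$copies <- circles$copies * circle_scaling
  list(condition = condition,
       linear = data.frame(transcript_id = names(truth$linear_copies),
                           copies = unname(truth$linear_copies) * linear_scaling,
                           stringsAsFactors = FALSE),
       circles = circles)
}

#' Apply RNase R to a molecule pool
#'
#' Binomial thinning: each linear molecule survives with probability
#' `rnaser_linear_survival`, each circular molecule with
#' `rnaser_circle_survival` (1 leaves circles untouched, deterministic).
#'
#' @param pool Pool from [simulate_pool()].
#' @param config [sim_config()].
#' @param seed Seed for the thinning draws (default `config$seed + 101`).
#' @return The thinned pool.
#' @export
apply_rnaser <- function(pool, config, seed = config$seed + 101L) {
  set.seed(seed)
  thin <- function(copies, p) {
    if (p == 1) return(copies)
    if (p == 0) return(rep(0, length(copies)))
    stats::rbinom(length(copies), round(copies), p)
  }
  pool$linear$copies <- thin(pool$linear$copies, config$rnaser_linear_survival)
  if (nrow(pool$circles))
    pool$circles$copies <- thin(pool$circles$copies,
                                config$rnaser_circle_survival)
  pool$condition <- paste0(pool$condition, "+rnaser")
  pool
}

.mutate_reads <- function(reads, error_rate) {
  if (error_rate == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < error_rate)
    if (!length(hit)) return(r)
    chars <- strsplit(r, "", fixed = TRUE)[[1L]]
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate single-end reads from a molecule pool
#'
#' Linear templates are the spliced transcripts; circular templates are
#' rolling-circle concatemers (`rolling_circle_laps` copies of the circle
#' sequence), so reads can cross the back-splice junction one or more
#' times. Read counts per template are Poisson with mean
#' `copies * depth * template_length / 1000`; start positions are
#' uniform; substitution errors at `error_rate` per base.
#'
#' @param pool Pool from [simulate_pool()].
#' @param genome Genome from [simulate_genome_and_models()].
#' @param models Exon table.
#' @param config [sim_config()].
#' @param seed Seed (default `config$seed + 202`).
#' @return `list(reads, provenance)`: `reads` a named character vector;
#'   `provenance` a data.frame with one row per read (`read_id`,
#'   `molecule` in `{"linear", "circle"}`, `transcript_id`,
#'   `acceptor_index`, `donor_index`, `crosses_backsplice`,
#'   `crosses_with_overhang`).
#' @export
simulate_reads <- function(pool, genome, models, config,
                           seed = config$seed + 202L) {
  set.seed(seed)
  L <- config$read_length
  tx_seq <- spliced_transcripts(genome, models)
  exlen <- split(models$end - models$start, models$transcript_id)
  exidx <- split(models$exon_index, models$transcript_id)
  exseq <- split(exon_sequences(genome, models), models$transcript_id)

  reads <- character(0)
  prov <- list()
  emit <- function(template, n_from, mol, tid, j, i, clen) {
    tlen <- nchar(template)
    if (tlen < L) return(NULL)
    nr <- stats::rpois(1L, n_from * config$depth * tlen / 1000)
    if (nr == 0L) return(NULL)
    starts <- sample.int(tlen - L + 1L, nr, replace = TRUE) - 1L
    segs <- substr(rep(template, nr), starts + 1L, starts + L)
    cross <- rep(FALSE, nr); cross15 <- rep(FALSE, nr)
    if (mol == "circle") {
      for (k in seq_len(config$rolling_circle_laps - 1L)) {
        b <- k * clen
        cross <- cross | (starts < b & starts + L > b)
        cross15 <- cross15 | (starts <= b - 15L & starts + L >= b + 15L)
      }
    }
    list(seqs = segs,
         prov = data.frame(molecule = mol, transcript_id = tid,
                           acceptor_index = j, donor_index = i,
                           crosses_backsplice = cross,
                           crosses_with_overhang = cross15,
                           stringsAsFactors = FALSE))
  }

  out <- list()
  for (k in seq_len(nrow(pool$linear))) {
    tid <- pool$linear$transcript_id[k]
    cop <- pool$linear$copies[k]
    if (cop <= 0) next
    out[[length(out) + 1L]] <-
      emit(tx_seq[[tid]], cop, "linear", tid, NA_integer_, NA_integer_, NA_integer_)
  }
  if (nrow(pool$circles)) {
    for (k in seq_len(nrow(pool$circles))) {
      cc <- pool$circles[k, ]
      if (cc$copies <= 0) next
      ord <- order(exidx[[cc$transcript_id]])
      circ <- paste(exseq[[cc$transcript_id]][ord][cc$acceptor_index:cc$donor_index],
                    collapse = "")
      template <- strrep(circ, config$rolling_circle_laps)
      if (nchar(circ) < L && config$rolling_circle_laps == 1L)
        warning("circle ", cc$transcript_id, " shorter than the read length ",
                "with a single lap; no junction reads possible")
      out[[length(out) + 1L]] <-
        emit(template, cc$copies, "circle", cc$transcript_id,
             cc$acceptor_index, cc$donor_index, nchar(circ))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  seqs <- unlist(lapply(out, `[[`, "seqs"))
  prov <- do.call(rbind, lapply(out, `[[`, "prov"))
  if (is.null(seqs) || length(seqs) == 0L) {
    return(list(reads = stats::setNames(character(0), character(0)),
                provenance = data.frame()))
  }
  seqs <- .mutate_reads(seqs, config$error_rate)
  ids <- sprintf("read_%06d", seq_along(seqs))
  names(seqs) <- ids
  prov <- cbind(read_id = ids, prov, stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  list(reads = seqs, provenance = prov)
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Counts-level simulation of junction reads
#'
#' Draws Poisson junction read counts directly, at `depth_per_copy`
#' expected reads per junction per molecule copy — for every planted
#' circle's back-splice junction and every canonical junction of every
#' multi-exon transcript. This samples the counting process the
#' abundance estimator assumes (one junction per molecule), bypassing
#' sequence space; see the vignette for why sequence-level rolling-circle
#' reads deliberately violate that assumption.
#'
#' @param pool Pool from [simulate_pool()].
#' @param models Exon table.
#' @param depth_per_copy Expected junction reads per molecule copy.
#' @param seed Seed.
#' @return `data.frame(junction_id, read_count)` using the
#'   [build_junction_db()] id scheme (`transcript|i-j`).
#' @export
simulate_junction_counts <- function(pool, models, depth_per_copy, seed = 1L) {
  set.seed(seed)
  nex <- n_exons(models)
  rows <- list()
  for (k in seq_len(nrow(pool$linear))) {
    tid <- pool$linear$transcript_id[k]
    n <- nex[[tid]]
    if (n < 2L) next
    cnt <- stats::rpois(n - 1L, pool$linear$copies[k] * depth_per_copy)
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = sprintf("%s|%d-%d", tid, 1:(n - 1L), 2:n),
      read_count = cnt, stringsAsFactors = FALSE)
  }
  if (nrow(pool$circles)) {
    cc <- pool$circles
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = sprintf("%s|%d-%d", cc$transcript_id, cc$donor_index,
                            cc$acceptor_index),
      read_count = stats::rpois(nrow(cc), cc$copies * depth_per_copy),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$read_count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate qPCR Ct values from molecule counts
#'
#' Ideal model: `Ct = c0 - log(copies) / log(1 + efficiency)`; at
#' efficiency 1 a doubling of template lowers Ct by exactly 1. Gaussian
#' noise of sd `noise_sd` is added per replicate. Zero copies give a
#' censored `NA` Ct.
#'
#' @param copies Molecule counts (vectorized).
#' @param c0 Ct of a single template copy.
#' @param efficiency Amplification efficiency in (0, 1].
#' @param noise_sd Gaussian Ct noise (0 = noiseless, exact).
#' @return `list(ct, censored)`.
#' @export
simulate_ct <- function(copies, c0 = 35, efficiency = 1, noise_sd = 0) {
  stopifnot(efficiency > 0, efficiency <= 1)
  censored <- copies <= 0
  ct <- rep(NA_real_, length(copies))
  ct[!censored] <- c0 - log(copies[!censored]) / log(1 + efficiency)
  if (noise_sd > 0)
    ct[!censored] <- ct[!censored] + stats::rnorm(sum(!censored), 0, noise_sd)
  list(ct = ct, censored = censored)
}

#' Simulate a long-format Ct table for mock vs RNase R pools
#'
#' For each gene with a planted circle, two assays (circular and linear
#' isoform) are measured in both treatments across replicates, using the
#' pool copy numbers under [simulate_ct()]'s ideal model.
#'
#' @param pool_mock,pool_rnaser Pools before and after [apply_rnaser()].
#' @param replicates Number of replicates per assay/treatment.
#' @param c0,efficiency,noise_sd See [simulate_ct()].
#' @param seed Seed.
#' @return Long data.frame with columns `assay_id`, `gene`, `isoform`,
#'   `treatment`, `replicate`, `ct`, `censored`.
#' @export
simulate_ct_table <- function(pool_mock, pool_rnaser, replicates = 3L,
                              c0 = 35, efficiency = 1, noise_sd = 0,
                              seed = 1L) {
  set.seed(seed)
  if (!nrow(pool_mock$circles)) stop("no planted circles to assay")
  rows <- list()
  for (k in seq_len(nrow(pool_mock$circles))) {
    cc <- pool_mock$circles[k, ]
    tid <- cc$transcript_id
    lin_mock <- pool_mock$linear$copies[pool_mock$linear$transcript_id == tid]
    lin_rr <- pool_rnaser$linear$copies[pool_rnaser$linear$transcript_id == tid]
    cir_rr <- pool_rnaser$circles$copies[
      pool_rnaser$circles$transcript_id == tid &
        pool_rnaser$circles$donor_index == cc$donor_index &
        pool_rnaser$circles$acceptor_index == cc$acceptor_index]
    grid <- expand.grid(isoform = c("circular", "linear"),
                        treatment = c("mock", "rnaser"),
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    copies <- ifelse(grid$isoform == "circular",
                     ifelse(grid$treatment == "mock", cc$copies, cir_rr),
                     ifelse(grid$treatment == "mock", lin_mock, lin_rr))
    sim <- simulate_ct(copies, c0, efficiency, noise_sd)
    rows[[k]] <- data.frame(
      assay_id = paste(cc$gene_id, grid$isoform, sep = ":"),
      gene = cc$gene_id, isoform = grid$isoform, treatment = grid$treatment,
      replicate = grid$replicate, ct = sim$ct, censored = sim$censored,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
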