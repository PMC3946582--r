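#' Canonical junction read rate of one transcript
#'
#' The canonical rate R_can of a multi-exon transcript is the number of
#' reads aligning to its canonical exon-exon junctions divided by the
#' number of such junctions (n - 1 for n exons). Transcripts with fewer
#' than two exons have no canonical junction and are excluded.
#'
#' @param counts Output of [count_junction_reads()].
#' @param db Junction table.
#' @param transcript_id Transcript to evaluate.
#' @param models Exon table (supplies the junction count n - 1).
#' @return Numeric rate (reads per canonical junction).
#' @export
canonical_rate <- function(counts, db, transcript_id, models) {
  n <- n_exons(models)[[transcript_id]]
  if (is.null(n) || is.na(n) || n < 2L)
    stop("transcript ", transcript_id, " has fewer than 2 exons; R_can undefined")
  can <- db$junction_id[db$transcript_id == transcript_id &
                          db$category == "canonical"]
  total <- sum(counts$read_count[counts$junction_id %in% can])
  total / (n - 1L)
}

#' Per-condition expression rates from junction counts
#'
#' R_cir: per gene, the number of reads spanning its scrambled
#' (back-splice) junctions. R_can: per multi-exon transcript, canonical
#' junction reads divided by the number of canonical junctions.
#' Transcripts with zero canonical reads still contribute 0 to the R_can
#' sum.
#'
#' @param counts Output of [count_junction_reads()].
#' @param db Junction table.
#' @param models Exon table.
#' @param condition Condition label.
#' @param replicate_id Replicate label.
#' @return List of class `expression_rates` with named numeric vectors
#'   `R_cir` (by gene) and `R_can` (by transcript).
#' @export
expression_rates <- function(counts, db, models, condition = "default",
                             replicate_id = 1L) {
  idx <- match(counts$junction_id, db$junction_id)
  if (anyNA(idx)) stop("counts reference junctions absent from the database")
  rec <- db[idx, , drop = FALSE]
  scr <- rec$category == "scrambled"
  r_cir <- if (any(scr)) {
    v <- tapply(counts$read_count[scr], rec$gene_id[scr], sum)
    stats::setNames(as.numeric(v), names(v))
  } else stats::setNames(numeric(0), character(0))
  nex <- n_exons(models)
  multi <- names(nex)[nex >= 2L]
  can <- rec$category == "canonical"
  r_can <- stats::setNames(rep(0, length(multi)), multi)
  if (any(can)) {
    can_reads <- tapply(counts$read_count[can], rec$transcript_id[can], sum)
    got <- intersect(names(can_reads), multi)
    r_can[got] <- as.numeric(can_reads[got])
  }
  r_can <- r_can / (nex[multi] - 1L)
  structure(list(condition = condition, replicate_id = replicate_id,
                 R_cir = r_cir, R_can = r_can),
            class = "expression_rates")
}

#' Average expression rates across replicates
#'
#' Element-wise arithmetic mean of the R_cir and R_can maps; a key absent
#' from a replicate counts as 0 for that replicate.
#'
#' @param rates List of `expression_rates`, all from the same condition.
#' @return A single `expression_rates` with `replicate_id = "mean"`.
#' @export
average_replicates <- function(rates) {
  stopifnot(length(rates) >= 1L)
  conds <- unique(vapply(rates, `[[`, "", "condition"))
  if (length(conds) != 1L)
    stop("cannot average across conditions: ", paste(conds, collapse = ", "))
  avg <- function(field) {
    keys <- unique(unlist(lapply(rates, function(r) names(r[[field]]))))
    if (is.null(keys)) return(stats::setNames(numeric(0), character(0)))
    m <- vapply(rates, function(r) {
      v <- stats::setNames(rep(0, length(keys)), keys)
      v[names(r[[field]])] <- r[[field]]
      v
    }, numeric(length(keys)))
    if (length(keys) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(keys))
    rowMeans(m)
  }
  structure(list(condition = conds, replicate_id = "mean",
                 R_cir = avg("R_cir"), R_can = avg("R_can")),
            class = "expression_rates")
}

#' Genome-wide circular fraction of the mRNA pool
#'
#' The fraction of circular molecules relative to total mRNA molecules:
#' `sum(R_cir) / sum(R_can) * M / (M + S)`, where M and S are the total
#' per-cell copy numbers of multi-exon and single-exon gene transcripts.
#' The first factor estimates circles relative to multi-exon mRNAs; the
#' second rescales to the whole mRNA pool, which single-exon genes (which
#' cannot produce junction reads) also populate.
#'
#' @param sum_R_cir Summed circular junction read rate.
#' @param sum_R_can Summed canonical rate over multi-exon transcripts.
#' @param M Total per-cell copies of multi-exon gene transcripts.
#' @param S Total per-cell copies of single-exon gene transcripts.
#' @return The circular:total-mRNA molecule fraction.
#' @export
circle_fraction <- function(sum_R_cir, sum_R_can, M, S) {
  if (sum_R_can <= 0) stop("sum(R_can) must be positive")
  if (M + S <= 0) stop("M + S must be positive")
  (sum_R_cir / sum_R_can) * (M / (M + S))
}

#' Circular RNA molecules per cell
#'
#' @param fraction Circular:total-mRNA fraction from [circle_fraction()].
#' @param total_mRNA_per_cell Total mRNA molecules per cell.
#' @return Estimated circular RNA molecules per cell.
#' @export
circles_per_cell <- function(fraction, total_mRNA_per_cell) {
  stopifnot(fraction >= 0, total_mRNA_per_cell >= 0)
  fraction * total_mRNA_per_cell
}

#' Per-condition circles-per-cell estimate
#'
#' Convenience wrapper: averages replicates, sums rates, applies
#' [circle_fraction()] and [circles_per_cell()].
#'
#' @param rates List of `expression_rates` for one condition.
#' @param copy_table One-row data.frame (or list) with `S`, `M`,
#'   `total_mRNA_per_cell`.
#' @return `data.frame(condition, sum_R_cir, sum_R_can, fraction,
#'   circles_per_cell)`.
#' @export
estimate_circles_per_cell <- function(rates, copy_table) {
  m <- average_replicates(rates)
  sum_cir <- sum(m$R_cir)
  sum_can <- sum(m$R_can)
  frac <- circle_fraction(sum_cir, sum_can, copy_table$M, copy_table$S)
  data.frame(
    condition = m$condition,
    sum_R_cir = sum_cir,
    sum_R_can = sum_can,
    fraction = frac,
    circles_per_cell = circles_per_cell(frac, copy_table$total_mRNA_per_cell),
    stringsAsFactors = FALSE
  )
}

#' Read a per-condition copy-number table
#'
#' Expected TSV columns: `condition`, `S`, `M`, `total_mRNA_per_cell`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_copy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "S", "M", "total_mRNA_per_cell")
  if (!all(need %in% names(tab)))
    stop("copy-number table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$S < 0 | tab$M < 0 | tab$total_mRNA_per_cell < 0))
    stop("copy numbers must be non-negative")
  tab
}
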