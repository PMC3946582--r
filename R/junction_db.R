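#' Flanks of an exon-exon junction, padded by tandem repeats
#'
#' A junction sequence joins the last `L - 15` bases of donor exon `i` to
#' the first `L - 15` bases of acceptor exon `j`. When an exon is shorter
#' than `L - 15`, the flank is padded with tandem repeats of the
#' `exon_j + exon_i` unit — the sequence a rolling-circle reverse
#' transcriptase would produce from a two-exon (or, when `i == j`,
#' one-exon) circle.
#'
#' The left flank is the last `L - 15` bases of the infinite repeat
#' `...exon_j exon_i` ending at the donor's 3' end; the right flank is the
#' first `L - 15` bases of `exon_j exon_i exon_j...` starting at the
#' acceptor's 5' base. When both exons have length >= `L - 15` this
#' reduces to a plain suffix and prefix.
#'
#' @param exon_i_seq Donor exon sequence (transcript orientation).
#' @param exon_j_seq Acceptor exon sequence.
#' @param L Effective (post-trim) read length; flanks have length `L - 15`.
#' @return `list(left = , right = )`, each a string of `L - 15` bases.
#' @export
pad_flanks <- function(exon_i_seq, exon_j_seq, L) {
  if (L <= 15L) stop("read length L must exceed 15 (got ", L, ")")
  if (!nzchar(exon_i_seq) || !nzchar(exon_j_seq))
    stop("exon sequences must be non-empty")
  flank <- L - 15L
  unit <- paste0(exon_j_seq, exon_i_seq)
  reps <- strrep(unit, ceiling(flank / nchar(unit)) + 1L)
  list(
    left = substr(reps, nchar(reps) - flank + 1L, nchar(reps)),
    right = substr(reps, 1L, flank)
  )
}

#' Build the intragenic exon-exon junction database
#'
#' For each transcript, generates the junction sequence of every ordered
#' exon pair (i, j) with no constraint that i < j, each sequence being
#' `2 * (L - 15)` bases (see [pad_flanks()]). Junction categories:
#' canonical (`j == i + 1`, normal linear splicing), skipping
#' (`j > i + 1`, exon-skipping), scrambled (`j <= i`, the back-splice
#' junction diagnostic of a circular RNA).
#'
#' Within a transcript, records with identical sequence are deduplicated,
#' keeping the lexicographically smallest `(i, j)` pair.
#'
#' @param models Exon table from [parse_annotation()].
#' @param genome [Biostrings::DNAStringSet].
#' @param L Effective read length used to size the flanks.
#' @param max_exons Only the first `max_exons` exons per transcript enter
#'   the database (`NULL` for no cap).
#' @param categories Character subset of
#'   `c("canonical", "skipping", "scrambled")`.
#' @return `data.frame` with columns `junction_id`, `transcript_id`,
#'   `gene_id`, `donor_index`, `acceptor_index`, `category`,
#'   `boundary_offset` (`L - 15`), `read_length`, `sequence`; ordered by
#'   `transcript_id`, `donor_index`, `acceptor_index`.
#' @export
build_junction_db <- function(models, genome, L, max_exons = NULL,
                              categories = c("canonical", "skipping", "scrambled")) {
  categories <- match.arg(categories, several.ok = TRUE)
  if (L <= 15L) stop("read length L must exceed 15 (got ", L, ")")
  flank <- L - 15L
  models <- models[order(models$transcript_id, models$exon_index), , drop = FALSE]
  seqs <- exon_sequences(genome, models)
  parts <- split(seq_len(nrow(models)), models$transcript_id)
  recs <- lapply(names(parts), function(tx) {
    rows <- parts[[tx]]
    n <- length(rows)
    if (!is.null(max_exons)) n <- min(n, max_exons)
    if (n == 0L) return(NULL)
    es <- seqs[rows][seq_len(n)]
    pairs <- expand.grid(acceptor_index = seq_len(n), donor_index = seq_len(n))
    cat <- classify_junction(pairs$donor_index, pairs$acceptor_index)
    keep <- cat %in% categories
    if (!any(keep)) return(NULL)
    pairs <- pairs[keep, , drop = FALSE]
    cat <- cat[keep]
    seq <- mapply(function(i, j) {
      fl <- pad_flanks(es[[i]], es[[j]], L)
      paste0(fl$left, fl$right)
    }, pairs$donor_index, pairs$acceptor_index)
    d <- data.frame(
      transcript_id = tx,
      gene_id = models$gene_id[rows[1L]],
      donor_index = pairs$donor_index,
      acceptor_index = pairs$acceptor_index,
      category = cat,
      boundary_offset = flank,
      read_length = L,
      sequence = as.character(seq),
      stringsAsFactors = FALSE
    )
    d <- d[order(d$donor_index, d$acceptor_index), , drop = FALSE]
    d[!duplicated(d$sequence), , drop = FALSE]  # keep smallest (i, j)
  })
  db <- do.call(rbind, recs)
  if (is.null(db) || nrow(db) == 0L)
    stop("no junction records generated")
  db$junction_id <- sprintf("%s|%d-%d", db$transcript_id,
                            db$donor_index, db$acceptor_index)
  rownames(db) <- NULL
  db[, c("junction_id", "transcript_id", "gene_id", "donor_index",
         "acceptor_index", "category", "boundary_offset", "read_length",
         "sequence")]
}

#' Write junction records as FASTA
#'
#' Headers encode `junction_id transcript_id donor acceptor category
#' boundary_offset` space-separated, so that a database can be
#' reconstructed from its FASTA.
#'
#' @param db Junction table from [build_junction_db()].
#' @param path Output FASTA path.
#' @export
write_junction_fasta <- function(db, path) {
  if (is.null(db) || nrow(db) == 0L) stop("empty junction record set")
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- sprintf("%s %s %d %d %s %d", db$junction_id,
                         db$transcript_id, db$donor_index,
                         db$acceptor_index, db$category, db$boundary_offset)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Re-read a junction FASTA written by [write_junction_fasta()]
#'
#' @param path FASTA path.
#' @return Junction table (without `gene_id`/`read_length`, which are
#'   recovered from the header-encoded fields present).
#' @export
read_junction_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(seqs), " ", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) != 6L))
    stop("malformed junction FASTA header in ", path)
  db <- data.frame(
    junction_id = vapply(fields, `[[`, "", 1L),
    transcript_id = vapply(fields, `[[`, "", 2L),
    donor_index = as.integer(vapply(fields, `[[`, "", 3L)),
    acceptor_index = as.integer(vapply(fields, `[[`, "", 4L)),
    category = vapply(fields, `[[`, "", 5L),
    boundary_offset = as.integer(vapply(fields, `[[`, "", 6L)),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  db$read_length <- db$boundary_offset + 15L
  rownames(db) <- NULL
  db
}

#' Write the junction manifest TSV
#'
#' @param db Junction table.
#' @param path Output TSV path.
#' @export
write_junction_manifest <- function(db, path) {
  out <- db[, c("junction_id", "transcript_id", "donor_index",
                "acceptor_index", "category")]
  out$length <- nchar(db$sequence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
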