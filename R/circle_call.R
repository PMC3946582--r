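#' Classify an exon-exon junction by donor/acceptor order
#'
#' Canonical junctions join exon i to exon i+1 (normal linear splicing);
#' skipping junctions jump forward over one or more exons (j > i + 1);
#' scrambled junctions run backwards or in place (j <= i) and are the
#' diagnostic signature of a back-splice, i.e. a circular RNA. The three
#' categories partition every (i, j) pair.
#'
#' @param i Donor exon index (vectorized).
#' @param j Acceptor exon index (vectorized).
#' @return Character vector in `c("canonical", "skipping", "scrambled")`.
#' @export
classify_junction <- function(i, j) {
  stopifnot(all(i >= 1L), all(j >= 1L))
  ifelse(j == i + 1L, "canonical", ifelse(j > i + 1L, "skipping", "scrambled"))
}

#' Call circular RNA candidates from junction read counts
#'
#' Every scrambled junction with at least one supporting read becomes a
#' candidate. The predicted circle size is the summed length of the exons
#' j..i of the transcript (the exons contained in the circle).
#' Single-exon-transcript circles (i == j == 1 on a 1-exon model) are
#' reported and flagged.
#'
#' @param counts Output of [count_junction_reads()] (its `assignments`
#'   attribute supplies supporting read ids when present).
#' @param db Junction table from [build_junction_db()].
#' @param models Exon table from [parse_annotation()].
#' @param min_reads Optional minimum read count (default 1: single-read
#'   candidates are retained).
#' @return `data.frame(transcript_id, gene_id, donor_index,
#'   acceptor_index, read_count, predicted_circle_size,
#'   single_exon_transcript)` sorted by gene_id then descending
#'   read_count, with `supporting_read_ids` (a list column) when
#'   assignments are available.
#' @export
call_circles <- function(counts, db, models, min_reads = 1L) {
  idx <- match(counts$junction_id, db$junction_id)
  if (anyNA(idx)) stop("counts reference junctions absent from the database")
  rec <- db[idx, , drop = FALSE]
  keep <- rec$category == "scrambled" & counts$read_count >= min_reads
  rec <- rec[keep, , drop = FALSE]
  nread <- counts$read_count[keep]
  jid <- counts$junction_id[keep]
  exlen <- split(models$end - models$start,
                 list(models$transcript_id),
                 drop = TRUE)
  exidx <- split(models$exon_index, models$transcript_id, drop = TRUE)
  nex <- n_exons(models)
  size <- integer(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    tx <- rec$transcript_id[k]
    lens <- exlen[[tx]][order(exidx[[tx]])]
    i <- rec$donor_index[k]; j <- rec$acceptor_index[k]
    if (is.null(lens) || i > length(lens) || j > length(lens))
      stop("junction ", jid[k], " refers to exon(s) absent from transcript ", tx)
    size[k] <- sum(lens[j:i])
  }
  out <- data.frame(
    transcript_id = rec$transcript_id,
    gene_id = rec$gene_id,
    donor_index = rec$donor_index,
    acceptor_index = rec$acceptor_index,
    read_count = nread,
    predicted_circle_size = size,
    single_exon_transcript = nex[rec$transcript_id] == 1L,
    stringsAsFactors = FALSE
  )
  asn <- attr(counts, "assignments")
  if (!is.null(asn))
    out$supporting_read_ids <- lapply(jid, function(id)
      asn$read_id[asn$junction_id == id])
  out <- out[order(out$gene_id, -out$read_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract exon-skipping events from junction read counts
#'
#' Skipping junctions (a, b) with b >= a + 2 observed with at least one
#' read: linear transcripts that splice exon a directly to exon b,
#' omitting exons a+1..b-1.
#'
#' @inheritParams call_circles
#' @return `data.frame(transcript_id, upstream_exon, downstream_exon,
#'   read_count)`.
#' @export
call_skipping <- function(counts, db, min_reads = 1L) {
  idx <- match(counts$junction_id, db$junction_id)
  if (anyNA(idx)) stop("counts reference junctions absent from the database")
  rec <- db[idx, , drop = FALSE]
  keep <- rec$category == "skipping" & counts$read_count >= min_reads
  out <- data.frame(
    transcript_id = rec$transcript_id[keep],
    upstream_exon = rec$donor_index[keep],
    downstream_exon = rec$acceptor_index[keep],
    read_count = counts$read_count[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Exon-skipping reciprocity of circle candidates
#'
#' A circle spanning exons j..i is "reciprocal" when the same dataset
#' contains a linear exon-skipping junction (a, b) with a == j - 1 and
#' b == i + 1 — a spliced transcript that skips exactly the exons present
#' in the circle. Partial overlaps do not count.
#'
#' @param candidates Output of [call_circles()].
#' @param skips Output of [call_skipping()].
#' @return `candidates` with a logical `reciprocal` column.
#' @export
skipping_reciprocity <- function(candidates, skips) {
  key <- function(tx, a, b) paste(tx, a, b, sep = "\r")
  have <- key(skips$transcript_id, skips$upstream_exon, skips$downstream_exon)
  candidates$reciprocal <- key(candidates$transcript_id,
                               candidates$acceptor_index - 1L,
                               candidates$donor_index + 1L) %in% have
  candidates
}

#' Write a circle candidate table as TSV
#'
#' Columns mirror the published per-circle supplementary schema: gene,
#' donor exon, acceptor exon, readcount, predicted circle size.
#'
#' @param candidates Output of [call_circles()].
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("gene_id", "transcript_id", "donor_index", "acceptor_index",
            "read_count", "predicted_circle_size", "single_exon_transcript")
  extra <- intersect("reciprocal", names(candidates))
  utils::write.table(candidates[, c(cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
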