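#' Read a genome FASTA into a normalized DNAStringSet
#'
#' Sequences are uppercased; only A/C/G/T/N are accepted after
#' normalization. Sequence identifiers are taken as the first
#' whitespace-delimited token of each FASTA header and must be unique.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers in ", path)
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other", drop = TRUE] -
    Biostrings::letterFrequency(seqs, "N")[, 1L]
  if (any(bad > 0))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad > 0], collapse = ", "))
  seqs
}

#' Parse a GFF3/GTF annotation into an exon model table
#'
#' Exon rows are grouped into transcripts and each transcript's exons are
#' indexed 1..n in transcript orientation (ascending genomic coordinates
#' on `+`, descending on `-`), matching the exon numbering used for
#' circle nomenclature (e.g. a "7-6" circle joins the donor of exon 7 to
#' the acceptor of exon 6).
#'
#' Coordinates are 1-based inclusive on disk and 0-based half-open in the
#' returned table; the conversion happens here and only here.
#'
#' @param path GFF3 or GTF file. Format is guessed from the extension
#'   (`.gtf` vs anything else); pass `format` to override.
#' @param feature_type Feature rows to use (default `"exon"`).
#' @param id_attribute Attribute naming the transcript grouping key.
#'   Defaults to `"Parent"` for GFF3 and `"transcript_id"` for GTF.
#' @param format `"gff3"`, `"gtf"` or `NULL` (guess).
#' @return A `data.frame` with columns `transcript_id`, `gene_id`,
#'   `exon_index`, `chrom`, `start`, `end`, `strand`, sorted by
#'   `transcript_id` then `exon_index`.
#' @export
parse_annotation <- function(path, feature_type = "exon", id_attribute = NULL,
                             format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  if (is.null(id_attribute))
    id_attribute <- if (format == "gtf") "transcript_id" else "Parent"
  .check_coordinates(path)
  gr <- rtracklayer::import(path, format = format)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", path)
  meta <- S4Vectors::mcols(gr)
  if (!id_attribute %in% colnames(meta))
    stop("attribute '", id_attribute, "' absent from ", feature_type, " rows")
  tid <- meta[[id_attribute]]
  if (methods::is(tid, "List") || is.list(tid))
    tid <- vapply(tid, function(x) if (length(x)) as.character(x[[1L]]) else NA_character_,
                  character(1))
  tid <- as.character(tid)
  gid <- if ("gene_id" %in% colnames(meta)) as.character(meta[["gene_id"]]) else tid
  keep <- !is.na(tid)
  if (!all(keep)) {
    warning(sum(!keep), " ", feature_type,
            " row(s) without a grouping key skipped")
    gr <- gr[keep]; tid <- tid[keep]; gid <- gid[keep]
  }
  df <- data.frame(
    transcript_id = tid,
    gene_id = ifelse(is.na(gid), tid, gid),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(df$strand == "*"))
    stop("unstranded ", feature_type, " feature(s); strand is required")
  parts <- split(df, df$transcript_id)
  parts <- lapply(parts, function(d) {
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L)
      stop("transcript ", d$transcript_id[1L],
           " mixes chromosomes or strands")
    byc <- d[order(d$start), , drop = FALSE]
    if (nrow(byc) > 1L && any(byc$start[-1L] < byc$end[-nrow(byc)]))
      stop("overlapping exons in transcript ", d$transcript_id[1L])
    d <- d[order(d$start, decreasing = (d$strand[1L] == "-")), , drop = FALSE]
    d$exon_index <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  out[, c("transcript_id", "gene_id", "exon_index", "chrom",
          "start", "end", "strand")]
}

# Cheap pre-scan so malformed coordinates are reported with a line number.
.check_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 5L
  s <- suppressWarnings(as.numeric(vapply(fields[ok], `[[`, "", 4L)))
  e <- suppressWarnings(as.numeric(vapply(fields[ok], `[[`, "", 5L)))
  bad <- which(!is.na(s) & !is.na(e) & e < s)
  if (length(bad)) {
    lineno <- which(body)[which(ok)[bad[1L]]]
    stop("malformed coordinates (end < start) at line ", lineno, " of ", path)
  }
  invisible(TRUE)
}

#' Extract the transcript-orientation sequence of one exon
#'
#' Returns the exon's sequence as read 5'->3' along the transcript:
#' the genomic sequence on `+`, its reverse complement on `-`.
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @param exon A one-row exon data.frame (or list) with `chrom`, `start`,
#'   `end` (0-based half-open) and `strand`.
#' @return A character scalar of length `end - start`.
#' @export
exon_sequence <- function(genome, exon) {
  chrom <- as.character(exon$chrom)
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not in genome")
  len <- Biostrings::width(genome[names(genome) == chrom])[1L]
  if (exon$start < 0L || exon$end > len || exon$end <= exon$start)
    stop("exon interval [", exon$start, ",", exon$end, ") of transcript ",
         exon$transcript_id %||% "?", " out of bounds for ", chrom,
         " (length ", len, ")")
  s <- Biostrings::subseq(genome[[chrom]], start = exon$start + 1L, end = exon$end)
  if (as.character(exon$strand) == "-")
    s <- Biostrings::reverseComplement(s)
  as.character(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-exon sequences for an exon model table
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param models Exon table from [parse_annotation()].
#' @return Character vector parallel to the rows of `models`.
#' @export
exon_sequences <- function(genome, models) {
  vapply(seq_len(nrow(models)),
         function(k) exon_sequence(genome, models[k, ]), character(1))
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in exon-index order for each transcript.
#'
#' @inheritParams exon_sequences
#' @return Named character vector, one element per transcript.
#' @export
spliced_transcripts <- function(genome, models) {
  ord <- order(models$transcript_id, models$exon_index)
  models <- models[ord, , drop = FALSE]
  seqs <- exon_sequences(genome, models)
  vapply(split(seqs, models$transcript_id), paste0, character(1), collapse = "")
}

#' Write an exon model table as normalized GFF3
#'
#' @param models Exon table (0-based half-open coordinates).
#' @param path Output file.
#' @export
write_models_gff3 <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand
  )
  gr$type <- "exon"
  gr$Parent <- models$transcript_id
  gr$gene_id <- models$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Exon counts per transcript
#'
#' @param models Exon table.
#' @return Named integer vector: number of exons per transcript.
#' @export
n_exons <- function(models) {
  vapply(split(models$exon_index, models$transcript_id), max, integer(1))
}
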