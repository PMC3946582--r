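#' Alignment settings emulating bowtie -v / -m 1 semantics
#'
#' @param v Maximum mismatches per end-to-end placement (bowtie `-v`).
#' @param unique_only Drop a read entirely when more than one
#'   minimum-mismatch placement survives (bowtie `-m 1`).
#' @param trim5,trim3 Bases trimmed from the 5'/3' read ends before
#'   alignment (bowtie `--trim5/--trim3`).
#' @param both_strands Also search the reverse complement.
#' @param min_overhang Minimum aligned bases required on each side of a
#'   junction boundary when counting junction reads. The default 15 is
#'   implied by the flank construction: with flanks of `L - 15` bases, any
#'   end-to-end placement of a full-length read overlaps the boundary by
#'   at least 15 bases on each side.
#' @return A list of class `align_settings`.
#' @export
align_settings <- function(v = 1L, unique_only = TRUE, trim5 = 0L, trim3 = 0L,
                           both_strands = TRUE, min_overhang = 15L) {
  stopifnot(v >= 0L, trim5 >= 0L, trim3 >= 0L, min_overhang >= 1L)
  structure(list(v = as.integer(v), unique_only = isTRUE(unique_only),
                 trim5 = as.integer(trim5), trim3 = as.integer(trim3),
                 both_strands = isTRUE(both_strands),
                 min_overhang = as.integer(min_overhang)),
            class = "align_settings")
}

#' Trim reads according to settings
#'
#' @param reads Named character vector of read sequences.
#' @param settings [align_settings()].
#' @return Named character vector of trimmed reads.
#' @export
trim_reads <- function(reads, settings) {
  if (settings$trim5 == 0L && settings$trim3 == 0L) return(reads)
  n <- nchar(reads)
  if (any(n <= settings$trim5 + settings$trim3))
    stop("read(s) shorter than trim5 + trim3")
  out <- substr(reads, settings$trim5 + 1L, n - settings$trim3)
  names(out) <- names(reads)
  out
}

#' Align reads end-to-end against a target sequence set
#'
#' Ungapped alignment reporting every minimum-mismatch placement with at
#' most `v` mismatches (N on either side counts as a mismatch). With
#' `unique_only`, a read whose minimum-mismatch placements number more
#' than one — counting distinct (target, offset, strand) across the whole
#' target set — is suppressed entirely.
#'
#' Trimming (`trim5`/`trim3`) is applied here; offsets refer to the
#' trimmed read placed on the target, `[offset, offset + length)`,
#' 0-based. Strand `-` means the reverse complement of the read matches
#' the target at that interval.
#'
#' @param reads Named character vector (names are read ids).
#' @param targets Named character vector of target sequences.
#' @param settings [align_settings()].
#' @return `data.frame(read_id, target_id, offset, strand, mismatches)`
#'   sorted by read_id, target_id, offset, strand.
#' @export
align_reads <- function(reads, targets, settings = align_settings()) {
  stopifnot(!is.null(names(reads)), !is.null(names(targets)))
  reads <- trim_reads(reads, settings)
  bad <- grepl("[^ACGTNacgtn]", reads)
  if (any(bad))
    stop("read(s) with non-ACGTN characters: ",
         paste(utils::head(names(reads)[bad], 5L), collapse = ", "))
  raw <- .align_reads_cpp(unname(reads), unname(targets),
                          settings$v, settings$unique_only,
                          settings$both_strands, FALSE)
  hits <- data.frame(
    read_id = names(reads)[raw$read],
    target_id = names(targets)[raw$target],
    offset = raw$offset,
    strand = c("+", "-")[raw$minus + 1L],
    mismatches = raw$mismatches,
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$read_id, hits$target_id, hits$offset, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Identify reads unalignable to genome and transcriptome
#'
#' The prefilter used for organisms with extensive annotated alternative
#' splicing: only reads that fail end-to-end alignment (within `v`
#' mismatches) to both the genome and the spliced transcriptome proceed
#' to the junction database. Pass `transcriptome = NULL` for the
#' genome-only variant.
#'
#' @param reads Named character vector of read sequences.
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param transcriptome Named character vector of spliced transcript
#'   sequences, or `NULL`.
#' @param settings [align_settings()]; `unique_only` is irrelevant here.
#' @return Character vector of read ids with zero placements.
#' @export
prefilter_unaligned <- function(reads, genome, transcriptome = NULL,
                                settings = align_settings()) {
  reads <- trim_reads(reads, settings)
  refs <- as.character(genome)
  if (!is.null(transcriptome)) refs <- c(refs, as.character(transcriptome))
  raw <- .align_reads_cpp(unname(reads), unname(refs),
                          settings$v, FALSE, settings$both_strands, TRUE)
  names(reads)[!raw$any_hit]
}

#' Count junction-spanning reads
#'
#' A hit contributes only when its aligned interval covers
#' `[boundary_offset - min_overhang, boundary_offset + min_overhang)`.
#' Each read is counted for at most one junction; among a read's
#' qualifying hits, ties go to the fewest mismatches, then the
#' lexicographically smallest junction_id.
#'
#' @param hits Hit table from [align_reads()] against a junction database.
#' @param db Junction table from [build_junction_db()].
#' @param min_overhang Required aligned bases on each side of the boundary.
#' @param read_length Effective (post-trim) read length; defaults to the
#'   database's `read_length`.
#' @return `data.frame(junction_id, read_count)` for junctions with at
#'   least one read, with the read-level assignment in
#'   `attr(, "assignments")` (`read_id`, `junction_id`, `mismatches`).
#' @export
count_junction_reads <- function(hits, db, min_overhang = 15L,
                                 read_length = NULL) {
  if (is.null(read_length)) read_length <- db$read_length[1L]
  if (read_length != db$read_length[1L])
    stop("effective read length (", read_length, ") does not match the L ",
         "the junction database was built with (", db$read_length[1L], "); ",
         "the overhang guarantee requires them to be equal")
  unknown <- setdiff(unique(hits$target_id), db$junction_id)
  if (length(unknown))
    stop("hit(s) reference unknown junction_id: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  if (nrow(hits) == 0L) {
    out <- data.frame(junction_id = character(), read_count = integer())
    attr(out, "assignments") <- data.frame(read_id = character(),
                                           junction_id = character(),
                                           mismatches = integer())
    return(out)
  }
  b <- db$boundary_offset[match(hits$target_id, db$junction_id)]
  covers <- hits$offset <= b - min_overhang &
    hits$offset + read_length >= b + min_overhang
  q <- hits[covers, , drop = FALSE]
  q <- q[order(q$read_id, q$mismatches, q$target_id), , drop = FALSE]
  q <- q[!duplicated(q$read_id), , drop = FALSE]
  counts <- as.data.frame(table(junction_id = q$target_id),
                          stringsAsFactors = FALSE)
  names(counts)[2L] <- "read_count"
  counts$read_count <- as.integer(counts$read_count)
  counts <- counts[order(counts$junction_id), , drop = FALSE]
  rownames(counts) <- NULL
  attr(counts, "assignments") <- data.frame(read_id = q$read_id,
                                            junction_id = q$target_id,
                                            mismatches = q$mismatches,
                                            stringsAsFactors = FALSE)
  counts
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a hit table as TSV
#'
#' @param hits Hit table.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
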