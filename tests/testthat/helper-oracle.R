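# Independent brute-force reference aligner: enumerates every
# (target, offset, strand) placement, counts Hamming mismatches (N on
# either side counts as a mismatch), keeps placements at the minimum
# mismatch count <= v, and applies -m 1 suppression. Deliberately naive
# and string-based; shares no code with the package aligner.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

oracle_align_one <- function(read, targets, v, unique_only, both_strands) {
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    q <- if (strand == "+") read else oracle_revcomp(read)
    qc <- strsplit(q, "", fixed = TRUE)[[1L]]
    L <- length(qc)
    for (t in names(targets)) {
      tc <- strsplit(targets[[t]], "", fixed = TRUE)[[1L]]
      if (length(tc) < L) next
      for (o in 0:(length(tc) - L)) {
        b <- tc[(o + 1L):(o + L)]
        mm <- sum(qc != b | qc == "N" | b == "N")
        if (mm <= v)
          rows[[length(rows) + 1L]] <-
            data.frame(target_id = t, offset = o, strand = strand,
                       mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  hits <- do.call(rbind, rows)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (unique_only && nrow(hits) > 1L) return(NULL)
  hits
}

oracle_align <- function(reads, targets, v, unique_only, both_strands) {
  rows <- lapply(names(reads), function(id) {
    h <- oracle_align_one(reads[[id]], targets, v, unique_only, both_strands)
    if (is.null(h)) return(NULL)
    cbind(read_id = id, h, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(read_id = character(), target_id = character(),
                      offset = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$read_id, out$target_id, out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, k) {
  if (k == 0L) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}
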