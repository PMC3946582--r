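# Sequence-free junction table covering all exon pairs of every
# transcript; sufficient for counting/rate functions, which never look
# at the junction sequence itself.
toy_full_db <- function(models) {
  parts <- lapply(split(models, models$transcript_id), function(m) {
    n <- max(m$exon_index)
    g <- expand.grid(donor_index = seq_len(n), acceptor_index = seq_len(n))
    data.frame(junction_id = sprintf("%s|%d-%d", m$transcript_id[1L],
                                     g$donor_index, g$acceptor_index),
               transcript_id = m$transcript_id[1L], gene_id = m$gene_id[1L],
               donor_index = g$donor_index, acceptor_index = g$acceptor_index,
               category = classify_junction(g$donor_index, g$acceptor_index),
               boundary_offset = 35L, read_length = 50L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
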