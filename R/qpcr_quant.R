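#' RNase R resistance of one assay (delta-Ct)
#'
#' RNase R resistance is the log2 fold-change in RNA abundance with
#' RNase R treatment, taken as `Ct(mock) - Ct(RNase R)`. A fully
#' resistant species gives 0; a species depleted 2^k-fold gives -k
#' (e.g. a greater than 32-fold drop corresponds to delta-Ct < -5).
#'
#' @param ct_mock Ct of the mock-treated sample (vectorized).
#' @param ct_rnaser Ct of the RNase R-treated sample.
#' @return delta-Ct (negative = depleted by the exonuclease).
#' @export
rnase_r_resistance <- function(ct_mock, ct_rnaser) {
  stopifnot(all(is.finite(ct_mock)), all(is.finite(ct_rnaser)))
  ct_mock - ct_rnaser
}

#' Fold-change in abundance implied by a delta-Ct
#'
#' Under ideal amplification efficiency, abundance scales as
#' `2^(delta-Ct)`; the fold *drop* is `2^(-delta-Ct)`.
#'
#' @param delta_ct delta-Ct value(s).
#' @return Fold drop in abundance (e.g. delta-Ct = -5 gives 32).
#' @export
fold_drop <- function(delta_ct) 2^(-delta_ct)

#' Relative RNase R resistance of a circle vs its linear isoform
#'
#' `ddCt = mean(delta-Ct circle) - mean(delta-Ct linear)`, with the
#' standard error of each replicate mean combined in quadrature. A
#' single replicate on a side contributes se = 0 (flagged via
#' `se_degenerate`).
#'
#' @param circle Replicate delta-Ct values of the circular isoform.
#' @param linear Replicate delta-Ct values of the linear isoform.
#' @return `list(ddct, se, se_degenerate)`.
#' @export
relative_resistance <- function(circle, linear) {
  if (length(circle) < 1L || length(linear) < 1L)
    stop("at least one replicate required on each side")
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  list(
    ddct = mean(circle) - mean(linear),
    se = sqrt(sem(circle)^2 + sem(linear)^2),
    se_degenerate = length(circle) < 2L || length(linear) < 2L
  )
}

#' Summarize a Ct table into per-assay resistance results
#'
#' Expects long-format records with columns `assay_id`, `isoform`
#' (`"circular"`/`"linear"`), `gene`, `treatment` (`"mock"`/`"rnaser"`),
#' `replicate`, `ct`. delta-Ct is computed per assay and replicate
#' (pairing mock and RNase R by replicate), then ddCt per gene from the
#' circular and linear assays.
#'
#' @param ct_table data.frame of Ct records.
#' @return `data.frame(gene, ddct, ddct_se, delta_ct_circle,
#'   delta_ct_linear)`.
#' @export
summarize_resistance <- function(ct_table) {
  need <- c("gene", "isoform", "treatment", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  dct <- function(gene, iso) {
    d <- ct_table[ct_table$gene == gene & ct_table$isoform == iso, ]
    mock <- d[d$treatment == "mock", ]
    rr <- d[d$treatment == "rnaser", ]
    reps <- intersect(mock$replicate, rr$replicate)
    if (length(reps) == 0L)
      stop("no paired mock/rnaser replicates for ", gene, " ", iso)
    rnase_r_resistance(mock$ct[match(reps, mock$replicate)],
                       rr$ct[match(reps, rr$replicate)])
  }
  genes <- sort(unique(ct_table$gene))
  rows <- lapply(genes, function(g) {
    circ <- dct(g, "circular")
    lin <- dct(g, "linear")
    rel <- relative_resistance(circ, lin)
    data.frame(gene = g, ddct = rel$ddct, ddct_se = rel$se,
               delta_ct_circle = mean(circ), delta_ct_linear = mean(lin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell log2 fold-change across a starvation timecourse
#'
#' qPCR input is an equal RNA mass per timepoint, so Ct differences
#' reflect a species' share of total RNA; multiplying by the per-cell
#' RNA yield converts to a per-cell quantity. The value as printed
#' alongside the published timecourse is
#' `Ct(t0) - Ct(tn) - log2(rna_tn / rna_t0)`. The `physical` convention
#' flips the sign of the mass-correction term
#' (`+ log2(rna_tn / rna_t0)`), which makes a species with constant
#' per-cell copy number read exactly 0; both are exposed and neither is
#' silently rescaled (see the package vignette).
#'
#' @param ct_t0 Ct at time zero.
#' @param ct_tn Ct at time n (vectorized).
#' @param rna_per_cell_t0 RNA mass per cell at time zero (pg).
#' @param rna_per_cell_tn RNA mass per cell at time n (pg, vectorized).
#' @param sign_convention `"as_printed"` (default) or `"physical"`.
#' @return log2 fold-change value(s).
#' @export
timecourse_log2fc <- function(ct_t0, ct_tn, rna_per_cell_t0, rna_per_cell_tn,
                              sign_convention = c("as_printed", "physical")) {
  sign_convention <- match.arg(sign_convention)
  if (any(rna_per_cell_t0 <= 0) || any(rna_per_cell_tn <= 0))
    stop("RNA mass per cell must be positive")
  corr <- log2(rna_per_cell_tn / rna_per_cell_t0)
  if (sign_convention == "as_printed") (ct_t0 - ct_tn) - corr
  else (ct_t0 - ct_tn) + corr
}

#' Evaluate a timecourse Ct series on a per-cell basis
#'
#' @param timepoints_hr Timepoints in hours (first must be time zero).
#' @param ct Ct values, parallel to `timepoints_hr`.
#' @param rna_per_cell RNA yield per cell (pg), parallel to
#'   `timepoints_hr`; the mapping must be stated explicitly and the
#'   lengths must agree.
#' @param sign_convention See [timecourse_log2fc()].
#' @return `data.frame(timepoint_hr, ct, rna_per_cell, log2fc_per_cell)`.
#' @export
timecourse_table <- function(timepoints_hr, ct, rna_per_cell,
                             sign_convention = c("as_printed", "physical")) {
  sign_convention <- match.arg(sign_convention)
  if (length(timepoints_hr) != length(ct) ||
      length(ct) != length(rna_per_cell))
    stop("timepoints, Ct values and RNA-per-cell values must have equal length")
  data.frame(
    timepoint_hr = timepoints_hr,
    ct = ct,
    rna_per_cell = rna_per_cell,
    log2fc_per_cell = timecourse_log2fc(ct[1L], ct, rna_per_cell[1L],
                                        rna_per_cell, sign_convention)
  )
}

#' Read a long-format Ct TSV
#'
#' @param path TSV with columns `assay_id`, `gene`, `isoform`,
#'   `treatment`, `replicate`, `ct` (and optionally `timepoint_hr`).
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"ct" %in% names(tab)) stop("Ct table must have a 'ct' column")
  if (any(!is.finite(tab$ct) | tab$ct <= 0))
    stop("Ct values must be finite and positive")
  tab
}
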