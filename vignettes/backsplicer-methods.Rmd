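---
title: "Detecting and quantifying circular RNAs with backsplicer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying circular RNAs with backsplicer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Exonic circular RNAs are covalently closed transcripts produced when a
splice donor at the 3′ end of exon *i* is joined to a splice acceptor at
the 5′ end of an upstream (or the same) exon *j* ≤ *i*. In intron-poor
eukaryotes — fission and budding yeast, *Plasmodium*, *Dictyostelium*,
*Arabidopsis* — introns average roughly 80–160 nt, alternative splicing
is rare, and most genes have at most a handful of exons, so the usual
metazoan heuristics for circRNA discovery (long flanking introns,
inverted repeats) do not apply. What does survive as a signature is the
back-splice junction itself: a read crossing it matches neither the
genome nor any linear spliced transcript.

backsplicer implements a junction-database strategy around this
signature, plus the downstream quantities used to interpret it: circles
per cell from RNA-seq, and RNase R resistance / per-cell timecourses
from qRT-PCR.

# Junction database

For a library with effective (post-trim) read length $L$, every ordered
exon pair $(i, j)$ of a transcript — with no constraint $i < j$ —
contributes a junction sequence formed from the last $L-15$ bases of
exon $i$ and the first $L-15$ bases of exon $j$. Categories partition
the grid: canonical ($j = i+1$), skipping ($j > i+1$), scrambled
($j \le i$). Canonical records allow the canonical-rate denominator and
the exon-skipping search to reuse the same alignment pass; scrambled
records are the circle detectors.

**Geometry.** A junction record is $2(L-15)$ nt with the boundary at
offset $L-15$. An end-to-end placement of an $L$-mer at offset $o$
satisfies $0 \le o \le L-30$, so the aligned interval always covers at
least 15 nt on each side of the boundary. This is the only overhang
rule in the package: the default `min_overhang = 15` in read counting is
the geometric consequence, restated so that it survives deliberate use
of shorter reads. For the guarantee to hold, the post-trim read length
must equal the database $L$; the counting function enforces this with a
hard error rather than a warning.

**Padding.** When an exon is shorter than $L-15$, the flank is extended
with tandem repeats of the `exon_j + exon_i` unit — the cDNA that
rolling-circle reverse transcription of a two-exon (or, for $i = j$,
one-exon) circle would produce. When a circle actually contains
intermediate exons ($j < i - 1$) and its terminal exons are short, the
true read context beyond the short exon is the intermediate exon, not
the repeat; such reads can exceed the mismatch budget and be lost. We
repeat only the named two exons because the identity of intermediate
exons is unknowable at database-construction time; the recall cost is
confined to circles whose boundary exons are shorter than $L-15$
(rare at these exon-length scales) and is visible in the synthetic
tests as a bounded, not silent, effect.

**Deduplication** removes records with identical sequence *within* a
transcript, keeping the lexicographically smallest $(i, j)$ — identical
sequences arise from repeated short exons under padding. Across genes
we deliberately do not deduplicate: paralogous junctions are instead
suppressed at alignment time by unique mapping, which is the behaviour
the `-m 1`-style flag would have produced in the original toolchain.

A `max_exons` cap (profile-dependent; 10 for the *Arabidopsis*-style
regime) bounds the quadratic growth of the database for the small
minority of genes with many exons.

# Alignment

The aligner is ungapped and end-to-end, reporting all minimum-mismatch
placements with at most $v$ mismatches on either strand; `N` on either
side counts as a mismatch. With `unique_only`, a read whose surviving
placements (distinct target/offset/strand) number more than one is
dropped entirely. Implementation: pigeonhole seeding over $v+1$
non-overlapping read segments against a sorted $w$-mer index of the
targets ($w = \lfloor L_{\min}/(v+1)\rfloor$, capped at 31), followed by
full Hamming verification with early exit. A placement with $\le v$
mismatches must contain an exactly matching segment, and an exactly
matching segment is N-free on both sides, so the seeding is lossless.
The test suite holds the aligner equal to an independent brute-force
scan over every (target, offset, strand) on hundreds of randomized
instances across $v \in \{0,1,3\}$, both uniqueness settings and both
strand settings.

Counting junction reads assigns each read to at most one junction:
among its boundary-covering hits, fewest mismatches wins, then the
lexicographically smallest junction id. The tie-break is arbitrary but
deterministic; at `unique_only = TRUE` it is almost never exercised.

Per-organism regimes are encoded as profiles: read length 60 / $v=3$ /
unique for the *P. falciparum*-style dataset; 50 / $v=1$ / unique for
the fission-yeast dataset; trim5 3, effective $L=40$, $v=1$, unique,
with a genome prefilter at $v=3$ for the lariat-enriched fission-yeast
dataset; 100 / $v=3$ with genome+transcriptome prefilter and the
10-exon cap for *Arabidopsis*; trim5 5 / trim3 5 / $v=3$ with prefilter
for *Dictyostelium*. Unique mapping is enabled exactly for the
organisms lacking extensive annotated alternative splicing (fission
yeast, *P. falciparum*); the prefilter exists because extensive
annotated splicing makes direct-to-database mapping ambiguous in the
other genomes.

# Circle calling and reciprocity

Every scrambled junction with at least one counted read becomes a
candidate — deliberately no read-count threshold, because at realistic
depths most genuine circles are seen in a single read; a `min_reads`
option exists for users who want stringency. The predicted circle size
is the summed length of exons $j..i$, which is strand-invariant.
Candidates are reported per transcript; no merging across isoforms is
attempted because isoform equivalence of a circle is not well defined
without extra evidence. Single-exon-transcript self-junctions are
reported but flagged, since they cannot use annotated splice sites on
both ends.

A circle $(i, j)$ is *reciprocal* when a skipping junction $(j-1, i+1)$
is observed in the same dataset — a linear transcript that skips
exactly the circled exons, the pattern expected if circles were
by-products of exon-skipping lariats. Partial overlaps are reported as
non-reciprocal; we do not attempt a looser definition because any
partial-overlap rule would be an invention with no ground truth to
calibrate against.

# Circles per cell

For each condition, $R_{cir}$ of a gene is its scrambled-junction read
count; $R_{can}$ of a multi-exon transcript is its canonical-junction
reads divided by its $n-1$ canonical junctions. Transcripts with zero
canonical reads stay in the sum as zeros; single-exon genes cannot
produce junction reads and enter only through their copy total $S$.
The circular fraction of the mRNA pool is

$$\frac{\sum R_{cir}}{\sum R_{can}} \times \frac{M}{M+S},$$

multiplied by total mRNAs per cell to give circles per cell. Replicates
are averaged at the rate level (element-wise mean of the $R$ maps,
absent keys counting as zero) before summation. When a gene hosts
several distinct circles, reads are summed over all its scrambled
junctions — the most literal reading of "summed across all genes".

Two biases are acknowledged and not corrected. First, circles smaller
than the library's fragment size are under-sampled by library
construction; no size correction is applied because the size
distribution of true circles is unknown. Second, rolling-circle reverse
transcription places $k-1$ back-splice junction copies on a $k$-lap
concatemer, so at the sequence level junction reads per circular
molecule exceed junction reads per linear molecule per junction by
roughly a factor $k-1$; the estimator assumes one junction per
molecule. This is inherent to the published formula, not to this
implementation. Consequently the package tests *ratio accuracy* of the
estimator on a counts-level generator that samples the process the
formula assumes (Poisson junction reads proportional to molecule
copies), and tests *detection* (recall, false positives) on the full
sequence-level generator where concatemers are real.

# qRT-PCR quantities

RNase R resistance is $\Delta Ct = Ct(\text{mock}) - Ct(\text{RNase
R})$: the log2 fold-change of the isoform under exonuclease treatment,
$-5$ corresponding to a 32-fold drop. Relative resistance is
$\Delta\Delta Ct = \overline{\Delta Ct}_{circle} -
\overline{\Delta Ct}_{linear}$ with replicate standard errors combined
in quadrature — the simplest propagation consistent with reporting
standard errors; a single replicate contributes zero error and is
flagged rather than imputed. Both quantities are invariant to a
constant plate offset, which the tests assert.

The timecourse value converts equal-mass qPCR measurements to a
per-cell basis with the measured RNA yield per cell:
$Ct(t_0) - Ct(t_n) - \log_2(\text{RNA/cell}_{t_n} /
\text{RNA/cell}_{t_0})$. Implemented verbatim as the default
(`as_printed`), this formula gives a *nonzero* value for a species with
constant per-cell copy number in a noiseless simulation; the
sign-flipped mass term (`physical`) gives exactly zero there. Both
conventions are exposed behind an explicit flag and neither is silently
substituted for the other, because the printed form is what published
panels used while the physical form is what a per-cell log fold-change
should satisfy. Relatedly, the source timecourse lists five timepoints
but six RNA-yield values; `timecourse_table` therefore requires an
explicit, equal-length mapping and hard-errors otherwise instead of
guessing which yield belongs to which timepoint.

Amplification efficiency appears only in the synthetic Ct generator
($Ct = c_0 - \log(\text{copies})/\log(1+E)$, default $E = 1$);
the analysis functions use raw Ct differences, matching how such
experiments are reported.

# Synthetic data: what it emulates, and what it does not

The generator is the package's ground-truth instrument, not a fixture:
genomes with one gene per contig, 1–13 exons weighted towards 2–9,
gamma exon lengths (mean 180 nt, sd 100, floor 30), gamma intron
lengths with organism-preset means (148, 82, 142, 134, 158 nt for the
budding-yeast, fission-yeast, *Dictyostelium*, *Plasmodium* and
*Arabidopsis* presets; sd half the mean, floor 20), lognormal linear
copy numbers (≈8 copies mean, matching a ~41,000-mRNA cell with ~5,000
genes), and a planted-circle fraction of 2% of genes by default (the
observed order of magnitude: ~1% of genes, ~3% of multi-intron genes).
Planted circles occupy contiguous internal exon runs ($2 \le j \le i
\le n-1$) of 1–3 exons; circle copies default to 1–10% of the host
gene's linear copies, since validated circles are minor isoforms.
Reads are sampled uniformly from templates at
`depth` reads per kb per molecule copy; circular templates are
`rolling_circle_laps` (default 3) concatemers; errors are
substitution-only because the aligner is ungapped; RNase R is binomial
thinning (default linear survival $2^{-6}$, circle survival 1). A
two-condition mode rescales total linear copies (e.g. by 7315/40909
for the starvation analogue) while leaving circle copies alone.

Everything is deterministic given the seed. Not emulated: PCR
duplicates, GC and positional bias, quality scores, paired-end
geometry, unannotated/cryptic splice sites (circles using them are
explicitly out of the method's reach), and any empirical circle
copy-number distribution (none is published; the defaults above are
stated assumptions). Passing synthetic tests therefore demonstrates
correctness of the algorithms under the stated statistical model, not
performance on real libraries with their biases.

# Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to give stable statistics at
interactive runtimes: 500-gene genomes (~15,000 reads, ~18,000 junction
records) for sequence-level recovery; 60-gene pools with ≥120 expected
reads per circle junction for ratio recovery (three planted ratios
spanning $10^{-4}$–$10^{-2}$, tolerance 15% relative — comfortably
above the ~6% Poisson noise at that depth); 204 randomized instances
for aligner-oracle equivalence; exhaustive offset enumeration for the
junction-geometry guarantee at $L \in \{40, 50, 60, 100, 150\}$.
Degenerate inputs fail loudly by design: zero canonical reads in a
denominator, zero-length records, mismatched read length vs database
$L$, mixed conditions in replicate averaging, and non-positive RNA
masses are all hard errors, never NaNs.

# Limitations

Only annotated splice sites are considered; circles using cryptic
sites are invisible by construction. The aligner has no gapped or
quality-aware mode. Circles-per-cell inherits the one-junction-per-
molecule assumption and the fragment-size bias discussed above, and
external per-cell copy-number tables (M, S, total mRNA) must come from
an independent quantification. Reciprocity is exact-complement only.
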