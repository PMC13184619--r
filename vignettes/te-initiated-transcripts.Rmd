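---
title: "Detecting and scoring TE-initiated transcripts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring TE-initiated transcripts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transposable elements (TEs) carry cryptic promoters that are silenced in
most somatic tissue but can reactivate — most prominently in tumours —
and drive transcription into neighbouring sequence.  The resulting
*TE-initiated transcripts* (a transcript whose transcription start site,
TSS, lies inside an annotated TE) include chimeric TE–gene products,
onco-exaptation events, and candidate tumour-specific antigens.  Finding
them in short-read RNA-seq is hard for one specific reason: assemblers
recover splice structure well but place 5' ends poorly, and a TE call
hinges entirely on where the 5' end is.

`teit` implements a complete desk-scale workflow around that problem:

1. a convolutional model that re-predicts each assembled transcript's TSS
   from DNA sequence plus RNA-seq coverage, trained on cap-based TSS
   labels (CapTrap/CAGE-style 5'-end evidence);
2. cross-sample TSS correction, TE intersection and reference-guided
   merging into a catalogue;
3. junction-read quantification and TE-family promoter activity;
4. structural and coding classification;
5. tumour-specificity, enrichment and clinical-association statistics;
6. a seeded synthetic-cohort generator that gives every stage ground
   truth.

# Coordinates and containers

All internal coordinates are 0-based half-open (`[start, end)`), the
BED/bedGraph convention; GTF input/output converts at the file boundary
(`read_gtf()` / `write_gtf()`, round-trip exact).  A transcript is an
exon chain on one chromosome and strand (`transcript_model`).  The
*first exon* is the 5'-most exon in transcription order and its *donor*
— the first splice donor, `end` on `+`, `start` on `-` — is the
cross-sample clustering key: splice sites are determined by sequence and
are stable across samples, while assembled 5' ends are not.
Single-exon assemblies carry no splice anchor (and are dominated by
artifacts), so the pipeline considers multi-exon transcripts only.

Two deliberate dialect choices in I/O: overlapping bedGraph records are
*summed* (not last-wins), and TE overlap tests ignore TE strand — a TE
promoter may fire in either orientation, so the sense/antisense relation
is metadata, not a filter.

# The TSS model

For each first-exon donor the model sees a window of `2 * flank` bases
centred on the donor: 4 one-hot DNA channels plus 2 coverage channels
(unique- and multi-mapping reads as separate channels, since repeat-rich
TE promoters are exactly where the two diverge).  Windows on `-` strand
transcripts are reverse-complemented (coverage reversed) so transcription
always runs left to right.  Coverage is `log1p`-transformed and
max-normalized per window — the model should read coverage *shape* (the
step at a TSS), not library depth.

The network is a residual multi-scale 1-D convolution stack: parallel
same-padding convolutions with kernel sizes {7, 15, 51} (motif scale up
to broad promoter context), a dilated middle convolution with a residual
connection, and a per-base linear head producing one logit per position.
The predicted signal is the softmax over the window; the label is the
cap signal in the window normalized to sum 1; training minimizes

$$L = \sum_i t^*_i\,[\ln(t^*_i + \epsilon) - \ln(p^*_i + \epsilon)],
\qquad \epsilon = e^{-10},$$

with Adam at learning rate 0.005, batch size 64, at most 10 epochs (the
published optimization recipe; these are the `train_config()` defaults).
Windows with no cap mass are negatives: with the $\epsilon$ guard they
contribute zero loss and zero gradient, which is how the loss copes with
positive/negative imbalance.  Negatives are subsampled to a 1:1 ratio by
default (`cohort_windows(negative_ratio=)`).

Forward and backward passes are exact analytic code over im2col matrix
products (BLAS); there is no deep-learning framework underneath, which
keeps training deterministic, dependency-free and fast at the window
sizes used here.  A gradient check against numeric differentiation is
part of the test suite.

The predicted TSS is the argmax of the softmax signal mapped back to
genomic coordinates (ties broken toward the window centre — the donor is
the only a-priori anchor); the confidence score is the maximum softmax
probability.  Records below `min_score` (default 0.1) are dropped before
clustering.  The threshold is a retention knob, deliberately exposed:
score correlates negatively with prediction error, so raising it trades
catalogue size for TSS accuracy.

Two points were genuinely open and are resolved as follows: the
normalization `*` is read as "normalize to sum 1 within the window" on
*both* target and prediction (KL compares distributions; training on raw
counts would conflate depth with position), and prediction uses the same
softmax normalization at inference.

# Detection

Within the pooled multi-exon assemblies:

1. **Degradation filter.**  A first exon overlapping (>= 1 bp) an
   *internal* exon of another transcript is excluded as a likely RNA
   degradation product.  Comparison is same-strand by default
   (antisense overlap is not degradation of the same RNA); a
   strand-blind switch exists.
2. **Support-weighted correction.**  Records are clustered by exact
   donor coordinate.  For each predicted position $t$ with sample
   support $s_t$,
   $$S_t = s_t + \sum_{k \in T} \frac{w - d_k}{w\,s_k},$$
   over other supported positions within $d_k < w$ (strict inequality;
   $t$ itself excluded), and the cluster's corrected TSS is the argmax
   (ties: higher $s_t$, then 5'-most in transcription order).  The
   division by the *neighbour's* support $s_k$ is implemented exactly as
   the formula is stated; because the $s_t$ term dominates, the
   correction behaves as majority-vote with distance-weighted
   tie-breaking.  A `support_proportional` variant
   ($({w-d_k})\,s_k/w$) is available for sensitivity analysis.  The
   window defaults to $w = 100$ bp, matching the 100-bp tolerance used
   throughout validation.  Donors are clustered exactly, never fuzzily —
   an exact key keeps every merge auditable against the assemblies.
3. **TE intersection.**  Corrected TSSs are kept iff they fall inside a
   TE interval (half-open point query); nested TEs resolve to the
   smallest (most specific) element.
4. **Reference-guided merge.**  One consensus chain per cluster: the
   member sharing most splice sites with a single reference transcript
   (ties: more exons, longer span, then lexicographic for determinism),
   its first exon rebuilt from the corrected TSS to the donor; the gene
   is taken from the best-matching reference transcript when at least
   one splice site is shared.  Keeping one consensus chain (rather than
   all distinct member chains) was an open choice; one chain per
   TSS-cluster keeps the catalogue unit identifiable with its promoter.

Catalogue IDs (`TE_000001`, ...) are assigned in (chrom, TSS, strand)
order, so identical inputs reproduce identical catalogues byte for byte.

# Quantification

A transcript is *expressed* in a sample iff at least one junction read
supports its first intron — donor and acceptor must both match exactly
(tolerance 0 bp): the first splice junction is the one part of a
TE-initiated transcript's structure that is unambiguous in short reads.
Family-level promoter activity sums first-exon junction counts per TE
family and normalizes per million total mapped reads (the totals are
caller-provided; the per-million scale is this package's choice and is
recorded in the output units).  Transcript-level TPM-style abundance is
out of scope — the downstream statistics all operate on the junction
counts and the expressed flags.

# Classification

Structural categories partition the catalogue by shared splice sites
with the reference: `annotated` (all sites known), `chimeric` (some
known, some novel — for TE-initiated transcripts the novel site is the
TE-contributed 5' donor), `intergenic` (no site known).

Coding consequence uses a deliberately self-contained rule instead of
external coding-potential/homology tools: the longest ATG-initiated ORF
(stop required inside the transcript) with at least `min_codons`
(default 100) codons, mapped back through the exon chain, then compared
with the assigned gene's annotated CDS by exact interval-and-frame
algebra on transcription-ordered base chains.  The six labels hinge on
the longest common 3'-coterminal run: identical (`annotated`); in-frame
proper suffix, no novel sequence (`five_prime_truncated`); novel 5'
segment joined in frame to the complete annotated CDS
(`five_prime_chimeric_normal`) or to a proper suffix
(`five_prime_chimeric_truncated`); coding with no in-frame shared run
(`novel`); no ORF (`non_coding`).  "Normal" versus "truncated" chimeric
hinges on whether the full annotated CDS is covered — these operational
definitions are this package's, chosen to be exact and testable, and any
out-of-frame overlap deliberately demotes to `novel` rather than
guessing.

# Cohort statistics

The tumour-specific score per transcript is
$S = \frac{(T_e+1)/T_t}{(N_e+1)/N_t}$ over expressing-sample counts,
with testicular normal samples excluded via the cohort `tissue` tag
(immune-privileged testis expresses many TEs).  The flag defaults to the
strict $S > 8$; since "greater than" and ">= 8" both circulate, the
comparator is an explicit option.  Tumour-type preference and family
enrichment use two-tailed Fisher tests (odds ratio reported as sample
$ad/bc$ with Haldane 0.5 when a cell is empty); calls require OR >= 3
and FDR < 0.05.  Clinical associations: Wilcoxon rank-sum
(tumour vs normal; exact permutation when combined n <= 12 — the exact
branch is enumerated explicitly so ties are handled — normal
approximation otherwise), Kruskal–Wallis across stages, and the
log-rank test with hazard ratio $(O_1/E_1)/(O_2/E_2)$ between expressing
and non-expressing samples (median split for continuous family
activity, where no natural expressed/not dichotomy exists).
Benjamini–Hochberg correction is applied within each analysis family
separately, never pooled across unrelated analyses.  The Tau
tissue-specificity index uses the standard max-normalized form
$\tau = \sum_i (1 - x_i/x_{\max})/(n-1)$.

# The synthetic cohort

`sim_config()` defines the study conditions; `simulate_reference()` and
`simulate_cohort()` realize them.  The generator emulates exactly the
inputs the pipeline consumes — genome FASTA, TE BED, reference GTF with
CDS, per-sample assembled GTFs, two-channel coverage, junction tables,
cap-label tracks, cohort metadata — plus a truth manifest.

Defaults (chosen once, as a realistic miniature): 200 kb genome over 2
chromosomes; 10 three-exon reference genes whose CDS regions are recoded
into genuine ATG...stop ORFs; 30 TE loci from 6 families spanning the
young-to-old range (L1HS ... MER20) with family-typical divergence
values; 20 planted TE-initiated chimeras (TSS inside a dedicated TE
upstream of a gene, novel first-exon donor, then the gene's exons 2–3);
100 tumour + 100 normal samples.  Five planted transcripts are
tumour-specific (never in normals; 0.5/0.1 expression in the two tumour
types, 0.3 overall), the rest null at 0.3 in both arms; transcript 1
carries a hazard ratio of 3 for expressing tumours (exponential
survival, baseline 0.01/day, uniform censoring to 150 days).  A promoter
consensus (TATA element 30 bp upstream, initiator at the start site) is
written into the genome at every true TSS; assembled 5' ends are
jittered by rounded Normal(0, 20 bp); per-transcript depth is lognormal
(sdlog 1.2) around 50x so that window difficulty spans the dynamic range
real expression has; junction counts are negative-binomial (mean 10 at
50x, scaling with depth, dispersion 0.5) so the ">= 1 junction read"
rule occasionally fails honestly; cap labels are point masses at the
*true* TSS, Gaussian-smoothed with sigma 2 bp (a minimal stand-in for
cap read-count profiles).  Noise assemblies — degradation fragments
whose first exon sits inside a gene's internal exon, and TE-free
intergenic transcripts — are present at 0.2 per sample and exercise the
filters.

What the generator does *not* emulate: read-level artifacts, alignment
ambiguity beyond the second coverage channel, assembler structural
errors, TE nesting/fragmentation, inter-sample batch effects, and any
biological correlation structure between transcripts.  Green tests here
demonstrate that the machinery is correct under its stated model, not
that the model captures everything real cohorts do.

# Numerical choices and reproducibility

Everything stochastic flows from integer seeds (`sim_config(seed=)`
fixes the reference, and the cohort stream is derived from it;
`train_config(seed=)` fixes weight initialization and shuffling).  TSS
jitter is a rounded Normal draw, so outputs are integer coordinates and
byte-identical across runs.  Degenerate inputs are defined, not
accidental: empty cap targets are valid negatives; all-constant value
vectors give statistic 0 / p 1 in the rank tests; zero-variance vectors
make Spearman `NA` with a warning; clusters whose corrected TSS is not
5' of the donor cannot form a first exon and are dropped.

Test and validation problem sizes are the package's own: unit tests run
a 60 kb, 10-sample miniature; the validation suite trains a reduced
model (flank 1000 bp, ~200 windows, 3 epochs, batch 16 — smaller batches
give the short schedule more update steps) and runs the full default
cohort (200 samples, 20 planted transcripts) end to end.  At these sizes
the whole suite trains and evaluates in minutes on one CPU core.

# Known limitations

- The model's published-scale counterpart trains on real cap data over
  10 kb flanks; here architecture depth/width and flank are
  config-driven and validated at reduced scale.
- Single-exon TE transcripts and TE exonization (TE sequence spliced
  internally) are out of scope by construction.
- Coding classification is coordinate-exact and will not recognize a
  homologous-but-shifted CDS the way a protein alignment would.
- Family activity normalizes by caller-supplied totals; no
  between-sample normalization beyond per-million is applied.
- The weight-score formula's division by neighbour support is kept as
  stated; under heavy multi-position jitter the `support_proportional`
  variant may be preferable, and both are exposed.
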