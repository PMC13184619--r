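# teit — transposable-element-initiated transcript discovery and scoring

`teit` finds transcripts that initiate inside annotated transposable
elements (TEs) in assembled short-read RNA-seq transcriptomes, and scores
them for tumour specificity and clinical association.  It is aimed at
transcriptomics researchers studying TE promoter reactivation in cancer
cohorts: onco-exaptation, chimeric TE–gene transcripts, and candidate
tumour-specific antigens.

Assemblers recover splice structure well but place transcript 5' ends
poorly, and calling a transcript "TE-initiated" depends entirely on where
its transcription start site (TSS) is.  The package therefore:

1. **re-predicts each transcript's TSS** with a convolutional network over
   a window centred on the first splice donor — 4 one-hot DNA channels
   plus 2 RNA-seq coverage channels (unique/multi-mapping) — trained
   against cap-based TSS labels with the KL loss

   *L* = Σᵢ *t*ᵢ\*[ln(*t*ᵢ\* + ε) − ln(*p*ᵢ\* + ε)],  ε = e⁻¹⁰

   (Adam, lr 0.005, batch 64, ≤ 10 epochs);
2. **corrects TSSs across samples** per splice-donor cluster with the
   support-weighted score *Sₜ* = *sₜ* + Σ_k (*w* − *d*_k)/(*w·s*_k),
   keeps corrected TSSs falling inside a TE, and merges each cluster into
   a reference-guided consensus transcript;
3. **quantifies** expression as first-exon junction read counts
   (expressed ⇔ ≥ 1 junction read) and TE-family promoter activity
   (junction counts per family, per million mapped reads);
4. **classifies** each catalogue entry structurally (annotated /
   chimeric / intergenic) and by coding consequence (six classes from
   exact CDS interval-and-frame algebra);
5. **scores cohorts**: tumour-specific score
   *S* = ((*T*ₑ+1)/*T*ₜ)/((*N*ₑ+1)/*N*ₜ) (flag at *S* > 8), Fisher/BH
   enrichment and tumour-type preference, Wilcoxon / Kruskal–Wallis /
   log-rank (+ hazard ratio) clinical tests, Tau tissue specificity;
6. **validates** against cap-signal gold standards (±100 bp precision,
   metaprofiles, Spearman concordance).

A seeded synthetic-cohort generator (`sim_config()`,
`simulate_reference()`, `simulate_cohort()`) produces a miniature genome,
TE annotation, reference genes, and a tumour/normal cohort with planted
TE-initiated transcripts and a full ground-truth manifest, so the entire
workflow is testable offline.  See the methods vignette
(`vignettes/te-initiated-transcripts.Rmd`) for the model, assumptions and
design decisions.

## Worked example

```r
library(teit)

cfg <- sim_config(n_tumour = 30, n_normal = 10, seed = 11)
ref <- simulate_reference(cfg)
co  <- simulate_cohort(cfg, ref)

model <- train_cohort_model(co, ref, flank = 1000,
                            sample_ids = names(co$samples)[1:15],
                            config = train_config(batch_size = 16,
                                                  max_epochs = 3, seed = 3),
                            max_windows = 200)
round(model$loss_history, 3)
#> [1] 3.008 0.645 0.309

res <- run_te_pipeline(model, co, ref)
res$catalogue
#> <teit_catalogue> 20 TE-initiated transcript(s)
head(res$catalogue$table[, c("teit_id", "chrom", "strand", "corrected_tss",
                             "family", "gene_id", "n_supporting_samples")], 3)
#>     teit_id chrom strand corrected_tss family gene_id n_supporting_samples
#> 1 TE_000001  chr1      +          1543  L1PA2 gene_01                    8
#> 2 TE_000002  chr1      +          2327   L1HS gene_01                    9
#> 3 TE_000003  chr1      -         20167 AluYa5 gene_02                    5
```

The training loss falls by an order of magnitude in three epochs; the
catalogue recovers all 20 planted TE-initiated transcripts (corrected TSS
within 0–2 bp of truth on this example), each anchored in its TE family
and assigned to its downstream gene, supported by 5–16 of the 40
samples.  Downstream:

```r
ts <- tumour_specificity(res$expression, co$cohort)
cl <- classify_catalogue(res$catalogue, ref$ref_transcripts, ref$genome)
sv <- clinical_tests(res$expression$counts, co$cohort, tests = "survival")
```

A thin command-line front end over the same functions is provided in
`inst/cli/teit.R` (subcommands `simulate`, `train`, `predict`, `detect`,
`quantify`, `classify`, `score`, `evaluate`).

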