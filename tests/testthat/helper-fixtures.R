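# Shared fixtures, built once per test run and cached.
#
# tiny_*: a 60 kb cohort (6 tumour + 4 normal, 4 planted transcripts) for
# fast unit tests.  acc_*: the full study-condition cohort (defaults of
# sim_config: 100 + 100 samples, 20 planted transcripts) plus a reduced
# model (flank 1000, ~200 windows, 3 epochs) shared by the model-sanity
# and end-to-end tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_config <- function(seed = 5L)
  sim_config(genome_length = 60000L, n_chroms = 2L, n_te_loci = 8L,
             n_ref_genes = 3L, n_planted_te_transcripts = 4L,
             n_tumour = 6L, n_normal = 4L, n_tumour_specific = 2L,
             n_noise = 4L, seed = seed)

tiny_reference <- function()
  fixture("tiny_ref", function() simulate_reference(tiny_config()))

tiny_cohort <- function()
  fixture("tiny_co", function() simulate_cohort(tiny_config(), tiny_reference()))

tiny_model <- function() fixture("tiny_model", function() {
  tr <- cohort_windows(tiny_cohort(), tiny_reference(), flank = 768L,
                       max_windows = 100L, seed = 2L)
  train_tss_model(tr$windows, tr$targets,
                  train_config(batch_size = 16L, max_epochs = 10L, seed = 3L),
                  filters = 8L)
})

tiny_pipeline <- function()
  fixture("tiny_pipe", function()
    run_te_pipeline(tiny_model(), tiny_cohort(), tiny_reference()))

# --- full-scale (study-condition) fixtures --------------------------------

acc_config <- function() sim_config(seed = 20L)

acc_reference <- function()
  fixture("acc_ref", function() simulate_reference(acc_config()))

acc_cohort <- function()
  fixture("acc_co", function() simulate_cohort(acc_config(), acc_reference()))

acc_train_samples <- function() names(acc_cohort()$samples)[1:12]

acc_model <- function() fixture("acc_model", function()
  train_cohort_model(acc_cohort(), acc_reference(), flank = 1000L,
                     sample_ids = acc_train_samples(),
                     config = train_config(batch_size = 16L, max_epochs = 3L,
                                           seed = 7L),
                     max_windows = 200L, filters = 16L))

acc_heldout <- function() fixture("acc_heldout", function()
  cohort_windows(acc_cohort(), acc_reference(), flank = 1000L,
                 sample_ids = names(acc_cohort()$samples)[13:30],
                 max_windows = 200L, negative_ratio = 0, seed = 8L))

acc_pipeline <- function()
  fixture("acc_pipe", function()
    run_te_pipeline(acc_model(), acc_cohort(), acc_reference()))

# catalogue row index for each planted transcript (by donor key), NA if absent
match_planted <- function(catalogue, planted) {
  key <- paste(catalogue$table$chrom, catalogue$table$strand,
               catalogue$table$donor)
  match(paste(planted$chrom, planted$strand, planted$donor), key)
}

# build a small transcript quickly
tx <- function(id, chrom, strand, starts, ends, gene = NA_character_,
               sample = NA_character_, cds = NULL)
  transcript_model(id, chrom, strand, data.frame(start = starts, end = ends),
                   gene_id = gene, sample_id = sample, cds = cds)
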