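#' Predict TSSs for every assembled transcript of a cohort
#'
#' Encodes one window per multi-exon transcript against its sample's
#' coverage and applies the trained model.  When `keys` is given (a
#' `data.frame` with `sample_id`, `transcript_id`), only those records
#' are predicted — the detection driver uses this to skip transcripts
#' already removed by the degradation filter.
#'
#' @param model a trained `tss_model`.
#' @param cohort a `te_cohort`.
#' @param genome named `DNAStringSet`.
#' @param keys optional record subset.
#' @return `data.frame`: `sample_id`, `transcript_id`, `chrom`,
#'   `position`, `strand`, `score`.
#' @export
predict_cohort_tss <- function(model, cohort, genome, keys = NULL) {
  rows <- list()
  for (sid in names(cohort$samples)) {
    sm <- cohort$samples[[sid]]
    want <- if (is.null(keys)) NULL
            else keys$transcript_id[keys$sample_id == sid]
    for (tx in sm$transcripts) {
      if (n_exons(tx) < 2) next
      if (!is.null(want) && !tx$transcript_id %in% want) next
      w <- encode_window(genome, sm$coverage, tx, model$flank)
      pr <- predict_tss(model, w)
      pr$sample_id <- sid
      rows[[length(rows) + 1L]] <- pr
    }
  }
  out <- do.call(rbind, rows)
  out[, c("sample_id", "transcript_id", "chrom", "position", "strand", "score")]
}

#' Train a TSS model on windows drawn from a simulated cohort
#'
#' Convenience wrapper: [cohort_windows()] on the requested samples, then
#' [train_tss_model()].
#'
#' @param cohort,reference simulated cohort and reference.
#' @param flank half-window size (bp).
#' @param sample_ids training samples.
#' @param config a [train_config()].
#' @param max_windows cap on training windows.
#' @param ... architecture arguments forwarded to [tss_net()].
#' @return a `tss_model`.
#' @export
train_cohort_model <- function(cohort, reference, flank = 1000L,
                               sample_ids = names(cohort$samples),
                               config = train_config(), max_windows = 400L,
                               ...) {
  tr <- cohort_windows(cohort, reference, flank, sample_ids,
                       max_windows = max_windows, seed = config$seed)
  train_tss_model(tr$windows, tr$targets, config, ...)
}

#' Run detection, quantification and scoring over a simulated cohort
#'
#' End-to-end driver: first-exon extraction and degradation filtering over
#' the pooled assemblies, TSS prediction for the retained records,
#' clustering/correction/TE-intersection/merging into a catalogue, then
#' first-exon junction quantification and family activity.
#'
#' @param model a trained `tss_model`.
#' @param cohort a `te_cohort`.
#' @param reference the matching `te_reference`.
#' @param w TSS-correction window (bp).
#' @param min_score model confidence threshold for record retention.
#' @return list: `catalogue`, `predictions`, `expression`
#'   (`expression_matrix`), `activity` (family x sample matrix).
#' @export
run_te_pipeline <- function(model, cohort, reference, w = 100,
                            min_score = 0.1) {
  pool <- unlist(lapply(cohort$samples, `[[`, "transcripts"),
                 recursive = FALSE)
  fe <- extract_first_exons(pool)
  fe_kept <- degradation_filter(fe, pool)
  preds <- predict_cohort_tss(model, cohort, reference$genome,
                              keys = fe_kept[, c("sample_id", "transcript_id")])
  catalogue <- detect_te_transcripts(preds, pool, reference$ref_transcripts,
                                     reference$te, w = w,
                                     min_score = min_score)
  if (nrow(catalogue$table) == 0)
    return(list(catalogue = catalogue, predictions = preds,
                expression = NULL, activity = NULL))
  jt <- lapply(cohort$samples, `[[`, "junctions")
  totals <- vapply(cohort$samples, `[[`, numeric(1), "total_mapped_reads")
  expression <- count_first_exon_junctions(catalogue, jt, totals)
  activity <- family_activity(expression, catalogue)
  list(catalogue = catalogue, predictions = preds, expression = expression,
       activity = activity)
}
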