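#' Build encoded training/validation windows from a simulated cohort
#'
#' Walks the requested samples, encodes one window per multi-exon
#' assembled transcript (anchored at its first splice donor) against that
#' sample's coverage, and slices the sample's cap-label track as the
#' target.  Windows whose target carries cap mass are positives; windows
#' without (noise assemblies) are negatives.  Negatives are subsampled to
#' at most `negative_ratio` times the positive count.
#'
#' @param cohort a `te_cohort` from [simulate_cohort()].
#' @param reference the matching `te_reference`.
#' @param flank half-window size in bp.
#' @param sample_ids samples to draw windows from (default: all).
#' @param max_windows cap on the number of windows returned (stratified
#'   draw, seeded).
#' @param negative_ratio maximum negatives per positive (default 1).
#' @param seed seed for the subsampling draws.
#' @return list with `windows` (list of `encoded_window`), `targets`
#'   (list of numeric vectors), and `truth` (`data.frame` with `uid`,
#'   `sample_id`, `transcript_id`, `origin`, `true_tss`; `NA` true TSS
#'   for noise windows).
#' @export
cohort_windows <- function(cohort, reference, flank = 1000L,
                           sample_ids = names(cohort$samples),
                           max_windows = Inf, negative_ratio = 1,
                           seed = 1L) {
  true_tss_of <- local({
    ids <- c(vapply(reference$ref_transcripts, `[[`, character(1), "transcript_id"),
             reference$planted$truth_id)
    pos <- c(vapply(reference$ref_transcripts, tss_position, numeric(1)),
             reference$planted$true_tss)
    stats::setNames(pos, ids)
  })
  origins <- cohort$manifest$origins
  windows <- list(); targets <- list(); truth <- list()
  for (sid in sample_ids) {
    sm <- cohort$samples[[sid]]
    for (tx in sm$transcripts) {
      if (n_exons(tx) < 2) next
      w <- encode_window(reference$genome, sm$coverage, tx, flank)
      t <- encode_target(sm$cap, w)
      org <- origins$origin[origins$sample_id == sid &
                              origins$transcript_id == tx$transcript_id]
      uid <- paste(sid, tx$transcript_id, sep = ".")
      w$transcript_id <- uid
      windows[[uid]] <- w
      targets[[uid]] <- t
      truth[[uid]] <- data.frame(
        uid = uid, sample_id = sid, transcript_id = tx$transcript_id,
        origin = org,
        true_tss = if (org %in% names(true_tss_of)) true_tss_of[[org]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  pos <- vapply(targets, function(t) sum(t) > 0, logical(1))
  set.seed(seed)
  keep_neg <- which(!pos)
  n_neg_max <- floor(negative_ratio * sum(pos))
  if (length(keep_neg) > n_neg_max)
    keep_neg <- sort(sample(keep_neg, n_neg_max))
  keep <- sort(c(which(pos), keep_neg))
  if (length(keep) > max_windows) keep <- sort(sample(keep, max_windows))
  list(windows = windows[keep], targets = targets[keep],
       truth = truth[keep, , drop = FALSE])
}
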