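#' Extract first-exon records from pooled multi-exon transcripts
#'
#' @param transcripts list of [transcript_model()] (typically pooled
#'   across samples, with `sample_id` set).
#' @return `data.frame`: `sample_id`, `transcript_id`, `chrom`, `strand`,
#'   `fe_start`, `fe_end`, `donor`.  Single-exon transcripts are skipped.
#' @export
extract_first_exons <- function(transcripts) {
  rows <- lapply(transcripts, function(tx) {
    if (n_exons(tx) < 2) return(NULL)
    fe <- first_exon(tx)
    data.frame(sample_id = tx$sample_id, transcript_id = tx$transcript_id,
               chrom = tx$chrom, strand = tx$strand,
               fe_start = fe$exon$start, fe_end = fe$exon$end,
               donor = fe$donor, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      fe_start = integer(), fe_end = integer(),
                      donor = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Drop first exons that overlap internal exons (degradation filter)
#'
#' A first exon overlapping (by at least 1 bp) an internal exon — any exon
#' of a multi-exon transcript other than its first and last — of another
#' transcript in the pooled set is likely a truncated degradation product
#' rather than a genuine alternative start, and is excluded.  Comparison
#' is on the same chromosome and, by default, the same strand (antisense
#' overlap is not degradation of the same RNA).
#'
#' @param first_exons `data.frame` from [extract_first_exons()].
#' @param transcripts the pooled transcript list the internal exons are
#'   drawn from.
#' @param strand_aware compare only same-strand exons (default `TRUE`).
#' @return the retained subset of `first_exons`.
#' @export
degradation_filter <- function(first_exons, transcripts, strand_aware = TRUE) {
  internals <- do.call(rbind, lapply(transcripts, function(tx) {
    ie <- internal_exons(tx)
    if (nrow(ie) == 0) return(NULL)
    data.frame(chrom = tx$chrom, strand = tx$strand, start = ie$start,
               end = ie$end, owner = paste(tx$sample_id, tx$transcript_id),
               stringsAsFactors = FALSE)
  }))
  if (is.null(internals) || nrow(first_exons) == 0) return(first_exons)
  fe_key <- paste(first_exons$sample_id, first_exons$transcript_id)
  drop <- logical(nrow(first_exons))
  fe_gr <- GenomicRanges::GRanges(
    first_exons$chrom,
    IRanges::IRanges(first_exons$fe_start + 1L, first_exons$fe_end),
    strand = if (strand_aware) first_exons$strand else "*")
  in_gr <- GenomicRanges::GRanges(
    internals$chrom, IRanges::IRanges(internals$start + 1L, internals$end),
    strand = if (strand_aware) internals$strand else "*")
  hits <- GenomicRanges::findOverlaps(fe_gr, in_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  drop[unique(qh[internals$owner[sh] != fe_key[qh]])] <- TRUE
  first_exons[!drop, , drop = FALSE]
}

#' Support-weighted TSS position score
#'
#' For a candidate position `t` supported by `s_t` samples:
#' \deqn{S_t = s_t + \sum_{k \in T} \frac{w - d_k}{w \cdot s_k}}
#' where `T` is the set of other supported positions at distance
#' \eqn{d_k < w} from `t`.  Note that, as printed, a neighbour's
#' contribution is divided by its own support \eqn{s_k}; the
#' `support_proportional` alternative \eqn{(w - d_k) s_k / w} is available
#' for sensitivity analysis.
#'
#' @param t candidate position.
#' @param support named numeric vector: supported position -> number of
#'   distinct supporting samples (all >= 1).
#' @param w window size in bp (> 0).
#' @param neighbor_weighting `"as_printed"` (default) or
#'   `"support_proportional"`.
#' @return scalar score `S_t >= s_t`.
#' @export
weight_score <- function(t, support, w, neighbor_weighting = "as_printed") {
  if (w <= 0) stop("window size w must be > 0")
  pos <- as.numeric(names(support))
  st <- support[[as.character(t)]]
  if (is.null(st)) stop("t must be a supported position")
  d <- abs(pos - t)
  nb <- d < w & pos != t
  contrib <- if (neighbor_weighting == "as_printed")
    (w - d[nb]) / (w * support[nb])
  else
    (w - d[nb]) * support[nb] / w
  st + sum(contrib)
}

#' Correct a TSS cluster to its best-supported position
#'
#' Returns the supported position maximizing [weight_score()]; ties are
#' broken by higher raw support `s_t`, then by the 5'-most position in
#' transcription order (smallest coordinate on `+`, largest on `-`).
#'
#' @param support named numeric vector (position -> sample count).
#' @param w window size passed to [weight_score()].
#' @param strand cluster strand, for the 5'-most tie-break.
#' @param neighbor_weighting see [weight_score()].
#' @return corrected position (integer).
#' @export
correct_tss <- function(support, w = 100, strand = "+",
                        neighbor_weighting = "as_printed") {
  if (length(support) == 0) stop("empty support map")
  pos <- as.numeric(names(support))
  S <- vapply(pos, function(t) weight_score(t, support, w, neighbor_weighting),
              numeric(1))
  best <- which(S >= max(S) - 1e-9)
  if (length(best) > 1) {
    smax <- max(support[best])
    best <- best[support[best] == smax]
  }
  if (length(best) > 1)
    best <- if (strand == "+") best[which.min(pos[best])]
            else best[which.max(pos[best])]
  as.integer(pos[best])
}

#' Find the TE annotation containing a corrected TSS
#'
#' Point-in-interval query (half-open).  When nested TEs both contain the
#' position, the smallest (most specific) interval wins.  TE strand is
#' ignored: a TE promoter can fire in either orientation relative to the
#' element.
#'
#' @param chrom,pos the corrected TSS.
#' @param te TE annotation `data.frame` (see [read_bed_te()]).
#' @return the matching TE row, or `NULL` when the TSS is in no TE.
#' @export
te_filter <- function(chrom, pos, te) {
  hit <- te[te$chrom == chrom & te$start <= pos & pos < te$end, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit[which.min(hit$end - hit$start), , drop = FALSE]
}

#' Merge a TSS cluster into one consensus transcript
#'
#' Picks the member chain whose splice sites best match a single
#' reference transcript (most shared sites; ties broken by more exons,
#' then longer genomic span, then lexicographically for determinism), and
#' rebuilds its first exon from the corrected TSS to the shared donor.
#' The gene is taken from the best-matching reference transcript when at
#' least one splice site is shared.
#'
#' @param members list of member [transcript_model()]s (all sharing the
#'   cluster donor).
#' @param corrected_tss the cluster's corrected TSS.
#' @param reference list of reference [transcript_model()]s.
#' @return list with `transcript` (the merged chain; `NULL` when the
#'   corrected TSS is not 5' of the donor) and `gene_id` (`NA` when no
#'   site is shared).
#' @export
merge_transcripts <- function(members, corrected_tss, reference) {
  ref_sites <- lapply(reference, splice_sites)
  score_member <- function(tx) {
    s <- splice_sites(tx)
    shared <- vapply(ref_sites, function(r) length(intersect(s, r)), integer(1))
    j <- which.max(shared)
    c(shared = shared[j], ref = j)
  }
  sc <- vapply(members, score_member, numeric(2))
  span <- vapply(members, function(tx) max(tx$exons$end) - min(tx$exons$start),
                 numeric(1))
  nex <- vapply(members, n_exons, integer(1))
  uid <- vapply(members, function(tx) paste(tx$sample_id, tx$transcript_id),
                character(1))
  ord <- order(-sc["shared", ], -nex, -span, uid)
  best <- members[[ord[1]]]
  gene_id <- if (sc["shared", ord[1]] >= 1)
    reference[[sc["ref", ord[1]]]]$gene_id else NA_character_

  ex <- best$exons
  if (best$strand == "+") {
    donor <- ex$end[1]
    if (corrected_tss >= donor) return(list(transcript = NULL, gene_id = gene_id))
    ex$start[1] <- corrected_tss
  } else {
    n <- nrow(ex)
    donor <- ex$start[n]
    if (corrected_tss < donor) return(list(transcript = NULL, gene_id = gene_id))
    ex$end[n] <- corrected_tss + 1L
  }
  merged <- transcript_model(best$transcript_id, best$chrom, best$strand, ex,
                             gene_id = gene_id)
  list(transcript = merged, gene_id = gene_id)
}

#' Build the cross-sample catalogue of TE-initiated transcripts
#'
#' Full detection pass: first-exon extraction, degradation filtering,
#' prediction-score thresholding, clustering by exact splice-donor
#' coordinate, support-weighted TSS correction, TE intersection, and
#' reference-guided merging.  Catalogue IDs (`TE_000001`, ...) are
#' assigned in (chrom, corrected TSS, strand) order, so re-running on the
#' same inputs reproduces them exactly.
#'
#' @param predictions `data.frame` with `sample_id`, `transcript_id`,
#'   `chrom`, `position`, `strand`, `score` (one row per assembled
#'   transcript, from [predict_tss()]).
#' @param transcripts pooled list of per-sample assembled
#'   [transcript_model()]s (with `sample_id` set).
#' @param reference list of reference [transcript_model()]s.
#' @param te TE annotation `data.frame`.
#' @param w TSS-correction window in bp (default 100).
#' @param min_score minimum model confidence for a record to enter
#'   clustering (default 0.1).
#' @param strand_aware_degradation see [degradation_filter()].
#' @param neighbor_weighting see [weight_score()].
#' @return object of class `teit_catalogue`: list with `table` (one row
#'   per catalogue entry) and `transcripts` (named list of merged
#'   chains).
#' @export
detect_te_transcripts <- function(predictions, transcripts, reference, te,
                                  w = 100, min_score = 0.1,
                                  strand_aware_degradation = TRUE,
                                  neighbor_weighting = "as_printed") {
  fe <- extract_first_exons(transcripts)
  fe <- degradation_filter(fe, transcripts, strand_aware_degradation)
  key <- paste(fe$sample_id, fe$transcript_id)
  pkey <- paste(predictions$sample_id, predictions$transcript_id)
  i <- match(key, pkey)
  if (anyNA(i))
    stop("missing TSS predictions for ", sum(is.na(i)), " first-exon record(s)")
  fe$predicted_tss <- predictions$position[i]
  fe$score <- predictions$score[i]
  fe <- fe[fe$score >= min_score, , drop = FALSE]

  txmap <- stats::setNames(transcripts,
                           vapply(transcripts, function(tx)
                             paste(tx$sample_id, tx$transcript_id), character(1)))
  fe$cluster <- paste(fe$chrom, fe$strand, fe$donor, sep = ":")
  entries <- list()
  for (cl in unique(fe$cluster)) {
    d <- fe[fe$cluster == cl, , drop = FALSE]
    # distinct samples supporting each predicted position
    sup_df <- unique(d[, c("sample_id", "predicted_tss")])
    support <- table(sup_df$predicted_tss)
    support <- stats::setNames(as.numeric(support), names(support))
    tss <- correct_tss(support, w, d$strand[1], neighbor_weighting)
    hit <- te_filter(d$chrom[1], tss, te)
    if (is.null(hit)) next
    members <- txmap[paste(d$sample_id, d$transcript_id)]
    mg <- merge_transcripts(members, tss, reference)
    if (is.null(mg$transcript)) next
    entries[[cl]] <- list(
      row = data.frame(chrom = d$chrom[1], strand = d$strand[1],
                       corrected_tss = tss, donor = d$donor[1],
                       te_name = hit$te_name, family = hit$family,
                       superfamily = hit$superfamily, te_class = hit$te_class,
                       gene_id = mg$gene_id,
                       n_supporting_samples = length(unique(d$sample_id)),
                       stringsAsFactors = FALSE),
      tx = mg$transcript)
  }
  if (length(entries) == 0)
    return(structure(list(table = data.frame(), transcripts = list()),
                     class = "teit_catalogue"))
  tab <- do.call(rbind, lapply(entries, `[[`, "row"))
  ord <- order(tab$chrom, tab$corrected_tss, tab$strand)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(teit_id = sprintf("TE_%06d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  txs <- lapply(entries, `[[`, "tx")[ord]
  for (j in seq_along(txs)) {
    txs[[j]]$transcript_id <- tab$teit_id[j]
    txs[[j]]$gene_id <- tab$gene_id[j]
    txs[[j]]$sample_id <- NA_character_
  }
  names(txs) <- tab$teit_id
  structure(list(table = tab, transcripts = txs), class = "teit_catalogue")
}

#' @export
print.teit_catalogue <- function(x, ...) {
  cat(sprintf("<teit_catalogue> %d TE-initiated transcript(s)\n", nrow(x$table)))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Write a catalogue to TSV (and optionally GTF)
#' @param catalogue a `teit_catalogue`.
#' @param tsv_path output table path.
#' @param gtf_path optional path for the merged transcript models.
#' @return `tsv_path`, invisibly.
#' @export
write_catalogue <- function(catalogue, tsv_path, gtf_path = NULL) {
  write.table(catalogue$table, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(gtf_path)) write_gtf(catalogue$transcripts, gtf_path)
  invisible(tsv_path)
}
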