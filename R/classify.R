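#' Structural category of a catalogue transcript
#'
#' Relative to the reference splice-site set (strand-aware):
#' `annotated` — every splice site of the transcript is a reference site;
#' `chimeric` — at least one reference site is shared but at least one
#' site is novel (in a TE-initiated transcript the novel site is the 5'
#' donor contributed by the TE first exon); `intergenic` — no site is
#' shared.  The three categories are exhaustive and mutually exclusive.
#'
#' @param transcript a multi-exon [transcript_model()].
#' @param reference list of reference [transcript_model()]s.
#' @return one of `"annotated"`, `"chimeric"`, `"intergenic"`.
#' @export
categorize_transcript <- function(transcript, reference) {
  ref_sites <- unique(unlist(lapply(reference, splice_sites)))
  s <- splice_sites(transcript)
  shared <- s %in% ref_sites
  if (all(shared)) "annotated"
  else if (any(shared)) "chimeric"
  else "intergenic"
}

#' Longest open reading frame of a spliced transcript
#'
#' Scans the three forward frames of the mature (spliced, sense-strand)
#' sequence for the longest ATG-initiated ORF terminated by a stop codon
#' within the transcript.  The transcript is called coding when the ORF
#' has at least `min_codons` codons (stop excluded).  The CDS — ATG
#' through stop codon inclusive — is mapped back to genomic intervals
#' through the exon chain.
#'
#' @param transcript a [transcript_model()].
#' @param genome named `DNAStringSet`.
#' @param min_codons minimum protein length in codons (default 100).
#' @return `NULL` when no qualifying ORF exists, else a list with
#'   `n_codons`, `tstart`/`tend` (transcript coordinates, half-open,
#'   stop included) and `cds` (genomic interval `data.frame`).
#' @export
predict_orf <- function(transcript, genome, min_codons = 100L) {
  seq <- as.character(spliced_sequence(transcript, genome))
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_idx <- which(is_stop)
    for (a in which(is_atg)) {
      s <- stop_idx[stop_idx > a]
      if (length(s) == 0) next
      s <- s[1]
      ncod <- s - a  # codons ATG..(stop-1)
      if (ncod >= min_codons && (is.null(best) || ncod > best$n_codons)) {
        best <- list(n_codons = ncod,
                     tstart = starts[a] - 1L,
                     tend = starts[s] + 2L)  # stop codon included
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$cds <- transcript_interval_to_genome(transcript, best$tstart, best$tend)
  best
}

# genomic bases of a CDS chain in transcription order
cds_bases <- function(cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  if (strand == "+") {
    unlist(lapply(seq_len(nrow(cds)), function(i)
      seq.int(cds$start[i], cds$end[i] - 1L)))
  } else {
    unlist(lapply(rev(seq_len(nrow(cds))), function(i)
      seq.int(cds$end[i] - 1L, cds$start[i])))
  }
}

#' Coding-consequence class of a predicted CDS
#'
#' Compares the predicted CDS with the annotated CDS of the assigned gene
#' by exact coordinate algebra on transcription-ordered base chains:
#'
#' * `annotated` — identical CDS;
#' * `five_prime_truncated` — the predicted CDS is an in-frame,
#'   3'-coterminal proper suffix of the annotated CDS (no novel
#'   sequence);
#' * `five_prime_chimeric_normal` — a novel 5' segment joined in frame to
#'   the complete annotated CDS (annotated interval fully covered, same
#'   stop);
#' * `five_prime_chimeric_truncated` — a novel 5' segment joined in frame
#'   to a 3'-coterminal proper suffix of the annotated CDS;
#' * `novel` — coding but sharing no in-frame 3'-coterminal run with the
#'   annotated CDS (including: no overlap at all, frame shift over the
#'   shared part, different stop, or no gene assignment);
#' * `non_coding` — no qualifying ORF.
#'
#' @param predicted output of [predict_orf()] (or `NULL`).
#' @param annotated_cds the assigned gene's annotated CDS intervals
#'   (`data.frame` with `start`, `end`), or `NULL` when the transcript
#'   has no gene assignment.
#' @param strand shared strand of the two CDS chains.
#' @return one of the six class labels.
#' @export
coding_class <- function(predicted, annotated_cds, strand = "+") {
  if (is.null(predicted)) return("non_coding")
  if (is.null(annotated_cds)) return("novel")
  p <- cds_bases(predicted$cds, strand)
  a <- cds_bases(annotated_cds, strand)
  if (length(p) == length(a) && all(p == a)) return("annotated")
  if (length(intersect(p, a)) == 0) return("novel")
  # longest common suffix of the transcription-ordered base chains
  nsuf <- 0L
  while (nsuf < min(length(p), length(a)) &&
         p[length(p) - nsuf] == a[length(a) - nsuf]) nsuf <- nsuf + 1L
  if (nsuf == 0L) return("novel")
  if ((length(p) - nsuf) %% 3L != 0L || (length(a) - nsuf) %% 3L != 0L)
    return("novel")  # shared 3' run out of frame
  if (nsuf == length(p)) return("five_prime_truncated")
  if (nsuf == length(a)) return("five_prime_chimeric_normal")
  "five_prime_chimeric_truncated"
}

#' Classify every catalogue entry
#'
#' Applies [categorize_transcript()], [predict_orf()] and
#' [coding_class()] across the catalogue.  The annotated CDS used for
#' comparison is that of the assigned gene's reference transcript.
#'
#' @param catalogue a `teit_catalogue`.
#' @param reference list of reference [transcript_model()]s (with CDS).
#' @param genome named `DNAStringSet`.
#' @param min_codons see [predict_orf()].
#' @return `data.frame`: `teit_id`, `category`, `coding_class`,
#'   `cds_intervals` (semicolon-joined `start-end` pairs, empty when
#'   non-coding).
#' @export
classify_catalogue <- function(catalogue, reference, genome,
                               min_codons = 100L) {
  ref_gene <- vapply(reference, `[[`, character(1), "gene_id")
  rows <- lapply(catalogue$table$teit_id, function(id) {
    tx <- catalogue$transcripts[[id]]
    cat_lab <- categorize_transcript(tx, reference)
    orf <- predict_orf(tx, genome, min_codons)
    ann <- NULL
    if (!is.na(tx$gene_id)) {
      j <- which(ref_gene == tx$gene_id)[1]
      if (!is.na(j)) ann <- reference[[j]]$cds
    }
    cls <- coding_class(orf, ann, tx$strand)
    data.frame(teit_id = id, category = cat_lab, coding_class = cls,
               cds_intervals = if (is.null(orf)) "" else
                 paste(sprintf("%d-%d", orf$cds$start, orf$cds$end),
                       collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
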