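#' First-exon junction read counts per catalogue transcript and sample
#'
#' A transcript's expression support in a sample is the read count of the
#' junction spanning its first intron: the junction whose donor equals the
#' transcript's first-exon splice donor and whose acceptor equals the
#' transcription-order second exon's boundary, on the same chromosome and
#' strand (exact coordinate match).  A transcript is "expressed" in a
#' sample when this count is at least 1; that threshold is part of the
#' method definition and is deliberately not configurable.
#'
#' @param catalogue a `teit_catalogue` (every entry must have >= 2 exons).
#' @param junction_tables named list (sample id -> junction `data.frame`,
#'   see [read_junctions()]).
#' @param totals named numeric vector: sample id -> total mapped reads
#'   (used by [family_activity()]; all > 0).
#' @return object of class `expression_matrix`: list with `counts`
#'   (integer matrix, transcripts x samples), `expressed` (logical matrix
#'   `counts >= 1`), `totals`.
#' @export
count_first_exon_junctions <- function(catalogue, junction_tables, totals) {
  txs <- catalogue$transcripts
  if (any(vapply(txs, n_exons, integer(1)) < 2))
    stop("catalogue transcript with fewer than 2 exons")
  if (!all(names(junction_tables) %in% names(totals)))
    stop("totals missing for some samples")
  if (any(totals[names(junction_tables)] <= 0))
    stop("total_mapped_reads must be > 0")
  keys <- vapply(txs, function(tx) {
    ik <- intron_keys(tx)[1, ]
    paste(tx$chrom, ik$donor, ik$acceptor, tx$strand)
  }, character(1))
  samples <- names(junction_tables)
  counts <- matrix(0L, length(txs), length(samples),
                   dimnames = list(names(txs), samples))
  for (s in samples) {
    j <- junction_tables[[s]]
    jk <- paste(j$chrom, j$donor, j$acceptor, j$strand)
    agg <- tapply(j$count, jk, sum)
    m <- agg[keys]
    counts[, s] <- ifelse(is.na(m), 0L, as.integer(m))
  }
  structure(list(counts = counts, expressed = counts >= 1L,
                 totals = totals[samples]),
            class = "expression_matrix")
}

#' TE-family promoter activity per sample
#'
#' First-exon junction counts of all catalogue transcripts from the same
#' TE family are summed per sample and normalized per million total
#' mapped reads:
#' \deqn{activity_{f,s} = 10^6 \sum_{i \in f} counts_{i,s} / total_s}
#' Families with no catalogue transcripts do not appear.
#'
#' @param expression an `expression_matrix` from
#'   [count_first_exon_junctions()].
#' @param catalogue the matching `teit_catalogue` (provides the
#'   transcript -> family map).
#' @return numeric matrix, families x samples.
#' @export
family_activity <- function(expression, catalogue) {
  fam <- catalogue$table$family[match(rownames(expression$counts),
                                      catalogue$table$teit_id)]
  if (anyNA(fam)) stop("catalogue transcript without family")
  if (any(expression$totals <= 0)) stop("total_mapped_reads must be > 0")
  raw <- rowsum(expression$counts, group = fam)
  sweep(raw, 2, expression$totals / 1e6, "/")
}
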