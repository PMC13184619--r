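#' Genomic interval constructor
#'
#' Internal coordinate convention: 0-based, half-open `[start, end)`, the
#' same as BED/bedGraph.  GTF I/O converts at the file boundary.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"` (`"*"` allowed for unstranded features
#'   such as TE annotations used only in overlap tests).
#' @return a one-row `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval must satisfy start < end")
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be one of '+', '-', '*'")
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Transcript model constructor
#'
#' An exon chain on one chromosome and strand.  Exons are stored sorted by
#' coordinate and must not overlap.  `cds`, when present, is a sub-chain in
#' the same convention.
#'
#' @param transcript_id,gene_id,sample_id identifiers (`gene_id` and
#'   `sample_id` may be `NA`).
#' @param chrom,strand shared by all exons.
#' @param exons `data.frame` with `start`, `end` (0-based half-open).
#' @param cds optional `data.frame` with `start`, `end` for the coding
#'   region.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             gene_id = NA_character_,
                             sample_id = NA_character_, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!is.null(cds)) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    rownames(cds) <- NULL
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 sample_id = sample_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s  %s:%s  %d exon(s)%s%s\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              if (!is.na(x$gene_id)) paste0("  gene=", x$gene_id) else "",
              if (!is.null(x$cds)) "  [CDS]" else ""))
  invisible(x)
}

#' Number of exons
#' @param tx a `transcript_model`.
#' @return integer exon count.
#' @export
n_exons <- function(tx) nrow(tx$exons)

#' First exon and splice-donor coordinate of a multi-exon transcript
#'
#' The first exon is the 5'-most exon in transcription order (smallest
#' coordinates on `+`, largest on `-`).  Its "donor" is the first splice
#' donor of the transcript: the exclusive `end` of the first exon on `+`,
#' the inclusive `start` on `-`.  The donor is used as the cross-sample
#' clustering key.
#'
#' Single-exon transcripts have no splice donor and are rejected: the
#' pipeline only considers multi-exon transcripts.
#'
#' @param tx a `transcript_model` with at least two exons.
#' @return list with `exon` (one-row interval `data.frame`) and `donor`
#'   (integer coordinate).
#' @export
first_exon <- function(tx) {
  if (n_exons(tx) < 2)
    stop("single-exon transcript has no first splice donor: ", tx$transcript_id)
  if (tx$strand == "+") {
    ex <- tx$exons[1, , drop = FALSE]
    donor <- ex$end
  } else {
    ex <- tx$exons[nrow(tx$exons), , drop = FALSE]
    donor <- ex$start
  }
  list(exon = genomic_interval(tx$chrom, ex$start, ex$end, tx$strand),
       donor = as.integer(donor))
}

#' 5' terminus (TSS coordinate) of a transcript
#'
#' The genomic coordinate of the transcript's 5'-most base: `start` of the
#' first exon on `+`, `end - 1` of the last-coordinate exon on `-`.
#'
#' @param tx a `transcript_model`.
#' @return integer coordinate.
#' @export
tss_position <- function(tx) {
  if (tx$strand == "+") tx$exons$start[1] else tx$exons$end[nrow(tx$exons)] - 1L
}

#' Internal exons of a transcript (all but the first and last)
#' @param tx a `transcript_model`.
#' @return `data.frame` of intervals (possibly zero rows).
#' @keywords internal
internal_exons <- function(tx) {
  n <- n_exons(tx)
  if (n < 3) return(tx$exons[0, , drop = FALSE])
  tx$exons[2:(n - 1), , drop = FALSE]
}

#' Splice sites of a transcript
#'
#' Each intron contributes a donor and an acceptor boundary.  Sites are
#' encoded as strings `"chrom:strand:pos"`; positions are the half-open
#' exon boundaries flanking each intron (exon `end` on the left, next exon
#' `start` on the right), so they are strand-symmetric keys.
#'
#' @param tx a `transcript_model`.
#' @return character vector (empty for single-exon transcripts).
#' @export
splice_sites <- function(tx) {
  n <- n_exons(tx)
  if (n < 2) return(character(0))
  left <- tx$exons$end[-n]     # intron starts
  right <- tx$exons$start[-1]  # intron ends
  c(paste(tx$chrom, tx$strand, left, sep = ":"),
    paste(tx$chrom, tx$strand, right, sep = ":"))
}

#' Intron chain key of a transcript
#'
#' Canonical string of all intron boundaries; two transcripts share it iff
#' their splice chains are identical.
#' @param tx a `transcript_model`.
#' @return single string.
#' @keywords internal
intron_chain <- function(tx) {
  n <- n_exons(tx)
  if (n < 2) return("")
  paste(tx$chrom, tx$strand,
        paste(tx$exons$end[-n], tx$exons$start[-1], sep = "-", collapse = ","),
        sep = ":")
}

#' Spliced (mature) sequence of a transcript
#'
#' Concatenates exon sequences in transcription order; reverse-complemented
#' for `-` strand transcripts.
#'
#' @param tx a `transcript_model`.
#' @param genome a named `Biostrings::DNAStringSet`.
#' @return a `Biostrings::DNAString`.
#' @export
spliced_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome))
    stop("chromosome not in genome: ", tx$chrom)
  chr <- genome[[tx$chrom]]
  parts <- lapply(seq_len(nrow(tx$exons)), function(i)
    Biostrings::subseq(chr, start = tx$exons$start[i] + 1L, end = tx$exons$end[i]))
  s <- do.call(Biostrings::xscat, parts)
  if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Map a position in transcript (spliced) coordinates to the genome
#'
#' @param tx a `transcript_model`.
#' @param tpos 0-based offsets along the spliced transcript (5' to 3').
#' @return integer genomic coordinates (0-based).
#' @keywords internal
transcript_to_genome <- function(tx, tpos) {
  widths <- tx$exons$end - tx$exons$start
  if (tx$strand == "-") {
    starts <- rev(tx$exons$start); ends <- rev(tx$exons$end)
    widths <- rev(widths)
  } else {
    starts <- tx$exons$start; ends <- tx$exons$end
  }
  offs <- cumsum(c(0L, widths))
  vapply(tpos, function(p) {
    i <- findInterval(p, offs)  # exon index containing p
    if (i < 1 || i > length(widths) || p >= offs[length(offs)])
      stop("transcript position out of range: ", p)
    within <- p - offs[i]
    if (tx$strand == "+") starts[i] + within else ends[i] - 1L - within
  }, integer(1))
}

#' Map a transcript-coordinate interval to genomic exon sub-intervals
#'
#' Used to project a predicted CDS (given in spliced coordinates) back onto
#' the genome through the exon chain.
#'
#' @param tx a `transcript_model`.
#' @param tstart,tend 0-based half-open interval along the spliced sequence.
#' @return `data.frame` of genomic intervals (`start`, `end`), sorted by
#'   coordinate.
#' @export
transcript_interval_to_genome <- function(tx, tstart, tend) {
  stopifnot(tstart < tend)
  widths <- tx$exons$end - tx$exons$start
  total <- sum(widths)
  if (tend > total) stop("interval exceeds spliced length")
  # walk exons in transcription order
  ord <- if (tx$strand == "+") seq_len(nrow(tx$exons)) else rev(seq_len(nrow(tx$exons)))
  out <- list(); off <- 0L
  for (i in ord) {
    w <- widths[i]
    lo <- max(tstart, off); hi <- min(tend, off + w)
    if (lo < hi) {
      if (tx$strand == "+") {
        gs <- tx$exons$start[i] + (lo - off); ge <- tx$exons$start[i] + (hi - off)
      } else {
        ge <- tx$exons$end[i] - (lo - off); gs <- tx$exons$end[i] - (hi - off)
      }
      out[[length(out) + 1L]] <- data.frame(start = gs, end = ge)
    }
    off <- off + w
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
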