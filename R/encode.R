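#' Encode the model input window around a transcript's first splice donor
#'
#' Extracts `flank` bases on either side of the first exon's splice donor:
#' 4 one-hot DNA channels (A, C, G, T; N and out-of-chromosome positions
#' are all-zero columns) plus 2 coverage channels (unique-mapping,
#' multi-mapping).  Coverage is `log1p`-transformed and max-normalized per
#' window and channel.  For `-` strand transcripts the sequence is
#' reverse-complemented and the coverage reversed, so the model always
#' sees transcription running left to right.
#'
#' @param genome named `DNAStringSet`.
#' @param coverage a coverage container accepted by [coverage_window()].
#' @param transcript a multi-exon [transcript_model()].
#' @param flank half-window size in bp (window length `L = 2 * flank`).
#' @return object of class `encoded_window`: list with `x` (`L x 6`
#'   matrix, columns A, C, G, T, unique, multi), `chrom`, `strand`,
#'   `window_start`, `window_end`, `center` (the donor), `flank`,
#'   `transcript_id`.
#' @export
encode_window <- function(genome, coverage, transcript, flank = 10000L) {
  if (!transcript$chrom %in% names(genome))
    stop("chromosome absent from genome: ", transcript$chrom)
  fe <- first_exon(transcript)
  center <- fe$donor
  ws <- center - flank; we <- center + flank
  L <- 2L * flank
  clen <- length(genome[[transcript$chrom]])

  seqcols <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  a <- max(ws, 0L); b <- min(we, clen)
  if (b > a) {
    s <- strsplit(as.character(
      Biostrings::subseq(genome[[transcript$chrom]], a + 1L, b)), "")[[1]]
    rows <- (a - ws + 1L):(b - ws)
    for (base in c("A", "C", "G", "T"))
      seqcols[rows[s == base], base] <- 1
  }
  covu <- coverage_window(coverage, transcript$chrom, ws, we, "unique")
  covm <- coverage_window(coverage, transcript$chrom, ws, we, "multi")
  norm1 <- function(v) { v <- log1p(v); m <- max(v); if (m > 0) v / m else v }
  x <- cbind(seqcols, unique = norm1(covu), multi = norm1(covm))

  if (transcript$strand == "-") {
    x <- x[L:1, , drop = FALSE]
    x <- x[, c("T", "G", "C", "A", "unique", "multi")]
    colnames(x) <- c("A", "C", "G", "T", "unique", "multi")
  }
  structure(list(x = x, chrom = transcript$chrom, strand = transcript$strand,
                 window_start = ws, window_end = we, center = center,
                 flank = flank, transcript_id = transcript$transcript_id),
            class = "encoded_window")
}

#' Cap-label target vector for an encoded window
#'
#' Slices the cap-signal track over the window, in the window's
#' orientation (reversed for `-` strand).  All-zero vectors are valid and
#' mark negative training windows.
#'
#' @param cap cap-signal container accepted by [coverage_window()] (dense
#'   list or sparse bedGraph-style `data.frame`).
#' @param window an `encoded_window`.
#' @return nonnegative numeric vector of length `2 * flank`.
#' @export
encode_target <- function(cap, window) {
  v <- coverage_window(cap, window$chrom, window$window_start,
                       window$window_end,
                       channel = if (inherits(cap, "coverage_track")) "unique" else "unique")
  if (window$strand == "-") v <- rev(v)
  v
}

#' Map a window offset back to a genomic coordinate
#'
#' Inverse of the strand-aware orientation applied by [encode_window()]:
#' offset `k` (0-based, transcription orientation) maps to
#' `window_start + k` on `+` and `window_end - 1 - k` on `-`.
#'
#' @param window an `encoded_window`.
#' @param k 0-based offset(s) into the window.
#' @return integer genomic coordinate(s).
#' @export
window_offset_to_genome <- function(window, k) {
  if (window$strand == "+") as.integer(window$window_start + k)
  else as.integer(window$window_end - 1L - k)
}

#' Map a genomic coordinate to its window offset (strand-aware)
#' @param window an `encoded_window`.
#' @param pos genomic coordinate(s).
#' @return 0-based offset(s); may fall outside `[0, 2*flank)`.
#' @export
genome_to_window_offset <- function(window, pos) {
  if (window$strand == "+") as.integer(pos - window$window_start)
  else as.integer(window$window_end - 1L - pos)
}
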