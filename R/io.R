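#' Read a GTF file into transcript models
#'
#' GTF is 1-based with closed intervals on disk; coordinates are converted
#' to the internal 0-based half-open convention.  Exon features are grouped
#' per `transcript_id` and sorted; `CDS` features, when present, become the
#' transcript's coding sub-chain.
#'
#' @param path GTF file.
#' @return list of [transcript_model()] objects.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 9)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ", nf)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0) return(list())
  if (anyNA(gr$transcript_id))
    stop("GTF exon/CDS feature without transcript_id")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    transcript_id = gr$transcript_id,
    gene_id = if (!is.null(gr$gene_id)) gr$gene_id else NA_character_,
    stringsAsFactors = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) stop("transcript without exon features: ", d$transcript_id[1])
    cds <- d[d$type == "CDS", c("start", "end"), drop = FALSE]
    transcript_model(
      transcript_id = d$transcript_id[1],
      chrom = ex$chrom[1], strand = ex$strand[1],
      exons = ex[, c("start", "end")],
      gene_id = ex$gene_id[1],
      cds = if (nrow(cds)) cds else NULL)
  })
  unname(out[order(names(out))])
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates are
#' written 1-based closed.  Exons (and CDS, when present) are emitted in
#' genomic order with `transcript_id`/`gene_id` attributes, so
#' `read_gtf(write_gtf(x))` reproduces the exon coordinates exactly.
#'
#' @param transcripts list of [transcript_model()].
#' @param path output file.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "teit") {
  fmt <- function(tx, feat, iv) {
    gid <- if (is.na(tx$gene_id)) tx$transcript_id else tx$gene_id
    sprintf('%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            tx$chrom, source, feat, iv$start + 1L, iv$end, tx$strand,
            gid, tx$transcript_id)
  }
  lines <- unlist(lapply(transcripts, function(tx) {
    c(vapply(seq_len(nrow(tx$exons)), function(i)
        fmt(tx, "exon", tx$exons[i, ]), character(1)),
      if (!is.null(tx$cds))
        vapply(seq_len(nrow(tx$cds)), function(i)
          fmt(tx, "CDS", tx$cds[i, ]), character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TE annotation BED file
#'
#' BED6+ with 0-based half-open intervals (preserved verbatim).  The name
#' field encodes `te_name:family:superfamily:class` (trailing components
#' optional; a missing family is an error).  Extension columns, when
#' present, are `kimura` (column 7).
#'
#' @param path BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `te_name`, `family`, `superfamily`, `te_class`, `kimura`.
#' @export
read_bed_te <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "kimura")
  empty <- stats::setNames(
    data.frame(character(), integer(), integer(), character(), character(),
               character(), character(), character(), numeric(),
               stringsAsFactors = FALSE),
    c("chrom", "start", "end", "strand", "te_name", "family", "superfamily",
      "te_class", "kimura"))
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) return(empty)
  names(raw)[seq_len(min(ncol(raw), length(cols)))] <-
    cols[seq_len(min(ncol(raw), length(cols)))]
  parts <- strsplit(as.character(raw$name), ":", fixed = TRUE)
  get <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else NA_character_, character(1))
  fam <- get(2)
  if (anyNA(fam) || any(!nzchar(fam)))
    stop("TE BED record without family in name field (te_name:family:superfamily:class)")
  data.frame(
    chrom = as.character(raw$chrom),
    start = as.integer(raw$start), end = as.integer(raw$end),
    strand = if ("strand" %in% names(raw)) as.character(raw$strand) else "*",
    te_name = get(1), family = fam, superfamily = get(3), te_class = get(4),
    kimura = if ("kimura" %in% names(raw)) as.numeric(raw$kimura) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Write a TE annotation BED file
#' @param te `data.frame` as returned by [read_bed_te()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_te <- function(te, path) {
  name <- paste(te$te_name, te$family, te$superfamily, te$te_class, sep = ":")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s%s",
                   te$chrom, te$start, te$end, name, "0", te$strand,
                   ifelse(is.na(te$kimura), "", sprintf("\t%.3f", te$kimura)))
  writeLines(lines, path)
  invisible(path)
}

#' Read one bedGraph channel into dense per-base vectors
#'
#' bedGraph is 0-based half-open.  Uncovered bases are 0.  Overlapping
#' records are summed (the dialect this package both reads and writes); an
#' interval extending past the chromosome length is an error.
#'
#' @param path bedGraph file.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return named list of numeric vectors, one per chromosome in
#'   `chrom_sizes`.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "value")),
    error = function(e) NULL)
  out <- lapply(chrom_sizes, function(n) numeric(n))
  if (is.null(raw) || nrow(raw) == 0) return(out)
  if (!all(raw$chrom %in% names(chrom_sizes)))
    stop("bedGraph chromosome absent from chrom_sizes: ",
         paste(setdiff(raw$chrom, names(chrom_sizes)), collapse = ", "))
  for (ch in unique(raw$chrom)) {
    d <- raw[raw$chrom == ch, , drop = FALSE]
    if (any(d$end > chrom_sizes[[ch]]))
      stop("bedGraph interval exceeds length of ", ch)
    cov <- IRanges::coverage(
      IRanges::IRanges(start = d$start + 1L, end = d$end),
      weight = d$value, width = chrom_sizes[[ch]])
    out[[ch]] <- as.numeric(cov)
  }
  out
}

#' Write dense per-base values as bedGraph
#'
#' Zero runs are omitted; adjacent equal values are merged into one record.
#'
#' @param values named list of numeric vectors (one per chromosome).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ch in names(values)) {
    r <- rle(values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read a two-channel coverage track (unique- and multi-mapping)
#'
#' @param unique_path,multi_path bedGraph files for the two channels.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return object of class `coverage_track`: named list per chromosome,
#'   each a list with numeric vectors `unique` and `multi`.
#' @export
read_coverage <- function(unique_path, multi_path, chrom_sizes) {
  u <- read_bedgraph(unique_path, chrom_sizes)
  m <- read_bedgraph(multi_path, chrom_sizes)
  structure(lapply(names(chrom_sizes), function(ch)
    list(unique = u[[ch]], multi = m[[ch]])) |>
      stats::setNames(names(chrom_sizes)),
    class = "coverage_track")
}

#' Read a splice-junction count table
#'
#' Tab-separated with header columns `chrom`, `donor`, `acceptor`,
#' `strand`, `count`.  Coordinates are the half-open exon boundaries
#' flanking the intron (donor = end of the upstream-in-coordinate exon,
#' acceptor = start of the downstream one), 0-based.
#'
#' @param path TSV file.
#' @return validated `data.frame`.
#' @export
read_junctions <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "donor", "acceptor", "strand", "count")
  if (!all(need %in% names(d)))
    stop("junction table must have columns: ", paste(need, collapse = ", "))
  if (any(d$count < 0)) stop("negative junction read count")
  if (any(d$donor == d$acceptor)) stop("junction with donor == acceptor")
  d[, need]
}

#' Write a splice-junction count table
#' @param junctions `data.frame` as from [read_junctions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' Tab-separated with header; required columns `sample_id`, `condition`
#' (`tumour`, `adjacent_normal` or `normal`), `cancer_type`.  Optional:
#' `stage` (ordinal), `survival_time` (> 0), `event` (0/1), `tissue`
#' (samples with tissue `"testis"` are excluded from normal totals in
#' tumour-specificity scoring).  `event` must be present exactly when
#' `survival_time` is.
#'
#' @param path TSV file.
#' @return validated `data.frame`.
#' @export
read_cohort <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_cohort(d)
}

#' @rdname read_cohort
#' @param cohort a cohort `data.frame` to validate in place.
#' @export
validate_cohort <- function(cohort) {
  need <- c("sample_id", "condition", "cancer_type")
  if (!all(need %in% names(cohort)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cohort$sample_id)) stop("duplicate sample_id in cohort")
  if (!"survival_time" %in% names(cohort)) cohort$survival_time <- NA_real_
  if (!"event" %in% names(cohort)) cohort$event <- NA_integer_
  if (any(is.na(cohort$survival_time) != is.na(cohort$event)))
    stop("event must be present exactly when survival_time is")
  if (any(cohort$survival_time <= 0, na.rm = TRUE))
    stop("survival_time must be > 0")
  if (!all(cohort$event %in% c(0, 1, NA)))
    stop("event must be 0/1")
  cohort
}

#' Write a cohort metadata table
#' @param cohort cohort `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
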