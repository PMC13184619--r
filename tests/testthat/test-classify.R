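test_that("structural categories follow shared-splice-site logic", {
  ref <- list(tx("r", "chr1", "+", c(1000, 2000, 3000), c(1500, 2200, 3500),
                 gene = "G"))
  ann <- tx("a", "chr1", "+", c(1100, 2000, 3000), c(1500, 2200, 3500))
  chi <- tx("c", "chr1", "+", c(500, 2000, 3000), c(700, 2200, 3500))
  intg <- tx("i", "chr1", "+", c(5000, 6000), c(5200, 6300))
  expect_equal(categorize_transcript(ann, ref), "annotated")
  expect_equal(categorize_transcript(chi, ref), "chimeric")
  expect_equal(categorize_transcript(intg, ref), "intergenic")
})

# write a designed spliced sequence into a genome through an exon chain
planted_genome <- function(spliced, exons, chrom_len = 2000) {
  chars <- rep("C", chrom_len)  # C background: no ATG, no stop codons
  s <- strsplit(spliced, "")[[1]]
  off <- 0
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i]
    chars[(exons$start[i] + 1):exons$end[i]] <- s[(off + 1):(off + w)]
    off <- off + w
  }
  Biostrings::DNAStringSet(stats::setNames(paste(chars, collapse = ""), "chr1"))
}

# codon pool chosen so that no concatenation creates an ATG or a stop
# codon in any frame (no codon ends in T or starts with TG/AA/TA)
safe_codons <- function(n) {
  pool <- c("GCC", "CCG", "GGA", "TTC")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

test_that("predict_orf recovers a planted splice-spanning ORF", {
  set.seed(21)
  exons <- data.frame(start = c(0, 300), end = c(200, 700))
  # spliced length 600: 10 nt lead, ATG + 149 codons + TAA, then filler
  orf <- paste0("ATG", safe_codons(149), "TAA")
  spliced <- paste0(strrep("C", 10), orf, strrep("C", 600 - 10 - nchar(orf)))
  genome <- planted_genome(spliced, exons)
  t1 <- transcript_model("t1", "chr1", "+", exons)
  res <- predict_orf(t1, genome, min_codons = 100)
  expect_equal(res$n_codons, 150)
  expect_equal(res$tstart, 10)
  # hand arithmetic: 190 nt in exon 1, remaining 263 in exon 2
  expect_equal(res$cds, data.frame(start = c(10, 300), end = c(200, 563)))

  expect_null(predict_orf(
    transcript_model("t0", "chr1", "+", data.frame(start = 1000, end = 1600)),
    genome, min_codons = 100))  # all-C region: no ATG
})

test_that("predict_orf picks the longest of competing ORFs", {
  set.seed(22)
  exons <- data.frame(start = 0, end = 1000)
  orf_a <- paste0("ATG", safe_codons(120), "TAA")   # 121-codon ORF
  orf_b <- paste0("ATG", safe_codons(150), "TAA")   # 151-codon ORF
  spliced <- paste0(orf_a, "C", orf_b,
                    strrep("C", 1000 - nchar(orf_a) - 1 - nchar(orf_b)))
  genome <- planted_genome(spliced, exons, 2000)
  res <- predict_orf(transcript_model("t", "chr1", "+", exons), genome,
                     min_codons = 100)
  expect_equal(res$n_codons, 151)
  expect_equal(res$tstart, nchar(orf_a) + 1)
})

test_that("predict_orf agrees with a brute-force scan on random sequences", {
  set.seed(23)
  brute_longest <- function(s) {
    best <- 0
    for (i in seq_len(nchar(s) - 2)) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i
      while (j + 5 <= nchar(s)) {
        j <- j + 3
        if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (j - i) / 3); break
        }
      }
    }
    best
  }
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(c(chr1 = s))
    t1 <- transcript_model("t", "chr1", "+", data.frame(start = 0, end = 500))
    res <- predict_orf(t1, genome, min_codons = 5)
    oracle <- brute_longest(s)
    if (oracle >= 5) expect_equal(res$n_codons, oracle)
    else expect_null(res)
  }
})

test_that("coding classes follow the interval-and-frame algebra", {
  ann <- data.frame(start = c(100, 300), end = c(199, 402))  # 99 + 102 nt
  p <- function(...) list(cds = data.frame(...))
  expect_equal(coding_class(p(start = c(100, 300), end = c(199, 402)), ann),
               "annotated")
  expect_equal(coding_class(p(start = c(160, 300), end = c(199, 402)), ann),
               "five_prime_truncated")     # in-frame 3'-coterminal suffix
  expect_equal(coding_class(p(start = c(40, 100, 300), end = c(61, 199, 402)),
                            ann),
               "five_prime_chimeric_normal")   # novel 21 nt + complete CDS
  expect_equal(coding_class(p(start = c(40, 160, 300), end = c(61, 199, 402)),
                            ann),
               "five_prime_chimeric_truncated")
  expect_equal(coding_class(p(start = 500, end = 560), ann), "novel")
  # out-of-frame novel extension is not chimeric
  expect_equal(coding_class(p(start = c(41, 100, 300), end = c(61, 199, 402)),
                            ann),
               "novel")
  expect_equal(coding_class(NULL, ann), "non_coding")
  expect_equal(coding_class(p(start = 100, end = 199), NULL), "novel")
})

test_that("catalogue classification partitions every entry", {
  pipe <- tiny_pipeline(); ref <- tiny_reference()
  cl <- classify_catalogue(pipe$catalogue, ref$ref_transcripts, ref$genome)
  expect_equal(nrow(cl), nrow(pipe$catalogue$table))
  expect_true(all(cl$category %in% c("annotated", "chimeric", "intergenic")))
  expect_true(all(cl$coding_class %in%
                    c("annotated", "five_prime_chimeric_normal",
                      "five_prime_chimeric_truncated", "five_prime_truncated",
                      "novel", "non_coding")))
  # planted chimeras carry the TE first exon: category must be chimeric
  i <- match_planted(pipe$catalogue, ref$planted)
  expect_true(all(cl$category[i] == "chimeric"))
  # self-consistency: a reference transcript categorizes as annotated
  expect_equal(categorize_transcript(ref$ref_transcripts[[1]],
                                     ref$ref_transcripts), "annotated")
})
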