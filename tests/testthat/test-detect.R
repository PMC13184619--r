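test_that("degradation filter drops first exons overlapping internal exons", {
  # host transcript with internal exon (150, 250)
  host <- tx("host", "chr1", "+", c(0, 150, 400), c(100, 250, 500),
             sample = "s1")
  overl <- tx("bad", "chr1", "+", c(100, 400), c(200, 500), sample = "s1")
  abut <- tx("ok", "chr1", "+", c(250, 400), c(300, 500), sample = "s1")
  pool <- list(host, overl, abut)
  fe <- extract_first_exons(pool)
  kept <- degradation_filter(fe, pool)
  expect_true("ok" %in% kept$transcript_id)     # half-open abutting retained
  expect_false("bad" %in% kept$transcript_id)
  expect_true("host" %in% kept$transcript_id)   # own exons don't disqualify

  # antisense overlap is kept by default, dropped in strand-blind mode
  anti <- tx("anti", "chr1", "-", c(50, 160), c(120, 200), sample = "s1")
  pool2 <- c(pool, list(anti))
  fe2 <- extract_first_exons(pool2)
  expect_true("anti" %in% degradation_filter(fe2, pool2)$transcript_id)
  expect_false("anti" %in%
                 degradation_filter(fe2, pool2, strand_aware = FALSE)$transcript_id)
})

test_that("degradation filter retains exactly the planted non-overlapping records", {
  # 10 candidate transcripts; 3 first exons planted to overlap internal
  # exons of two host transcripts
  hosts <- list(
    tx("h1", "chr1", "+", c(1000, 2000, 3000), c(1200, 2200, 3200), sample = "s1"),
    tx("h2", "chr2", "+", c(1000, 2000, 3000), c(1200, 2200, 3200), sample = "s1"))
  starts <- c(2100, 100, 300, 500, 700, 2150, 900, 1100, 2190, 1300)
  chroms <- c("chr1", rep("chr1", 4), "chr2", rep("chr1", 2), "chr2", "chr1")
  cands <- lapply(1:10, function(i)
    tx(paste0("c", i), chroms[i], "+", c(starts[i], 5000 + 100 * i),
       c(starts[i] + 80, 5100 + 100 * i), sample = "s2"))
  pool <- c(hosts, cands)
  fe <- extract_first_exons(cands)
  kept <- degradation_filter(fe, pool)
  # brute-force all-pairs oracle
  internal <- data.frame(chrom = c("chr1", "chr2"), start = 2000, end = 2200)
  oracle <- vapply(1:10, function(i) {
    !any(internal$chrom == chroms[i] & starts[i] < internal$end &
           internal$start < starts[i] + 80)
  }, logical(1))
  expect_equal(sum(oracle), 7)
  expect_setequal(kept$transcript_id, paste0("c", which(oracle)))
})

test_that("weight_score matches hand arithmetic and the brute-force double loop", {
  expect_equal(weight_score(500, c("500" = 3), w = 10), 3)
  expect_equal(weight_score(100, c("100" = 2, "105" = 1), w = 10),
               2 + (10 - 5) / (10 * 1))
  expect_error(weight_score(100, c("100" = 1), w = 0), "w must be")

  brute <- function(t, support, w) {
    pos <- as.numeric(names(support))
    s <- support[[as.character(t)]]
    for (k in seq_along(pos)) {
      d <- abs(pos[k] - t)
      if (pos[k] != t && d < w) s <- s + (w - d) / (w * support[[k]])
    }
    s
  }
  set.seed(13)
  for (rep in 1:1000) {
    n <- sample(1:50, 1)
    pos <- sample(1:200, n)
    support <- stats::setNames(sample(1:8, n, TRUE), pos)
    w <- sample(1:20, 1)
    t <- as.numeric(sample(names(support), 1))
    expect_equal(weight_score(t, support, w), brute(t, support, w))
  }
})

test_that("correct_tss picks the maximum-score position with documented ties", {
  expect_equal(correct_tss(c("42" = 1), w = 10), 42L)
  # hand enumeration: S(100) = 3, S(103) = 1 + (10-3)/(10*3)
  expect_equal(correct_tss(c("100" = 3, "103" = 1), w = 10), 100L)
  # symmetric tie: equal support, equal scores -> 5'-most by strand
  expect_equal(correct_tss(c("100" = 2, "110" = 2), w = 5, strand = "+"), 100L)
  expect_equal(correct_tss(c("100" = 2, "110" = 2), w = 5, strand = "-"), 110L)
})

test_that("te_filter respects half-open boundaries and prefers nested TEs", {
  te <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                   start = c(500, 500, 550), end = c(700, 900, 650),
                   strand = "+", te_name = c("outer1", "outer2", "inner"),
                   family = "F", superfamily = "SF", te_class = "LINE",
                   kimura = NA_real_, stringsAsFactors = FALSE)
  expect_equal(te_filter("chr1", 600, te)$te_name, "inner")
  expect_equal(te_filter("chr1", 680, te[1:2, ])$te_name, "outer1")
  expect_null(te_filter("chr1", 700, te[1, , drop = FALSE]))  # exclusive end
  expect_equal(te_filter("chr1", 500, te[1, , drop = FALSE])$te_name, "outer1")
  expect_null(te_filter("chr2", 600, te))
})

test_that("merge_transcripts picks the best reference match and rebuilds the first exon", {
  refg <- tx("r1", "chr1", "+", c(1000, 2000, 3000), c(1500, 2200, 3500),
             gene = "G")
  # member sharing all 4 reference splice sites
  m3 <- tx("a", "chr1", "+", c(800, 2000, 3000), c(1500, 2200, 3500),
           sample = "s1")
  # member sharing only 2 (donor 1500, acceptor 2000)
  m1 <- tx("b", "chr1", "+", c(800, 2000), c(1500, 2050), sample = "s2")
  mg <- merge_transcripts(list(m1, m3), corrected_tss = 850,
                          reference = list(refg))
  expect_equal(mg$gene_id, "G")
  expect_equal(mg$transcript$exons$start[1], 850)
  expect_equal(mg$transcript$exons$end[1], 1500)  # donor preserved
  expect_equal(n_exons(mg$transcript), 3)

  # '-' strand: corrected TSS becomes the (exclusive) end of the first exon
  refm <- tx("r2", "chr1", "-", c(1000, 2000, 3000), c(1500, 2200, 3500),
             gene = "H")
  mm <- tx("c", "chr1", "-", c(1000, 2000, 3000), c(1500, 2200, 3700),
           sample = "s1")
  mgm <- merge_transcripts(list(mm), corrected_tss = 3600,
                           reference = list(refm))
  expect_equal(mgm$gene_id, "H")
  expect_equal(mgm$transcript$exons$end[3], 3601)
  # corrected TSS not 5' of the donor: no valid transcript
  bad <- merge_transcripts(list(m3), corrected_tss = 1600,
                           reference = list(refg))
  expect_null(bad$transcript)
})

test_that("catalogue construction is deterministic and IDs are stable", {
  p1 <- tiny_pipeline()
  p2 <- run_te_pipeline(tiny_model(), tiny_cohort(), tiny_reference())
  expect_identical(p1$catalogue$table, p2$catalogue$table)
  expect_identical(p1$expression$counts, p2$expression$counts)
  expect_true(all(grepl("^TE_\\d{6}$", p1$catalogue$table$teit_id)))
})

test_that("the tiny cohort's planted transcripts are recovered with their genes", {
  p <- tiny_pipeline()
  ref <- tiny_reference()
  i <- match_planted(p$catalogue, ref$planted)
  expect_false(anyNA(i))
  expect_true(all(abs(p$catalogue$table$corrected_tss[i] -
                        ref$planted$true_tss) <= 100))
  expect_equal(p$catalogue$table$gene_id[i], ref$planted$gene_id)
  expect_equal(p$catalogue$table$family[i], ref$planted$family)
})
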