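test_that("tumour-specific score matches hand arithmetic including the boundary", {
  expect_equal(tumour_specific_score(0, 10, 0, 10), 1)
  expect_equal(tumour_specific_score(7, 10, 0, 10), 8)
  expect_equal(tumour_specific_score(30, 100, 0, 100), 31)
  expect_error(tumour_specific_score(1, 0, 0, 10), "> 0")
  expect_error(tumour_specific_score(11, 10, 0, 10), "\\[0, total\\]")
  # strictly increasing in T_e, decreasing in N_e
  s <- tumour_specific_score(0:10, 10, 3, 10)
  expect_true(all(diff(s) > 0))
  s2 <- tumour_specific_score(5, 10, 0:10, 10)
  expect_true(all(diff(s2) < 0))
})

test_that("tumour-specificity flags respect comparator and testis exclusion", {
  ex <- matrix(c(rep(TRUE, 7), rep(FALSE, 3), rep(FALSE, 10)), nrow = 1,
               dimnames = list("t1", paste0("s", 1:20)))
  cohort <- data.frame(sample_id = paste0("s", 1:20),
                       condition = rep(c("tumour", "normal"), each = 10),
                       cancer_type = "A",
                       tissue = c(rep("generic", 18), "testis", "testis"))
  # with testis excluded: N_t = 8, S = (8/10)/(1/8) = 6.4
  res <- tumour_specificity(ex, cohort)
  expect_equal(res$N_t, 8)
  expect_equal(res$score, (8 / 10) / (1 / 8))
  expect_false(res$tumour_specific)
  # S exactly 8 flags under ge but not gt
  ex2 <- ex; cohort2 <- cohort; cohort2$tissue <- "generic"
  r_gt <- tumour_specificity(ex2, cohort2, comparator = "gt")
  r_ge <- tumour_specificity(ex2, cohort2, comparator = "ge")
  expect_equal(r_gt$score, 8)
  expect_false(r_gt$tumour_specific)
  expect_true(r_ge$tumour_specific)
})

test_that("onco-exaptation flags listed genes of gene-linked categories only", {
  tab <- data.frame(
    teit_id = sprintf("TE_%06d", 1:20),
    gene_id = c(rep("MYC", 2), rep("KRAS", 2), rep("OTHER", 10),
                rep(NA_character_, 6)),
    stringsAsFactors = FALSE)
  cat <- structure(list(table = tab, transcripts = list()),
                   class = "teit_catalogue")
  classes <- data.frame(
    teit_id = tab$teit_id,
    category = c("chimeric", "annotated", "chimeric", "annotated",
                 rep("chimeric", 10), rep("intergenic", 6)),
    stringsAsFactors = FALSE)
  res <- onco_exaptation(cat, classes, oncogenes = c("MYC", "KRAS"))
  expect_equal(sum(res$onco_exaptation), 4)   # recount oracle
  expect_true(all(res$teit_id[res$onco_exaptation] == tab$teit_id[1:4]))
  # intergenic transcripts are never flagged, even on a listed gene
  classes$category[1] <- "intergenic"
  expect_equal(sum(onco_exaptation(cat, classes, c("MYC", "KRAS"))$onco_exaptation), 3)
})

test_that("fisher_exact_2x2 matches hypergeometric enumeration", {
  # (5,0,0,5): 6 tables share the margins; only the two extremes are as
  # extreme as observed
  ft <- fisher_exact_2x2(5, 0, 0, 5)
  expect_equal(ft$p_value, 2 / 252)
  expect_equal(fisher_exact_2x2(2, 2, 2, 2)$p_value, 1)
  # Haldane-corrected odds ratio
  expect_equal(ft$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
  expect_equal(fisher_exact_2x2(4, 2, 1, 3)$odds_ratio, 6)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")

  enum_p <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    xs <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(xs, c1, n - c1, r1)
    sum(probs[probs <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
  }
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    ft <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ft$p_value, enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment performs the standard step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(32)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_true(all(q <= 1) && all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    # hand step-up oracle
    o <- order(p); m <- length(p)
    qo <- rev(cummin(rev(p[o] * m / seq_len(m))))
    expect_equal(q[o], pmin(qo, 1))
  }
})

test_that("Wilcoxon branch: exact permutation for small n, ties handled", {
  w <- teit:::wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$method, "exact")
  # permutation oracle with ties
  set.seed(33)
  for (rep in 1:10) {
    x <- sample(1:4, 5, TRUE); y <- sample(2:6, 6, TRUE)
    w <- teit:::wilcoxon_rank_sum(x, y)
    r <- rank(c(x, y)); n1 <- length(x); n <- length(r)
    splits <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[splits], nrow = n1))
    EW <- n1 * (n + 1) / 2
    obs <- sum(r[seq_len(n1)])
    expect_equal(w$p_value, mean(abs(Ws - EW) >= abs(obs - EW) - 1e-9))
  }
  # large-n branch agrees with the tie-corrected normal approximation
  set.seed(34)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  w <- teit:::wilcoxon_rank_sum(x, y)
  expect_equal(w$p_value,
               suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value))
})

test_that("log-rank statistic and hazard ratio match risk-set arithmetic", {
  # group A events at 1,2,3; group B at 4,5,6; no censoring
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  lr <- teit:::logrank_hr(time, event, grp)
  # hand-tabulated risk sets: at each event time one death; E_A = sum of
  # (A at risk)/(total at risk) over event times
  nA <- c(3, 3, 3, 0, 0, 0); nB <- c(3, 3, 3, 3, 2, 1)
  atA <- c(3, 2, 1, 0, 0, 0); atB <- rep(3, 6) - c(0, 0, 0, 0, 1, 2)
  EA <- sum(atA / (atA + atB))
  V <- sum((atA * atB) / (atA + atB)^2)  # one death per time, no ties
  OA <- 3
  expect_equal(lr$chisq, (OA - EA)^2 / V, tolerance = 1e-6)
  expect_gt(lr$hazard_ratio, 1)  # all early events are in A
  expect_equal(lr$hazard_ratio, (3 / EA) / (3 / (6 - EA)), tolerance = 1e-6)
})

test_that("clinical tests run per family with degenerate units skipped", {
  set.seed(35)
  n <- 40
  cohort <- data.frame(
    sample_id = paste0("s", 1:n),
    condition = rep(c("tumour", "normal"), each = n / 2),
    cancer_type = rep(c("A", "B"), n / 2),
    stage = c(sample(c("I", "II", "III"), n / 2, TRUE), rep(NA, n / 2)),
    survival_time = c(round(rexp(n / 2, 0.05), 2) + 0.01, rep(NA, n / 2)),
    event = c(rbinom(n / 2, 1, 0.7), rep(NA, n / 2)))
  vals <- rbind(up = c(rpois(n / 2, 20), rpois(n / 2, 5)) + 1,
                flat = rpois(n, 10) + 1,
                const = rep(3, n),
                surv = rbinom(n, 1, 0.5) * rpois(n, 5))
  colnames(vals) <- cohort$sample_id
  res <- clinical_tests(vals, cohort)
  expect_named(res, c("differential", "stage", "survival"))
  dif <- res$differential
  expect_lt(dif$p_value[dif$unit == "up"], 0.001)
  expect_equal(dif$statistic[dif$unit == "const"], 0)
  expect_equal(dif$p_value[dif$unit == "const"], 1)
  expect_equal(res$stage$statistic[res$stage$unit == "const"], 0)
  expect_equal(res$differential$fdr, bh_adjust(res$differential$p_value))
  # units whose values are all >= 1 have no non-expressing group: skipped
  expect_equal(res$survival$unit, "surv")
  sk <- attr(res, "skipped")
  expect_true("const" %in% sk$unit[sk$test == "survival"])
  expect_true("up" %in% sk$unit[sk$test == "survival"])
})

test_that("preferential expression recovers extreme and stays silent on uniform", {
  set.seed(36)
  n <- 200
  cohort <- data.frame(sample_id = paste0("s", 1:n), condition = "tumour",
                       cancer_type = rep(c("A", "B", "C", "D"), n / 4))
  ex <- matrix(FALSE, 2, n,
               dimnames = list(c("only_A", "uniform"), cohort$sample_id))
  ex["only_A", cohort$cancer_type == "A"] <- TRUE
  ex["uniform", ] <- runif(n) < 0.3
  res <- preferential_expression(ex, cohort)
  callA <- res[res$teit_id == "only_A" & res$cancer_type == "A", ]
  expect_true(callA$preferential)
  expect_false(any(res$preferential[res$teit_id == "uniform"]))
})

test_that("tau index matches direct arithmetic", {
  expect_equal(tau_index(c(5, 0, 0, 0)), 1)
  expect_equal(tau_index(c(3, 3, 3)), 0)
  expect_equal(tau_index(c(4, 2, 0)), 0.75)
  expect_error(tau_index(c(0, 0, 0)), "all-zero")
  expect_error(tau_index(5), "at least 2")
  expect_error(tau_index(c(-1, 2)), "nonnegative")
})
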