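test_that("kl_loss matches direct arithmetic and is zero at identity", {
  eps <- exp(-10)
  t1 <- c(0.3, 0.2, 0.5)
  expect_equal(kl_loss(t1, t1), 0)
  # hand-computed: target (1,0) vs pred (.5,.5)
  expect_equal(kl_loss(c(1, 0), c(0.5, 0.5)),
               1 * (log(1 + eps) - log(0.5 + eps)))
  expect_equal(kl_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-4)
  # reversed direction is asymmetric
  rev_case <- 0.5 * (log(0.5 + eps) - log(0 + eps)) +
    0.5 * (log(0.5 + eps) - log(1 + eps))
  expect_equal(kl_loss(c(0.5, 0.5), c(1, 0)), rev_case)
  expect_gt(kl_loss(c(0.5, 0.5), c(1, 0)), kl_loss(c(1, 0), c(0.5, 0.5)))
  expect_error(kl_loss(c(1, 0), c(1, 0, 0)), "length")
})

test_that("kl_loss is nonnegative up to epsilon slack on random distributions", {
  set.seed(1)
  for (i in 1:50) {
    t <- runif(20); t <- t / sum(t)
    p <- runif(20); p <- p / sum(p)
    expect_gte(kl_loss(t, p), -1e-3)
  }
  # all-zero target (negative window) contributes nothing
  expect_equal(kl_loss(numeric(10), rep(0.1, 10)), 0)
})

test_that("encode_window pads boundaries, one-hots sequence and orients strands", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 25), collapse = "")))  # 100 bp
  cov <- sparse_coverage(c(chr1 = 100L),
                         unique = data.frame(chrom = "chr1", start = 40,
                                             end = 100, value = 2),
                         multi = data.frame(chrom = "chr1", start = 0,
                                            end = 0, value = 0)[0, ])
  plus <- tx("p", "chr1", "+", c(20, 60), c(50, 90))
  w <- encode_window(genome, cov, plus, flank = 60L)
  expect_equal(dim(w$x), c(120, 6))
  # donor = 50, window = [-10, 110): first 10 and last 10 columns zero-padded
  expect_equal(sum(w$x[1:10, 1:4]), 0)
  expect_equal(sum(w$x[111:120, 1:4]), 0)
  expect_true(all(rowSums(w$x[11:110, 1:4]) == 1))
  expect_true(all(w$x[, 5:6] >= 0 & w$x[, 5:6] <= 1))

  # a '-' transcript with the same donor sees the reverse complement
  minus <- tx("m", "chr1", "-", c(10, 50), c(40, 90))  # donor = 50
  wm <- encode_window(genome, cov, minus, flank = 60L)
  expect_equal(unname(wm$x[, 1:4]),
               unname(w$x[120:1, c(4, 3, 2, 1)]))
})

test_that("window offsets map to mirrored genomic coordinates by strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 50)))
  cov <- sparse_coverage(c(chr1 = 200L),
                         unique = data.frame(chrom = character(), start = integer(),
                                             end = integer(), value = numeric()),
                         multi = data.frame(chrom = character(), start = integer(),
                                            end = integer(), value = numeric()))
  plus <- tx("p", "chr1", "+", c(20, 120), c(100, 150))
  minus <- tx("m", "chr1", "-", c(20, 100), c(60, 150))  # donor = 100
  wp <- encode_window(genome, cov, plus, flank = 50L)
  wm <- encode_window(genome, cov, minus, flank = 50L)
  k <- 0:99
  expect_equal(window_offset_to_genome(wp, k), 50L + k)
  expect_equal(window_offset_to_genome(wm, k), 149L - k)
  expect_equal(genome_to_window_offset(wp, window_offset_to_genome(wp, k)), k)
  expect_equal(genome_to_window_offset(wm, window_offset_to_genome(wm, k)), k)
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(4)
  L <- 16L
  net <- tss_net(flank = L / 2L, kernels = c(3L, 5L), filters = 2L,
                 mid_kernel = 3L, mid_dilation = 2L, seed = 11L)
  X <- matrix(runif(L * 6), L, 6)
  tstar <- runif(L); tstar <- tstar / sum(tstar)
  eps_kl <- exp(-10)
  loss_of <- function(par) {
    old <- net$params; net$params <- par
    fw <- teit:::net_forward(net, X)
    net$params <- old
    teit:::kl_forward_backward(fw$logits, tstar, eps_kl)$loss
  }
  fw <- teit:::net_forward(net, X, keep_cache = TRUE)
  kb <- teit:::kl_forward_backward(fw$logits, tstar, eps_kl)
  g <- teit:::net_backward(net, fw$cache, kb$dz)
  h <- 1e-6
  for (nm in c("W1", "W2", "Wm", "Wh", "b1", "bm", "bh")) {
    p <- net$params
    idx <- if (length(p[[nm]]) > 4) sample(length(p[[nm]]), 4) else
      seq_along(p[[nm]])
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_equal(as.numeric(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  co <- tiny_cohort(); ref <- tiny_reference()
  tr <- cohort_windows(co, ref, flank = 768L, max_windows = 30L, seed = 2L)
  cfg <- train_config(batch_size = 64L, max_epochs = 3L, seed = 3L)
  m1 <- train_tss_model(tr$windows, tr$targets, cfg, filters = 4L)
  expect_length(m1$loss_history, 3)
  expect_lt(m1$loss_history[3], m1$loss_history[1])
  # batch_size larger than the dataset: one batch per epoch, no error
  m2 <- train_tss_model(tr$windows, tr$targets, cfg, filters = 4L)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_error(train_tss_model(list(), list()), "empty")
})

test_that("a serialized model reloads with bit-identical predictions", {
  m <- tiny_model()
  co <- tiny_cohort(); ref <- tiny_reference()
  te <- cohort_windows(co, ref, flank = 768L, max_windows = 10L,
                       negative_ratio = 0, seed = 9L)
  f <- withr::local_tempfile(fileext = ".rds")
  save_tss_model(m, f)
  m2 <- load_tss_model(f)
  for (w in te$windows)
    expect_identical(predict_tss(m, w), predict_tss(m2, w))
})

test_that("predict_tss maps the argmax strand-awarely and scores in [0,1]", {
  m <- tiny_model()
  co <- tiny_cohort(); ref <- tiny_reference()
  te <- cohort_windows(co, ref, flank = 768L, max_windows = 20L,
                       negative_ratio = 0, seed = 10L)
  for (w in te$windows) {
    pr <- predict_tss(m, w)
    expect_gte(pr$score, 0); expect_lte(pr$score, 1)
    expect_gte(pr$position, w$window_start)
    expect_lt(pr$position, w$window_end)
    # the reported position is the argmax of the predicted signal
    sig <- predict_signal(m, w)
    expect_equal(pr$position,
                 window_offset_to_genome(w, which.max(sig) - 1L))
    expect_equal(pr$score, max(sig))
  }
  wrong <- te$windows[[1]]; wrong$flank <- 999L
  expect_error(predict_tss(m, wrong), "flank")
})

test_that("evaluate_distances summarizes errors and recounts exactly", {
  pr <- data.frame(transcript_id = c("a", "b", "c"),
                   position = c(100, 150, 350))
  tr <- data.frame(transcript_id = c("a", "b", "c"),
                   position = c(100, 100, 200))
  ev <- evaluate_distances(pr, tr)
  expect_equal(unname(ev$distances), c(0, 50, 150))
  expect_equal(ev$exact_fraction, 1 / 3)
  expect_equal(ev$within_100bp_fraction, 2 / 3)
  expect_equal(evaluate_distances(tr, tr)$exact_fraction, 1)
  expect_equal(evaluate_distances(tr, tr)$within_100bp_fraction, 1)

  set.seed(6)
  n <- 40
  pr <- data.frame(transcript_id = paste0("t", 1:n),
                   position = sample(1000, n))
  tr <- data.frame(transcript_id = sample(paste0("t", 1:n)),
                   position = sample(1000, n))
  ev <- evaluate_distances(pr, tr)
  oracle <- abs(pr$position - tr$position[match(pr$transcript_id,
                                                tr$transcript_id)])
  expect_equal(unname(ev$distances), oracle)
  expect_equal(ev$within_100bp_fraction, mean(oracle <= 100))

  expect_error(evaluate_distances(pr[-1, ], tr), "unmatched")
})
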