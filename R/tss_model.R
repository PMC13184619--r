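#' KL-divergence training loss for TSS signal prediction
#'
#' \deqn{L = \sum_i t^*_i [\ln(t^*_i + \epsilon) - \ln(p^*_i + \epsilon)]}
#'
#' where \eqn{t^*} and \eqn{p^*} are the target and predicted signals,
#' each normalized to sum 1 within the window (the default), and
#' \eqn{\epsilon = e^{-10}} guards empty windows: an all-zero target (a
#' negative window) contributes 0.  The loss is 0 when target equals
#' prediction and nonnegative up to the small \eqn{\epsilon}-induced
#' slack.
#'
#' @param target,pred nonnegative vectors of equal length.
#' @param epsilon stabilizer (default `exp(-10)`).
#' @param normalize divide each vector by its sum when the sum is positive
#'   (the `*` operation); set `FALSE` if inputs are already normalized.
#' @return scalar loss.
#' @export
kl_loss <- function(target, pred, epsilon = exp(-10), normalize = TRUE) {
  if (length(target) != length(pred))
    stop("target and pred must have equal length")
  if (any(target < 0) || any(pred < 0)) stop("signals must be nonnegative")
  if (normalize) {
    st <- sum(target); if (st > 0) target <- target / st
    sp <- sum(pred); if (sp > 0) pred <- pred / sp
  }
  sum(target * (log(target + epsilon) - log(pred + epsilon)))
}

#' Training configuration for the TSS model
#'
#' Defaults follow the published optimization recipe: Adam with learning
#' rate 0.005, batch size 64, at most 10 epochs, \eqn{\epsilon = e^{-10}}.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size windows per gradient step.
#' @param max_epochs passes over the training set.
#' @param epsilon KL loss stabilizer.
#' @param seed seed for shuffling and weight initialization.
#' @return `train_config` list.
#' @export
train_config <- function(learning_rate = 0.005, batch_size = 64L,
                         max_epochs = 10L, epsilon = exp(-10), seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 1 || epsilon <= 0)
    stop("train_config values must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), epsilon = epsilon,
                 seed = as.integer(seed)), class = "train_config")
}

# loss and d(loss)/d(logits) for one window (target already normalized)
kl_forward_backward <- function(logits, tstar, epsilon) {
  z <- logits - max(logits)
  e <- exp(z); p <- e / sum(e)
  loss <- sum(tstar * (log(tstar + epsilon) - log(p + epsilon)))
  a <- tstar / (p + epsilon)
  dz <- p * (sum(a * p) - a)
  list(loss = loss, dz = dz, p = p)
}

#' Train the convolutional TSS model
#'
#' Minimizes the KL loss ([kl_loss()]) between the softmax of per-base
#' logits and the normalized cap-label signal, with Adam.  Targets with
#' zero mass (negative windows) contribute zero loss and gradient.
#'
#' @param windows list of [encode_window()] outputs.
#' @param targets list of numeric target vectors (raw cap mass per base,
#'   window-oriented; see [encode_target()]).
#' @param config a [train_config()].
#' @param net optionally a pre-initialized [tss_net()]; otherwise one is
#'   created for the windows' flank.
#' @param ... architecture arguments passed to [tss_net()] (e.g.
#'   `filters`, `kernels`).
#' @param verbose print the per-epoch mean loss.
#' @return object of class `tss_model`: list with `net`, `flank`,
#'   `config`, `loss_history` (mean training loss per epoch).
#' @export
train_tss_model <- function(windows, targets, config = train_config(),
                            net = NULL, ..., verbose = FALSE) {
  if (length(windows) == 0) stop("empty training set")
  if (length(windows) != length(targets))
    stop("windows and targets must have equal length")
  flank <- windows[[1]]$flank
  if (is.null(net)) net <- tss_net(flank, seed = config$seed, ...)
  if (net$flank != flank) stop("network flank does not match windows")
  tstars <- lapply(targets, function(t) {
    if (length(t) != 2L * flank) stop("target length must be 2*flank")
    s <- sum(t); if (s > 0) t / s else t
  })
  set.seed(config$seed)
  st <- adam_init(net$params)
  n <- length(windows)
  loss_history <- numeric(0)
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric(0)
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        fw <- net_forward(net, windows[[i]]$x, keep_cache = TRUE)
        kb <- kl_forward_backward(fw$logits, tstars[[i]], config$epsilon)
        ep_losses <- c(ep_losses, kb$loss)
        g <- net_backward(net, fw$cache, kb$dz)
        acc <- if (is.null(acc)) g
               else Map(`+`, acc, g)
      }
      acc <- lapply(acc, function(x) x / length(idx))
      upd <- adam_step(net$params, acc, st, config$learning_rate)
      net$params <- upd$params; st <- upd$state
    }
    loss_history <- c(loss_history, mean(ep_losses))
    if (verbose)
      message(sprintf("epoch %d/%d  mean loss %.4f", ep, config$max_epochs,
                      loss_history[ep]))
  }
  structure(list(net = net, flank = flank, config = config,
                 loss_history = loss_history), class = "tss_model")
}

#' Predict the TSS for one encoded window
#'
#' The predicted signal is the softmax of the per-base logits; the TSS is
#' its argmax mapped back to genomic coordinates (strand-aware), with
#' ties broken toward the window centre; the confidence score is the
#' maximum softmax probability.
#'
#' @param model a trained `tss_model`.
#' @param window an [encode_window()] output with the same flank.
#' @return one-row `data.frame`: `transcript_id`, `chrom`, `position`,
#'   `strand`, `score`.
#' @export
predict_tss <- function(model, window) {
  if (window$flank != model$flank)
    stop("window flank (", window$flank, ") does not match model flank (",
         model$flank, ")")
  fw <- net_forward(model$net, window$x)
  z <- fw$logits - max(fw$logits)
  p <- exp(z); p <- p / sum(p)
  mx <- max(p)
  k <- which(p >= mx - 1e-12)
  if (length(k) > 1) {
    centre <- length(p) / 2
    k <- k[which.min(abs(k - centre))]
  }
  data.frame(transcript_id = window$transcript_id, chrom = window$chrom,
             position = window_offset_to_genome(window, k - 1L),
             strand = window$strand, score = mx, stringsAsFactors = FALSE)
}

#' Predicted per-base TSS signal for a window (softmax scale)
#' @param model a trained `tss_model`.
#' @param window an [encode_window()] output.
#' @return numeric vector of length `2 * flank` summing to 1.
#' @export
predict_signal <- function(model, window) {
  fw <- net_forward(model$net, window$x)
  z <- fw$logits - max(fw$logits)
  p <- exp(z)
  p / sum(p)
}

#' Save / load a trained TSS model
#'
#' Serialization is exact: a reloaded model produces bit-identical
#' predictions.
#'
#' @param model a `tss_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_tss_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tss_model
#' @export
load_tss_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "tss_model")) stop("not a tss_model file: ", path)
  m
}

#' Distance-based evaluation of TSS predictions
#'
#' Pairs predictions with truth by `transcript_id` and summarizes the
#' absolute genomic distance between predicted and true TSS.
#'
#' @param predictions `data.frame` with `transcript_id`, `position`.
#' @param truth `data.frame` with `transcript_id`, `position` (the true
#'   TSS).
#' @return list: `exact_fraction` (distance 0), `within_100bp_fraction`
#'   (distance <= 100), `distances` (named integer vector).
#' @export
evaluate_distances <- function(predictions, truth) {
  miss <- c(setdiff(predictions$transcript_id, truth$transcript_id),
            setdiff(truth$transcript_id, predictions$transcript_id))
  if (length(miss))
    stop("unmatched transcript ids: ", paste(unique(miss), collapse = ", "))
  i <- match(predictions$transcript_id, truth$transcript_id)
  d <- abs(predictions$position - truth$position[i])
  names(d) <- predictions$transcript_id
  list(exact_fraction = mean(d == 0),
       within_100bp_fraction = mean(d <= 100),
       distances = d)
}
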