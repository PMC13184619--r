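# Minimal 1-D convolutional network used by the TSS predictor.
#
# Residual multi-scale stack: parallel same-padding convolutions with
# several kernel sizes over the 6 input channels, concatenated and
# rectified; a dilated middle convolution with a residual connection; and
# a per-base linear head producing one logit per position.  Convolutions
# are evaluated as im2col matrix products (BLAS), gradients are exact
# analytic backpropagation, optimization is Adam.  Small enough to train
# on a CPU in seconds-to-minutes at test scale.

conv_pad <- function(k, dil) as.integer(((k - 1L) %/% 2L) * dil)

im2col <- function(Xpad, L, pad, k, dil) {
  C <- ncol(Xpad)
  M <- matrix(0, L, k * C)
  offs <- (seq_len(k) - (k + 1L) / 2) * dil
  for (j in seq_len(k)) {
    rows <- (pad + 1L + offs[j]):(pad + L + offs[j])
    M[, ((j - 1L) * C + 1L):(j * C)] <- Xpad[rows, , drop = FALSE]
  }
  M
}

col2im_add <- function(dM, L, pad, k, dil, C) {
  dXpad <- matrix(0, L + 2L * pad, C)
  offs <- (seq_len(k) - (k + 1L) / 2) * dil
  for (j in seq_len(k)) {
    rows <- (pad + 1L + offs[j]):(pad + L + offs[j])
    dXpad[rows, ] <- dXpad[rows, ] + dM[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dXpad[(pad + 1L):(pad + L), , drop = FALSE]
}

pad_rows <- function(X, pad) {
  z <- matrix(0, pad, ncol(X))
  rbind(z, X, z)
}

#' Initialize the convolutional TSS network
#'
#' @param flank half-window size the network is configured for.
#' @param kernels kernel sizes (odd) of the parallel first-stage
#'   convolutions.
#' @param filters filters per first-stage kernel (stage output has
#'   `length(kernels) * filters` channels).
#' @param mid_kernel,mid_dilation middle (residual) convolution geometry.
#' @param in_channels input channels (4 DNA + 2 coverage).
#' @param seed seed for weight initialization.
#' @return object of class `tss_net`.
#' @export
tss_net <- function(flank, kernels = c(7L, 15L, 51L), filters = 16L,
                    mid_kernel = 15L, mid_dilation = 4L, in_channels = 6L,
                    seed = 1L) {
  stopifnot(all(kernels %% 2L == 1L), mid_kernel %% 2L == 1L)
  set.seed(seed)
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  C1 <- length(kernels) * filters
  params <- list()
  for (i in seq_along(kernels))
    params[[paste0("W", i)]] <- he(in_channels * kernels[i], filters)
  for (i in seq_along(kernels))
    params[[paste0("b", i)]] <- numeric(filters)
  params$Wm <- he(C1 * mid_kernel, C1)
  params$bm <- numeric(C1)
  params$Wh <- matrix(rnorm(C1, 0, 0.01), C1, 1)
  params$bh <- 0
  structure(list(flank = as.integer(flank), kernels = as.integer(kernels),
                 filters = as.integer(filters),
                 mid_kernel = as.integer(mid_kernel),
                 mid_dilation = as.integer(mid_dilation),
                 in_channels = as.integer(in_channels), params = params),
            class = "tss_net")
}

net_forward <- function(net, X, keep_cache = FALSE) {
  p <- net$params
  L <- nrow(X)
  pad1 <- max(vapply(net$kernels, conv_pad, integer(1), dil = 1L))
  Xpad <- pad_rows(X, pad1)
  cols1 <- lapply(seq_along(net$kernels), function(i)
    im2col(Xpad, L, pad1, net$kernels[i], 1L))
  H1 <- do.call(cbind, lapply(seq_along(net$kernels), function(i)
    sweep(cols1[[i]] %*% p[[paste0("W", i)]], 2, p[[paste0("b", i)]], "+")))
  A1 <- pmax(H1, 0)
  pad2 <- conv_pad(net$mid_kernel, net$mid_dilation)
  A1pad <- pad_rows(A1, pad2)
  colsm <- im2col(A1pad, L, pad2, net$mid_kernel, net$mid_dilation)
  H2 <- sweep(colsm %*% p$Wm, 2, p$bm, "+")
  A2 <- pmax(H2, 0) + A1
  z <- drop(A2 %*% p$Wh) + p$bh
  if (!keep_cache) return(list(logits = z))
  list(logits = z, cache = list(cols1 = cols1, H1 = H1, A1 = A1,
                                colsm = colsm, H2 = H2, A2 = A2, L = L))
}

# gradient of the loss w.r.t. every parameter, given d(loss)/d(logits)
net_backward <- function(net, cache, dz) {
  p <- net$params
  L <- cache$L
  g <- list()
  g$Wh <- t(cache$A2) %*% matrix(dz, ncol = 1)
  g$bh <- sum(dz)
  dA2 <- matrix(dz, ncol = 1) %*% t(p$Wh)      # L x C1
  dH2 <- dA2 * (cache$H2 > 0)
  g$Wm <- t(cache$colsm) %*% dH2
  g$bm <- colSums(dH2)
  pad2 <- conv_pad(net$mid_kernel, net$mid_dilation)
  dA1 <- dA2 + col2im_add(dH2 %*% t(p$Wm), L, pad2, net$mid_kernel,
                          net$mid_dilation, ncol(dA2))
  dH1 <- dA1 * (cache$H1 > 0)
  F <- net$filters
  for (i in seq_along(net$kernels)) {
    cols <- ((i - 1L) * F + 1L):(i * F)
    g[[paste0("W", i)]] <- t(cache$cols1[[i]]) %*% dH1[, cols, drop = FALSE]
    g[[paste0("b", i)]] <- colSums(dH1[, cols, drop = FALSE])
  }
  g
}

adam_init <- function(params)
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
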