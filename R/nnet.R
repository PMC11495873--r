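# Low-level neural network machinery: a lightweight WaveNet-style encoder
# (dilated causal convolutions with gated residual units and summed skip
# connections), the dual-stream MIL aggregator, and a fully connected
# pseudo-labelling head. Implemented directly on BLAS matrix products with
# hand-derived gradients; reads are batched within a bag by concatenating
# their time axes (the causal shift never crosses a read boundary).

#' Encoder architecture configuration
#'
#' @param channels residual channel width of the dilated convolution stack.
#' @param skip_channels width of the summed skip pathway.
#' @param post_channels width of the post-processing 1x1 convolution.
#' @param embed_dim dimensionality of the read embedding (default 1024).
#' @param n_blocks number of residual blocks (default 2).
#' @param dilations dilation factors within each block (default 1, 2, 4; the
#'   kernel has 2 taps, so each block spans `1 + sum(dilations)` = 8 steps).
#' @param pool_stride width of the non-overlapping average pooling applied
#'   after the post-processing convolution; the pooled maps are flattened
#'   (position is preserved at `pool_stride`-step resolution, which matters
#'   because the modified base always sits at the window centre) and fed to
#'   the fully connected embedding layer together with an identically pooled
#'   copy of the raw input window — a linear bypass that keeps simple
#'   level/probability shifts directly visible to the embedding layer while
#'   the convolution stack contributes the nonlinear context features.
#' @param input_channels input channels (5: signal + trace A/C/G/U).
#' @param width time steps per read (256).
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(channels = 12L, skip_channels = 24L,
                           post_channels = 16L, embed_dim = 1024L,
                           n_blocks = 2L, dilations = c(1L, 2L, 4L),
                           pool_stride = 4L, input_channels = 5L,
                           width = 256L) {
  stopifnot(all(dilations > 0), !is.unsorted(dilations), n_blocks >= 1,
            width %% pool_stride == 0)
  structure(list(channels = channels, skip_channels = skip_channels,
                 post_channels = post_channels, embed_dim = embed_dim,
                 n_blocks = n_blocks, dilations = dilations,
                 pool_stride = as.integer(pool_stride),
                 input_channels = input_channels, width = width),
            class = "encoder_config")
}

#' Aggregator / head configuration
#'
#' @param q_dim,v_dim query and value projection widths of the MIL
#'   aggregator's second stream.
#' @param stoich_hidden hidden width of the stoichiometry head.
#' @return list of class `head_config`.
#' @export
head_config <- function(q_dim = 64L, v_dim = 64L, stoich_hidden = 32L) {
  structure(list(q_dim = q_dim, v_dim = v_dim, stoich_hidden = stoich_hidden),
            class = "head_config")
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize all model parameters
#'
#' @param enc an [encoder_config()].
#' @param heads a [head_config()].
#' @param seed RNG seed for the initial weights.
#' @return named list of parameter matrices/vectors.
#' @keywords internal
init_params <- function(enc, heads, seed = 1L) {
  with_seed(seed, {
    C <- enc$channels; K <- enc$skip_channels; K2 <- enc$post_channels
    E <- enc$embed_dim
    p <- list(W_in = rmat(C, enc$input_channels, sqrt(2 / enc$input_channels)),
              b_in = numeric(C))
    dils <- rep(enc$dilations, enc$n_blocks)
    for (l in seq_along(dils)) {
      sd_c <- sqrt(1 / (2 * C))
      p[[paste0("L", l, "_Wf")]] <- rmat(C, C, sd_c)
      p[[paste0("L", l, "_Wfs")]] <- rmat(C, C, sd_c)
      p[[paste0("L", l, "_bf")]] <- numeric(C)
      p[[paste0("L", l, "_Wg")]] <- rmat(C, C, sd_c)
      p[[paste0("L", l, "_Wgs")]] <- rmat(C, C, sd_c)
      p[[paste0("L", l, "_bg")]] <- numeric(C)
      p[[paste0("L", l, "_Wsk")]] <- rmat(K, C, sqrt(1 / C))
      p[[paste0("L", l, "_Wr")]] <- rmat(C, C, sqrt(1 / C))
    }
    p$Wp <- rmat(K2, K, sqrt(2 / K)); p$bp <- numeric(K2)
    flat <- (K2 + enc$input_channels) * enc$width %/% enc$pool_stride
    p$We <- rmat(E, flat, sqrt(2 / flat)); p$be <- numeric(E)
    p$Wi <- rmat(2L, E, sqrt(1 / E)); p$bi <- numeric(2L)
    p$Wq <- rmat(heads$q_dim, E, sqrt(1 / E))
    p$Wv <- rmat(heads$v_dim, E, sqrt(1 / E))
    p$Wb <- rmat(2L, heads$v_dim, sqrt(1 / heads$v_dim)); p$bb <- numeric(2L)
    p$Sh_W1 <- rmat(heads$stoich_hidden, E, sqrt(2 / E))
    p$Sh_b1 <- numeric(heads$stoich_hidden)
    p$Sh_W2 <- rmat(2L, heads$stoich_hidden, sqrt(2 / heads$stoich_hidden))
    p$Sh_b2 <- numeric(2L)
    p
  })
}

# Causal shift by d within each read of width `width`; leading d columns of
# each read are zero-padded.
shift_cols <- function(X, d, width) {
  T <- ncol(X)
  valid <- (seq_len(T) - 1L) %% width >= d
  Xs <- matrix(0, nrow(X), T)
  Xs[, valid] <- X[, which(valid) - d]
  Xs
}

# Reshape an n x 1280 feature matrix into the 5 x (256 n) encoder input.
features_to_input <- function(feats, enc) {
  n <- nrow(feats)
  a <- array(t(feats), dim = c(enc$width, enc$input_channels, n))
  matrix(aperm(a, c(2L, 1L, 3L)), nrow = enc$input_channels)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' WaveNet encoder forward pass (batched over the reads of one bag)
#'
#' @param params parameter list from [init_params()].
#' @param X input matrix `input_channels x (width * n_reads)`.
#' @param n_reads number of reads concatenated in `X`.
#' @param enc the [encoder_config()].
#' @param keep_cache store intermediates for [encoder_backward()].
#' @return list: `E` (embed_dim x n_reads embeddings) and `cache`.
#' @keywords internal
encoder_forward <- function(params, X, n_reads, enc, keep_cache = FALSE) {
  width <- enc$width
  dils <- rep(enc$dilations, enc$n_blocks)
  H <- params$W_in %*% X + params$b_in
  skip <- matrix(0, enc$skip_channels, ncol(X))
  layers <- if (keep_cache) vector("list", length(dils)) else NULL
  for (l in seq_along(dils)) {
    d <- dils[l]
    Hs <- shift_cols(H, d, width)
    A1 <- params[[paste0("L", l, "_Wf")]] %*% H +
      params[[paste0("L", l, "_Wfs")]] %*% Hs + params[[paste0("L", l, "_bf")]]
    B1 <- params[[paste0("L", l, "_Wg")]] %*% H +
      params[[paste0("L", l, "_Wgs")]] %*% Hs + params[[paste0("L", l, "_bg")]]
    Tn <- tanh(A1)
    Sg <- sigmoid(B1)
    Z <- Tn * Sg
    skip <- skip + params[[paste0("L", l, "_Wsk")]] %*% Z
    Hn <- H + params[[paste0("L", l, "_Wr")]] %*% Z
    if (keep_cache) layers[[l]] <- list(H = H, Hs = Hs, Tn = Tn, Sg = Sg, Z = Z, d = d)
    H <- Hn
  }
  R1 <- pmax(skip, 0)
  P1 <- params$Wp %*% R1 + params$bp
  R2 <- pmax(P1, 0)
  stride <- enc$pool_stride
  grp <- (seq_len(ncol(R2)) - 1L) %/% stride + 1L
  pooled <- t(rowsum(t(R2), grp)) / stride       # post_channels x (T/stride)
  pooledX <- t(rowsum(t(X), grp)) / stride       # input bypass, same pooling
  per_read <- width %/% stride
  F0 <- rbind(matrix(pooled, nrow = nrow(pooled) * per_read, ncol = n_reads),
              matrix(pooledX, nrow = nrow(X) * per_read, ncol = n_reads))
  E <- params$We %*% F0 + params$be
  cache <- if (keep_cache) {
    list(X = X, layers = layers, skip = skip, P1 = P1, R1 = R1, F0 = F0,
         n_reads = n_reads)
  }
  list(E = E, cache = cache)
}

#' Backward pass of the encoder
#' @param dE gradient of the loss wrt the embeddings (embed_dim x n_reads).
#' @return named list of parameter gradients.
#' @keywords internal
encoder_backward <- function(params, cache, dE, enc) {
  width <- enc$width
  n <- cache$n_reads
  g <- list()
  g$We <- dE %*% t(cache$F0)
  g$be <- rowSums(dE)
  dF0 <- t(params$We) %*% dE
  K2 <- nrow(cache$P1)
  stride <- enc$pool_stride
  conv_rows <- K2 * width %/% stride             # input-bypass rows carry no
  dF0 <- dF0[seq_len(conv_rows), , drop = FALSE] # upstream parameters
  dpooled <- matrix(dF0, nrow = K2)
  dR2 <- dpooled[, rep(seq_len(ncol(dpooled)), each = stride),
                 drop = FALSE] / stride
  dP1 <- dR2 * (cache$P1 > 0)
  g$Wp <- dP1 %*% t(cache$R1)
  g$bp <- rowSums(dP1)
  dR1 <- t(params$Wp) %*% dP1
  dskip <- dR1 * (cache$skip > 0)
  dH <- matrix(0, nrow(cache$layers[[1]]$H), ncol(cache$X))
  for (l in rev(seq_along(cache$layers))) {
    ly <- cache$layers[[l]]
    dZ <- t(params[[paste0("L", l, "_Wsk")]]) %*% dskip +
      t(params[[paste0("L", l, "_Wr")]]) %*% dH
    g[[paste0("L", l, "_Wsk")]] <- dskip %*% t(ly$Z)
    g[[paste0("L", l, "_Wr")]] <- dH %*% t(ly$Z)
    dA1 <- dZ * ly$Sg * (1 - ly$Tn^2)
    dB1 <- dZ * ly$Tn * ly$Sg * (1 - ly$Sg)
    g[[paste0("L", l, "_Wf")]] <- dA1 %*% t(ly$H)
    g[[paste0("L", l, "_Wfs")]] <- dA1 %*% t(ly$Hs)
    g[[paste0("L", l, "_bf")]] <- rowSums(dA1)
    g[[paste0("L", l, "_Wg")]] <- dB1 %*% t(ly$H)
    g[[paste0("L", l, "_Wgs")]] <- dB1 %*% t(ly$Hs)
    g[[paste0("L", l, "_bg")]] <- rowSums(dB1)
    dHnew <- dH + t(params[[paste0("L", l, "_Wf")]]) %*% dA1 +
      t(params[[paste0("L", l, "_Wg")]]) %*% dB1
    dHs <- t(params[[paste0("L", l, "_Wfs")]]) %*% dA1 +
      t(params[[paste0("L", l, "_Wgs")]]) %*% dB1
    valid <- (seq_len(ncol(dHs)) - 1L) %% width >= ly$d
    cols <- which(valid)
    dHnew[, cols - ly$d] <- dHnew[, cols - ly$d, drop = FALSE] +
      dHs[, cols, drop = FALSE]
    dH <- dHnew
  }
  g$W_in <- dH %*% t(cache$X)
  g$b_in <- rowSums(dH)
  g
}

#' Dual-stream MIL forward pass on one bag of embeddings
#'
#' Stream 1 scores each read with a linear instance classifier and max-pools
#' the modified-class scores; the argmax read is the critical instance.
#' Stream 2 projects every read to a query and a value, weights values by a
#' softmax over inner products of queries with the critical instance's query,
#' and classifies the resulting bag embedding. The two streams' class scores
#' are averaged and softmaxed into P(mod).
#'
#' @param H embeddings, embed_dim x n_reads.
#' @return list: `C1`, `C2`, `C`, `p` (2-class probs), `p_mod`, `att`
#'   (attention weights, sum 1), `m` (critical instance index), `B`
#'   (bag embedding), plus intermediates for the backward pass.
#' @keywords internal
dsmil_forward <- function(params, H) {
  n <- ncol(H)
  if (n < 1L) stop("empty bag", call. = FALSE)
  Si <- params$Wi %*% H + params$bi          # 2 x n instance scores
  m <- which.max(Si[2L, ] - Si[1L, ])        # largest modified-class margin
  C1 <- Si[, m]
  Q <- params$Wq %*% H
  att_log <- as.vector(t(Q) %*% Q[, m])
  att <- softmax_vec(att_log)
  V <- params$Wv %*% H
  B <- as.vector(V %*% att)
  C2 <- as.vector(params$Wb %*% B + params$bb)
  C <- (C1 + C2) / 2
  p <- softmax_vec(C)
  list(C1 = C1, C2 = C2, C = C, p = p, p_mod = p[2L], att = att, m = m,
       B = B, Si = Si, Q = Q, V = V)
}

#' Backward pass of the MIL aggregator
#' @param dC gradient wrt the averaged class scores `C` (length 2).
#' @return list: parameter gradients `grads` and `dH` (gradient wrt the
#'   embeddings).
#' @keywords internal
dsmil_backward <- function(params, H, fw, dC) {
  n <- ncol(H)
  half <- dC / 2
  g <- list()
  dH <- matrix(0, nrow(H), n)
  # stream 1 (critical instance index treated as constant)
  g$Wi <- tcrossprod(half, H[, fw$m])
  g$bi <- half
  dH[, fw$m] <- dH[, fw$m] + as.vector(t(params$Wi) %*% half)
  # stream 2
  g$Wb <- tcrossprod(half, fw$B)
  g$bb <- half
  dB <- as.vector(t(params$Wb) %*% half)
  dV <- tcrossprod(dB, fw$att)
  dU <- as.vector(t(fw$V) %*% dB)
  datt <- fw$att * (dU - sum(fw$att * dU))
  dQ <- tcrossprod(fw$Q[, fw$m], datt)
  dQ[, fw$m] <- dQ[, fw$m] + as.vector(fw$Q %*% datt)
  g$Wv <- dV %*% t(H)
  g$Wq <- dQ %*% t(H)
  dH <- dH + t(params$Wv) %*% dV + t(params$Wq) %*% dQ
  list(grads = g, dH = dH)
}

#' Stoichiometry head forward: per-read 2-class scores
#' @keywords internal
stoich_forward <- function(params, H) {
  H1 <- pmax(params$Sh_W1 %*% H + params$Sh_b1, 0)
  S <- params$Sh_W2 %*% H1 + params$Sh_b2
  list(H1 = H1, S = S)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Adam with decoupled weight decay on the weight matrices (never on biases).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (weight_decay > 0 && grepl("W", nm, fixed = TRUE)) {
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
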