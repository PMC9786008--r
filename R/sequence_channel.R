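#' Sequence channel: self-attention encoding of FP2 substructure sequences
#'
#' The 256-token hexadecimal substructure sequence is embedded through a
#' 16-row lookup table, layer-normalized, passed through one multi-head
#' self-attention block with a residual connection and a second layer
#' normalization, flattened, and compressed by a feedforward unit
#' (linear -> batch norm -> linear -> LeakyReLU) into the sequence feature
#' of width `dim_out`. No positional encoding is used: token positions are
#' distinguished only through their symbol values, and the attention block
#' is permutation-equivariant by construction.
#'
#' @name sequence_channel
#' @keywords internal
NULL

.LN_EPS <- 1e-5
.BN_EPS <- 1e-5
.LEAKY_SLOPE <- 0.01

#' Construct (randomly initialized) sequence-encoder parameters
#'
#' Projections use variance-scaled Gaussian initialization
#' (`sd = 1/sqrt(fan_in)`); embeddings `N(0, 0.1^2)`; norm affines start at
#' identity. The per-head value width is `d_v = dim_embed / n_heads` and
#' must divide exactly.
#'
#' @param dim_embed token embedding width `dim'` (default 64).
#' @param n_heads number of attention heads `H` (default 2).
#' @param dim_ff feedforward hidden width (default 1024).
#' @param dim_out output feature width `dim` (default 300, matching the
#'   graph channel so the fused drug representation has width `4*dim`).
#' @param seq_len sequence length (256 for FP2 hex sequences).
#' @param dropout dropout rate applied, in training mode only, to attention
#'   weights and to the feedforward hidden layer (default 0.5).
#' @param seed optional seed for reproducible initialization.
#' @return an object of class `encoder_params`.
#' @export
encoder_params <- function(dim_embed = 64, n_heads = 2, dim_ff = 1024,
                           dim_out = 300, seq_len = 256, dropout = 0.5,
                           seed = NULL) {
  if (dim_embed %% n_heads != 0) {
    stop_config(sprintf("dim_embed (%d) must be divisible by n_heads (%d): d_v = dim_embed/n_heads must be an integer",
                        dim_embed, n_heads), field = "n_heads")
  }
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)", field = "dropout")
  d_v <- dim_embed %/% n_heads
  with_seed(seed, {
    rnm <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    structure(list(
      dim_embed = as.integer(dim_embed), n_heads = as.integer(n_heads),
      d_v = as.integer(d_v), dim_ff = as.integer(dim_ff),
      dim_out = as.integer(dim_out), seq_len = as.integer(seq_len),
      dropout = dropout,
      embed = rnm(16, dim_embed, 0.1),
      ln1_gamma = rep(1, dim_embed), ln1_beta = rep(0, dim_embed),
      Wq = lapply(seq.int(n_heads), function(h) rnm(dim_embed, d_v, 1 / sqrt(dim_embed))),
      Wk = lapply(seq.int(n_heads), function(h) rnm(dim_embed, d_v, 1 / sqrt(dim_embed))),
      Wv = lapply(seq.int(n_heads), function(h) rnm(dim_embed, d_v, 1 / sqrt(dim_embed))),
      Wo = rnm(n_heads * d_v, dim_embed, 1 / sqrt(n_heads * d_v)),
      ln2_gamma = rep(1, dim_embed), ln2_beta = rep(0, dim_embed),
      W1 = rnm(seq_len * dim_embed, dim_ff, 1 / sqrt(seq_len * dim_embed)),
      bn_gamma = rep(1, dim_ff), bn_beta = rep(0, dim_ff),
      bn_running_mean = rep(0, dim_ff), bn_running_var = rep(1, dim_ff),
      bn_momentum = 0.1,
      W2 = rnm(dim_ff, dim_out, 1 / sqrt(dim_ff))
    ), class = "encoder_params")
  })
}

.check_encoder <- function(params) {
  if (!inherits(params, "encoder_params")) stop_config("expected encoder_params")
  if (params$d_v * params$n_heads != params$dim_embed) {
    stop_config("d_v * n_heads must equal dim_embed", field = "d_v")
  }
}

# row-wise layer normalization with cache
.ln_forward <- function(X, gamma, beta, eps = .LN_EPS) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, gamma, `*`) + matrix(beta, nrow(X), ncol(X), byrow = TRUE),
       xhat = xhat, inv = inv)
}

.ln_backward <- function(dY, cache, gamma) {
  d <- ncol(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Embed a substructure sequence and layer-normalize it
#'
#' Each hexadecimal token indexes a row of the 16-entry embedding table;
#' each embedded row is then standardized across the embedding dimension
#' (mean `mu`, variance `sigma^2`) and affinely transformed by the
#' learnable scale/bias.
#'
#' @param seq a `substructure_sequence`, a 256-character hex string, or an
#'   integer token vector (values 1..16, any length; used by reduced-length
#'   oracle tests).
#' @param params an `encoder_params`.
#' @return a numeric matrix, length(seq) x `dim_embed`.
#' @export
embed_and_norm <- function(seq, params) {
  .check_encoder(params)
  tokens <- if (is.numeric(seq)) as.integer(seq) else sequence_tokens(seq)
  if (any(tokens < 1L | tokens > 16L)) {
    stop_featurize("token index outside the 16-symbol alphabet")
  }
  Eraw <- params$embed[tokens, , drop = FALSE]
  .ln_forward(Eraw, params$ln1_gamma, params$ln1_beta)$Y
}

#' Single-head scaled dot-product self-attention
#'
#' Computes `Q = E Wq`, `K = E Wk`, `V = E Wv`, attention weights
#' `softmax(Q K' / sqrt(d_v))` row by row, and the weighted sum `A V`.
#'
#' @param E an embedded sequence matrix (rows = tokens, `dim_embed` cols).
#' @param params an `encoder_params`.
#' @param head head index in `1..n_heads`.
#' @return the per-position output matrix (rows x `d_v`), with the attention
#'   weight matrix in attribute `"attention"`.
#' @export
self_attention <- function(E, params, head = 1) {
  .check_encoder(params)
  if (!is.matrix(E) || ncol(E) != params$dim_embed) {
    stop_config("E must have dim_embed columns", field = "E")
  }
  if (head < 1 || head > params$n_heads) stop_config("head index out of range", field = "head")
  Q <- E %*% params$Wq[[head]]
  K <- E %*% params$Wk[[head]]
  V <- E %*% params$Wv[[head]]
  A <- .row_softmax(Q %*% t(K) / sqrt(params$d_v))
  structure(A %*% V, attention = A)
}

#' Multi-head self-attention block with residual and layer normalization
#'
#' Runs every head, concatenates the per-head outputs, projects by `Wo`,
#' adds the input (residual connection) and applies the second layer
#' normalization.
#'
#' @inheritParams self_attention
#' @return matrix of the same shape as `E`.
#' @export
multi_head_encode <- function(E, params) {
  .check_encoder(params)
  heads <- lapply(seq_len(params$n_heads), function(h) self_attention(E, params, h))
  C <- do.call(cbind, heads)
  R <- E + C %*% params$Wo
  .ln_forward(R, params$ln2_gamma, params$ln2_beta)$Y
}

#' Feedforward compression of the encoded sequence
#'
#' Flattens the encoder output (token-major order), applies the first linear
#' map, batch normalization (running statistics in evaluation mode), the
#' second linear map, and a LeakyReLU activation (negative slope 0.01), in
#' exactly that nesting.
#'
#' @param O encoder output matrix (`seq_len` x `dim_embed`).
#' @param params an `encoder_params`.
#' @return numeric vector of length `dim_out`.
#' @export
feedforward_project <- function(O, params) {
  .check_encoder(params)
  x <- as.numeric(t(O))                       # token-major flatten
  if (length(x) != nrow(params$W1)) {
    stop_config("flattened input does not match W1", field = "W1")
  }
  z1 <- as.numeric(x %*% params$W1)
  z2 <- (z1 - params$bn_running_mean) / sqrt(params$bn_running_var + .BN_EPS) *
    params$bn_gamma + params$bn_beta
  z3 <- as.numeric(z2 %*% params$W2)
  ifelse(z3 >= 0, z3, .LEAKY_SLOPE * z3)
}

#' Full sequence channel in evaluation mode
#'
#' @param seq a `substructure_sequence` (or token vector of length
#'   `seq_len`).
#' @param params an `encoder_params`.
#' @return the sequence feature vector `X^f` of length `dim_out`.
#' @export
sequence_channel <- function(seq, params) {
  E <- embed_and_norm(seq, params)
  if (nrow(E) != params$seq_len) {
    stop_config(sprintf("sequence length %d does not match seq_len %d",
                        nrow(E), params$seq_len), field = "seq_len")
  }
  feedforward_project(multi_head_encode(E, params), params)
}

# --- training-mode forward/backward (internal) ------------------------------

# Attention block forward with cache for one sample. Dropout masks (inverted
# dropout on attention weights) are drawn from the ambient RNG when
# train = TRUE and dropout > 0.
.seq_attn_forward <- function(tokens, params, train = FALSE) {
  Eraw <- params$embed[tokens, , drop = FALSE]
  ln1 <- .ln_forward(Eraw, params$ln1_gamma, params$ln1_beta)
  E <- ln1$Y
  L <- nrow(E)
  heads <- vector("list", params$n_heads)
  for (h in seq_len(params$n_heads)) {
    Q <- E %*% params$Wq[[h]]
    K <- E %*% params$Wk[[h]]
    V <- E %*% params$Wv[[h]]
    A <- .row_softmax(Q %*% t(K) / sqrt(params$d_v))
    mask <- NULL
    Ad <- A
    if (train && params$dropout > 0) {
      mask <- matrix(stats::rbinom(L * L, 1, 1 - params$dropout), L, L) /
        (1 - params$dropout)
      Ad <- A * mask
    }
    heads[[h]] <- list(Q = Q, K = K, V = V, A = A, mask = mask, O = Ad %*% V)
  }
  C <- do.call(cbind, lapply(heads, `[[`, "O"))
  Oo <- C %*% params$Wo
  R <- E + Oo
  ln2 <- .ln_forward(R, params$ln2_gamma, params$ln2_beta)
  list(tokens = tokens, ln1 = ln1, E = E, heads = heads, C = C,
       out = ln2$Y, ln2 = ln2)
}

# Backward through the attention block for one sample given dOut.
# Returns parameter gradients and nothing else (the embedding table gradient
# is accumulated into `acc`, an environment-like list passed by the caller).
.seq_attn_backward <- function(cache, params, dOut, grads) {
  lb2 <- .ln_backward(dOut, cache$ln2, params$ln2_gamma)
  grads$ln2_gamma <- grads$ln2_gamma + lb2$dgamma
  grads$ln2_beta <- grads$ln2_beta + lb2$dbeta
  dR <- lb2$dX
  dE <- dR                                   # residual path
  dOo <- dR
  grads$Wo <- grads$Wo + t(cache$C) %*% dOo
  dC <- dOo %*% t(params$Wo)
  d_v <- params$d_v
  for (h in seq_len(params$n_heads)) {
    hc <- cache$heads[[h]]
    dOh <- dC[, ((h - 1) * d_v + 1):(h * d_v), drop = FALSE]
    Ad_grad <- dOh %*% t(hc$V)               # gradient wrt (possibly masked) A
    dV <- if (is.null(hc$mask)) t(hc$A) %*% dOh else t(hc$A * hc$mask) %*% dOh
    dA <- if (is.null(hc$mask)) Ad_grad else Ad_grad * hc$mask
    dS <- hc$A * (dA - rowSums(dA * hc$A))   # softmax backward
    dS <- dS / sqrt(d_v)
    dQ <- dS %*% hc$K
    dK <- t(dS) %*% hc$Q
    grads$Wq[[h]] <- grads$Wq[[h]] + t(cache$E) %*% dQ
    grads$Wk[[h]] <- grads$Wk[[h]] + t(cache$E) %*% dK
    grads$Wv[[h]] <- grads$Wv[[h]] + t(cache$E) %*% dV
    dE <- dE + dQ %*% t(params$Wq[[h]]) + dK %*% t(params$Wk[[h]]) +
      dV %*% t(params$Wv[[h]])
  }
  lb1 <- .ln_backward(dE, cache$ln1, params$ln1_gamma)
  grads$ln1_gamma <- grads$ln1_gamma + lb1$dgamma
  grads$ln1_beta <- grads$ln1_beta + lb1$dbeta
  rs <- rowsum(lb1$dX, cache$tokens)
  grads$embed[as.integer(rownames(rs)), ] <-
    grads$embed[as.integer(rownames(rs)), , drop = FALSE] + rs
  grads
}

# zero-filled gradient container matching encoder_params
.encoder_zero_grads <- function(params) {
  list(
    embed = matrix(0, 16, params$dim_embed),
    ln1_gamma = rep(0, params$dim_embed), ln1_beta = rep(0, params$dim_embed),
    Wq = lapply(params$Wq, function(w) w * 0),
    Wk = lapply(params$Wk, function(w) w * 0),
    Wv = lapply(params$Wv, function(w) w * 0),
    Wo = params$Wo * 0,
    ln2_gamma = rep(0, params$dim_embed), ln2_beta = rep(0, params$dim_embed),
    W1 = params$W1 * 0,
    bn_gamma = rep(0, params$dim_ff), bn_beta = rep(0, params$dim_ff),
    W2 = params$W2 * 0
  )
}

# Batch feedforward unit with batch-norm statistics over the minibatch.
# X: n x (seq_len * dim_embed). Returns output n x dim_out plus cache; in
# training mode updates running statistics (returned in `params`).
.seq_ff_forward <- function(X, params, train = FALSE) {
  Z1 <- X %*% params$W1
  n <- nrow(X)
  if (train && n > 1) {
    mu <- colMeans(Z1)
    zc <- sweep(Z1, 2, mu)
    v <- colMeans(zc^2)
    params$bn_running_mean <- (1 - params$bn_momentum) * params$bn_running_mean +
      params$bn_momentum * mu
    params$bn_running_var <- (1 - params$bn_momentum) * params$bn_running_var +
      params$bn_momentum * v * n / max(n - 1, 1)
  } else {
    mu <- params$bn_running_mean
    v <- params$bn_running_var
    zc <- sweep(Z1, 2, mu)
  }
  inv <- 1 / sqrt(v + .BN_EPS)
  xhat <- sweep(zc, 2, inv, `*`)
  Z2 <- sweep(xhat, 2, params$bn_gamma, `*`) +
    matrix(params$bn_beta, n, params$dim_ff, byrow = TRUE)
  mask <- NULL
  Z2d <- Z2
  if (train && params$dropout > 0) {
    mask <- matrix(stats::rbinom(length(Z2), 1, 1 - params$dropout),
                   nrow(Z2), ncol(Z2)) / (1 - params$dropout)
    Z2d <- Z2 * mask
  }
  Z3 <- Z2d %*% params$W2
  Y <- ifelse(Z3 >= 0, Z3, .LEAKY_SLOPE * Z3)
  list(Y = Y, cache = list(X = X, xhat = xhat, inv = inv, mask = mask,
                           Z2d = Z2d, Z3 = Z3, train = train && n > 1),
       params = params)
}

.seq_ff_backward <- function(dY, cache, params, grads) {
  dZ3 <- dY * ifelse(cache$Z3 >= 0, 1, .LEAKY_SLOPE)
  grads$W2 <- grads$W2 + t(cache$Z2d) %*% dZ3
  dZ2 <- dZ3 %*% t(params$W2)
  if (!is.null(cache$mask)) dZ2 <- dZ2 * cache$mask
  grads$bn_gamma <- grads$bn_gamma + colSums(dZ2 * cache$xhat)
  grads$bn_beta <- grads$bn_beta + colSums(dZ2)
  dxhat <- sweep(dZ2, 2, params$bn_gamma, `*`)
  n <- nrow(dZ2)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dZ1 <- sweep(dxhat - matrix(m1, n, ncol(dxhat), byrow = TRUE) -
                   cache$xhat * matrix(m2, n, ncol(dxhat), byrow = TRUE),
                 2, cache$inv, `*`)
  } else {
    dZ1 <- sweep(dxhat, 2, cache$inv, `*`)
  }
  grads$W1 <- grads$W1 + t(cache$X) %*% dZ1
  dX <- dZ1 %*% t(params$W1)
  list(dX = dX, grads = grads)
}
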