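make_enc <- function(...) encoder_params(dim_embed = 8, n_heads = 2,
                                         dim_ff = 12, dim_out = 6,
                                         seq_len = 8, dropout = 0, ...)

test_that("the head-count constraint d_v * H = dim' is enforced at construction", {
  expect_error(encoder_params(dim_embed = 10, n_heads = 3),
               class = "moladr_config_error")
  p <- make_enc(seed = 1)
  expect_equal(p$d_v * p$n_heads, p$dim_embed)
})

test_that("embedding + layer norm standardizes each token row", {
  p <- make_enc(seed = 2)
  tok <- c(1L, 5L, 16L, 9L, 3L, 3L, 12L, 7L)
  E <- embed_and_norm(tok, p)
  expect_equal(dim(E), c(8L, 8L))
  expect_equal(rowMeans(E), rep(0, 8), tolerance = 1e-12)
  expect_equal(apply(E, 1, function(r) mean(r^2)), rep(1, 8), tolerance = 1e-2)

  # a constant embedding row normalizes to zero before the affine
  p2 <- p
  p2$embed[4, ] <- 2.5
  expect_equal(as.numeric(embed_and_norm(4L, p2)), rep(0, 8), tolerance = 1e-2)

  # full-length contract on a real sequence
  p256 <- encoder_params(dim_embed = 8, n_heads = 2, dim_ff = 12, dim_out = 6,
                         seed = 3)
  E256 <- embed_and_norm(fp2_hex_sequence("CCO"), p256)
  expect_equal(dim(E256), c(256L, 8L))

  expect_error(embed_and_norm(c(0L, 5L), p), class = "moladr_featurize_error")
})

test_that("attention weights are row-stochastic and uniform for identical rows", {
  p <- make_enc(seed = 4)
  E <- matrix(rnorm(8 * 8), 8, 8)
  O <- self_attention(E, p, head = 1)
  A <- attr(O, "attention")
  expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-6)
  expect_true(all(A >= 0))

  # identical input rows -> every attention row uniform
  E2 <- matrix(rep(rnorm(8), each = 8), 8, 8)
  A2 <- attr(self_attention(E2, p, 1), "attention")
  expect_equal(as.numeric(A2), rep(1 / 8, 64), tolerance = 1e-9)

  # and at full length the uniform weight is 1/256
  p256 <- encoder_params(dim_embed = 8, n_heads = 2, dim_ff = 12, dim_out = 6,
                         seed = 5)
  E3 <- matrix(rep(rnorm(8), each = 256), 256, 8)
  A3 <- attr(self_attention(E3, p256, 2), "attention")
  expect_equal(max(abs(A3 - 1 / 256)), 0, tolerance = 1e-9)
})

test_that("single-head attention matches the brute-force double-loop oracle", {
  p <- make_enc(seed = 6)
  tok <- sample(16, 8, replace = TRUE)
  E <- embed_and_norm(tok, p)
  for (h in 1:2) {
    or <- attention_oracle(E, p$Wq[[h]], p$Wk[[h]], p$Wv[[h]])
    O <- self_attention(E, p, h)
    expect_equal(unname(as.matrix(O)), or$O, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(unname(attr(O, "attention")), or$A, tolerance = 1e-9)
  }
})

test_that("multi-head encoding = concat heads, project, residual, layer norm", {
  p <- make_enc(seed = 7)
  E <- embed_and_norm(sample(16, 8, replace = TRUE), p)
  o1 <- attention_oracle(E, p$Wq[[1]], p$Wk[[1]], p$Wv[[1]])$O
  o2 <- attention_oracle(E, p$Wq[[2]], p$Wk[[2]], p$Wv[[2]])$O
  R <- E + cbind(o1, o2) %*% p$Wo
  mu <- rowMeans(R); v <- apply(R, 1, function(r) mean((r - mean(r))^2))
  expected <- (R - mu) / sqrt(v + 1e-5)
  expect_equal(unname(multi_head_encode(E, p)), unname(expected),
               tolerance = 1e-9, ignore_attr = TRUE)

  # zero Q/K/V/O weights: the block reduces to LN of the residual input
  p0 <- p
  for (h in 1:2) { p0$Wq[[h]][] <- 0; p0$Wk[[h]][] <- 0; p0$Wv[[h]][] <- 0 }
  p0$Wo[] <- 0
  mu <- rowMeans(E); v <- apply(E, 1, function(r) mean((r - mean(r))^2))
  expect_equal(unname(multi_head_encode(E, p0)),
               unname((E - mu) / sqrt(v + 1e-5)), tolerance = 1e-9)
})

test_that("a single head with identity output projection degenerates to head + residual + norm", {
  p <- encoder_params(dim_embed = 6, n_heads = 1, dim_ff = 10, dim_out = 4,
                      seq_len = 8, dropout = 0, seed = 8)
  p$Wo <- diag(6)
  E <- embed_and_norm(sample(16, 8, replace = TRUE), p)
  O1 <- as.matrix(self_attention(E, p, 1))
  R <- E + O1
  mu <- rowMeans(R); v <- apply(R, 1, function(r) mean((r - mean(r))^2))
  expect_equal(unname(multi_head_encode(E, p)),
               unname((R - mu) / sqrt(v + 1e-5)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the attention block is permutation-equivariant over token positions", {
  p <- make_enc(seed = 9)
  E <- embed_and_norm(sample(16, 8, replace = TRUE), p)
  perm <- sample(8)
  expect_equal(multi_head_encode(E[perm, ], p),
               multi_head_encode(E, p)[perm, ], tolerance = 1e-9)
})

test_that("the feedforward unit computes LeakyReLU(BN(flatten(O) W1) W2)", {
  p <- make_enc(seed = 10)
  O <- matrix(rnorm(8 * 8), 8, 8)
  # closed form with unit running stats and identity affine
  x <- as.numeric(t(O))
  z1 <- as.numeric(x %*% p$W1)
  z2 <- z1 / sqrt(1 + 1e-5)
  z3 <- as.numeric(z2 %*% p$W2)
  expect_equal(feedforward_project(O, p), ifelse(z3 >= 0, z3, 0.01 * z3),
               tolerance = 1e-12)

  # W2 = 0 gives exactly zero output
  p0 <- p; p0$W2[] <- 0
  expect_equal(feedforward_project(O, p0), rep(0, 6))

  # identity-padded linear maps pass through the leading coordinates
  pid <- p
  pid$W1[] <- 0; diag(pid$W1[1:12, 1:12]) <- 1
  pid$W2[] <- 0; diag(pid$W2[1:6, 1:6]) <- 1
  lead <- x[1:6] / sqrt(1 + 1e-5)
  expect_equal(feedforward_project(O, pid),
               ifelse(lead >= 0, lead, 0.01 * lead), tolerance = 1e-12)
})

test_that("the full sequence channel is deterministic in evaluation mode", {
  p <- encoder_params(dim_embed = 8, n_heads = 2, dim_ff = 12, dim_out = 6,
                      seed = 11)
  s <- fp2_hex_sequence("CC(=O)Oc1ccccc1C(=O)O")
  x1 <- sequence_channel(s, p)
  x2 <- sequence_channel(s, p)
  expect_identical(x1, x2)
  expect_length(x1, 6)
})
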