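test_that("the fused representation has width exactly 4*dim and sigmoid outputs", {
  m <- tiny_model(n_labels = 4, seed = 1)
  expect_equal(nrow(m$W_pred), 4 * m$dim)
  mol <- list(id = "x", smiles = "CC(=O)Oc1ccccc1C(=O)O")
  p <- model_forward(m, mol)
  expect_length(p, 4)
  expect_true(all(p > 0 & p < 1))

  # zero prediction weights: sigmoid(0) = 0.5 for every label
  m0 <- m; m0$W_pred[] <- 0
  expect_equal(unname(model_forward(m0, mol)), rep(0.5, 4))

  # evaluation mode is deterministic
  expect_identical(model_forward(m, mol), model_forward(m, mol))
})

test_that("featurization errors propagate through the forward pass with the id", {
  m <- tiny_model(seed = 2)
  err <- expect_error(model_forward(m, list(id = "bad", smiles = "C(")),
                      class = "moladr_featurize_error")
  expect_match(conditionMessage(err), "C\\(")
})

test_that("binary cross-entropy matches its closed forms and a direct oracle", {
  expect_equal(bce_loss(c(0.5, 0.5, 0.5), c(1, 0, 1)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.5, 0.5), c(0, 0)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-9)
  set.seed(3)
  p <- runif(6, 0.05, 0.95); y <- rbinom(6, 1, 0.5)
  expect_equal(bce_loss(p, y), -mean(y * log(p) + (1 - y) * log(1 - p)),
               tolerance = 1e-12)
  expect_error(bce_loss(c(0.2, 0.3), c(1)), class = "moladr_config_error")
})

test_that("analytic gradients agree with central finite differences", {
  m <- adr_model(n_labels = 3, dim = 5, dim_embed = 4, n_heads = 2, dim_ff = 6,
                 n_iter = 2, dropout = 0, seed = 11)
  recs <- tiny_records(n = 3, n_labels = 3, seed = 5)
  feats <- lapply(recs, function(r) {
    f <- list(id = r$id, smiles = r$smiles,
              graph = smiles_to_graph(r$smiles),
              seq = fp2_hex_sequence(r$smiles))
    f$tokens <- sequence_tokens(f$seq)
    f
  })
  Y <- do.call(rbind, lapply(recs, `[[`, "labels"))
  bg <- moladr:::.batch_grad(m, feats, Y, train = TRUE)
  flat <- moladr:::.flat_params(m)
  loss_at <- function(model) moladr:::.batch_grad(model, feats, Y, train = TRUE)$loss
  eps <- 1e-6
  set.seed(21)
  for (nm in names(flat)) {
    x <- flat[[nm]]
    for (i in sample(length(x), min(2, length(x)))) {
      f2 <- flat
      f2[[nm]][i] <- f2[[nm]][i] + eps
      lp <- loss_at(moladr:::.unflat_params(m, f2))
      f2[[nm]][i] <- f2[[nm]][i] - 2 * eps
      lm_ <- loss_at(moladr:::.unflat_params(m, f2))
      num <- (lp - lm_) / (2 * eps)
      expect_equal(bg$grads[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("analytic gradient of %s[%d]", nm, i))
    }
  }
})

test_that("training is seed-deterministic and overfits a small noise-free set", {
  recs <- tiny_records(n = 8, n_labels = 3, seed = 7)
  m <- tiny_model(n_labels = 3, seed = 2)
  f1 <- train_adr_model(recs, m, epochs = 3, batch_size = 4, seed = 3)
  f2 <- train_adr_model(recs, m, epochs = 3, batch_size = 4, seed = 3)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$model, f2$model)

  fit <- train_adr_model(recs, m, epochs = 200, batch_size = 8, seed = 3)
  expect_lt(fit$loss[200], 0.05)
  # loss on separable toy data trends down in full-batch mode
  expect_lt(mean(fit$loss[191:200]), mean(fit$loss[1:10]))
})

test_that("L2 regularization shrinks parameter norms on identical seeds/data", {
  recs <- tiny_records(n = 6, n_labels = 3, seed = 9)
  norm_of <- function(l2) {
    m <- adr_model(n_labels = 3, dim = 8, dim_embed = 8, n_heads = 2,
                   dim_ff = 16, n_iter = 2, dropout = 0, l2 = l2, seed = 4)
    fit <- train_adr_model(recs, m, epochs = 15, batch_size = 6, seed = 5)
    sum(vapply(moladr:::.flat_params(fit$model),
               function(x) sum(x^2), numeric(1)))
  }
  expect_lt(norm_of(0.01), norm_of(0))
})

test_that("prediction binarizes at the threshold with the >= tie rule", {
  m <- tiny_model(n_labels = 2, seed = 6)
  m$W_pred[] <- 0   # every probability exactly 0.5
  mols <- data.frame(id = c("a", "b"), smiles = c("CCO", "CCN"))
  out <- predict_batch(m, mols, threshold = 0.5)
  expect_true(all(out$labels == 1L))       # tie 0.5 >= 0.5 -> 1
  expect_true(all(predict_batch(m, mols, threshold = 0)$labels == 1L))
  expect_true(all(predict_batch(m, mols, threshold = 1)$labels == 0L))

  # featurization failures are collected, not fatal
  mols2 <- data.frame(id = c("a", "bad"), smiles = c("CCO", "C("))
  out2 <- predict_batch(m, mols2)
  expect_equal(nrow(out2$prob), 1)
  expect_equal(out2$failed$id, "bad")
})

test_that("checkpoints round-trip predictions bit-for-bit and validate schema", {
  recs <- tiny_records(n = 4, n_labels = 3, seed = 8)
  m <- tiny_model(n_labels = 3, seed = 7)
  fit <- train_adr_model(recs, m, epochs = 2, batch_size = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  mol <- list(id = "q", smiles = "CCOC(C)C")
  expect_identical(model_forward(fit$model, mol), model_forward(m2, mol))

  expect_error(load_checkpoint(path, n_labels = 5),
               class = "moladr_config_error")
  expect_error(load_checkpoint(tempfile()), class = "moladr_io_error")

  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 80), trunc)
  expect_error(load_checkpoint(trunc), class = "moladr_io_error")
})
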