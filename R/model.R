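#' Fused dual-channel multi-label ADR predictor
#'
#' The drug representation is the concatenation
#' `X = [X^m, X^e, X^c, X^f]` of the three objective-tagged graph
#' embeddings and the sequence feature, of width exactly `4*dim`. A single
#' linear layer with a sigmoid produces one probability per ADR label;
#' training minimizes mean per-label binary cross-entropy with Adam
#' (learning rate 0.001) and L2 regularization (coefficient 0.001), the
#' rates at which the reference configuration performs best, with 2
#' attention heads and dropout 0.5.
#'
#' @name model
#' @keywords internal
NULL

#' Construct an untrained dual-channel ADR model
#'
#' @param n_labels number of ADR classes (27 for the SOC setting, 4 for the
#'   OMOP-style setting).
#' @param dim width of each of the four structural features (default 300).
#' @param dim_embed sequence-channel token embedding width (default 64).
#' @param n_heads attention heads (default 2).
#' @param dim_ff feedforward hidden width (default 1024).
#' @param n_iter GIN message-passing rounds (default 5).
#' @param dropout dropout rate (default 0.5; training mode only).
#' @param lr Adam learning rate (default 0.001).
#' @param l2 L2-regularization coefficient (default 0.001).
#' @param finetune_gin should the three GIN encoders be updated during
#'   supervised training (default TRUE)? When FALSE they stay frozen, e.g.
#'   after loading pretrained weights.
#' @param seed optional seed for reproducible initialization.
#' @param gin_weights optional named list (`m`, `e`, `c`) of `gin_params`
#'   (e.g. from [load_gin_weights()]) used instead of random initialization.
#' @return an object of class `adr_model`.
#' @export
adr_model <- function(n_labels, dim = 300, dim_embed = 64, n_heads = 2,
                      dim_ff = 1024, n_iter = 5, dropout = 0.5, lr = 0.001,
                      l2 = 0.001, finetune_gin = TRUE, seed = NULL,
                      gin_weights = NULL) {
  if (n_labels < 1) stop_config("n_labels must be >= 1", field = "n_labels")
  with_seed(seed, {
    gin <- if (is.null(gin_weights)) {
      list(m = gin_params(dim, n_iter, "m"),
           e = gin_params(dim, n_iter, "e"),
           c = gin_params(dim, n_iter, "c"))
    } else {
      for (tag in c("m", "e", "c")) {
        p <- gin_weights[[tag]]
        if (!inherits(p, "gin_params")) stop_config("gin_weights must hold gin_params for m/e/c")
        if (p$dim != dim) stop_config("gin_weights dim mismatch", field = "dim")
      }
      gin_weights
    }
    enc <- encoder_params(dim_embed = dim_embed, n_heads = n_heads,
                          dim_ff = dim_ff, dim_out = dim, dropout = dropout)
    structure(list(
      n_labels = as.integer(n_labels),
      dim = as.integer(dim),
      finetune_gin = isTRUE(finetune_gin),
      gin = gin,
      enc = enc,
      W_pred = matrix(stats::rnorm(4 * dim * n_labels, sd = 1 / sqrt(4 * dim)),
                      4 * dim, n_labels),
      hyper = list(n_heads = n_heads, dropout = dropout, lr = lr, l2 = l2)
    ), class = "adr_model")
  })
}

#' @export
print.adr_model <- function(x, ...) {
  cat(sprintf(
    "<adr_model> %d labels | dim=%d (fused %d) | heads=%d dropout=%g lr=%g l2=%g | GIN %s\n",
    x$n_labels, x$dim, 4 * x$dim, x$hyper$n_heads, x$hyper$dropout,
    x$hyper$lr, x$hyper$l2, if (x$finetune_gin) "fine-tuned" else "frozen"))
  invisible(x)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.featurize_one <- function(x) {
  if (!is.null(x$graph) && !is.null(x$seq)) return(x)
  if (is.null(x$smiles)) stop_validation("molecule needs a 'smiles' field")
  list(id = x$id, smiles = x$smiles,
       graph = smiles_to_graph(x$smiles),
       seq = fp2_hex_sequence(x$smiles))
}

#' Forward pass: per-label ADR probabilities for one molecule
#'
#' Concatenates the three graph embeddings and the sequence feature and
#' applies the sigmoid prediction layer. Evaluation mode is deterministic;
#' training mode draws dropout masks from the ambient RNG.
#'
#' @param model an `adr_model`.
#' @param molecule a list with `smiles` (and optionally `id`), or an
#'   already-featurized `list(graph =, seq =)`.
#' @param mode `"eval"` (default) or `"train"`.
#' @return numeric vector of `n_labels` probabilities, each strictly in
#'   (0, 1).
#' @export
model_forward <- function(model, molecule, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  f <- .featurize_one(molecule)
  tokens <- sequence_tokens(f$seq)
  xm <- as.numeric(gin_encode(f$graph, model$gin$m))
  xe <- as.numeric(gin_encode(f$graph, model$gin$e))
  xc <- as.numeric(gin_encode(f$graph, model$gin$c))
  train <- mode == "train"
  attn <- .seq_attn_forward(tokens, model$enc, train = train)
  # single-molecule forward: batch-norm always uses running statistics
  ff <- .seq_ff_forward(matrix(as.numeric(t(attn$out)), 1), model$enc,
                        train = FALSE)
  xf <- as.numeric(ff$Y)
  X <- c(xm, xe, xc, xf)
  p <- .sigmoid(as.numeric(X %*% model$W_pred))
  names(p) <- colnames(model$W_pred)
  p
}

#' Mean per-label binary cross-entropy
#'
#' @param pred probability vector (or matrix) in (0, 1).
#' @param truth binary vector (or matrix) of the same shape.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_config("pred and truth lengths differ", field = "truth")
  }
  p <- pmin(pmax(as.numeric(pred), 1e-12), 1 - 1e-12)
  y <- as.numeric(truth)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- parameter flattening for the optimizer ---------------------------------

.flat_params <- function(model) {
  out <- list(W_pred = model$W_pred)
  e <- model$enc
  for (f in c("embed", "ln1_gamma", "ln1_beta", "Wo", "ln2_gamma", "ln2_beta",
              "W1", "bn_gamma", "bn_beta", "W2")) {
    out[[paste0("enc.", f)]] <- e[[f]]
  }
  for (h in seq_len(e$n_heads)) {
    out[[paste0("enc.Wq.", h)]] <- e$Wq[[h]]
    out[[paste0("enc.Wk.", h)]] <- e$Wk[[h]]
    out[[paste0("enc.Wv.", h)]] <- e$Wv[[h]]
  }
  if (model$finetune_gin) {
    for (tag in c("m", "e", "c")) {
      g <- model$gin[[tag]]
      for (t in seq_len(g$n_iter)) {
        out[[paste0("gin.", tag, ".W.", t)]] <- g$W[[t]]
      }
      for (f in c("emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
        out[[paste0("gin.", tag, ".", f)]] <- g[[f]]
      }
    }
  }
  out
}

.unflat_params <- function(model, flat) {
  model$W_pred <- flat$W_pred
  e <- model$enc
  for (f in c("embed", "ln1_gamma", "ln1_beta", "Wo", "ln2_gamma", "ln2_beta",
              "W1", "bn_gamma", "bn_beta", "W2")) {
    e[[f]] <- flat[[paste0("enc.", f)]]
  }
  for (h in seq_len(e$n_heads)) {
    e$Wq[[h]] <- flat[[paste0("enc.Wq.", h)]]
    e$Wk[[h]] <- flat[[paste0("enc.Wk.", h)]]
    e$Wv[[h]] <- flat[[paste0("enc.Wv.", h)]]
  }
  model$enc <- e
  if (model$finetune_gin) {
    for (tag in c("m", "e", "c")) {
      g <- model$gin[[tag]]
      for (t in seq_len(g$n_iter)) {
        g$W[[t]] <- flat[[paste0("gin.", tag, ".W.", t)]]
      }
      for (f in c("emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
        g[[f]] <- flat[[paste0("gin.", tag, ".", f)]]
      }
      model$gin[[tag]] <- g
    }
  }
  model
}

.flat_grads <- function(model, dW_pred, enc_grads, gin_grads) {
  out <- list(W_pred = dW_pred)
  for (f in c("embed", "ln1_gamma", "ln1_beta", "Wo", "ln2_gamma", "ln2_beta",
              "W1", "bn_gamma", "bn_beta", "W2")) {
    out[[paste0("enc.", f)]] <- enc_grads[[f]]
  }
  for (h in seq_len(model$enc$n_heads)) {
    out[[paste0("enc.Wq.", h)]] <- enc_grads$Wq[[h]]
    out[[paste0("enc.Wk.", h)]] <- enc_grads$Wk[[h]]
    out[[paste0("enc.Wv.", h)]] <- enc_grads$Wv[[h]]
  }
  if (model$finetune_gin) {
    for (tag in c("m", "e", "c")) {
      g <- gin_grads[[tag]]
      for (t in seq_along(g$W)) {
        out[[paste0("gin.", tag, ".W.", t)]] <- g$W[[t]]
      }
      for (f in c("emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
        out[[paste0("gin.", tag, ".", f)]] <- g[[f]]
      }
    }
  }
  out
}

.zero_gin_grads <- function(params) {
  list(W = lapply(params$W, function(w) w * 0),
       emb_atomic = params$emb_atomic * 0,
       emb_chirality = params$emb_chirality * 0,
       emb_bond_type = params$emb_bond_type * 0,
       emb_bond_dir = params$emb_bond_dir * 0)
}

# Forward + backward over one minibatch; returns loss, flat gradients and
# the (BN-updated) encoder params.
.batch_grad <- function(model, feats, Y, train = TRUE) {
  nb <- length(feats)
  dim <- model$dim
  gin_caches <- list()
  attn_caches <- vector("list", nb)
  Xg <- matrix(0, nb, 3 * dim)
  Xflat <- matrix(0, nb, model$enc$seq_len * model$enc$dim_embed)
  for (i in seq_len(nb)) {
    f <- feats[[i]]
    cm <- gin_forward(f$graph, model$gin$m)
    ce <- gin_forward(f$graph, model$gin$e)
    cc <- gin_forward(f$graph, model$gin$c)
    gin_caches[[i]] <- list(m = cm, e = ce, c = cc)
    Xg[i, ] <- c(cm$embedding, ce$embedding, cc$embedding)
    attn_caches[[i]] <- .seq_attn_forward(f$tokens, model$enc, train = train)
    Xflat[i, ] <- as.numeric(t(attn_caches[[i]]$out))
  }
  ffw <- .seq_ff_forward(Xflat, model$enc, train = train)
  model$enc <- ffw$params               # running BN statistics advanced
  X <- cbind(Xg, ffw$Y)
  P <- .sigmoid(X %*% model$W_pred)
  loss <- bce_loss(P, Y)

  dZ <- (P - Y) / (nb * model$n_labels)
  dW_pred <- t(X) %*% dZ
  dX <- dZ %*% t(model$W_pred)

  enc_grads <- .encoder_zero_grads(model$enc)
  fb <- .seq_ff_backward(dX[, (3 * dim + 1):(4 * dim), drop = FALSE],
                         ffw$cache, model$enc, enc_grads)
  enc_grads <- fb$grads
  gin_grads <- NULL
  if (model$finetune_gin) {
    gin_grads <- list(m = .zero_gin_grads(model$gin$m),
                      e = .zero_gin_grads(model$gin$e),
                      c = .zero_gin_grads(model$gin$c))
  }
  for (i in seq_len(nb)) {
    dOut <- matrix(fb$dX[i, ], ncol = model$enc$dim_embed, byrow = TRUE)
    enc_grads <- .seq_attn_backward(attn_caches[[i]], model$enc, dOut, enc_grads)
    if (model$finetune_gin) {
      f <- feats[[i]]
      for (k in seq_along(c("m", "e", "c"))) {
        tag <- c("m", "e", "c")[k]
        d_emb <- dX[i, ((k - 1) * dim + 1):(k * dim)]
        gr <- gin_backward(f$graph, model$gin[[tag]], gin_caches[[i]][[tag]], d_emb)
        gin_grads[[tag]] <- .add_grads(gin_grads[[tag]], gr)
      }
    }
  }
  list(loss = loss, model = model,
       grads = .flat_grads(model, dW_pred, enc_grads, gin_grads))
}

#' Train the dual-channel ADR model
#'
#' Minibatch Adam on mean binary cross-entropy, with L2 regularization
#' added to every learnable tensor's gradient. Dropout and batch-norm batch
#' statistics are active; the run is deterministic given `seed`. Molecules
#' are featurized once up front (strict policy).
#'
#' @param records a list of drug records (`id`, `smiles`, `labels`) as
#'   returned by [load_drug_dataset()] or [generate_synthetic()], or a
#'   data.frame with `id`, `smiles` and binary label columns.
#' @param model an `adr_model` whose `n_labels` matches the records.
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return a list of class `adr_fit`: `model` (trained), `loss` (per-epoch
#'   mean training loss), `epochs`, `batch_size`, `seed`.
#' @export
train_adr_model <- function(records, model, epochs = 100, batch_size = 32,
                            seed = NULL, verbose = FALSE) {
  records <- as_drug_records(records)
  if (length(records) == 0) stop_validation("empty training set")
  Y <- do.call(rbind, lapply(records, `[[`, "labels"))
  dimnames(Y) <- NULL          # keep label names out of the weight tensors
  if (ncol(Y) != model$n_labels) {
    stop_config(sprintf("records have %d labels but model expects %d",
                        ncol(Y), model$n_labels), field = "n_labels")
  }
  feats <- lapply(records, function(r) {
    f <- .featurize_one(r)
    f$tokens <- sequence_tokens(f$seq)
    f
  })
  lr <- model$hyper$lr
  l2 <- model$hyper$l2
  adam_m <- NULL; adam_v <- NULL; step <- 0L
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(feats))
      batch_losses <- c()
      for (start in seq(1, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ord))]
        bg <- .batch_grad(model, feats[idx], Y[idx, , drop = FALSE], train = TRUE)
        model <- bg$model
        batch_losses <- c(batch_losses, bg$loss)
        flat <- .flat_params(model)
        g <- bg$grads
        if (is.null(adam_m)) {
          adam_m <- lapply(flat, function(x) x * 0)
          adam_v <- adam_m
        }
        step <- step + 1L
        for (nm in names(flat)) {
          gr <- g[[nm]] + l2 * flat[[nm]]
          adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * gr
          adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * gr^2
          mhat <- adam_m[[nm]] / (1 - 0.9^step)
          vhat <- adam_v[[nm]] / (1 - 0.999^step)
          flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
        model <- .unflat_params(model, flat)
      }
      losses[ep] <- mean(batch_losses)
      if (!is.finite(losses[ep])) {
        stop_divergence(sprintf("non-finite training loss at epoch %d", ep),
                        epoch = ep)
      }
      if (verbose) message(sprintf("epoch %d: loss %.5f", ep, losses[ep]))
    }
  })
  structure(list(model = model, loss = losses, epochs = epochs,
                 batch_size = batch_size, seed = seed), class = "adr_fit")
}

#' @export
print.adr_fit <- function(x, ...) {
  cat(sprintf("<adr_fit> %d epochs, final loss %.5f\n",
              x$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict ADR probabilities and labels for a batch of molecules
#'
#' Probabilities come from the deterministic evaluation-mode forward pass;
#' labels binarize at the threshold with the tie rule `>=` (a probability
#' exactly equal to the threshold maps to 1). Featurization failures are
#' collected per molecule id, not fatal.
#'
#' @param model a trained `adr_model`.
#' @param molecules data.frame with `id`, `smiles`, or a list of records.
#' @param threshold binarization threshold in \[0, 1\] (default 0.5).
#' @return list with `prob` (matrix, rows = molecules), `labels` (binary
#'   matrix), `failed` (data.frame id/reason).
#' @export
predict_batch <- function(model, molecules, threshold = 0.5) {
  if (is.data.frame(molecules)) {
    molecules <- lapply(seq_len(nrow(molecules)), function(i)
      list(id = as.character(molecules$id[i]), smiles = molecules$smiles[i]))
  }
  probs <- list(); ids <- character(0)
  failed <- data.frame(id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  for (m in molecules) {
    p <- tryCatch(model_forward(model, m, mode = "eval"),
                  moladr_featurize_error = function(e) e)
    if (inherits(p, "moladr_featurize_error")) {
      failed <- rbind(failed, data.frame(id = as.character(m$id),
                                         reason = conditionMessage(p),
                                         stringsAsFactors = FALSE))
    } else {
      probs[[length(probs) + 1L]] <- p
      ids <- c(ids, as.character(m$id))
    }
  }
  prob <- do.call(rbind, probs)
  if (is.null(prob)) prob <- matrix(0, 0, model$n_labels)
  rownames(prob) <- ids
  labels <- (prob >= threshold) * 1L
  list(prob = prob, labels = labels, failed = failed)
}

# --- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned JSON (`moladr-model/1`) holding every weight,
#' batch-norm running statistic and hyperparameter at full precision, so a
#' reloaded model reproduces evaluation-mode predictions bit for bit.
#'
#' @param model an `adr_model`.
#' @param path file path.
#' @param n_labels optional expectation checked against the stored model;
#'   a mismatch raises a configuration error.
#' @return `load_checkpoint` returns an `adr_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "adr_model")) stop_config("expected adr_model")
  enc <- unclass(model$enc)
  # per-head / per-round tensor lists are stored as named objects so JSON
  # readers cannot collapse them into single arrays
  name_heads <- function(x) stats::setNames(x, paste0("h", seq_along(x)))
  enc$Wq <- name_heads(enc$Wq); enc$Wk <- name_heads(enc$Wk)
  enc$Wv <- name_heads(enc$Wv)
  obj <- list(
    schema = "moladr-model/1",
    n_labels = model$n_labels, dim = model$dim,
    finetune_gin = model$finetune_gin,
    hyper = model$hyper,
    enc = enc,
    gin = lapply(model$gin, function(g) {
      g <- unclass(g)
      g$W <- stats::setNames(g$W, paste0("t", seq_along(g$W)))
      g
    }),
    W_pred = model$W_pred
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, n_labels = NULL) {
  if (!file.exists(path)) stop_io(sprintf("checkpoint not found: %s", path),
                                  path = path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(obj) || !identical(obj$schema, "moladr-model/1")) {
    stop_io(sprintf("not a moladr-model/1 checkpoint: %s", path), path = path)
  }
  if (!is.null(n_labels) && as.integer(obj$n_labels) != as.integer(n_labels)) {
    stop_config(sprintf("checkpoint has n_labels=%d, expected %d",
                        as.integer(obj$n_labels), as.integer(n_labels)),
                field = "n_labels")
  }
  enc <- obj$enc
  enc$Wq <- unname(lapply(if (is.list(enc$Wq)) enc$Wq else list(enc$Wq), .as_matrix))
  enc$Wk <- unname(lapply(if (is.list(enc$Wk)) enc$Wk else list(enc$Wk), .as_matrix))
  enc$Wv <- unname(lapply(if (is.list(enc$Wv)) enc$Wv else list(enc$Wv), .as_matrix))
  for (f in c("embed", "Wo", "W1", "W2")) enc[[f]] <- .as_matrix(enc[[f]])
  for (f in c("dim_embed", "n_heads", "d_v", "dim_ff", "dim_out", "seq_len")) {
    enc[[f]] <- as.integer(enc[[f]])
  }
  class(enc) <- "encoder_params"
  gin <- lapply(obj$gin, function(g) {
    g$W <- unname(lapply(if (is.list(g$W)) g$W else list(g$W), .as_matrix))
    for (f in c("emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
      g[[f]] <- .as_matrix(g[[f]])
    }
    g$dim <- as.integer(g$dim); g$n_iter <- as.integer(g$n_iter)
    class(g) <- "gin_params"
    g
  })
  m <- structure(list(
    n_labels = as.integer(obj$n_labels), dim = as.integer(obj$dim),
    finetune_gin = isTRUE(obj$finetune_gin),
    gin = gin, enc = enc, W_pred = .as_matrix(obj$W_pred),
    hyper = obj$hyper
  ), class = "adr_model")
  if (nrow(m$W_pred) != 4 * m$dim || ncol(m$W_pred) != m$n_labels) {
    stop_config("W_pred shape inconsistent with dim/n_labels", field = "W_pred")
  }
  m
}
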