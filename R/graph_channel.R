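#' Graph channel: GIN message passing with max-pool readout
#'
#' The graph channel encodes a molecular graph by `n_iter` rounds of linear
#' message passing. Node states start as the sum of atomic-number and
#' chirality embeddings; each round aggregates, over the neighbours `v` of
#' node `u`, the linear map `W (h_v + e_uv)` (with `e_uv` the sum of
#' bond-type and bond-direction embeddings), and updates
#' `h_u <- W (h_u + m_u)`. Aggregation and update share the square weight
#' matrix `W` of each round. The graph embedding is the element-wise maximum
#' over final node states. Three independently parameterized encoders,
#' tagged `m` (Infomax), `e` (Edge) and `c` (Context), yield the three
#' graph-level features the predictor fuses.
#'
#' @name graph_channel
#' @keywords internal
NULL

.GIN_VOCAB <- c(atomic_number = 103L, chirality = 4L,
                bond_type = 4L, bond_direction = 3L)

#' Construct (randomly initialized) GIN encoder parameters
#'
#' Weights are drawn from variance-scaled Gaussians: embedding rows from
#' `N(0, 0.1^2)`, message/update matrices from `N(0, (0.5/sqrt(dim))^2)` so
#' repeated linear rounds neither explode nor vanish on typical molecules.
#'
#' @param dim embedding width (default 300).
#' @param n_iter number of message-passing rounds (default 5).
#' @param objective objective tag, one of `"m"` (Infomax), `"e"` (Edge),
#'   `"c"` (Context).
#' @param seed optional integer seed for reproducible initialization.
#' @return an object of class `gin_params`.
#' @export
gin_params <- function(dim = 300, n_iter = 5, objective = c("m", "e", "c"),
                       seed = NULL) {
  objective <- match.arg(objective)
  if (n_iter < 1) stop_config("n_iter must be >= 1", field = "n_iter")
  if (dim < 1) stop_config("dim must be >= 1", field = "dim")
  with_seed(seed, {
    sdw <- 0.5 / sqrt(dim)
    structure(list(
      dim = as.integer(dim),
      n_iter = as.integer(n_iter),
      objective = objective,
      W = lapply(seq_len(n_iter), function(t)
        matrix(stats::rnorm(dim * dim, sd = sdw), dim, dim)),
      emb_atomic = matrix(stats::rnorm(.GIN_VOCAB["atomic_number"] * dim, sd = 0.1),
                          .GIN_VOCAB["atomic_number"], dim),
      emb_chirality = matrix(stats::rnorm(.GIN_VOCAB["chirality"] * dim, sd = 0.1),
                             .GIN_VOCAB["chirality"], dim),
      emb_bond_type = matrix(stats::rnorm(.GIN_VOCAB["bond_type"] * dim, sd = 0.1),
                             .GIN_VOCAB["bond_type"], dim),
      emb_bond_dir = matrix(stats::rnorm(.GIN_VOCAB["bond_direction"] * dim, sd = 0.1),
                            .GIN_VOCAB["bond_direction"], dim)
    ), class = "gin_params")
  })
}

.check_graph_params <- function(graph, params) {
  if (!inherits(graph, "molecular_graph")) {
    stop_validation("expected a molecular_graph")
  }
  if (!inherits(params, "gin_params")) stop_config("expected gin_params")
  if (any(graph$atomic_number > nrow(params$emb_atomic))) {
    stop_config("atomic number outside embedding vocabulary",
                field = "emb_atomic")
  }
}

# index helpers into the categorical embedding tables
.chir_idx <- function(graph) match(graph$chirality, CHIRALITY_LEVELS)
.btype_idx <- function(graph) match(graph$bond_type, BOND_TYPE_LEVELS)
.bdir_idx <- function(graph) match(graph$bond_direction, BOND_DIR_LEVELS)

#' Initial node states of a graph under a GIN encoder
#'
#' State of node `u` is the atomic-number embedding plus the chirality
#' embedding.
#'
#' @inheritParams gin_encode
#' @return a numeric matrix, one row per node, `params$dim` columns.
#' @export
gin_init_states <- function(graph, params) {
  .check_graph_params(graph, params)
  params$emb_atomic[graph$atomic_number, , drop = FALSE] +
    params$emb_chirality[.chir_idx(graph), , drop = FALSE]
}

.edge_embeddings <- function(graph, params) {
  if (nrow(graph$edges) == 0) {
    return(matrix(0, 0, params$dim))
  }
  params$emb_bond_type[.btype_idx(graph), , drop = FALSE] +
    params$emb_bond_dir[.bdir_idx(graph), , drop = FALSE]
}

#' One round of GIN message passing
#'
#' Computes `m_u = sum_{v in N(u)} W_t (h_v + e_uv)` followed by
#' `h_u <- W_t (h_u + m_u)`.
#'
#' @param graph a `molecular_graph`.
#' @param states node-state matrix (rows = nodes).
#' @param params a `gin_params`.
#' @param t round index in `1..params$n_iter`.
#' @return the updated node-state matrix.
#' @export
gin_message_pass <- function(graph, states, params, t) {
  .check_graph_params(graph, params)
  if (!is.matrix(states) || nrow(states) != graph$n_nodes ||
      ncol(states) != params$dim) {
    stop_config("states matrix does not match graph/params dimensions",
                field = "states")
  }
  if (t < 1 || t > params$n_iter) stop_config("round index out of range", field = "t")
  W <- params$W[[t]]
  n <- graph$n_nodes
  M <- matrix(0, n, params$dim)
  if (nrow(graph$edges) > 0) {
    eemb <- .edge_embeddings(graph, params)
    src <- c(graph$edges[, 1], graph$edges[, 2])
    dst <- c(graph$edges[, 2], graph$edges[, 1])
    eidx <- rep(seq_len(nrow(graph$edges)), 2L)
    QW <- (states[src, , drop = FALSE] + eemb[eidx, , drop = FALSE]) %*% t(W)
    rs <- rowsum(QW, dst)
    M[as.integer(rownames(rs)), ] <- rs
  }
  (states + M) %*% t(W)
}

# Forward pass retaining per-round states (needed for backpropagation).
gin_forward <- function(graph, params) {
  H <- vector("list", params$n_iter + 1L)
  H[[1]] <- gin_init_states(graph, params)
  for (t in seq_len(params$n_iter)) {
    H[[t + 1L]] <- gin_message_pass(graph, H[[t]], params, t)
  }
  final <- H[[params$n_iter + 1L]]
  argmax <- apply(final, 2, which.max)
  emb <- final[cbind(argmax, seq_len(ncol(final)))]
  list(states = H, embedding = emb, argmax = argmax)
}

#' Encode a molecular graph into a graph-level embedding
#'
#' Runs `params$n_iter` rounds of message passing from the initial node
#' states, then takes the element-wise maximum over nodes (max-pool
#' readout). The result carries the encoder's objective tag.
#'
#' @param graph a `molecular_graph`.
#' @param params a `gin_params`.
#' @return a numeric vector of length `params$dim` of class
#'   `graph_embedding`, with attribute `objective`.
#' @export
gin_encode <- function(graph, params) {
  .check_graph_params(graph, params)
  if (graph$n_nodes < 1) stop_featurize("cannot encode an empty graph")
  fw <- gin_forward(graph, params)
  structure(fw$embedding, class = "graph_embedding", objective = params$objective)
}

#' Encode a graph under the three pretraining objectives
#'
#' @param graph a `molecular_graph`.
#' @param params_m,params_e,params_c `gin_params` tagged `"m"`, `"e"`, `"c"`.
#' @return a named list `list(m = , e = , c = )` of `graph_embedding`s, in
#'   that fixed order.
#' @export
encode_three_objectives <- function(graph, params_m, params_e, params_c) {
  for (pr in list(m = params_m, e = params_e, c = params_c)) {
    if (!inherits(pr, "gin_params")) stop_config("expected gin_params")
  }
  list(m = gin_encode(graph, params_m),
       e = gin_encode(graph, params_e),
       c = gin_encode(graph, params_c))
}

# Backward pass through readout + all rounds. `d_emb` is the loss gradient
# with respect to the graph embedding; the max-pool readout routes each
# coordinate to its argmax node. Returns gradients shaped like `params`.
gin_backward <- function(graph, params, cache, d_emb) {
  dH <- matrix(0, graph$n_nodes, params$dim)
  dH[cbind(cache$argmax, seq_len(params$dim))] <- d_emb
  .gin_backward_states(graph, params, cache, dH)
}

# --- weight persistence -----------------------------------------------------

#' Save / load GIN encoder weights
#'
#' Weights are stored as a versioned JSON document (schema `moladr-gin/1`)
#' holding `dim`, `n_iter`, the objective tag, vocabulary sizes and all
#' tensors at full precision, so that `load_gin_weights(save_gin_weights(p))`
#' reproduces `p` exactly.
#'
#' @param params a `gin_params`.
#' @param path file path.
#' @return `load_gin_weights` returns a `gin_params`.
#' @export
save_gin_weights <- function(params, path) {
  if (!inherits(params, "gin_params")) stop_config("expected gin_params")
  obj <- list(
    schema = "moladr-gin/1",
    dim = params$dim, n_iter = params$n_iter, objective = params$objective,
    vocab = as.list(.GIN_VOCAB),
    # a named object so JSON readers cannot collapse it into one array
    W = stats::setNames(params$W, paste0("t", seq_along(params$W))),
    emb_atomic = params$emb_atomic, emb_chirality = params$emb_chirality,
    emb_bond_type = params$emb_bond_type, emb_bond_dir = params$emb_bond_dir
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

.as_matrix <- function(x) {
  if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
}

#' @rdname save_gin_weights
#' @export
load_gin_weights <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("weight file not found: %s", path),
                                  path = path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(obj) || !identical(obj$schema, "moladr-gin/1")) {
    stop_io(sprintf("not a moladr-gin/1 weight file: %s", path), path = path)
  }
  dim <- as.integer(obj$dim)
  W <- if (is.list(obj$W)) unname(lapply(obj$W, .as_matrix)) else list(.as_matrix(obj$W))
  p <- structure(list(
    dim = dim, n_iter = as.integer(obj$n_iter), objective = obj$objective,
    W = W,
    emb_atomic = .as_matrix(obj$emb_atomic),
    emb_chirality = .as_matrix(obj$emb_chirality),
    emb_bond_type = .as_matrix(obj$emb_bond_type),
    emb_bond_dir = .as_matrix(obj$emb_bond_dir)
  ), class = "gin_params")
  for (f in c("W", "emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
    mats <- if (f == "W") p$W else list(p[[f]])
    for (m in mats) {
      if (ncol(m) != dim) {
        stop_config(sprintf("field '%s' has width %d, expected dim=%d",
                            f, ncol(m), dim), field = f)
      }
    }
  }
  if (length(p$W) != p$n_iter) {
    stop_config("number of W matrices does not match n_iter", field = "W")
  }
  exp_rows <- c(emb_atomic = .GIN_VOCAB[["atomic_number"]],
                emb_chirality = .GIN_VOCAB[["chirality"]],
                emb_bond_type = .GIN_VOCAB[["bond_type"]],
                emb_bond_dir = .GIN_VOCAB[["bond_direction"]])
  for (f in names(exp_rows)) {
    if (nrow(p[[f]]) != exp_rows[[f]]) {
      stop_config(sprintf("field '%s' has %d rows, expected %d",
                          f, nrow(p[[f]]), exp_rows[[f]]), field = f)
    }
  }
  if (!p$objective %in% c("m", "e", "c")) {
    stop_config("objective tag must be one of m/e/c", field = "objective")
  }
  p
}

# --- desk-scale self-supervised pretraining ---------------------------------

.sample_non_edges <- function(graph, k) {
  n <- graph$n_nodes
  if (n < 2) return(matrix(integer(0), ncol = 2))
  present <- if (nrow(graph$edges) > 0) {
    paste(graph$edges[, 1], graph$edges[, 2])
  } else character(0)
  out <- matrix(integer(0), ncol = 2)
  tries <- 0L
  while (nrow(out) < k && tries < 50L * k) {
    a <- sample.int(n, 1L); b <- sample.int(n, 1L)
    tries <- tries + 1L
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    if (key %in% present) next
    out <- rbind(out, c(min(a, b), max(a, b)))
    present <- c(present, key)
  }
  out
}

#' Desk-scale self-supervised pretraining of a GIN encoder
#'
#' Two simplified objectives are provided. `"edge"`: discriminate true bonds
#' from uniformly sampled non-bonded node pairs by the dot product of final
#' node states. `"infomax"`: discriminate (node state, own-graph mean
#' summary) pairs from (node state, other-graph summary) pairs, again by dot
#' product. Both minimize binary cross-entropy by full-batch gradient
#' descent; the run is deterministic given `seed`. The context objective is
#' not provided.
#'
#' @param graphs list of `molecular_graph` (at least 2).
#' @param objective `"edge"` or `"infomax"` (`"context"` signals
#'   not-implemented).
#' @param params starting `gin_params`.
#' @param epochs number of passes (0 returns `params` unchanged).
#' @param seed integer seed controlling negative sampling.
#' @param lr gradient-descent step size.
#' @return the updated `gin_params`.
#' @export
toy_pretrain <- function(graphs, objective = c("edge", "infomax", "context"),
                         params, epochs = 50, seed = NULL, lr = 0.01) {
  objective <- match.arg(objective)
  if (objective == "context") {
    stop_not_implemented("the context pretraining objective is not provided")
  }
  if (length(graphs) < 2) stop_validation("toy_pretrain needs at least 2 graphs")
  if (epochs == 0) return(params)
  sig <- function(x) 1 / (1 + exp(-x))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      caches <- lapply(graphs, gin_forward, params = params)
      grad <- NULL
      for (gi in seq_along(graphs)) {
        g <- graphs[[gi]]
        H <- caches[[gi]]$states[[params$n_iter + 1L]]
        dH <- matrix(0, g$n_nodes, params$dim)
        if (objective == "edge") {
          pos <- g$edges
          neg <- .sample_non_edges(g, nrow(pos))
          pairs <- rbind(pos, neg)
          if (nrow(pairs) == 0) next
          y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
          logit <- rowSums(H[pairs[, 1], , drop = FALSE] *
                           H[pairs[, 2], , drop = FALSE])
          dl <- (sig(logit) - y) / nrow(pairs)
          for (r in seq_len(nrow(pairs))) {
            dH[pairs[r, 1], ] <- dH[pairs[r, 1], ] + dl[r] * H[pairs[r, 2], ]
            dH[pairs[r, 2], ] <- dH[pairs[r, 2], ] + dl[r] * H[pairs[r, 1], ]
          }
        } else {
          s_own <- colMeans(H)
          other <- sample(setdiff(seq_along(graphs), gi), 1L)
          Ho <- caches[[other]]$states[[params$n_iter + 1L]]
          s_oth <- colMeans(Ho)
          np <- 2L * g$n_nodes
          logit_p <- as.numeric(H %*% s_own)
          logit_n <- as.numeric(H %*% s_oth)
          dlp <- (sig(logit_p) - 1) / np
          dln <- (sig(logit_n) - 0) / np
          dH <- dH + outer(dlp, s_own) + outer(dln, s_oth)
          # gradient through the own-graph summary (mean of node states)
          ds_own <- as.numeric(t(H) %*% dlp)
          dH <- dH + matrix(ds_own / g$n_nodes, g$n_nodes, params$dim, byrow = TRUE)
        }
        # the loss acts on the final node states directly (no readout)
        gr <- .gin_backward_states(g, params, caches[[gi]], dH)
        grad <- if (is.null(grad)) gr else .add_grads(grad, gr)
      }
      if (!is.null(grad)) params <- .sgd_step(params, grad, lr)
    }
    params
  })
}

# backward from a gradient on the final node states (no readout)
.gin_backward_states <- function(graph, params, cache, dH_final) {
  dim <- params$dim
  n <- graph$n_nodes
  gW <- lapply(params$W, function(w) matrix(0, dim, dim))
  g_atomic <- matrix(0, nrow(params$emb_atomic), dim)
  g_chir <- matrix(0, nrow(params$emb_chirality), dim)
  g_btype <- matrix(0, nrow(params$emb_bond_type), dim)
  g_bdir <- matrix(0, nrow(params$emb_bond_dir), dim)
  dH <- dH_final
  has_edges <- nrow(graph$edges) > 0
  if (has_edges) {
    eemb <- .edge_embeddings(graph, params)
    src <- c(graph$edges[, 1], graph$edges[, 2])
    dst <- c(graph$edges[, 2], graph$edges[, 1])
    eidx <- rep(seq_len(nrow(graph$edges)), 2L)
    dEemb_total <- matrix(0, nrow(graph$edges), dim)
  }
  for (t in rev(seq_len(params$n_iter))) {
    W <- params$W[[t]]
    Hprev <- cache$states[[t]]
    if (has_edges) {
      Q <- Hprev[src, , drop = FALSE] + eemb[eidx, , drop = FALSE]
      QW <- Q %*% t(W)
      rs <- rowsum(QW, dst)
      M <- matrix(0, n, dim)
      M[as.integer(rownames(rs)), ] <- rs
    } else {
      M <- matrix(0, n, dim)
    }
    P <- Hprev + M
    gW[[t]] <- gW[[t]] + t(dH) %*% P
    dP <- dH %*% W
    dHprev <- dP
    if (has_edges) {
      dQW <- dP[dst, , drop = FALSE]
      gW[[t]] <- gW[[t]] + t(dQW) %*% Q
      dQ <- dQW %*% W
      rs2 <- rowsum(dQ, src)
      dHprev[as.integer(rownames(rs2)), ] <-
        dHprev[as.integer(rownames(rs2)), , drop = FALSE] + rs2
      rs3 <- rowsum(dQ, eidx)
      dEemb_total[as.integer(rownames(rs3)), ] <-
        dEemb_total[as.integer(rownames(rs3)), , drop = FALSE] + rs3
    }
    dH <- dHprev
  }
  za <- rowsum(dH, graph$atomic_number)
  g_atomic[as.integer(rownames(za)), ] <- za
  zc <- rowsum(dH, .chir_idx(graph))
  g_chir[as.integer(rownames(zc)), ] <- zc
  if (has_edges) {
    zb <- rowsum(dEemb_total, .btype_idx(graph))
    g_btype[as.integer(rownames(zb)), ] <- zb
    zd <- rowsum(dEemb_total, .bdir_idx(graph))
    g_bdir[as.integer(rownames(zd)), ] <- zd
  }
  list(W = gW, emb_atomic = g_atomic, emb_chirality = g_chir,
       emb_bond_type = g_btype, emb_bond_dir = g_bdir)
}

.add_grads <- function(a, b) {
  a$W <- Map(`+`, a$W, b$W)
  for (f in c("emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
    a[[f]] <- a[[f]] + b[[f]]
  }
  a
}

# SGD with global gradient-norm clipping: linear message passing has no
# saturating nonlinearity, so raw gradients can explode on denser graphs.
.sgd_step <- function(params, grad, lr, max_norm = 5) {
  gn <- sqrt(sum(vapply(grad$W, function(g) sum(g^2), numeric(1))) +
               sum(grad$emb_atomic^2) + sum(grad$emb_chirality^2) +
               sum(grad$emb_bond_type^2) + sum(grad$emb_bond_dir^2))
  scale <- if (is.finite(gn) && gn > max_norm) max_norm / gn else 1
  params$W <- Map(function(w, g) w - lr * scale * g, params$W, grad$W)
  for (f in c("emb_atomic", "emb_chirality", "emb_bond_type", "emb_bond_dir")) {
    params[[f]] <- params[[f]] - lr * scale * grad[[f]]
  }
  params
}

#' Held-out edge discrimination accuracy of a GIN encoder
#'
#' Scores true bonds and an equal number of sampled non-bonded pairs by the
#' sigmoid of the node-state dot product; reports the fraction classified
#' correctly at threshold 0.5.
#'
#' @param graphs list of `molecular_graph`.
#' @param params a `gin_params`.
#' @param seed seed for negative-pair sampling.
#' @return accuracy in \[0, 1\].
#' @export
edge_discrimination_accuracy <- function(graphs, params, seed = NULL) {
  with_seed(seed, {
    correct <- 0L; total <- 0L
    for (g in graphs) {
      H <- gin_forward(g, params)$states[[params$n_iter + 1L]]
      pos <- g$edges
      neg <- .sample_non_edges(g, nrow(pos))
      if (nrow(pos) == 0) next
      sp <- rowSums(H[pos[, 1], , drop = FALSE] * H[pos[, 2], , drop = FALSE])
      correct <- correct + sum(sp > 0)
      total <- total + length(sp)
      if (nrow(neg) > 0) {
        sn <- rowSums(H[neg[, 1], , drop = FALSE] * H[neg[, 2], , drop = FALSE])
        correct <- correct + sum(sn <= 0)
        total <- total + length(sn)
      }
    }
    if (total == 0) stop_validation("no edges to score")
    correct / total
  })
}
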