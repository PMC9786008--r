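# Shared fixtures and independent oracles used across the test files.

# ~50 drug-like SMILES (common small-molecule drugs and fragments), used for
# property-style checks of the featurizers.
DRUGLIKE_SMILES <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                     # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                # caffeine
  "CC(=O)Nc1ccc(O)cc1",                        # paracetamol
  "Clc1ccccc1",
  "c1ccc2ccccc2c1",
  "CCN(CC)CC",
  "CC(N)Cc1ccccc1",                            # amphetamine
  "OC(=O)c1ccccc1O",                           # salicylic acid
  "Nc1ccc(cc1)S(=O)(=O)N",                     # sulfanilamide
  "CN1CCC[C@H]1c1cccnc1",                      # nicotine
  "OCC(O)CO",                                  # glycerol
  "NCCc1ccc(O)c(O)c1",                         # dopamine
  "CC(=O)OCC[N+](C)(C)C",                      # acetylcholine
  "O=C(O)CCC(=O)O",                            # succinic acid
  "C1CCNCC1",
  "c1ccoc1",
  "c1ccsc1",
  "c1ccncc1",
  "C1=CC(=O)NC(=O)N1",                         # uracil
  "Nc1ncnc2[nH]cnc12",                         # adenine
  "CSCCC(N)C(=O)O",                            # methionine
  "NC(Cc1ccccc1)C(=O)O",                       # phenylalanine
  "NC(CO)C(=O)O",                              # serine
  "CC(C)CC(N)C(=O)O",                          # leucine
  "OC(=O)C=Cc1ccccc1",                         # cinnamic acid
  "COc1cc2c(cc1OC)CCN2",
  "CCOC(=O)c1ccccc1N",
  "FC(F)(F)c1ccccc1",
  "N#Cc1ccccc1",
  "O=[N+]([O-])c1ccccc1",
  "Brc1ccccc1",
  "Ic1ccccc1",
  "OC1CCCCC1",
  "O=C1CCCCC1",
  "CC1CCCCC1",
  "C1CCOC1",
  "C1COCCN1",
  "CN(C)c1ccccc1",
  "COc1ccccc1",
  "CCOCC",
  "CC(C)O",
  "CC(C)=O",
  "CCC#N",
  "CC(Cl)C",
  "C(/F)=C\\F",
  "C[C@@H](N)C(=O)O",                          # alanine
  "OC[C@H](O)[C@@H](O)CO",
  "CC(C)(C)NCC(O)c1ccc(O)c(O)c1",              # salbutamol-like
  "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc12"        # diazepam
)

# small model for fast training tests
tiny_model <- function(n_labels = 3, seed = 2, dropout = 0, ...) {
  adr_model(n_labels = n_labels, dim = 8, dim_embed = 8, n_heads = 2,
            dim_ff = 16, n_iter = 2, dropout = dropout, seed = seed, ...)
}

tiny_records <- function(n = 8, n_labels = 3, seed = 7, noise = 0) {
  generate_synthetic(synthetic_spec(n, n_labels, label_noise = noise,
                                    seed = seed))
}

# random molecular graph (valid per the type invariants), for GIN oracles
random_graph <- function(n_nodes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- if (n_nodes >= 2) t(utils::combn(n_nodes, 2)) else
    matrix(integer(0), ncol = 2)
  keep <- if (nrow(pairs) > 0) {
    k <- sample(nrow(pairs), sample(0:nrow(pairs), 1))
    pairs[sort(k), , drop = FALSE]
  } else pairs
  structure(list(
    n_nodes = n_nodes,
    atomic_number = sample(c(6L, 7L, 8L, 16L, 17L), n_nodes, replace = TRUE),
    chirality = sample(c("unspecified", "cw", "ccw", "other"), n_nodes,
                       replace = TRUE),
    edges = keep,
    bond_type = sample(c("single", "double", "triple", "aromatic"),
                       nrow(keep), replace = TRUE),
    bond_direction = sample(c("none", "end_up", "end_down"), nrow(keep),
                            replace = TRUE),
    smiles = "<synthetic>"
  ), class = "molecular_graph")
}

# relabel nodes: position i of the new graph is old node ord[i]
relabel_graph <- function(g, ord) {
  inv <- integer(g$n_nodes)
  inv[ord] <- seq_len(g$n_nodes)
  e <- g$edges
  if (nrow(e) > 0) {
    e <- cbind(inv[e[, 1]], inv[e[, 2]])
    flip <- e[, 1] > e[, 2]
    e[flip, ] <- e[flip, c(2, 1), drop = FALSE]
  }
  structure(list(
    n_nodes = g$n_nodes,
    atomic_number = g$atomic_number[ord],
    chirality = g$chirality[ord],
    edges = e,
    bond_type = g$bond_type,
    bond_direction = g$bond_direction,
    smiles = g$smiles
  ), class = "molecular_graph")
}

# brute-force double-loop GIN oracle (message passing + update + max pool)
gin_oracle_states <- function(g, p) {
  chir <- match(g$chirality, c("unspecified", "cw", "ccw", "other"))
  bt <- match(g$bond_type, c("single", "double", "triple", "aromatic"))
  bd <- match(g$bond_direction, c("none", "end_up", "end_down"))
  H <- p$emb_atomic[g$atomic_number, , drop = FALSE] +
    p$emb_chirality[chir, , drop = FALSE]
  for (t in seq_len(p$n_iter)) {
    W <- p$W[[t]]
    Hn <- matrix(0, nrow(H), ncol(H))
    for (u in seq_len(g$n_nodes)) {
      m <- rep(0, p$dim)
      for (e in seq_len(nrow(g$edges))) {
        a <- g$edges[e, 1]; b <- g$edges[e, 2]
        ee <- p$emb_bond_type[bt[e], ] + p$emb_bond_dir[bd[e], ]
        if (a == u) m <- m + as.numeric(W %*% (H[b, ] + ee))
        if (b == u) m <- m + as.numeric(W %*% (H[a, ] + ee))
      }
      Hn[u, ] <- as.numeric(W %*% (H[u, ] + m))
    }
    H <- Hn
  }
  H
}

# brute-force double-loop single-head attention oracle
attention_oracle <- function(E, Wq, Wk, Wv) {
  L <- nrow(E); dv <- ncol(Wq)
  Q <- E %*% Wq; K <- E %*% Wk; V <- E %*% Wv
  O <- matrix(0, L, dv)
  A <- matrix(0, L, L)
  for (s in seq_len(L)) {
    sc <- vapply(seq_len(L), function(j) sum(Q[s, ] * K[j, ]) / sqrt(dv),
                 numeric(1))
    a <- exp(sc - max(sc)); a <- a / sum(a)
    A[s, ] <- a
    for (j in seq_len(L)) O[s, ] <- O[s, ] + a[j] * V[j, ]
  }
  list(O = O, A = A)
}

# pairwise (concordant / tied) AUC oracle
auc_pair_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# explicit threshold-sweep average-precision oracle
aupr_sweep_oracle <- function(y, s) {
  np <- sum(y == 1)
  if (np == 0 || np == length(y)) return(NA_real_)
  th <- sort(unique(s), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
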