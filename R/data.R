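#' Datasets, label statistics, splits and the synthetic generator
#'
#' A drug record is `list(id, smiles, labels)` with a strictly binary label
#' vector of length `N_l`. Datasets travel as CSV with columns
#' `id, smiles, <label columns>`. Besides loading/filtering, this module
#' computes label cardinality ("base"), density and co-occurrence, produces
#' the three evaluation protocols (90/10 holdout, k-fold, jackknife), and
#' generates synthetic datasets in which each label is planted by a marker
#' substructure.
#'
#' @name data
#' @keywords internal
NULL

#' Coerce a data.frame (or list) to a list of drug records
#'
#' @param x a data.frame with `id`, `smiles` and binary label columns, or a
#'   list of `list(id, smiles, labels)`.
#' @return list of drug records.
#' @export
as_drug_records <- function(x) {
  if (is.data.frame(x)) {
    lab_cols <- setdiff(names(x), c("id", "smiles"))
    if (!all(c("id", "smiles") %in% names(x)) || length(lab_cols) == 0) {
      stop_validation("data.frame needs 'id', 'smiles' and at least one label column")
    }
    return(lapply(seq_len(nrow(x)), function(i) {
      lab <- as.integer(unlist(x[i, lab_cols]))
      names(lab) <- lab_cols
      list(id = as.character(x$id[i]), smiles = as.character(x$smiles[i]),
           labels = lab)
    }))
  }
  if (!is.list(x)) stop_validation("cannot interpret input as drug records")
  for (r in x) {
    if (is.null(r$id) || is.null(r$smiles) || is.null(r$labels)) {
      stop_validation("each drug record needs id, smiles and labels")
    }
    if (!all(r$labels %in% c(0L, 1L))) {
      stop_validation(sprintf("record '%s' has non-binary labels", r$id))
    }
  }
  x
}

#' Binary label matrix of a record list
#'
#' @param records list of drug records.
#' @return integer matrix, rows named by record id.
#' @export
label_matrix <- function(records) {
  Y <- do.call(rbind, lapply(records, `[[`, "labels"))
  rownames(Y) <- vapply(records, `[[`, character(1), "id")
  Y
}

#' Load a drug/ADR dataset from CSV
#'
#' The CSV must carry `id`, `smiles` and one column per ADR label. Records
#' with a missing or empty id or SMILES are dropped and counted (attribute
#' `dropped`), mirroring the curation rule that drugs without a structure
#' cannot enter a structure-based predictor. Non-binary label cells and
#' duplicated ids are errors.
#'
#' @param path CSV file path.
#' @return list of drug records with attribute `dropped` (number of rows
#'   removed) and `label_names`.
#' @export
load_drug_dataset <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("dataset not found: %s", path), path = path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_io(sprintf("malformed CSV: %s", conditionMessage(e)),
                                             path = path))
  if (nrow(df) == 0) stop_validation("dataset is empty")
  if (!all(c("id", "smiles") %in% names(df))) {
    stop_validation("dataset needs 'id' and 'smiles' columns")
  }
  lab_cols <- setdiff(names(df), c("id", "smiles"))
  if (length(lab_cols) == 0) stop_validation("dataset has no label columns")
  for (j in lab_cols) {
    bad <- which(!(df[[j]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_validation(sprintf("non-binary value in label column '%s' at row %d",
                              j, bad[1]), column = j, row = bad[1])
    }
  }
  keep <- !is.na(df$id) & nzchar(as.character(df$id)) &
    !is.na(df$smiles) & nzchar(as.character(df$smiles))
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop_validation("no records left after filtering")
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0) {
    stop_validation(sprintf("duplicate record id '%s'", dup[1]), id = dup[1])
  }
  recs <- as_drug_records(df)
  attr(recs, "dropped") <- dropped
  attr(recs, "label_names") <- lab_cols
  recs
}

#' Write drug records as CSV
#'
#' @param records list of drug records.
#' @param path output CSV path.
#' @export
write_drug_dataset <- function(records, path) {
  Y <- label_matrix(records)
  df <- data.frame(id = rownames(Y),
                   smiles = vapply(records, `[[`, character(1), "smiles"),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(Y, row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Label statistics: cardinality ("base"), density, co-occurrence
#'
#' Cardinality is the mean number of positive labels per sample; density is
#' cardinality divided by the number of labels; the co-occurrence matrix
#' counts joint positives for every label pair. Low density together with a
#' large base makes the multi-label problem harder.
#'
#' @param labels binary label matrix (samples x labels), or a list of drug
#'   records.
#' @return object of class `dataset_stats` with fields `n_samples`,
#'   `n_labels`, `cardinality`, `density`, `prevalence`, `co_occurrence`.
#' @examples
#' # a dataset averaging 16.5 positive labels over 27 classes has density
#' # 16.5 / 27 = 0.6111
#' @export
label_stats <- function(labels) {
  if (is.list(labels) && !is.data.frame(labels) && !is.matrix(labels)) {
    labels <- label_matrix(labels)
  }
  labels <- as.matrix(labels)
  if (nrow(labels) == 0 || ncol(labels) == 0) {
    stop_validation("label matrix is empty")
  }
  if (!all(labels %in% c(0, 1))) stop_validation("label matrix must be binary")
  card <- mean(rowSums(labels))
  structure(list(
    n_samples = nrow(labels),
    n_labels = ncol(labels),
    cardinality = card,
    density = card / ncol(labels),
    prevalence = colMeans(labels),
    co_occurrence = t(labels) %*% labels
  ), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("<dataset_stats> N=%d, L=%d | cardinality %.4f, density %.4f\n",
              x$n_samples, x$n_labels, x$cardinality, x$density))
  invisible(x)
}

#' Write dataset statistics (CSV per-label table + JSON summary)
#'
#' @param stats a `dataset_stats`.
#' @param path output path stem.
#' @export
write_dataset_stats <- function(stats, path) {
  if (!inherits(stats, "dataset_stats")) stop_config("expected dataset_stats")
  utils::write.csv(data.frame(label = colnames(stats$co_occurrence) %||%
                                paste0("label_", seq_len(stats$n_labels)),
                              prevalence = stats$prevalence),
                   paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(n_samples = stats$n_samples,
                            n_labels = stats$n_labels,
                            cardinality = stats$cardinality,
                            density = stats$density),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- evaluation protocols ---------------------------------------------------

#' Seeded train/test split (floor rule on the training side)
#'
#' @param records list of drug records.
#' @param fraction training fraction in (0, 1); default 0.9 (so 2248
#'   records split 2023/225).
#' @param seed integer seed.
#' @return `list(train =, test =)`, disjoint and exhaustive.
#' @export
split_train_test <- function(records, fraction = 0.9, seed = NULL) {
  n <- length(records)
  if (n < 2) stop_validation("need at least 2 records to split")
  if (fraction <= 0 || fraction >= 1) stop_validation("fraction must be in (0, 1)")
  n_train <- floor(n * fraction)
  with_seed(seed, {
    ord <- sample.int(n)
    list(train = records[ord[seq_len(n_train)]],
         test = records[ord[(n_train + 1):n]])
  })
}

#' Seeded k-fold cross-validation folds
#'
#' @param records list of drug records.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` elements `list(train =, validation =)`; validation
#'   folds partition the records with sizes differing by at most one.
#' @export
kfold_split <- function(records, k = 5, seed = NULL) {
  n <- length(records)
  if (n < k) stop_validation(sprintf("need at least k=%d records, got %d", k, n))
  with_seed(seed, {
    ord <- sample.int(n)
    fold_id <- rep(seq_len(k), length.out = n)
    lapply(seq_len(k), function(f) {
      val <- ord[fold_id == f]
      list(train = records[ord[fold_id != f]], validation = records[val])
    })
  })
}

#' Jackknife (leave-one-out) pairs
#'
#' @param records list of drug records (N >= 2).
#' @return list of N elements `list(train = N-1 records, test = 1 record)`,
#'   each record left out exactly once, in input order.
#' @export
jackknife_split <- function(records) {
  n <- length(records)
  if (n < 2) stop_validation("jackknife needs at least 2 records")
  lapply(seq_len(n), function(i) list(train = records[-i], test = records[i]))
}

# --- synthetic planted-substructure generator -------------------------------

# Marker substructures, one per label. Chemically disjoint so that, at zero
# label noise, label j is exactly "molecule contains marker j".
.DEFAULT_MARKERS <- c("C(F)(F)F", "C#N", "S(=O)(=O)N", "[N+](=O)[O-]",
                      "Cl", "Br", "I", "C(=O)O")

default_fragment_pool <- function() {
  path <- system.file("extdata", "fragment_pool.smi", package = "moladr")
  if (!nzchar(path)) stop_io("fragment pool fixture not found")
  readLines(path)
}

#' Specification of a synthetic planted-rule dataset
#'
#' Molecules are assembled as a methylene backbone carrying randomly drawn
#' filler fragments; label `j` is planted by attaching marker substructure
#' `j` with probability `marker_prevalence`, then flipped independently
#' with probability `label_noise`.
#'
#' @param n_molecules number of molecules.
#' @param n_labels number of labels (each needs one marker; at most
#'   `length(markers)`).
#' @param label_noise flip probability `rho` in \[0, 1\] (default 0).
#' @param marker_prevalence probability a marker is attached (default 0.35).
#' @param seed integer seed.
#' @param markers one marker substructure (SMILES, also used as the SMARTS
#'   oracle pattern) per label; defaults to a curated set of 8.
#' @param fragment_pool filler fragments; defaults to the shipped pool.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules, n_labels, label_noise = 0,
                           marker_prevalence = 0.35, seed = 1,
                           markers = NULL, fragment_pool = NULL) {
  if (is.null(markers)) markers <- .DEFAULT_MARKERS
  if (is.null(fragment_pool)) fragment_pool <- default_fragment_pool()
  if (n_labels < 1 || n_labels > length(markers)) {
    stop_validation(sprintf("n_labels must be in 1..%d (one marker per label)",
                            length(markers)))
  }
  if (label_noise < 0 || label_noise > 1) {
    stop_validation("label_noise must be a probability")
  }
  for (m in markers[seq_len(n_labels)]) {
    ok <- tryCatch({smiles_to_graph(paste0("C(", m, ")C")); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop_validation(sprintf("marker pattern '%s' cannot be built into a molecule", m))
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_labels = as.integer(n_labels),
                 label_noise = label_noise,
                 marker_prevalence = marker_prevalence,
                 seed = as.integer(seed),
                 markers = markers[seq_len(n_labels)],
                 fragment_pool = fragment_pool),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-label drug dataset
#'
#' Each molecule is a backbone of `C(unit)` groups: 1-3 filler fragments
#' drawn from the pool plus the marker fragment of every planted label, in
#' shuffled order. All generated SMILES parse; generation is deterministic
#' per seed. At `label_noise = 0` the labels are exactly recoverable by
#' substructure matching of the markers.
#'
#' @param spec a `synthetic_spec`.
#' @return list of drug records (attribute `clean_labels` holds the labels
#'   before noise).
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop_validation("expected a synthetic_spec")
  L <- spec$n_labels
  with_seed(spec$seed, {
    records <- vector("list", spec$n_molecules)
    clean <- matrix(0L, spec$n_molecules, L)
    for (i in seq_len(spec$n_molecules)) {
      n_fill <- sample(1:3, 1)
      units <- sample(spec$fragment_pool, n_fill, replace = TRUE)
      planted <- stats::rbinom(L, 1, spec$marker_prevalence)
      units <- c(units, spec$markers[planted == 1])
      units <- sample(units)
      smiles <- paste0("C(", units, ")", collapse = "")
      labels <- planted
      if (spec$label_noise > 0) {
        flip <- stats::rbinom(L, 1, spec$label_noise)
        labels <- as.integer(xor(labels, flip))
      }
      names(labels) <- paste0("label_", seq_len(L))
      clean[i, ] <- planted
      records[[i]] <- list(id = sprintf("syn%05d", i), smiles = smiles,
                           labels = as.integer(labels))
      names(records[[i]]$labels) <- paste0("label_", seq_len(L))
    }
    attr(records, "clean_labels") <- clean
    attr(records, "label_names") <- paste0("label_", seq_len(L))
    records
  })
}

#' Detect planted markers by substructure matching (oracle)
#'
#' Uses Open Babel SMARTS matching to test which marker substructures are
#' present in each molecule; at zero label noise this reproduces the
#' generated labels exactly.
#'
#' @param records list of drug records.
#' @param markers marker patterns (SMARTS).
#' @return binary matrix (records x markers).
#' @export
match_markers <- function(records, markers) {
  out <- matrix(0L, length(records), length(markers))
  for (i in seq_along(records)) {
    mol <- ChemmineOB::forEachMol("SMILES", records[[i]]$smiles, identity)
    for (j in seq_along(markers)) {
      cnt <- ChemmineOB::smartsSearch_OB(list(mol[[1]]), markers[j],
                                         uniqueMatches = FALSE)
      out[i, j] <- as.integer(cnt > 0)
    }
  }
  out
}
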