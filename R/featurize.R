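#' Molecular featurization: structure graphs and FP2 substructure sequences
#'
#' SMILES strings are converted into the two representations the predictor
#' consumes: a heavy-atom molecular graph (atomic number + chirality on
#' nodes, bond type + bond direction on edges) and the 256-digit hexadecimal
#' rendering of the 1024-bit FP2 path fingerprint. All chemistry is delegated
#' to Open Babel through ChemmineOB; this file only reshapes its output.
#'
#' @name featurize
#' @keywords internal
NULL

# Symbol -> atomic number, elements 1..103. Standard periodic table data.
.ELEMENTS <- c(
  "H" = 1, "He" = 2, "Li" = 3, "Be" = 4, "B" = 5, "C" = 6, "N" = 7, "O" = 8,
  "F" = 9, "Ne" = 10, "Na" = 11, "Mg" = 12, "Al" = 13, "Si" = 14, "P" = 15,
  "S" = 16, "Cl" = 17, "Ar" = 18, "K" = 19, "Ca" = 20, "Sc" = 21, "Ti" = 22,
  "V" = 23, "Cr" = 24, "Mn" = 25, "Fe" = 26, "Co" = 27, "Ni" = 28, "Cu" = 29,
  "Zn" = 30, "Ga" = 31, "Ge" = 32, "As" = 33, "Se" = 34, "Br" = 35, "Kr" = 36,
  "Rb" = 37, "Sr" = 38, "Y" = 39, "Zr" = 40, "Nb" = 41, "Mo" = 42, "Tc" = 43,
  "Ru" = 44, "Rh" = 45, "Pd" = 46, "Ag" = 47, "Cd" = 48, "In" = 49, "Sn" = 50,
  "Sb" = 51, "Te" = 52, "I" = 53, "Xe" = 54, "Cs" = 55, "Ba" = 56, "La" = 57,
  "Ce" = 58, "Pr" = 59, "Nd" = 60, "Pm" = 61, "Sm" = 62, "Eu" = 63, "Gd" = 64,
  "Tb" = 65, "Dy" = 66, "Ho" = 67, "Er" = 68, "Tm" = 69, "Yb" = 70, "Lu" = 71,
  "Hf" = 72, "Ta" = 73, "W" = 74, "Re" = 75, "Os" = 76, "Ir" = 77, "Pt" = 78,
  "Au" = 79, "Hg" = 80, "Tl" = 81, "Pb" = 82, "Bi" = 83, "Po" = 84, "At" = 85,
  "Rn" = 86, "Fr" = 87, "Ra" = 88, "Ac" = 89, "Th" = 90, "Pa" = 91, "U" = 92,
  "Np" = 93, "Pu" = 94, "Am" = 95, "Cm" = 96, "Bk" = 97, "Cf" = 98, "Es" = 99,
  "Fm" = 100, "Md" = 101, "No" = 102, "Lr" = 103
)

CHIRALITY_LEVELS <- c("unspecified", "cw", "ccw", "other")
BOND_TYPE_LEVELS <- c("single", "double", "triple", "aromatic")
BOND_DIR_LEVELS <- c("none", "end_up", "end_down")

# --- SMILES well-formedness -------------------------------------------------

# Open Babel silently repairs some malformed SMILES (e.g. "C(" parses as
# methane), so syntactic validity is checked first: balanced parentheses and
# brackets, paired ring-closure numbers, and only legal bare-atom tokens
# outside brackets. This is input validation, not a structure parser.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "I",
                     "b", "c", "n", "o", "p", "s")

check_smiles_syntax <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return("SMILES must be a non-empty string")
  }
  if (grepl("[[:space:]]", smiles)) return("SMILES contains whitespace")
  chars <- strsplit(smiles, "")[[1]]

  depth <- 0L
  in_bracket <- FALSE
  bare <- character(0)     # characters outside brackets
  ring_digits <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "[") return("nested '[' in SMILES")
      if (ch == "]") in_bracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") {
      in_bracket <- TRUE
    } else if (ch == "]") {
      return("unmatched ']' in SMILES")
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return("unmatched ')' in SMILES")
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        return("'%' ring closure must be followed by two digits")
      }
      ring_digits <- c(ring_digits, paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
      next
    } else if (grepl("[0-9]", ch)) {
      ring_digits <- c(ring_digits, ch)
    } else {
      bare <- c(bare, ch)
    }
    i <- i + 1L
  }
  if (in_bracket) return("unmatched '[' in SMILES")
  if (depth != 0L) return("unmatched '(' in SMILES")
  counts <- table(ring_digits)
  if (any(counts %% 2L != 0L)) {
    return(sprintf("unpaired ring-closure number(s): %s",
                   paste(names(counts)[counts %% 2L != 0L], collapse = ", ")))
  }

  # Outside brackets only organic-subset atoms, bonds and branch symbols are
  # legal. Consume two-letter halogens first.
  rest <- paste(bare, collapse = "")
  rest <- gsub("Cl|Br", "", rest)
  rest <- gsub("[=#$:/\\\\.~*-]|\\+", "", rest)
  letters_left <- strsplit(rest, "")[[1]]
  bad <- setdiff(letters_left, .ORGANIC_SUBSET)
  if (length(bad) > 0) {
    return(sprintf("illegal character(s) outside brackets: %s",
                   paste(unique(bad), collapse = ", ")))
  }
  NULL
}

.ob_convert <- function(smiles, to) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, paste0(smiles, " mol")),
    error = function(e) NULL
  )
  if (is.null(out) || !nzchar(out)) {
    stop_featurize(sprintf("Open Babel failed to parse SMILES '%s'", smiles),
                   smiles = smiles)
  }
  out
}

# --- molecular graph --------------------------------------------------------

#' Convert a SMILES string to a molecular structure graph
#'
#' Atoms become nodes carrying atomic number and a chirality tag; bonds
#' become undirected edges carrying a bond type (single/double/triple/
#' aromatic) and a direction tag recovered from cis/trans stereo annotation.
#' Implicit hydrogens are not nodes. Node order follows the order atoms
#' appear in the SMILES string.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `molecular_graph`: a list with `n_nodes`,
#'   integer `atomic_number`, character `chirality` (one of
#'   `r paste(CHIRALITY_LEVELS, collapse=", ")`), an `edges` matrix (E x 2,
#'   each unordered pair once, smaller index first), and per-edge
#'   `bond_type`, `bond_direction`.
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_nodes        # 3
#' g$bond_type      # "single" "single"
#' @export
smiles_to_graph <- function(smiles) {
  msg <- check_smiles_syntax(smiles)
  if (!is.null(msg)) stop_featurize(paste0(msg, ": '", smiles, "'"), smiles = smiles)

  cml <- .ob_convert(smiles, "CML")
  doc <- tryCatch(xml2::read_xml(cml), error = function(e) NULL)
  if (is.null(doc)) {
    stop_featurize(sprintf("unparseable SMILES '%s'", smiles), smiles = smiles)
  }
  xml2::xml_ns_strip(doc)
  atoms <- xml2::xml_find_all(doc, ".//atom")
  if (length(atoms) == 0) {
    stop_featurize(sprintf("SMILES '%s' yields no atoms", smiles), smiles = smiles)
  }
  atom_ids <- xml2::xml_attr(atoms, "id")
  symbols <- xml2::xml_attr(atoms, "elementType")
  z <- unname(.ELEMENTS[symbols])
  if (anyNA(z)) {
    stop_featurize(sprintf("unknown element '%s' in '%s'",
                           symbols[which(is.na(z))[1]], smiles), smiles = smiles)
  }

  chirality <- rep("unspecified", length(atoms))
  for (k in seq_along(atoms)) {
    par <- xml2::xml_find_first(atoms[[k]], ".//atomParity")
    if (!inherits(par, "xml_missing")) {
      v <- suppressWarnings(as.integer(xml2::xml_text(par)))
      chirality[k] <- if (identical(v, 1L)) "cw" else if (identical(v, -1L)) "ccw" else "other"
    }
  }

  # Bond list and types from mol2 (the only Open Babel text format that
  # keeps aromatic bonds as 'ar' rather than kekulizing them). Atom order in
  # mol2 matches CML (both follow SMILES input order).
  mol2 <- .ob_convert(smiles, "MOL2")
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  b0 <- which(lines == "@<TRIPOS>BOND")
  edges <- matrix(integer(0), ncol = 2)
  bond_type <- character(0)
  if (length(b0) == 1) {
    j <- b0 + 1L
    while (j <= length(lines) && !startsWith(lines[j], "@") && nzchar(trimws(lines[j]))) {
      f <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]]
      a <- as.integer(f[2]); b <- as.integer(f[3])
      ty <- switch(f[4],
                   "1" = "single", "2" = "double", "3" = "triple",
                   "ar" = "aromatic", "am" = "single", "single")
      edges <- rbind(edges, c(min(a, b), max(a, b)))
      bond_type <- c(bond_type, ty)
      j <- j + 1L
    }
  }
  if (nrow(edges) > 0 && max(edges) > length(atoms)) {
    stop_featurize(sprintf("inconsistent atom/bond blocks for '%s'", smiles),
                   smiles = smiles)
  }

  # Bond direction tags from cis/trans stereo: for a stereo double bond with
  # reference atoms (a b c d), the flanking single bonds a-b and c-d are the
  # directional bonds; trans (T) -> (end_up, end_up), cis (C) ->
  # (end_up, end_down). Equivalent to SMILES up/down tags modulo a global
  # flip, which carries no physical information.
  bond_direction <- rep("none", nrow(edges))
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- if (nrow(edges) > 0) edge_key(edges[, 1], edges[, 2]) else character(0)
  stereo <- xml2::xml_find_all(doc, ".//bondStereo")
  for (st in stereo) {
    lab <- xml2::xml_text(st)
    if (!lab %in% c("C", "T")) next
    refs <- strsplit(xml2::xml_attr(st, "atomRefs4"), " ")[[1]]
    idx <- match(refs, atom_ids)
    if (anyNA(idx)) next
    i1 <- match(edge_key(idx[1], idx[2]), keys)
    i2 <- match(edge_key(idx[3], idx[4]), keys)
    if (!is.na(i1)) bond_direction[i1] <- "end_up"
    if (!is.na(i2)) bond_direction[i2] <- if (lab == "T") "end_up" else "end_down"
  }

  structure(list(
    n_nodes = length(atoms),
    atomic_number = as.integer(z),
    chirality = chirality,
    edges = edges,
    bond_type = bond_type,
    bond_direction = bond_direction,
    smiles = smiles
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d nodes, %d edges (%s)\n",
              x$n_nodes, nrow(x$edges), x$smiles))
  invisible(x)
}

# --- FP2 hexadecimal substructure sequence ----------------------------------

.HEX_CHARS <- c(as.character(0:9), letters[1:6])

#' FP2 fingerprint as a 256-digit hexadecimal substructure sequence
#'
#' The 1024-bit path-based FP2 fingerprint (Open Babel) is grouped four bits
#' at a time into 256 hexadecimal digits: digit `k` (0-based) is formed from
#' bits `4k..4k+3` with bit `4k` most significant, rendered in lowercase.
#' Each hexadecimal digit therefore summarises four path substructures.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `substructure_sequence`: a list with `hex`
#'   (a 256-character lowercase string) and `smiles`.
#' @examples
#' s <- fp2_hex_sequence("CCO")
#' nchar(s$hex)   # 256
#' @export
fp2_hex_sequence <- function(smiles) {
  msg <- check_smiles_syntax(smiles)
  if (!is.null(msg)) stop_featurize(paste0(msg, ": '", smiles, "'"), smiles = smiles)
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) == 0) {
    stop_featurize(sprintf("Open Babel failed to parse SMILES '%s'", smiles),
                   smiles = smiles)
  }
  bits <- tryCatch(
    as.integer(ChemmineOB::fingerprint_OB(list(mols[[1]]), "FP2")),
    error = function(e) NULL
  )
  if (is.null(bits) || length(bits) != 1024L) {
    stop_featurize(sprintf("FP2 fingerprint failed for '%s'", smiles),
                   smiles = smiles)
  }
  m <- matrix(bits, nrow = 4)               # column k = bits 4k..4k+3
  vals <- 8L * m[1, ] + 4L * m[2, ] + 2L * m[3, ] + m[4, ]
  structure(list(
    hex = paste(.HEX_CHARS[vals + 1L], collapse = ""),
    smiles = smiles
  ), class = "substructure_sequence")
}

#' @export
print.substructure_sequence <- function(x, ...) {
  cat(sprintf("<substructure_sequence> %s... (%s)\n",
              substr(x$hex, 1, 24), x$smiles))
  invisible(x)
}

#' Integer token indices of a substructure sequence
#'
#' @param seq a `substructure_sequence` (or a bare 256-character hex string).
#' @return integer vector of length 256 with values in 1..16 (row indices
#'   into the 16-symbol embedding table).
#' @export
sequence_tokens <- function(seq) {
  hex <- if (inherits(seq, "substructure_sequence")) seq$hex else seq
  if (!is.character(hex) || length(hex) != 1L || nchar(hex) != 256L) {
    stop_featurize("substructure sequence must be a 256-character hex string")
  }
  idx <- match(strsplit(tolower(hex), "")[[1]], .HEX_CHARS)
  if (anyNA(idx)) stop_featurize("substructure sequence contains non-hex symbols")
  idx
}

# --- batch featurization ----------------------------------------------------

#' Featurize a batch of molecules
#'
#' Produces, for each molecule, the molecular graph and the FP2 substructure
#' sequence. Order is preserved. Failures follow the `policy`: `"strict"`
#' aborts on the first failure; `"skip"` drops failing molecules and records
#' them in the `skipped` attribute (id + reason), with a warning per skip.
#'
#' @param molecules a data.frame with columns `id` and `smiles`, or a list of
#'   lists with those fields.
#' @param policy `"strict"` or `"skip"`.
#' @return a list (one element per successfully featurized molecule) of
#'   `list(id, smiles, graph, seq)`; attribute `skipped` is a data.frame of
#'   failures.
#' @export
featurize_batch <- function(molecules, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (is.data.frame(molecules)) {
    if (!all(c("id", "smiles") %in% names(molecules))) {
      stop_validation("molecules data.frame needs 'id' and 'smiles' columns")
    }
    molecules <- lapply(seq_len(nrow(molecules)), function(i) {
      list(id = as.character(molecules$id[i]), smiles = molecules$smiles[i])
    })
  }
  out <- list()
  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (m in molecules) {
    res <- tryCatch(
      list(id = m$id, smiles = m$smiles,
           graph = smiles_to_graph(m$smiles),
           seq = fp2_hex_sequence(m$smiles)),
      moladr_featurize_error = function(e) e
    )
    if (inherits(res, "moladr_featurize_error")) {
      if (policy == "strict") {
        stop_featurize(sprintf("molecule '%s': %s", m$id, conditionMessage(res)),
                       smiles = m$smiles, id = m$id)
      }
      warning(sprintf("skipping molecule '%s': %s", m$id, conditionMessage(res)),
              call. = FALSE)
      skipped <- rbind(skipped, data.frame(id = as.character(m$id),
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else {
      out[[length(out) + 1L]] <- res
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' JSON debug dump of a featurized molecule
#'
#' @param x a `molecular_graph` or `substructure_sequence`.
#' @return a JSON string.
#' @export
featurization_json <- function(x) {
  if (inherits(x, "molecular_graph")) {
    jsonlite::toJSON(list(
      kind = "molecular_graph", smiles = x$smiles, n_nodes = x$n_nodes,
      atomic_number = x$atomic_number, chirality = x$chirality,
      edges = x$edges, bond_type = x$bond_type,
      bond_direction = x$bond_direction
    ), auto_unbox = TRUE)
  } else if (inherits(x, "substructure_sequence")) {
    jsonlite::toJSON(list(kind = "substructure_sequence", smiles = x$smiles,
                          hex = x$hex), auto_unbox = TRUE)
  } else {
    stop_validation("featurization_json expects a featurized object")
  }
}
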