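# Substructure-embedding featurization ---------------------------------------
#
# Molecules become "sentences" of atom-centered circular (Morgan) substructure
# identifiers, one word per (heavy atom, radius) pair; a molecule vector is
# the element-wise sum of the embedding vectors of its words, and a pocket
# vector is the sum of its residues' molecule vectors. The classifier input
# is the concatenation [ligand vector | pocket vector].
#
# Identifier scheme (deterministic, platform independent):
#   radius 0: hash of (element symbol, heavy-atom degree, sum of bond orders)
#   radius r: hash of (r, own id at r-1, sorted (bond order, neighbour id at
#             r-1) pairs)
# Hashing is the exact-integer polynomial hash in utils.R. Identifiers are
# rendered as decimal strings, the vocabulary convention of word2vec text
# tables.

#' Canonical free amino-acid SMILES used to featurize pocket residues
#'
#' Named character vector mapping the 20 standard three-letter residue names
#' to the SMILES of the free amino acid. Pocket residues are featurized as
#' these molecules (avoids broken-bond valence artifacts and needs no 3-D
#' perception); the lookup is extensible via the `extra_smiles` argument of
#' [residue_to_vector()].
#' @export
AA_SMILES <- c(
  ALA = "CC(N)C(=O)O",
  ARG = "N=C(N)NCCCC(N)C(=O)O",
  ASN = "NC(=O)CC(N)C(=O)O",
  ASP = "OC(=O)CC(N)C(=O)O",
  CYS = "NC(CS)C(=O)O",
  GLN = "NC(=O)CCC(N)C(=O)O",
  GLU = "OC(=O)CCC(N)C(=O)O",
  GLY = "NCC(=O)O",
  HIS = "NC(Cc1c[nH]cn1)C(=O)O",
  ILE = "CCC(C)C(N)C(=O)O",
  LEU = "CC(C)CC(N)C(=O)O",
  LYS = "NCCCCC(N)C(=O)O",
  MET = "CSCCC(N)C(=O)O",
  PHE = "NC(Cc1ccccc1)C(=O)O",
  PRO = "OC(=O)C1CCCN1",
  SER = "OCC(N)C(=O)O",
  THR = "CC(O)C(N)C(=O)O",
  TRP = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  TYR = "NC(Cc1ccc(O)cc1)C(=O)O",
  VAL = "CC(C)C(N)C(=O)O"
)

.pkg_cache <- new.env(parent = emptyenv())

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Uses the Open Babel backend of ChemmineR for SMILES perception (aromatic
#' rings are kekulized to alternating bond orders; implicit hydrogens are
#' not instantiated).
#'
#' @param smiles SMILES string.
#' @return A list with `elements` (character vector, one per heavy atom) and
#'   `bonds` (data.frame with columns a1, a2, order).
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  key <- paste0("graph:", smiles)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]],
    error = function(e) stop(sprintf("cannot parse SMILES '%s': %s",
                                     smiles, conditionMessage(e)))
  )
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  if (length(elements) == 0) stop(sprintf("SMILES '%s' has no heavy atoms", smiles))
  if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    # atom-only molecules come back without a usable bond block
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    bonds <- bonds[bonds$a1 >= 1 & bonds$a2 >= 1, , drop = FALSE]
  }
  g <- list(elements = elements, bonds = bonds)
  .pkg_cache[[key]] <- g
  g
}

# Per-atom circular substructure identifiers up to max(radii).
# Returns a matrix: rows atoms, one column per radius value 0..rmax.
morgan_identifiers <- function(graph, rmax) {
  n <- length(graph$elements)
  deg <- integer(n); bos <- integer(n)
  nbrs <- vector("list", n)
  b <- graph$bonds
  for (i in seq_len(nrow(b))) {
    a1 <- b$a1[i]; a2 <- b$a2[i]; o <- b$order[i]
    deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
    bos[a1] <- bos[a1] + o; bos[a2] <- bos[a2] + o
    nbrs[[a1]] <- rbind(nbrs[[a1]], c(a2, o))
    nbrs[[a2]] <- rbind(nbrs[[a2]], c(a1, o))
  }
  ids <- matrix(0, nrow = n, ncol = rmax + 1)
  for (a in seq_len(n)) {
    ids[a, 1] <- hash_ints(c(chars_to_ints(graph$elements[a]), deg[a], bos[a]))
  }
  if (rmax >= 1) {
    for (r in seq_len(rmax)) {
      for (a in seq_len(n)) {
        if (is.null(nbrs[[a]])) {
          ids[a, r + 1] <- hash_ints(c(r, ids[a, r]))
        } else {
          pairs <- cbind(nbrs[[a]][, 2], ids[nbrs[[a]][, 1], r])
          ord <- order(pairs[, 1], pairs[, 2])
          ids[a, r + 1] <- hash_ints(c(r, ids[a, r], t(pairs[ord, , drop = FALSE])))
        }
      }
    }
  }
  ids
}

#' Convert a molecule to its substructure sentence
#'
#' One word per (heavy atom, radius) pair: for every heavy atom, its
#' atom-centered circular substructure identifier at each requested radius.
#' Word order is atom index ascending, radius ascending within an atom; the
#' order is irrelevant to the embedding sum but fixed for reproducibility.
#'
#' @param molecule A SMILES string, a [ligand_record()] carrying SMILES, or
#'   a graph from [smiles_to_graph()].
#' @param radii Integer radii of the circular substructures (default 0:1).
#' @return Character vector of identifier words (class
#'   `molecular_sentence`).
#' @examples
#' length(mol_to_sentence("CCO"))  # 3 atoms x 2 radii = 6 words
#' @export
mol_to_sentence <- function(molecule, radii = c(0L, 1L)) {
  radii <- sort(unique(as.integer(radii)))
  stopifnot(length(radii) >= 1, all(radii >= 0))
  if (inherits(molecule, "ligand_record")) {
    if (is.null(molecule$smiles)) {
      stop(sprintf("ligand '%s' has no SMILES; cannot featurize", molecule$id))
    }
    molecule <- molecule$smiles
  }
  graph <- if (is.character(molecule)) smiles_to_graph(molecule) else molecule
  ids <- morgan_identifiers(graph, max(radii))
  words <- as.character(t(ids[, radii + 1, drop = FALSE]))
  structure(words, class = "molecular_sentence")
}

# Embedding table --------------------------------------------------------

#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per vocabulary word; rownames are
#'   the identifier words.
#' @param unk_policy Out-of-vocabulary policy: "zero" (OOV words contribute
#'   a zero vector) or "unk_vector" (OOV words contribute the vector of the
#'   designated `UNK` row, which must exist).
#' @return An object of class `embedding_table` with fields `dim`,
#'   `vectors`, `unk_policy`.
#' @export
embedding_table <- function(vectors, unk_policy = c("zero", "unk_vector")) {
  unk_policy <- match.arg(unk_policy)
  stopifnot(is.matrix(vectors), nrow(vectors) >= 1, ncol(vectors) >= 1,
            !is.null(rownames(vectors)), all(is.finite(vectors)))
  if (unk_policy == "unk_vector" && !("UNK" %in% rownames(vectors))) {
    stop("unk_policy 'unk_vector' requires an 'UNK' row in the table")
  }
  structure(list(dim = ncol(vectors), vectors = vectors,
                 unk_policy = unk_policy),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words x %d dims, unk_policy=%s\n",
              nrow(x$vectors), x$dim, x$unk_policy))
  invisible(x)
}

#' Read an embedding table in word2vec text format
#'
#' Format: a header line `<vocab> <dim>`, then one line per word:
#' `<identifier> <f1> ... <fdim>`.
#'
#' @param path File path.
#' @param unk_policy Passed to [embedding_table()].
#' @return An `embedding_table`.
#' @export
read_embedding_table <- function(path, unk_policy = "zero") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("embedding table file too short")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) {
    stop("malformed word2vec header (expected '<vocab> <dim>')")
  }
  vocab <- hdr[1]; dim <- hdr[2]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != vocab) {
    stop(sprintf("header promises %d words, file has %d", vocab, length(body)))
  }
  parts <- strsplit(trimws(body), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  mat <- matrix(NA_real_, nrow = vocab, ncol = dim, dimnames = list(words, NULL))
  for (i in seq_len(vocab)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (length(v) != dim || anyNA(v)) {
      stop(sprintf("word '%s' has %d values, expected %d", words[i],
                   length(v), dim))
    }
    mat[i, ] <- v
  }
  embedding_table(mat, unk_policy = unk_policy)
}

#' Write an embedding table in word2vec text format
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$dim), con)
  rows <- apply(table$vectors, 1, function(v)
    paste(sprintf("%.8g", v), collapse = " "))
  writeLines(paste(rownames(table$vectors), rows), con)
  invisible(path)
}

#' Sum the embedding vectors of a sentence's words
#'
#' @param sentence Character vector of identifier words.
#' @param table An `embedding_table`.
#' @return Numeric vector of length `table$dim`.
#' @export
embed_sentence <- function(sentence, table) {
  stopifnot(inherits(table, "embedding_table"))
  if (length(sentence) == 0) stop("cannot embed an empty sentence")
  hit <- match(as.character(sentence), rownames(table$vectors))
  v <- numeric(table$dim)
  known <- !is.na(hit)
  if (any(known)) {
    v <- v + colSums(table$vectors[hit[known], , drop = FALSE])
  }
  if (any(!known) && table$unk_policy == "unk_vector") {
    v <- v + sum(!known) * table$vectors["UNK", ]
  }
  v
}

#' Embedding vector of a pocket residue
#'
#' The residue name is mapped to its canonical free amino-acid SMILES and
#' featurized as a molecule ([mol_to_sentence()] then [embed_sentence()]).
#' Sentences are cached per residue name.
#'
#' @param residue_name Three-letter residue name (e.g. "GLY").
#' @param table An `embedding_table`.
#' @param strict If TRUE, unknown residue names are an error; otherwise they
#'   contribute a zero vector with a warning.
#' @param extra_smiles Named character vector extending the residue-to-SMILES
#'   lookup (e.g. modified residues).
#' @return Numeric vector of length `table$dim`.
#' @export
residue_to_vector <- function(residue_name, table, strict = FALSE,
                              extra_smiles = NULL) {
  lut <- c(AA_SMILES, extra_smiles)
  smiles <- if (residue_name %in% names(lut)) lut[[residue_name]] else NULL
  if (is.null(smiles)) {
    if (strict) stop(sprintf("unknown residue name '%s'", residue_name))
    warning(sprintf("unknown residue name '%s': contributing zero vector",
                    residue_name))
    return(numeric(table$dim))
  }
  key <- paste0("sentence:", smiles)
  sentence <- .pkg_cache[[key]]
  if (is.null(sentence)) {
    sentence <- mol_to_sentence(smiles)
    .pkg_cache[[key]] <- sentence
  }
  embed_sentence(sentence, table)
}

#' Embedding vector of a pocket
#'
#' Sum over the pocket's residues of their residue vectors (one term per
#' residue occurrence, so the map is additive over disjoint residue sets).
#'
#' @param pocket A `pocket`.
#' @param table An `embedding_table`.
#' @param strict If TRUE, fail when every residue is unknown.
#' @inheritParams residue_to_vector
#' @return Numeric vector of length `table$dim`.
#' @export
pocket_vector <- function(pocket, table, strict = FALSE, extra_smiles = NULL) {
  stopifnot(inherits(pocket, "pocket"))
  names <- pocket$residues$resname
  known <- names %in% names(c(AA_SMILES, extra_smiles))
  if (strict && !any(known)) {
    stop(sprintf("pocket '%s': no residue has a known featurization", pocket$id))
  }
  v <- numeric(table$dim)
  for (nm in names) {
    v <- v + suppressWarnings(
      residue_to_vector(nm, table, strict = FALSE, extra_smiles = extra_smiles))
  }
  v
}

#' Embedding vector of a ligand
#'
#' @param ligand A [ligand_record()] with SMILES, or a SMILES string.
#' @param table An `embedding_table`.
#' @param radii Circular substructure radii (default 0:1).
#' @return Numeric vector of length `table$dim`.
#' @export
ligand_vector <- function(ligand, table, radii = c(0L, 1L)) {
  embed_sentence(mol_to_sentence(ligand, radii = radii), table)
}

#' Concatenate ligand and pocket vectors into the classifier input
#'
#' @param ligand_vec,pocket_vec Numeric vectors of equal length d.
#' @param meta Optional list (e.g. complex id, pocket id) stored as an
#'   attribute.
#' @return Numeric vector of length 2d with class `pair_vector`; the ligand
#'   part occupies indices 1..d, the pocket part d+1..2d.
#' @export
pair_vector <- function(ligand_vec, pocket_vec, meta = NULL) {
  if (length(ligand_vec) != length(pocket_vec)) {
    stop(sprintf("ligand vector length %d != pocket vector length %d",
                 length(ligand_vec), length(pocket_vec)))
  }
  v <- c(as.numeric(ligand_vec), as.numeric(pocket_vec))
  if (!all(is.finite(v))) stop("pair vector has non-finite entries")
  structure(v, meta = meta, dim_part = length(ligand_vec),
            class = "pair_vector")
}

#' @export
#' @rdname pair_vector
#' @param pair A `pair_vector`.
ligand_part <- function(pair) {
  d <- attr(pair, "dim_part")
  as.numeric(pair)[seq_len(d)]
}

#' @export
#' @rdname pair_vector
pocket_part <- function(pair) {
  d <- attr(pair, "dim_part")
  as.numeric(pair)[d + seq_len(d)]
}
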