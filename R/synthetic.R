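# Synthetic fixtures -----------------------------------------------------------
#
# Generators for everything the pipeline consumes, so every stage can be
# exercised without external downloads: random embedding tables covering the
# amino-acid vocabulary, toy protein-ligand complexes whose pocket decoys sit
# at controlled centroid distances from the known pocket, and labeled
# 600-d vector sets with a controllable class separation (Bayes AUC has the
# closed form pnorm(separation / sqrt(2))).

#' Generate a random embedding table
#'
#' Vectors are i.i.d. standard normal, deterministic under the seed. By
#' default the vocabulary covers every substructure identifier produced by
#' the 20 standard amino acids (so residue featurization never goes out of
#' vocabulary) plus the identifiers of any SMILES in `ligand_smiles`;
#' `vocab_size` adds random filler identifiers beyond that coverage (with
#' coverage off, the table is exactly `vocab_size` random identifiers).
#'
#' @param vocab_size Minimum vocabulary size (filler identifiers are added
#'   up to this count).
#' @param dim Embedding dimensionality (default 300).
#' @param seed Integer seed.
#' @param ligand_smiles Character vector of SMILES whose identifiers must be
#'   covered.
#' @param cover_amino_acids Include all amino-acid identifiers (default
#'   TRUE).
#' @param unk_policy Passed to [embedding_table()]; "unk_vector" adds an
#'   `UNK` row.
#' @return An `embedding_table`.
#' @export
make_embedding_table <- function(vocab_size = 0L, dim = 300L, seed = 1L,
                                 ligand_smiles = character(),
                                 cover_amino_acids = TRUE,
                                 unk_policy = "zero") {
  stopifnot(dim >= 1, vocab_size >= 0)
  words <- character()
  if (cover_amino_acids) {
    words <- unlist(lapply(unname(AA_SMILES), mol_to_sentence))
  }
  for (smi in ligand_smiles) {
    words <- c(words, mol_to_sentence(smi))
  }
  words <- unique(as.character(words))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  n_fill <- max(0L, as.integer(vocab_size) - length(words))
  if (n_fill > 0) {
    fill <- as.character(sample.int(.HASH_MOD - 1L, 4L * n_fill))
    fill <- setdiff(fill, words)[seq_len(n_fill)]
    words <- c(words, fill)
  }
  if (identical(unk_policy, "unk_vector")) words <- c(words, "UNK")
  if (length(words) == 0) stop("empty vocabulary: set vocab_size or coverage")
  mat <- matrix(stats::rnorm(length(words) * dim), nrow = length(words),
                dimnames = list(words, NULL))
  embedding_table(mat, unk_policy = unk_policy)
}

# Orthonormal pair perpendicular to a unit vector u.
.perp_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- a - sum(a * u) * u
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2] * w1[3] - u[3] * w1[2],
          u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  list(w1, w2)
}

# Deterministic well-spread unit directions (golden-angle spiral).
.spread_directions <- function(n) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / max(n, 2)
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * 2.399963229728653
  cbind(r * cos(phi), r * sin(phi), z)
}

.ca_atoms <- function(centers, resnames, resno_start) {
  n <- nrow(centers)
  data.frame(
    record = "ATOM", name = "CA", element = "C",
    resname = resnames, chain = "A",
    resno = resno_start + seq_len(n) - 1L, insert = "",
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    stringsAsFactors = FALSE
  )
}

#' Generate a toy protein-ligand complex with controlled decoy geometry
#'
#' Builds a C-alpha scaffold protein with a small ligand at the origin: a
#' shell of 8 pocket residues 6 Angstrom from the ligand (the known
#' pocket, centroid exactly at the origin), distant bulk residues, and one
#' decoy pocket per requested distance whose C-alpha centroid sits exactly
#' at that distance from the known pocket's centroid (residues are placed
#' in +/- offset pairs 15 Angstrom from the decoy center, so decoy atoms
#' never intrude into the ligand's 1 nm shell). Residue names cycle through
#' the standard amino acids: near-native decoys reuse the known pocket's
#' composition with one substitution, far decoys get a fresh 4-residue
#' composition, so pocket vectors of negatives are not collinear with the
#' known pocket's vector.
#'
#' Writes the same dialects the real pipeline consumes: `protein.pdb`
#' (ATOM records plus the HETATM ligand), `pockets/pocket<k>_atm.pdb`, and
#' `manifest.tsv` with the intended label of every decoy under the default
#' thresholds.
#'
#' @param decoy_distances_nm Numeric vector of requested centroid distances.
#' @param dir Output directory (created).
#' @param seed Integer seed (residue-name draws).
#' @param ligand_smiles Ligand SMILES; its heavy-atom count must be 3 (the
#'   placed coordinates) unless `ligand_coords` is supplied.
#' @param ligand_coords Optional matrix of ligand heavy-atom coordinates.
#' @param n_bulk Number of distant bulk residues (default 30).
#' @param duplicate_decoy If TRUE, append one extra decoy at 2.0 nm whose
#'   residue composition copies the known pocket exactly (its pocket vector
#'   is collinear with the known vector, so the similarity filter removes
#'   it).
#' @return List with `dir`, `structure`, `ligand`, `known`, `pockets`,
#'   `manifest` (data.frame: pocket_id, requested_distance_nm,
#'   intended_label, composition).
#' @export
make_toy_complex <- function(decoy_distances_nm, dir = tempfile("toycomplex"),
                             seed = 1L, ligand_smiles = "CCO",
                             ligand_coords = NULL, n_bulk = 30L,
                             duplicate_decoy = FALSE) {
  stopifnot(length(decoy_distances_nm) >= 1, all(decoy_distances_nm > 0))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  palette <- names(AA_SMILES)

  # known-pocket shell: 8 residues 6 A from the origin in +/- direction
  # pairs, centroid exactly (0,0,0)
  s3 <- 1 / sqrt(3)
  shell_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1), c(s3, s3, s3), c(-s3, -s3, -s3))
  shell_centers <- 6 * shell_dirs
  shell_names <- sample(palette, 8, replace = TRUE)

  # ligand: three heavy atoms within ~1.3 A of the origin (matches "CCO")
  if (is.null(ligand_coords)) {
    ligand_coords <- rbind(c(-0.6, 0, 0), c(0.6, 0, 0), c(1.2, 0.6, 0))
  }
  lig_graph <- smiles_to_graph(ligand_smiles)
  if (nrow(ligand_coords) != length(lig_graph$elements)) {
    stop("ligand_coords rows must match the SMILES heavy-atom count")
  }
  lig_atoms <- data.frame(
    record = "HETATM",
    name = paste0(lig_graph$elements, seq_along(lig_graph$elements)),
    element = lig_graph$elements, resname = "LIG", chain = "A",
    resno = 9000L, insert = "",
    x = ligand_coords[, 1], y = ligand_coords[, 2], z = ligand_coords[, 3],
    stringsAsFactors = FALSE
  )

  # decoys: residues in +/- offset pairs 15 A from the decoy center so the
  # centroid is exact and no decoy atom comes within 1 nm of the ligand
  dists <- decoy_distances_nm
  labels <- ifelse(dists < 0.3, "positive",
                   ifelse(dists > 1.0, "negative", "excluded"))
  comps <- vector("list", length(dists))
  for (i in seq_along(dists)) {
    if (labels[i] == "positive") {
      comp <- shell_names
      comp[sample.int(8, 1)] <- sample(palette, 1)
    } else {
      comp <- sample(palette, 4, replace = TRUE)
    }
    comps[[i]] <- comp
  }
  if (duplicate_decoy) {
    dists <- c(dists, 2.0)
    labels <- c(labels, "negative_similar")
    comps <- c(comps, list(shell_names))
  }

  dirs <- .spread_directions(length(dists))
  resno_next <- 101L
  decoy_atoms <- vector("list", length(dists))
  for (i in seq_along(dists)) {
    centre <- nm_to_ang(dists[i]) * dirs[i, ]
    nres <- length(comps[[i]])
    stopifnot(nres %% 2 == 0)
    basis <- .perp_basis(dirs[i, ])
    offs <- matrix(0, nrow = nres, ncol = 3)
    for (j in seq_len(nres / 2)) {
      ang <- pi * (j - 1) / (nres / 2)
      w <- 15 * (cos(ang) * basis[[1]] + sin(ang) * basis[[2]])
      offs[2 * j - 1, ] <- w
      offs[2 * j, ] <- -w
    }
    centers <- sweep(offs, 2, centre, "+")
    decoy_atoms[[i]] <- .ca_atoms(centers, comps[[i]], resno_next)
    resno_next <- resno_next + nres
  }

  # bulk residues along a distant strand
  bulk_centers <- cbind(40 + 3.8 * seq_len(n_bulk), 0, 0)
  bulk <- .ca_atoms(bulk_centers, sample(palette, n_bulk, replace = TRUE),
                    resno_next)

  shell <- .ca_atoms(shell_centers, shell_names, 1L)
  protein <- rbind(shell, do.call(rbind, decoy_atoms), bulk)

  dir.create(file.path(dir, "pockets"), recursive = TRUE, showWarnings = FALSE)
  write_structure(rbind(protein, lig_atoms), file.path(dir, "protein.pdb"))
  for (i in seq_along(decoy_atoms)) {
    write_structure(decoy_atoms[[i]],
                    file.path(dir, "pockets", sprintf("pocket%d_atm.pdb", i)))
  }
  manifest <- data.frame(
    pocket_id = as.character(seq_along(dists)),
    requested_distance_nm = dists,
    intended_label = labels,
    composition = vapply(comps, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  structure_obj <- read_structure(file.path(dir, "protein.pdb"))
  ligand <- ligand_record("toy-ligand", smiles = ligand_smiles,
                          atoms = lig_atoms, source_format = "synthetic")
  pockets <- read_pocket_dir(file.path(dir, "pockets"))
  known <- known_pocket(structure_obj, ligand, 1.0)
  list(dir = dir, structure = structure_obj, ligand = ligand, known = known,
       pockets = pockets, manifest = manifest, seed = seed)
}

#' Generate two labeled Gaussian classes with controlled separation
#'
#' Positives ~ N(mu+, I), negatives ~ N(mu-, I) with |mu+ - mu-| =
#' `separation` (the mean difference is spread evenly over all dimensions).
#' The Bayes-optimal AUC is pnorm(separation / sqrt(2)).
#'
#' @param n_pos,n_neg Class sizes.
#' @param separation Distance between class means in within-class SD units.
#' @param dim Dimensionality (default 600).
#' @param seed Integer seed.
#' @return List of class `labeled_vectors`: `X` (rows shuffled), `y`,
#'   `separation`, `dim`, `seed`, `bayes_auc`.
#' @export
make_separable_vectors <- function(n_pos, n_neg, separation, dim = 600L,
                                   seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, separation >= 0, dim >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  u <- rep(1 / sqrt(dim), dim)
  mu_pos <- (separation / 2) * u
  mu_neg <- -(separation / 2) * u
  Xp <- matrix(stats::rnorm(n_pos * dim), nrow = n_pos)
  Xp <- sweep(Xp, 2, mu_pos, "+")
  Xn <- matrix(stats::rnorm(n_neg * dim), nrow = n_neg)
  Xn <- sweep(Xn, 2, mu_neg, "+")
  X <- rbind(Xp, Xn)
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  perm <- sample.int(n_pos + n_neg)
  structure(list(X = X[perm, , drop = FALSE], y = y[perm],
                 separation = separation, dim = dim, seed = seed,
                 bayes_auc = stats::pnorm(separation / sqrt(2))),
            class = "labeled_vectors")
}
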