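# Structure, pocket and ligand input ----------------------------------------
#
# Structures are held as a flat atom table (one row per atom) grouped by
# residue identity (chain, residue number, insertion code). Distance
# thresholds are expressed in nm throughout the package; coordinates stay in
# Angstrom and are converted at the boundary.

# Waters and common monoatomic ions are never counted as protein pocket
# residues.
.NON_PROTEIN_RES <- c(
  "HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE",
  "CO", "NI", "CU", "CD", "HG", "BR", "IOD", "CS", "LI", "RB", "SR", "BA"
)

.ATOM_COLS <- c(
  "record", "name", "element", "resname", "chain", "resno", "insert",
  "x", "y", "z"
)

#' Read a protein structure from PDB text or a PDB file
#'
#' Parses ATOM and HETATM records into a flat atom table grouped by residue
#' (chain, residue number, insertion code). Alternate locations are resolved
#' by keeping the first-listed conformation of each atom; hydrogens are kept.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB record lines.
#' @return An object of class `pocket_structure`: a list with element
#'   `atoms`, a data.frame with columns record, name, element, resname,
#'   chain, resno, insert, x, y, z.
#' @examples
#' lines <- c(
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
#'   "END")
#' s <- read_structure(lines)
#' nrow(s$atoms)
#' @export
read_structure <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records found: empty structure")
  }
  idx <- which(is_atom)
  # validate coordinate fields up front so errors can name the line
  for (i in idx) {
    coords <- substr(lines[i], 31, 54)
    vals <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54)
    )))
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop(sprintf("unparseable coordinates at line %d: '%s'", i, coords))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdbobj <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdbobj$atom
  atoms <- data.frame(
    record = at$type,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     toupper(substr(trimws(at$elety), 1, 1)), at$elesy),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  # altloc: keep the first-listed alternate location per atom
  atom_key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  keep <- !duplicated(atom_key)
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  cat(sprintf("<pocket_structure> %d atoms, %d residues\n",
              nrow(x$atoms), nrow(unique(residue_table(x$atoms)))))
  invisible(x)
}

residue_table <- function(atoms) {
  unique(atoms[, c("chain", "resno", "insert", "resname"), drop = FALSE])
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

protein_atoms <- function(structure) {
  a <- structure$atoms
  a[a$record == "ATOM" & !(a$resname %in% .NON_PROTEIN_RES), , drop = FALSE]
}

#' Construct a pocket from an atom table
#'
#' A pocket is a set of residues with their atoms; it must contain at least
#' one C-alpha atom (needed for the centroid that drives decoy labeling).
#'
#' @param atoms Atom data.frame (as in [read_structure()]).
#' @param id Pocket identifier string.
#' @param source Either "known" (ligand-defined) or "predicted" (decoy).
#' @return An object of class `pocket` with fields `id`, `residues`,
#'   `atoms`, `source`.
#' @export
new_pocket <- function(atoms, id, source = c("predicted", "known")) {
  source <- match.arg(source)
  if (nrow(atoms) == 0) stop(sprintf("pocket '%s' is empty", id))
  if (!any(trimws(atoms$name) == "CA" & atoms$record == "ATOM")) {
    stop(sprintf("pocket '%s' has no C-alpha atom", id))
  }
  structure(
    list(id = as.character(id), residues = residue_table(atoms),
         atoms = atoms, source = source),
    class = "pocket"
  )
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket %s> %d residues, %d atoms, source=%s\n",
              x$id, nrow(x$residues), nrow(x$atoms), x$source))
  invisible(x)
}

#' Create a ligand record
#'
#' Holds a ligand either as a SMILES string (for featurization) or as an
#' atom table with coordinates (for pocket geometry), or both when a
#' generator supplies them together.
#'
#' @param id Ligand identifier.
#' @param smiles SMILES string, or NULL.
#' @param atoms Atom data.frame with x, y, z columns, or NULL.
#' @param source_format One of "SMILES", "SDF", "MOL2", "PDB", "synthetic".
#' @return An object of class `ligand_record`.
#' @export
ligand_record <- function(id, smiles = NULL, atoms = NULL,
                          source_format = "SMILES") {
  if (is.null(smiles) && is.null(atoms)) {
    stop("ligand_record needs a SMILES string or an atom table")
  }
  if (!is.null(atoms) && !all(c("x", "y", "z") %in% names(atoms))) {
    stop("ligand atom table must have x, y, z columns")
  }
  structure(list(id = as.character(id), smiles = smiles, atoms = atoms,
                 source_format = source_format),
            class = "ligand_record")
}

#' Read a ligand from SMILES, SDF or PDB input
#'
#' @param input SMILES string, or path to an SDF/PDB file.
#' @param format "auto" (from file extension, non-file input is SMILES),
#'   "smiles", "sdf" or "pdb".
#' @param id Identifier for the record; defaults to the file base name or
#'   "ligand".
#' @param resname For PDB input: HETATM residue name selecting the ligand;
#'   default takes the largest HETATM residue that is not water or an ion.
#' @return A [ligand_record()].
#' @export
read_ligand <- function(input, format = c("auto", "smiles", "sdf", "pdb"),
                        id = NULL, resname = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    if (length(input) == 1 && file.exists(input)) {
      ext <- tolower(tools::file_ext(input))
      format <- switch(ext, sdf = "sdf", mol = "sdf", pdb = "pdb",
                       stop(sprintf("cannot infer ligand format from '%s'", input)))
    } else {
      format <- "smiles"
    }
  }
  if (format == "smiles") {
    return(ligand_record(id %||% "ligand", smiles = input,
                         source_format = "SMILES"))
  }
  id <- id %||% sub("\\.[A-Za-z0-9]+$", "", basename(input))
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(input)[[1]]
    ab <- ChemmineR::atomblock(sdf)
    atoms <- data.frame(
      record = "HETATM",
      name = rownames(ab),
      element = sub("_.*$", "", rownames(ab)),
      resname = "LIG", chain = "", resno = 1L, insert = "",
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      stringsAsFactors = FALSE
    )
    return(ligand_record(id, atoms = atoms, source_format = "SDF"))
  }
  # PDB: pull HETATM atoms of the chosen residue
  s <- read_structure(input)
  het <- s$atoms[s$atoms$record == "HETATM" &
                   !(s$atoms$resname %in% .NON_PROTEIN_RES), , drop = FALSE]
  if (nrow(het) == 0) stop("no HETATM ligand found in PDB input")
  if (is.null(resname)) {
    sizes <- table(het$resname)
    resname <- names(sizes)[which.max(sizes)]
  }
  atoms <- het[het$resname == resname, , drop = FALSE]
  if (nrow(atoms) == 0) stop(sprintf("no HETATM residue '%s' in PDB input", resname))
  ligand_record(id, atoms = atoms, source_format = "PDB")
}

#' Extract the known (ligand-defined) pocket from a structure
#'
#' The known pocket is every protein residue with at least one atom within
#' `radius_nm` of any ligand atom. Waters and ions are never pocket
#' residues; hydrogens participate in the distance test if present.
#'
#' @param structure A `pocket_structure`.
#' @param ligand A [ligand_record()] carrying atom coordinates.
#' @param radius_nm Inclusion radius in nm (default 1.0, i.e. 10 Angstrom).
#' @return A `pocket` with `source = "known"`.
#' @export
known_pocket <- function(structure, ligand, radius_nm = 1.0) {
  stopifnot(inherits(structure, "pocket_structure"),
            inherits(ligand, "ligand_record"))
  if (is.null(ligand$atoms)) {
    stop("ligand record has no atom coordinates; a positioned ligand is required")
  }
  if (radius_nm <= 0) stop("radius_nm must be positive")
  prot <- protein_atoms(structure)
  if (nrow(prot) == 0) stop("structure has no protein atoms")
  lx <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  px <- as.matrix(prot[, c("x", "y", "z")])
  # min distance of each protein atom to any ligand atom
  cutoff <- nm_to_ang(radius_nm)
  d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * px %*% t(lx)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  near_res <- unique(residue_key(prot)[mind <= cutoff])
  sel <- residue_key(prot) %in% near_res
  if (!any(sel)) {
    stop(sprintf("no protein residue within %.2f nm of the ligand: empty pocket",
                 radius_nm))
  }
  new_pocket(prot[sel, , drop = FALSE], id = "known", source = "known")
}

#' Read an fpocket-style directory of per-pocket PDB files
#'
#' Expects files named `pocket<k>_atm.pdb` (the fpocket output dialect; the
#' pattern is configurable). Files without any C-alpha atom are skipped with
#' a warning, as are files that fail to parse.
#'
#' @param path Directory containing the pocket files.
#' @param pattern Regular expression with one capture group giving the
#'   pocket rank.
#' @return A list of `pocket` objects with ids taken from the file rank.
#' @export
read_pocket_dir <- function(path, pattern = "^pocket([0-9]+)_atm\\.pdb$") {
  if (!dir.exists(path)) stop(sprintf("pocket directory '%s' does not exist", path))
  files <- list.files(path, full.names = FALSE)
  hits <- grepl(pattern, files)
  if (!any(hits)) {
    stop(sprintf("no files matching '%s' in '%s'", pattern, path))
  }
  files <- files[hits]
  ranks <- sub(pattern, "\\1", files)
  ord <- order(as.integer(ranks))
  files <- files[ord]; ranks <- ranks[ord]
  pockets <- list()
  for (i in seq_along(files)) {
    pk <- tryCatch({
      s <- read_structure(file.path(path, files[i]))
      new_pocket(s$atoms, id = ranks[i], source = "predicted")
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", files[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(pk)) pockets[[length(pockets) + 1L]] <- pk
  }
  if (length(pockets) == 0) stop("no usable pocket files (all skipped)")
  pockets
}

#' C-alpha centroid of a pocket
#'
#' @param pocket A `pocket`.
#' @return Numeric length-3 vector, Angstrom.
#' @export
calpha_center <- function(pocket) {
  stopifnot(inherits(pocket, "pocket"))
  ca <- pocket$atoms[trimws(pocket$atoms$name) == "CA" &
                       pocket$atoms$record == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0) stop(sprintf("pocket '%s' has no C-alpha atom", pocket$id))
  c(mean(ca$x), mean(ca$y), mean(ca$z))
}

#' Distance between the C-alpha centroids of two pockets
#'
#' @param a,b `pocket` objects.
#' @return Distance in nm.
#' @export
center_distance <- function(a, b) {
  ang_to_nm(sqrt(sum((calpha_center(a) - calpha_center(b))^2)))
}

# Fixed-column PDB ATOM/HETATM formatting used by the synthetic generator
# and the structure writer. Coordinates are written to 3 decimals (the PDB
# precision), which bounds round-trip error at 5e-4 Angstrom.
format_pdb_atoms <- function(atoms) {
  n <- nrow(atoms)
  name4 <- ifelse(nchar(atoms$name) <= 3,
                  sprintf(" %-3s", atoms$name), substr(atoms$name, 1, 4))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, seq_len(n), name4, "", atoms$resname,
          ifelse(atoms$chain == "", "A", atoms$chain),
          atoms$resno, ifelse(is.na(atoms$insert), "", atoms$insert),
          atoms$x, atoms$y, atoms$z, 1.0, 0.0, atoms$element)
}

#' Write an atom table as a PDB file
#'
#' @param atoms Atom data.frame (columns as in [read_structure()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  writeLines(c(format_pdb_atoms(atoms), "END"), path)
  invisible(path)
}
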