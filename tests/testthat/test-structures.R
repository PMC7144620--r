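test_that("PDB parsing maps ATOM records to atoms grouped by residue", {
  s <- read_structure(pdb_text(list(
    list(resname = "ALA", resno = 1,
         atoms = list(list(name = "CA", xyz = c(1, 2, 3)))))))
  expect_equal(nrow(s$atoms), 1)
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))

  two <- read_structure(pdb_text(list(
    list(resname = "ALA", resno = 1, atoms = list(
      list(name = "N", xyz = c(0, 0, 0)), list(name = "CA", xyz = c(1, 0, 0)),
      list(name = "C", xyz = c(2, 0, 0)))),
    list(resname = "GLY", resno = 2, atoms = list(
      list(name = "N", xyz = c(3, 0, 0)), list(name = "CA", xyz = c(4, 0, 0)),
      list(name = "C", xyz = c(5, 0, 0)))))))
  expect_equal(nrow(two$atoms), 6)
  expect_equal(nrow(pocketrank:::residue_table(two$atoms)), 2)
})

test_that("parsing rejects empty and malformed input with line numbers", {
  expect_error(read_structure(c("REMARK nothing", "END")), "empty structure")
  bad <- pdb_text(list(list(resname = "ALA", resno = 1,
                            atoms = list(list(name = "CA", xyz = c(1, 2, 3))))))
  substr(bad[1], 31, 38) <- "   abc  "
  expect_error(read_structure(bad), "line 1")
})

test_that("write-then-read round-trips coordinates to PDB precision", {
  tc <- make_toy_complex(c(0.2, 1.5), seed = 4)
  tf <- tempfile(fileext = ".pdb")
  write_structure(tc$structure$atoms, tf)
  back <- read_structure(tf)
  expect_equal(nrow(back$atoms), nrow(tc$structure$atoms))
  expect_equal(back$atoms$x, tc$structure$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, tc$structure$atoms$y, tolerance = 1e-3)
  expect_equal(back$atoms$z, tc$structure$atoms$z, tolerance = 1e-3)
})

test_that("known pocket selects residues by atom distance to the ligand", {
  s <- read_structure(pdb_text(list(
    list(resname = "ALA", resno = 1,
         atoms = list(list(name = "CA", xyz = c(5, 0, 0)))),
    list(resname = "GLY", resno = 2,
         atoms = list(list(name = "CA", xyz = c(12, 0, 0)))))))
  lig <- ligand_record("l", atoms = data.frame(x = 0, y = 0, z = 0))

  p1 <- known_pocket(s, lig, radius_nm = 1.0)
  expect_equal(p1$residues$resname, "ALA")
  expect_equal(p1$source, "known")

  p2 <- known_pocket(s, lig, radius_nm = 1.2)
  expect_setequal(p2$residues$resname, c("ALA", "GLY"))

  expect_error(known_pocket(s, lig, radius_nm = 0.2), "empty pocket")
})

test_that("known pocket matches a brute-force all-pairs scan and is monotone in radius", {
  tc <- make_toy_complex(c(0.2, 0.5, 1.5), seed = 9)
  lig <- tc$ligand
  prot <- tc$structure$atoms
  prot <- prot[prot$record == "ATOM", , drop = FALSE]
  for (r_nm in c(0.8, 1.0, 1.3)) {
    got <- known_pocket(tc$structure, lig, r_nm)
    # O(N*M) oracle over every (protein atom, ligand atom) pair
    keys <- character()
    for (i in seq_len(nrow(prot))) {
      for (j in seq_len(nrow(lig$atoms))) {
        d <- sqrt(sum((unlist(prot[i, c("x", "y", "z")]) -
                         unlist(lig$atoms[j, c("x", "y", "z")]))^2))
        if (d <= r_nm * 10) {
          keys <- c(keys, paste(prot$chain[i], prot$resno[i], prot$insert[i]))
        }
      }
    }
    expect_setequal(paste(got$residues$chain, got$residues$resno, got$residues$insert),
                    unique(keys))
  }
  small <- known_pocket(tc$structure, lig, 0.8)$residues
  big <- known_pocket(tc$structure, lig, 1.3)$residues
  expect_true(all(paste(small$chain, small$resno) %in% paste(big$chain, big$resno)))
})

test_that("C-alpha centroid is the arithmetic mean of CA coordinates", {
  expect_equal(calpha_center(pocket_at(c(1, 1, 1))), c(1, 1, 1))
  expect_equal(calpha_center(pocket_at(rbind(c(0, 0, 0), c(2, 0, 0)))),
               c(1, 0, 0))
  set.seed(42)
  coords <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(calpha_center(pocket_at(coords)),
               c(mean(coords[, 1]), mean(coords[, 2]), mean(coords[, 3])))
})

test_that("centroid distance is in nm, symmetric, and satisfies the triangle inequality", {
  a <- pocket_at(c(0, 0, 0)); b <- pocket_at(c(10, 0, 0))
  expect_equal(center_distance(a, a), 0)
  expect_equal(center_distance(a, b), 1.0)
  set.seed(7)
  for (i in 1:20) {
    ps <- lapply(1:3, function(k) pocket_at(matrix(rnorm(12, sd = 8), ncol = 3)))
    dab <- center_distance(ps[[1]], ps[[2]])
    dba <- center_distance(ps[[2]], ps[[1]])
    dac <- center_distance(ps[[1]], ps[[3]])
    dcb <- center_distance(ps[[3]], ps[[2]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

test_that("pockets without a C-alpha atom are rejected", {
  atoms <- data.frame(record = "ATOM", name = "CB", element = "C",
                      resname = "ALA", chain = "A", resno = 1L, insert = "",
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  expect_error(new_pocket(atoms, "x"), "C-alpha")
})

test_that("fpocket-style directories are read with ids from filename rank", {
  tc <- make_toy_complex(c(0.2, 0.6, 1.4, 1.8, 2.4), seed = 5)
  pockets <- read_pocket_dir(file.path(tc$dir, "pockets"))
  expect_length(pockets, 5)
  expect_equal(vapply(pockets, `[[`, character(1), "id"), as.character(1:5))
  # residue sets match the generator manifest
  for (i in seq_along(pockets)) {
    expect_setequal(pockets[[i]]$residues$resname,
                    strsplit(tc$manifest$composition[i], ",")[[1]])
  }
  expect_error(read_pocket_dir(tempfile()), "does not exist")
  empty <- tempfile(); dir.create(empty)
  expect_error(read_pocket_dir(empty), "no files matching")
  # a file without CA is skipped with a warning
  writeLines(pdb_text(list(list(resname = "ALA", resno = 1,
                                atoms = list(list(name = "CB", xyz = c(0, 0, 0)))))),
             file.path(tc$dir, "pockets", "pocket9_atm.pdb"))
  expect_warning(p2 <- read_pocket_dir(file.path(tc$dir, "pockets")), "skipping")
  expect_length(p2, 5)
})
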