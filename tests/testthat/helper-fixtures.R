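# Shared fixtures and independent oracles used across test files.

# Small embedding table covering the amino acids and the toy ligand.
tiny_table <- function(dim = 16, seed = 3) {
  make_embedding_table(vocab_size = 0, dim = dim, seed = seed,
                       ligand_smiles = "CCO")
}

# A PDB text fixture: residues given as list(resname=, resno=, atoms=list of
# list(name=, xyz=)). All chain A.
pdb_text <- function(residues, record = "ATOM") {
  lines <- character(); serial <- 0L
  for (r in residues) {
    for (a in r$atoms) {
      serial <- serial + 1L
      nm <- if (nchar(a$name) <= 3) sprintf(" %-3s", a$name) else a$name
      lines <- c(lines, sprintf(
        "%-6s%5d %s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        record, serial, nm, r$resname, r$resno,
        a$xyz[1], a$xyz[2], a$xyz[3], toupper(substr(a$name, 1, 1))))
    }
  }
  c(lines, "END")
}

# Single-CA pocket placed at given coordinates (one residue per row).
pocket_at <- function(coords, id = "p", resnames = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  n <- nrow(coords)
  resnames <- resnames %||% rep("ALA", n)
  atoms <- data.frame(
    record = "ATOM", name = "CA", element = "C", resname = resnames,
    chain = "A", resno = seq_len(n), insert = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE)
  new_pocket(atoms, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A model with zero hidden weights and a hand-set output weight on one
# pocket-part coordinate gives analytically known scores, so ranking logic
# can be checked without training.
scoring_probe <- function(dim = 4) {
  cfg <- dfcnn_config(input_dim = 2 * dim, n_blocks = 1, units = 2, seed = 1)
  m <- init_dfcnn(cfg)
  m$W[[1]] <- m$W[[1]] * 0
  m$w_out <- m$w_out * 0
  m$w_out[dim + 1] <- 1  # score = sigmoid(first pocket coordinate)
  m$norm_params <- norm_params("fixed", mean = 0, std = 1)
  m
}

# Independent forward-pass oracle: scalar loops, no matrix algebra shared
# with the implementation.
oracle_forward <- function(model, X) {
  cfg <- model$config
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    h <- as.numeric(X[i, ])
    for (k in seq_len(cfg$n_blocks)) {
      W <- model$W[[k]]; b <- model$b[[k]]
      z <- numeric(cfg$units)
      for (j in seq_len(cfg$units)) {
        acc <- b[j]
        for (m in seq_along(h)) acc <- acc + h[m] * W[m, j]
        z[j] <- max(acc, 0)
      }
      h <- c(h, z)
    }
    acc <- model$b_out
    for (m in seq_along(h)) acc <- acc + h[m] * model$w_out[m]
    out[i] <- 1 / (1 + exp(-acc))
  }
  out
}

# Brute-force all-pairs AUC with half-credit ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Train a small classifier on separable vectors; returns list(model, dat,
# holdout index). Used by dfcnn and ranking tests.
fit_small_classifier <- function(n = 300, dim = 20, separation = 3,
                                 epochs = 15, seed = 11) {
  dat <- make_separable_vectors(n, n, separation, dim = dim, seed = seed)
  Xn <- normalize_features(dat$X, norm_params("self"))
  cfg <- dfcnn_config(input_dim = dim, n_blocks = 2, units = 16,
                      epochs = epochs, seed = seed)
  model <- init_dfcnn(cfg)
  model$norm_params <- attr(Xn, "norm_params")
  ntr <- floor(1.5 * n)
  model <- train_dfcnn(model, Xn[1:ntr, ], dat$y[1:ntr], epochs = epochs)
  list(model = model, dat = dat, Xn = Xn, holdout = (ntr + 1):(2 * n))
}
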