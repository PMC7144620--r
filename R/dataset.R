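# Decoy labeling and dataset construction ------------------------------------
#
# Positives: decoys whose C-alpha centroid lies within 0.3 nm of the known
# (ligand-defined) pocket's centroid ("near_native" strategy), or the known
# pocket itself ("native" strategy). Negatives: up to three randomly chosen
# decoys farther than 1 nm from the known pocket, after removing decoys
# whose pocket vector is nearly collinear with the known pocket's vector
# (cosine similarity >= 0.995).

#' Labeling thresholds of the decoy protocol
#'
#' @param pocket_radius Known-pocket inclusion radius around the ligand, nm.
#' @param near_native_max Maximum centroid distance of a positive decoy, nm.
#' @param negative_min Minimum centroid distance of a negative candidate, nm.
#' @param negatives_per_protein Number of negatives sampled per complex.
#' @param similarity_cutoff Cosine-similarity cutoff above which a negative
#'   candidate is considered a disguised copy of the known pocket and
#'   removed (removal at S >= cutoff).
#' @param far_rationale_distance Informational only: the distance beyond
#'   which a decoy is safely assumed non-native.
#' @return A list of class `labeling_thresholds`.
#' @export
labeling_thresholds <- function(pocket_radius = 1.0,
                                near_native_max = 0.3,
                                negative_min = 1.0,
                                negatives_per_protein = 3L,
                                similarity_cutoff = 0.995,
                                far_rationale_distance = 3.0) {
  stopifnot(near_native_max > 0, negative_min > near_native_max,
            similarity_cutoff > 0, similarity_cutoff <= 1,
            negatives_per_protein >= 1)
  structure(list(pocket_radius = pocket_radius,
                 near_native_max = near_native_max,
                 negative_min = negative_min,
                 negatives_per_protein = as.integer(negatives_per_protein),
                 similarity_cutoff = similarity_cutoff,
                 far_rationale_distance = far_rationale_distance),
            class = "labeling_thresholds")
}

#' Cosine similarity between two vectors
#'
#' @param v_i,v_j Numeric vectors of equal length, each with nonzero norm.
#' @return Scalar in [-1, 1].
#' @export
cosine_similarity <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) stop("vectors differ in length")
  ni <- sqrt(sum(v_i^2)); nj <- sqrt(sum(v_j^2))
  if (ni == 0 || nj == 0) stop("cosine similarity undefined for a zero vector")
  s <- sum(v_i * v_j) / (ni * nj)
  max(-1, min(1, s))
}

#' Partition decoys by centroid distance to the known pocket
#'
#' Distance d to the known pocket's C-alpha centroid: d < `near_native_max`
#' is a positive; d > `negative_min` is a negative candidate; the band in
#' between (inclusive at both ends) is excluded from both classes.
#'
#' @param known The known `pocket`.
#' @param decoys List of decoy `pocket`s.
#' @param thr [labeling_thresholds()].
#' @return A list with `positives`, `negative_candidates`, `excluded_band`
#'   (lists of pockets) and `distances` (named numeric, nm). The three parts
#'   always add up to the input.
#' @export
label_decoys <- function(known, decoys, thr = labeling_thresholds()) {
  stopifnot(inherits(known, "pocket"), length(decoys) >= 1)
  d <- vapply(decoys, center_distance, numeric(1), b = known)
  names(d) <- vapply(decoys, function(p) p$id, character(1))
  pos <- d < thr$near_native_max
  neg <- d > thr$negative_min
  list(
    positives = decoys[pos],
    negative_candidates = decoys[neg],
    excluded_band = decoys[!pos & !neg],
    distances = d
  )
}

#' Sample negatives uniformly without replacement
#'
#' Takes all candidates when fewer than `k` are available. Uses the current
#' RNG state unless `seed` is given, in which case the state is restored on
#' exit.
#'
#' @param candidates List of pockets (or any list).
#' @param k Number to draw (default 3).
#' @param seed Optional integer seed for a self-contained draw.
#' @return A sublist of `candidates`.
#' @export
select_negatives <- function(candidates, k = 3L, seed = NULL) {
  n <- length(candidates)
  if (n == 0) return(candidates[0])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  if (n <= k) return(candidates)
  candidates[sort(sample.int(n, k))]
}

#' Remove negatives nearly collinear with the known pocket vector
#'
#' A candidate is removed when its cosine similarity to the known pocket's
#' vector is at or above the cutoff. A zero-norm candidate vector (e.g. all
#' residues out of vocabulary) is treated as dissimilar and retained, with a
#' warning.
#'
#' @param vectors Numeric matrix (one candidate per row) or list of vectors.
#' @param known_vec The known pocket's vector (nonzero).
#' @param cutoff Similarity cutoff (default 0.995).
#' @return Logical keep vector with attribute `similarity` holding the
#'   computed similarities (NA for zero-norm candidates).
#' @export
similarity_filter <- function(vectors, known_vec, cutoff = 0.995) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  sims <- rep(NA_real_, nrow(vectors))
  keep <- rep(TRUE, nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    if (sum(vectors[i, ]^2) == 0) {
      warning(sprintf("candidate %d has a zero vector: retained as dissimilar", i))
      next
    }
    sims[i] <- cosine_similarity(vectors[i, ], known_vec)
    keep[i] <- sims[i] < cutoff
  }
  attr(keep, "similarity") <- sims
  keep
}

# Normalization -----------------------------------------------------------

#' Normalization parameters
#'
#' A single affine map `(t - mean) / std` applied to every entry of the
#' feature matrix (scalar mean and std, not per-dimension). In "fixed" mode
#' the constants come from a training dataset; in "self" mode they are
#' computed from the matrix being normalized.
#'
#' @param mode "fixed" or "self".
#' @param mean,std Scalars (required in fixed mode; std > 0).
#' @return A list of class `norm_params`.
#' @export
norm_params <- function(mode = c("fixed", "self"), mean = NA_real_,
                        std = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(is.finite(mean), is.finite(std))
    if (std <= 0) stop("std must be positive in fixed mode")
  }
  structure(list(mode = mode, mean = mean, std = std), class = "norm_params")
}

#' Reference fixed normalization constants
#'
#' The training-set constants of the two positive-set strategies:
#' mean -0.5696, std 30.8744 for near-native positives; mean -0.9610,
#' std 63.6607 for native positives.
#'
#' @param strategy "near_native" or "native".
#' @return A fixed-mode [norm_params()].
#' @export
reference_norm_params <- function(strategy = c("near_native", "native")) {
  strategy <- match.arg(strategy)
  if (strategy == "near_native") {
    norm_params("fixed", mean = -0.5696, std = 30.8744)
  } else {
    norm_params("fixed", mean = -0.9610, std = 63.6607)
  }
}

#' Normalize a feature matrix
#'
#' @param x Numeric matrix (n x 2d pair vectors as rows) or vector.
#' @param params [norm_params()]. In self mode the scalar mean and standard
#'   deviation are computed over all entries of `x` and recorded in the
#'   returned attribute.
#' @return Normalized matrix with attribute `norm_params` (fixed-mode
#'   parameters actually applied).
#' @export
normalize_features <- function(x, params = norm_params("self")) {
  stopifnot(inherits(params, "norm_params"))
  if (params$mode == "self") {
    v <- as.vector(x)
    if (length(v) <= 1) stop("self normalization needs more than one value")
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) stop("zero standard deviation: cannot normalize")
    params <- norm_params("fixed", mean = m, std = s)
  }
  out <- (x - params$mean) / params$std
  attr(out, "norm_params") <- params
  out
}

#' Invert a fixed normalization
#'
#' @param x Normalized matrix or vector.
#' @param params Fixed-mode [norm_params()] (e.g. the attribute left by
#'   [normalize_features()]).
#' @return The de-normalized values.
#' @export
denormalize_features <- function(x, params) {
  stopifnot(inherits(params, "norm_params"), params$mode == "fixed")
  out <- x * params$std + params$mean
  attr(out, "norm_params") <- NULL
  out
}

# Dataset build ------------------------------------------------------------

#' Build a labeled pair-vector dataset from complexes and their decoys
#'
#' For each complex: extract the known pocket around the ligand, label the
#' decoys by centroid distance, remove negative candidates whose pocket
#' vector is nearly collinear with the known pocket's vector (similarity
#' filter applied before sampling), sample up to
#' `thr$negatives_per_protein` negatives, and take positives from the
#' strategy (near-native decoys, or the known pocket itself). Complexes
#' whose positive class is empty contribute only negatives; per-complex
#' failures are logged as warnings and skipped.
#'
#' @param complexes A list; each element a list with fields `id`,
#'   `structure` (a `pocket_structure`), `ligand` (a [ligand_record()] with
#'   both coordinates and SMILES), and either `pocket_dir` (fpocket-style
#'   directory) or `decoys` (list of `pocket`s).
#' @param table An `embedding_table`.
#' @param strategy Positive-set strategy: "near_native" or "native".
#' @param thr [labeling_thresholds()].
#' @param seed Integer seed driving negative sampling (one stream over the
#'   whole build, so the build is reproducible bit-for-bit).
#' @param replicate_positives Integer; each positive row is repeated this
#'   many times (class-balance knob for training; default 1).
#' @return An object of class `pocket_dataset`: list with `X` (n x 2d
#'   matrix of raw pair vectors), `y` (0/1 labels), `meta` (data.frame with
#'   complex_id, pocket_id, label, strategy, center_distance_nm,
#'   similarity_to_known), `strategy`, `seed`, `dim`.
#' @export
build_dataset <- function(complexes, table,
                          strategy = c("near_native", "native"),
                          thr = labeling_thresholds(), seed = 1L,
                          replicate_positives = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(length(complexes) >= 1, inherits(table, "embedding_table"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)

  rows <- list(); meta <- list()
  add_row <- function(lv, pv, label, cid, pid, dist, sim) {
    pair <- pair_vector(lv, pv, meta = list(complex = cid, pocket = pid))
    rows[[length(rows) + 1L]] <<- as.numeric(pair)
    meta[[length(meta) + 1L]] <<- data.frame(
      complex_id = cid, pocket_id = pid, label = label, strategy = strategy,
      center_distance_nm = dist, similarity_to_known = sim,
      stringsAsFactors = FALSE)
  }

  for (cx in complexes) {
    res <- tryCatch({
      known <- known_pocket(cx$structure, cx$ligand, thr$pocket_radius)
      decoys <- if (!is.null(cx$decoys)) cx$decoys else read_pocket_dir(cx$pocket_dir)
      lv <- ligand_vector(cx$ligand, table)
      kv <- pocket_vector(known, table)
      part <- label_decoys(known, decoys, thr)

      # negatives: similarity filter on the candidate pool, then sample
      cand <- part$negative_candidates
      if (length(cand) > 0) {
        cvecs <- do.call(rbind, lapply(cand, pocket_vector, table = table))
        keep <- similarity_filter(cvecs, kv, thr$similarity_cutoff)
        sims <- attr(keep, "similarity")
        cand <- cand[keep]; cvecs <- cvecs[keep, , drop = FALSE]
        sims <- sims[keep]
        sel <- select_negatives(seq_along(cand), k = thr$negatives_per_protein)
        sel <- unlist(sel)
        for (j in sel) {
          add_row(lv, cvecs[j, ], 0L, cx$id, cand[[j]]$id,
                  part$distances[[cand[[j]]$id]], sims[j])
        }
      }

      # positives per strategy
      if (strategy == "near_native") {
        if (length(part$positives) == 0) {
          warning(sprintf("complex '%s': no near-native decoy; positive class skipped",
                          cx$id))
        }
        for (p in part$positives) {
          pv <- pocket_vector(p, table)
          s <- if (sum(pv^2) > 0) cosine_similarity(pv, kv) else NA_real_
          for (r in seq_len(replicate_positives)) {
            add_row(lv, pv, 1L, cx$id, p$id, part$distances[[p$id]], s)
          }
        }
      } else {
        for (r in seq_len(replicate_positives)) {
          add_row(lv, kv, 1L, cx$id, known$id, 0.0, 1.0)
        }
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("complex '%s' skipped: %s", cx$id %||% "?",
                      conditionMessage(e)))
      FALSE
    })
  }
  if (length(rows) == 0) stop("dataset build produced zero examples")
  X <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  y <- meta$label
  structure(list(X = X, y = y, meta = meta, strategy = strategy,
                 seed = seed, dim = ncol(X) / 2),
            class = "pocket_dataset")
}

#' @export
print.pocket_dataset <- function(x, ...) {
  cat(sprintf("<pocket_dataset> %d examples (%d positive / %d negative), strategy=%s, dim=%d\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0), x$strategy, ncol(x$X)))
  invisible(x)
}

#' Write a dataset as plain text: manifest TSV, feature matrix, JSON sidecar
#'
#' @param dataset A `pocket_dataset`.
#' @param dir Output directory (created if needed).
#' @param params Optional [norm_params()] recorded in the JSON sidecar.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, params = NULL) {
  stopifnot(inherits(dataset, "pocket_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$meta, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(dataset$X, digits = 12, trim = TRUE, scientific = TRUE),
                     file.path(dir, "features.txt"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(strategy = dataset$strategy, seed = dataset$seed,
                  n = length(dataset$y), dim = dataset$dim)
  if (!is.null(params)) {
    sidecar$normalization <- list(mode = params$mode, mean = params$mean,
                                  std = params$std)
  }
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing manifest.tsv, features.txt, dataset.json.
#' @return A `pocket_dataset` (with `norm_params` attribute when the
#'   sidecar recorded one).
#' @export
read_dataset <- function(dir) {
  meta <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  meta$pocket_id <- as.character(meta$pocket_id)
  meta$complex_id <- as.character(meta$complex_id)
  X <- as.matrix(utils::read.table(file.path(dir, "features.txt")))
  dimnames(X) <- NULL
  side <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  ds <- structure(list(X = X, y = meta$label, meta = meta,
                       strategy = side$strategy, seed = side$seed,
                       dim = side$dim),
                  class = "pocket_dataset")
  if (!is.null(side$normalization)) {
    attr(ds, "norm_params") <- norm_params(side$normalization$mode,
                                           side$normalization$mean,
                                           side$normalization$std)
  }
  ds
}
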