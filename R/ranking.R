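# Pocket ranking --------------------------------------------------------------

#' Score and rank a protein's pocket decoys for a ligand
#'
#' Each pocket is featurized into a pair vector with the ligand, normalized
#' with the supplied (or the model's stored) parameters, and scored by the
#' classifier in inference mode. Pockets are sorted by score descending;
#' ties break by pocket id ascending. Pockets that fail featurization are
#' kept in the output with NA score and rank (sentinel), with a warning.
#'
#' @param model A trained `dfcnn_model`.
#' @param ligand A [ligand_record()] with SMILES.
#' @param pockets List of `pocket`s.
#' @param table An `embedding_table` with `2 * table$dim == input_dim`.
#' @param params [norm_params()]; default the model's stored parameters.
#' @param reference Optional reference `pocket`; when given, each row also
#'   reports the centroid distance to it (nm).
#' @return data.frame with columns pocket_id, score, rank (NA for failed
#'   pockets) and optionally center_distance_nm, ordered by rank.
#' @export
rank_pockets <- function(model, ligand, pockets, table,
                         params = model$norm_params, reference = NULL) {
  stopifnot(inherits(model, "dfcnn_model"), length(pockets) >= 1)
  if (2 * table$dim != model$config$input_dim) {
    stop(sprintf("table dim %d incompatible with model input_dim %d",
                 table$dim, model$config$input_dim))
  }
  if (is.null(params)) {
    stop("no normalization parameters: pass params= or train/set model$norm_params")
  }
  lv <- ligand_vector(ligand, table)
  ids <- vapply(pockets, function(p) p$id, character(1))
  vecs <- vector("list", length(pockets))
  ok <- logical(length(pockets))
  for (i in seq_along(pockets)) {
    vecs[[i]] <- tryCatch({
      ok[i] <- TRUE
      as.numeric(pair_vector(lv, pocket_vector(pockets[[i]], table)))
    }, error = function(e) {
      ok[i] <<- FALSE
      warning(sprintf("pocket '%s' could not be featurized: %s", ids[i],
                      conditionMessage(e)))
      NULL
    })
  }
  if (!any(ok)) stop("no pocket could be featurized")
  X <- do.call(rbind, vecs[ok])
  Xn <- normalize_features(X, params)
  scores <- rep(NA_real_, length(pockets))
  scores[ok] <- forward_dfcnn(model, Xn)
  out <- data.frame(pocket_id = ids, score = scores, rank = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    out$center_distance_nm <- vapply(pockets, center_distance, numeric(1),
                                     b = reference)
  }
  scored <- which(ok)
  ord <- scored[order(-scores[scored], ids[scored])]
  out$rank[ord] <- seq_along(ord)
  out[order(out$rank, out$pocket_id, na.last = TRUE), , drop = FALSE]
}

#' Top-k entries of a ranking
#'
#' @param ranked data.frame from [rank_pockets()] (or any ranked frame).
#' @param k Number of entries (default 3, the reporting convention).
#' @return The first `min(k, n)` ranked rows (unranked sentinels excluded).
#' @export
top_k <- function(ranked, k = 3L) {
  stopifnot(k >= 1)
  ranked <- ranked[!is.na(ranked$rank), , drop = FALSE]
  ranked[ranked$rank <= k, , drop = FALSE]
}

#' Write a ranking as TSV
#'
#' @param ranked data.frame from [rank_pockets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate scores against labels with the full metric suite
#'
#' @param labels 0/1 labels.
#' @param scores Probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `auc`, `report` (a `metric_report`), `counts`,
#'   `pos_size`, `neg_size`.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  counts <- confusion(labels, scores, threshold)
  list(auc = auc_score(labels, scores), report = metric_suite(counts),
       counts = counts, pos_size = sum(labels == 1),
       neg_size = sum(labels == 0))
}
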