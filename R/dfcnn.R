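# Densely connected feed-forward classifier ----------------------------------
#
# Each hidden block receives the concatenation of the raw input and the
# outputs of ALL preceding blocks (the input counts as layer 0), so block k
# has input width input_dim + (k-1)*units and the output unit reads the full
# input_dim + n_blocks*units concatenation. Hidden blocks are
# ReLU + (inverted) dropout; the single output unit is a sigmoid giving the
# native-like probability. Training minimizes binary cross-entropy with
# mini-batch Adam.

#' Configuration of the densely connected classifier
#'
#' Defaults follow the reference architecture: 16 blocks of 100 units on a
#' 600-dimensional input, dropout 0.25 after every hidden block, Adam at
#' learning rate 1e-3 on binary cross-entropy, 1,500 epochs, batch size 128.
#'
#' @param input_dim Width of the input pair vector.
#' @param n_blocks Number of densely connected hidden blocks.
#' @param units Units per hidden block.
#' @param dropout Dropout rate in [0, 1) applied after each block's ReLU.
#' @param learning_rate Adam step size.
#' @param epochs Default number of training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for initialization and training.
#' @return A list of class `dfcnn_config`.
#' @export
dfcnn_config <- function(input_dim = 600L, n_blocks = 16L, units = 100L,
                         dropout = 0.25, learning_rate = 1e-3,
                         epochs = 1500L, batch_size = 128L, seed = 1L) {
  problems <- character()
  if (!(is.numeric(input_dim) && input_dim >= 1)) problems <- c(problems, "input_dim")
  if (!(is.numeric(n_blocks) && n_blocks >= 1)) problems <- c(problems, "n_blocks")
  if (!(is.numeric(units) && units >= 1)) problems <- c(problems, "units")
  if (!(is.numeric(dropout) && dropout >= 0 && dropout < 1)) problems <- c(problems, "dropout")
  if (!(is.numeric(learning_rate) && learning_rate > 0)) problems <- c(problems, "learning_rate")
  if (!(is.numeric(epochs) && epochs >= 1)) problems <- c(problems, "epochs")
  if (!(is.numeric(batch_size) && batch_size >= 1)) problems <- c(problems, "batch_size")
  if (length(problems) > 0) {
    stop(sprintf("invalid dfcnn_config field(s): %s", paste(problems, collapse = ", ")))
  }
  structure(list(input_dim = as.integer(input_dim),
                 n_blocks = as.integer(n_blocks),
                 units = as.integer(units), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "dfcnn_config")
}

block_input_widths <- function(config) {
  config$input_dim + (seq_len(config$n_blocks) - 1L) * config$units
}

#' Initialize a densely connected classifier
#'
#' He-style uniform initialization (limit sqrt(6 / fan_in)) for the weight
#' matrices, zero biases; reproducible from the config seed.
#'
#' @param config A [dfcnn_config()].
#' @return An object of class `dfcnn_model` with fields `config`, `W`, `b`
#'   (per-block weights/biases), `w_out`, `b_out`, `norm_params`,
#'   `history`.
#' @export
init_dfcnn <- function(config = dfcnn_config()) {
  stopifnot(inherits(config, "dfcnn_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(config$seed)
  widths <- block_input_widths(config)
  W <- vector("list", config$n_blocks)
  b <- vector("list", config$n_blocks)
  for (k in seq_len(config$n_blocks)) {
    lim <- sqrt(6 / widths[k])
    W[[k]] <- matrix(stats::runif(widths[k] * config$units, -lim, lim),
                     nrow = widths[k])
    b[[k]] <- numeric(config$units)
  }
  out_width <- config$input_dim + config$n_blocks * config$units
  lim <- sqrt(6 / out_width)
  structure(list(config = config, W = W, b = b,
                 w_out = stats::runif(out_width, -lim, lim), b_out = 0,
                 norm_params = NULL, history = NULL),
            class = "dfcnn_model")
}

#' @export
print.dfcnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dfcnn_model> %d blocks x %d units on %d inputs, dropout %.2f%s\n",
              cfg$n_blocks, cfg$units, cfg$input_dim, cfg$dropout,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

# Forward pass retaining the per-block caches needed by backprop.
# Dropout masks are pre-scaled by 1/keep (inverted dropout); in inference
# mode masks are absent and the pass is deterministic.
forward_cached <- function(model, X, train_mode = FALSE) {
  cfg <- model$config
  if (ncol(X) != cfg$input_dim) {
    stop(sprintf("input width %d does not match model input_dim %d",
                 ncol(X), cfg$input_dim))
  }
  n <- nrow(X)
  total <- cfg$input_dim + cfg$n_blocks * cfg$units
  H <- matrix(0, nrow = n, ncol = total)
  H[, seq_len(cfg$input_dim)] <- X
  A <- vector("list", cfg$n_blocks)
  M <- vector("list", cfg$n_blocks)
  keep <- 1 - cfg$dropout
  for (k in seq_len(cfg$n_blocks)) {
    in_k <- cfg$input_dim + (k - 1L) * cfg$units
    a <- H[, seq_len(in_k), drop = FALSE] %*% model$W[[k]]
    a <- sweep(a, 2, model$b[[k]], "+")
    z <- pmax(a, 0)
    if (train_mode && cfg$dropout > 0) {
      m <- matrix(stats::rbinom(n * cfg$units, 1, keep), nrow = n) / keep
      z <- z * m
      M[[k]] <- m
    }
    H[, in_k + seq_len(cfg$units)] <- z
    A[[k]] <- a
  }
  logits <- drop(H %*% model$w_out) + model$b_out
  list(H = H, A = A, M = M, logits = logits, p = 1 / (1 + exp(-logits)))
}

#' Forward pass: native-like probabilities for a matrix of pair vectors
#'
#' @param model A `dfcnn_model`.
#' @param X Numeric matrix (n x input_dim), already normalized with the
#'   model's normalization parameters.
#' @param train_mode If TRUE, dropout is active (stochastic); inference
#'   mode (default) is deterministic.
#' @return Numeric vector of n probabilities in (0, 1).
#' @export
forward_dfcnn <- function(model, X, train_mode = FALSE) {
  stopifnot(inherits(model, "dfcnn_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  forward_cached(model, X, train_mode = train_mode)$p
}

#' @export
predict.dfcnn_model <- function(object, newdata, normalize = TRUE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (normalize) {
    if (is.null(object$norm_params)) {
      stop("model carries no normalization parameters; pass normalize = FALSE ",
           "or set model$norm_params")
    }
    newdata <- normalize_features(newdata, object$norm_params)
  }
  forward_dfcnn(object, newdata, train_mode = FALSE)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train the classifier with mini-batch Adam on binary cross-entropy
#'
#' @param model An initialized `dfcnn_model`.
#' @param X,y Training matrix (n x input_dim, normalized) and 0/1 labels;
#'   both classes must be present.
#' @param val Optional list(X, y) monitored each epoch.
#' @param epochs Number of epochs (default from the config).
#' @param seed Seed for shuffling and dropout (default config seed + 1);
#'   fixed seed gives a bit-reproducible trajectory.
#' @param verbose Print per-epoch progress every `verbose` epochs (0 = silent).
#' @return The trained model; `$history` is a data.frame with epoch,
#'   train_loss, train_acc, val_loss, val_acc.
#' @export
train_dfcnn <- function(model, X, y, val = NULL, epochs = NULL, seed = NULL,
                        verbose = 0L) {
  stopifnot(inherits(model, "dfcnn_model"))
  cfg <- model$config
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("training set contains a single class")
  if (nrow(X) != length(y)) stop("X and y disagree in length")
  epochs <- as.integer(epochs %||% cfg$epochs)
  seed <- as.integer(seed %||% (cfg$seed + 1L))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)

  # Adam state, one slot per parameter tensor
  zeros_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  mW <- lapply(model$W, zeros_like); vW <- lapply(model$W, zeros_like)
  mb <- lapply(model$b, zeros_like); vb <- lapply(model$b, zeros_like)
  mwo <- zeros_like(model$w_out); vwo <- zeros_like(model$w_out)
  mbo <- 0; vbo <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  step <- 0L

  n <- nrow(X)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  for (epoch in seq_len(epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (batch in batches) {
      Xb <- X[batch, , drop = FALSE]; yb <- y[batch]
      fw <- forward_cached(model, Xb, train_mode = TRUE)
      loss <- bce_loss(fw$p, yb)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d; aborting (inputs normalized? learning rate too high?)",
                     epoch))
      }
      ep_loss <- ep_loss + loss * length(batch)
      ep_correct <- ep_correct + sum((fw$p >= 0.5) == (yb == 1))

      # backward
      nb <- length(batch)
      dz <- (fw$p - yb) / nb                         # d loss / d logits
      gwo <- drop(crossprod(fw$H, dz))
      gbo <- sum(dz)
      gH <- tcrossprod(dz, model$w_out)              # nb x total width
      gW <- vector("list", cfg$n_blocks); gb <- vector("list", cfg$n_blocks)
      for (k in rev(seq_len(cfg$n_blocks))) {
        in_k <- cfg$input_dim + (k - 1L) * cfg$units
        cols <- in_k + seq_len(cfg$units)
        da <- gH[, cols, drop = FALSE] * (fw$A[[k]] > 0)
        if (!is.null(fw$M[[k]])) da <- da * fw$M[[k]]
        gW[[k]] <- crossprod(fw$H[, seq_len(in_k), drop = FALSE], da)
        gb[[k]] <- colSums(da)
        gH[, seq_len(in_k)] <- gH[, seq_len(in_k), drop = FALSE] +
          tcrossprod(da, model$W[[k]])
      }

      # Adam update
      step <- step + 1L
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      adam <- function(p, g, m, v) {
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
        list(p = p, m = m, v = v)
      }
      for (k in seq_len(cfg$n_blocks)) {
        u <- adam(model$W[[k]], gW[[k]], mW[[k]], vW[[k]])
        model$W[[k]] <- u$p; mW[[k]] <- u$m; vW[[k]] <- u$v
        u <- adam(model$b[[k]], gb[[k]], mb[[k]], vb[[k]])
        model$b[[k]] <- u$p; mb[[k]] <- u$m; vb[[k]] <- u$v
      }
      u <- adam(model$w_out, gwo, mwo, vwo)
      model$w_out <- u$p; mwo <- u$m; vwo <- u$v
      u <- adam(model$b_out, gbo, mbo, vbo)
      model$b_out <- u$p; mbo <- u$m; vbo <- u$v
    }
    row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                      train_acc = ep_correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      pv <- forward_dfcnn(model, val$X)
      row$val_loss <- bce_loss(pv, val$y)
      row$val_acc <- mean((pv >= 0.5) == (val$y == 1))
    }
    history <- rbind(history, row)
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %d: train loss %.4f acc %.3f%s", epoch,
                      row$train_loss, row$train_acc,
                      if (!is.null(val)) sprintf(", val loss %.4f acc %.3f",
                                                 row$val_loss, row$val_acc) else ""))
    }
  }
  model$history <- history
  model
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a single RDS archive holding weights, config,
#' normalization parameters and training history, accompanied by a JSON
#' sidecar (`<path>.json`) with the human-readable config.
#'
#' @param model A `dfcnn_model`.
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_dfcnn <- function(model, path) {
  stopifnot(inherits(model, "dfcnn_model"))
  payload <- list(format = "pocketrank-dfcnn", version = 1L, model = model)
  saveRDS(payload, path)
  side <- c(unclass(model$config),
            list(normalization = if (!is.null(model$norm_params))
              unclass(model$norm_params) else NULL))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_dfcnn
#' @export
load_dfcnn <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "pocketrank-dfcnn")) {
    stop("not a pocketrank classifier checkpoint")
  }
  if (!identical(payload$version, 1L)) {
    stop(sprintf("unsupported checkpoint version %s", payload$version))
  }
  payload$model
}
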