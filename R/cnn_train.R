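# Forward/backward passes and the Adam training loop. Activations live in
# n x length x channels arrays; convolutions are im2col matrix products so
# all heavy lifting is BLAS gemm.

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Activations are (n, L*C) matrices with column (l, c) -> l + (c-1)*L, so
# padding, im2col and pooling are all C-level column indexing; the only
# heavy operations are BLAS gemms.

# column indices of positions `ls` (1..L-based) across all C channel blocks
# of a matrix whose per-channel block is `blk` columns wide
chan_cols <- function(ls, C, blk) {
  as.vector(outer(ls, (seq_len(C) - 1L) * blk, "+"))
}

conv_forward <- function(Xm, L, C, W, b, width) {
  n <- nrow(Xm)
  pad <- (width - 1L) %/% 2L
  Lp <- L + 2L * pad
  Mp <- matrix(0, n, Lp * C)
  Mp[, chan_cols(pad + seq_len(L), C, Lp)] <- Xm
  Cout <- ncol(W)
  Xcol <- matrix(0, n * L, width * C)
  for (off in seq_len(width)) {
    s <- Mp[, chan_cols(off - 1L + seq_len(L), C, Lp), drop = FALSE]
    dim(s) <- c(n * L, C)
    Xcol[, (off - 1L) * C + seq_len(C)] <- s
  }
  Z <- add_bias(Xcol %*% W, b)
  mask <- Z > 0
  A <- Z * mask
  dim(A) <- c(n, L * Cout)
  list(A = A, Xcol = Xcol, mask = mask, L = L, C = C)
}

conv_backward <- function(dAm, cache, W, width) {
  n <- nrow(dAm)
  L <- cache$L; C <- cache$C
  pad <- (width - 1L) %/% 2L
  Lp <- L + 2L * pad
  dZ <- dAm
  dim(dZ) <- c(n * L, ncol(W))
  dZ <- dZ * cache$mask
  dXcol <- tcrossprod(dZ, W)
  dMp <- matrix(0, n, Lp * C)
  for (off in seq_len(width)) {
    s <- dXcol[, (off - 1L) * C + seq_len(C), drop = FALSE]
    dim(s) <- c(n, L * C)
    cols <- chan_cols(off - 1L + seq_len(L), C, Lp)
    dMp[, cols] <- dMp[, cols, drop = FALSE] + s
  }
  list(dW = crossprod(cache$Xcol, dZ),
       db = colSums(dZ),
       dX = dMp[, chan_cols(pad + seq_len(L), C, Lp), drop = FALSE])
}

pool_forward <- function(Xm, L, C, width) {
  n <- nrow(Xm)
  Lo <- L %/% width
  best <- Xm[, chan_cols((seq_len(Lo) - 1L) * width + 1L, C, L), drop = FALSE]
  arg <- matrix(1L, n, Lo * C)
  if (width > 1L) {
    for (off in 2:width) {
      s <- Xm[, chan_cols((seq_len(Lo) - 1L) * width + off, C, L),
              drop = FALSE]
      upd <- s > best
      best[upd] <- s[upd]
      arg[upd] <- off
    }
  }
  list(A = best, arg = arg, L = L, C = C, Lo = Lo)
}

pool_backward <- function(dAm, cache, width) {
  n <- nrow(dAm)
  L <- cache$L; C <- cache$C; Lo <- cache$Lo
  dX <- matrix(0, n, L * C)
  ci <- 0:(Lo * C - 1L)
  j0 <- ci %% Lo            # 0-based pooled position per output column
  c0 <- ci %/% Lo           # 0-based channel per output column
  l_in <- rep(j0 * width, each = n) + as.vector(cache$arg)  # 1..L
  col <- l_in + rep(c0 * L, each = n)
  dX[rep_len(seq_len(n), n * Lo * C) + (col - 1L) * n] <- as.vector(dAm)
  dX
}

# He-scaled seeded initialization for one architecture
init_params <- function(spec) {
  ch <- 1L
  lapply(spec$layers, function(ly) {
    switch(ly$kind,
      conv = {
        fan_in <- ly$width * ch
        W <- matrix(rnorm(fan_in * ly$kernels, sd = sqrt(2 / fan_in)),
                    fan_in, ly$kernels)
        ch <<- ly$kernels
        list(W = W, b = numeric(ly$kernels))
      },
      pool = list(),
      dense = , softmax = {
        fan_in <- if (ly$kind == "dense") {
          attr(propagate_shapes(spec), "flat_inputs")
        } else ch
        W <- matrix(rnorm(fan_in * ly$units, sd = sqrt(2 / fan_in)),
                    fan_in, ly$units)
        ch <<- ly$units
        list(W = W, b = numeric(ly$units))
      })
  })
}

# full forward pass; train = TRUE draws dropout masks (inverted dropout)
forward_pass <- function(params, spec, X, dropout_rate = 0, train = FALSE) {
  n <- nrow(X)
  A <- as.matrix(X)
  L <- ncol(X); C <- 1L
  caches <- vector("list", length(spec$layers))
  for (k in seq_along(spec$layers)) {
    ly <- spec$layers[[k]]
    if (ly$kind == "conv") {
      cc <- conv_forward(A, L, C, params[[k]]$W, params[[k]]$b, ly$width)
      A <- cc$A
      C <- ly$kernels
      caches[[k]] <- cc[c("Xcol", "mask", "L", "C")]
    } else if (ly$kind == "pool") {
      pc <- pool_forward(A, L, C, ly$width)
      A <- pc$A
      L <- pc$Lo
      caches[[k]] <- pc[c("arg", "L", "C", "Lo")]
    } else if (ly$kind == "dense") {
      Z <- add_bias(A %*% params[[k]]$W, params[[k]]$b)
      relu_mask <- Z > 0
      H <- Z * relu_mask
      mask <- NULL
      if (train && dropout_rate > 0) {
        keep <- 1 - dropout_rate
        mask <- matrix(runif(length(H)) < keep, nrow(H)) / keep
        H <- H * mask
      }
      caches[[k]] <- list(flat = A, relu_mask = relu_mask, drop_mask = mask)
      A <- H
      L <- 1L; C <- ly$units
    } else if (ly$kind == "softmax") {
      Z <- add_bias(A %*% params[[k]]$W, params[[k]]$b)
      caches[[k]] <- list(H = A)
      A <- softmax_rows(Z)
      L <- 1L; C <- ly$units
    }
  }
  list(probs = A, caches = caches)
}

backward_pass <- function(params, spec, fw, Y1hot) {
  n <- nrow(Y1hot)
  grads <- vector("list", length(spec$layers))
  dA <- (fw$probs - Y1hot) / n      # softmax + cross-entropy gradient
  for (k in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[k]]
    cache <- fw$caches[[k]]
    if (ly$kind == "softmax") {
      grads[[k]] <- list(W = crossprod(cache$H, dA), b = colSums(dA))
      dA <- tcrossprod(dA, params[[k]]$W)
    } else if (ly$kind == "dense") {
      if (!is.null(cache$drop_mask)) dA <- dA * cache$drop_mask
      dZ <- dA * cache$relu_mask
      grads[[k]] <- list(W = crossprod(cache$flat, dZ), b = colSums(dZ))
      dA <- tcrossprod(dZ, params[[k]]$W)
    } else if (ly$kind == "pool") {
      dA <- pool_backward(dA, cache, ly$width)
    } else if (ly$kind == "conv") {
      cb <- conv_backward(dA, cache, params[[k]]$W, ly$width)
      grads[[k]] <- list(W = cb$dW, b = cb$db)
      dA <- cb$dX
    }
  }
  grads
}

# integer layer table consumed by the C++ engine:
# columns kind (0 conv, 1 pool, 2 dense, 3 softmax), width, Lin, Cin, Lout, Cout
layer_table <- function(spec) {
  len <- spec$input_len
  ch <- 1L
  rows <- lapply(spec$layers, function(ly) {
    switch(ly$kind,
      conv = {
        r <- c(0L, ly$width, len, ch, len, ly$kernels)
        ch <<- ly$kernels
        r
      },
      pool = {
        lo <- len %/% ly$width
        r <- c(1L, ly$width, len, ch, lo, ch)
        len <<- lo
        r
      },
      dense = {
        r <- c(2L, 0L, len, ch, 1L, ly$units)
        len <<- 1L
        ch <<- ly$units
        r
      },
      softmax = {
        r <- c(3L, 0L, len, ch, 1L, ly$units)
        len <<- 1L
        ch <<- ly$units
        r
      })
  })
  do.call(rbind, rows)
}

#' Training configuration
#'
#' @param alpha Adam learning rate.
#' @param epochs number of passes over the training data (>= 1).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param dropout_rate dropout probability in the dense layer (default 0.5).
#' @param batch_size mini-batch size; `Inf` gives full-batch steps
#'   (default 128).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return A list of class `secnn_config`.
#' @export
train_config <- function(alpha = 5e-5, epochs = 130, seed = 1,
                         dropout_rate = 0.5, batch_size = 128,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(epochs >= 1, alpha > 0, dropout_rate >= 0, dropout_rate < 1)
  structure(list(alpha = alpha, epochs = as.integer(epochs), seed = seed,
                 dropout_rate = dropout_rate, batch_size = batch_size,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "secnn_config")
}

#' Train a convolutional classifier
#'
#' Seeded He initialization, then per epoch: shuffle, forward pass, binary
#' cross-entropy on the positive-class softmax output, backpropagation, Adam
#' update per mini-batch. Dropout is active only in the dense layer and only
#' during training. Deterministic given `config$seed`.
#'
#' @param spec architecture from [build_cnn()] (or a compatible custom spec).
#' @param x feature matrix (samples x `spec$input_len`), or a
#'   [feature_matrix()] (then `y` is taken from it).
#' @param y binary labels.
#' @param config a [train_config()].
#' @param engine `"cpp"` (compiled production path, default) or `"r"` (pure-R
#'   reference implementation; same algorithm, kept as an independent check).
#'   The two paths share seeding for initialization but shuffle batches
#'   differently, so they agree exactly only in full-batch mode with dropout
#'   off.
#' @return Object of class `secnn_model`: `spec`, fitted `params`, `config`,
#'   and `history` (`data.frame` of per-epoch mean batch loss and accuracy).
#' @export
train_cnn <- function(spec, x, y = NULL, config = train_config(),
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$features
  }
  x <- as.matrix(x)
  if (ncol(x) != spec$input_len) {
    stop_usage("input has ", ncol(x), " features; spec expects ",
               spec$input_len)
  }
  if (length(y) != nrow(x)) stop_usage("label length mismatch")
  n <- nrow(x)
  set.seed(config$seed)
  params <- init_params(spec)
  if (engine == "cpp") {
    fit <- .cpp_train(x, as.integer(y), layer_table(spec), params,
                      as.integer(config$epochs), config$alpha,
                      config$dropout_rate,
                      as.integer(min(config$batch_size, n)),
                      config$beta1, config$beta2, config$eps)
    return(structure(
      list(spec = spec, params = fit$params, config = config,
           history = data.frame(epoch = seq_len(config$epochs),
                                loss = fit$loss, accuracy = fit$accuracy)),
      class = "secnn_model"))
  }
  m1 <- rapply(params, function(p) p * 0, how = "replace")
  m2 <- m1
  t_step <- 0L
  bs <- min(config$batch_size, n)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    losses <- numeric(length(starts))
    correct <- 0L
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + bs - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- forward_pass(params, spec, xb, config$dropout_rate, train = TRUE)
      h <- fw$probs[, 2L]
      losses[bi] <- cross_entropy(h, yb) * length(idx)
      if (!is.finite(losses[bi])) {
        stop("non-finite loss at epoch ", epoch, ", batch ", bi,
             "; try a smaller learning rate")
      }
      correct <- correct + sum((fw$probs[, 2L] > fw$probs[, 1L]) == (yb == 1L))
      Y1hot <- cbind(1 - yb, yb, deparse.level = 0)
      grads <- backward_pass(params, spec, fw, Y1hot)
      t_step <- t_step + 1L
      for (k in seq_along(params)) {
        for (nm in names(params[[k]])) {
          g <- grads[[k]][[nm]]
          m1[[k]][[nm]] <- config$beta1 * m1[[k]][[nm]] + (1 - config$beta1) * g
          m2[[k]][[nm]] <- config$beta2 * m2[[k]][[nm]] +
            (1 - config$beta2) * g * g
          mhat <- m1[[k]][[nm]] / (1 - config$beta1^t_step)
          vhat <- m2[[k]][[nm]] / (1 - config$beta2^t_step)
          params[[k]][[nm]] <- params[[k]][[nm]] -
            config$alpha * mhat / (sqrt(vhat) + config$eps)
        }
      }
    }
    history$loss[epoch] <- sum(losses) / n
    history$accuracy[epoch] <- correct / n
  }
  structure(list(spec = spec, params = params, config = config,
                 history = history),
            class = "secnn_model")
}

#' @export
print.secnn_model <- function(x, ...) {
  h <- tail(x$history, 1)
  cat("secnn_model", x$spec$name, "- trained", nrow(x$history),
      "epochs; final loss", format(h$loss, digits = 4),
      "accuracy", format(h$accuracy, digits = 4), "\n")
  invisible(x)
}

#' Class probabilities and labels for new samples
#'
#' Deterministic forward pass (dropout off). Rows of the returned matrix sum
#' to 1; the predicted label is the class with the larger probability, with
#' exact ties resolved to class 0.
#'
#' @param model a trained `secnn_model`.
#' @param x feature matrix or [feature_matrix()].
#' @param engine `"cpp"` or `"r"` forward pass (see [train_cnn()]).
#' @return `predict_proba`: n x 2 matrix (columns `p0`, `p1`);
#'   `predict_label`: integer vector of 0/1.
#' @export
predict_proba <- function(model, x, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(x, "feature_matrix")) x <- x$features
  x <- as.matrix(x)
  if (ncol(x) != model$spec$input_len) {
    stop_usage("input has ", ncol(x), " features; model expects ",
               model$spec$input_len)
  }
  p <- if (engine == "cpp") {
    .cpp_forward(x, layer_table(model$spec), model$params)
  } else {
    forward_pass(model$params, model$spec, x)$probs
  }
  colnames(p) <- c("p0", "p1")
  p
}

#' @rdname predict_proba
#' @export
predict_label <- function(model, x) {
  p <- predict_proba(model, x)
  as.integer(p[, 2L] > p[, 1L])
}

#' Stratified k-fold cross-validation
#'
#' Samples of each class are shuffled (seeded) and dealt round-robin into k
#' folds, so folds partition the data and preserve the class ratio. Each
#' fold is scored by a model trained on the remaining folds.
#'
#' @param spec architecture.
#' @param fm a [feature_matrix()].
#' @param config a [train_config()]; fold f trains with seed
#'   `config$seed + f`.
#' @param k number of folds (default 5).
#' @return List with `folds` (per-fold [eval_report()]s) and `mean`
#'   (averaged metrics).
#' @export
cross_validate <- function(spec, fm, config = train_config(), k = 5) {
  y <- fm$labels
  n <- length(y)
  if (k < 2 || k > n) stop_usage("k must be in [2, n]")
  if (min(table(factor(y, levels = 0:1))) < k) {
    stop_usage("fewer than k samples in one class; stratified folds impossible")
  }
  set.seed(config$seed)
  fold <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  reports <- lapply(seq_len(k), function(f) {
    cfg <- config
    cfg$seed <- config$seed + f
    tr <- fold != f
    model <- train_cnn(spec, fm$features[tr, , drop = FALSE], y[tr], cfg)
    scores <- predict_proba(model, fm$features[!tr, , drop = FALSE])[, 2L]
    eval_report(y[!tr], as.integer(scores > 0.5), scores)
  })
  metrics <- c("precision", "recall", "f1", "accuracy", "auc")
  means <- vapply(metrics, function(m) {
    mean(vapply(reports, function(r) {
      v <- r[[m]]
      if (is.null(v)) NA_real_ else v
    }, 0), na.rm = TRUE)
  }, 0)
  list(folds = reports, mean = as.list(means), fold_assignment = fold)
}

#' Hyper-parameter grid search
#'
#' Evaluates every (layers, epochs, learning-rate) combination by
#' cross-validated accuracy and returns the argmax. The default grid is the
#' published tuning range: L in 2..4, epochs 50..150 in steps of 10, and the
#' eight learning rates 1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2 (264
#' cells). Ties break toward smaller L, then fewer epochs, then smaller
#' alpha.
#'
#' @param fm a [feature_matrix()].
#' @param seed RNG seed for fold assignment and training.
#' @param grid list with elements `L`, `epochs`, `alpha` (non-empty vectors).
#' @param k folds for the inner cross-validation (default 5).
#' @param config_base base [train_config()] supplying the remaining tunables.
#' @return List with `best` (row of the winning combination) and `surface`
#'   (`data.frame` of the full accuracy surface).
#' @export
grid_search_cnn <- function(fm, seed = 1,
                            grid = list(L = 2:4,
                                        epochs = seq(50L, 150L, 10L),
                                        alpha = c(1e-5, 5e-5, 1e-4, 5e-4,
                                                  1e-3, 5e-3, 1e-2, 5e-2)),
                            k = 5, config_base = train_config()) {
  if (!length(grid$L) || !length(grid$epochs) || !length(grid$alpha)) {
    stop_usage("empty hyper-parameter grid")
  }
  surface <- expand.grid(alpha = grid$alpha, epochs = grid$epochs, L = grid$L,
                         KEEP.OUT.ATTRS = FALSE)
  surface <- surface[order(surface$L, surface$epochs, surface$alpha), ]
  rownames(surface) <- NULL
  surface$accuracy <- vapply(seq_len(nrow(surface)), function(i) {
    cfg <- config_base
    cfg$alpha <- surface$alpha[i]
    cfg$epochs <- as.integer(surface$epochs[i])
    cfg$seed <- seed
    spec <- build_cnn(surface$L[i], input_len = ncol(fm$features))
    cross_validate(spec, fm, cfg, k = k)$mean$accuracy
  }, 0)
  best <- surface[which.max(surface$accuracy), ]  # first max: L, epochs, alpha order
  list(best = best, surface = surface)
}

#' Serialize / restore a trained model as JSON
#'
#' @param model a `secnn_model`.
#' @param path JSON path.
#' @return `write_model`: `path` invisibly; `read_model`: the restored
#'   `secnn_model`.
#' @export
write_model <- function(model, path) {
  payload <- list(
    spec = unclass(model$spec),
    config = unclass(model$config),
    history = as.list(model$history),
    params = lapply(model$params, function(p) {
      if (!length(p)) return(list())
      list(W = list(dim = dim(p$W), data = as.vector(p$W)), b = p$b)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_data("model file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  spec <- structure(p$spec, class = "secnn_spec")
  spec$layers <- lapply(p$spec$layers, as.list)
  params <- lapply(p$params, function(q) {
    if (!length(q)) return(list())
    list(W = matrix(q$W$data, q$W$dim[1], q$W$dim[2]), b = q$b)
  })
  structure(list(spec = spec, params = params,
                 config = structure(as.list(p$config), class = "secnn_config"),
                 history = as.data.frame(p$history)),
            class = "secnn_model")
}
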