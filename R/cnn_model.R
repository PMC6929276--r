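# 1-D convolutional classifier over the 36-feature vector, built from
# scratch: im2col convolutions (width 3, stride 1, same padding), ReLU,
# max-pooling, one dropout-regularized dense layer, softmax output,
# cross-entropy loss, backpropagation with Adam updates.

#' Build a canonical convolutional architecture
#'
#' The three published layouts share one pattern: conv kernel counts double
#' per layer (32, 64, 128, 256), every conv uses width-3 kernels with stride
#' 1 and same padding, each conv is followed by a max-pool (widths 3, 3, 2,
#' 2), then a 256-to-64 fully connected layer with dropout and a 64-to-2
#' softmax. All three variants flatten to exactly 256 dense inputs from an
#' input of length 36.
#'
#' @param L number of convolutional layers, 2, 3 or 4.
#' @param input_len input feature-vector length (default 36).
#' @param n_classes output classes (default 2).
#' @return An object of class `secnn_spec`.
#' @export
build_cnn <- function(L, input_len = 36, n_classes = 2) {
  if (!L %in% 2:4) stop_usage("L must be 2, 3 or 4, got ", L)
  kernels <- c(32L, 64L, 128L, 256L)
  pools <- c(3L, 3L, 2L, 2L)
  layers <- list()
  for (k in seq_len(L)) {
    layers <- c(layers,
                list(list(kind = "conv", kernels = kernels[k], width = 3L,
                          stride = 1L, padding = "same"),
                     list(kind = "pool", width = pools[k])))
  }
  layers <- c(layers, list(list(kind = "dense", units = 64L),
                           list(kind = "softmax", units = as.integer(n_classes))))
  spec <- structure(list(name = sprintf("se-cnn-%dL", L), L = L,
                         input_len = as.integer(input_len),
                         n_classes = as.integer(n_classes), layers = layers),
                    class = "secnn_spec")
  propagate_shapes(spec)  # fail fast on inconsistent lengths
  spec
}

#' @export
print.secnn_spec <- function(x, ...) {
  sh <- propagate_shapes(x)
  cat(x$name, ": input", x$input_len, "\n")
  print(sh, row.names = FALSE)
  invisible(x)
}

#' Per-layer output shapes of an architecture
#'
#' Same-padding stride-1 convolution preserves spatial length and sets the
#' channel count to the kernel count; a width-w max-pool maps length n to
#' `floor(n/w)`; the dense layer flattens `channels * length` inputs.
#'
#' @param spec a `secnn_spec`.
#' @return `data.frame` with one row per layer (`kind`, `length`, `channels`)
#'   plus attribute `flat_inputs`, the flattened count entering the dense
#'   layer.
#' @export
propagate_shapes <- function(spec) {
  len <- spec$input_len
  ch <- 1L
  flat <- NA_integer_
  rows <- lapply(spec$layers, function(ly) {
    switch(ly$kind,
      conv = {
        ch <<- ly$kernels
      },
      pool = {
        len <<- len %/% ly$width
        if (len < 1L) stop_usage("pooling collapses length below 1")
      },
      dense = {
        flat <<- len * ch
        len <<- 1L
        ch <<- ly$units
      },
      softmax = {
        len <<- 1L
        ch <<- ly$units
      },
      stop_usage("unknown layer kind: ", ly$kind))
    data.frame(kind = ly$kind, length = len, channels = ch)
  })
  out <- do.call(rbind, rows)
  attr(out, "flat_inputs") <- flat
  out
}

#' Rectified linear unit
#'
#' @param x numeric vector, matrix or array.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Row-wise softmax
#'
#' Numerically stable (row max subtracted before exponentiation); invariant
#' to adding a constant to every logit in a row.
#'
#' @param z numeric matrix of logits (or a vector, treated as one row).
#' @return Matrix of the same shape with positive rows summing to 1.
#' @export
softmax_rows <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of the positive-class probability:
#' `-(1/m) * sum(y*log(h) + (1-y)*log(1-h))`, with `h` clipped to
#' `[eps, 1-eps]`.
#'
#' @param h predicted positive-class probabilities.
#' @param y binary labels (0/1).
#' @param eps clipping bound (default 1e-12).
#' @return Scalar loss, >= 0.
#' @export
cross_entropy <- function(h, y, eps = 1e-12) {
  if (length(h) == 0L) stop_usage("cross_entropy on zero samples")
  if (length(h) != length(y)) stop_usage("h and y lengths differ")
  h <- pmin(pmax(h, eps), 1 - eps)
  -mean(y * log(h) + (1 - y) * log(1 - h))
}
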