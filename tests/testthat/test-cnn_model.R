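# architecture table shared by the shape tests: per-layer (kind, spatial
# length, channels) expectations for the three published layouts
shape_expectations <- list(
  `2` = list(lens = c(36, 12, 12, 4), flat = 256),
  `3` = list(lens = c(36, 12, 12, 4, 4, 2), flat = 256),
  `4` = list(lens = c(36, 12, 12, 4, 4, 2, 2, 1), flat = 256)
)

test_that("build_cnn reproduces the published layer layouts and shapes", {
  for (L in 2:4) {
    spec <- build_cnn(L)
    kinds <- vapply(spec$layers, `[[`, "", "kind")
    expect_equal(kinds, c(rep(c("conv", "pool"), L), "dense", "softmax"))
    kernels <- vapply(spec$layers[kinds == "conv"], `[[`, 0L, "kernels")
    expect_equal(kernels, c(32L, 64L, 128L, 256L)[seq_len(L)])
    pools <- vapply(spec$layers[kinds == "pool"], `[[`, 0L, "width")
    expect_equal(pools, c(3L, 3L, 2L, 2L)[seq_len(L)])

    sh <- propagate_shapes(spec)
    exp <- shape_expectations[[as.character(L)]]
    expect_equal(sh$length[seq_along(exp$lens)], exp$lens)
    expect_equal(attr(sh, "flat_inputs"), exp$flat)
    expect_equal(tail(sh$channels, 2), c(64L, 2L))  # dense 64, softmax 2
  }
  expect_error(build_cnn(5), "must be 2, 3 or 4")
  # pooling below length 1 is rejected
  expect_error(build_cnn(2, input_len = 4), "below 1")
})

test_that("relu and softmax satisfy their defining identities", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  set.seed(29)
  x <- rnorm(200)
  expect_equal(relu(x) - relu(-x), x)

  expect_equal(as.vector(softmax_rows(c(0, 0))), c(0.5, 0.5))
  expect_equal(as.vector(softmax_rows(c(7, 7, 7))), rep(1 / 3, 3))
  expect_equal(as.vector(softmax_rows(c(1, 0))),
               c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))))
  z <- matrix(rnorm(20), 4)
  expect_equal(softmax_rows(z + 5), softmax_rows(z))
  expect_equal(rowSums(softmax_rows(z)), rep(1, 4))
})

test_that("cross_entropy matches its closed forms and the scalar-loop oracle", {
  y <- c(1, 0, 1, 1, 0)
  expect_lt(cross_entropy(y, y), 1e-10)
  expect_equal(cross_entropy(rep(0.5, 5), y), log(2))
  set.seed(31)
  h <- runif(7)
  yy <- rbinom(7, 1, 0.5)
  expect_equal(cross_entropy(h, yy), cross_entropy_oracle(h, yy))
  expect_equal(cross_entropy(h, yy), cross_entropy(rev(h), rev(yy)))
  expect_error(cross_entropy(numeric(), numeric()), "zero samples")
})

# small custom architecture usable with 2 input features
small_spec <- function(input_len = 2) {
  structure(list(name = "stub", L = 1L, input_len = as.integer(input_len),
                 n_classes = 2L,
                 layers = list(
                   list(kind = "conv", kernels = 8L, width = 3L, stride = 1L,
                        padding = "same"),
                   list(kind = "pool", width = 2L),
                   list(kind = "dense", units = 8L),
                   list(kind = "softmax", units = 2L))),
            class = "secnn_spec")
}

test_that("training fits a separable problem and degenerates gracefully", {
  set.seed(37)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(rnorm(n) + 6 * y, rnorm(n) - 6 * y)  # wide margin
  m <- train_cnn(small_spec(), x, y,
                 train_config(alpha = 1e-3, epochs = 100, seed = 37,
                              dropout_rate = 0.2, batch_size = 64))
  acc <- mean(predict_label(m, x) == y)
  expect_gte(acc, 0.99)
  expect_equal(nrow(m$history), 100)
  expect_true(all(is.finite(m$history$loss)))

  # all-zero labels converge to the constant class-0 predictor
  m0 <- train_cnn(small_spec(), x, rep(0, n),
                  train_config(alpha = 1e-3, epochs = 30, seed = 1,
                               batch_size = 64))
  expect_equal(mean(predict_label(m0, x) == 0), 1)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(123)
  x <- matrix(rnorm(80 * 2), 80)
  y <- rbinom(80, 1, 0.4)
  cfg <- train_config(alpha = 1e-3, epochs = 15, seed = 11, batch_size = 16)
  m1 <- train_cnn(small_spec(), x, y, cfg)
  m2 <- train_cnn(small_spec(), x, y, cfg)
  expect_equal(tail(m1$history$loss, 1), tail(m2$history$loss, 1),
               tolerance = 1e-6)
  expect_identical(m1$params, m2$params)
})

test_that("compiled engine agrees with the pure-R reference implementation", {
  set.seed(7)
  x <- matrix(rnorm(60 * 36), 60)
  y <- rbinom(60, 1, 0.3)
  # full batch + no dropout: batch composition cannot differ between engines
  cfg <- train_config(alpha = 1e-3, epochs = 4, seed = 3, dropout_rate = 0,
                      batch_size = 1e9)
  for (L in c(2, 4)) {
    mr <- train_cnn(build_cnn(L), x, y, cfg, engine = "r")
    mc <- train_cnn(build_cnn(L), x, y, cfg, engine = "cpp")
    expect_equal(mc$history$loss, mr$history$loss, tolerance = 1e-10)
    expect_equal(mc$params, mr$params, tolerance = 1e-10)
    pr <- predict_proba(mr, x, engine = "r")
    pc <- predict_proba(mr, x, engine = "cpp")
    expect_equal(pc, pr, tolerance = 1e-12)
  }
})

test_that("backpropagation gradients match finite differences", {
  sp <- build_cnn(2)
  set.seed(99)
  x <- matrix(rnorm(6 * 36), 6)
  y <- c(1, 0, 1, 0, 1, 1)
  set.seed(1)
  params <- secnn:::init_params(sp)
  fw <- secnn:::forward_pass(params, sp, x)
  grads <- secnn:::backward_pass(params, sp, fw, cbind(1 - y, y))
  loss_at <- function(p) {
    cross_entropy(secnn:::forward_pass(p, sp, x)$probs[, 2], y)
  }
  set.seed(2)
  for (k in seq_along(params)) {
    for (nm in names(params[[k]])) {
      i <- sample(length(params[[k]][[nm]]), 1)
      eps <- 1e-6
      up <- params; up[[k]][[nm]][i] <- up[[k]][[nm]][i] + eps
      dn <- params; dn[[k]][[nm]][i] <- dn[[k]][[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(grads[[k]][[nm]][i] - num), 1e-6 + 1e-4 * abs(num))
    }
  }
})

test_that("predict_proba is a hand-checkable softmax forward pass", {
  # one-layer stub: softmax straight on 3 inputs with hand-set weights
  stub_spec <- structure(list(name = "softmax-stub", input_len = 3L,
                              n_classes = 2L,
                              layers = list(list(kind = "softmax",
                                                 units = 2L))),
                         class = "secnn_spec")
  W <- matrix(c(1, 0, -1, 0, 2, 1), 3)
  b <- c(0.5, -0.5)
  model <- structure(list(spec = stub_spec,
                          params = list(list(W = W, b = b))),
                     class = "secnn_model")
  x <- matrix(c(1, 2, 3), 1)
  z <- as.vector(x %*% W + b)
  expect_equal(as.vector(predict_proba(model, x)),
               exp(z - max(z)) / sum(exp(z - max(z))))

  p <- predict_proba(model, rbind(x, x, x))
  expect_equal(p[1, ], p[3, ], ignore_attr = TRUE)
  expect_equal(rowSums(p), rep(1, 3))
  expect_error(predict_proba(model, matrix(0, 1, 5)), "features")
})

test_that("oversized learning rates collapse to the majority class", {
  # the published failure mode: alpha in [1e-2, 5e-2] on 9:1 imbalance gives
  # an all-negative predictor whose accuracy equals the majority fraction
  weak <- setNames(rep(0.2, 36), feature_registry())
  fm <- simulate_feature_table(n_pos = 100, n_neg = 900, effect_sizes = weak,
                               seed = 21)
  for (a in c(1e-2, 5e-2)) {
    m <- train_cnn(build_cnn(2), fm,
                   train_config(alpha = a, epochs = 15, seed = 2))
    acc <- mean(predict_label(m, fm) == fm$labels)
    expect_equal(acc, 0.9, tolerance = 0.01 / 0.9)
  }
})

test_that("stratified cross-validation partitions and scores correctly", {
  fm <- simulate_feature_table(n_pos = 150, n_neg = 350,
                               effect_sizes = setNames(rep(0, 36),
                                                       feature_registry()),
                               seed = 41)
  cfg <- train_config(alpha = 1e-4, epochs = 30, seed = 41, batch_size = 64)
  cv <- cross_validate(build_cnn(2), fm, cfg, k = 5)
  expect_length(cv$folds, 5)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(as.vector(table(cv$fold_assignment)), rep(100L, 5))
  # stratification: each fold holds 30 positives
  for (f in 1:5) {
    expect_equal(sum(fm$labels[cv$fold_assignment == f]), 30L)
  }
  # label-independent features: held-out accuracy near the majority fraction
  expect_equal(cv$mean$accuracy, 0.7, tolerance = 0.08)

  expect_error(cross_validate(build_cnn(2), fm, cfg, k = 200),
               "fewer than k")
  expect_error(cross_validate(build_cnn(2), fm, cfg, k = 1), "k must be")
})

test_that("grid search enumerates the published grid and finds optima", {
  # published ranges: 3 layer counts x 11 epoch values x 8 learning rates
  default_grid <- eval(formals(grid_search_cnn)$grid)
  expect_equal(length(default_grid$L) * length(default_grid$epochs) *
                 length(default_grid$alpha), 264L)
  expect_equal(default_grid$alpha,
               c(1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2))

  fm <- simulate_feature_table(n_pos = 40, n_neg = 120, seed = 43)
  single <- grid_search_cnn(fm, seed = 43,
                            grid = list(L = 2, epochs = 10, alpha = 1e-3),
                            k = 2, config_base = train_config(batch_size = 64))
  expect_equal(nrow(single$surface), 1L)
  expect_equal(single$best$L, 2)

  # planted optimum: a sane rate beats a divergent one
  gs <- grid_search_cnn(fm, seed = 43,
                        grid = list(L = 2, epochs = 15,
                                    alpha = c(1e-3, 5e-2)),
                        k = 2, config_base = train_config(batch_size = 64))
  expect_equal(nrow(gs$surface), 2L)
  expect_equal(gs$best$alpha, 1e-3)

  expect_error(grid_search_cnn(fm, grid = list(L = integer(), epochs = 1,
                                               alpha = 1)),
               "empty")
})

test_that("models serialize to JSON and back without behavioural change", {
  set.seed(5)
  x <- matrix(rnorm(30 * 36), 30)
  y <- rbinom(30, 1, 0.5)
  m <- train_cnn(build_cnn(3), x, y,
                 train_config(alpha = 1e-3, epochs = 3, seed = 5,
                              batch_size = 16))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict_proba(m2, x), predict_proba(m, x), tolerance = 1e-12)
  expect_equal(m2$history$loss, m$history$loss, tolerance = 1e-12)
})
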