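test_that("sequence_composition counts bases with soft-mask convention", {
  sc <- sequence_composition("GGCC")
  expect_equal(as.vector(sc), c(0, 1, 0))

  sc <- sequence_composition("ATat")
  expect_equal(sc[, "AT_content"], 1, ignore_attr = TRUE)
  expect_equal(sc[, "repeat_fraction"], 0.5, ignore_attr = TRUE)

  # N ignored for AT/GC denominators, counted for repeat denominator
  sc <- sequence_composition("ANGN")
  expect_equal(as.vector(sc), c(0.5, 0.5, 0))

  set.seed(19)
  seq <- paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N"), 1000,
                      replace = TRUE), collapse = "")
  chars <- strsplit(seq, "")[[1]]
  acgt <- sum(chars %in% c("A", "C", "G", "T", "a", "c", "g", "t"))
  sc <- sequence_composition(seq)
  expect_equal(sc[, "AT_content"],
               sum(chars %in% c("A", "T", "a", "t")) / acgt,
               ignore_attr = TRUE)
  expect_equal(sc[, "GC_content"],
               sum(chars %in% c("G", "C", "g", "c")) / acgt,
               ignore_attr = TRUE)
  expect_equal(sc[, "repeat_fraction"],
               sum(chars %in% letters) / 1000, ignore_attr = TRUE)
  expect_equal(sum(sc[, c("AT_content", "GC_content")]), 1)

  expect_error(sequence_composition(""), "empty sequence")
})

test_that("conservation_features computes mean score and conserved fraction", {
  region <- genomic_regions("chr1", 0, 100)
  flat1 <- structure(list(chr1 = data.frame(start = 0, end = 100, value = 1)),
                     class = "score_track")
  expect_equal(as.vector(conservation_features(region, flat1)), c(1, 1))

  flat0 <- structure(list(chr1 = data.frame(start = 0, end = 100, value = 0)),
                     class = "score_track")
  expect_equal(as.vector(conservation_features(region, flat0)), c(0, 0))

  mix <- structure(list(chr1 = data.frame(start = c(0, 30),
                                          end = c(30, 100),
                                          value = c(0.9, 0.1))),
                   class = "score_track")
  expect_equal(as.vector(conservation_features(region, mix)),
               c(0.3 * 0.9 + 0.7 * 0.1, 0.30))

  # bases missing from the track score zero
  half <- structure(list(chr1 = data.frame(start = 0, end = 50, value = 1)),
                    class = "score_track")
  expect_equal(as.vector(conservation_features(region, half)), c(0.5, 0.5))
})

test_that("motif_affinity scores best-hit log2 odds on both strands", {
  m <- pwm("test", matrix(c(0.85, 0.05, 0.05, 0.05,
                            0.05, 0.85, 0.05, 0.05,
                            0.05, 0.05, 0.05, 0.85), 4))
  consensus <- "ACT"
  expect_equal(motif_affinity(consensus, m), 3 * log2(0.85 / 0.25))

  set.seed(23)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  counts <- matrix(sample(1:20, 32, replace = TRUE), 4)
  pf <- withr::local_tempfile()
  writeLines(c(">r8", apply(counts, 1, paste, collapse = " ")), pf)
  m8 <- read_pwm(pf)[[1]]
  expect_equal(motif_affinity(seq, m8), motif_oracle(seq, m8))

  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  expect_equal(motif_affinity(rc, m8), motif_affinity(seq, m8))

  expect_error(motif_affinity("AC", m8), "shorter than motif")

  # sum-over-threshold alternative is bounded below by nothing but is
  # consistent: it sums exactly the windows the scan scores above 0
  both <- motif_affinity(seq, m8, method = "sumthr", threshold = 1e9)
  expect_equal(both, 0)
})

test_that("assemble_features enforces the 36-column registry contract", {
  expect_length(feature_registry(), 36L)
  expect_false(anyDuplicated(feature_registry()) > 0)

  n <- 10
  set.seed(77)
  dens <- matrix(rnorm(n * 31), n,
                 dimnames = list(NULL, feature_registry()[1:31]))
  seqf <- matrix(runif(n * 3), n,
                 dimnames = list(NULL, c("AT_content", "GC_content",
                                         "repeat_fraction")))
  cons <- matrix(runif(n * 2), n,
                 dimnames = list(NULL, c("phastCons", "phastConsP")))
  labels <- rep(c(1, 0), c(3, 7))

  fm <- assemble_features(dens, seqf, cons, labels = labels, zscore = FALSE)
  expect_equal(colnames(fm$features), feature_registry())
  expect_equal(fm$features[, "Brd4"], dens[, "Brd4"], ignore_attr = TRUE)
  expect_equal(fm$features[, "phastCons"], cons[, "phastCons"],
               ignore_attr = TRUE)

  z <- assemble_features(dens, seqf, cons, labels = labels, zscore = TRUE)
  expect_true(all(abs(colMeans(z$features)) < 1e-9))
  expect_true(all(abs(apply(z$features, 2, sd) - 1) < 1e-9))

  # permutation equivariance in samples
  perm <- sample.int(n)
  fp <- assemble_features(dens[perm, ], seqf[perm, ], cons[perm, ],
                          labels = labels[perm], zscore = FALSE)
  expect_equal(fp$features, fm$features[perm, ], ignore_attr = TRUE)

  empty <- assemble_features(dens[0, ], seqf[0, ], cons[0, ],
                             labels = integer())
  expect_equal(dim(empty$features), c(0L, 36L))
  expect_equal(colnames(empty$features), feature_registry())

  expect_error(assemble_features(dens, seqf[1:5, ], cons, labels = labels),
               "different sample counts")
  expect_error(assemble_features(dens[, 1:30], seqf, cons, labels = labels),
               "missing feature columns: Nr5a2")
  med1 <- cbind(dens, Med1 = rnorm(n))
  expect_error(assemble_features(med1, seqf, cons, labels = labels),
               "Med1 defines the labels")
})
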