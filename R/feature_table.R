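# The canonical 36-column feature matrix: 31 signal-track/TF columns plus
# sequence composition (AT, GC, repeat fraction) and conservation
# (phastCons mean, conserved-base proportion).

.FEATURE_REGISTRY <- c(
  "H3K27ac", "H3K4me1", "H3K4me3", "H3K9me3", "Brd4", "Cdk8", "Cdk9",
  "Med12", "p300", "CBP", "Pol2", "Lsd1", "Brg1", "Smc1", "Nipbl", "Mi2b",
  "CHD7", "HDAC2", "HDAC", "DNaseI", "Oct4", "Sox2", "Nanog", "Smad3",
  "Stat3", "Tcf3", "Esrrb", "Klf4", "Prdm14", "Tcfcp2l1", "Nr5a2",
  "AT_content", "GC_content", "phastCons", "phastConsP", "repeat_fraction")

#' The canonical 36-feature registry
#'
#' Fixed, ordered names of the 36 model features: four histone marks,
#' coactivators/chromatin regulators/Mediator subunits (Med12 — Med1 itself
#' defines the labels and is deliberately absent), DNaseI, eleven
#' transcription factors, then the five sequence-derived columns. HDAC and
#' HDAC2 are kept in the registry even though no standard mESC track exists
#' for them; they are typically filled from motif/affinity proxies or zeros.
#'
#' @return Character vector of length 36.
#' @export
feature_registry <- function() {
  stopifnot(length(.FEATURE_REGISTRY) == 36L,
            !anyDuplicated(.FEATURE_REGISTRY))
  .FEATURE_REGISTRY
}

#' Feature matrix constructor
#'
#' @param features numeric matrix (samples x features) with column names.
#' @param labels binary vector (0/1), one per row.
#' @param sample_ids optional row identifiers.
#' @param validate_names require exactly the 36 [feature_registry()] columns
#'   in order (default TRUE; readers of external tables may relax this).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels, sample_ids = NULL,
                           validate_names = TRUE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop_data("labels length (", length(labels), ") != sample count (",
              nrow(features), ")")
  }
  if (nrow(features) && !all(labels %in% c(0L, 1L))) {
    stop_data("labels must be binary 0/1")
  }
  if (anyNA(features)) stop_data("feature matrix contains missing values")
  if (validate_names && !identical(colnames(features), feature_registry())) {
    stop_data("feature columns must be exactly the 36 registry names in order")
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(features)))
  structure(list(features = features, labels = labels,
                 sample_ids = as.character(sample_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$features), "samples x", ncol(x$features),
      "features;", sum(x$labels == 1L), "positive /",
      sum(x$labels == 0L), "negative\n")
  invisible(x)
}

#' Sequence composition features
#'
#' AT and GC content over unambiguous bases (`N` ignored in the denominator)
#' and the soft-masked repeat fraction (lowercase bases over all bases).
#'
#' @param seq character vector of DNA sequences over `A C G T N` and
#'   lowercase.
#' @return Matrix with columns `AT_content`, `GC_content`, `repeat_fraction`.
#' @export
sequence_composition <- function(seq) {
  if (!length(seq) || any(!nzchar(seq))) stop_data("empty sequence")
  count <- function(keep) nchar(gsub(keep, "", seq))  # chars NOT removed
  rep_frac <- count("[^a-z]") / nchar(seq)
  at <- count("[^AaTt]")
  gc <- count("[^GgCc]")
  acgt <- at + gc
  cbind(AT_content = ifelse(acgt > 0, at / acgt, NA_real_),
        GC_content = ifelse(acgt > 0, gc / acgt, NA_real_),
        repeat_fraction = rep_frac)
}

#' Conservation features of a region
#'
#' `phastCons` is the mean per-base conservation score over the region
#' (bases missing from the track score 0); `phastConsP` is the proportion of
#' bases with score at or above `threshold`.
#'
#' @param regions region `data.frame`.
#' @param track a [read_score_track()] object.
#' @param threshold conserved-base threshold (default 0.5).
#' @return Matrix with columns `phastCons` and `phastConsP`, one row per
#'   region.
#' @export
conservation_features <- function(regions, track, threshold = 0.5) {
  if (any(regions$end - regions$start <= 0)) stop_data("zero-length region")
  out <- t(vapply(seq_len(nrow(regions)), function(i) {
    len <- regions$end[i] - regions$start[i]
    d <- track[[regions$chrom[i]]]
    if (is.null(d)) return(c(0, 0))
    ov <- pmin(d$end, regions$end[i]) - pmax(d$start, regions$start[i])
    keep <- ov > 0
    c(sum(d$value[keep] * ov[keep]) / len,
      sum(ov[keep & d$value >= threshold]) / len)
  }, numeric(2)))
  colnames(out) <- c("phastCons", "phastConsP")
  out
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer-encode an uppercase DNA string; ambiguous bases -> NA
encode_dna <- function(seq) {
  unname(.BASE_CODE[strsplit(toupper(seq), "")[[1]]])
}

#' Motif binding-affinity score of a sequence
#'
#' Scores every window on both strands with the log2-odds of the PWM against
#' its background, `sum_k log2(p[base_k, k] / bg[base_k])`; ambiguous bases
#' contribute 0. `method = "best"` (default) returns the maximum window
#' score; `method = "sumthr"` sums all window scores above `threshold`
#' (0 when no window qualifies).
#'
#' @param seq a DNA sequence (character scalar), length >= motif width.
#' @param motif a [pwm()].
#' @param method `"best"` or `"sumthr"`.
#' @param threshold score threshold for `method = "sumthr"` (default 0).
#' @return Scalar affinity score.
#' @export
motif_affinity <- function(seq, motif, method = c("best", "sumthr"),
                           threshold = 0) {
  method <- match.arg(method)
  w <- ncol(motif$mat)
  n <- nchar(seq)
  if (n < w) stop_data("sequence (", n, " bp) shorter than motif width ", w)
  lodds <- log2(motif$mat / motif$background)
  scan <- function(code) {
    nw <- length(code) - w + 1L
    pos <- matrix(code[rep(seq_len(nw), each = w) + (seq_len(w) - 1L)],
                  nrow = w)
    contrib <- lodds[cbind(as.vector(pos), rep(seq_len(w), nw))]
    contrib[is.na(contrib)] <- 0
    colSums(matrix(contrib, nrow = w))
  }
  code <- encode_dna(seq)
  scores <- c(scan(code), scan(rev(5L - code)))  # 5 - code = complement
  if (method == "best") max(scores)
  else sum(scores[scores > threshold])
}

#' Assemble the 36-column feature matrix
#'
#' Column-binds the supplied parts, reorders them to the canonical
#' [feature_registry()] order, optionally z-scores each column, and attaches
#' labels. All parts must cover the same samples in the same order. Med1
#' density must not appear among the parts: Med1 defines the labels, not a
#' feature (Med12 is the Mediator feature).
#'
#' @param ... numeric matrices or data frames with named feature columns and
#'   equal row counts (e.g. a [density_matrix()], [sequence_composition()],
#'   [conservation_features()], a matrix of motif affinities).
#' @param labels binary label vector.
#' @param sample_ids optional identifiers.
#' @param zscore per-column standardization (default TRUE: mean 0, sd 1;
#'   constant columns are left centred at 0).
#' @return A [feature_matrix()]. The source part of each column is recorded
#'   in the `sources` attribute of `$features`.
#' @export
assemble_features <- function(..., labels, sample_ids = NULL, zscore = TRUE) {
  parts <- list(...)
  nr <- unique(vapply(parts, nrow, 0L))
  if (length(nr) > 1L) {
    stop_data("parts cover different sample counts: ",
              paste(vapply(parts, nrow, 0L), collapse = ", "))
  }
  mats <- lapply(parts, as.matrix)
  all_cols <- unlist(lapply(mats, colnames))
  if ("Med1" %in% all_cols) {
    stop_data("Med1 defines the labels and cannot be a feature column")
  }
  if (anyDuplicated(all_cols)) {
    stop_data("duplicate feature columns: ",
              paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "))
  }
  big <- do.call(cbind, mats)
  missing <- setdiff(feature_registry(), colnames(big))
  if (length(missing)) {
    stop_data("missing feature columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(big), feature_registry())
  if (length(extra)) {
    stop_data("unknown feature columns: ", paste(extra, collapse = ", "))
  }
  big <- big[, feature_registry(), drop = FALSE]
  src <- rep(seq_along(mats), vapply(mats, ncol, 0L))
  names(src) <- all_cols
  if (zscore && nrow(big) > 0L) big <- zscore_columns(big)
  attr(big, "sources") <- src[feature_registry()]
  feature_matrix(big, labels, sample_ids)
}

#' Z-score matrix columns
#'
#' Centres each column and scales to unit standard deviation; columns with
#' zero variance are centred only.
#'
#' @param x numeric matrix.
#' @return Standardized matrix of the same shape.
#' @export
zscore_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}
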