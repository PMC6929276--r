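# Seeded simulators: ChIP-seq-like reads with planted enriched peaks, and
# class-imbalanced feature tables with planted per-feature effect sizes.
# Everything is a pure function of its arguments (seed included), so
# fixtures regenerate byte-for-byte.

#' Simulate a read set with planted peaks
#'
#' Background reads fall uniformly at `background_rate` reads per bp; inside
#' each planted peak the rate is multiplied by its fold enrichment. Read
#' counts per segment are Poisson; strands are assigned 50/50.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param background_rate expected background reads per bp.
#' @param peaks optional region `data.frame` with an extra `fold` column
#'   (fold >= 1) marking enriched intervals.
#' @param read_len read length in bp (default 36, typical short-read ChIP).
#' @param seed RNG seed.
#' @return A [read_set()]; reads are sorted by (chrom, start) so output files
#'   are deterministic.
#' @export
simulate_reads <- function(chrom_lengths, background_rate, peaks = NULL,
                           read_len = 36, seed = 1) {
  if (!length(chrom_lengths) || any(chrom_lengths <= 0)) {
    stop_usage("chrom_lengths must be positive")
  }
  if (!is.null(peaks) && any(peaks$fold < 1)) stop_usage("peak fold must be >= 1")
  set.seed(seed)
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    # piecewise-constant rate: background everywhere, fold x inside peaks
    brk <- c(0, len)
    fold <- NULL
    pk <- if (is.null(peaks)) NULL else peaks[peaks$chrom == chrom, , drop = FALSE]
    if (!is.null(pk) && nrow(pk)) {
      brk <- sort(unique(c(0, len, pmin(pk$start, len), pmin(pk$end, len))))
    }
    seg_start <- brk[-length(brk)]
    seg_end <- brk[-1]
    fold <- rep(1, length(seg_start))
    if (!is.null(pk) && nrow(pk)) {
      for (i in seq_len(nrow(pk))) {
        inside <- seg_start >= pk$start[i] & seg_end <= pk$end[i]
        fold[inside] <- fold[inside] * pk$fold[i]
      }
    }
    counts <- rpois(length(seg_start),
                    background_rate * fold * (seg_end - seg_start))
    starts <- unlist(lapply(seq_along(counts), function(i) {
      if (counts[i] == 0) return(numeric())
      floor(runif(counts[i], seg_start[i], seg_end[i]))
    }))
    if (!length(starts)) next
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = starts,
      end = pmin(starts + read_len, len),
      strand = ifelse(runif(length(starts)) < 0.5, "+", "-"),
      stringsAsFactors = FALSE)
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), stringsAsFactors = FALSE)
  reads <- reads[order(reads$chrom, reads$start, reads$end, reads$strand), ]
  rownames(reads) <- NULL
  read_set(reads)
}

#' Default planted effect sizes for the simulated feature table
#'
#' Class-mean shifts (in within-class standard-deviation units) per feature.
#' The six Mediator/coactivator columns that dominate real feature rankings
#' get large-to-moderate shifts in strictly decreasing order (Med12 3.0,
#' Cdk8 2.5, Brd4 2.0, Cdk9 1.5, p300 1.25, H3K27ac 1.0); the remaining
#' signal tracks get a weak 0.1 shift; the sequence-derived columns get 0.
#'
#' @return Named numeric vector over [feature_registry()].
#' @export
default_effect_sizes <- function() {
  d <- setNames(rep(0.1, 36), feature_registry())
  d[c("Med12", "Cdk8", "Brd4", "Cdk9", "p300", "H3K27ac")] <-
    c(3.0, 2.5, 2.0, 1.5, 1.25, 1.0)
  d[c("AT_content", "GC_content", "phastCons", "phastConsP",
      "repeat_fraction")] <- 0
  d
}

#' Simulate a class-imbalanced 36-feature table
#'
#' Class-conditional Gaussian columns: negatives have mean 0, positives mean
#' `effect_sizes[j]`, both with standard deviation `noise_sd`. Defaults
#' mirror the published training set: 1119 positives, 9981 negatives (11100
#' samples, negatives:positives = 9).
#'
#' @param n_pos,n_neg class sizes.
#' @param effect_sizes named length-36 vector of per-feature class-mean
#'   shifts ([default_effect_sizes()]).
#' @param noise_sd within-class standard deviation (> 0, default 1).
#' @param seed RNG seed.
#' @return A [feature_matrix()] with positives first.
#' @export
simulate_feature_table <- function(n_pos = 1119, n_neg = 9981,
                                   effect_sizes = default_effect_sizes(),
                                   noise_sd = 1, seed = 1) {
  if (n_pos < 0 || n_neg < 0) stop_usage("class sizes must be >= 0")
  if (noise_sd <= 0) stop_usage("noise_sd must be positive")
  if (length(effect_sizes) != 36L) stop_usage("need 36 effect sizes")
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(rnorm(n * 36L, sd = noise_sd), n, 36L,
              dimnames = list(NULL, feature_registry()))
  y <- rep(c(1L, 0L), c(n_pos, n_neg))
  if (n_pos > 0) {
    x[y == 1L, ] <- sweep(x[y == 1L, , drop = FALSE], 2, effect_sizes, "+")
  }
  feature_matrix(x, y)
}

#' Build an end-to-end super-enhancer calling fixture
#'
#' Plants `n_clusters` enhancer clusters (2-4 constituents within stitching
#' range) along one synthetic chromosome, with `n_se` of them strongly
#' Med1-enriched (fold `se_fold`) and the rest weakly enriched (fold 2-4,
#' hockey-stick body). A flat control library is included. Expected labels
#' record which stitched clusters were planted as super-enhancers.
#'
#' @param seed RNG seed.
#' @param n_clusters total enhancer clusters (default 100).
#' @param n_se planted super-enhancer clusters (default 5).
#' @param se_fold Med1 fold enrichment of planted super-enhancers
#'   (default 60).
#' @param background_rate background read rate (default 0.02 reads/bp).
#' @param dir optional directory: writes `enhancers.bed`, `med1.sam`,
#'   `control.sam`, `expected_labels.tsv` deterministically.
#' @return List with `enhancers` (regions), `med1`, `control` ([read_set()]s),
#'   `expected` (`data.frame` of cluster spans and labels), and `files` when
#'   `dir` is given.
#' @export
make_se_fixture <- function(seed = 1, n_clusters = 100, n_se = 5,
                            se_fold = 60, background_rate = 0.02, dir = NULL) {
  stopifnot(n_se <= n_clusters)
  set.seed(seed)
  spacing <- 60000           # > 12.5 kb stitching gap between clusters
  chrom_len <- (n_clusters + 1) * spacing
  regions <- list()
  expected <- list()
  se_idx <- if (n_se > 0) sort(sample.int(n_clusters, n_se)) else integer()
  for (i in seq_len(n_clusters)) {
    base <- (i - 1) * spacing + 10000
    k <- sample(2:4, 1)
    starts <- base + cumsum(c(0, sample(2000:8000, k - 1, replace = TRUE)))
    widths <- sample(500:1500, k, replace = TRUE)
    regions[[i]] <- genomic_regions("chrS", starts, starts + widths,
                                    sprintf("enh_%d_%d", i, seq_len(k)))
    expected[[i]] <- data.frame(chrom = "chrS", start = starts[1],
                                end = starts[k] + widths[k],
                                cluster = i,
                                label = as.integer(i %in% se_idx))
  }
  enhancers <- do.call(rbind, regions)
  expected <- do.call(rbind, expected)
  fold <- ifelse(expected$label == 1L, se_fold,
                 2 + 2 * runif(n_clusters))
  peaks <- data.frame(chrom = "chrS", start = expected$start,
                      end = expected$end, fold = fold)
  med1 <- simulate_reads(c(chrS = chrom_len), background_rate, peaks,
                         seed = seed + 1000L)
  control <- simulate_reads(c(chrS = chrom_len), background_rate,
                            seed = seed + 2000L)
  out <- list(enhancers = enhancers, med1 = med1, control = control,
              expected = expected)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(dir, c("enhancers.bed", "med1.sam", "control.sam",
                              "expected_labels.tsv"))
    write_bed(enhancers, files[1])
    write_sam(med1, files[2], c(chrS = chrom_len))
    write_sam(control, files[3], c(chrS = chrom_len))
    write.table(expected, files[4], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$files <- setNames(files, c("enhancers", "med1", "control", "expected"))
  }
  out
}
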