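# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# transitive-closure stitching via union-find over all pairs
stitch_oracle <- function(regions, max_gap) {
  n <- nrow(regions)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (regions$chrom[i] != regions$chrom[j]) next
      gap <- max(regions$start[i], regions$start[j]) -
        min(regions$end[i], regions$end[j])
      if (gap <= max_gap) {
        parent[find_root(i)] <- find_root(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find_root, 0L)
  unname(split(seq_len(n), roots))
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# cross-entropy by scalar loop
cross_entropy_oracle <- function(h, y, eps = 1e-12) {
  s <- 0
  for (i in seq_along(h)) {
    hi <- min(max(h[i], eps), 1 - eps)
    s <- s - (y[i] * log(hi) + (1 - y[i]) * log(1 - hi))
  }
  s / length(h)
}

# best-hit log2-odds motif score by explicit window/strand loops
motif_oracle <- function(seq, motif) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }
  score_window <- function(win) {
    bases <- strsplit(toupper(win), "")[[1]]
    s <- 0
    for (k in seq_along(bases)) {
      if (bases[k] %in% rownames(motif$mat)) {
        s <- s + log2(motif$mat[bases[k], k] / motif$background[
          match(bases[k], rownames(motif$mat))])
      }
    }
    s
  }
  w <- ncol(motif$mat)
  best <- -Inf
  for (strand_seq in c(seq, revcomp(seq))) {
    for (i in seq_len(nchar(strand_seq) - w + 1)) {
      best <- max(best, score_window(substr(strand_seq, i, i + w - 1)))
    }
  }
  best
}

# elbow cutoff by an explicit scan over the scaled ranked curve
cutoff_oracle <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  if (max(s) == min(s)) return(max(s))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  for (i in seq_len(n - 1)) {
    if ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) > 1) return(s[i])
  }
  max(s)
}

# per-base coverage density oracle: walks every base of the region
density_oracle <- function(rs, region, ext_len = 0) {
  reads <- secnn::extend_reads(rs$reads, ext_len)
  covered <- 0
  for (pos in seq(region$start, region$end - 1)) {
    covered <- covered + sum(reads$chrom == region$chrom &
                               reads$start <= pos & reads$end > pos)
  }
  covered / (region$end - region$start) * 1e6 / rs$total_mapped
}

# random region set used by round-trip and stitching tests
random_regions <- function(n, seed, chrom_pool = c("chr1", "chr2"),
                           max_start = 1e6, max_len = 5000) {
  set.seed(seed)
  start <- sort(sample.int(max_start, n))
  genomic_regions(sample(chrom_pool, n, replace = TRUE), start,
                  start + sample.int(max_len, n, replace = TRUE),
                  sprintf("r%03d", seq_len(n)))
}

# tiny read set helper: reads fully specified, library size explicit
tiny_reads <- function(start, end, strand = "+", chrom = "chr1",
                       total_mapped = length(start)) {
  read_set(data.frame(chrom = rep_len(chrom, length(start)), start = start,
                      end = end, strand = rep_len(strand, length(start)),
                      stringsAsFactors = FALSE),
           total_mapped = total_mapped)
}

# the ranked-signal hockey-stick: 95 background signals in [0, 1] and 5
# planted outliers in [50, 100]
hockey_signals <- function() {
  c(seq(0, 1, length.out = 95), seq(50, 100, length.out = 5))
}
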