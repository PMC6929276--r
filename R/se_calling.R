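# ROSE-style super-enhancer calling: stitch enhancers within 12.5 kb, rank
# stitched entities by total background-normalized Med1 signal, cut at the
# elbow of the ranked-signal curve.

#' Stitch enhancer regions
#'
#' Regions on the same chromosome whose gap (`next start - previous end`) is
#' at most `max_gap` are merged transitively into one stitched entity;
#' overlapping regions (gap <= 0) always merge. Regions without a neighbour
#' within `max_gap` pass through as singleton entities.
#'
#' @param regions region `data.frame` ([genomic_regions()]).
#' @param max_gap maximum stitching gap in bp (default 12500).
#' @return An object of class `stitched_entities`: a `data.frame` with columns
#'   `chrom`, `start`, `end`, `n_constituents`, plus a `constituents`
#'   attribute mapping each entity to the row indices of its input regions.
#'   Entities are ordered by (chrom, start).
#' @export
stitch_regions <- function(regions, max_gap = 12500) {
  stopifnot(max_gap >= 0)
  if (!nrow(regions)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_constituents = integer())
    attr(out, "constituents") <- list()
    class(out) <- c("stitched_entities", "data.frame")
    return(out)
  }
  ord <- order(regions$chrom, regions$start, regions$end)
  r <- regions[ord, , drop = FALSE]
  n <- nrow(r)
  # new entity whenever chromosome changes or the gap to the running end
  # exceeds max_gap; running end is the max end seen in the current entity
  grp <- integer(n)
  grp[1] <- 1L
  cur_end <- r$end[1]
  for (i in seq_len(n)[-1]) {
    if (r$chrom[i] != r$chrom[i - 1] || r$start[i] - cur_end > max_gap) {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- r$end[i]
    } else {
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, r$end[i])
    }
  }
  idx <- split(ord, grp)
  out <- data.frame(
    chrom = vapply(idx, function(k) regions$chrom[k[1]], ""),
    start = vapply(idx, function(k) min(regions$start[k]), 0),
    end = vapply(idx, function(k) max(regions$end[k]), 0),
    n_constituents = lengths(idx),
    row.names = NULL)
  attr(out, "constituents") <- unname(idx)
  class(out) <- c("stitched_entities", "data.frame")
  out
}

#' Total background-normalized signal of stitched entities
#'
#' Density over each entity's span (sample minus control, no flooring) times
#' the span length — the quantity stitched entities are ranked by.
#'
#' @param entities a [stitch_regions()] result (or any region `data.frame`).
#' @param signal_reads [read_set()] of the ranking signal (Med1).
#' @param control_reads optional control [read_set()].
#' @param ext_len fragment-extension length (default 200).
#' @return Numeric vector of total signals.
#' @export
entity_total_signal <- function(entities, signal_reads, control_reads = NULL,
                                ext_len = 200) {
  dens <- region_density(signal_reads, entities, ext_len)
  if (!is.null(control_reads)) {
    dens <- background_normalize(dens,
                                 region_density(control_reads, entities, ext_len))
  }
  dens * (entities$end - entities$start)
}

#' Elbow cutoff on a ranked signal curve
#'
#' Signals are sorted ascending; both the rank axis and the signal axis are
#' min-max scaled to \[0, 1\]. The cutoff is the signal at the left end of the
#' first segment whose discrete slope exceeds 1 (the point where a tangent of
#' slope 1 would touch the hockey-stick curve). If no slope exceeds 1 (e.g.
#' all signals equal) the cutoff is the maximum signal, so nothing lies above
#' it.
#'
#' @param signals numeric vector of entity total signals (length >= 2).
#' @return The cutoff value; entities with `signal > cutoff` are
#'   super-enhancers.
#' @export
find_se_cutoff <- function(signals) {
  if (length(signals) < 2L) stop_usage("need >= 2 entities to place a cutoff")
  s <- sort(signals)
  n <- length(s)
  rng <- s[n] - s[1]
  if (rng == 0) return(s[n])
  y <- (s - s[1]) / rng
  slope <- diff(y) * (n - 1)          # x-step is 1/(n-1) after scaling
  hit <- which(slope > 1)
  if (!length(hit)) return(s[n])
  s[hit[1]]
}

#' Call super-enhancers from enhancer intervals and Med1 reads
#'
#' The full ROSE-style composition: [stitch_regions()] at `max_gap`, rank by
#' [entity_total_signal()], cut with [find_se_cutoff()]. Entities whose total
#' signal exceeds the cutoff are labelled super-enhancers (1); the rest are
#' typical enhancers (0). In training downstream models the 0-labelled
#' stitched entities serve as the negative class — note this is a modelling
#' convention, not a biological definition of "typical enhancer".
#'
#' @param regions enhancer intervals ([genomic_regions()]); must be nonempty.
#' @param med1_reads [read_set()] of Med1 (Mediator) ChIP-seq reads.
#' @param control_reads optional input/control [read_set()].
#' @param max_gap stitching gap (default 12500 bp).
#' @param ext_len fragment-extension length (default 200 bp).
#' @return An object of class `se_calls`: list with `entities` (the stitched
#'   table plus `total_signal`, `label` and `name` columns), `cutoff`, and
#'   `ranked` (entity indices sorted by ascending signal).
#' @export
call_super_enhancers <- function(regions, med1_reads, control_reads = NULL,
                                 max_gap = 12500, ext_len = 200) {
  if (!nrow(regions)) stop_usage("no enhancer regions supplied")
  ent <- stitch_regions(regions, max_gap)
  sig <- entity_total_signal(ent, med1_reads, control_reads, ext_len)
  cutoff <- find_se_cutoff(sig)
  label <- as.integer(sig > cutoff)
  ent$total_signal <- sig
  ent$label <- label
  ent$name <- sprintf("entity_%d_%s", seq_len(nrow(ent)),
                      ifelse(label == 1L, "SE", "TE"))
  structure(list(entities = ent, cutoff = cutoff, ranked = order(sig)),
            class = "se_calls")
}

#' @export
print.se_calls <- function(x, ...) {
  cat("se_calls:", nrow(x$entities), "stitched entities,",
      sum(x$entities$label), "super-enhancers (cutoff",
      format(x$cutoff, digits = 4), ")\n")
  invisible(x)
}
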