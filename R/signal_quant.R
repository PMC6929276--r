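# Normalized read densities (rpm/bp) over genomic regions.

#' Extend reads in their strand direction
#'
#' Standard ChIP-seq fragment extension: each read is extended to length
#' `max(read length, ext_len)` downstream of its 5' end; starts are clipped
#' at 0.
#'
#' @param reads read `data.frame` (`chrom`, `start`, `end`, `strand`).
#' @param ext_len target fragment length in bp (>= 0); 0 leaves reads
#'   unchanged.
#' @return The read `data.frame` with adjusted coordinates.
#' @export
extend_reads <- function(reads, ext_len) {
  stopifnot(ext_len >= 0)
  if (ext_len == 0 || !nrow(reads)) return(reads)
  len <- pmax(reads$end - reads$start, ext_len)
  plus <- reads$strand == "+"
  reads$end[plus] <- reads$start[plus] + len[plus]
  reads$start[!plus] <- pmax(0, reads$end[!plus] - len[!plus])
  reads
}

# per-region sum of overlapped bases of (already extended) reads; linear in
# read multiplicity, so duplicated reads count twice
overlap_bases <- function(reads, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    on <- reads$chrom == regions$chrom[i]
    if (!any(on)) return(0)
    ov <- pmin(reads$end[on], regions$end[i]) -
      pmax(reads$start[on], regions$start[i])
    sum(ov[ov > 0])
  }, 0)
}

#' Read density of a region
#'
#' Density in rpm/bp: total overlapped bases of (strand-extended) reads within
#' the region, divided by region length, scaled per million mapped reads:
#' `(overlap bases / region length) * 1e6 / total_mapped`.
#'
#' @param rs a [read_set()]; `total_mapped` must be positive.
#' @param regions one or more regions ([genomic_regions()]).
#' @param ext_len fragment-extension length (default 200 bp).
#' @return Numeric vector of densities, one per region.
#' @export
region_density <- function(rs, regions, ext_len = 200) {
  stopifnot(inherits(rs, "read_set"))
  if (any(regions$end - regions$start <= 0)) stop_data("zero-length region")
  if (rs$total_mapped <= 0) stop_data("empty library: total_mapped must be > 0")
  reads <- extend_reads(rs$reads, ext_len)
  overlap_bases(reads, regions) / (regions$end - regions$start) *
    (1e6 / rs$total_mapped)
}

#' Background-normalize a density
#'
#' Subtracts the matched control (input) density; no flooring, so values may
#' go negative. With `control = NULL` the sample density is returned
#' unchanged.
#'
#' @param sample_density,control_density densities computed over the same
#'   regions with the same `ext_len`.
#' @return `sample_density - control_density`.
#' @export
background_normalize <- function(sample_density, control_density = NULL) {
  if (is.null(control_density)) return(sample_density)
  sample_density - control_density
}

#' Density matrix of regions x signal tracks
#'
#' Entry (i, j) is the background-normalized density of track j over region i.
#'
#' @param regions region `data.frame`.
#' @param tracks named list of [read_set()] objects; names become columns.
#' @param ext_len fragment-extension length (default 200).
#' @param controls optional named list of control [read_set()]s; a track with
#'   a control entry of the same name is background-subtracted.
#' @return Numeric matrix, `nrow(regions)` x `length(tracks)`.
#' @export
density_matrix <- function(regions, tracks, ext_len = 200, controls = NULL) {
  if (is.null(names(tracks)) || anyDuplicated(names(tracks))) {
    stop_data("tracks must have unique names")
  }
  ctrl_dens <- lapply(names(tracks), function(nm) {
    if (!is.null(controls) && nm %in% names(controls)) {
      region_density(controls[[nm]], regions, ext_len)
    } else NULL
  })
  out <- vapply(seq_along(tracks), function(j) {
    background_normalize(region_density(tracks[[j]], regions, ext_len),
                         ctrl_dens[[j]])
  }, numeric(nrow(regions)))
  out <- matrix(out, nrow = nrow(regions),
                dimnames = list(NULL, names(tracks)))
  out
}
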