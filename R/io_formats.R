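# Readers/writers for the plain-text formats the pipeline touches.
# All intervals are 0-based half-open internally (BED convention).

#' Genomic region constructor
#'
#' A region set is a plain `data.frame` with columns `chrom` (character),
#' `start` and `end` (0-based half-open integers) and optional `name`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` per row.
#' @param name optional labels (recycled); `NA` allowed.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
#' @examples
#' genomic_regions("chr1", 100, 200, "e1")
genomic_regions <- function(chrom, start, end, name = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop_data("region start must be >= 0")
  if (any(end <= start)) stop_data("region end must be > start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = rep_len(as.character(name), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Read a BED file of regions
#'
#' Parses BED3/BED4+ lines (tab-separated, 0-based half-open). `track` and
#' `browser` lines and blank lines are skipped. Columns past the fourth are
#' ignored except a numeric fifth column, returned as `score`.
#'
#' @param path path to a BED file.
#' @return Region `data.frame` in file order (see [genomic_regions()]); zero
#'   rows for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_data("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(genomic_regions(character(), numeric(), numeric())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_data("BED line ", lineno[which(nf < 3L)[1]], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop_data("BED line ", lineno[bad[1]], ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop_data("BED line ", lineno[bad[1]], ": end <= start or negative start")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  out <- genomic_regions(chrom, start, end, name)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), NA)))
  if (any(!is.na(score))) out$score <- score
  out
}

#' Write regions as BED
#'
#' @param regions region `data.frame`; an optional `score` column becomes the
#'   fifth BED field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name else NA_character_
  name <- ifelse(is.na(name), ".", name)
  cols <- list(regions$chrom, format_num(regions$start), format_num(regions$end),
               name)
  if ("score" %in% names(regions)) cols <- c(cols, list(format_num(regions$score)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# fixed decimal formatting: integers print without decimals, reals with 6
# significant digits (reproducible text round-trips)
format_num <- function(x) {
  ifelse(is.finite(x) & x == floor(x), sprintf("%d", as.integer(x)),
         sprintf("%.6g", x))
}

#' Read set constructor
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (`+`/`-`).
#' @param total_mapped library size used for per-million normalization;
#'   defaults to `nrow(reads)`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads, total_mapped = nrow(reads)) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads)) {
    if (any(reads$end <= reads$start)) stop_data("read end must be > start")
    if (!all(reads$strand %in% c("+", "-"))) {
      stop_data("read strand must be '+' or '-'")
    }
  }
  structure(list(reads = reads, total_mapped = as.numeric(total_mapped)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x$reads), "reads,", x$total_mapped, "mapped in library\n")
  invisible(x)
}

#' Read aligned reads from SAM or a simple interval TSV
#'
#' SAM input uses only the 11 mandatory columns: unmapped records (FLAG bit
#' 0x4) are dropped, strand comes from FLAG bit 0x10, and the read span is
#' `POS-1 .. POS-1+length(SEQ)` (CIGAR is ignored). The TSV dialect has four
#' columns `chrom start end strand`, 0-based half-open, no header.
#'
#' @param path input path. Format is auto-detected: lines starting with `@`
#'   or 11+ tab fields with a numeric FLAG column mean SAM.
#' @param min_mapq drop SAM records with MAPQ below this (default 0).
#' @return A [read_set()]; `total_mapped` is the number of retained records.
#' @export
read_alignments <- function(path, min_mapq = 0) {
  if (!file.exists(path)) stop_data("alignment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- grepl("^@", lines)
  body <- lines[!header]
  empty <- read_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), strand = character(),
                               stringsAsFactors = FALSE), total_mapped = 0)
  if (!length(body)) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  is_sam <- any(header) || all(nf >= 11L)
  if (is_sam) {
    if (any(nf < 11L)) {
      stop_data("SAM record ", which(nf < 11L)[1],
                ": fewer than 11 mandatory columns")
    }
    flag <- as.integer(vapply(fields, `[`, "", 2L))
    if (anyNA(flag)) stop_data("SAM: non-integer FLAG field")
    mapq <- as.integer(vapply(fields, `[`, "", 5L))
    pos <- as.numeric(vapply(fields, `[`, "", 4L))
    seq <- vapply(fields, `[`, "", 10L)
    keep <- bitwAnd(flag, 4L) == 0L & mapq >= min_mapq
    reads <- data.frame(
      chrom = vapply(fields, `[`, "", 3L)[keep],
      start = pos[keep] - 1,
      end = pos[keep] - 1 + nchar(seq[keep]),
      strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
      stringsAsFactors = FALSE)
    return(read_set(reads, total_mapped = sum(keep)))
  }
  if (any(nf < 4L)) stop_data("read TSV line ", which(nf < 4L)[1],
                              ": need chrom, start, end, strand")
  reads <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.numeric(vapply(fields, `[`, "", 2L)),
    end = as.numeric(vapply(fields, `[`, "", 3L)),
    strand = vapply(fields, `[`, "", 4L),
    stringsAsFactors = FALSE)
  if (anyNA(reads$start) || anyNA(reads$end)) {
    stop_data("read TSV: non-numeric coordinates")
  }
  read_set(reads, total_mapped = nrow(reads))
}

#' Write a read set as minimal SAM
#'
#' Emits `@HD`/`@SQ` header lines and one 11-column record per read, with the
#' SEQ field a run of `N` of the read's length (sequence content is not
#' tracked). Round-trips through [read_alignments()].
#'
#' @param rs a [read_set()].
#' @param path output path.
#' @param chrom_lengths named vector of reference lengths for `@SQ` lines;
#'   inferred from the reads when missing.
#' @return `path`, invisibly.
#' @export
write_sam <- function(rs, path, chrom_lengths = NULL) {
  reads <- rs$reads
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(reads$end, reads$chrom), max, 0)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  rec <- sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                 seq_len(nrow(reads)),
                 ifelse(reads$strand == "-", 16L, 0L),
                 reads$chrom,
                 as.integer(reads$start + 1),
                 as.integer(reads$end - reads$start),
                 strrep("N", reads$end - reads$start))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character vectors so soft-masking (lowercase) is preserved for
#' [sequence_composition()].
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_data("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Position weight matrix constructor
#'
#' Columns are per-position base probabilities (rows A, C, G, T); each column
#' must sum to 1 within 1e-6.
#'
#' @param id motif identifier.
#' @param mat 4 x width numeric matrix of probabilities.
#' @param background length-4 background probabilities (default uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L || ncol(mat) < 1L) stop_data("PWM must be 4 x width >= 1")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop_data("PWM columns must sum to 1 (motif ", id, ")")
  }
  structure(list(id = id, mat = mat, background = background), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", ncol(x$mat), "\n")
  invisible(x)
}

#' Read JASPAR-style motif matrices
#'
#' Each motif is a `>id` line followed by four base rows (A, C, G, T) of
#' counts or frequencies, optionally in the `A [ 1 2 3 ]` JASPAR layout.
#' Counts are regularized with a pseudocount per cell and normalized to
#' column probabilities.
#'
#' @param path motif text file.
#' @param pseudocount added to every cell before normalization (default 0.01).
#' @return List of [pwm()] objects.
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop_data("PWM file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_data("no '>' motif header in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- sub("\\s.*$", "", id)
    rows <- lines[(starts[i] + 1L):ends[i]]
    if (length(rows) != 4L) {
      stop_data("motif ", id, ": expected 4 base rows, got ", length(rows))
    }
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", " ", r)
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (anyNA(v)) stop_data("motif ", id, ": non-numeric matrix entry")
      v
    })
    if (length(unique(lengths(vals))) != 1L) {
      stop_data("motif ", id, ": rows of unequal width")
    }
    counts <- do.call(rbind, vals) + pseudocount
    pwm(id, sweep(counts, 2, colSums(counts), "/"))
  })
}

#' Read a per-base score track (fixedStep wiggle or bedGraph)
#'
#' Supports the fixedStep wiggle dialect (`fixedStep chrom=... start=...
#' step=...`, 1-based starts per the wiggle convention, optional `span`) and
#' 4-column bedGraph (`chrom start end value`, 0-based half-open). Bases not
#' covered by the track score 0 downstream.
#'
#' @param path track file.
#' @return An object of class `score_track`: per-chromosome interval tables
#'   (`start`, `end`, `value`), 0-based half-open, sorted by start.
#' @export
read_score_track <- function(path) {
  if (!file.exists(path)) stop_data("score track not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b)", lines)]
  chroms <- list()
  if (any(grepl("^fixedStep", lines))) {
    blocks <- grep("^fixedStep", lines)
    block_end <- c(blocks[-1] - 1L, length(lines))
    for (i in seq_along(blocks)) {
      hdr <- lines[blocks[i]]
      get <- function(key, default = NA) {
        m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
        if (!length(m)) return(default)
        sub(paste0(key, "="), "", m)
      }
      chrom <- get("chrom")
      start1 <- as.numeric(get("start"))
      step <- as.numeric(get("step", "1"))
      span <- as.numeric(get("span", "1"))
      if (is.na(chrom) || is.na(start1)) {
        stop_data("fixedStep header missing chrom/start: ", hdr)
      }
      vals <- as.numeric(lines[(blocks[i] + 1L):block_end[i]])
      if (anyNA(vals)) stop_data("non-numeric wiggle value under: ", hdr)
      s <- (start1 - 1) + step * (seq_along(vals) - 1)
      df <- data.frame(start = s, end = s + span, value = vals)
      chroms[[chrom]] <- rbind(chroms[[chrom]], df)
    }
  } else {
    fields <- strsplit(lines, "\\s+")
    if (any(lengths(fields) < 4L)) {
      stop_data("bedGraph line ", which(lengths(fields) < 4L)[1],
                ": need chrom start end value")
    }
    df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                     start = as.numeric(vapply(fields, `[`, "", 2L)),
                     end = as.numeric(vapply(fields, `[`, "", 3L)),
                     value = as.numeric(vapply(fields, `[`, "", 4L)))
    if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
      stop_data("bedGraph: non-numeric field")
    }
    chroms <- lapply(split(df[c("start", "end", "value")], df$chrom),
                     function(d) d)
  }
  chroms <- lapply(chroms, function(d) d[order(d$start), , drop = FALSE])
  structure(chroms, class = "score_track")
}

#' Write a feature matrix as TSV
#'
#' Header row holds the 36 feature names plus `sample_id` and `label`;
#' numeric values are printed with 6 significant digits.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- apply(fm$features, 2, sprintf, fmt = "%.6g")
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(fm$features))
  tab <- cbind(sample_id = fm$sample_ids, vals, label = fm$labels)
  lines <- c(paste(colnames(tab), collapse = "\t"),
             apply(tab, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-table TSV
#'
#' @param path TSV written by [write_feature_table()] (or compatible: a header
#'   of unique column names including `label`; an optional `sample_id`
#'   column).
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_data("feature table not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(tab))) {
    stop_data("duplicate column names in ", path, ": ",
              paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "))
  }
  if (!"label" %in% names(tab)) stop_data("feature table lacks a 'label' column")
  ids <- if ("sample_id" %in% names(tab)) as.character(tab$sample_id) else
    as.character(seq_len(nrow(tab)))
  labels <- tab$label
  feats <- tab[setdiff(names(tab), c("sample_id", "label"))]
  feature_matrix(as.matrix(feats), labels, sample_ids = ids, validate_names = FALSE)
}
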