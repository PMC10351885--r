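#' Genomic intervals (BED convention)
#'
#' A light data.table container for genomic intervals in the BED convention:
#' 0-based inclusive `start`, 0-based exclusive `end`. Site tables, by
#' contrast, use 1-based point positions; [sites_to_intervals()] is the
#' explicit converter.
#'
#' @param contig,start,end,strand,name Vectors (recycled) describing the
#'   intervals; `strand` in `{+,-,.}`, `name` a free-text label.
#' @return A data.table of class `genomic_intervals` with columns `contig`,
#'   `start`, `end`, `name`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 201)
#' @export
genomic_intervals <- function(contig = character(), start = integer(),
                              end = integer(), strand = ".", name = ".") {
  iv <- data.table(contig = as.character(contig),
                   start = as.integer(start),
                   end = as.integer(end),
                   name = as.character(name),
                   strand = as.character(strand))
  if (nrow(iv)) {
    if (anyNA(iv$start) || anyNA(iv$end)) validation_stop("NA interval bounds")
    if (any(iv$start < 0L)) validation_stop("interval start must be >= 0")
    if (any(iv$end <= iv$start)) validation_stop("interval end must exceed start")
    if (!all(iv$strand %in% c("+", "-", "."))) {
      validation_stop("strand must be one of +, -, .")
    }
  }
  setattr(iv, "class", c("genomic_intervals", class(iv)))
  iv[]
}

#' @noRd
intervals_to_granges <- function(iv) {
  GenomicRanges::GRanges(iv$contig,
                         IRanges::IRanges(start = iv$start + 1L, end = iv$end),
                         strand = ifelse(iv$strand == ".", "*", iv$strand))
}

#' Expand intervals by a fixed flank ("slop")
#'
#' Each interval `[start, end)` becomes
#' `[max(0, start - flank), min(L, end + flank))` where `L` is the contig
#' length when `contig_lengths` is supplied (otherwise no right clamp).
#' Order and labels are preserved.
#'
#' @param iv A [genomic_intervals()].
#' @param flank Non-negative flank, bp.
#' @param contig_lengths Optional named vector of contig lengths; intervals on
#'   contigs absent from it are an error.
#' @return The expanded [genomic_intervals()].
#' @export
slop <- function(iv, flank, contig_lengths = NULL) {
  if (flank < 0) validation_stop("flank must be >= 0")
  out <- copy(iv)
  out[, start := pmax(0L, start - as.integer(flank))]
  out[, end := end + as.integer(flank)]
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(out$contig), names(contig_lengths))
    if (length(unknown)) {
      validation_stop("contig not in contig_lengths: ",
                      paste(unknown, collapse = ", "))
    }
    out[, end := pmin(end, as.integer(contig_lengths[contig])), by = contig]
  }
  out[]
}

#' Intersect two interval sets
#'
#' Reports every pair (a in A, b in B) on the same contig whose overlap,
#' `min(endA, endB) - max(startA, startB)`, is at least `min_overlap` bp, and
#' partitions A into "common" (>= 1 reported pair) and "unique" intervals.
#' The published overlap analyses used the intersection tool's default of
#' >= 1 bp; pass `min_overlap = 2` for a literal "> 1 bp" reading.
#'
#' @param a,b [genomic_intervals()].
#' @param min_overlap Minimum overlap in bp (>= 1).
#' @return A list with `pairs` (data.table `a_idx`, `b_idx`, `overlap_bp`),
#'   `common` and `unique` (subsets of `a`), and `n_common`/`n_unique`.
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  if (min_overlap < 1) validation_stop("min_overlap must be >= 1")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    pairs <- data.table(a_idx = integer(), b_idx = integer(),
                        overlap_bp = integer())
  } else {
    gra <- intervals_to_granges(a)
    grb <- intervals_to_granges(b)
    hits <- GenomicRanges::findOverlaps(gra, grb,
                                        minoverlap = as.integer(min_overlap),
                                        ignore.strand = TRUE)
    ai <- S4Vectors::queryHits(hits)
    bi <- S4Vectors::subjectHits(hits)
    ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
    pairs <- data.table(a_idx = ai, b_idx = bi, overlap_bp = as.integer(ov))
  }
  common_idx <- sort(unique(pairs$a_idx))
  list(pairs = pairs,
       common = a[common_idx],
       unique = a[setdiff(seq_len(nrow(a)), common_idx)],
       n_common = length(common_idx),
       n_unique = nrow(a) - length(common_idx))
}

#' Distance to the nearest interval
#'
#' Gap distance (number of bases strictly between query and subject) to the
#' nearest subject interval on the same contig: 0 when they overlap (or are
#' book-ended), `Inf` when the contig has no subject interval.
#'
#' @param query A [genomic_intervals()] of query intervals (make points as
#'   width-1 intervals).
#' @param subjects A [genomic_intervals()] of subjects.
#' @return Numeric vector, one distance per query row.
#' @export
nearest_distance <- function(query, subjects) {
  n <- nrow(query)
  if (n == 0L) return(numeric(0))
  out <- rep(Inf, n)
  if (nrow(subjects) == 0L) return(out)
  # suppressed: GRanges warns when query/subject seqlevel sets differ, which
  # is an expected situation here (contigs with no subject get Inf)
  suppressWarnings({
    grq <- intervals_to_granges(query)
    grs <- intervals_to_granges(subjects)
    GenomicRanges::strand(grq) <- "*"
    GenomicRanges::strand(grs) <- "*"
    hits <- GenomicRanges::distanceToNearest(grq, grs, ignore.strand = TRUE)
    out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  })
  out
}

#' Read a BED3/BED6 file
#'
#' @param path BED file (tab-separated, no header; 3 or 6 columns).
#' @return A [genomic_intervals()]; BED `score` is kept as a `score` column
#'   when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) validation_stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0) return(genomic_intervals())
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 3L) validation_stop(path, ": BED needs >= 3 columns")
  iv <- genomic_intervals(contig = dt[[1]], start = dt[[2]], end = dt[[3]],
                          name = if (ncol(dt) >= 4L) dt[[4]] else ".",
                          strand = if (ncol(dt) >= 6L) dt[[6]] else ".")
  if (ncol(dt) >= 5L) iv[, score := as.numeric(dt[[5]])]
  iv[]
}

#' Write intervals as BED6
#'
#' @param iv A [genomic_intervals()]; a `score` column is used when present
#'   (0 otherwise).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  score <- if ("score" %in% names(iv)) iv$score else rep(0, nrow(iv))
  out <- data.table(iv$contig, iv$start, iv$end, iv$name, score, iv$strand)
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert 1-based editing sites to BED intervals
#'
#' Each site becomes the half-open interval `[pos - 1, pos)` named
#' `ref>alt|sample` with BED score `round(100 * edit fraction)`.
#'
#' @param sites A site table (see [call_candidate_sites()]).
#' @return A [genomic_intervals()] with a `score` column.
#' @export
sites_to_intervals <- function(sites) {
  iv <- genomic_intervals(contig = sites$contig,
                          start = sites$pos - 1L,
                          end = sites$pos,
                          name = paste0(sites$ref, ">", sites$alt, "|",
                                        if ("sample" %in% names(sites))
                                          sites$sample else ""),
                          strand = sites$strand)
  iv[, score := round(100 * sites$frac)]
  iv[]
}
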