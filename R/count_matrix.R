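#' Per-position nucleotide count matrix
#'
#' The central data structure of the pipeline: for every covered genomic
#' position, the number of reads supporting each of A, C, G and T on the
#' reference forward strand. Strand resolution happens later, at site calling.
#'
#' @param x A data.frame/data.table with columns `contig`, `pos` (1-based),
#'   `A`, `C`, `G`, `T`.
#' @param mapped_reads Total uniquely mapped reads of the library (used for
#'   per-million normalisation and the sequencing-depth QC warning); `NA` when
#'   unknown.
#' @param sample_label Free-text sample name.
#' @return A `count_matrix`: a data.table sorted by (`contig`, `pos`) with an
#'   added `coverage` column (`A+C+G+T`) and attributes `mapped_reads` and
#'   `sample_label`.
#' @examples
#' count_matrix(data.frame(contig = "chr1", pos = 5L,
#'                         A = 10L, C = 0L, G = 2L, T = 0L))
#' @export
count_matrix <- function(x, mapped_reads = NA_real_, sample_label = "") {
  req <- c("contig", "pos", "A", "C", "G", "T")
  x <- as.data.table(x)
  if (!all(req %in% names(x))) {
    validation_stop("count matrix needs columns: ", paste(req, collapse = ", "))
  }
  x <- x[, req, with = FALSE]
  x[, contig := as.character(contig)]
  for (b in c("pos", "A", "C", "G", "T")) {
    v <- x[[b]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      validation_stop("column ", b, " must be integer-valued and non-missing")
    }
    set(x, j = b, value = as.integer(v))
  }
  if (nrow(x) && any(x$pos < 1L)) validation_stop("positions must be >= 1")
  if (nrow(x) && any(x$A < 0L | x$C < 0L | x$G < 0L | x$T < 0L)) {
    validation_stop("base counts must be non-negative")
  }
  setorder(x, contig, pos)
  if (nrow(x) && anyDuplicated(x, by = c("contig", "pos"))) {
    validation_stop("duplicate (contig, position) rows in count matrix")
  }
  x[, coverage := A + C + G + T]
  setattr(x, "mapped_reads", as.numeric(mapped_reads))
  setattr(x, "sample_label", as.character(sample_label))
  setattr(x, "class", c("count_matrix", class(x)))
  x[]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d positions on %d contig(s); mapped_reads=%s\n",
              attr(x, "sample_label"), nrow(x),
              length(unique(x$contig)), format(attr(x, "mapped_reads"))))
  NextMethod()
}

#' Library size of a count matrix
#' @param x A [count_matrix()].
#' @return Numeric scalar (possibly `NA`).
#' @export
mapped_reads <- function(x) attr(x, "mapped_reads")

#' Read a count matrix from TSV
#'
#' Expects a tab-separated file with header
#' `contig  position  A  C  G  T` and 1-based positions. Validation is strict:
#' malformed rows, non-integer or negative counts, positions < 1 and duplicate
#' (contig, position) pairs all fail with the offending line number.
#'
#' @param path TSV file path.
#' @param mapped_reads,sample_label Passed to [count_matrix()]; the TSV itself
#'   carries neither.
#' @return A [count_matrix()], rows sorted by (contig, position).
#' @export
read_count_matrix <- function(path, mapped_reads = NA_real_, sample_label = "") {
  if (!file.exists(path)) validation_stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) validation_stop(path, ": empty file (header required)")
  bad <- which(nf != 6L)
  if (length(bad)) {
    validation_stop(path, ": malformed row (expected 6 tab-separated fields) at line ",
                    bad[1])
  }
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = 1), data.table = TRUE)
  if (!identical(names(dt), c("contig", "position", "A", "C", "G", "T"))) {
    validation_stop(path, ": header must be contig, position, A, C, G, T")
  }
  # line number of data row i is i + 1 (header is line 1)
  for (b in c("position", "A", "C", "G", "T")) {
    v <- suppressWarnings(as.numeric(dt[[b]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      validation_stop(path, ": non-integer value in column ", b,
                      " at line ", bad[1] + 1L)
    }
    if (b != "position") {
      neg <- which(v < 0)
      if (length(neg)) {
        validation_stop(path, ": negative count in column ", b,
                        " at line ", neg[1] + 1L)
      }
    } else {
      neg <- which(v < 1)
      if (length(neg)) {
        validation_stop(path, ": position < 1 at line ", neg[1] + 1L)
      }
    }
    set(dt, j = b, value = as.integer(v))
  }
  dup <- which(duplicated(dt, by = c("contig", "position")))
  if (length(dup)) {
    validation_stop(path, ": duplicate (contig, position) at line ", dup[1] + 1L)
  }
  setnames(dt, "position", "pos")
  count_matrix(dt, mapped_reads = mapped_reads, sample_label = sample_label)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]: `read_count_matrix(write_count_matrix(x))`
#' reproduces `x` field-by-field (library size and label are not serialised).
#'
#' @param x A [count_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  out <- data.table(contig = x$contig, position = x$pos,
                    A = x$A, C = x$C, G = x$G, T = x$T)
  setorder(out, contig, position)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pile up per-position base counts from an alignment file
#'
#' Tallies aligned (match/mismatch) read bases at every covered reference
#' position. Insertions, deletions, clipped bases and reference skips (spliced
#' reads) contribute nothing; read `N` bases are ignored. Duplicate reads are
#' counted as-is. Base- and mapping-quality filters default to off so the
#' matrix reflects the raw tally.
#'
#' @param alignments Path to a coordinate-sorted BAM or SAM file. The header
#'   must declare `SO:coordinate`; anything else is an explicit failure.
#' @param reference Genome as a FASTA path or a [Biostrings::DNAStringSet].
#'   Every contig carrying mapped reads must be present.
#' @param regions Optional [genomic_intervals()] (0-based half-open) to
#'   restrict the pileup; overlapping regions are reduced first so no position
#'   is double counted.
#' @param min_base_quality,min_mapq Optional quality filters (default 0 = off).
#' @param sample_label Sample name recorded on the result.
#' @return A [count_matrix()] with `mapped_reads` set to the number of
#'   primary mapped records in the file.
#' @export
pileup_counts <- function(alignments, reference, regions = NULL,
                          min_base_quality = 0L, min_mapq = 0L,
                          sample_label = basename(alignments)) {
  if (!file.exists(alignments)) validation_stop("no such file: ", alignments)
  is_sam <- grepl("\\.sam$", alignments, ignore.case = TRUE)
  if (is_sam) {
    hd <- readLines(alignments, n = 1L)
    if (!grepl("^@HD\t.*SO:coordinate", hd)) {
      validation_stop(alignments, ": alignments are not coordinate-sorted ",
                      "(header must declare SO:coordinate)")
    }
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(alignments, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    hd <- Rsamtools::scanBamHeader(alignments)[[1]]$text
    so <- unlist(hd[names(hd) == "@HD"])
    if (!any(grepl("^SO:coordinate$", so))) {
      validation_stop(alignments, ": alignments are not coordinate-sorted ",
                      "(header must declare SO:coordinate)")
    }
    bam <- alignments
    if (!file.exists(paste0(bam, ".bai"))) {
      tmp <- file.path(tempdir(), basename(bam))
      file.copy(bam, tmp, overwrite = TRUE)
      Rsamtools::indexBam(tmp)
      bam <- tmp
    }
  }

  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  stats <- Rsamtools::idxstatsBam(bam)
  used <- as.character(stats$seqnames[stats$mapped > 0])
  missing <- setdiff(used, names(reference))
  if (length(missing)) {
    validation_stop("contig absent from reference: ",
                    paste(missing, collapse = ", "))
  }

  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  if (is.null(regions)) {
    sbp <- Rsamtools::ScanBamParam(flag = flag)
  } else {
    gr <- GenomicRanges::reduce(intervals_to_granges(regions))
    sbp <- Rsamtools::ScanBamParam(flag = flag, which = gr)
  }
  pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                               min_base_quality = as.integer(min_base_quality),
                               min_mapq = as.integer(min_mapq),
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  p <- as.data.table(p)[nucleotide %in% c("A", "C", "G", "T")]
  n_mapped <- Rsamtools::countBam(bam, param = Rsamtools::ScanBamParam(flag = flag))$records
  if (nrow(p) == 0L) {
    return(count_matrix(data.table(contig = character(), pos = integer(),
                                   A = integer(), C = integer(),
                                   G = integer(), T = integer()),
                        mapped_reads = n_mapped, sample_label = sample_label))
  }
  wide <- dcast(p, seqnames + pos ~ nucleotide, value.var = "count",
                fun.aggregate = sum, fill = 0L)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(wide)) wide[, (b) := 0L]
  }
  setnames(wide, "seqnames", "contig")
  wide[, contig := as.character(contig)]
  count_matrix(wide[, .(contig, pos, A, C, G, T)],
               mapped_reads = n_mapped, sample_label = sample_label)
}
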