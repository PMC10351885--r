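#' Transcript models
#'
#' Exon/CDS structure for a set of transcripts, enabling 5'UTR/CDS/3'UTR
#' assignment, transcript-coordinate arithmetic and 3'-directed shifts.
#' Coordinates are genomic, 1-based inclusive (GTF convention).
#'
#' @param exons data.table/data.frame with columns `transcript_id`,
#'   `gene_id`, `contig`, `strand` (`+`/`-`), `start`, `end` (1-based,
#'   inclusive). Exons of one transcript must be disjoint.
#' @param cds Optional table with columns `transcript_id`, `start`, `end`
#'   giving CDS segments; a transcript absent from it is non-coding.
#' @return An object of class `transcript_models`: a list with
#'   * `exons`: validated exon table, sorted by transcript and start;
#'   * `tx`: one row per transcript with `cds_start`/`cds_end` (genomic CDS
#'     bounds, `NA` for non-coding) and `tx_len` (exonic length, bp).
#' @export
transcript_models <- function(exons, cds = NULL) {
  exons <- as.data.table(exons)
  req <- c("transcript_id", "gene_id", "contig", "strand", "start", "end")
  if (!all(req %in% names(exons))) {
    validation_stop("exon table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(exons) == 0L) validation_stop("empty annotation")
  exons <- exons[, req, with = FALSE]
  exons[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(exons$end < exons$start)) validation_stop("exon end < start")
  if (!all(exons$strand %in% c("+", "-"))) {
    validation_stop("exon strand must be + or -")
  }
  setorder(exons, transcript_id, start)
  overl <- exons[, any(start[-1] <= head(end, -1)), by = transcript_id]
  if (any(overl$V1)) {
    validation_stop("overlapping exons in transcript ",
                    overl$transcript_id[which(overl$V1)[1]])
  }
  tx <- exons[, .(gene_id = gene_id[1], contig = contig[1], strand = strand[1],
                  tx_start = min(start), tx_end = max(end),
                  tx_len = sum(end - start + 1L)), by = transcript_id]
  if (!is.null(cds) && nrow(as.data.table(cds))) {
    cds <- as.data.table(cds)
    cdsb <- cds[, .(cds_start = as.integer(min(start)),
                    cds_end = as.integer(max(end))), by = transcript_id]
    tx <- merge(tx, cdsb, by = "transcript_id", all.x = TRUE)
    bad <- tx[!is.na(cds_start) & (cds_start < tx_start | cds_end > tx_end)]
    if (nrow(bad)) {
      validation_stop("CDS outside exon span in transcript ",
                      bad$transcript_id[1])
    }
  } else {
    tx[, `:=`(cds_start = NA_integer_, cds_end = NA_integer_)]
  }
  setorder(tx, transcript_id)
  structure(list(exons = exons[], tx = tx[]), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts (%d coding), %d exons\n",
              nrow(x$tx), sum(!is.na(x$tx$cds_start)), nrow(x$exons)))
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Uses `exon` and `CDS` features; `transcript_id` and `gene_id` attributes
#' are required on exons.
#'
#' @param path GTF file.
#' @return A [transcript_models()] object.
#' @export
read_transcript_models <- function(path) {
  if (!file.exists(path)) validation_stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  typ <- as.character(gr$type)
  ex <- gr[typ == "exon"]
  if (length(ex) == 0L) validation_stop(path, ": no exon features")
  exons <- data.table(transcript_id = as.character(ex$transcript_id),
                      gene_id = as.character(ex$gene_id),
                      contig = as.character(GenomicRanges::seqnames(ex)),
                      strand = as.character(GenomicRanges::strand(ex)),
                      start = GenomicRanges::start(ex),
                      end = GenomicRanges::end(ex))
  cd <- gr[typ == "CDS"]
  cds <- if (length(cd)) {
    data.table(transcript_id = as.character(cd$transcript_id),
               start = GenomicRanges::start(cd),
               end = GenomicRanges::end(cd))
  } else NULL
  transcript_models(exons, cds)
}

#' @noRd
# One row per (query position, containing transcript), with the feature of
# the position in that transcript (NA feature for non-coding transcripts).
position_transcripts <- function(models, contig, pos) {
  ex <- models$exons
  gr_ex <- GenomicRanges::GRanges(ex$contig, IRanges::IRanges(ex$start, ex$end))
  gr_q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(gr_q, gr_ex, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) {
    return(data.table(q = integer(), transcript_id = character(),
                      gene_id = character(), strand = character(),
                      feature = character()))
  }
  dt <- data.table(q = qi, transcript_id = ex$transcript_id[ei],
                   gene_id = ex$gene_id[ei], pos = pos[qi])
  dt <- unique(dt, by = c("q", "transcript_id"))
  dt <- merge(dt, models$tx[, .(transcript_id, strand, cds_start, cds_end)],
              by = "transcript_id", sort = FALSE)
  dt[, feature := fifelse(is.na(cds_start), NA_character_,
                   fifelse(strand == "+",
                     fifelse(pos < cds_start, "5UTR",
                             fifelse(pos > cds_end, "3UTR", "CDS")),
                     fifelse(pos > cds_end, "5UTR",
                             fifelse(pos < cds_start, "3UTR", "CDS"))))]
  dt[, .(q, transcript_id, gene_id, strand, feature)]
}

#' @noRd
# Majority-vote feature per position across containing coding transcripts;
# ties broken 3UTR > 5UTR > CDS; NA when no coding transcript contains it.
assign_feature <- function(models, contig, pos) {
  pt <- position_transcripts(models, contig, pos)
  out <- rep(NA_character_, length(pos))
  pt <- pt[!is.na(feature)]
  if (nrow(pt) == 0L) return(out)
  prio <- c("3UTR" = 1L, "5UTR" = 2L, "CDS" = 3L)
  votes <- pt[, .N, by = .(q, feature)]
  votes[, p := prio[feature]]
  setorder(votes, q, -N, p)
  top <- votes[, .SD[1], by = q]
  out[top$q] <- top$feature
  out
}

#' @noRd
# Transcript-coordinate (1-based, 5' -> 3') of a genomic position within one
# transcript; exons assumed validated.
genome_to_tx <- function(ex_start, ex_end, strand, pos) {
  w <- ex_end - ex_start + 1L
  if (strand == "+") {
    i <- which(pos >= ex_start & pos <= ex_end)
    sum(w[seq_len(i - 1L)]) + (pos - ex_start[i] + 1L)
  } else {
    # exons sorted by genomic start; 5'->3' order is reversed on minus strand
    n <- length(w)
    i <- which(pos >= ex_start & pos <= ex_end)
    after <- if (i < n) sum(w[(i + 1L):n]) else 0L
    after + (ex_end[i] - pos + 1L)
  }
}

#' @noRd
tx_to_genome <- function(ex_start, ex_end, strand, t) {
  w <- ex_end - ex_start + 1L
  if (strand == "+") {
    cum <- cumsum(w)
    i <- which(t <= cum)[1]
    off <- t - c(0L, cum)[i]
    ex_start[i] + off - 1L
  } else {
    wrev <- rev(w)
    cum <- cumsum(wrev)
    i <- which(t <= cum)[1]
    off <- t - c(0L, cum)[i]
    n <- length(w)
    ex_end[n - i + 1L] - off + 1L
  }
}
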