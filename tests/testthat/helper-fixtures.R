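suppressPackageStartupMessages({
  library(data.table)
})

# ---- count matrices --------------------------------------------------------

make_cm <- function(contig, pos, A = 0L, C = 0L, G = 0L, T = 0L,
                    mapped_reads = NA_real_, sample_label = "test") {
  n <- max(length(contig), length(pos))
  count_matrix(data.table(contig = rep_len(contig, n), pos = rep_len(pos, n),
                          A = rep_len(A, n), C = rep_len(C, n),
                          G = rep_len(G, n), T = rep_len(T, n)),
               mapped_reads = mapped_reads, sample_label = sample_label)
}

# Random matrix over `n` positions: mostly clean piles of a random base with
# occasional mixed piles, so every calling branch gets exercised.
random_cm <- function(n, seed, contigs = c("chr1", "chr2"),
                      max_cov = 60L, label = "random") {
  set.seed(seed)
  ctg <- sample(contigs, n, replace = TRUE)
  pos <- integer(n)
  for (cc in unique(ctg)) {
    idx <- which(ctg == cc)
    pos[idx] <- sample(seq_len(n * 10L), length(idx))
  }
  cov <- sample(0:max_cov, n, replace = TRUE)
  major <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt_n <- pmin(cov, rbinom(n, cov, 0.08))
  cnt <- matrix(0L, nrow = n, ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  alt_base <- vapply(major, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  cnt[cbind(seq_len(n), match(major, colnames(cnt)))] <- cov - alt_n
  cnt[cbind(seq_len(n), match(alt_base, colnames(cnt)))] <-
    cnt[cbind(seq_len(n), match(alt_base, colnames(cnt)))] + alt_n
  dt <- data.table(contig = ctg, pos = pos, A = cnt[, "A"], C = cnt[, "C"],
                   G = cnt[, "G"], T = cnt[, "T"])
  dt <- unique(dt, by = c("contig", "pos"))
  count_matrix(dt, sample_label = label)
}

make_sites <- function(contig, pos, ref = "A", alt = "G", strand = "+",
                       coverage = 50L, edited = 10L,
                       frac = edited / coverage, sample = "s", replicate = 1L) {
  n <- max(length(contig), length(pos))
  out <- data.table(contig = rep_len(contig, n), pos = as.integer(rep_len(pos, n)),
                    ref = rep_len(ref, n), alt = rep_len(alt, n),
                    strand = rep_len(strand, n),
                    coverage = as.integer(rep_len(coverage, n)),
                    edited = as.integer(rep_len(edited, n)),
                    frac = rep_len(frac, n), sample = rep_len(sample, n),
                    replicate = as.integer(rep_len(replicate, n)))
  setorder(out, contig, pos)
  out[]
}

# ---- independent brute-force evaluators ------------------------------------

# Per-position re-evaluation of the printed control / experimental /
# background criteria with plain scalar loops (independent of the vectorised
# implementation path).
brute_editable <- function(control, enzyme, th) {
  out <- list()
  for (i in seq_len(nrow(control))) {
    row <- control[i]
    cov <- row$A + row$C + row$G + row$T
    for (j in seq_len(nrow(enzyme$signatures))) {
      s <- enzyme$signatures[j]
      if (cov >= th$control_min_reads &&
          row[[s$ref]] / cov >= th$control_min_ref_frac &&
          row[[s$alt]] / cov < th$control_max_alt_frac) {
        out[[length(out) + 1L]] <- data.table(contig = row$contig,
                                              pos = row$pos, ref = s$ref,
                                              alt = s$alt, strand = s$strand)
      }
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(contig = character(), pos = integer(), ref = character(),
               alt = character(), strand = character())
}

brute_call <- function(expt, editable, th) {
  out <- list()
  ekey <- paste(editable$contig, editable$pos)
  mkey <- paste(expt$contig, expt$pos)
  for (i in seq_len(nrow(editable))) {
    j <- match(ekey[i], mkey)
    if (is.na(j)) next
    row <- expt[j]
    cov <- row$A + row$C + row$G + row$T
    edited <- row[[editable$alt[i]]]
    if (cov >= th$expt_min_reads &&
        edited >= th$expt_min_edited_reads &&
        edited / cov > th$expt_min_edit_frac) {
      out[[length(out) + 1L]] <- data.table(contig = row$contig, pos = row$pos,
                                            ref = editable$ref[i],
                                            alt = editable$alt[i],
                                            edited = edited, coverage = cov)
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(contig = character(), pos = integer(), ref = character(),
               alt = character(), edited = integer(), coverage = integer())
}

brute_blacklist <- function(reps, enzyme, th) {
  out <- list()
  for (rep in reps) {
    for (i in seq_len(nrow(rep))) {
      row <- rep[i]
      cov <- row$A + row$C + row$G + row$T
      for (j in seq_len(nrow(enzyme$signatures))) {
        s <- enzyme$signatures[j]
        if (cov >= th$background_min_reads &&
            row[[s$alt]] / cov >= th$background_edit_frac) {
          out[[length(out) + 1L]] <- data.table(contig = row$contig,
                                                pos = row$pos, ref = s$ref,
                                                alt = s$alt)
        }
      }
    }
  }
  if (length(out)) unique(rbindlist(out)) else
    data.table(contig = character(), pos = integer(), ref = character(),
               alt = character())
}

sig_key <- function(x) sort(paste(x$contig, x$pos, x$ref, x$alt))

# Full-enumeration rank-sum oracle (two-sided, ties via midranks).
bf_ranksum <- function(x, y) {
  N <- length(x) + length(y); n <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n)])
  sums <- combn(N, n, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}

# ---- brute-force interval algebra ------------------------------------------

bf_overlap_bp <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2)

bf_intersect_pairs <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$contig[i] != b$contig[j]) next
    ov <- bf_overlap_bp(a$start[i], a$end[i], b$start[j], b$end[j])
    if (ov >= min_overlap) {
      out[[length(out) + 1L]] <- data.table(a_idx = i, b_idx = j,
                                            overlap_bp = as.integer(ov))
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(a_idx = integer(), b_idx = integer(), overlap_bp = integer())
}

bf_nearest <- function(q, subjects) {
  out <- rep(Inf, nrow(q))
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(subjects))) {
      if (q$contig[i] != subjects$contig[j]) next
      d <- max(0L, q$start[i] - subjects$end[j], subjects$start[j] - q$end[i])
      out[i] <- min(out[i], d)
    }
  }
  out
}

bf_nearest_points <- function(qc, qp, sc, sp) {
  out <- rep(Inf, length(qp))
  for (i in seq_along(qp)) {
    same <- which(sc == qc[i])
    if (length(same)) out[i] <- min(abs(sp[same] - qp[i]))
  }
  out
}

# ---- SAM fixtures and a brute-force pileup oracle --------------------------

write_sam <- function(reads, contig_lengths, path,
                      so = "coordinate") {
  hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s", so),
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                 reads$qname, reads$flag, reads$contig, reads$pos,
                 reads$cigar, reads$seq, strrep("I", nchar(reads$seq)))
  writeLines(c(hdr, rec), path)
  path
}

# Independent per-read CIGAR walk: tally aligned M/=/X bases, skip I/S/H,
# advance reference over D/N, ignore read N bases.
brute_pileup <- function(reads) {
  tally <- new.env()
  for (i in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[i]))[[1]]
    ref_pos <- reads$pos[i]
    seq_chars <- strsplit(reads$seq[i], "")[[1]]
    si <- 1L
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          b <- seq_chars[si]
          if (b %in% c("A", "C", "G", "T")) {
            key <- paste(reads$contig[i], ref_pos, b)
            tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
          }
          ref_pos <- ref_pos + 1L
          si <- si + 1L
        }
      } else if (type %in% c("I", "S")) {
        si <- si + len
      } else if (type %in% c("D", "N")) {
        ref_pos <- ref_pos + len
      }
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L) {
    return(data.table(contig = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer()))
  }
  parts <- tstrsplit(keys, " ")
  dt <- data.table(contig = parts[[1]], pos = as.integer(parts[[2]]),
                   base = parts[[3]],
                   n = vapply(keys, function(k) tally[[k]], integer(1)))
  wide <- dcast(dt, contig + pos ~ base, value.var = "n", fill = 0L)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(wide)) wide[, (b) := 0L]
  setorder(wide, contig, pos)
  wide[, .(contig, pos, A, C, G, T)]
}

random_reads <- function(n, seed, contig = "ctg", contig_len = 100L) {
  set.seed(seed)
  mk_seq <- function(len) paste(sample(c("A", "C", "G", "T", "N"), len,
                                       replace = TRUE,
                                       prob = c(24, 24, 24, 24, 4)),
                                collapse = "")
  reads <- lapply(seq_len(n), function(i) {
    pos <- sample(1:(contig_len - 30L), 1L)
    style <- sample(5L, 1L)
    if (style == 1L) { cigar <- "20M"; slen <- 20L }
    else if (style == 2L) { cigar <- "5S10M"; slen <- 15L }
    else if (style == 3L) { cigar <- "8M2I5M"; slen <- 15L }
    else if (style == 4L) { cigar <- "6M3D6M"; slen <- 12L }
    else { cigar <- "5M10N5M"; slen <- 10L }
    data.table(qname = sprintf("r%03d", i), flag = 0L, contig = contig,
               pos = pos, cigar = cigar, seq = mk_seq(slen))
  })
  out <- rbindlist(reads)
  setorder(out, pos)
  out[]
}

# ---- tiny hand-built annotation --------------------------------------------

# Two coding transcripts on separate contigs:
#   txP (+): exons 101-200 and 301-400 (200 exonic bp), CDS 141-360
#            -> 5'UTR 101-140 (40 bp), CDS 141-200 + 301-360, 3'UTR 361-400
#   txM (-): single exon 101-400 (300 bp), CDS 161-340
#            -> 5'UTR 341-400, CDS 161-340, 3'UTR 101-160
tiny_models <- function() {
  exons <- data.table(
    transcript_id = c("txP", "txP", "txM"),
    gene_id = c("gP", "gP", "gM"),
    contig = c("cP", "cP", "cM"),
    strand = c("+", "+", "-"),
    start = c(101L, 301L, 101L),
    end = c(200L, 400L, 400L))
  cds <- data.table(transcript_id = c("txP", "txP", "txM"),
                    start = c(141L, 301L, 161L),
                    end = c(200L, 360L, 340L))
  transcript_models(exons, cds)
}

tiny_genome <- function(seed = 99L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(c(
    cP = paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = ""),
    cM = paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")))
  g
}

quiet_call <- function(...) suppressWarnings(call_candidate_sites(...))
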