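#' @noRd
load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Editing sites per transcript
#'
#' Assigns each site to every transcript whose exons contain it and counts
#' sites per transcript. Transcripts without sites are not targets and are
#' omitted; the summary statistics are over targeted transcripts only.
#'
#' @param sites A site table.
#' @param models A [transcript_models()] object.
#' @return A list with `per_transcript` (data.table `transcript_id`,
#'   `gene_id`, `n_sites`) and `summary` (`n_targets`, `mean`, `median`,
#'   `max` sites per targeted transcript).
#' @export
sites_per_transcript <- function(sites, models) {
  stopifnot(inherits(models, "transcript_models"))
  if (nrow(models$exons) == 0L) validation_stop("empty annotation")
  pt <- position_transcripts(models, sites$contig, sites$pos)
  per <- pt[, .(n_sites = .N), by = .(transcript_id, gene_id)]
  setorder(per, -n_sites, transcript_id)
  summ <- list(n_targets = nrow(per),
               mean = if (nrow(per)) mean(per$n_sites) else NA_real_,
               median = if (nrow(per)) median(per$n_sites) else NA_real_,
               max = if (nrow(per)) max(per$n_sites) else NA_integer_)
  list(per_transcript = per[], summary = summ)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of location difference between two samples. When both
#' sample sizes are at most `exact_max` the null distribution of the rank sum
#' is computed exactly by enumeration over all assignments of the pooled
#' (mid)ranks (a dynamic program equivalent to full enumeration, correct
#' under ties); the two-sided p-value is `min(1, 2 * min(lower, upper))`
#' with the observed value included in both tails. Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_max Largest per-group size for the exact path (default 12).
#' @return A list: `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    validation_stop("rank_sum_test needs two non-empty samples")
  }
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  if (n <= exact_max && m <= exact_max) {
    # exact null distribution of the rank sum: midranks are multiples of 1/2,
    # so double them and run an integer subset-sum dynamic program over all
    # C(N, n) assignments.
    r2 <- as.integer(round(2 * r))
    maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
    # counts[k+1, s+1] = number of k-subsets of processed ranks with sum s
    counts <- matrix(0, nrow = n + 1L, ncol = maxs + 1L)
    counts[1L, 1L] <- 1
    for (v in r2) {
      kmax <- n
      for (k in kmax:1L) {
        src <- counts[k, ]
        if (any(src > 0)) {
          shifted <- c(rep(0, v), src)[seq_len(maxs + 1L)]
          counts[k + 1L, ] <- counts[k + 1L, ] + shifted
        }
      }
    }
    dist <- counts[n + 1L, ]
    total <- sum(dist)
    w2 <- as.integer(round(2 * W))
    lower <- sum(dist[seq_len(w2 + 1L)]) / total
    upper <- sum(dist[(w2 + 1L):(maxs + 1L)]) / total
    p <- min(1, 2 * min(lower, upper))
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  mu <- n * (N + 1) / 2
  ties <- table(r)
  tie_adj <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_adj)
  if (sigma2 <= 0) return(list(statistic = W, p.value = 1, method = "normal"))
  z <- W - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2) # continuity correction
  p <- 2 * pnorm(-abs(z))
  list(statistic = W, p.value = min(1, p), method = "normal")
}

#' Compare editing fractions of two site sets
#'
#' Means and medians of the per-site edited fraction, with a two-sided
#' Wilcoxon rank-sum test of the difference (see [rank_sum_test()]).
#'
#' @param sites_a,sites_b Site tables (or bare numeric vectors of fractions).
#' @return A list: `mean_a`, `mean_b`, `median_a`, `median_b`, `statistic`,
#'   `p.value`, `method`.
#' @export
editing_fraction_stats <- function(sites_a, sites_b) {
  fa <- if (is.numeric(sites_a)) sites_a else sites_a$frac
  fb <- if (is.numeric(sites_b)) sites_b else sites_b$frac
  if (length(fa) == 0L || length(fb) == 0L) {
    validation_stop("both site sets must be non-empty")
  }
  ts <- rank_sum_test(fa, fb)
  list(mean_a = mean(fa), mean_b = mean(fb),
       median_a = median(fa), median_b = median(fb),
       statistic = ts$statistic, p.value = ts$p.value, method = ts$method)
}

#' Trinucleotide context profile of editing sites
#'
#' For each site, the reference triplet (5' neighbour, edited base, 3'
#' neighbour) in transcribed-strand orientation: plus-strand signatures use
#' the forward reference bases at (pos-1, pos, pos+1); minus-strand
#' signatures use their reverse complement, so the centre base is always the
#' enzyme's substrate. Sites at contig termini are skipped (with a QC
#' warning) and counted in the `skipped` attribute.
#'
#' @param sites A site table.
#' @param genome FASTA path or [Biostrings::DNAStringSet] covering all site
#'   contigs.
#' @return A data.table of class `context_profile` with columns `triplet`,
#'   `count`, `fraction` (fractions over retained sites, summing to 1);
#'   attribute `skipped` counts edge sites.
#' @export
triplet_context <- function(sites, genome) {
  genome <- load_genome(genome)
  missing <- setdiff(unique(sites$contig), names(genome))
  if (length(missing)) {
    validation_stop("contig absent from genome: ", paste(missing, collapse = ", "))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  edge <- sites$pos <= 1L | sites$pos >= lens[sites$contig]
  n_skip <- sum(edge)
  if (n_skip > 0L) {
    qc_warn(sprintf("%d site(s) at contig termini skipped in context profile", n_skip))
  }
  s <- sites[!edge]
  if (nrow(s) == 0L) {
    out <- data.table(triplet = character(), count = integer(),
                      fraction = numeric())
  } else {
    trips <- character(nrow(s))
    for (ctg in unique(s$contig)) {
      idx <- which(s$contig == ctg)
      seq_chr <- as.character(genome[[ctg]])
      trips[idx] <- substring(seq_chr, s$pos[idx] - 1L, s$pos[idx] + 1L)
    }
    minus <- s$strand == "-"
    if (any(minus)) {
      trips[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(trips[minus])))
    }
    tab <- sort(table(trips), decreasing = TRUE)
    out <- data.table(triplet = names(tab), count = as.integer(tab),
                      fraction = as.numeric(tab) / nrow(s))
  }
  setattr(out, "skipped", n_skip)
  setattr(out, "class", c("context_profile", class(out)))
  out[]
}

#' Feature distribution of RNA-seq coverage
#'
#' Per-feature (5'UTR/CDS/3'UTR) coverage shares of a count matrix, the
#' in-package stand-in for an external read-distribution tool: each matrix
#' position is assigned a feature by the same majority rule used for sites
#' and coverage is summed per feature, renormalised over the three exonic
#' features.
#'
#' @param mat A [count_matrix()] (typically the control library).
#' @param models A [transcript_models()] object.
#' @return Named numeric vector over `5UTR`, `CDS`, `3UTR` summing to 1.
#' @export
read_feature_distribution <- function(mat, models) {
  feat <- assign_feature(models, mat$contig, mat$pos)
  keep <- !is.na(feat)
  if (!any(keep)) validation_stop("no matrix position falls in an annotated feature")
  agg <- tapply(mat$coverage[keep], factor(feat[keep],
                                           levels = c("5UTR", "CDS", "3UTR")),
                sum, default = 0)
  agg <- as.numeric(agg) / sum(agg)
  setNames(agg, c("5UTR", "CDS", "3UTR"))
}

#' Fold enrichment of editing sites across transcript features
#'
#' Assigns each site a single feature (majority vote across containing coding
#' transcripts; ties broken 3'UTR > 5'UTR > CDS) and compares the site
#' distribution to the read distribution of the sequencing library:
#' `fold_enrichment = site_fraction / read_fraction`, with a two-sided
#' one-sample proportion z-test of the site proportion against the
#' read-derived expectation. A feature with zero read fraction but observed
#' sites reports `Inf` fold and p = 0.
#'
#' @param sites A site table.
#' @param models A [transcript_models()] object.
#' @param read_distribution Named fractions over `5UTR`, `CDS`, `3UTR`
#'   summing to 1 (see [read_feature_distribution()]).
#' @return A data.table of class `feature_distribution` with columns
#'   `feature`, `site_count`, `site_fraction`, `read_fraction`,
#'   `fold_enrichment`, `p_value`; attribute `n_unassigned` counts sites in
#'   no annotated coding transcript.
#' @export
feature_fold_enrichment <- function(sites, models, read_distribution) {
  feats <- c("5UTR", "CDS", "3UTR")
  rd <- read_distribution[feats]
  if (anyNA(rd)) validation_stop("read_distribution needs 5UTR, CDS, 3UTR")
  if (abs(sum(rd) - 1) > 1e-6) validation_stop("read_distribution must sum to 1")
  assigned <- assign_feature(models, sites$contig, sites$pos)
  n_un <- sum(is.na(assigned))
  f <- factor(assigned[!is.na(assigned)], levels = feats)
  n <- length(f)
  if (n == 0L) validation_stop("no site falls in an annotated coding transcript")
  cnt <- as.integer(table(f))
  sf <- cnt / n
  fold <- ifelse(rd > 0, sf / rd, ifelse(cnt > 0, Inf, NaN))
  p <- numeric(3)
  for (i in 1:3) {
    if (rd[i] > 0 && rd[i] < 1) {
      z <- (sf[i] - rd[i]) / sqrt(rd[i] * (1 - rd[i]) / n)
      p[i] <- 2 * pnorm(-abs(z))
    } else if (rd[i] == 0) {
      p[i] <- if (cnt[i] > 0) 0 else 1   # binomial tail at p0 = 0
    } else {
      p[i] <- if (cnt[i] < n) 0 else 1   # p0 = 1 degenerate case
    }
  }
  out <- data.table(feature = feats, site_count = cnt, site_fraction = sf,
                    read_fraction = as.numeric(rd), fold_enrichment = fold,
                    p_value = p)
  setattr(out, "n_unassigned", n_un)
  setattr(out, "class", c("feature_distribution", class(out)))
  out[]
}

#' Shift sites toward the transcript 3' end
#'
#' Moves each site `shift` bases toward the 3' terminus of its host
#' transcript *in transcript coordinates* (so the move follows the exon
#' chain; on minus-strand transcripts the genomic coordinate decreases),
#' clamped at the transcript's last base. The host is the containing
#' transcript in which the site is already closest to the 3' end (the most
#' 3'-biased assignment); sites contained in no transcript are left in place
#' and flagged.
#'
#' Rationale: editing sites just 5' of the stop codon frequently reflect
#' binding at the CDS/3'UTR border; a 50-bp 3' shift reclassifies them.
#'
#' @param sites A site table.
#' @param models A [transcript_models()] object.
#' @param shift Shift distance, bp (default 50).
#' @return A copy of `sites` with updated `pos` plus columns `shifted`
#'   (logical) and `host_transcript`.
#' @export
shift_toward_3prime <- function(sites, models, shift = 50L) {
  out <- copy(sites)
  out[, `:=`(shifted = FALSE, host_transcript = NA_character_)]
  if (nrow(out) == 0L) return(out[])
  pt <- position_transcripts(models, out$contig, out$pos)
  if (nrow(pt) == 0L) return(out[])
  ex_by_tx <- split(models$exons, by = "transcript_id")
  txl <- setNames(models$tx$tx_len, models$tx$transcript_id)
  # transcript coordinate of the site in each candidate host
  t_coord <- integer(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    e <- ex_by_tx[[pt$transcript_id[i]]]
    t_coord[i] <- genome_to_tx(e$start, e$end, pt$strand[i], out$pos[pt$q[i]])
  }
  pt[, t_coord := t_coord]
  pt[, dist3 := txl[transcript_id] - t_coord]
  # most 3'-biased host: smallest remaining distance to the 3' terminus
  setorder(pt, q, dist3, transcript_id)
  host <- pt[, .SD[1], by = q]
  for (i in seq_len(nrow(host))) {
    qi <- host$q[i]
    e <- ex_by_tx[[host$transcript_id[i]]]
    t_new <- min(host$t_coord[i] + as.integer(shift),
                 txl[host$transcript_id[i]])
    out$pos[qi] <- tx_to_genome(e$start, e$end, host$strand[i], t_new)
    out$shifted[qi] <- TRUE
    out$host_transcript[qi] <- host$transcript_id[i]
  }
  out[]
}

#' Normalise a site count per million mapped reads
#'
#' @param site_count Number of sites.
#' @param mapped_reads Uniquely mapped reads of the library (> 0).
#' @return `site_count * 1e6 / mapped_reads`.
#' @examples
#' normalize_per_million(30000, 15e6) # 2000
#' @export
normalize_per_million <- function(site_count, mapped_reads) {
  if (!is.numeric(mapped_reads) || is.na(mapped_reads) || mapped_reads <= 0) {
    validation_stop("mapped_reads must be > 0")
  }
  site_count * 1e6 / mapped_reads
}

#' Fraction of regions containing a fixed motif
#'
#' Scans each region's reference sequence for an IUPAC motif on both strands
#' (forward sequence scanned for the motif and for its reverse complement)
#' and reports the fraction of regions with at least one match. A fixed-motif
#' stand-in for de-novo discovery: the canonical use is the GT-rich
#' (GTGTGT) element in 50-bp-expanded edited regions.
#'
#' @param regions A [genomic_intervals()] (pre-expanded by the caller, e.g.
#'   via [slop()] with `motif_flank`).
#' @param genome FASTA path or [Biostrings::DNAStringSet].
#' @param motif IUPAC motif string (non-empty).
#' @return A list: `fraction`, `n_matching`, `n_regions`, and per-region
#'   logical `matched`.
#' @export
motif_fraction <- function(regions, genome, motif = "GTGTGT") {
  if (!nzchar(motif)) validation_stop("motif must be non-empty")
  genome <- load_genome(genome)
  n <- nrow(regions)
  if (n == 0L) return(list(fraction = NaN, n_matching = 0L, n_regions = 0L,
                           matched = logical(0)))
  lens <- setNames(Biostrings::width(genome), names(genome))
  missing <- setdiff(unique(regions$contig), names(genome))
  if (length(missing)) {
    validation_stop("contig absent from genome: ", paste(missing, collapse = ", "))
  }
  seqs <- character(n)
  for (ctg in unique(regions$contig)) {
    idx <- which(regions$contig == ctg)
    s <- pmax(regions$start[idx] + 1L, 1L)
    e <- pmin(regions$end[idx], lens[ctg])
    seq_chr <- as.character(genome[[ctg]])
    seqs[idx] <- substring(seq_chr, s, e)
  }
  ss <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::vcountPattern(motif, ss, fixed = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  rev <- Biostrings::vcountPattern(rc, ss, fixed = FALSE)
  matched <- (fwd + rev) > 0
  list(fraction = mean(matched), n_matching = sum(matched), n_regions = n,
       matched = matched)
}
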