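#' Simulation parameters
#'
#' The stated world of the synthetic benchmark: a compact transcriptome with
#' planted editing ground truth, sized so the full pipeline runs in seconds.
#' Defaults emulate a deep bulk Smart-seq2 experiment at desk scale:
#' 200 transcripts, ~100x coverage, Illumina-like per-base error 1e-3,
#' 500 planted sites edited at 20%, two biological replicates.
#'
#' @param n_transcripts Number of transcripts (one per contig).
#' @param transcript_length Range (min, max) of exonic transcript length, bp.
#' @param exon_count_range Range of exons per transcript.
#' @param intron_length_range Range of intron lengths, bp.
#' @param utr_fractions Fractions of exonic length in the (5'UTR, 3'UTR).
#' @param flank Intergenic flank on each side of a transcript, bp.
#' @param coverage_mean Mean per-position read coverage (Poisson).
#' @param seq_error_rate Per-base sequencing error rate, split evenly across
#'   the three alternative bases.
#' @param n_truth_sites Number of planted editing sites (fusion samples).
#' @param truth_edit_frac Planted edited-read fraction at truth sites.
#' @param enzyme An [enzyme_spec()] (or its name).
#' @param context_whitelist Optional character vector of transcribed-strand
#'   triplets; truth sites are then planted only at matching positions
#'   (e.g. `c("ACA","ACT","TCA","TCT")` for APOBEC's A/T-flanked preference).
#' @param background_rate Edited fraction at background positions in the
#'   enzyme-only samples.
#' @param n_background_sites Number of background positions (shared across
#'   enzyme-only replicates, disjoint from truth).
#' @param feature_bias Named placement weights over `5UTR`, `CDS`, `3UTR`
#'   for truth sites (default uniform per available position).
#' @param reps Number of biological replicates (fusion and enzyme-only).
#' @param rep_jitter_bp Maximum inter-replicate displacement of planted sites
#'   (APOBEC-like dispersion): replicate >= 2 plants each edit at a position
#'   drawn Uniform{0..rep_jitter_bp} bp away (random sign), snapped to the
#'   nearest substrate base of the same transcript. 0 = ADAR-like identical
#'   positions.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_transcripts = 200L,
                       transcript_length = c(900L, 2500L),
                       exon_count_range = c(1L, 3L),
                       intron_length_range = c(50L, 300L),
                       utr_fractions = c(utr5 = 0.2, utr3 = 0.3),
                       flank = 100L,
                       coverage_mean = 100,
                       seq_error_rate = 0.001,
                       n_truth_sites = 500L,
                       truth_edit_frac = 0.2,
                       enzyme = enzyme_spec("ADAR"),
                       context_whitelist = NULL,
                       background_rate = 0.05,
                       n_background_sites = 200L,
                       feature_bias = c("5UTR" = 1, "CDS" = 1, "3UTR" = 1),
                       reps = 2L,
                       rep_jitter_bp = 0L) {
  if (is.character(enzyme)) enzyme <- enzyme_spec(enzyme)
  p <- list(n_transcripts = as.integer(n_transcripts),
            transcript_length = as.integer(transcript_length),
            exon_count_range = as.integer(exon_count_range),
            intron_length_range = as.integer(intron_length_range),
            utr_fractions = utr_fractions,
            flank = as.integer(flank),
            coverage_mean = coverage_mean,
            seq_error_rate = seq_error_rate,
            n_truth_sites = as.integer(n_truth_sites),
            truth_edit_frac = truth_edit_frac,
            enzyme = enzyme,
            context_whitelist = context_whitelist,
            background_rate = background_rate,
            n_background_sites = as.integer(n_background_sites),
            feature_bias = feature_bias,
            reps = as.integer(reps),
            rep_jitter_bp = as.integer(rep_jitter_bp))
  for (f in c("seq_error_rate", "truth_edit_frac", "background_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) validation_stop(f, " must be in [0, 1]")
  }
  if (any(p$utr_fractions < 0) || sum(p$utr_fractions) >= 1) {
    validation_stop("utr_fractions must be non-negative and sum below 1")
  }
  if (p$n_transcripts < 0 || p$reps < 1) {
    validation_stop("need n_transcripts >= 0 and reps >= 1")
  }
  structure(p, class = "sim_params")
}

#' @noRd
# Independent deterministic RNG streams derived from one master seed.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + 97 * k) %% 2147483647)
}

#' Simulate a reference genome and transcript annotation
#'
#' One transcript per contig: random sequence, 1-3 exons separated by
#' introns, intergenic flanks, alternating strand, and a 5'UTR/CDS/3'UTR
#' partition of the exonic bases following `utr_fractions`. Deterministic
#' given `seed`; when `dir` is supplied, `genome.fa` and `annotation.gtf`
#' are written there (byte-identical across runs).
#'
#' @param params A [sim_params()] object.
#' @param seed Integer master seed.
#' @param dir Optional output directory.
#' @return A list: `genome` ([Biostrings::DNAStringSet]), `models`
#'   ([transcript_models()], `NULL` when `n_transcripts = 0`),
#'   `contig_lengths` (named integer), `paths` (when `dir` given).
#' @export
simulate_reference <- function(params = sim_params(), seed = 1L, dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stream_seed(seed, 1L))
  n <- params$n_transcripts
  seqs <- character(n)
  exon_rows <- vector("list", n)
  cds_rows <- vector("list", n)
  gtf_lines <- character(0)
  contigs <- sprintf("tig%04d", seq_len(max(n, 0L)))
  for (i in seq_len(n)) {
    L <- sample(params$transcript_length[1]:params$transcript_length[2], 1L)
    k <- sample(params$exon_count_range[1]:params$exon_count_range[2], 1L)
    strand <- if (i %% 2L == 1L) "+" else "-"
    # split exonic length into k exons (each >= 50 bp when possible)
    if (k > 1L) {
      cuts <- sort(sample(seq(50L, L - 50L), k - 1L))
      widths <- diff(c(0L, cuts, L))
    } else widths <- L
    introns <- if (k > 1L) {
      sample(params$intron_length_range[1]:params$intron_length_range[2],
             k - 1L, replace = TRUE)
    } else integer(0)
    starts <- params$flank + 1L + cumsum(c(0L, widths[-k] + introns))
    ends <- starts + widths - 1L
    ctg_len <- max(ends) + params$flank
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), ctg_len, replace = TRUE),
                     collapse = "")
    tid <- sprintf("tx%04d", i)
    gid <- sprintf("gene%04d", i)
    exon_rows[[i]] <- data.table(transcript_id = tid, gene_id = gid,
                                 contig = contigs[i], strand = strand,
                                 start = starts, end = ends)
    # UTR partition in transcript coordinates
    u5 <- as.integer(round(params$utr_fractions[1] * L))
    u3 <- as.integer(round(params$utr_fractions[2] * L))
    if (L - u5 - u3 < 3L) validation_stop("transcript too short for a CDS")
    cds_t <- c(u5 + 1L, L - u3)
    g1 <- tx_to_genome(starts, ends, strand, cds_t[1])
    g2 <- tx_to_genome(starts, ends, strand, cds_t[2])
    cds_g <- sort(c(g1, g2))
    # clip the CDS genomic span to the exons for well-formed GTF records
    seg_s <- pmax(starts, cds_g[1]); seg_e <- pmin(ends, cds_g[2])
    ok <- seg_s <= seg_e
    cds_rows[[i]] <- data.table(transcript_id = tid, start = seg_s[ok],
                                end = seg_e[ok])
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    gtf_lines <- c(gtf_lines,
      sprintf("%s\teditscreen_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
              contigs[i], starts, ends, strand, attrs),
      sprintf("%s\teditscreen_sim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              contigs[i], seg_s[ok], seg_e[ok], strand, attrs))
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- contigs[seq_len(n)]
  models <- if (n > 0L) {
    transcript_models(rbindlist(exon_rows), rbindlist(cds_rows))
  } else NULL
  out <- list(genome = genome, models = models,
              contig_lengths = setNames(Biostrings::width(genome),
                                        names(genome)),
              params = params, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    Biostrings::writeXStringSet(genome, fa)
    writeLines(gtf_lines, gtf)
    out$paths <- list(genome = fa, gtf = gtf)
  }
  out
}

#' @noRd
# Every exonic position with its forward reference base, transcribed strand
# and feature. One transcript per contig keeps positions unique per contig.
exonic_positions <- function(reference) {
  ex <- reference$models$exons
  pos_list <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    pos_list[[i]] <- data.table(transcript_id = ex$transcript_id[i],
                                contig = ex$contig[i], strand = ex$strand[i],
                                pos = ex$start[i]:ex$end[i])
  }
  dt <- rbindlist(pos_list)
  base <- character(nrow(dt))
  for (ctg in unique(dt$contig)) {
    idx <- which(dt$contig == ctg)
    s <- as.character(reference$genome[[ctg]])
    base[idx] <- substring(s, dt$pos[idx], dt$pos[idx])
  }
  dt[, base := base]
  dt[, feature := assign_feature(reference$models, contig, pos)]
  setorder(dt, contig, pos)
  dt[]
}

#' Plant editing ground truth
#'
#' Draws `n_truth_sites` positions among exonic substrate bases (the enzyme's
#' substrate on the transcribed strand), optionally restricted to a
#' trinucleotide `context_whitelist` and weighted by `feature_bias`.
#'
#' @param reference Output of [simulate_reference()].
#' @param params A [sim_params()] object.
#' @param seed Integer master seed (same one passed to the other simulate
#'   steps).
#' @return A `truth_table`: data.table with columns `contig`, `pos`, `ref`,
#'   `alt`, `strand`, `edit_frac`, `feature`, `triplet`, `transcript_id`.
#' @export
simulate_truth <- function(reference, params = reference$params, seed = 1L) {
  set.seed(stream_seed(seed, 2L))
  epos <- exonic_positions(reference)
  sig <- params$enzyme$signatures
  cand <- merge(epos, sig, by.x = c("strand", "base"), by.y = c("strand", "ref"),
                sort = FALSE)
  setnames(cand, "base", "ref")
  if (!is.null(params$context_whitelist)) {
    prof_in <- data.table(contig = cand$contig, pos = cand$pos,
                          strand = cand$strand)
    trip <- triplet_of(reference$genome, prof_in)
    cand <- cand[trip %in% params$context_whitelist]
    cand[, triplet := trip[trip %in% params$context_whitelist]]
  } else {
    cand[, triplet := triplet_of(reference$genome,
                                 data.table(contig = contig, pos = pos,
                                            strand = strand))]
  }
  cand <- cand[!is.na(feature)]
  if (nrow(cand) < params$n_truth_sites) {
    validation_stop("not enough candidate positions for n_truth_sites")
  }
  w <- params$feature_bias[cand$feature]
  w[is.na(w)] <- 0
  idx <- sample(nrow(cand), params$n_truth_sites, prob = w)
  truth <- cand[sort(idx),
                .(contig, pos, ref, alt, strand,
                  edit_frac = params$truth_edit_frac, feature, triplet,
                  transcript_id)]
  setattr(truth, "class", c("truth_table", class(truth)))
  truth[]
}

#' @noRd
triplet_of <- function(genome, dt) {
  out <- rep(NA_character_, nrow(dt))
  lens <- setNames(Biostrings::width(genome), names(genome))
  ok <- dt$pos > 1L & dt$pos < lens[dt$contig]
  for (ctg in unique(dt$contig[ok])) {
    idx <- which(ok & dt$contig == ctg)
    s <- as.character(genome[[ctg]])
    out[idx] <- substring(s, dt$pos[idx] - 1L, dt$pos[idx] + 1L)
  }
  minus <- ok & dt$strand == "-"
  if (any(minus)) {
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  }
  out
}

#' Simulate control, enzyme-only and fusion count matrices
#'
#' Per-position model at every exonic position: coverage ~ Poisson(mean);
#' base counts multinomial with the reference base carrying the remaining
#' probability, each alternative base carrying `seq_error_rate / 3`, plus the
#' planted edited fraction added to the signature alternative where a sample
#' plants edits (truth positions in fusion samples, background positions in
#' enzyme-only samples). The control carries error only. With
#' `rep_jitter_bp > 0`, replicate >= 2 fusion samples displace each planted
#' site toward a nearby substrate base (APOBEC-like dispersion).
#'
#' @param reference Output of [simulate_reference()].
#' @param truth Output of [simulate_truth()].
#' @param params A [sim_params()] object.
#' @param seed Integer master seed.
#' @return A list: `control` ([count_matrix()]), `enzyme_only` (list of
#'   matrices), `fusion` (list of matrices), `rep_truth` (list of per-
#'   replicate planted positions), `background` (enzyme-only background
#'   positions).
#' @export
simulate_counts <- function(reference, truth, params = reference$params,
                            seed = 1L) {
  epos <- exonic_positions(reference)
  bad <- !paste(truth$contig, truth$pos) %in% paste(epos$contig, epos$pos)
  if (any(bad)) {
    validation_stop("truth position not in reference exons: ",
                    truth$contig[bad][1], ":", truth$pos[bad][1])
  }
  sig <- params$enzyme$signatures
  sig_alt <- setNames(sig$alt, sig$ref)   # substrate (fwd ref) -> edited base
  key <- function(ctg, p) paste(ctg, p, sep = "\r")
  epos_key <- key(epos$contig, epos$pos)

  # per-replicate planted positions (replicate 1 = canonical truth)
  set.seed(stream_seed(seed, 3L))
  substrate <- epos[base %in% names(sig_alt)]
  rep_truth <- vector("list", params$reps)
  rep_truth[[1]] <- copy(truth)
  if (params$reps >= 2L) {
    for (r in 2:params$reps) {
      if (params$rep_jitter_bp == 0L) {
        rep_truth[[r]] <- copy(truth)
      } else {
        jit <- copy(truth)
        d <- sample(0:params$rep_jitter_bp, nrow(jit), replace = TRUE) *
          sample(c(-1L, 1L), nrow(jit), replace = TRUE)
        target <- jit$pos + d
        spl <- split(substrate$pos, paste(substrate$transcript_id, substrate$base))
        for (j in seq_len(nrow(jit))) {
          cand <- spl[[paste(jit$transcript_id[j], jit$ref[j])]]
          jit$pos[j] <- cand[which.min(abs(cand - target[j]))]
        }
        rep_truth[[r]] <- unique(jit, by = c("contig", "pos"))
      }
    }
  }

  # shared enzyme-only background positions, disjoint from truth
  bg_cand <- substrate[!key(contig, pos) %in% key(truth$contig, truth$pos)]
  nbg <- min(params$n_background_sites, nrow(bg_cand))
  bg <- bg_cand[sort(sample(nrow(bg_cand), nbg))]

  # per-base lookup of the three alternative bases, signature alt in slot 1
  bases <- c("A", "C", "G", "T")
  alt_lookup <- t(vapply(bases, function(b) {
    oth <- setdiff(bases, b)
    a1 <- if (b %in% names(sig_alt)) sig_alt[[b]] else oth[1]
    c(a1, setdiff(oth, a1))
  }, character(3)))
  alt_mat <- alt_lookup[match(epos$base, bases), , drop = FALSE]

  draw_sample <- function(extra_key, extra_frac, stream, label) {
    set.seed(stream_seed(seed, stream))
    npos <- nrow(epos)
    N <- rpois(npos, params$coverage_mean)
    p_extra <- numeric(npos)
    if (length(extra_key)) {
      hit <- match(extra_key, epos_key)
      p_extra[hit] <- extra_frac
    }
    e3 <- params$seq_error_rate / 3
    p1 <- p_extra + e3
    n1 <- rbinom(npos, N, p1)
    n2 <- rbinom(npos, N - n1, e3 / (1 - p1))
    n3 <- rbinom(npos, N - n1 - n2, e3 / (1 - p1 - e3))
    cnt <- matrix(0L, nrow = npos, ncol = 4L, dimnames = list(NULL, bases))
    cnt[cbind(seq_len(npos), match(epos$base, bases))] <- N - n1 - n2 - n3
    cnt[cbind(seq_len(npos), match(alt_mat[, 1L], bases))] <-
      cnt[cbind(seq_len(npos), match(alt_mat[, 1L], bases))] + n1
    cnt[cbind(seq_len(npos), match(alt_mat[, 2L], bases))] <-
      cnt[cbind(seq_len(npos), match(alt_mat[, 2L], bases))] + n2
    cnt[cbind(seq_len(npos), match(alt_mat[, 3L], bases))] <-
      cnt[cbind(seq_len(npos), match(alt_mat[, 3L], bases))] + n3
    count_matrix(data.table(contig = epos$contig, pos = epos$pos,
                            A = cnt[, "A"], C = cnt[, "C"],
                            G = cnt[, "G"], T = cnt[, "T"]),
                 mapped_reads = round(sum(N) / 75),  # ~75 bp reads
                 sample_label = label)
  }

  control <- draw_sample(character(0), 0, 10L, "control")
  enzyme_only <- lapply(seq_len(params$reps), function(r) {
    draw_sample(key(bg$contig, bg$pos), params$background_rate, 20L + r,
                sprintf("%s_only_rep%d", tolower(params$enzyme$name), r))
  })
  fusion <- lapply(seq_len(params$reps), function(r) {
    tt <- rep_truth[[r]]
    draw_sample(key(tt$contig, tt$pos), params$truth_edit_frac, 30L + r,
                sprintf("fusion_rep%d", r))
  })
  list(control = control, enzyme_only = enzyme_only, fusion = fusion,
       rep_truth = rep_truth, background = bg)
}

#' Score called sites against planted truth
#'
#' A called site matches truth when a truth position lies within `tolerance`
#' bp on the same contig. Precision = matched called / called (NaN when
#' nothing was called); recall = matched truth / total truth. For sites
#' matching at the exact position, the mean absolute difference between the
#' called and planted edited fraction is reported.
#'
#' @param called A site table.
#' @param truth A truth table from [simulate_truth()].
#' @param tolerance Matching tolerance, bp.
#' @return A list: `precision`, `recall`, `n_called`, `n_truth`,
#'   `mean_frac_error`.
#' @export
evaluate_calls <- function(called, truth, tolerance = 0L) {
  n_called <- nrow(called); n_truth <- nrow(truth)
  if (n_called == 0L) {
    return(list(precision = NaN, recall = 0, n_called = 0L,
                n_truth = n_truth, mean_frac_error = NaN))
  }
  d_called <- nearest_point_distance(called$contig, called$pos,
                                     truth$contig, truth$pos)
  d_truth <- nearest_point_distance(truth$contig, truth$pos,
                                    called$contig, called$pos)
  exact <- merge(called[, .(contig, pos, frac)],
                 truth[, .(contig, pos, edit_frac)],
                 by = c("contig", "pos"))
  list(precision = mean(d_called <= tolerance),
       recall = mean(d_truth <= tolerance),
       n_called = n_called, n_truth = n_truth,
       mean_frac_error = if (nrow(exact))
         mean(abs(exact$frac - exact$edit_frac)) else NaN)
}
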