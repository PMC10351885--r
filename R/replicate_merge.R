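#' @noRd
# Nearest |pos - pos'| from each query point to a set of subject points,
# per contig; Inf when the query's contig has no subject point.
nearest_point_distance <- function(q_contig, q_pos, s_contig, s_pos) {
  n <- length(q_pos)
  out <- rep(Inf, n)
  if (length(s_pos) == 0L || n == 0L) return(out)
  for (ctg in unique(q_contig)) {
    sp <- sort(s_pos[s_contig == ctg])
    if (length(sp) == 0L) next
    qi <- which(q_contig == ctg)
    qp <- q_pos[qi]
    idx <- findInterval(qp, sp)
    d_lo <- ifelse(idx >= 1L, qp - sp[pmax(idx, 1L)], Inf)
    d_hi <- ifelse(idx < length(sp), sp[pmin(idx + 1L, length(sp))] - qp, Inf)
    out[qi] <- pmin(d_lo, d_hi)
  }
  out
}

#' Merge replicates by exact position (ADAR rule)
#'
#' Keeps sites called at the identical (contig, position, signature) in both
#' biological replicates — the appropriate rule for ADAR, which tends to
#' re-edit the same adenosine. The merged record reports the mean edited
#' fraction and keeps each replicate's coverage and edited-read count.
#'
#' @param rep1,rep2 Site tables from [call_candidate_sites()].
#' @return A site table with extra columns `coverage_rep1`, `edited_rep1`,
#'   `frac_rep1` (and `_rep2`); `frac` is the replicate mean and
#'   `coverage`/`edited` are the replicate means (rounded) for downstream
#'   convenience.
#' @export
merge_exact <- function(rep1, rep2) {
  m <- merge(rep1[, .(contig, pos, ref, alt, strand, coverage, edited, frac,
                      sample)],
             rep2[, .(contig, pos, ref, alt, strand, coverage, edited, frac)],
             by = c("contig", "pos", "ref", "alt", "strand"),
             suffixes = c("_rep1", "_rep2"), sort = FALSE)
  out <- m[, .(contig, pos, ref, alt, strand,
               coverage = as.integer(round((coverage_rep1 + coverage_rep2) / 2)),
               edited = as.integer(round((edited_rep1 + edited_rep2) / 2)),
               frac = (frac_rep1 + frac_rep2) / 2,
               sample, replicate = NA_integer_,
               coverage_rep1, edited_rep1, frac_rep1,
               coverage_rep2, edited_rep2, frac_rep2)]
  setorder(out, contig, pos)
  out[]
}

#' Merge replicates by proximity (APOBEC rule)
#'
#' APOBEC edits nearby cytosines rather than the identical one, so a site is
#' accepted when the *other* replicate has a site within `window` bp (distance
#' = |pos1 - pos2|; signature identity is not required across replicates — in
#' unstranded data both strand signatures describe one biological event).
#'
#' By default the merge is symmetric and keeps qualifying sites from both
#' replicates (duplicated identical positions collapse to one record with the
#' mean fraction), so it is always a superset of [merge_exact()].
#' `mode = "rep1"` reproduces the asymmetric reading that emits replicate-1
#' coordinates only.
#'
#' @param rep1,rep2 Site tables.
#' @param window Maximum partner distance, bp (>= 0).
#' @param mode `"both"` (default) or `"rep1"`.
#' @return A site table.
#' @export
merge_proximity <- function(rep1, rep2, window = 100L, mode = c("both", "rep1")) {
  if (window < 0) validation_stop("window must be >= 0")
  mode <- match.arg(mode)
  d1 <- nearest_point_distance(rep1$contig, rep1$pos, rep2$contig, rep2$pos)
  keep <- rep1[d1 <= window]
  if (mode == "both") {
    d2 <- nearest_point_distance(rep2$contig, rep2$pos, rep1$contig, rep1$pos)
    keep <- rbindlist(list(keep, rep2[d2 <= window]), use.names = TRUE,
                      fill = TRUE)
  }
  if (nrow(keep) == 0L) return(empty_sites())
  # collapse records at identical positions (mean fraction, first signature)
  out <- keep[, .(ref = ref[1], alt = alt[1], strand = strand[1],
                  coverage = as.integer(round(mean(coverage))),
                  edited = as.integer(round(mean(edited))),
                  frac = mean(frac), sample = sample[1],
                  replicate = NA_integer_),
              by = .(contig, pos)]
  setorder(out, contig, pos)
  setcolorder(out, c("contig", "pos", "ref", "alt", "strand", "coverage",
                     "edited", "frac", "sample", "replicate"))
  out[]
}

#' Classify between-replicate site distances
#'
#' For every replicate-1 site, the distance to the nearest replicate-2 site is
#' binned: `identical` (0 bp), `within_100bp` (1-100), `within_200bp`
#' (101-200), `beyond_200bp` (> 200, or no replicate-2 site on the contig).
#' ADAR typically concentrates mass in `identical`; APOBEC spreads it into the
#' proximity bins.
#'
#' @param rep1,rep2 Non-empty site tables.
#' @return A data.table of class `distance_classification` with columns
#'   `category`, `count`, `fraction` (fractions over replicate-1 sites,
#'   summing to 1).
#' @export
classify_replicate_distances <- function(rep1, rep2) {
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) {
    validation_stop("both replicates must be non-empty")
  }
  d <- nearest_point_distance(rep1$contig, rep1$pos, rep2$contig, rep2$pos)
  cat_levels <- c("identical", "within_100bp", "within_200bp", "beyond_200bp")
  category <- fifelse(d == 0, "identical",
                      fifelse(d <= 100, "within_100bp",
                              fifelse(d <= 200, "within_200bp", "beyond_200bp")))
  counts <- table(factor(category, levels = cat_levels))
  out <- data.table(category = cat_levels,
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / nrow(rep1))
  setattr(out, "class", c("distance_classification", class(out)))
  out[]
}
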