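#' @noRd
empty_sites <- function() {
  data.table(contig = character(), pos = integer(), ref = character(),
             alt = character(), strand = character(), coverage = integer(),
             edited = integer(), frac = numeric(), sample = character(),
             replicate = integer())
}

#' @noRd
signature_key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, sep = "\r")

#' Screen the no-enzyme control for editable positions
#'
#' A position is "editable" for a signature (ref > alt) when the matched
#' no-enzyme control shows it as cleanly reference: coverage of at least
#' `control_min_reads`, a reference-base fraction of at least
#' `control_min_ref_frac`, and an edited-base fraction strictly below
#' `control_max_alt_frac`. Because an enzyme's two strand signatures have
#' disjoint reference bases, a position carries at most one signature.
#' SNPs and endogenously edited positions fail this screen, which is why no
#' external variant catalog is needed.
#'
#' @param control [count_matrix()] of the matched no-enzyme control sample.
#' @param enzyme An [enzyme_spec()].
#' @param th A [thresholds()].
#' @return data.table with columns `contig`, `pos`, `ref`, `alt`, `strand`:
#'   the editable positions and the signature each carries.
#' @export
control_editable_positions <- function(control, enzyme, th = thresholds()) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (nrow(enzyme$signatures) == 0L) validation_stop("enzyme has no signatures")
  if (nrow(control) == 0L) {
    qc_warn("control matrix is empty; no position is editable")
    return(data.table(contig = character(), pos = integer(), ref = character(),
                      alt = character(), strand = character()))
  }
  out <- vector("list", nrow(enzyme$signatures))
  for (i in seq_len(nrow(enzyme$signatures))) {
    s <- enzyme$signatures[i]
    refc <- control[[s$ref]]
    altc <- control[[s$alt]]
    cov <- control$coverage
    keep <- cov >= th$control_min_reads &
      refc / cov >= th$control_min_ref_frac &
      altc / cov < th$control_max_alt_frac
    out[[i]] <- data.table(contig = control$contig[keep],
                           pos = control$pos[keep],
                           ref = s$ref, alt = s$alt, strand = s$strand)
  }
  ed <- rbindlist(out)
  setorder(ed, contig, pos)
  ed[]
}

#' Call candidate editing sites in an experimental sample
#'
#' At each control-editable position, a site is emitted when the experimental
#' sample has at least `expt_min_reads` reads, at least `expt_min_edited_reads`
#' reads of the edited base, and an edited-read fraction strictly above
#' `expt_min_edit_frac`. The edited fraction uses total coverage (A+C+G+T) as
#' its denominator. Positions absent from the experimental matrix are silently
#' not callable.
#'
#' A QC warning (class `editscreen_qc`) is raised when the experimental
#' library's `mapped_reads` is known and below `th$min_mapped_reads`:
#' shallow libraries under-detect editing in low-abundance transcripts.
#'
#' @param expt Experimental [count_matrix()] (an RBP-enzyme fusion sample).
#' @param editable Output of [control_editable_positions()] from the same
#'   genome build.
#' @param enzyme An [enzyme_spec()] (recorded on the result).
#' @param th A [thresholds()].
#' @param replicate Integer replicate id recorded on the result.
#' @param warn_depth Set `FALSE` to silence the depth QC warning.
#' @return A site table: data.table with columns `contig`, `pos`, `ref`,
#'   `alt`, `strand`, `coverage`, `edited`, `frac`, `sample`, `replicate`.
#' @export
call_candidate_sites <- function(expt, editable, enzyme, th = thresholds(),
                                 replicate = NA_integer_, warn_depth = TRUE) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  mr <- attr(expt, "mapped_reads")
  if (warn_depth && length(mr) && !is.na(mr) && mr < th$min_mapped_reads) {
    qc_warn(sprintf(
      "library '%s' has %.0f uniquely mapped reads (< %.0f); editing in low-abundance transcripts may be missed",
      attr(expt, "sample_label"), mr, th$min_mapped_reads))
  }
  if (nrow(editable) == 0L || nrow(expt) == 0L) return(empty_sites())
  m <- merge(editable, expt, by = c("contig", "pos"), sort = FALSE)
  if (nrow(m) == 0L) return(empty_sites())
  cols <- as.matrix(m[, .(A, C, G, T)])
  edited <- cols[cbind(seq_len(nrow(m)), match(m$alt, c("A", "C", "G", "T")))]
  cov <- m$coverage
  frac <- edited / cov
  keep <- cov >= th$expt_min_reads &
    edited >= th$expt_min_edited_reads &
    frac > th$expt_min_edit_frac
  sites <- data.table(contig = m$contig[keep], pos = m$pos[keep],
                      ref = m$ref[keep], alt = m$alt[keep],
                      strand = m$strand[keep],
                      coverage = as.integer(cov[keep]),
                      edited = as.integer(edited[keep]),
                      frac = frac[keep],
                      sample = attr(expt, "sample_label"),
                      replicate = as.integer(replicate))
  setorder(sites, contig, pos)
  sites[]
}

#' Blacklist positions edited in enzyme-only controls
#'
#' Positions edited at a fraction of at least `background_edit_frac`
#' (inclusive, matching the published script's 0.01 cutoff) with at least
#' `background_min_reads` coverage in *any* enzyme-only replicate are
#' background: editing there reflects the free enzyme, not RBP binding. The
#' result is the union over replicates and enzyme signatures.
#'
#' @param enzyme_only_reps A list of one or more enzyme-only [count_matrix()]
#'   replicates (a single matrix is accepted).
#' @param enzyme An [enzyme_spec()].
#' @param th A [thresholds()].
#' @return data.table with columns `contig`, `pos`, `ref`, `alt`, `strand`.
#' @export
background_blacklist <- function(enzyme_only_reps, enzyme, th = thresholds()) {
  if (inherits(enzyme_only_reps, "count_matrix")) {
    enzyme_only_reps <- list(enzyme_only_reps)
  }
  if (length(enzyme_only_reps) == 0L) {
    validation_stop("background_blacklist needs >= 1 enzyme-only replicate")
  }
  out <- list()
  for (rep in enzyme_only_reps) {
    if (nrow(rep) == 0L) next
    for (i in seq_len(nrow(enzyme$signatures))) {
      s <- enzyme$signatures[i]
      altc <- rep[[s$alt]]
      cov <- rep$coverage
      keep <- cov >= th$background_min_reads &
        altc / cov >= th$background_edit_frac
      out[[length(out) + 1L]] <- data.table(contig = rep$contig[keep],
                                            pos = rep$pos[keep],
                                            ref = s$ref, alt = s$alt,
                                            strand = s$strand)
    }
  }
  bl <- unique(rbindlist(out))
  if (nrow(bl) == 0L) {
    bl <- data.table(contig = character(), pos = integer(), ref = character(),
                     alt = character(), strand = character())
  }
  setorder(bl, contig, pos)
  bl[]
}

#' Remove blacklisted positions from a site list
#'
#' Drops every site whose (contig, position, signature) appears in the
#' blacklist. Order is preserved; the output is always a subset of the input
#' and the operation is idempotent.
#'
#' @param sites A site table.
#' @param blacklist Output of [background_blacklist()] (or any data.table with
#'   columns `contig`, `pos`, `ref`, `alt`).
#' @return The filtered site table.
#' @export
subtract_blacklist <- function(sites, blacklist) {
  if (nrow(sites) == 0L || nrow(blacklist) == 0L) return(copy(sites))
  sites[!signature_key(sites) %in% signature_key(blacklist)]
}

#' Write a site table
#'
#' Writes the full TSV (all columns) and, when `bed` is given, a
#' BED6-compatible companion: 0-based start, `name = ref>alt|sample`,
#' `score = round(100 * frac)`, strand as inferred from the signature.
#'
#' @param sites A site table.
#' @param path Output TSV path.
#' @param bed Optional BED output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, bed = NULL) {
  fwrite(sites, path, sep = "\t", quote = FALSE)
  if (!is.null(bed)) write_bed(sites_to_intervals(sites), bed)
  invisible(path)
}

#' Read a site table written by [write_sites()]
#' @param path TSV path.
#' @return A site table.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) validation_stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("contig", "ref", "alt", "strand")))
  if (nrow(dt) == 0L) return(empty_sites())
  dt[]
}
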