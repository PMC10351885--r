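#' Deaminase signature specification
#'
#' Describes which base change an editing enzyme leaves on the reference
#' forward strand and how biological replicates should be combined. Libraries
#' prepared with Smart-seq2 are unstranded, so each enzyme carries two
#' signatures: the substrate base read on the forward strand and its
#' complement for transcripts on the minus strand.
#'
#' * `ADAR` (adenosine deaminase, A-to-I read as G): signatures A>G (+) and
#'   T>C (-); replicates merged by exact position (`merge_mode = "exact"`),
#'   reflecting ADAR's tendency to re-edit the same adenosine.
#' * `APOBEC` (cytidine deaminase, C-to-U read as T): signatures C>T (+) and
#'   G>A (-); replicates merged by 100-bp proximity
#'   (`merge_mode = "proximity"`), reflecting APOBEC's dispersed editing of
#'   nearby cytosines.
#'
#' @param name `"ADAR"` or `"APOBEC"`.
#' @param merge_mode Override the default replicate-merge rule
#'   (`"exact"` or `"proximity"`); `NULL` keeps the enzyme default.
#' @return An object of class `enzyme_spec` with elements `name`,
#'   `signatures` (data.table with columns `ref`, `alt`, `strand`) and
#'   `merge_mode`.
#' @examples
#' enzyme_spec("ADAR")
#' enzyme_spec("APOBEC", merge_mode = "exact")
#' @export
enzyme_spec <- function(name = c("ADAR", "APOBEC"), merge_mode = NULL) {
  name <- match.arg(name)
  sig <- switch(name,
    ADAR   = data.table(ref = c("A", "T"), alt = c("G", "C"), strand = c("+", "-")),
    APOBEC = data.table(ref = c("C", "G"), alt = c("T", "A"), strand = c("+", "-"))
  )
  default_mode <- if (name == "ADAR") "exact" else "proximity"
  if (is.null(merge_mode)) merge_mode <- default_mode
  merge_mode <- match.arg(merge_mode, c("exact", "proximity"))
  if (anyDuplicated(sig$ref)) {
    validation_stop("enzyme signatures must have disjoint reference bases")
  }
  structure(list(name = name, signatures = sig, merge_mode = merge_mode),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s (merge: %s)\n", x$name, x$merge_mode))
  cat(sprintf("  %s>%s (%s)\n", x$signatures$ref, x$signatures$alt,
              x$signatures$strand), sep = "")
  invisible(x)
}

#' Pipeline thresholds
#'
#' All numeric cutoffs of the site-identification pipeline in one place.
#' Defaults are the published operating point of the dual-enzyme pipeline:
#'
#' * Control (no-enzyme) editability screen: a position is "editable" when it
#'   has at least `control_min_reads` reads (9), at least
#'   `control_min_ref_frac` (80%) of them the substrate base, and fewer than
#'   `control_max_alt_frac` (0.5%) the edited base. This absorbs SNPs and
#'   endogenous editing without any external catalog.
#' * Experimental calling: at least `expt_min_reads` (20) reads, strictly more
#'   than `expt_min_edit_frac` (6%) of reads edited, and at least
#'   `expt_min_edited_reads` (2) edited reads to rule out single-read
#'   technical errors. The fraction cutoff is configurable (historical runs
#'   used 4-10%).
#' * Enzyme-only background: positions edited at `background_edit_frac`
#'   (>= 1%, inclusive) with `background_min_reads` (20) coverage in any
#'   enzyme-only replicate are blacklisted.
#' * Geometry: `proximity_window` (100 bp) replicate merge window for APOBEC,
#'   `region_flank` (100 bp) site expansion for overlap analysis,
#'   `motif_flank` (50 bp) expansion for motif scans, `shift_3prime` (50 bp)
#'   3'-directed site shift.
#' * `min_mapped_reads` (12e6): libraries below this uniquely-mapped depth
#'   trigger a QC warning (not an error).
#'
#' @param control_min_ref_frac,control_max_alt_frac,control_min_reads Control
#'   screen cutoffs.
#' @param expt_min_reads,expt_min_edit_frac,expt_min_edited_reads Experimental
#'   calling cutoffs.
#' @param background_edit_frac,background_min_reads Enzyme-only blacklist
#'   cutoffs.
#' @param proximity_window,region_flank,motif_flank,shift_3prime Distances, bp.
#' @param min_mapped_reads QC depth threshold (reads).
#' @return An object of class `thresholds` (a validated named list).
#' @examples
#' thresholds()
#' thresholds(expt_min_edit_frac = 0.04) # the 4% sensitivity re-analysis
#' @export
thresholds <- function(control_min_ref_frac = 0.80,
                       control_max_alt_frac = 0.005,
                       control_min_reads = 9L,
                       expt_min_reads = 20L,
                       expt_min_edit_frac = 0.06,
                       expt_min_edited_reads = 2L,
                       background_edit_frac = 0.01,
                       background_min_reads = 20L,
                       proximity_window = 100L,
                       region_flank = 100L,
                       motif_flank = 50L,
                       shift_3prime = 50L,
                       min_mapped_reads = 12e6) {
  th <- list(control_min_ref_frac = control_min_ref_frac,
             control_max_alt_frac = control_max_alt_frac,
             control_min_reads = as.integer(control_min_reads),
             expt_min_reads = as.integer(expt_min_reads),
             expt_min_edit_frac = expt_min_edit_frac,
             expt_min_edited_reads = as.integer(expt_min_edited_reads),
             background_edit_frac = background_edit_frac,
             background_min_reads = as.integer(background_min_reads),
             proximity_window = as.integer(proximity_window),
             region_flank = as.integer(region_flank),
             motif_flank = as.integer(motif_flank),
             shift_3prime = as.integer(shift_3prime),
             min_mapped_reads = as.numeric(min_mapped_reads))
  fracs <- c("control_min_ref_frac", "control_max_alt_frac",
             "expt_min_edit_frac", "background_edit_frac")
  for (f in fracs) {
    if (!is.numeric(th[[f]]) || is.na(th[[f]]) || th[[f]] < 0 || th[[f]] > 1) {
      validation_stop(f, " must be a fraction in [0, 1]")
    }
  }
  counts <- setdiff(names(th), fracs)
  for (f in counts) {
    if (!is.numeric(th[[f]]) || is.na(th[[f]]) || th[[f]] < 0) {
      validation_stop(f, " must be a non-negative number")
    }
  }
  structure(th, class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("<thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
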