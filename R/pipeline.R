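#' Pipeline run configuration
#'
#' Bundles the sample table, enzyme, thresholds and I/O locations for
#' [run_pipeline()]. Samples may be [count_matrix()] objects or TSV paths
#' (read with [read_count_matrix()]).
#'
#' @param control The no-enzyme control sample (exactly one).
#' @param fusion List of 1-2 RBP-fusion replicates.
#' @param enzyme_only Optional list of enzyme-only replicates (background
#'   subtraction is skipped when empty).
#' @param enzyme An [enzyme_spec()] or enzyme name.
#' @param th A [thresholds()] object.
#' @param genome,gtf Optional genome FASTA / annotation GTF for the
#'   site-characterisation stage.
#' @param out_dir Optional output directory for per-stage tables and the
#'   JSON summary.
#' @return A validated `run_config` list.
#' @export
run_config <- function(control, fusion, enzyme_only = list(),
                       enzyme = "ADAR", th = thresholds(),
                       genome = NULL, gtf = NULL, out_dir = NULL) {
  if (is.character(enzyme)) enzyme <- enzyme_spec(enzyme)
  # normalise a sample argument to a list of count matrices / TSV paths
  as_sample_list <- function(x) {
    if (is.null(x)) return(list())
    if (inherits(x, "count_matrix")) return(list(x))
    if (is.character(x)) return(as.list(x))
    if (is.list(x)) return(x)
    validation_stop("samples must be count_matrix objects or TSV paths")
  }
  controls <- as_sample_list(control)
  fusion <- as_sample_list(fusion)
  enzyme_only <- as_sample_list(enzyme_only)
  if (length(controls) != 1L) {
    validation_stop("exactly one control sample is required")
  }
  control <- controls[[1]]
  if (length(fusion) < 1L) validation_stop("at least one fusion replicate is required")
  if (length(fusion) > 2L) validation_stop("at most two fusion replicates are supported")
  structure(list(control = control, fusion = fusion,
                 enzyme_only = enzyme_only, enzyme = enzyme, th = th,
                 genome = genome, gtf = gtf, out_dir = out_dir),
            class = "run_config")
}

#' @noRd
as_count_matrix <- function(x, label) {
  if (inherits(x, "count_matrix")) return(x)
  if (is.character(x)) return(read_count_matrix(x, sample_label = label))
  validation_stop("sample must be a count_matrix or a TSV path")
}

#' Run the full site-identification pipeline
#'
#' Executes, in order: control editability screen, per-replicate candidate
#' calling, replicate merging under the enzyme's rule (exact for ADAR,
#' proximity for APOBEC; skipped with a single replicate), enzyme-only
#' background blacklisting and subtraction, and (when genome + annotation are
#' configured) site characterisation. Per-stage site counts are collected in
#' a machine-readable summary; with `out_dir` set, each stage's table plus
#' `summary.json` are written there. The pipeline is deterministic: rerunning
#' on identical inputs reproduces every output byte-for-byte.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list: `sites` (final site table), `candidates` (per-replicate
#'   lists), `merged`, `editable`, `blacklist`, `summary` (stage counts),
#'   and `annotation` (characterisation results, when configured).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  control <- as_count_matrix(config$control, "control")
  fusion <- lapply(seq_along(config$fusion), function(i)
    as_count_matrix(config$fusion[[i]], sprintf("fusion_rep%d", i)))
  enzyme_only <- lapply(seq_along(config$enzyme_only), function(i)
    as_count_matrix(config$enzyme_only[[i]], sprintf("enzyme_only_rep%d", i)))
  th <- config$th; enz <- config$enzyme

  editable <- control_editable_positions(control, enz, th)
  say("editable positions: %d", nrow(editable))

  candidates <- lapply(seq_along(fusion), function(i)
    call_candidate_sites(fusion[[i]], editable, enz, th, replicate = i))
  for (i in seq_along(candidates)) {
    say("candidate sites, replicate %d: %d", i, nrow(candidates[[i]]))
  }

  merged <- if (length(candidates) == 2L) {
    if (enz$merge_mode == "exact") {
      merge_exact(candidates[[1]], candidates[[2]])
    } else {
      merge_proximity(candidates[[1]], candidates[[2]],
                      window = th$proximity_window)
    }
  } else candidates[[1]]
  say("replicate-merged sites (%s): %d", enz$merge_mode, nrow(merged))

  if (length(enzyme_only)) {
    blacklist <- background_blacklist(enzyme_only, enz, th)
    final <- subtract_blacklist(merged, blacklist)
  } else {
    blacklist <- background_blacklist(list(control[0]), enz, th)
    final <- copy(merged)
  }
  say("blacklisted positions: %d; final sites: %d", nrow(blacklist), nrow(final))

  summary <- list(
    n_editable = nrow(editable),
    n_candidates = lapply(seq_along(candidates),
                          function(i) nrow(candidates[[i]])),
    n_merged = nrow(merged),
    n_blacklist = nrow(blacklist),
    n_final = nrow(final),
    enzyme = enz$name, merge_mode = enz$merge_mode,
    sites_per_million = if (!is.na(mapped_reads(fusion[[1]])))
      normalize_per_million(nrow(final), mapped_reads(fusion[[1]])) else NULL)

  annotation <- NULL
  if (!is.null(config$gtf) && !is.null(config$genome) && nrow(final)) {
    models <- if (inherits(config$gtf, "transcript_models")) config$gtf
              else read_transcript_models(config$gtf)
    genome <- load_genome(config$genome)
    spt <- sites_per_transcript(final, models)
    ctx <- withCallingHandlers(
      triplet_context(final, genome),
      editscreen_qc = function(w) invokeRestart("muffleWarning"))
    rd <- read_feature_distribution(control, models)
    enr <- feature_fold_enrichment(final, models, rd)
    annotation <- list(sites_per_transcript = spt, context = ctx,
                       read_distribution = rd, enrichment = enr)
    summary$sites_per_transcript_mean <- spt$summary$mean
    summary$n_target_transcripts <- spt$summary$n_targets
  }

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    fwrite(editable, file.path(d, "editable.tsv"), sep = "\t")
    for (i in seq_along(candidates)) {
      write_sites(candidates[[i]], file.path(d, sprintf("candidates_rep%d.tsv", i)))
    }
    write_sites(merged, file.path(d, "merged.tsv"),
                bed = file.path(d, "merged.bed"))
    fwrite(blacklist, file.path(d, "blacklist.tsv"), sep = "\t")
    write_sites(final, file.path(d, "sites.tsv"),
                bed = file.path(d, "sites.bed"))
    jsonlite::write_json(summary, file.path(d, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(sites = final, candidates = candidates, merged = merged,
       editable = editable, blacklist = blacklist, summary = summary,
       annotation = annotation)
}
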