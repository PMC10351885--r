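# Small worlds keep the unit suite fast; the full stated world (200
# transcripts, 500 sites) is exercised in test-acceptance.R.
small <- sim_params(n_transcripts = 12L, n_truth_sites = 40L,
                    n_background_sites = 30L)

test_that("simulate_reference is deterministic and writes identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_reference(small, 5L, dir = d1)
  r2 <- simulate_reference(small, 5L, dir = d2)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  # a different seed produces a different genome
  r3 <- simulate_reference(small, 6L)
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("emitted GTF reproduces the models and the UTR partition", {
  d <- withr::local_tempdir()
  ref <- simulate_reference(small, 7L, dir = d)
  back <- read_transcript_models(file.path(d, "annotation.gtf"))
  expect_equal(back$exons[, .(transcript_id, contig, strand, start, end)],
               ref$models$exons[, .(transcript_id, contig, strand, start, end)])
  # exonic base shares per feature follow utr_fractions (0.2 / 0.5 / 0.3)
  ex <- back$exons
  shares <- sapply(unique(ex$transcript_id), function(tid) {
    e <- ex[transcript_id == tid]
    pos <- unlist(Map(seq, e$start, e$end))
    f <- editscreen:::assign_feature(back, rep(e$contig[1], length(pos)), pos)
    as.numeric(table(factor(f, c("5UTR", "CDS", "3UTR")))) / length(pos)
  })
  expect_true(all(abs(shares[1, ] - 0.2) < 0.01))
  expect_true(all(abs(shares[2, ] - 0.5) < 0.01))
  expect_true(all(abs(shares[3, ] - 0.3) < 0.01))
})

test_that("n_transcripts = 0 yields empty but valid outputs", {
  d <- withr::local_tempdir()
  ref <- simulate_reference(sim_params(n_transcripts = 0L), 1L, dir = d)
  expect_equal(length(ref$genome), 0L)
  expect_null(ref$models)
  expect_true(file.exists(file.path(d, "genome.fa")))
  expect_identical(readLines(file.path(d, "annotation.gtf")), character(0))
})

test_that("infeasible parameters fail fast", {
  expect_error(sim_params(utr_fractions = c(0.6, 0.5)), "sum below 1")
  expect_error(sim_params(seq_error_rate = 1.5), "in \\[0, 1\\]")
})

test_that("zero noise means zero alternative counts in control and enzyme-only", {
  p0 <- sim_params(n_transcripts = 6L, n_truth_sites = 20L,
                   seq_error_rate = 0, background_rate = 0,
                   n_background_sites = 0L)
  ref <- simulate_reference(p0, 9L)
  truth <- simulate_truth(ref, p0, 9L)
  cnt <- simulate_counts(ref, truth, p0, 9L)
  alt_mass <- function(m) {
    base <- editscreen:::exonic_positions(ref)$base
    tot <- m$A + m$C + m$G + m$T
    refc <- as.matrix(m[, .(A, C, G, T)])[
      cbind(seq_len(nrow(m)), match(base, c("A", "C", "G", "T")))]
    sum(tot - refc)
  }
  expect_equal(alt_mass(cnt$control), 0L)
  expect_equal(alt_mass(cnt$enzyme_only[[1]]), 0L)
  expect_equal(alt_mass(cnt$enzyme_only[[2]]), 0L)
  expect_gt(alt_mass(cnt$fusion[[1]]), 0L)
})

test_that("planted alt fractions follow the binomial moments", {
  p <- sim_params(n_transcripts = 40L, n_truth_sites = 500L,
                  coverage_mean = 100, truth_edit_frac = 0.2,
                  seq_error_rate = 0)
  ref <- simulate_reference(p, 11L)
  truth <- simulate_truth(ref, p, 11L)
  cnt <- simulate_counts(ref, truth, p, 11L)
  fus <- cnt$fusion[[1]]
  m <- merge(truth[, .(contig, pos, alt)], fus, by = c("contig", "pos"))
  altc <- as.matrix(m[, .(A, C, G, T)])[
    cbind(seq_len(nrow(m)), match(m$alt, c("A", "C", "G", "T")))]
  obs <- altc / m$coverage
  se <- sqrt(0.2 * 0.8 / 100) / sqrt(nrow(m))
  expect_lt(abs(mean(obs) - 0.2), 3 * se)
})

test_that("the whole simulate chain is seed-deterministic", {
  ref <- simulate_reference(small, 3L)
  t1 <- simulate_truth(ref, small, 3L)
  t2 <- simulate_truth(ref, small, 3L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  c1 <- simulate_counts(ref, t1, small, 3L)
  c2 <- simulate_counts(ref, t2, small, 3L)
  expect_identical(as.data.frame(c1$fusion[[2]]), as.data.frame(c2$fusion[[2]]))
  expect_identical(as.data.frame(c1$enzyme_only[[1]]),
                   as.data.frame(c2$enzyme_only[[1]]))
})

test_that("context whitelist restricts planted sites to matching triplets", {
  p <- sim_params(n_transcripts = 20L, n_truth_sites = 60L,
                  enzyme = enzyme_spec("APOBEC"),
                  context_whitelist = c("ACA", "ACT", "TCA", "TCT"))
  ref <- simulate_reference(p, 15L)
  truth <- simulate_truth(ref, p, 15L)
  expect_true(all(truth$triplet %in% c("ACA", "ACT", "TCA", "TCT")))
  prof <- triplet_context(truth[, .(contig, pos, strand)], ref$genome)
  expect_equal(sum(prof[triplet %in% c("ACA", "ACT", "TCA", "TCT"), fraction]), 1)
})

test_that("evaluate_calls scores precision/recall with tolerance", {
  truth <- simulate_truth(simulate_reference(small, 19L), small, 19L)
  as_called <- truth[, .(contig, pos, ref, alt, strand, coverage = 100L,
                         edited = 20L, frac = edit_frac, sample = "x",
                         replicate = 1L)]
  ev <- evaluate_calls(as_called, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$mean_frac_error, 0)
  ev0 <- evaluate_calls(editscreen:::empty_sites(), truth)
  expect_true(is.nan(ev0$precision))
  expect_equal(ev0$recall, 0)
  # jittered calls scored with a window match the brute-force count
  set.seed(1)
  jit <- copy(as_called)[, pos := pos + sample(-120:120, .N, TRUE)]
  ev100 <- evaluate_calls(jit, truth, tolerance = 100L)
  d <- bf_nearest_points(truth$contig, truth$pos, jit$contig, jit$pos)
  expect_equal(ev100$recall, mean(d <= 100))
})

test_that("pipeline on clean synthetic data recovers the planted truth", {
  p0 <- sim_params(n_transcripts = 20L, n_truth_sites = 80L,
                   seq_error_rate = 0, background_rate = 0.05)
  ref <- simulate_reference(p0, 23L)
  truth <- simulate_truth(ref, p0, 23L)
  cnt <- simulate_counts(ref, truth, p0, 23L)
  res <- suppressWarnings(run_pipeline(
    run_config(cnt$control, cnt$fusion, cnt$enzyme_only, enzyme = p0$enzyme),
    quiet = TRUE))
  ev <- evaluate_calls(res$sites, truth)
  # with zero sequencing error nothing blocks the planted sites and nothing
  # else can be called
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})
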