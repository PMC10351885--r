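th <- thresholds()
adar <- enzyme_spec("ADAR")
apobec <- enzyme_spec("APOBEC")

test_that("control editability applies the three printed criteria", {
  ctl <- make_cm("c", 1:5,
                 A = c(10L, 8L, 8L, 160L, 200L),
                 G = c(0L, 1L, 0L, 0L, 1L),
                 T = c(0L, 1L, 0L, 40L, 0L))
  ed <- control_editable_positions(ctl, adar, th)
  # pos 1: clean A pile -> editable; pos 2: alt frac 0.1; pos 3: coverage 8;
  # pos 4: ref frac 0.8 exactly -> editable; pos 5: alt frac 1/201 < 0.005
  expect_setequal(ed[ref == "A", pos], c(1L, 4L, 5L))
})

test_that("editability boundaries sit exactly where the methods place them", {
  # coverage 8 vs 9
  ctl <- make_cm("c", 1:2, A = c(8L, 9L))
  expect_equal(control_editable_positions(ctl, adar, th)[ref == "A", pos], 2L)
  # ref frac 0.79 vs 0.80 (coverage 100)
  ctl <- make_cm("c", 1:2, A = c(79L, 80L), C = c(21L, 20L))
  expect_equal(control_editable_positions(ctl, adar, th)[ref == "A", pos], 2L)
  # alt frac 0.004 vs 0.005 (coverage 1000)
  ctl <- make_cm("c", 1:2, A = c(996L, 995L), G = c(4L, 5L))
  expect_equal(control_editable_positions(ctl, adar, th)[ref == "A", pos], 1L)
})

test_that("experimental calling applies coverage, fraction and edited-read rules", {
  ed <- data.table(contig = "c", pos = 1:6, ref = "A", alt = "G", strand = "+")
  expt <- make_cm("c", 1:6,
                  A = c(18L, 19L, 17L, 18L, 93L, 470L),
                  G = c(2L, 1L, 2L, 2L, 7L, 30L),
                  C = c(0L, 0L, 0L, 1L, 0L, 0L))
  # pos1: cov 20, frac 0.10 -> site; pos2: frac 0.05 -> no; pos3: cov 19 -> no
  # pos4: cov 21, frac 2/21=0.095 -> site; pos5: frac 0.07 -> site
  # pos6: frac 0.06 exactly -> NOT > 0.06 -> no
  s <- quiet_call(expt, ed, adar, th)
  expect_equal(s$pos, c(1L, 4L, 5L))
  expect_equal(s[pos == 1L, frac], 0.1)
  # edited-read rule: 1 edited read at 6.7% never passes
  expt2 <- make_cm("c", 1L, A = c(14L), G = c(1L))
  expect_equal(nrow(quiet_call(expt2, ed, adar, th)), 0L)
})

test_that("calling equals a brute-force evaluator on random matrices", {
  for (seed in c(5L, 6L)) {
    ctl <- random_cm(800L, seed)
    expt <- random_cm(800L, seed + 100L)
    for (enz in list(adar, apobec)) {
      ed <- control_editable_positions(ctl, enz, th)
      expect_equal(sig_key(ed), sig_key(brute_editable(ctl, enz, th)))
      got <- quiet_call(expt, ed, enz, th)
      want <- brute_call(expt, ed, th)
      expect_equal(sig_key(got), sig_key(want))
      if (nrow(got)) {
        cmp <- merge(got, want, by = c("contig", "pos", "ref", "alt"))
        expect_equal(cmp$edited.x, cmp$edited.y)
        expect_equal(cmp$coverage.x, cmp$coverage.y)
      }
    }
  }
})

test_that("background blacklist is inclusive at 1% and unions replicates", {
  r1 <- make_cm("c", 1:3, C = c(196L, 99L, 9L), T = c(4L, 1L, 1L))
  r2 <- make_cm("c", 3L, C = 500L, T = 10L)
  bl <- background_blacklist(list(r1, r2), apobec, th)
  # pos1 frac 0.02; pos2 frac exactly 0.01 (inclusive); pos3 only via rep2
  expect_setequal(bl[ref == "C", pos], 1:3)
  bl1 <- background_blacklist(list(r1), apobec, th)
  expect_false(3L %in% bl1[ref == "C", pos])
  expect_error(background_blacklist(list(), apobec, th), "replicate")
  expect_equal(sig_key(bl), sig_key(brute_blacklist(list(r1, r2), apobec, th)))
})

test_that("blacklist subtraction is an order-preserving set difference", {
  sites <- make_sites("chr1", c(100L, 200L, 50L))
  bl <- data.table(contig = "chr1", pos = 200L, ref = "A", alt = "G",
                   strand = "+")
  out <- subtract_blacklist(sites, bl)
  expect_equal(out$pos, c(50L, 100L))
  expect_equal(subtract_blacklist(sites, bl[0]), sites)        # empty blacklist
  expect_equal(subtract_blacklist(out, bl), out)               # idempotent
  bl_all <- data.table(contig = "chr1", pos = c(50L, 100L, 200L),
                       ref = "A", alt = "G", strand = "+")
  expect_equal(nrow(subtract_blacklist(sites, bl_all)), 0L)
  # different signature at the same position is kept
  bl_other <- data.table(contig = "chr1", pos = 100L, ref = "T", alt = "C")
  expect_equal(nrow(subtract_blacklist(sites, bl_other)), 3L)
})

test_that("raising thresholds never increases the site count", {
  ctl <- random_cm(2000L, 7L)
  expt <- random_cm(2000L, 8L)
  ed <- control_editable_positions(ctl, adar, th)
  n_prev <- Inf
  for (cut in c(0.04, 0.06, 0.08, 0.10)) {
    n <- nrow(quiet_call(expt, ed, adar, thresholds(expt_min_edit_frac = cut)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_reads <- vapply(c(10L, 20L, 40L), function(r)
    nrow(quiet_call(expt, ed, adar, thresholds(expt_min_reads = r))), 0L)
  expect_true(all(diff(n_reads) <= 0))
})

test_that("a shallow library triggers the depth QC warning", {
  ed <- data.table(contig = "c", pos = 1L, ref = "A", alt = "G", strand = "+")
  expt <- make_cm("c", 1L, A = 90L, G = 10L, mapped_reads = 1e6)
  expect_warning(call_candidate_sites(expt, ed, adar, th),
                 class = "editscreen_qc")
  expect_no_warning(call_candidate_sites(expt, ed, adar, th,
                                         warn_depth = FALSE))
})
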