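models <- tiny_models()

test_that("feature assignment is strand-aware and majority-voted", {
  # txP (+): 5'UTR 101-140, CDS 141-200 & 301-360, 3'UTR 361-400
  # txM (-): 5'UTR 341-400, CDS 161-340, 3'UTR 101-160
  got <- editscreen:::assign_feature(
    models,
    c("cP", "cP", "cP", "cP", "cM", "cM", "cM"),
    c(120L, 150L, 330L, 380L, 350L, 200L, 120L))
  expect_equal(got, c("5UTR", "CDS", "CDS", "3UTR", "5UTR", "CDS", "3UTR"))
  # intronic / intergenic positions have no feature
  expect_true(is.na(editscreen:::assign_feature(models, "cP", 250L)))
})

test_that("sites_per_transcript counts exonic containment", {
  s <- make_sites("cP", c(120L, 150L, 380L))
  res <- sites_per_transcript(s, models)
  expect_equal(res$per_transcript$n_sites, 3L)
  expect_equal(res$summary$mean, 3)
  # intron-only site targets nothing
  res2 <- sites_per_transcript(make_sites("cP", 250L), models)
  expect_equal(res2$summary$n_targets, 0L)
  # random placement equals a brute-force containment scan
  set.seed(13)
  pos <- sample(1:450, 60L, replace = FALSE)
  s3 <- make_sites("cP", sort(pos))
  want <- sum(vapply(pos, function(p)
    (p >= 101 & p <= 200) | (p >= 301 & p <= 400), TRUE))
  res3 <- sites_per_transcript(s3, models)
  expect_equal(if (nrow(res3$per_transcript)) res3$per_transcript$n_sites else 0L,
               want)
})

test_that("rank-sum test: frozen exact examples", {
  expect_equal(rank_sum_test(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))$p.value, 0.1)
  x <- c(0.1, 0.25, 0.3, 0.4)
  expect_equal(rank_sum_test(x, x)$p.value, 1)
  expect_equal(rank_sum_test(x, x)$method, "exact")
})

test_that("rank-sum exact path equals full enumeration (with and without ties)", {
  set.seed(17)
  cases <- list(
    list(x = runif(4), y = runif(6)),
    list(x = runif(8), y = runif(5)),
    list(x = sample(1:4, 6, TRUE) / 10, y = sample(1:4, 7, TRUE) / 10),  # ties
    list(x = rep(0.2, 5), y = c(rep(0.2, 3), 0.5, 0.6)))                 # heavy ties
  for (cs in cases) {
    expect_equal(rank_sum_test(cs$x, cs$y)$p.value, bf_ranksum(cs$x, cs$y),
                 tolerance = 1e-12)
  }
  # tie-free exact path also matches stats::wilcox.test's exact p
  x <- runif(9); y <- runif(10)
  expect_equal(rank_sum_test(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("rank-sum normal approximation matches the reference implementation", {
  set.seed(18)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(rank_sum_test(x, y)$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  xt <- sample(1:5, 40, TRUE); yt <- sample(1:5, 35, TRUE)   # tie correction
  expect_equal(rank_sum_test(xt, yt)$p.value,
               wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  # p decreases with effect size
  p_small <- rank_sum_test(rnorm(50), rnorm(50, 0.2))$p.value
  p_large <- rank_sum_test(rnorm(50), rnorm(50, 2.0))$p.value
  expect_lt(p_large, p_small)
})

test_that("editing_fraction_stats reports moments and the rank-sum p", {
  a <- make_sites("c", 1:3, frac = c(0.1, 0.2, 0.3))
  b <- make_sites("c", 4:6, frac = c(0.7, 0.8, 0.9))
  st <- editing_fraction_stats(a, b)
  expect_equal(st$mean_a, 0.2)
  expect_equal(st$median_b, 0.8)
  expect_equal(st$p.value, 0.1)
  expect_error(editing_fraction_stats(a, make_sites(character(0), integer(0))),
               "non-empty")
})

test_that("triplet context follows the transcribed strand", {
  g <- Biostrings::DNAStringSet(c(g1 = "TTAGCT"))
  plus <- make_sites("g1", 3L, ref = "A", alt = "G", strand = "+")
  expect_equal(triplet_context(plus, g)$triplet, "TAG")
  minus <- make_sites("g1", 3L, ref = "A", alt = "G", strand = "-")
  expect_equal(triplet_context(minus, g)$triplet, "CTA")
  # terminal sites are skipped with a QC warning and counted
  edge <- make_sites("g1", c(1L, 3L))
  expect_warning(prof <- triplet_context(edge, g), class = "editscreen_qc")
  expect_equal(attr(prof, "skipped"), 1L)
  expect_equal(sum(prof$fraction), 1)
})

test_that("fold enrichment is site_fraction / read_fraction with a proportion test", {
  set.seed(29)
  s <- make_sites("cP", c(365L, 367L, 369L, 372L, 380L,
                          150L, 151L, 152L, 120L, 121L))
  feats <- editscreen:::assign_feature(models, s$contig, s$pos)
  sf <- as.numeric(table(factor(feats, c("5UTR", "CDS", "3UTR")))) / length(feats)
  rd <- c("5UTR" = 0.25, "CDS" = 0.5, "3UTR" = 0.25)
  fd <- feature_fold_enrichment(s, models, rd)
  expect_equal(fd$site_fraction, sf)
  expect_equal(fd$fold_enrichment, sf / as.numeric(rd))
  expect_equal(sum(fd$site_fraction), 1)
  # null case: read distribution equal to the site distribution
  fd0 <- feature_fold_enrichment(s, models, setNames(sf, names(rd)))
  expect_equal(fd0$fold_enrichment, rep(1, 3))
  expect_true(all(fd0$p_value > 0.9))
  # strong 3'UTR planting is significant
  s3 <- make_sites("cP", sample(361:400, 200, replace = TRUE))
  fd3 <- feature_fold_enrichment(s3, models, rd)
  expect_gt(fd3[feature == "3UTR", fold_enrichment], 1)
  expect_lt(fd3[feature == "3UTR", p_value], 0.01)
  expect_lt(fd3[feature == "CDS", fold_enrichment], 1)
  # zero read fraction with observed sites -> Inf fold, p = 0
  fdz <- feature_fold_enrichment(s3, models, c("5UTR" = 0.5, "CDS" = 0.5,
                                               "3UTR" = 0))
  expect_equal(fdz[feature == "3UTR", fold_enrichment], Inf)
  expect_equal(fdz[feature == "3UTR", p_value], 0)
})

test_that("read_feature_distribution computes coverage shares over features", {
  m <- make_cm("cP", c(120L, 150L, 380L), A = c(10L, 30L, 60L))
  rd <- read_feature_distribution(m, models)
  expect_equal(as.numeric(rd), c(0.1, 0.3, 0.6))
  expect_equal(sum(rd), 1)
})

test_that("3' shifting follows the exon chain, clamps, and flags orphans", {
  # + strand: site at genomic 350 (tx coord 150 of 200) + 50 -> transcript end
  s <- make_sites("cP", 350L)
  sh <- shift_toward_3prime(s, models, 50L)
  expect_equal(sh$pos, 400L)
  expect_true(sh$shifted)
  expect_equal(sh$host_transcript, "txP")
  # CDS -> 3'UTR reclassification across the junction
  s2 <- make_sites("cP", 195L)   # tx coord 95, CDS
  sh2 <- shift_toward_3prime(s2, models, 50L)
  expect_equal(sh2$pos, 345L)    # lands in exon 2 (tx coord 145), still CDS
  sh2b <- shift_toward_3prime(s2, models, 120L)
  expect_equal(editscreen:::assign_feature(models, "cP", sh2b$pos), "3UTR")
  # clamp at the 3' terminus
  expect_equal(shift_toward_3prime(make_sites("cP", 395L), models, 50L)$pos, 400L)
  # minus strand: genomic coordinate decreases
  sm <- shift_toward_3prime(make_sites("cM", 300L), models, 50L)
  expect_equal(sm$pos, 250L)
  # shift 0 is the identity
  expect_equal(shift_toward_3prime(s, models, 0L)$pos, 350L)
  # site outside any transcript is flagged, not moved
  orphan <- shift_toward_3prime(make_sites("cP", 250L), models, 50L)
  expect_equal(orphan$pos, 250L)
  expect_false(orphan$shifted)
})

test_that("per-million normalisation is exact arithmetic", {
  expect_equal(normalize_per_million(30000, 15e6), 2000)
  expect_equal(normalize_per_million(0, 5e6), 0)
  expect_equal(normalize_per_million(1, 1e6), 1)
  expect_error(normalize_per_million(10, 0), "> 0")
})

test_that("motif_fraction scans both strands of region sequences", {
  g <- Biostrings::DNAStringSet(c(m1 = "ACGTGTGTGTAC",
                                  m2 = "AAAAAAAAAAAA",
                                  m3 = "TTACACACACTT"))
  iv <- genomic_intervals(c("m1", "m2"), 0L, 12L)
  expect_equal(motif_fraction(iv, g)$fraction, 0.5)
  # reverse-strand occurrence (ACACAC on the forward strand) counts
  expect_equal(motif_fraction(genomic_intervals("m3", 0L, 12L), g)$fraction, 1)
  expect_error(motif_fraction(iv, g, ""), "non-empty")
  # planted-truth recovery
  set.seed(23)
  # A/T-only background cannot contain GTGTGT on either strand
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "T"), 60, TRUE), collapse = ""), "")
  planted <- sort(sample(40, 15))
  for (i in planted) {
    seqs[i] <- paste0(substr(seqs[i], 1, 20), "GTGTGT",
                      substr(seqs[i], 27, 60))
  }
  gg <- Biostrings::DNAStringSet(setNames(seqs, paste0("r", 1:40)))
  ivv <- genomic_intervals(paste0("r", 1:40), 0L, 60L)
  res <- motif_fraction(ivv, gg)
  expect_equal(which(res$matched), planted)
  expect_equal(res$fraction, 15 / 40)
})
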