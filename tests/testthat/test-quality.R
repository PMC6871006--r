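uvig_of_length <- function(L, id = "u1", phred = NULL) {
  uv <- group_contigs_to_uvigs(contig_set(id, rand_seq(L)))[[1]]
  uv$uvig_id <- id
  uv$read_quality_phred <- phred
  uv
}

test_that("expected length is the taxon mean with CV = sd/mean", {
  tab <- data.frame(taxon = c("T", "T"), rank = "genus",
                    length_bp = c(50000, 50000))
  e <- expected_length("T", tab)
  expect_equal(e$mean_length, 50000)
  expect_equal(e$cv, 0)
  expect_false(e$homogeneity_warning)

  tab2 <- data.frame(taxon = c("T", "T"), rank = "genus",
                     length_bp = c(40000, 60000))
  e2 <- expected_length("T", tab2)
  expect_equal(e2$mean_length, 50000)
  # hand arithmetic: sd of {40000, 60000} = sqrt(2*10000^2/1) = 14142.14
  expect_equal(e2$cv, sqrt(2 * 10000^2 / 1) / 50000, tolerance = 1e-12)
  expect_true(e2$homogeneity_warning)

  unknown <- expected_length("nope", tab)
  expect_equal(unknown$n, 0)
  expect_true(is.na(unknown$mean_length))
})

test_that("length_cv_report flags heterogeneous taxa and skips singletons", {
  tab <- data.frame(
    taxon = c("A", "A", "B", "B", "C"), rank = "genus",
    length_bp = c(40000, 40000, 30000, 70000, 12345))
  rep <- length_cv_report(tab)
  expect_equal(rep$cv[rep$taxon == "A"], 0)
  expect_false(rep$flagged[rep$taxon == "A"])
  expect_true(rep$flagged[rep$taxon == "B"])
  expect_true(is.na(rep$cv[rep$taxon == "C"]))
  expect_equal(rep$n[rep$taxon == "C"], 1)
})

test_that("completeness routes: termini > integration site > reference > none", {
  set.seed(31)
  tab <- data.frame(taxon = "T", rank = "genus", length_bp = 50000)

  # reference route: plain arithmetic
  uv <- uvig_of_length(45000)
  cmp <- estimate_completeness(uv, taxon = "T", table = tab)
  expect_equal(cmp$method, "reference_length")
  expect_equal(cmp$completeness_pct, 90)
  expect_false(cmp$predicted_complete)

  # DTR wins over the reference route
  r <- rand_seq(30)
  circ <- contig_set("c", paste0(r, rand_seq(4000), r))
  uvc <- group_contigs_to_uvigs(circ)[[1]]
  cmp2 <- estimate_completeness(uvc, detect_termini(circ), taxon = "T",
                                table = tab)
  expect_equal(cmp2$method, "dtr")
  expect_true(cmp2$predicted_complete)
  expect_true(is.na(cmp2$completeness_pct))

  # integration-site flag
  cmp3 <- estimate_completeness(uv, integration_site = TRUE)
  expect_equal(cmp3$method, "integration_site")
  expect_true(cmp3$predicted_complete)

  # nothing available
  cmp4 <- estimate_completeness(uv)
  expect_equal(cmp4$method, "none")
  expect_true(is.na(cmp4$completeness_pct))
  expect_false(cmp4$predicted_complete)
})

test_that("tier rules: >=90% drafts, undetermined fragments, phred gate", {
  set.seed(32)
  tab <- data.frame(taxon = "T", rank = "genus", length_bp = 50000)
  uv92 <- uvig_of_length(46000)
  t92 <- classify_quality(uv92, estimate_completeness(uv92, taxon = "T",
                                                      table = tab))
  expect_equal(t92$tier, "high_quality_draft")

  uvna <- uvig_of_length(46000)
  tna <- classify_quality(uvna, estimate_completeness(uvna))
  expect_equal(tna$tier, "genome_fragment")
  expect_match(paste(tna$rationale, collapse = " "), "no genome size")

  # single-read UViG at 95% completeness but phred 19 stays a fragment
  uvp <- uvig_of_length(47500, phred = 19)
  tp <- classify_quality(uvp, estimate_completeness(uvp, taxon = "T",
                                                    table = tab))
  expect_equal(tp$tier, "genome_fragment")
  expect_match(paste(tp$rationale, collapse = " "), "phred")

  uvp2 <- uvig_of_length(47500, phred = 30)
  expect_equal(classify_quality(
    uvp2, estimate_completeness(uvp2, taxon = "T", table = tab))$tier,
    "high_quality_draft")
})

test_that("finished needs single gapless contig, completeness and curation", {
  set.seed(33)
  r <- rand_seq(25)
  circ <- contig_set("c", paste0(r, rand_seq(30000), r))
  uvc <- group_contigs_to_uvigs(circ)[[1]]
  cmp <- estimate_completeness(uvc, detect_termini(circ))
  all_flags <- curation_flags(TRUE, TRUE, TRUE)

  expect_equal(classify_quality(uvc, cmp, all_flags)$tier, "finished")
  # missing curation drops to draft
  expect_equal(classify_quality(uvc, cmp)$tier, "high_quality_draft")

  # an N-run >= 10 counts as a gap and disqualifies finished
  gappy <- contig_set("g", paste0(r, rand_seq(15000), strrep("N", 12),
                                  rand_seq(15000), r))
  uvg <- group_contigs_to_uvigs(gappy)[[1]]
  cmpg <- estimate_completeness(uvg, detect_termini(gappy))
  tg <- classify_quality(uvg, cmpg, all_flags)
  expect_equal(tg$tier, "high_quality_draft")
  expect_match(paste(tg$rationale, collapse = " "), "gap")
})

test_that("tier assignment is total and monotone in completeness", {
  set.seed(34)
  uv <- uvig_of_length(10000)
  tiers <- c("genome_fragment", "high_quality_draft", "finished")
  rank_of <- function(pct) {
    cmp <- structure(list(uvig_id = "u1", method = "reference_length",
                          expected_length = 10000, observed_length = 10000,
                          completeness_pct = pct, predicted_complete = FALSE,
                          homogeneity_warning = FALSE, notes = character(0)),
                     class = "completeness_estimate")
    match(classify_quality(uv, cmp)$tier, tiers)
  }
  grid <- seq(0, 100, by = 0.5)
  ranks <- vapply(grid, rank_of, integer(1))
  expect_true(all(!is.na(ranks)))
  expect_true(all(diff(ranks) >= 0))
})

test_that("truncated genomes recover their true fraction exactly", {
  set.seed(35)
  n <- 200
  fracs <- runif(n, 0.2, 1)
  src_len <- sample(20000:60000, n, TRUE)
  for (i in seq_len(n)) {
    obs <- round(fracs[i] * src_len[i])
    uv <- list(uvig_id = "u", total_length = obs,
               contigs = data.frame(id = "c", sequence = "ACGT",
                                    length = obs),
               read_quality_phred = NULL, metadata = list())
    class(uv) <- "uvig"
    tab <- data.frame(taxon = "T", rank = "genus", length_bp = src_len[i])
    cmp <- estimate_completeness(uv, taxon = "T", table = tab)
    expect_equal(cmp$completeness_pct, 100 * obs / src_len[i],
                 tolerance = 1e-12)
    expect_lt(abs(cmp$completeness_pct - 100 * fracs[i]), 0.1 + 100 / src_len[i])
  }
})

test_that("phred 20 corresponds to 99% base-call accuracy", {
  expect_equal(phred_to_accuracy(20), 99)
  expect_equal(phred_to_accuracy(10), 90)
  expect_error(phred_to_accuracy(-1))
})

test_that("implausibly short circular contigs are flagged", {
  tab <- data.frame(taxon = "T", rank = "genus", length_bp = 40000)
  expect_warning(res <- circular_plausibility(5000, "T", tab), "partial")
  expect_false(res$plausible)

  ok <- circular_plausibility(39000, "T", tab)
  expect_true(ok$plausible)

  unk <- circular_plausibility(5000)
  expect_true(unk$plausible)
  expect_match(unk$note, "unverifiable")
})
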