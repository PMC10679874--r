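test_that("generation is fully deterministic under (seed, scenario)", {
  p1 <- make_panel(15, c(40, 60), seed = 5)
  p2 <- make_panel(15, c(40, 60), seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_panel(15, c(40, 60), seed = 6)))

  sc <- scenario_easy()
  t1 <- make_transcriptome(p1, sc, seed = 3)
  t2 <- make_transcriptome(p1, sc, seed = 3)
  expect_identical(t1, t2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synth_make(d1, "easy", seed = 4, n_genes = 8, length_range = c(40, 60))
  synth_make(d2, "easy", seed = 4, n_genes = 8, length_range = c(40, 60))
  for (f in c("panel.fa", "ngs.fa", "flreads.fa", "contigs.fa", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("adding a gene never shifts another gene's sequences", {
  pA <- make_panel(10, c(40, 60), seed = 9)
  pB <- make_panel(12, c(40, 60), seed = 9)
  expect_identical(pA$sequences, pB$sequences[1:10])
})

test_that("panel lengths respect the requested range", {
  p <- make_panel(50, c(33, 47), seed = 12)
  lens <- nchar(p$sequences)
  expect_true(all(lens >= 33 & lens <= 47))
  expect_true(all(substr(p$sequences, 1, 1) == "M"))
})

test_that("evolve_orthologue follows the binomial substitution model", {
  prot <- random_aa(1000)
  expect_identical(evolve_orthologue(prot, 0, seed = 1), prot)
  ev <- evolve_orthologue(prot, 0.3, seed = 2)
  expect_equal(nchar(ev), 1000)
  ndiff <- sum(strsplit(prot, "")[[1]] != strsplit(ev, "")[[1]])
  # within 3 sigma of Binomial(1000, 0.3)
  expect_lt(abs(ndiff - 300), 3 * sqrt(1000 * 0.3 * 0.7))
  # different seeds diverge from each other
  expect_false(identical(ev, evolve_orthologue(prot, 0.3, seed = 3)))
})

test_that("back-translation is exact under re-translation", {
  prot <- random_aa(120)
  cds <- back_translate(prot)
  tf <- translate_six_frames(cds)
  expect_equal(tf$peptide[tf$frame == 1], paste0(prot, "*"))
})

test_that("sl_prevalence 1 puts the leader on every full-length read", {
  p <- make_panel(12, c(40, 60), seed = 21)
  sc <- scenario_easy(sl_prevalence = 1, present_fraction = 1)
  tr <- make_transcriptome(p, sc, seed = 21)
  expect_true(all(startsWith(unname(tr$fl), sc$sl_seq)))
  expect_true(all(tr$truth$sl_added))
})

test_that("chimera_rate 0 produces no chimeras and no chimera flags", {
  p <- make_panel(12, c(60, 90), seed = 22)
  sc <- scenario_easy(chimera_rate = 0)
  tr <- make_transcriptome(p, sc, seed = 22)
  expect_equal(nrow(tr$chimera_truth), 0)
  r <- reciprocal_assign(tr$ngs, p)
  flags <- vapply(names(tr$ngs), function(tid)
    flag_chimera(r$hsps[[tid]], panel = p)$flagged, logical(1))
  expect_false(any(flags))  # zero false positives on honest transcripts
})

test_that("truth table is internally consistent with the emitted records", {
  p <- make_panel(15, c(40, 60), seed = 23)
  tr <- make_transcriptome(p, scenario_easy(), seed = 23)
  for (i in seq_len(nrow(tr$truth))) {
    gid <- tr$truth$panel_id[i]
    have <- sum(startsWith(names(tr$ngs), paste0("tx_", gid)))
    if (tr$truth$present[i]) expect_equal(have, tr$truth$copy_count[i])
    else expect_equal(have, 0)
  }
  # every chimera row has a record and vice versa
  expect_setequal(tr$chimera_truth$record_id,
                  grep("chimera", names(tr$ngs), value = TRUE))
})

test_that("empirical SL fraction at 0.727 falls inside its Wilson band", {
  p <- make_panel(2000, c(30, 40), seed = 24)
  sc <- scenario_easy(sl_prevalence = 0.727, present_fraction = 1,
                      divergence = 0, two_copy_rate = 0, chimera_rate = 0,
                      n_background = 0, utr_range = c(10, 20))
  tr <- make_transcriptome(p, sc, seed = 25)
  frac <- mean(tr$truth$sl_added)
  ci <- wilson_ci(sum(tr$truth$sl_added), nrow(tr$truth))
  expect_true(ci["low"] <= 0.727 && 0.727 <= ci["high"])
  expect_lt(abs(frac - 0.727), 0.05)
})

test_that("make_genome splits the CDS with GT..AG introns as recorded", {
  p <- make_panel(3, c(100, 140), seed = 26)
  it <- setNames(c(0, 3), p$entries$id[1:2])
  gen <- make_genome(p, it, seed = 26)
  expect_equal(nrow(gen$truth), 2)
  expect_equal(gen$truth$intron_count, c(0, 3))
  # contig for the intronless gene contains the CDS verbatim
  cds <- back_translate(p$sequences[[p$entries$id[1]]])
  expect_true(grepl(cds, gen$contigs[[paste0("contig_", p$entries$id[1])]],
                    fixed = TRUE))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
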