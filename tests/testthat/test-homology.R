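test_that("six-frame translation covers both strands with N and stop handling", {
  tf <- translate_six_frames("ATG")
  expect_equal(tf$peptide[tf$frame == 1], "M")
  expect_equal(tf$peptide[tf$frame == 2], "")  # too short

  tf2 <- translate_six_frames("ATGNNNTAA")
  expect_equal(tf2$peptide[tf2$frame == 1], "MX*")

  # frame peptide lengths follow floor((n - offset) / 3)
  set.seed(8)
  for (i in 1:5) {
    n <- sample(20:70, 1)
    nt <- random_dna(n)
    tf <- translate_six_frames(nt)
    for (f in 1:3) {
      expect_equal(nchar(tf$peptide[tf$frame == f]), (n - (f - 1)) %/% 3)
      expect_equal(nchar(tf$peptide[tf$frame == -f]), (n - (f - 1)) %/% 3)
    }
    # frame -1 equals independent reverse-complement + translate
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    L <- nchar(rc) - nchar(rc) %% 3
    ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(rc, 1, L)), no.init.codon = TRUE))
    expect_equal(tf$peptide[tf$frame == -1], ref)
  }

  expect_error(translate_six_frames("ATXG"), "invalid nucleotide")
})

test_that("translated_search finds an exact back-translated protein on top", {
  set.seed(21)
  db <- setNames(vapply(1:6, function(i) random_aa(60), ""),
                 paste0("p", 1:6))
  tx <- back_translate(db[["p3"]])
  hits <- translated_search(tx, db, e_max = 1e-6, transcript_id = "t1")
  expect_gt(length(hits), 0)
  expect_equal(hits[[1]]$subject_id, "p3")
  expect_equal(hits[[1]]$identity_fraction, 1.0)
  expect_equal(hits[[1]]$frame, 1L)
  # sorted by ascending evalue
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  expect_equal(ev, sort(ev))
})

test_that("E-value acceptance is strictly less than the threshold", {
  set.seed(22)
  db <- setNames(list(a = random_aa(50))["a"], "a")
  tx <- back_translate(db[["a"]])
  hits <- translated_search(tx, unlist(db), e_max = 1e-6)
  ev <- hits[[1]]$evalue
  # re-running with e_max equal to the hit's own evalue must reject it
  hits2 <- translated_search(tx, unlist(db), e_max = ev)
  expect_false(any(vapply(hits2, `[[`, numeric(1), "evalue") == ev))
})

test_that("dinucleotide-shuffled transcript yields no hit at 1e-6", {
  set.seed(23)
  prot <- random_aa(80)
  tx <- back_translate(prot)
  # shuffle dinucleotides (fixed seed)
  pairs <- substring(tx, seq(1, nchar(tx) - 1, 2), seq(2, nchar(tx), 2))
  shuf <- paste(sample(pairs), collapse = "")
  hits <- translated_search(shuf, c(p = prot), e_max = 1e-6)
  expect_length(hits, 0)
})

test_that("reciprocal_assign recovers constructed orthologues exactly", {
  set.seed(31)
  panel <- make_panel(5, c(60, 90), seed = 31)
  decoys <- make_decoys(5, c(60, 90), seed = 32)
  txs <- setNames(vapply(panel$entries$id, function(id)
    back_translate(panel$sequences[[id]]), ""),
    paste0("tx_", panel$entries$id))
  r <- reciprocal_assign(txs, panel, decoys)
  status <- vapply(r$calls, `[[`, character(1), "status")
  expect_true(all(status == "found"))
  expect_length(r$decoy_assignments, 0)
  # each transcript assigned to its own entry
  expect_equal(r$assignments$panel_id,
               sub("^tx_", "", r$assignments$transcript_id))
})

test_that("reciprocal_assign on an empty transcript set marks all absent", {
  panel <- make_panel(4, c(40, 60), seed = 7)
  r <- reciprocal_assign(character(0), panel)
  expect_true(all(vapply(r$calls, `[[`, character(1), "status") == "absent"))
  expect_true(all(vapply(r$calls, `[[`, numeric(1), "copy_count") == 0))
})

test_that("decoy ids colliding with panel member ids are rejected", {
  panel <- make_panel(3, c(40, 50), seed = 9)
  bad <- setNames("MKL", panel$entries$id[1])
  expect_error(reciprocal_assign(character(0), panel, bad), "disjoint")
})

test_that("copy-number clustering separates diverged copies, merges identical ones", {
  set.seed(41)
  panel <- make_panel(1, c(80, 80), seed = 41)
  id <- panel$entries$id[1]
  cds <- back_translate(panel$sequences[[id]])
  # identical duplicates -> one copy
  txs <- c(t1 = cds, t2 = cds)
  r <- reciprocal_assign(txs, panel)
  r <- call_copy_number(r, txs, 0.95)
  expect_equal(r$calls[[id]]$copy_count, 1)
  # ~80% identity copies at threshold 0.95 -> two copies
  t2 <- spliceopanel:::with_seed(5, spliceopanel:::mutate_nt(cds, 0.2))
  txs2 <- c(t1 = cds, t2 = t2)
  r2 <- reciprocal_assign(txs2, panel)
  r2 <- call_copy_number(r2, txs2, 0.95)
  expect_equal(r2$calls[[id]]$copy_count, 2)
  # single transcript -> one copy
  r3 <- call_copy_number(reciprocal_assign(txs2[1], panel), txs2[1], 0.95)
  expect_equal(r3$calls[[id]]$copy_count, 1)
})

test_that("HSP tables are outfmt-6 shaped with 1-based inclusive coordinates", {
  h <- local_align_protein("MKLVFAGH", "MKLVFAGH")
  h$query_id <- "q"; h$subject_id <- "s"
  tab <- spliceopanel:::hsp_table(list(h))
  expect_named(tab, c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore", "frame"))
  expect_equal(tab$qstart, 1); expect_equal(tab$qend, 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hsp_table(list(h), f)
  expect_equal(nrow(read.delim(f)), 1)
})
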