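test_that("find_orfs handles construction examples", {
  o <- find_orfs("ATGAAATAG", min_aa = 1)
  fwd <- o[o$frame == 1, ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$end - fwd$start, 9)     # 3 codons incl. stop
  expect_equal(fwd$aa_length, 2)
  expect_true(fwd$has_start && fwd$has_stop)

  expect_equal(nrow(find_orfs(strrep("C", 120), min_aa = 1)), 0)

  # stop-less 3'-open span
  o2 <- find_orfs("ATGAAAAAAAAA", min_aa = 1)
  expect_true(any(o2$frame == 1 & !o2$has_stop))
})

test_that("find_orfs equals the exhaustive codon-walk oracle on random 300-mers", {
  set.seed(51)
  for (rep in 1:5) {
    nt <- random_dna(300)
    got <- find_orfs(nt, min_aa = 5)
    want <- oracle_orfs(nt, min_aa = 5)
    expect_equal(nrow(got), length(want))
    if (nrow(got) > 0) {
      key_got <- sort(paste(got$frame, got$aa_length, got$has_stop))
      key_want <- sort(vapply(want, function(w)
        paste(w$frame, w$aa_length, w$has_stop), ""))
      expect_equal(key_got, key_want)
    }
  }
})

test_that("intactness classification uses the inclusive coverage boundary", {
  orf <- list(has_start = TRUE, has_stop = TRUE, aa_length = 80)
  expect_true(classify_intactness(orf, panel_len = 100, min_cov = 0.8))
  expect_false(classify_intactness(orf, panel_len = 101, min_cov = 0.8))
  orf$has_stop <- FALSE
  expect_false(classify_intactness(orf, 100, 0.8))
  orf$has_stop <- TRUE; orf$has_start <- FALSE
  expect_false(classify_intactness(orf, 100, 0.8))
})

test_that("platform reconciliation reproduces the published class fixture", {
  # fixture mirroring the printed intactness classes 118 / 40 / 2 / 9
  # (the source's own arithmetic is internally inconsistent by one:
  #  118 + 40 + 2 + 9 = 169 against a stated universe of 168)
  genes <- sprintf("g%03d", 1:169)
  ngs <- setNames(rep(FALSE, 169), genes)
  fl <- setNames(rep(FALSE, 169), genes)
  ngs[1:118] <- TRUE; fl[1:118] <- TRUE        # both
  ngs[119:158] <- TRUE                          # ngs_only (40)
  fl[159:160] <- TRUE                           # fl_only (2)
  r <- reconcile_platforms(ngs, fl)
  expect_equal(unname(r$tally),
               c(118L, 40L, 2L, 9L))
  expect_equal(sum(r$tally), 169L)
  expect_error(reconcile_platforms(ngs, fl[-1]), "mismatched")
})

test_that("reconciliation tallies always sum to the universe (property)", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(0:50, 1)
    genes <- paste0("g", seq_len(n))
    ngs <- setNames(sample(c(TRUE, FALSE), n, TRUE), genes)
    fl <- setNames(sample(c(TRUE, FALSE), n, TRUE), genes)
    r <- reconcile_platforms(ngs, fl)
    expect_equal(sum(r$tally), n)
    expect_true(all(r$records$panel_id == genes))
  }
})

test_that("chimera flagging fires on fusions and spares honest transcripts", {
  set.seed(61)
  panel <- make_panel(6, c(80, 120), seed = 61)
  ids <- panel$entries$id
  cds_a <- back_translate(panel$sequences[[ids[1]]])
  cds_b <- back_translate(panel$sequences[[ids[2]]])
  bp <- floor(nchar(cds_a) / 2)
  fusion <- paste0(substr(cds_a, 1, bp),
                   substr(cds_b, floor(nchar(cds_b) / 2) + 1, nchar(cds_b)))
  hsps <- translated_search(fusion, panel$sequences, e_max = 1e-6,
                            transcript_id = "fusion")
  fc <- flag_chimera(hsps, panel = panel)
  expect_true(fc$flagged)
  expect_lte(abs(fc$breakpoint - bp), 30)
  expect_setequal(fc$subjects, ids[1:2])

  # single-subject transcripts never flagged
  hsps1 <- translated_search(cds_a, panel$sequences, transcript_id = "t")
  expect_false(flag_chimera(hsps1, panel = panel)$flagged)

  # members of the same paralogue group never flagged
  pg <- panel
  pg$groups <- list(gX = ids[1:2])
  pg$entries$paralogue_group[1:2] <- "gX"
  expect_false(flag_chimera(hsps, panel = pg)$flagged)
})

test_that("contig projection reports coverage with a strict majority rule", {
  set.seed(71)
  panel <- make_panel(1, c(160, 160), seed = 71)
  prot <- panel$sequences[[1]]
  cds <- back_translate(prot, stop = FALSE)
  # contig with the full uninterrupted CDS
  pr <- project_to_contig("p", prot, c(full = cds))
  expect_equal(pr[["full"]]$covered_fraction, 1.0)
  expect_true(pr[["full"]]$majority_single_contig)
  expect_equal(pr[["full"]]$exon_count, 1)

  # contig with exactly half the CDS: coverage 0.5 is NOT a majority
  half <- substr(cds, 1, 3 * (nchar(prot) %/% 2))
  pr2 <- project_to_contig("p", prot, c(half = half))
  expect_equal(pr2[["half"]]$covered_fraction, 0.5)
  expect_false(pr2[["half"]]$majority_single_contig)

  # absent protein -> empty result
  pr3 <- project_to_contig("p", random_aa(120), c(full = cds))
  expect_length(pr3, 0)
})

test_that("exon chains recover generator truth for 0-7 introns", {
  panel <- make_panel(2, c(150, 200), seed = 3)
  for (k in c(0, 2, 5, 7)) {
    gen <- make_genome(panel, intron_table = setNames(k, panel$entries$id[1]),
                       seed = 100 + k)
    pr <- project_to_contig(panel$entries$id[1], panel$sequences[[1]],
                            gen$contigs)
    expect_equal(pr[[1]]$exon_count, k + 1, info = paste("introns", k))
    expect_length(pr[[1]]$intron_ranges, k)
    if (k > 0) expect_true(all(pr[[1]]$introns_gt_ag))
  }
})

test_that("introns shorter than min_intron are merged into one exon", {
  panel <- make_panel(1, c(150, 170), seed = 5)
  gen <- make_genome(panel, intron_table = setNames(1, panel$entries$id[1]),
                     seed = 5, intron_len_range = c(12, 20))
  pr <- project_to_contig(panel$entries$id[1], panel$sequences[[1]],
                          gen$contigs, min_intron = 30)
  expect_equal(pr[[1]]$exon_count, 1)
})

test_that("projection exports well-formed GFF3", {
  panel <- make_panel(1, c(140, 160), seed = 6)
  gen <- make_genome(panel, intron_table = setNames(2, panel$entries$id[1]),
                     seed = 6)
  pr <- project_to_contig(panel$entries$id[1], panel$sequences[[1]],
                          gen$contigs)
  f <- withr::local_tempfile(fileext = ".gff3")
  projection_to_gff3(pr, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  types <- vapply(strsplit(body, "\t"), `[[`, "", 3)
  expect_equal(sum(types == "gene"), 1)
  expect_equal(sum(types == "exon"), 3)
})
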