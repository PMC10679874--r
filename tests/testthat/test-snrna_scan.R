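make_unit <- function(seed = 91, len = 180) {
  spliceopanel:::with_seed(seed, random_dna(len))
}

test_that("scan_contigs finds an exact query copy with identity 1", {
  unit <- make_unit()
  contig <- paste0(random_dna(200), unit, random_dna(200))
  sc <- scan_contigs(c(c1 = contig), c(speciesA = unit))
  expect_equal(sc$status, "ok")
  expect_equal(sc$successful_query, "speciesA")
  expect_equal(nrow(sc$hits), 1)
  expect_equal(sc$hits$identity_fraction, 1.0)
  expect_equal(sc$hits$start, 200)
  expect_equal(sc$hits$hit_length, 180)
  expect_equal(sc$hits$strand, "+")
})

test_that("queries are tried in order and failures recorded", {
  unit <- make_unit(92)
  contig <- paste0(random_dna(150), unit, random_dna(150))
  queries <- c(far1 = spliceopanel:::with_seed(1, random_dna(180)),
               far2 = spliceopanel:::with_seed(2, random_dna(180)),
               matching = unit)
  sc <- scan_contigs(c(c1 = contig), queries)
  expect_equal(sc$successful_query, "matching")
  expect_equal(sc$failed_queries, c("far1", "far2"))

  # empty contig set
  sc0 <- scan_contigs(setNames(character(0), character(0)), queries)
  expect_equal(sc0$status, "all queries failed")
})

test_that("minus-strand copies are reported in forward coordinates", {
  unit <- make_unit(93)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  contig <- paste0(random_dna(100), rc, random_dna(100))
  sc <- scan_contigs(c(c1 = contig), c(q = unit))
  expect_equal(sc$hits$strand, "-")
  expect_equal(sc$hits$start, 100)
  expect_equal(sc$hits$end, 100 + nchar(unit))
})

test_that("tandem arrays are called from generator fixtures across sizes", {
  unit <- make_unit(94)
  panel <- make_panel(1, c(40, 50), seed = 94)
  for (copies in c(2, 5, 12)) {
    gen <- make_genome(panel, intron_table = setNames(integer(0), character(0)),
                       snrna_unit = unit, tandem_copies = copies,
                       spacer_range = c(100, 700), seed = copies)
    sc <- scan_contigs(gen$contigs, c(q = unit))
    arr <- find_tandem_arrays(sc$hits, max_spacer = 1000)
    expect_length(arr, 1)
    expect_equal(arr[[1]]$copy_count, copies)
    expect_length(arr[[1]]$spacings, copies - 1)
    expect_true(all(arr[[1]]$spacings <= 1000))
  }
  # minus-strand array
  gen <- make_genome(panel, intron_table = setNames(integer(0), character(0)),
                     snrna_unit = unit, tandem_copies = 4,
                     spacer_range = c(200, 400), seed = 9,
                     array_strand = "-")
  sc <- scan_contigs(gen$contigs, c(q = unit))
  arr <- find_tandem_arrays(sc$hits, 1000)
  expect_length(arr, 1)
  expect_equal(arr[[1]]$strand, "-")
  expect_equal(arr[[1]]$copy_count, 4)
})

test_that("single hits and opposite strands never form arrays", {
  hits1 <- data.frame(contig_id = "c", query_id = "q", start = 10, end = 100,
                      strand = "+", identity_fraction = 1, evalue = 0,
                      hit_length = 90)
  expect_length(find_tandem_arrays(hits1, 1000), 0)
  hits2 <- rbind(hits1, within(hits1, { start <- 400; end <- 490
                                        strand <- "-" }))
  expect_length(find_tandem_arrays(hits2, 1000), 0)
  # spacing beyond max_spacer breaks the run
  hits3 <- rbind(hits1, within(hits1, { start <- 2000; end <- 2090 }))
  expect_length(find_tandem_arrays(hits3, 1000), 0)
})

test_that("motif annotation matches patterns within windows", {
  seq <- paste0(random_dna(30), "AATTTTTGG", random_dna(30))
  cfg <- data.frame(motif_name = "Sm site", pattern = "RATTTTTGR",
                    window_start = NA, window_end = NA)
  set.seed(1)
  m <- annotate_motifs(seq, cfg)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 30)
  expect_equal(m$end, 39)

  # absent pattern
  m2 <- annotate_motifs(strrep("C", 60),
                        data.frame(motif_name = "x", pattern = "AAAA"))
  expect_equal(nrow(m2), 0)

  # invalid IUPAC symbol
  expect_error(annotate_motifs(seq, data.frame(motif_name = "x",
                                               pattern = "AXX")),
               "invalid IUPAC")

  # window restricts match starts
  cfg3 <- data.frame(motif_name = "Sm site", pattern = "RATTTTTGR",
                     window_start = 1, window_end = 10)
  expect_equal(nrow(annotate_motifs(seq, cfg3)), 0)
})

test_that("degenerate patterns equal the sliding-window oracle", {
  set.seed(95)
  for (rep in 1:5) {
    seq <- random_dna(150)
    pat <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N", "W"), 6,
                        replace = TRUE), collapse = "")
    got <- annotate_motifs(seq, data.frame(motif_name = "m", pattern = pat))
    want <- oracle_motif(seq, pat)
    expect_equal(nrow(got), length(want), info = pat)
    if (nrow(got) > 0)
      expect_equal(got$start, vapply(want, `[[`, 0L, 1))
  }
})

test_that("helix complementarity counts Watson-Crick and wobble pairs", {
  expect_equal(helix_complementarity("ACGU", "ACGU"), 1)  # self-reverse pairs
  expect_equal(helix_complementarity("AAAA", "CCCC"), 0)
  expect_equal(helix_complementarity("GGGG", "UUUU"), 1)  # G-U wobble
  expect_error(helix_complementarity("ACG", "AC"), "length mismatch")
  # hand enumeration: ACGU vs reversed UGCA -> A:A no, C:C no, G:G no, U:U no
  expect_equal(helix_complementarity("ACGU", "ACGU"), 1)
  u2 <- "AUGAUC"; u6 <- "GAUCAU"
  a <- strsplit(gsub("U", "T", u2), "")[[1]]
  b <- rev(strsplit(gsub("U", "T", u6), "")[[1]])
  hand <- mean(paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG"))
  expect_equal(helix_complementarity(u2, u6), hand)
})

test_that("hits export as BED with 0-based starts preserved", {
  unit <- make_unit(96)
  contig <- paste0(random_dna(50), unit, random_dna(50))
  sc <- scan_contigs(c(c1 = contig), c(q = unit))
  f <- withr::local_tempfile(fileext = ".bed")
  hits_to_bed(sc$hits, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 50)          # BED start is 0-based
  expect_equal(bed$V3, 50 + nchar(unit))
  expect_equal(bed$V6, "+")
})
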