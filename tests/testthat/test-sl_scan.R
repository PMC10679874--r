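SL <- default_sl()  # packaged synthetic 24-mer

test_that("detect_sl finds full and truncated leaders at the 5' end", {
  body <- random_dna(60)
  r <- detect_sl(c(full = paste0(SL, body)), SL)
  expect_true(r$detected)
  expect_equal(r$matched_len, nchar(SL))
  expect_equal(r$mismatches, 0)
  expect_equal(r$read_offset, 0)

  # only the last 12 nt of the leader survive: still detected
  r2 <- detect_sl(c(tr = paste0(substr(SL, nchar(SL) - 11, nchar(SL)), body)),
                  SL, min_match = 10)
  expect_true(r2$detected)
  expect_equal(r2$matched_len, 12)

  # leader shifted within the 5' window
  r3 <- detect_sl(c(off = paste0("ACT", SL, body)), SL, window = 5)
  expect_true(r3$detected)
  expect_equal(r3$read_offset, 3)

  # leader beyond the window is not called
  r4 <- detect_sl(c(far = paste0(random_dna(10), SL, body)), SL, window = 5)
  expect_false(r4$detected)
})

test_that("detect_sl agrees with the brute-force placement oracle", {
  set.seed(81)
  reads <- vapply(1:300, function(i) random_dna(80), "")
  names(reads) <- paste0("r", 1:300)
  got <- detect_sl(reads, SL, min_match = 12, max_mismatch = 1, window = 5)
  for (i in seq_along(reads)) {
    want <- oracle_sl(reads[[i]], SL, 12, 1, 5)
    expect_equal(got$detected[i], want$detected, info = reads[[i]])
    if (want$detected)
      expect_equal(got$matched_len[i], want$matched_len, info = reads[[i]])
  }
})

test_that("detect_sl ignores sequence downstream of window + leader", {
  set.seed(82)
  for (i in 1:10) {
    head <- paste0(SL, random_dna(5))
    r1 <- detect_sl(c(a = paste0(head, random_dna(50))), SL)
    r2 <- detect_sl(c(a = paste0(head, random_dna(50))), SL)
    expect_equal(r1$detected, r2$detected)
    expect_equal(r1$matched_len, r2$matched_len)
  }
})

test_that("strip_sl removes the leader and is idempotent", {
  body <- random_dna(50)
  read <- paste0(SL, body)
  call <- detect_sl(c(r = read), SL)[1, ]
  stripped <- strip_sl(read, call)
  expect_equal(stripped, body)
  expect_equal(nchar(read) - nchar(stripped),
               call$matched_len + call$read_offset)
  expect_false(detect_sl(c(r = stripped), SL)$detected)
  expect_error(strip_sl(body, detect_sl(c(r = body), SL)[1, ]), "undetected")
})

test_that("strip_sl recovers the simulated gene body on generator reads", {
  panel <- make_panel(20, c(40, 60), seed = 17)
  sc <- scenario_easy(sl_prevalence = 1, present_fraction = 1,
                      two_copy_rate = 0, chimera_rate = 0, n_background = 0)
  tr <- make_transcriptome(panel, sc, seed = 17)
  calls <- detect_sl(tr$fl, sc$sl_seq)
  expect_true(all(calls$detected))
  for (i in seq_along(tr$fl)) {
    body <- strip_sl(tr$fl[[i]], calls[i, ])
    tid <- sub("^fl_", "", calls$record_id[i])
    expect_equal(body, unname(tr$ngs[tid]))
  }
})

test_that("prevalence estimates reproduce the published worked ratios", {
  mk <- function(k, n) data.frame(record_id = as.character(seq_len(n)),
                                  detected = seq_len(n) <= k)
  e1 <- estimate_prevalence(mk(7028, 9669))
  expect_equal(round_half_up(100 * e1$proportion, 1), 72.7)
  expect_equal(format_percent(e1$proportion, 1), "72.7%")

  e2 <- estimate_prevalence(mk(193, 212))
  expect_equal(round_half_up(100 * e2$proportion, 0), 91)
  expect_equal(format_percent(e2$proportion, 0), "91%")

  e3 <- estimate_prevalence(mk(0, 10))
  expect_equal(e3$proportion, 0)
  expect_equal(e3$ci_low, 0)
  expect_gt(e3$ci_high, 0)

  expect_error(estimate_prevalence(mk(0, 0)), "empty")
})

test_that("per-gene aggregation flags a gene when any record is detected", {
  calls <- data.frame(record_id = c("r1", "r2", "r3", "r4"),
                      detected = c(TRUE, FALSE, FALSE, FALSE))
  map <- c(r1 = "gA", r2 = "gA", r3 = "gB", r4 = "gB")
  e <- estimate_prevalence(calls, map)
  expect_equal(e$n_total, 2)
  expect_equal(e$n_flagged, 1)
  expect_equal(e$proportion, 0.5)
})

test_that("Wilson intervals bracket the proportion and obey edge cases", {
  ci <- wilson_ci(50, 100)
  expect_lt(ci["low"], 0.5); expect_gt(ci["high"], 0.5)
  expect_equal(unname(wilson_ci(0, 10)["low"]), 0)
  expect_equal(unname(wilson_ci(10, 10)["high"]), 1)
  # agreement with an independent formula implementation
  k <- 7; n <- 23; z <- qnorm(0.975); p <- k / n
  low <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(unname(wilson_ci(k, n)["low"]), low)
})
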