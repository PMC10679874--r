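# Independent oracles: plain-R reimplementations used only to check the
# package's compiled/vectorized paths on small inputs.

# Full affine-gap DP, textbook three-matrix form, no optimizations.
oracle_score <- function(a, b, scheme, local = FALSE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEGI <- -1e9
  H <- matrix(0, n + 1, m + 1); E <- matrix(NEGI, n + 1, m + 1)
  F <- matrix(NEGI, n + 1, m + 1)
  if (!local) {
    for (j in seq_len(m)) H[1, j + 1] <- -(go + ge * j)
    for (i in seq_len(n)) H[i + 1, 1] <- -(go + ge * i)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, E[i, j + 1] - ge)
    F[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, F[i + 1, j] - ge)
    h <- max(H[i, j] + scheme$matrix[A[i], B[j]],
             E[i + 1, j + 1], F[i + 1, j + 1])
    if (local) h <- max(h, 0)
    H[i + 1, j + 1] <- h
  }
  if (local) max(H) else H[n + 1, m + 1]
}

# Exhaustive codon walk over all six frames.
oracle_orfs <- function(nt, min_aa) {
  nt <- toupper(nt)
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]),
              collapse = "")
  gc <- Biostrings::GENETIC_CODE
  res <- list()
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    s <- if (fr > 0) nt else rc
    off <- abs(fr) - 1
    L <- nchar(s) - off; L <- L - L %% 3
    if (L < 3) next
    codons <- substring(s, seq(off + 1, off + L, 3), seq(off + 3, off + L + 2, 3))
    aa <- unname(gc[codons]); aa[is.na(aa)] <- "X"
    i <- 1
    while (i <= length(aa)) {
      if (aa[i] == "M") {
        j <- i
        while (j <= length(aa) && aa[j] != "*") j <- j + 1
        has_stop <- j <= length(aa)
        aa_len <- (if (has_stop) j - 1 else length(aa)) - i + 1
        if (aa_len >= min_aa)
          res[[length(res) + 1]] <- list(frame = fr, codon_start = i,
                                         aa_length = aa_len,
                                         has_stop = has_stop)
        i <- if (has_stop) j + 1 else length(aa) + 1
      } else if (aa[i] == "*") i <- i + 1
      else i <- i + 1
    }
  }
  res
}

# Brute-force SL suffix placement scan.
oracle_sl <- function(read, sl, min_match, max_mismatch, window) {
  read <- toupper(read); sl <- toupper(sl)
  ls <- nchar(sl)
  for (len in seq(ls, min_match)) {
    for (off in 0:window) {
      if (off + len > nchar(read)) next
      suf <- substring(sl, ls - len + 1, ls)
      seg <- substring(read, off + 1, off + len)
      mm <- sum(strsplit(suf, "")[[1]] != strsplit(seg, "")[[1]])
      if (mm <= max_mismatch)
        return(list(detected = TRUE, matched_len = len, mismatches = mm,
                    read_offset = off))
    }
  }
  list(detected = FALSE, matched_len = 0L)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Sliding-window IUPAC match enumeration (0-based half-open ranges).
oracle_motif <- function(seq, pattern) {
  seq <- toupper(gsub("U", "T", toupper(seq)))
  pat <- strsplit(toupper(gsub("U", "T", toupper(pattern))), "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  out <- list()
  np <- length(pat)
  for (i in seq_len(length(sc) - np + 1)) {
    ok <- all(vapply(seq_len(np), function(k)
      sc[i + k - 1] %in% IUPAC_SETS[[pat[k]]], logical(1)))
    if (ok) out[[length(out) + 1]] <- c(i - 1L, i + np - 1L)
  }
  out
}

random_aa <- function(n, alphabet = spliceopanel:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
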