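#' Find open reading frames in all six frames
#'
#' Reports every maximal ATG-to-stop span of at least `min_aa` codons
#' (excluding the stop) in each of the six frames, plus stop-less 3'-open
#' spans (first ATG after the last stop, running to the frame end) flagged
#' `has_stop = FALSE`. Within one stop-to-stop segment the first ATG opens
#' the (maximal) ORF.
#'
#' @param nt nucleotide sequence.
#' @param min_aa minimum ORF length in amino acids (>= 1), stop excluded.
#' @param transcript_id id recorded on the annotations.
#' @return data.frame with columns `transcript_id`, `frame`, `start`, `end`
#'   (0-based half-open on the forward strand, stop codon included when
#'   present), `aa_length`, `has_start`, `has_stop`.
#' @export
find_orfs <- function(nt, min_aa = 30, transcript_id = "tx") {
  stopifnot(min_aa >= 1)
  nt <- check_nucleotide(nt)
  frames <- translate_six_frames(nt)
  L <- nchar(nt)
  out <- list()
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    np <- nchar(pep)
    if (np == 0) next
    ch <- strsplit(pep, "", fixed = TRUE)[[1]]
    stops <- which(ch == "*")
    seg_starts <- c(1L, stops + 1L)
    seg_ends <- c(stops, np)          # segment end = stop position (or frame end)
    for (s in seq_along(seg_starts)) {
      a <- seg_starts[s]; b <- seg_ends[s]
      if (a > b) next
      has_stop <- b %in% stops
      seg <- ch[a:b]
      matg <- which(seg == "M")
      if (length(matg) == 0) next
      start_codon <- a + matg[1] - 1L
      aa_len <- (b - start_codon + 1L) - as.integer(has_stop)
      if (aa_len < min_aa) next
      rng <- frame_to_nt_range(frames$frame[i],
                               c(start_codon - 1L, b), L)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = transcript_id, frame = frames$frame[i],
        start = rng[1], end = rng[2], aa_length = aa_len,
        has_start = TRUE, has_stop = has_stop, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(transcript_id = character(), frame = integer(),
                      start = integer(), end = integer(), aa_length = integer(),
                      has_start = logical(), has_stop = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify an ORF as intact relative to a reference protein length
#'
#' Intact means: has a start codon, has a stop codon, and covers at least
#' `min_cov` of the reference protein length (inclusive boundary).
#'
#' @param orf one row of [find_orfs()] output (or any list with `has_start`,
#'   `has_stop`, `aa_length`).
#' @param panel_len reference protein length in amino acids (>= 1).
#' @param min_cov minimum coverage fraction, default 0.8.
#' @return logical.
#' @export
classify_intactness <- function(orf, panel_len, min_cov = 0.8) {
  stopifnot(panel_len >= 1)
  isTRUE(orf$has_start) && isTRUE(orf$has_stop) &&
    (orf$aa_length / panel_len) >= min_cov
}

#' Reconcile ORF intactness between two sequencing platforms
#'
#' @param ngs named logical vector: intact on the short-read (NGS) assembly.
#' @param fl named logical vector over the same gene universe: intact in
#'   full-length reads.
#' @return list with `records` (data.frame `panel_id`, `intact_class` in
#'   both/ngs_only/fl_only/neither) and `tally` (named integer vector over
#'   the four classes; sums to the universe size).
#' @export
reconcile_platforms <- function(ngs, fl) {
  if (!setequal(names(ngs), names(fl)) || length(ngs) != length(fl))
    stop("mismatched gene universes")
  fl <- fl[names(ngs)]
  cls <- ifelse(ngs & fl, "both",
                ifelse(ngs & !fl, "ngs_only",
                       ifelse(!ngs & fl, "fl_only", "neither")))
  lev <- c("both", "ngs_only", "fl_only", "neither")
  tally <- table(factor(cls, levels = lev))
  list(records = data.frame(panel_id = names(ngs), intact_class = unname(cls),
                            stringsAsFactors = FALSE),
       tally = stats::setNames(as.integer(tally), lev))
}

#' Flag a transcript as a putative assembly chimera
#'
#' A transcript is flagged when two of its HSPs hit different panel entries
#' (different paralogue groups), occupy query ranges that overlap by less
#' than 10\% of the shorter range, and each covers at least
#' `min_segment_cov` of its own subject. This is the signature of a fusion
#' of two near-disjoint gene fragments produced during de novo assembly.
#'
#' @param transcript_hsps list of `hsp` objects, all from one transcript,
#'   with query ranges in transcript nucleotide coordinates.
#' @param min_segment_cov minimum per-segment subject coverage, default 0.25.
#' @param panel optional `panel`; when given, subjects that are members of
#'   the same paralogue group (or the same collapsed entry) never trigger
#'   the flag.
#' @param scheme the [scoring_scheme()] used when trimming each HSP to its
#'   near-optimal core before the overlap test.
#' @return list `flagged` (logical), `breakpoint` (nt position midway
#'   between the two ranges, or `NA`), `subjects` (the two subject ids).
#' @export
flag_chimera <- function(transcript_hsps, min_segment_cov = 0.25,
                         panel = NULL, scheme = scoring_scheme()) {
  no <- list(flagged = FALSE, breakpoint = NA_real_, subjects = character(0))
  if (length(transcript_hsps) < 2) return(no)
  # trim each HSP to its best X-drop core segment: full-DP local alignments
  # over-extend across the fusion junction into the partner gene's region,
  # which would otherwise hide the near-disjoint two-segment signature
  transcript_hsps <- lapply(transcript_hsps, trim_hsp_core, scheme = scheme)
  group_of <- NULL
  if (!is.null(panel)) {
    group_of <- character(0)
    for (id in panel$entries$id)
      group_of[panel$members[[id]]] <- id
    for (g in names(panel$groups))
      group_of[panel$groups[[g]]] <- g
  }
  # keep the best HSP per subject
  subj <- vapply(transcript_hsps, `[[`, character(1), "subject_id")
  best <- transcript_hsps[order(vapply(transcript_hsps, `[[`, numeric(1),
                                       "evalue"))]
  best <- best[!duplicated(vapply(best, `[[`, character(1), "subject_id"))]
  n <- length(best)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    hi <- best[[i]]; hj <- best[[j]]
    if (!is.null(group_of)) {
      gi <- group_of[[hi$subject_id]]; gj <- group_of[[hj$subject_id]]
      if (!is.na(gi) && !is.na(gj) && gi == gj) next
    }
    ri <- hi$query_range; rj <- hj$query_range
    ov <- max(0, min(ri[2], rj[2]) - max(ri[1], rj[1]))
    shorter <- min(ri[2] - ri[1], rj[2] - rj[1])
    if (shorter <= 0 || ov >= 0.1 * shorter) next
    cov_i <- (hi$subject_range[2] - hi$subject_range[1]) / hi$subject_len
    cov_j <- (hj$subject_range[2] - hj$subject_range[1]) / hj$subject_len
    if (cov_i < min_segment_cov || cov_j < min_segment_cov) next
    first <- if (ri[1] <= rj[1]) ri else rj
    second <- if (ri[1] <= rj[1]) rj else ri
    return(list(flagged = TRUE,
                breakpoint = (first[2] + second[1]) / 2,
                subjects = c(hi$subject_id, hj$subject_id)))
  }
  no
}

# Reduce a translated-search HSP to its shortest near-optimal core: the
# shortest column span whose score is within `delta` of the full alignment
# score. Over-extension tails are weakly-positive chance similarity and
# contribute less than delta, so they are dropped; genuine homologous
# extension (steady positive columns) survives. Ranges are mapped back to
# transcript coordinates.
trim_hsp_core <- function(h, scheme, delta = 30) {
  if (is.null(h$peptide_range) || is.null(h$transcript_len)) return(h)
  a <- strsplit(h$a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(h$b_aln, "", fixed = TRUE)[[1]]
  ncol <- length(a)
  if (ncol == 0) return(h)
  colsc <- numeric(ncol)
  for (i in seq_len(ncol)) {
    if (a[i] == "-" || b[i] == "-") {
      open <- i == 1 || (a[i - 1] != "-" && b[i - 1] != "-")
      colsc[i] <- -(if (open) scheme$gap_open + scheme$gap_extend
                    else scheme$gap_extend)
    } else colsc[i] <- scheme$matrix[a[i], b[i]]
  }
  pre <- cumsum(colsc)
  jend <- which(pre >= max(pre) - delta)[1]
  suf <- rev(cumsum(rev(colsc[seq_len(jend)])))
  jstart <- max(which(suf >= max(suf) - delta))
  if (jstart == 1 && jend == ncol) return(h)
  qpos <- cumsum(a != "-"); spos <- cumsum(b != "-")
  h$raw_score <- sum(colsc[jstart:jend])
  h$peptide_range <- h$peptide_range[1] +
    c(if (jstart == 1) 0L else qpos[jstart - 1L], qpos[jend])
  h$subject_range <- h$subject_range[1] +
    c(if (jstart == 1) 0L else spos[jstart - 1L], spos[jend])
  h$query_range <- frame_to_nt_range(h$frame, h$peptide_range,
                                     h$transcript_len)
  h$a_aln <- paste(a[jstart:jend], collapse = "")
  h$b_aln <- paste(b[jstart:jend], collapse = "")
  h
}

# Split one HSP into maximal-scoring sub-segments, cutting wherever the
# running column score drops more than `xdrop` below its maximum (the
# analogue of BLAST's X-drop termination). A full-DP local alignment will
# happily bridge an intron with an affine gap or a frameshifted-junk
# mismatch run; the drop across such a bridge exceeds xdrop, so splitting
# recovers the per-exon HSPs that seeded-extension search would report.
# Operates in the HSP's native (peptide) coordinates.
split_hsp_xdrop <- function(h, scheme, m, n, xdrop = 12) {
  a <- strsplit(h$a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(h$b_aln, "", fixed = TRUE)[[1]]
  ncol <- length(a)
  if (ncol == 0) return(list(h))
  colsc <- numeric(ncol)
  for (i in seq_len(ncol)) {
    if (a[i] == "-" || b[i] == "-") {
      open <- i == 1 || (a[i - 1] != "-" && b[i - 1] != "-")
      colsc[i] <- -(if (open) scheme$gap_open + scheme$gap_extend
                    else scheme$gap_extend)
    } else colsc[i] <- scheme$matrix[a[i], b[i]]
  }
  segs <- list()
  i <- 1L
  while (i <= ncol) {
    if (colsc[i] <= 0) { i <- i + 1L; next }
    s <- 0; smax <- 0; jmax <- i - 1L; j <- i
    while (j <= ncol) {
      s <- s + colsc[j]
      if (s > smax) { smax <- s; jmax <- j }
      if (smax - s > xdrop) break
      j <- j + 1L
    }
    if (jmax >= i) segs[[length(segs) + 1L]] <- c(i, jmax, smax)
    i <- jmax + 1L
  }
  if (length(segs) <= 1) return(list(h))
  qpos <- cumsum(a != "-"); spos <- cumsum(b != "-")
  lapply(segs, function(sg) {
    cols <- sg[1]:sg[2]
    h2 <- h
    h2$raw_score <- sg[3]
    h2$bit_score <- bit_score(sg[3], scheme)
    h2$evalue <- evalue(h2$bit_score, m, n)
    h2$query_range <- h$query_range[1] +
      c(if (sg[1] == 1) 0L else qpos[sg[1] - 1L], qpos[sg[2]])
    h2$subject_range <- h$subject_range[1] +
      c(if (sg[1] == 1) 0L else spos[sg[1] - 1L], spos[sg[2]])
    h2$a_aln <- paste(a[cols], collapse = "")
    h2$b_aln <- paste(b[cols], collapse = "")
    ca <- match(a[cols], rownames(scheme$matrix)) - 1L
    cb <- match(b[cols], rownames(scheme$matrix)) - 1L
    ca[is.na(ca)] <- -1L; cb[is.na(cb)] <- -1L
    st <- aln_stats(ca, cb, scheme)
    h2$identity_fraction <- st$identity
    h2$positive_fraction <- st$positive
    h2
  })
}

# Iteratively extract local hits of `subject` inside `query_codes`,
# masking each reported query region, until the E-value threshold stops
# being met (strict <) or max_hits is reached.
iterative_local_hits <- function(query, subject, scheme, m, n, e_max,
                                 query_id, subject_id, frame = NA_integer_,
                                 max_hits = 50L) {
  qc <- encode_seq(query, scheme)
  sc <- encode_seq(subject, scheme)
  hits <- list()
  repeat {
    raw <- local_score(qc, sc, scheme)
    ev <- evalue(bit_score(raw, scheme), m, n)
    if (!(ev < e_max) || length(hits) >= max_hits) break
    h <- align_pair(query, subject, scheme, local = TRUE, m = m, n = n,
                    query_id = query_id, subject_id = subject_id,
                    frame = frame, codes_a = qc, codes_b = sc)
    if (h$query_range[2] <= h$query_range[1]) break
    hits[[length(hits) + 1L]] <- h
    qc[(h$query_range[1] + 1L):h$query_range[2]] <- -1L
  }
  hits
}

#' Project a panel protein onto genomic contigs
#'
#' Each contig is translated in six frames and searched (iteratively, so
#' that a gene split by introns yields one HSP per exon) against the
#' protein. Per contig the covered fraction is the union of matched protein
#' ranges over the protein length; `majority_single_contig` is strictly
#' `covered_fraction > 0.5`. Exon structure comes from [infer_exon_chain()].
#'
#' @param protein_id,protein id and amino-acid sequence of the panel protein.
#' @param contigs named character vector of contig nucleotide sequences.
#' @param scheme a [scoring_scheme()].
#' @param e_max strict E-value threshold.
#' @param min_intron minimum intron length (nt) passed to the exon chainer.
#' @param min_segment_score raw-score floor for per-exon sub-segments after
#'   X-drop splitting, default 25.
#' @return list of `projection_result` (one per contig with hits): fields
#'   `protein_id`, `contig_id`, `covered_fraction`, `majority_single_contig`,
#'   `exon_count`, `intron_ranges`, `strand`, `hsps`, `introns_gt_ag`.
#' @export
project_to_contig <- function(protein_id, protein, contigs,
                              scheme = scoring_scheme(), e_max = 1e-6,
                              min_intron = 30, min_segment_score = 25) {
  stopifnot(length(contigs) > 0)
  n_db <- nchar(protein)
  out <- list()
  for (cid in names(contigs)) {
    contig <- check_nucleotide(contigs[[cid]])
    frames <- translate_six_frames(contig)
    L <- nchar(contig)
    hsps <- list()
    for (i in seq_len(nrow(frames))) {
      pep <- frames$peptide[i]
      if (nchar(pep) < 5) next
      fh <- iterative_local_hits(pep, protein, scheme, m = nchar(pep),
                                 n = n_db, e_max = e_max, query_id = cid,
                                 subject_id = protein_id,
                                 frame = frames$frame[i])
      fh <- unlist(lapply(fh, split_hsp_xdrop, scheme = scheme,
                          m = nchar(pep), n = n_db),
                   recursive = FALSE)
      # sub-segments inherit the parent hit's significance but must clear a
      # seeding-style raw-score floor, discarding chance micro-matches
      fh <- Filter(function(h) h$raw_score >= min_segment_score, fh)
      for (h in fh) {
        h$peptide_range <- h$query_range
        h$query_range <- frame_to_nt_range(h$frame, h$query_range, L)
        hsps[[length(hsps) + 1L]] <- h
      }
    }
    if (length(hsps) == 0) next
    pr <- infer_exon_chain(hsps, contig_seq = contig, min_intron = min_intron)
    pr$protein_id <- protein_id
    pr$contig_id <- cid
    cov <- subject_union_coverage(hsps, nchar(protein))
    pr$covered_fraction <- cov
    pr$majority_single_contig <- cov > 0.5
    out[[cid]] <- pr
  }
  out
}

subject_union_coverage <- function(hsps, protein_len) {
  if (length(hsps) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = vapply(hsps, function(h) h$subject_range[1] + 1L, integer(1)),
    end = vapply(hsps, function(h) h$subject_range[2], integer(1))))
  min(1, sum(IRanges::width(ir)) / protein_len)
}

#' Infer the exon chain of a gene from its HSPs on one contig
#'
#' Finds the collinear chain of HSPs (increasing in both protein and contig
#' coordinates on one strand) maximizing summed raw score; contig gaps of at
#' least `min_intron` nt between consecutive chain members become introns,
#' smaller gaps are merged into one exon. When `check_gt_ag` and the contig
#' sequence is available, each intron is annotated (never filtered) with
#' whether it begins GT and ends AG on the gene strand.
#'
#' @param hsps list of `hsp` objects on one contig (query = contig, nt
#'   coordinates; subject = protein, aa coordinates; `frame` sign = strand).
#' @param contig_seq the contig sequence (needed for GT..AG annotation and
#'   for minus-strand chaining).
#' @param min_intron minimum intron length in nt, default 30.
#' @param check_gt_ag annotate intron boundaries, default `TRUE`.
#' @param overlap_tol allowed query overlap in nt between chained HSPs at
#'   exon boundaries (local alignments over-extend past splice junctions by
#'   chance matches, so generous tolerance is needed), default 60.
#' @param splice_window half-width (nt) of the window around each raw exon
#'   boundary searched for a canonical GT..AG pair; boundary refinement is
#'   annotation-driven and never discards an intron.
#' @return a `projection_result` (exon/intron structure only; coverage
#'   fields are filled by [project_to_contig()]).
#' @export
infer_exon_chain <- function(hsps, contig_seq = NULL, min_intron = 30,
                             check_gt_ag = TRUE, overlap_tol = 150,
                             splice_window = 90) {
  stopifnot(length(hsps) > 0)
  strands <- ifelse(vapply(hsps, `[[`, integer(1), "frame") > 0, 1L, -1L)
  best <- NULL
  for (st in unique(strands)) {
    hs <- hsps[strands == st]
    ch <- chain_hsps(hs, st, overlap_tol)
    if (is.null(best) || ch$score > best$score) { best <- ch; best$strand <- st }
  }
  chain <- best$chain
  # merge chain members into exons; gaps >= min_intron become introns
  qs <- vapply(chain, function(h) h$query_range[1], numeric(1))
  ord <- order(qs)
  chain <- chain[ord]
  exons <- list(); introns <- list()
  cur <- chain[[1]]$query_range
  cur_s_end <- if (best$strand > 0) chain[[1]]$subject_range[2]
               else chain[[1]]$subject_range[1]
  if (length(chain) > 1) for (i in 2:length(chain)) {
    r <- chain[[i]]$query_range
    sr <- chain[[i]]$subject_range
    gap <- c(cur[2], r[1])
    # Decide whether the junction is intron-like. Splitting artefacts
    # inside one exon leave a small gap in BOTH query and subject and must
    # merge, never acquiring a fabricated nearby GT..AG pair. A genuine
    # intron shows either an intron-sized query gap, or -- when a local
    # alignment over-extended across the junction and absorbed it -- a
    # clear subject-range overlap between the neighbouring HSPs.
    s_overlap <- if (best$strand > 0) cur_s_end - sr[1] else sr[2] - cur_s_end
    raw_len <- gap[2] - gap[1]
    # total unexplained contig length at the junction: the raw gap plus the
    # nucleotides hidden inside the over-extended alignments (3 nt per
    # doubly-claimed subject residue)
    evidence_len <- raw_len + 3 * max(0, s_overlap)
    refined <- NULL
    if (evidence_len >= min_intron && check_gt_ag && !is.null(contig_seq) &&
        best$strand > 0) {
      cand <- refine_splice_sites(contig_seq, gap, cur[1], r[2],
                                  min_intron, splice_window,
                                  target_len = evidence_len)
      if (!is.null(cand) && cand[2] - cand[1] >= min_intron) refined <- cand
    }
    if (!is.null(refined)) {
      exons[[length(exons) + 1L]] <- c(cur[1], refined[1])
      introns[[length(introns) + 1L]] <- refined
      cur <- c(refined[2], max(refined[2], r[2]))
    } else if (raw_len >= min_intron) {
      exons[[length(exons) + 1L]] <- c(cur[1], gap[1])
      introns[[length(introns) + 1L]] <- gap
      cur <- c(gap[2], max(gap[2], r[2]))
    } else cur <- c(cur[1], max(cur[2], r[2]))
    cur_s_end <- if (best$strand > 0) max(cur_s_end, sr[2])
                 else min(cur_s_end, sr[1])
  }
  exons[[length(exons) + 1L]] <- cur
  gt_ag <- rep(NA, length(introns))
  if (check_gt_ag && !is.null(contig_seq) && length(introns) > 0) {
    gt_ag <- vapply(introns, function(r) {
      s <- substr(contig_seq, r[1] + 1, r[2])
      if (best$strand < 0)
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      startsWith(s, "GT") && endsWith(s, "AG")
    }, logical(1))
  }
  structure(list(protein_id = chain[[1]]$subject_id,
                 contig_id = chain[[1]]$query_id,
                 covered_fraction = NA_real_,
                 majority_single_contig = NA,
                 exon_count = length(exons),
                 exon_ranges = exons, intron_ranges = introns,
                 introns_gt_ag = gt_ag, strand = best$strand,
                 hsps = chain, chain_score = best$score),
            class = "projection_result")
}

# Snap a raw intron gap to the nearest canonical GT..AG pair. Local
# alignments over-extend across splice junctions, so the true donor may sit
# up to `window` nt inside the upstream exon alignment (and the acceptor
# inside the downstream one). Returns the refined (start, end) 0-based
# half-open intron range, or the raw gap when no canonical pair is found.
refine_splice_sites <- function(contig_seq, gap, lo, hi, min_intron,
                                window = 90, target_len = NULL) {
  d_cand <- seq(max(lo + 1, gap[1] - window), min(nchar(contig_seq) - 1,
                                                  gap[1] + window))
  d_cand <- d_cand[substring(contig_seq, d_cand + 1, d_cand + 2) == "GT"]
  a_cand <- seq(max(1, gap[2] - window), min(nchar(contig_seq), hi - 1,
                                             gap[2] + window))
  a_cand <- a_cand[substring(contig_seq, a_cand - 1, a_cand) == "AG"]
  if (length(d_cand) == 0 || length(a_cand) == 0) return(NULL)
  best <- NULL; best_cost <- Inf
  for (d in d_cand) for (a in a_cand) {
    len <- a - d
    if (len < min_intron) next
    # length consistency with the junction evidence: never fabricate an
    # intron much longer than the unexplained sequence
    if (!is.null(target_len) && len > target_len + 45) next
    cost <- abs(d - gap[1]) + abs(a - gap[2])
    if (cost < best_cost) { best_cost <- cost; best <- c(d, a) }
  }
  best
}

# Best collinear chain by summed raw score (DP over HSPs). Local
# alignments over-extend past exon boundaries, so overlap between chained
# neighbours is allowed generously but charged at a typical per-residue
# match score; a duplicate hit of the same exon overlaps almost fully and
# is thereby priced out of the chain.
chain_hsps <- function(hs, strand, overlap_tol, overlap_cost = 5) {
  n <- length(hs)
  qs <- vapply(hs, function(h) h$query_range[1], numeric(1))
  qe <- vapply(hs, function(h) h$query_range[2], numeric(1))
  ss <- vapply(hs, function(h) h$subject_range[1], numeric(1))
  se <- vapply(hs, function(h) h$subject_range[2], numeric(1))
  sc <- vapply(hs, `[[`, numeric(1), "raw_score")
  ord <- order(qs)
  dp <- sc[ord]; prev <- rep(0L, n)
  tol_aa <- ceiling(overlap_tol / 3)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    a <- ord[j]; b <- ord[i]
    ok_q <- qs[b] >= qe[a] - overlap_tol && qe[b] > qe[a] && qs[b] > qs[a]
    ok_s <- if (strand > 0) ss[b] >= se[a] - tol_aa && se[b] > se[a] &&
                            ss[b] > ss[a]
            else se[b] <= ss[a] + tol_aa && ss[b] < ss[a] && se[b] < se[a]
    if (!ok_q || !ok_s) next
    ov_q <- max(0, qe[a] - qs[b]) / 3
    ov_s <- if (strand > 0) max(0, se[a] - ss[b]) else max(0, se[b] - ss[a])
    gain <- sc[b] - overlap_cost * max(ov_q, ov_s)
    if (gain > 0 && dp[j] + gain > dp[i]) {
      dp[i] <- dp[j] + gain; prev[i] <- j
    }
  }
  k <- which.max(dp)
  idx <- integer(0)
  while (k > 0) { idx <- c(ord[k], idx); k <- prev[k] }
  list(chain = hs[idx], score = max(dp))
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %s on %s: coverage=%.2f exons=%d strand=%+d\n",
              x$protein_id, x$contig_id,
              ifelse(is.na(x$covered_fraction), NaN, x$covered_fraction),
              x$exon_count, x$strand))
  invisible(x)
}

#' Export projection results as GFF3 gene/mRNA/exon features
#'
#' @param results list of `projection_result`.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
projection_to_gff3 <- function(results, path) {
  grl <- list()
  for (pr in results) {
    strand <- if (pr$strand > 0) "+" else "-"
    span <- range(unlist(pr$exon_ranges))
    mk <- function(type, s, e, id, parent = NA) {
      GenomicRanges::GRanges(
        seqnames = pr$contig_id,
        ranges = IRanges::IRanges(start = s + 1L, end = e),
        strand = strand, type = type, ID = id,
        Parent = ifelse(is.na(parent), NA_character_, parent))
    }
    gid <- paste0("gene:", pr$protein_id, ":", pr$contig_id)
    feats <- list(mk("gene", span[1], span[2], gid),
                  mk("mRNA", span[1], span[2], paste0(gid, ".t1"), gid))
    for (i in seq_along(pr$exon_ranges)) {
      r <- pr$exon_ranges[[i]]
      feats[[length(feats) + 1L]] <- mk("exon", r[1], r[2],
                                        paste0(gid, ".t1.exon", i),
                                        paste0(gid, ".t1"))
    }
    grl[[length(grl) + 1L]] <- do.call(c, feats)
  }
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a cross-platform validation report as TSV
#' @param recon result of [reconcile_platforms()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crossval_report <- function(recon, path) {
  utils::write.table(recon$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
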