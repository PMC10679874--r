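#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 start at offsets 0..2 of the forward strand; frames -1..-3
#' at offsets 0..2 of the reverse complement. Codons containing N translate
#' to `X`; stop codons are rendered `*`; trailing partial codons are dropped.
#'
#' @param nt nucleotide sequence over `A,C,G,T,N` (case-insensitive).
#' @return data.frame with columns `frame` (+1,+2,+3,-1,-2,-3) and `peptide`.
#' @export
translate_six_frames <- function(nt) {
  nt <- check_nucleotide(nt)
  rc <- rev_comp(nt)
  one <- function(s, off) {
    L <- nchar(s) - off
    L <- L - (L %% 3)
    if (L < 3) return("")
    starts <- seq.int(off + 1L, off + L, by = 3L)
    aa <- GENETIC_CODE_TABLE[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"   # codons containing N (or other ambiguity)
    paste(aa, collapse = "")
  }
  data.frame(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    peptide = c(vapply(0:2, function(o) one(nt, o), character(1)),
                vapply(0:2, function(o) one(rc, o), character(1))),
    stringsAsFactors = FALSE)
}

# standard genetic code (DNA codons), taken once from Biostrings
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
rev_comp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Map a peptide-coordinate range (0-based half-open, within one frame) back
# to forward-strand nucleotide coordinates on the transcript.
frame_to_nt_range <- function(frame, pep_range, nt_len) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    c(off + 3L * pep_range[1], off + 3L * pep_range[2])
  } else {
    c(nt_len - (off + 3L * pep_range[2]), nt_len - (off + 3L * pep_range[1]))
  }
}

#' Six-frame translated search of one transcript against a protein set
#'
#' Every reading frame of the transcript is aligned (full affine-gap
#' Smith-Waterman, no seeding heuristics) against every database protein.
#' At most one best HSP per (frame, subject) is retained; acceptance is
#' strict `evalue < e_max`. The E-value search space is m = frame peptide
#' length, n = total residues in the database set.
#'
#' @param transcript nucleotide sequence.
#' @param db named character vector of protein sequences.
#' @param scheme a [scoring_scheme()]; default BLOSUM62 11/1.
#' @param e_max E-value acceptance threshold (strict `<`).
#' @param transcript_id id recorded on the HSPs.
#' @return list of `hsp` objects sorted by ascending E-value (ties by
#'   descending bit score, then subject id). `query_range` is in
#'   forward-strand nucleotide coordinates on the transcript.
#' @export
translated_search <- function(transcript, db, scheme = scoring_scheme(),
                              e_max = 1e-6, transcript_id = "query") {
  stopifnot(length(db) > 0)
  frames <- translate_six_frames(transcript)
  n_db <- sum(nchar(db))
  nt_len <- nchar(transcript)
  db_codes <- lapply(db, encode_seq, scheme = scheme)
  hits <- list()
  for (i in seq_len(nrow(frames))) {
    pep <- frames$peptide[i]
    if (nchar(pep) == 0) next
    qc <- encode_seq(pep, scheme)
    m <- nchar(pep)
    for (j in seq_along(db)) {
      raw <- local_score(qc, db_codes[[j]], scheme)
      ev <- evalue(bit_score(raw, scheme), m, n_db)
      if (ev < e_max) {
        h <- align_pair(pep, db[[j]], scheme, local = TRUE, m = m, n = n_db,
                        query_id = transcript_id, subject_id = names(db)[j],
                        frame = frames$frame[i], codes_a = qc,
                        codes_b = db_codes[[j]])
        h$peptide_range <- h$query_range
        h$query_range <- frame_to_nt_range(h$frame, h$query_range, nt_len)
        h$transcript_len <- nt_len
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (length(hits) == 0) return(hits)
  ord <- order(vapply(hits, `[[`, numeric(1), "evalue"),
               -vapply(hits, `[[`, numeric(1), "bit_score"),
               vapply(hits, `[[`, character(1), "subject_id"))
  hits[ord]
}

best_hit <- function(hits) {
  if (length(hits) == 0) return(NULL)
  hits[[1]]
}

#' Reciprocal best-hit orthologue assignment
#'
#' A transcript is assigned to a panel entry `p` iff (forward) its best hit
#' across the panel member sequences plus the decoy background is a member
#' sequence of `p` with `evalue < e_max`, and (reciprocal) its best hit
#' within the panel alone is also `p` with `evalue < e_max`. Each transcript
#' is assigned to at most one entry; the returned calls cover every panel
#' entry (status `"absent"` when no transcript qualifies).
#'
#' @param transcripts named character vector of nucleotide sequences.
#' @param panel a `panel` (typically collapsed with [collapse_paralogues()]).
#' @param decoys named character vector of background proteins (ids must be
#'   disjoint from panel member ids); may be empty to reproduce the looser
#'   panel-only screen (`no_forward_background`).
#' @param scheme a [scoring_scheme()].
#' @param e_max strict E-value threshold.
#' @param no_forward_background if `TRUE`, skip the decoy background in the
#'   forward step (panel-only screen).
#' @return list with `calls` (list of `orthologue_call`: `panel_id`,
#'   `status`, `transcript_ids`, `copy_count`, `best_evalue`), `assignments`
#'   (data.frame transcript -> panel entry), `decoy_assignments` (character
#'   vector of transcripts whose forward best hit was a decoy), and `hsps`
#'   (per-transcript HSP lists against panel + decoys).
#' @export
reciprocal_assign <- function(transcripts, panel, decoys = character(0),
                              scheme = scoring_scheme(), e_max = 1e-6,
                              no_forward_background = FALSE) {
  stopifnot(inherits(panel, "panel"))
  member_of <- unlist(lapply(panel$entries$id, function(id)
    stats::setNames(rep(id, length(panel$members[[id]])), panel$members[[id]])))
  panel_db <- panel$sequences[names(member_of)]
  if (length(decoys) > 0 && any(names(decoys) %in% names(panel_db)))
    stop("decoy ids must be disjoint from panel member ids")
  full_db <- if (no_forward_background) panel_db else c(panel_db, decoys)

  assignments <- data.frame(transcript_id = character(), panel_id = character(),
                            evalue = numeric(), stringsAsFactors = FALSE)
  decoy_assignments <- character(0)
  all_hsps <- list()
  for (tid in names(transcripts)) {
    hits <- translated_search(transcripts[[tid]], full_db, scheme, e_max, tid)
    all_hsps[[tid]] <- hits
    fwd <- best_hit(hits)
    if (is.null(fwd)) next
    if (!(fwd$subject_id %in% names(member_of))) {
      decoy_assignments <- c(decoy_assignments, tid)
      next
    }
    p <- member_of[[fwd$subject_id]]
    # reciprocal step: best hit within the panel alone
    panel_hits <- Filter(function(h) h$subject_id %in% names(member_of), hits)
    rec <- best_hit(panel_hits)
    if (is.null(rec) || member_of[[rec$subject_id]] != p) next
    assignments <- rbind(assignments, data.frame(
      transcript_id = tid, panel_id = p, evalue = fwd$evalue,
      stringsAsFactors = FALSE))
  }

  calls <- lapply(panel$entries$id, function(id) {
    rows <- assignments[assignments$panel_id == id, , drop = FALSE]
    structure(list(panel_id = id,
                   status = if (nrow(rows) > 0) "found" else "absent",
                   transcript_ids = rows$transcript_id,
                   copy_count = nrow(rows),
                   best_evalue = if (nrow(rows) > 0) min(rows$evalue) else NA_real_),
              class = "orthologue_call")
  })
  names(calls) <- panel$entries$id
  list(calls = calls, assignments = assignments,
       decoy_assignments = decoy_assignments, hsps = all_hsps)
}

#' @export
print.orthologue_call <- function(x, ...) {
  cat(sprintf("<orthologue_call> %s: %s (copies = %d, best E = %s)\n",
              x$panel_id, x$status, x$copy_count,
              ifelse(is.na(x$best_evalue), "NA",
                     format(x$best_evalue, digits = 3))))
  invisible(x)
}

# Global nucleotide identity (matches / alignment columns) for clustering.
nt_identity <- function(a, b, scheme = nucleotide_scheme()) {
  ca <- encode_seq(a, scheme); cb <- encode_seq(b, scheme)
  r <- gotoh_align_cpp(ca, cb, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend, FALSE)
  aln_stats(r$a_aln, r$b_aln, scheme)$identity
}

#' Refine copy counts by clustering assigned transcripts
#'
#' Transcripts assigned to one panel entry are single-linkage clustered at
#' `>= identity_cluster_threshold` global nucleotide identity; the entry's
#' `copy_count` becomes the number of clusters (so redundant assemblies of
#' one locus count once, diverged duplicates count separately).
#'
#' @param rbh result of [reciprocal_assign()].
#' @param transcripts the named nucleotide sequences searched.
#' @param identity_cluster_threshold clustering identity, default 0.95.
#' @param exclude transcript ids to leave out of the clustering (typically
#'   assembly chimeras flagged by [flag_chimera()]).
#' @return `rbh` with updated `copy_count` on each call.
#' @export
call_copy_number <- function(rbh, transcripts,
                             identity_cluster_threshold = 0.95,
                             exclude = character(0)) {
  for (id in names(rbh$calls)) {
    tids <- setdiff(rbh$calls[[id]]$transcript_ids, exclude)
    k <- length(tids)
    if (k <= 1) { rbh$calls[[id]]$copy_count <- k; next }
    # single linkage via union-find
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (nt_identity(transcripts[[tids[i]]], transcripts[[tids[j]]]) >=
          identity_cluster_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    rbh$calls[[id]]$copy_count <-
      length(unique(vapply(seq_len(k), find, integer(1))))
  }
  rbh
}
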