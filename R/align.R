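#' Optimal local (Smith-Waterman) alignment of two protein sequences
#'
#' Full affine-gap dynamic programming, no heuristics. Deterministic
#' tie-breaking: among co-optimal alignments the one with the smallest query
#' start, then smallest subject start, is reported.
#'
#' @param a,b protein sequences (character scalars, standard residues + X).
#' @param scheme a [scoring_scheme()]; default BLOSUM62 11/1.
#' @param m,n search-space sizes for the E-value; default the two sequence
#'   lengths.
#' @return an `hsp` object: list with `query_id`, `subject_id`, `frame`
#'   (`NA` for protein-protein), `query_range` and `subject_range` (0-based
#'   half-open), `raw_score`, `bit_score`, `evalue`, `identity_fraction`,
#'   `positive_fraction`, and the two gapped alignment strings.
#' @export
local_align_protein <- function(a, b, scheme = scoring_scheme(),
                                m = nchar(a), n = nchar(b)) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  align_pair(a, b, scheme, local = TRUE, m = m, n = n)
}

#' Optimal global (Needleman-Wunsch) alignment of two protein sequences
#'
#' Affine-gap global alignment with deterministic traceback
#' (match preferred over insertion over deletion).
#'
#' @inheritParams local_align_protein
#' @return an alignment object of class `pairwise_alignment`: list with
#'   `score`, gapped strings `a_aln` / `b_aln`, `identity_fraction`,
#'   `positive_fraction` and the scheme used.
#' @export
global_align_protein <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ca <- encode_seq(a, scheme); cb <- encode_seq(b, scheme)
  r <- gotoh_align_cpp(ca, cb, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend, FALSE)
  stats <- aln_stats(r$a_aln, r$b_aln, scheme)
  structure(list(score = r$score,
                 a_aln = decode_aln(r$a_aln, scheme),
                 b_aln = decode_aln(r$b_aln, scheme),
                 identity_fraction = stats$identity,
                 positive_fraction = stats$positive,
                 scheme = scheme),
            class = "pairwise_alignment")
}

# Shared local-alignment driver; also used on nucleotides and on masked
# (pre-encoded) sequences during iterative hit extraction.
align_pair <- function(a, b, scheme, local = TRUE, m = nchar(a), n = nchar(b),
                       query_id = NA_character_, subject_id = NA_character_,
                       frame = NA_integer_, codes_a = NULL, codes_b = NULL) {
  ca <- if (is.null(codes_a)) encode_seq(a, scheme) else codes_a
  cb <- if (is.null(codes_b)) encode_seq(b, scheme) else codes_b
  r <- gotoh_align_cpp(ca, cb, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend, local)
  stats <- aln_stats(r$a_aln, r$b_aln, scheme)
  bits <- bit_score(r$score, scheme)
  structure(list(query_id = query_id, subject_id = subject_id, frame = frame,
                 query_range = c(r$a_start, r$a_end),
                 subject_range = c(r$b_start, r$b_end),
                 raw_score = r$score, bit_score = bits,
                 evalue = evalue(bits, m, n),
                 query_len = length(ca), subject_len = length(cb),
                 identity_fraction = stats$identity,
                 positive_fraction = stats$positive,
                 a_aln = decode_aln(r$a_aln, scheme),
                 b_aln = decode_aln(r$b_aln, scheme)),
            class = "hsp")
}

aln_stats <- function(a_codes, b_codes, scheme) {
  ncol <- length(a_codes)
  if (ncol == 0) return(list(identity = 0, positive = 0, matches = 0L,
                             mismatches = 0L, gapopen = 0L))
  both <- a_codes >= 0 & b_codes >= 0
  ident <- sum(both & a_codes == b_codes)
  pos <- 0L
  if (any(both))
    pos <- sum(scheme$matrix[cbind(a_codes[both] + 1L, b_codes[both] + 1L)] > 0)
  gaps <- a_codes < 0 | b_codes < 0
  gapopen <- sum(diff(c(FALSE, gaps)) == 1L)
  list(identity = ident / ncol, positive = pos / ncol,
       matches = as.integer(ident), mismatches = as.integer(sum(both) - ident),
       gapopen = as.integer(gapopen))
}

# Raw local score only (no traceback) -- the fast path of translated_search.
local_score <- function(codes_a, codes_b, scheme) {
  gotoh_score_cpp(codes_a, codes_b, scheme$matrix, scheme$gap_open,
                  scheme$gap_extend, TRUE)
}

#' @export
print.hsp <- function(x, ...) {
  cat(sprintf("<hsp> %s vs %s  frame=%s  score=%g  bits=%.1f  E=%.3g  id=%.1f%%\n",
              x$query_id, x$subject_id,
              ifelse(is.na(x$frame), ".", x$frame),
              x$raw_score, x$bit_score, x$evalue,
              100 * x$identity_fraction))
  invisible(x)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score=%g  id=%.1f%%  pos=%.1f%%\n",
              x$score, 100 * x$identity_fraction, 100 * x$positive_fraction))
  cat(substr(x$a_aln, 1, 60), "\n")
  cat(substr(x$b_aln, 1, 60), "\n")
  invisible(x)
}

# Hsp list -> data.frame with BLAST outfmt-6 compatible columns + frame.
hsp_table <- function(hsps) {
  if (length(hsps) == 0)
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      frame = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(hsps, function(h) {
    ncol <- nchar(h$a_aln)
    data.frame(qseqid = h$query_id, sseqid = h$subject_id,
               pident = round(100 * h$identity_fraction, 2),
               length = ncol,
               mismatch = NA_integer_, gapopen = NA_integer_,
               qstart = h$query_range[1] + 1L, qend = h$query_range[2],
               sstart = h$subject_range[1] + 1L, send = h$subject_range[2],
               evalue = h$evalue, bitscore = round(h$bit_score, 1),
               frame = h$frame, stringsAsFactors = FALSE)
  }))
}

#' Write HSPs as a BLAST outfmt-6-style TSV (plus a frame column)
#' @param hsps list of `hsp` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hsp_table <- function(hsps, path) {
  utils::write.table(hsp_table(hsps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
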