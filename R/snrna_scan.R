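#' Scan genomic contigs for snRNA candidates with an ordered query list
#'
#' Queries (typically the same snRNA from increasingly distant species) are
#' tried in order; the first query yielding at least one hit with
#' `evalue < e_max` is reported as the successful query and all of its hits
#' on both strands are returned. With `exhaustive = TRUE` every query is
#' run and the union of hits is returned (the success label is unchanged).
#'
#' Hits are extracted iteratively per contig and strand (masking each
#' reported region) so tandem copies yield one hit each.
#'
#' @param contigs named character vector of contig sequences.
#' @param queries named character vector of snRNA query sequences, in
#'   preference order (names = query ids, e.g. species labels).
#' @param e_max strict E-value threshold.
#' @param scheme nucleotide [scoring_scheme()]; default [nucleotide_scheme()].
#' @param exhaustive run all queries instead of stopping at the first success.
#' @return list with `status` (`"ok"` or `"all queries failed"`),
#'   `successful_query`, `failed_queries`, and `hits`: data.frame
#'   `contig_id`, `query_id`, `start`, `end` (0-based half-open, forward
#'   coords), `strand`, `identity_fraction`, `evalue`, `hit_length`.
#' @export
scan_contigs <- function(contigs, queries, e_max = 1e-6,
                         scheme = nucleotide_scheme(), exhaustive = FALSE) {
  stopifnot(length(queries) > 0)
  n_db <- sum(nchar(contigs))
  empty <- data.frame(contig_id = character(), query_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity_fraction = numeric(), evalue = numeric(),
                      hit_length = integer(), stringsAsFactors = FALSE)
  run_query <- function(qid) {
    q <- check_nucleotide(queries[[qid]], qid)
    rows <- list()
    for (cid in names(contigs)) {
      contig <- check_nucleotide(contigs[[cid]], cid)
      L <- nchar(contig)
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") contig else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
        hs <- iterative_local_hits(subj, q, scheme, m = nchar(q), n = n_db,
                                   e_max = e_max, query_id = cid,
                                   subject_id = qid)
        for (h in hs) {
          r <- h$query_range
          if (strand == "-") r <- c(L - r[2], L - r[1])
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = cid, query_id = qid, start = r[1], end = r[2],
            strand = strand, identity_fraction = h$identity_fraction,
            evalue = h$evalue, hit_length = r[2] - r[1],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0) empty else do.call(rbind, rows)
  }
  failed <- character(0)
  success <- NA_character_
  hits <- empty
  for (qid in names(queries)) {
    h <- run_query(qid)
    if (nrow(h) > 0 && is.na(success)) success <- qid
    if (nrow(h) == 0 && is.na(success)) failed <- c(failed, qid)
    if (nrow(h) > 0) hits <- rbind(hits, h)
    if (!is.na(success) && !exhaustive) break
  }
  list(status = if (is.na(success)) "all queries failed" else "ok",
       successful_query = success, failed_queries = failed,
       hits = hits[order(hits$contig_id, hits$start), , drop = FALSE])
}

#' Call tandem arrays from snRNA hits
#'
#' Maximal runs of two or more hits to the same element, on the same strand
#' of the same contig, with successive start-to-start spacing at most
#' `max_spacer` nt, are reported as tandem arrays.
#'
#' @param hits the `hits` data.frame from [scan_contigs()].
#' @param max_spacer maximum start-to-start spacing in nt, default 1000.
#' @return list of `tandem_array`: `contig_id`, `element_id`, `copy_count`,
#'   `strand`, `unit_starts` (sorted), `spacings` (length `copy_count - 1`).
#' @export
find_tandem_arrays <- function(hits, max_spacer = 1000) {
  out <- list()
  if (nrow(hits) == 0) return(out)
  key <- paste(hits$contig_id, hits$query_id, hits$strand, sep = "\r")
  for (k in unique(key)) {
    sub <- hits[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    runs <- cumsum(c(TRUE, diff(sub$start) > max_spacer))
    for (r in unique(runs)) {
      s <- sub[runs == r, , drop = FALSE]
      if (nrow(s) < 2) next
      out[[length(out) + 1L]] <- structure(
        list(contig_id = s$contig_id[1], element_id = s$query_id[1],
             copy_count = nrow(s), strand = s$strand[1],
             unit_starts = s$start, spacings = diff(s$start)),
        class = "tandem_array")
    }
  }
  out
}

#' @export
print.tandem_array <- function(x, ...) {
  cat(sprintf("<tandem_array> %d copies of %s on %s (%s), spacing %d-%d nt\n",
              x$copy_count, x$element_id, x$contig_id, x$strand,
              min(x$spacings), max(x$spacings)))
  invisible(x)
}

IUPAC_OK <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Annotate sequence motifs on an snRNA with IUPAC patterns
#'
#' @param snrna the snRNA nucleotide sequence (T or U alphabet).
#' @param motif_config data.frame with columns `motif_name`, `pattern`
#'   (IUPAC), and optional `window_start`, `window_end` (1-based inclusive
#'   position window for the match start; `NA` = whole sequence).
#' @return data.frame `motif_name`, `start`, `end` (0-based half-open),
#'   `pattern`. Overlapping matches are all reported.
#' @export
annotate_motifs <- function(snrna, motif_config) {
  snrna <- toupper(gsub("U", "T", toupper(snrna)))
  snrna <- check_nucleotide(snrna, "snRNA")
  out <- list()
  for (i in seq_len(nrow(motif_config))) {
    pat <- toupper(gsub("U", "T", toupper(motif_config$pattern[i])))
    bad <- setdiff(strsplit(pat, "")[[1]], IUPAC_OK)
    if (length(bad) > 0)
      stop("invalid IUPAC symbol in pattern '", motif_config$pattern[i],
           "': ", paste(bad, collapse = ""))
    mm <- Biostrings::matchPattern(pat, Biostrings::DNAString(snrna),
                                   fixed = FALSE)
    st <- BiocGenerics::start(mm); en <- BiocGenerics::end(mm)
    ws <- if ("window_start" %in% names(motif_config))
      motif_config$window_start[i] else NA
    we <- if ("window_end" %in% names(motif_config))
      motif_config$window_end[i] else NA
    keep <- rep(TRUE, length(st))
    if (!is.na(ws)) keep <- keep & st >= ws
    if (!is.na(we)) keep <- keep & st <= we
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        motif_name = motif_config$motif_name[i],
        start = st[keep] - 1L, end = en[keep],
        pattern = motif_config$pattern[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(motif_name = character(), start = integer(),
                      end = integer(), pattern = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Base-pairing fraction of two snRNA helix regions
#'
#' The two regions are paired antiparallel (the second is reversed);
#' Watson-Crick (A-U/T, G-C) and wobble G-U/T pairs count as paired.
#'
#' @param u2_region,u6_region equal-length nucleotide regions (T or U).
#' @return fraction of paired positions in \[0, 1\].
#' @export
helix_complementarity <- function(u2_region, u6_region) {
  a <- strsplit(gsub("U", "T", toupper(u2_region)), "")[[1]]
  b <- rev(strsplit(gsub("U", "T", toupper(u6_region)), "")[[1]])
  if (length(a) != length(b)) stop("length mismatch")
  pair <- paste0(a, b)
  ok <- pair %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  mean(ok)
}

#' Export snRNA hits and arrays as BED6
#'
#' @param hits `hits` from [scan_contigs()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
hits_to_bed <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  gr$name <- hits$query_id
  gr$score <- round(1000 * hits$identity_fraction)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
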