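#' Detect the spliced-leader exon at the 5' end of reads
#'
#' A read is flagged when some suffix of the SL exon of length at least
#' `min_match` occurs (no indels, at most `max_mismatch` mismatches) with
#' its start within the first `window` nt of the read. Only SL suffixes are
#' considered because trans-splicing adds the leader 5'-terminally, possibly
#' truncated by library preparation. The longest qualifying suffix is
#' reported; ties go to the smallest read offset.
#'
#' @param reads named character vector of nucleotide reads.
#' @param sl the SL exon sequence (length >= `min_match`).
#' @param min_match minimum matched suffix length, default 12 nt.
#' @param max_mismatch maximum mismatches, default 1.
#' @param window maximum start offset on the read, default 5 nt.
#' @return data.frame (`sl_calls`): `record_id`, `detected`, `matched_len`,
#'   `mismatches`, `read_offset`.
#' @export
detect_sl <- function(reads, sl, min_match = 12, max_mismatch = 1,
                      window = 5) {
  sl <- check_nucleotide(sl, "SL")
  if (nchar(sl) < min_match) stop("sl length must be >= min_match")
  reads_chr <- toupper(unname(reads))
  df <- sl_scan_cpp(reads_chr, sl, as.integer(min_match),
                    as.integer(max_mismatch), as.integer(window))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  cbind(data.frame(record_id = ids, stringsAsFactors = FALSE), df)
}

#' Remove a detected SL leader (and any 5' overhang) from a read
#'
#' @param read the nucleotide read.
#' @param call the matching row of [detect_sl()] output (must have
#'   `detected = TRUE`).
#' @return the read with the first `read_offset + matched_len` nt removed.
#' @export
strip_sl <- function(read, call) {
  if (!isTRUE(call$detected)) stop("strip_sl on an undetected record")
  substr(read, call$read_offset + call$matched_len + 1, nchar(read))
}

#' Estimate trans-splicing prevalence with a Wilson 95 percent interval
#'
#' @param calls [detect_sl()] output.
#' @param per_gene optional named character vector mapping `record_id` to a
#'   gene id; a gene counts as flagged when at least one of its records is
#'   detected. Without it, records are counted directly.
#' @return a `prevalence_estimate`: `n_flagged`, `n_total`, `proportion`,
#'   `ci_low`, `ci_high`. Its print method reports the percentage rounded
#'   half-up to one decimal.
#' @export
estimate_prevalence <- function(calls, per_gene = NULL) {
  if (nrow(calls) == 0) stop("empty input")
  if (!is.null(per_gene)) {
    gene <- per_gene[calls$record_id]
    if (anyNA(gene)) stop("per_gene map missing records")
    flagged_genes <- unique(gene[calls$detected])
    k <- length(flagged_genes)
    n <- length(unique(gene))
  } else {
    k <- sum(calls$detected)
    n <- nrow(calls)
  }
  ci <- wilson_ci(k, n)
  structure(list(n_flagged = k, n_total = n, proportion = k / n,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"])),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("<prevalence_estimate> %d / %d = %s (Wilson 95%%: %s - %s)\n",
              x$n_flagged, x$n_total,
              format_percent(x$proportion, digits),
              format_percent(x$ci_low, digits),
              format_percent(x$ci_high, digits)))
  invisible(x)
}

#' Write SL calls (TSV) and the prevalence summary (JSON)
#' @param calls [detect_sl()] output.
#' @param est [estimate_prevalence()] output.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, a list of the written paths.
#' @export
write_sl_report <- function(calls, est, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n_flagged = est$n_flagged, n_total = est$n_total,
           proportion = est$proportion,
           percent = round_half_up(100 * est$proportion, 1),
           ci_low = est$ci_low, ci_high = est$ci_high),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tsv = tsv_path, json = json_path))
}
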