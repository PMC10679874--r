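#' Read a splicing-modulator contact-residue configuration
#'
#' Tab-separated with header `modulator  protein  position  residue`
#' (1-based positions on the ungapped reference sequence, matching
#' published residue labels). The packaged default
#' (`system.file("extdata", "modulator_contacts.tsv",
#' package = "spliceopanel")`) carries the residues named in print for
#' pladienolide B (SF3B1 V1078, PHF5A C36) and OTS964 (CDK11 H572, G579);
#' users extend it with further structure-defined contacts.
#'
#' @param path TSV path.
#' @return data.frame `modulator`, `protein`, `position`, `residue`, sorted
#'   by protein then position.
#' @export
read_contact_config <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("modulator", "protein", "position", "residue")
  if (!all(need %in% names(df))) stop("contact config missing columns")
  if (any(nchar(df$residue) != 1)) stop("residues must be single letters")
  df <- df[order(df$protein, df$position), need]
  for (p in unique(df$protein))
    if (anyDuplicated(df$position[df$protein == p]))
      stop("duplicate contact position for ", p)
  df
}

#' Overall percent similarity of a pairwise alignment
#'
#' Defined as 100 x (columns whose two residues have a positive
#' substitution score; gap columns never count) / (all alignment columns,
#' gaps included), rounded half-up to the nearest integer.
#'
#' @param alignment a `pairwise_alignment` from [global_align_protein()].
#' @param scheme scoring scheme used for positivity; defaults to the one
#'   stored on the alignment.
#' @return integer percentage.
#' @export
percent_similarity <- function(alignment, scheme = alignment$scheme) {
  a <- strsplit(alignment$a_aln, "")[[1]]
  b <- strsplit(alignment$b_aln, "")[[1]]
  ncol <- length(a)
  both <- a != "-" & b != "-"
  pos <- sum(scheme$matrix[cbind(a[both], b[both])] > 0)
  round_half_up(100 * pos / ncol, 0)
}

#' Map structure-defined contact residues onto a query protein
#'
#' Each reference contact position is projected through a global pairwise
#' alignment onto the query. A contact is conserved when the aligned query
#' residue equals the reference residue; contacts aligned to a gap are
#' reported unmapped and counted as divergent.
#'
#' @param alignment a `pairwise_alignment` of reference (`a`) vs query
#'   (`b`) from [global_align_protein()].
#' @param contacts data.frame with `position` (1-based on the ungapped
#'   reference) and `residue` columns, e.g. one modulator/protein slice of
#'   [read_contact_config()].
#' @return list with `mappings` (data.frame `ref_pos`, `ref_res`,
#'   `query_pos`, `query_res`, `conserved`) and `verdict` (either
#'   `"all contacts conserved"` or `"divergence at: <pos list>"`).
#' @export
map_contact_residues <- function(alignment, contacts) {
  a <- strsplit(alignment$a_aln, "")[[1]]
  b <- strsplit(alignment$b_aln, "")[[1]]
  ref_pos_at_col <- cumsum(a != "-")
  qry_pos_at_col <- cumsum(b != "-")
  ref_len <- max(ref_pos_at_col)
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    p <- contacts$position[i]
    if (p < 1 || p > ref_len) stop("contact position out of range: ", p)
    col <- match(p, ref_pos_at_col * (a != "-"))
    ref_res <- a[col]
    exp_res <- toupper(contacts$residue[i])
    if (ref_res != exp_res)
      warning("reference residue at ", p, " is ", ref_res,
              ", config says ", exp_res)
    gap <- b[col] == "-"
    rows[[i]] <- data.frame(
      ref_pos = p, ref_res = ref_res,
      query_pos = if (gap) NA_integer_ else qry_pos_at_col[col],
      query_res = if (gap) NA_character_ else b[col],
      conserved = !gap && b[col] == ref_res,
      stringsAsFactors = FALSE)
  }
  mappings <- do.call(rbind, rows)
  verdict <- if (all(mappings$conserved)) "all contacts conserved"
  else {
    div <- mappings[!mappings$conserved, , drop = FALSE]
    lab <- vapply(seq_len(nrow(div)), function(i) {
      if (is.na(div$query_res[i]))
        paste0(div$ref_res[i], div$ref_pos[i], "->gap")
      else paste0(div$ref_res[i], div$ref_pos[i], "->", div$query_res[i])
    }, character(1))
    paste0("divergence at: ", paste(lab, collapse = ", "))
  }
  list(mappings = mappings, verdict = verdict)
}

#' Full modulator-sensitivity report for one reference/query protein pair
#'
#' Aligns the query against the reference, computes overall percent
#' similarity, and maps every configured contact residue of every modulator
#' for that protein.
#'
#' @param ref_seq,query_seq reference and query protein sequences.
#' @param protein protein name used to slice `contacts`.
#' @param contacts a [read_contact_config()] data.frame.
#' @param scheme a [scoring_scheme()].
#' @return list with `alignment`, `similarity_percent`, and per-modulator
#'   `reports` (each a [map_contact_residues()] result).
#' @export
modulator_report <- function(ref_seq, query_seq, protein, contacts,
                             scheme = scoring_scheme()) {
  aln <- global_align_protein(ref_seq, query_seq, scheme)
  cc <- contacts[contacts$protein == protein, , drop = FALSE]
  reports <- lapply(split(cc, cc$modulator), function(x)
    map_contact_residues(aln, x))
  list(alignment = aln, similarity_percent = percent_similarity(aln),
       reports = reports)
}

#' Write contact-residue mappings as TSV plus a verdict text file
#' @param report a [modulator_report()] result.
#' @param protein protein name (used in the text).
#' @param tsv_path,txt_path output paths (either may be `NULL`).
#' @return invisibly, the written paths.
#' @export
write_modulator_report <- function(report, protein, tsv_path = NULL,
                                   txt_path = NULL) {
  tab <- do.call(rbind, lapply(names(report$reports), function(m)
    cbind(modulator = m, protein = protein,
          report$reports[[m]]$mappings)))
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(txt_path)) {
    lines <- c(sprintf("%s: overall similarity %d%%", protein,
                       report$similarity_percent),
               vapply(names(report$reports), function(m)
                 sprintf("  %s: %s", m, report$reports[[m]]$verdict),
                 character(1)))
    writeLines(lines, txt_path)
  }
  invisible(list(tsv = tsv_path, txt = txt_path))
}
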