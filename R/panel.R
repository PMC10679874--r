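#' @name panel
#' @title The reference spliceosomal-protein panel
#'
#' @description
#' A `panel` holds the inventory of reference spliceosomal proteins against
#' which a transcriptome is screened: for each entry an id, display name,
#' functional category from a closed vocabulary, an optional paralogue-group
#' token, and one or more amino-acid sequences. Paralogue groups model sets
#' of related human proteins that are screened as a single unit.
#'
#' The packaged manifest (`system.file("extdata",
#' "spliceosomal_panel_fig1.tsv", package = "spliceopanel")`) reproduces the
#' published 257-protein inventory by category; entries whose names the
#' source text does not print carry systematic placeholder names (see the
#' manifest header).
NULL

PANEL_CATEGORIES <- c(
  "Sm/LSm", "U1", "U2-related", "U4/U5/U6", "NTC/NTR/IBC", "RES",
  "EJC/TREX", "ATPase", "CBC", "LDE",
  "stage-specific:A", "stage-specific:pre-B", "stage-specific:B",
  "stage-specific:pre-Bact", "stage-specific:Bact", "stage-specific:B*/C",
  "stage-specific:pre-C*", "stage-specific:C*/P", "stage-specific:C/C*-misc",
  "stage-specific:ILS",
  "SR", "hnRNP", "pre-mRNA-binding", "miscellaneous")

# The ten snRNP/non-snRNP subcategories making up published subgroup (i).
SNRNP_CATEGORIES <- PANEL_CATEGORIES[1:10]

new_panel <- function(entries, sequences, groups, members = NULL) {
  if (anyDuplicated(entries$id)) stop("duplicate entry")
  if (!all(entries$category %in% PANEL_CATEGORIES))
    stop("unknown category: ",
         paste(setdiff(entries$category, PANEL_CATEGORIES), collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequences)
  if (any(bad)) stop("sequence with non-standard residues: ",
                     paste(utils::head(names(sequences)[bad], 3), collapse = ", "))
  gm <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(gm)) stop("an entry belongs to two paralogue groups")
  if (!all(gm %in% names(sequences)))
    stop("group member without a sequence record")
  if (is.null(members)) {
    members <- as.list(entries$id)
    names(members) <- entries$id
  }
  structure(list(entries = entries, sequences = sequences,
                 groups = groups, members = members),
            class = "panel")
}

#' Load a panel from a manifest TSV and a sequence FASTA
#'
#' The manifest is tab-separated with header
#' `id  name  category  paralogue_group` (empty group = ungrouped). Lines
#' starting with `#` are comments. When `sequences` is `NULL` every entry
#' receives the placeholder sequence `"X"`, which supports panel accounting
#' without bundled protein sequences.
#'
#' @param manifest path to the manifest TSV.
#' @param sequences path to a protein FASTA keyed by manifest id, or `NULL`.
#' @return a `panel` object; entry order follows the manifest.
#' @export
load_panel <- function(manifest, sequences = NULL) {
  df <- utils::read.delim(manifest, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  need <- c("id", "name", "category", "paralogue_group")
  if (!all(need %in% names(df))) stop("manifest missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate entry")
  if (is.null(sequences)) {
    seqs <- rep("X", nrow(df)); names(seqs) <- df$id
  } else {
    seqs <- if (is.character(sequences) && length(sequences) == 1 &&
                file.exists(sequences)) read_fasta(sequences, "AA") else sequences
    missing <- setdiff(df$id, names(seqs))
    if (length(missing) > 0)
      stop("manifest/FASTA mismatch: no sequence for ",
           paste(utils::head(missing, 5), collapse = ", "))
    seqs <- toupper(seqs[df$id])
  }
  grp <- df$paralogue_group
  grp[is.na(grp)] <- ""
  groups <- split(df$id[nzchar(grp)], grp[nzchar(grp)])
  new_panel(df[, need], seqs, groups)
}

#' Collapse paralogue groups to single panel entries
#'
#' Each paralogue group is replaced by one representative entry (the
#' first-listed member). All member sequences are retained on the
#' representative, so a homology hit to any member still counts for the
#' collapsed entry. Ungrouped entries are unchanged. The output has
#' `|entries| - sum(group size - 1)` entries.
#'
#' @param panel a `panel`.
#' @return a collapsed `panel`; `members` maps each surviving entry id to
#'   the ids of the sequences it carries.
#' @export
collapse_paralogues <- function(panel) {
  stopifnot(inherits(panel, "panel"))
  if (length(panel$groups) == 0) return(panel)
  e <- panel$entries
  drop <- character(0)
  members <- panel$members
  for (g in names(panel$groups)) {
    ids <- panel$groups[[g]]
    ids <- ids[order(match(ids, e$id))]
    rep_id <- ids[1]
    members[[rep_id]] <- unlist(members[ids], use.names = FALSE)
    drop <- c(drop, ids[-1])
  }
  keep <- !(e$id %in% drop)
  new_panel(e[keep, , drop = FALSE], panel$sequences,
            groups = panel$groups, members = members[e$id[keep]])
}

# All member sequences searchable for one (possibly collapsed) entry.
entry_sequences <- function(panel, id) {
  panel$sequences[panel$members[[id]]]
}

#' Summarize a panel by category
#'
#' @param panel a `panel`.
#' @return a `panel_summary`: list with `counts` (named integer vector over
#'   the full category vocabulary), `snrnp_subtotal` (sum over the ten
#'   snRNP/non-snRNP subcategories, published subgroup (i)) and `total`.
#' @export
summarize_panel <- function(panel) {
  stopifnot(inherits(panel, "panel"))
  counts <- table(factor(panel$entries$category, levels = PANEL_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), PANEL_CATEGORIES)
  structure(list(counts = counts,
                 snrnp_subtotal = sum(counts[SNRNP_CATEGORIES]),
                 total = sum(counts)),
            class = "panel_summary")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %d entries, %d paralogue groups\n",
              nrow(x$entries), length(x$groups)))
  invisible(x)
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> total = %d (snRNP/non-snRNP subgroup = %d)\n",
              x$total, x$snrnp_subtotal))
  nz <- x$counts[x$counts > 0]
  for (i in seq_along(nz)) cat(sprintf("  %-26s %d\n", names(nz)[i], nz[i]))
  invisible(x)
}

#' Serialize a panel to JSON
#' @param panel a `panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
panel_to_json <- function(panel, path) {
  jsonlite::write_json(
    list(entries = panel$entries,
         sequences = as.list(panel$sequences),
         groups = panel$groups,
         members = panel$members),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a panel from JSON written by [panel_to_json()]
#' @param path JSON path.
#' @return a `panel`.
#' @export
panel_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(x$entries, stringsAsFactors = FALSE)
  entries$paralogue_group[is.na(entries$paralogue_group)] <- ""
  seqs <- unlist(x$sequences)
  groups <- lapply(x$groups, as.character)
  members <- lapply(x$members, as.character)
  new_panel(entries, seqs, groups, members)
}
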