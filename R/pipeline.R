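#' Percentage of circular-consensus reads passing FLNC classification
#'
#' @param n_ccs number of CCS reads (>= 1).
#' @param n_flnc number of full-length non-chimeric reads (<= n_ccs).
#' @return percentage, rounded half-up to one decimal.
#' @export
flnc_pass_rate <- function(n_ccs, n_flnc) {
  stopifnot(n_ccs >= 1)
  if (n_flnc > n_ccs) stop("n_flnc must be <= n_ccs")
  round_half_up(100 * n_flnc / n_ccs, 1)
}

#' Cross-species presence/absence matrix of panel entries
#'
#' @param call_sets named list: species -> list of `orthologue_call` (all
#'   over the same collapsed panel, e.g. from [reciprocal_assign()]).
#' @return a `species_matrix`: list with `matrix` (logical, rows = panel
#'   entries, columns = species), `totals` (per-species present counts),
#'   `unique_to` (entries present in exactly one species, named by
#'   species), `absent_everywhere` (entry ids).
#' @export
compare_species <- function(call_sets) {
  stopifnot(length(call_sets) >= 1)
  ids <- names(call_sets[[1]])
  for (cs in call_sets)
    if (!identical(names(cs), ids)) stop("mismatched panels across species")
  m <- vapply(call_sets, function(cs)
    vapply(cs, function(x) x$status == "found", logical(1)), logical(length(ids)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(call_sets),
                                   dimnames = list(ids, names(call_sets)))
  rownames(m) <- ids
  rs <- rowSums(m)
  uniq <- lapply(colnames(m), function(sp) ids[m[, sp] & rs == 1])
  names(uniq) <- colnames(m)
  structure(list(matrix = m,
                 totals = colSums(m),
                 unique_to = uniq,
                 absent_everywhere = ids[rs == 0]),
            class = "species_matrix")
}

#' @export
print.species_matrix <- function(x, ...) {
  cat("<species_matrix>", nrow(x$matrix), "entries x",
      ncol(x$matrix), "species\n")
  print(x$totals)
  invisible(x)
}

log_stage <- function(log, stage, n_in, n_out, t0) {
  rec <- list(stage = stage, n_in = n_in, n_out = n_out,
              elapsed = round(as.numeric(Sys.time()) - t0, 3))
  message(sprintf("[%s] in=%d out=%d (%.2fs)", stage, n_in, n_out,
                  rec$elapsed))
  c(log, list(rec))
}

#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its package default. Values
#' can be overridden in the JSON config passed to [run_pipeline()].
#' @return named list.
#' @export
default_config <- function() {
  list(e_max = 1e-6,
       min_cov = 0.8,
       min_aa = 30,
       min_intron = 30,
       identity_cluster_threshold = 0.95,
       min_segment_cov = 0.25,
       sl_min_match = 12, sl_max_mismatch = 1, sl_window = 5,
       max_spacer = 1000,
       gap_open = 11, gap_extend = 1,
       n_ccs = NA, n_flnc = NA)
}

#' Run the full identification pipeline
#'
#' Stages, in order: panel loading and paralogue collapsing; translated
#' reciprocal best-hit search with copy-number calling; cross-platform ORF
#' verification and chimera flagging; spliced-leader scanning of the
#' full-length reads (skipped with a warning when no SL sequence is
#' configured); genomic snRNA scan with tandem-array calling (when contigs
#' and snRNA queries are configured). All module outputs plus a run-summary
#' JSON are written under `out_dir`; reruns on identical inputs are
#' byte-identical. A stage error aborts with the stage name.
#'
#' @param config a named list or path to a JSON file. Recognized fields:
#'   `panel_manifest`, `panel_fasta` (or an in-memory `panel`), `ngs_fasta`,
#'   `fl_fasta`, `decoy_fasta`, `sl_fasta` (or `sl_seq`), `contigs_fasta`,
#'   `snrna_queries_fasta`, `read_gene_map` (2-column TSV), plus any
#'   threshold from [default_config()].
#' @param out_dir output directory.
#' @return a report bundle: list with `panel`, `rbh`, `crossval`,
#'   `sl`, `snrna`, `summary`, `log`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("spliceopanel_run_")) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- scoring_scheme(gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
  log <- list()
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    tryCatch(fn(t0), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- panel ---
  panel <- run_stage("panel", function(t0) {
    p <- if (!is.null(cfg[["panel"]]) && inherits(cfg[["panel"]], "panel")) cfg[["panel"]]
    else load_panel(cfg[["panel_manifest"]], cfg[["panel_fasta"]])
    pc <- collapse_paralogues(p)
    log <<- log_stage(log, "panel", nrow(p$entries), nrow(pc$entries), t0)
    pc
  })

  # --- homology ---
  transcripts <- if (!is.null(cfg[["ngs"]])) cfg[["ngs"]]
  else if (!is.null(cfg[["ngs_fasta"]])) read_fasta(cfg[["ngs_fasta"]]) else character(0)
  decoys <- if (!is.null(cfg[["decoys"]])) cfg[["decoys"]]
  else if (!is.null(cfg[["decoy_fasta"]])) read_fasta(cfg[["decoy_fasta"]], "AA")
  else character(0)
  rbh <- run_stage("homology", function(t0) {
    r <- reciprocal_assign(transcripts, panel, decoys, scheme, cfg$e_max)
    found <- sum(vapply(r$calls, function(x) x$status == "found", logical(1)))
    log <<- log_stage(log, "homology", length(transcripts), found, t0)
    r
  })
  write_hsp_table(unlist(rbh$hsps, recursive = FALSE),
                  file.path(out_dir, "hsps.tsv"))

  # --- crossval: ORF intactness on both platforms + chimera flags ---
  fl <- if (!is.null(cfg[["fl"]])) cfg[["fl"]]
  else if (!is.null(cfg[["fl_fasta"]])) read_fasta(cfg[["fl_fasta"]]) else character(0)
  crossval <- run_stage("crossval", function(t0) {
    ref_len <- vapply(panel$entries$id, function(id)
      max(nchar(entry_sequences(panel, id))), numeric(1))
    intact_on <- function(seqs, ids) {
      vapply(panel$entries$id, function(pid) {
        tids <- rbh$calls[[pid]]$transcript_ids
        recs <- seqs[names(seqs) %in% ids[tids]]
        if (length(recs) == 0) return(FALSE)
        any(vapply(recs, function(s) {
          orfs <- find_orfs(s, min_aa = cfg$min_aa, transcript_id = "x")
          nrow(orfs) > 0 && any(vapply(seq_len(nrow(orfs)), function(i)
            classify_intactness(orfs[i, ], ref_len[[pid]], cfg$min_cov),
            logical(1)))
        }, logical(1)))
      }, logical(1))
    }
    ngs_ids <- stats::setNames(names(transcripts), names(transcripts))
    fl_ids <- stats::setNames(paste0("fl_", names(transcripts)),
                              names(transcripts))
    ngs_intact <- intact_on(transcripts, ngs_ids)
    fl_intact <- intact_on(fl, fl_ids)
    recon <- reconcile_platforms(ngs_intact, fl_intact)
    chim <- vapply(names(transcripts), function(tid) {
      flag_chimera(rbh$hsps[[tid]], cfg$min_segment_cov, panel)$flagged
    }, logical(1))
    log <<- log_stage(log, "crossval", length(panel$entries$id),
                      sum(recon$tally), t0)
    list(reconciliation = recon, chimera_flags = chim)
  })
  write_crossval_report(crossval$reconciliation,
                        file.path(out_dir, "crossval.tsv"))
  # copy counts on non-chimeric assignments only
  rbh <- call_copy_number(rbh, transcripts, cfg$identity_cluster_threshold,
                          exclude = names(which(crossval$chimera_flags)))
  calls_df <- do.call(rbind, lapply(rbh$calls, function(x)
    data.frame(panel_id = x$panel_id, status = x$status,
               copy_count = x$copy_count,
               transcripts = paste(x$transcript_ids, collapse = ","),
               best_evalue = ifelse(is.na(x$best_evalue), NA, x$best_evalue),
               stringsAsFactors = FALSE)))
  utils::write.table(calls_df, file.path(out_dir, "orthologue_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- sl_scan ---
  sl_seq <- if (!is.null(cfg[["sl_seq"]])) cfg[["sl_seq"]]
  else if (!is.null(cfg[["sl_fasta"]])) read_fasta(cfg[["sl_fasta"]])[[1]] else NULL
  sl <- NULL
  if (is.null(sl_seq)) {
    warning("sl_scan skipped: no SL sequence configured")
  } else if (length(fl) > 0) {
    sl <- run_stage("sl_scan", function(t0) {
      calls <- detect_sl(fl, sl_seq, cfg$sl_min_match, cfg$sl_max_mismatch,
                         cfg$sl_window)
      per_gene <- if (!is.null(cfg[["read_gene_map"]])) cfg[["read_gene_map"]] else NULL
      est <- estimate_prevalence(calls, per_gene)
      log <<- log_stage(log, "sl_scan", length(fl), est$n_flagged, t0)
      list(calls = calls, estimate = est)
    })
    write_sl_report(sl$calls, sl$estimate,
                    file.path(out_dir, "sl_calls.tsv"),
                    file.path(out_dir, "sl_summary.json"))
  }

  # --- snrna_scan ---
  snrna <- NULL
  contigs <- if (!is.null(cfg[["contigs"]])) cfg[["contigs"]]
  else if (!is.null(cfg[["contigs_fasta"]])) read_fasta(cfg[["contigs_fasta"]])
  else character(0)
  queries <- if (!is.null(cfg[["snrna_queries"]])) cfg[["snrna_queries"]]
  else if (!is.null(cfg[["snrna_queries_fasta"]])) read_fasta(cfg[["snrna_queries_fasta"]])
  else character(0)
  if (length(contigs) > 0 && length(queries) > 0) {
    snrna <- run_stage("snrna_scan", function(t0) {
      sc <- scan_contigs(contigs, queries, cfg$e_max)
      arrays <- find_tandem_arrays(sc$hits, cfg$max_spacer)
      log <<- log_stage(log, "snrna_scan", length(contigs), nrow(sc$hits), t0)
      list(scan = sc, arrays = arrays)
    })
    if (nrow(snrna$scan$hits) > 0)
      hits_to_bed(snrna$scan$hits, file.path(out_dir, "snrna_hits.bed"))
  }

  # --- summary ---
  n_found <- sum(vapply(rbh$calls, function(x) x$status == "found",
                        logical(1)))
  summary <- list(
    n_ccs = cfg$n_ccs, n_flnc = cfg$n_flnc,
    flnc_pass_rate = if (!is.na(cfg$n_ccs) && !is.na(cfg$n_flnc))
      flnc_pass_rate(cfg$n_ccs, cfg$n_flnc) else NA,
    n_genes = nrow(panel$entries), n_found = n_found,
    n_sl_flagged = if (!is.null(sl)) sl$estimate$n_flagged else NA,
    prevalence = if (!is.null(sl))
      list(proportion = sl$estimate$proportion,
           percent = round_half_up(100 * sl$estimate$proportion, 1),
           ci_low = sl$estimate$ci_low, ci_high = sl$estimate$ci_high)
    else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(log, file.path(out_dir, "stages.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, rbh = rbh, crossval = crossval, sl = sl,
                 snrna = snrna, summary = summary, log = log,
                 out_dir = out_dir))
}
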