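#' @name synthetic
#' @title Seeded synthetic-data generator with ground truth
#'
#' @description
#' Emulates the statistical structure of the real study inputs at desk
#' scale: a reference protein panel, a short-read-style assembled
#' transcriptome containing diverged orthologues, duplications and
#' assembly chimeras, full-length reads carrying a spliced-leader exon at a
#' controlled prevalence, and genomic contigs with GT..AG-intron-split
#' genes and tandem small-RNA arrays. Every stochastic choice is recorded
#' in a truth table. One top-level seed drives per-record derived streams,
#' so adding a record never shifts another record's sequences.
NULL

# Most-frequent human codon per residue; deterministic back-translation
# keeps translated search exact at divergence 0. X maps to NNN.
CODON1 <- c(A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC",
            Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
            L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
            S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG",
            X = "NNN", `*` = "TAA")

#' Back-translate a protein with the fixed most-frequent-codon table
#' @param protein amino-acid sequence.
#' @param stop append a TAA stop codon, default `TRUE`.
#' @return nucleotide CDS.
#' @export
back_translate <- function(protein, stop = TRUE) {
  ch <- strsplit(toupper(protein), "")[[1]]
  cds <- paste(CODON1[ch], collapse = "")
  if (anyNA(CODON1[ch])) stop("non-standard residue in protein")
  if (stop) cds <- paste0(cds, "TAA")
  cds
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1, replace = TRUE), collapse = ""))
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a random reference panel
#'
#' @param n number of entries (>= 1).
#' @param length_range protein length range in aa, default `c(100, 250)`
#'   (short relative to real spliceosomal proteins, chosen for desk-scale
#'   runtimes; lengths are uniform in the range).
#' @param seed integer seed; same seed gives byte-identical panels.
#' @param n_groups number of 2-member paralogue groups to create (from the
#'   first `2 * n_groups` entries).
#' @return a `panel`; categories are sampled from the standard vocabulary.
#' @export
make_panel <- function(n, length_range = c(100, 250), seed = 1,
                       n_groups = 0) {
  stopifnot(n >= 1, 2 * n_groups <= n)
  ids <- sprintf("SYN%03d", seq_len(n))
  seqs <- character(n); cats <- character(n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(seed, "panelgene", i), {
      len <- sample(length_range[1]:length_range[2], 1)
      seqs[i] <- random_protein(len)
      cats[i] <- sample(PANEL_CATEGORIES, 1)
    })
  }
  grp <- rep("", n)
  if (n_groups > 0)
    for (g in seq_len(n_groups)) grp[c(2 * g - 1, 2 * g)] <- sprintf("g%02d", g)
  entries <- data.frame(id = ids, name = ids, category = cats,
                        paralogue_group = grp, stringsAsFactors = FALSE)
  names(seqs) <- ids
  groups <- split(ids[nzchar(grp)], grp[nzchar(grp)])
  new_panel(entries, seqs, groups)
}

#' Generate a decoy (background) protein set
#' @param n number of decoys.
#' @param length_range aa length range.
#' @param seed integer seed.
#' @return named character vector `DECOY###`.
#' @export
make_decoys <- function(n, length_range = c(100, 250), seed = 1) {
  out <- character(n)
  for (i in seq_len(n))
    with_seed(derive_seed(seed, "decoy", i), {
      out[i] <- random_protein(sample(length_range[1]:length_range[2], 1))
    })
  stats::setNames(out, sprintf("DECOY%03d", seq_len(n)))
}

#' Evolve an orthologue by per-site substitution
#'
#' Each site is substituted independently with probability `divergence`;
#' the replacement is uniform over the other 19 residues.
#'
#' @param protein amino-acid sequence.
#' @param divergence expected substitutions per site, in \[0, 1).
#' @param seed integer seed.
#' @return the diverged sequence (same length).
#' @export
evolve_orthologue <- function(protein, divergence, seed = 1) {
  stopifnot(divergence >= 0, divergence < 1)
  if (divergence == 0) return(protein)
  with_seed(seed, {
    ch <- strsplit(protein, "")[[1]]
    hit <- stats::runif(length(ch)) < divergence
    if (any(hit))
      ch[hit] <- vapply(ch[hit], function(r)
        sample(setdiff(AA20, r), 1), character(1))
    paste(ch, collapse = "")
  })
}

mutate_nt <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T")
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

#' Default (easy) generation scenario
#'
#' The conditions under which every truth field is recoverable by the
#' analysis modules at their default settings: moderate orthologue
#' divergence, no length variation, a small duplication and chimera load,
#' and the study-level trans-splicing prevalence of 0.727.
#'
#' @param ... overrides for individual fields.
#' @return named list of scenario parameters.
#' @export
scenario_easy <- function(...) {
  s <- list(present_fraction = 0.9, divergence = 0.15,
            two_copy_rate = 0.1, copy_nt_divergence = 0.10,
            chimera_rate = 0.05, sl_prevalence = 0.727,
            sl_seq = default_sl(), utr_range = c(20, 80),
            n_background = 10, background_len = c(300, 600))
  utils::modifyList(s, list(...))
}

#' Paper-scale scenario (presence fraction of the published screen)
#' @param ... overrides.
#' @return named list; like [scenario_easy()] but with presence 166/241 and
#'   higher divergence 0.3.
#' @export
scenario_paperlike <- function(...) {
  scenario_easy(present_fraction = 166 / 241, divergence = 0.3, ...)
}

#' The packaged synthetic SL exon (24-mer)
#'
#' The organism's real SL exon sequence is not printed in the source study,
#' so the generator ships a fixed synthetic 24-mer; any SL sequence can be
#' supplied instead.
#' @return character scalar.
#' @export
default_sl <- function() {
  read_fasta(system.file("extdata", "sl_exon_synthetic.fa",
                         package = "spliceopanel"), "DNA")[[1]]
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Present panel genes receive a diverged, back-translated CDS flanked by
#' random UTRs (the short-read-assembly emulation); a controlled fraction
#' get a second, nucleotide-diverged copy; chimeras fuse the head of one
#' gene transcript to the tail of another; full-length reads are the same
#' transcripts with the SL exon prepended per gene with probability
#' `sl_prevalence`.
#'
#' @param panel a `panel` (the truth reference).
#' @param scenario a [scenario_easy()]-style list.
#' @param seed integer seed.
#' @return list with `ngs` (named transcript set), `fl` (named full-length
#'   read set), `truth` (per-gene data.frame: `panel_id`, `present`,
#'   `copy_count`, `divergence`, `sl_added`), `chimera_truth` (data.frame
#'   `record_id`, `gene_a`, `gene_b`, `breakpoint`), and `read_gene_map`
#'   (named vector read id -> gene id).
#' @export
make_transcriptome <- function(panel, scenario = scenario_easy(), seed = 1) {
  ids <- panel$entries$id
  n <- length(ids)
  ngs <- character(0); fl <- character(0)
  truth <- data.frame(panel_id = ids, present = FALSE, copy_count = 0L,
                      divergence = scenario$divergence, sl_added = FALSE,
                      stringsAsFactors = FALSE)
  read_gene_map <- character(0)
  for (i in seq_len(n)) {
    gid <- ids[i]
    with_seed(derive_seed(seed, "tx", i), {
      present <- stats::runif(1) < scenario$present_fraction
      truth$present[i] <- present
      if (present) {
        copies <- 1L + as.integer(stats::runif(1) < scenario$two_copy_rate)
        truth$copy_count[i] <- copies
        prot <- evolve_orthologue(panel$sequences[[gid]], scenario$divergence,
                                  derive_seed(seed, "div", i))
        cds <- back_translate(prot)
        for (k in seq_len(copies)) {
          cds_k <- if (k == 1) cds else
            mutate_nt(cds, scenario$copy_nt_divergence)
          u5 <- random_nt(sample(scenario$utr_range[1]:scenario$utr_range[2], 1))
          u3 <- random_nt(sample(scenario$utr_range[1]:scenario$utr_range[2], 1))
          tx <- paste0(u5, cds_k, u3)
          tid <- if (copies == 1) paste0("tx_", gid) else
            paste0("tx_", gid, letters[k])
          ngs[tid] <- tx
          sl_added <- stats::runif(1) < scenario$sl_prevalence
          truth$sl_added[i] <- truth$sl_added[i] || sl_added
          rid <- paste0("fl_", tid)
          fl[rid] <- if (sl_added) paste0(scenario$sl_seq, tx) else tx
          read_gene_map[rid] <- gid
        }
      }
    })
  }
  # chimeras: head of gene a + tail of gene b (distinct entries)
  chim <- data.frame(record_id = character(), gene_a = character(),
                     gene_b = character(), breakpoint = integer(),
                     stringsAsFactors = FALSE)
  present_ids <- truth$panel_id[truth$present]
  n_chim <- round(scenario$chimera_rate * length(present_ids))
  if (n_chim >= 1 && length(present_ids) >= 2) {
    with_seed(derive_seed(seed, "chimera"), {
      for (k in seq_len(n_chim)) {
        pair <- sample(present_ids, 2)
        tx_of <- function(g) {
          nm <- paste0("tx_", g)
          if (!nm %in% names(ngs)) nm <- paste0(nm, "a")
          ngs[[nm]]
        }
        ta <- tx_of(pair[1])
        tb <- tx_of(pair[2])
        bp <- floor(nchar(ta) / 2)
        tx <- paste0(substr(ta, 1, bp),
                     substr(tb, floor(nchar(tb) / 2) + 1, nchar(tb)))
        rid <- sprintf("tx_chimera%02d", k)
        ngs[rid] <- tx
        chim[k, ] <- list(rid, pair[1], pair[2], bp)
      }
    })
  }
  if (scenario$n_background > 0) {
    for (k in seq_len(scenario$n_background))
      with_seed(derive_seed(seed, "bg", k), {
        ngs[sprintf("tx_background%02d", k)] <-
          random_nt(sample(scenario$background_len[1]:scenario$background_len[2], 1))
      })
  }
  list(ngs = ngs, fl = fl, truth = truth, chimera_truth = chim,
       read_gene_map = read_gene_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate synthetic genomic contigs with ground truth
#'
#' Each selected gene's CDS is split by the stated number of introns
#' (each `GT ... AG` on the gene strand) inside one contig with random
#' flanks; one additional contig carries a tandem array of `tandem_copies`
#' copies of `snrna_unit` separated by spacers.
#'
#' @param panel a `panel`.
#' @param intron_table named integer vector: introns per selected gene id
#'   (0 allowed).
#' @param snrna_unit nucleotide sequence of the small-RNA unit (or `NULL`
#'   for no array contig).
#' @param tandem_copies copies in the array (>= 0).
#' @param spacer_range inter-copy gap range in nt, default `c(300, 600)`
#'   (start-to-start spacing stays sub-kilobase for a ~200 nt unit).
#' @param seed integer seed.
#' @param intron_len_range intron length range, default `c(40, 120)`.
#' @param flank_range contig flank length range, default `c(100, 300)`.
#' @param divergence amino-acid divergence applied to the genomic copy,
#'   default 0 (the genome matches the panel protein).
#' @param array_strand strand of the tandem array, `"+"` or `"-"`.
#' @return list with `contigs` (named nucleotide vector) and `truth`
#'   (data.frame `panel_id`, `contig_id`, `intron_count`; plus one row per
#'   array with `element` and `copy_count` in `array_truth`).
#' @export
make_genome <- function(panel, intron_table, snrna_unit = NULL,
                        tandem_copies = 0, spacer_range = c(300, 600),
                        seed = 1, intron_len_range = c(40, 120),
                        flank_range = c(100, 300), divergence = 0,
                        array_strand = "+") {
  contigs <- character(0)
  truth <- data.frame(panel_id = character(), contig_id = character(),
                      intron_count = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(intron_table)) {
    gid <- names(intron_table)[i]
    stopifnot(gid %in% panel$entries$id)
    k <- intron_table[[i]]
    with_seed(derive_seed(seed, "contig", i), {
      prot <- panel$sequences[[gid]]
      if (divergence > 0)
        prot <- evolve_orthologue(prot, divergence,
                                  derive_seed(seed, "gdiv", i))
      cds <- back_translate(prot)
      L <- nchar(cds)
      # k interior cut points at codon boundaries, near-equally spaced with
      # jitter so every exon stays large enough for translated search
      cuts <- integer(0)
      if (k > 0) {
        base <- round(L * seq_len(k) / (k + 1) / 3) * 3
        jit <- sample(-2:2, k, replace = TRUE) * 3
        cuts <- sort(pmin(pmax(base + jit, 3), L - 3))
        cuts <- unique(cuts)
      }
      starts <- c(1, cuts + 1)
      ends <- c(cuts, L)
      exons <- substring(cds, starts, ends)
      introns <- vapply(seq_len(k), function(j) {
        len <- sample(intron_len_range[1]:intron_len_range[2], 1)
        paste0("GT", random_nt(len - 4), "AG")
      }, character(1))
      body <- exons[1]
      for (j in seq_len(k)) body <- paste0(body, introns[j], exons[j + 1])
      f5 <- random_nt(sample(flank_range[1]:flank_range[2], 1))
      f3 <- random_nt(sample(flank_range[1]:flank_range[2], 1))
      cid <- paste0("contig_", gid)
      contigs[cid] <- paste0(f5, body, f3)
      truth <- rbind(truth, data.frame(panel_id = gid, contig_id = cid,
                                       intron_count = k,
                                       stringsAsFactors = FALSE))
    })
  }
  array_truth <- NULL
  if (!is.null(snrna_unit) && tandem_copies > 0) {
    with_seed(derive_seed(seed, "array"), {
      unit <- check_nucleotide(snrna_unit, "snRNA unit")
      if (array_strand == "-")
        unit <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(unit)))
      parts <- character(0)
      for (k in seq_len(tandem_copies)) {
        parts <- c(parts, unit)
        if (k < tandem_copies)
          parts <- c(parts, random_nt(sample(spacer_range[1]:spacer_range[2], 1)))
      }
      f5 <- random_nt(sample(flank_range[1]:flank_range[2], 1))
      f3 <- random_nt(sample(flank_range[1]:flank_range[2], 1))
      contigs["contig_array"] <- paste0(f5, paste(parts, collapse = ""), f3)
      array_truth <- data.frame(contig_id = "contig_array",
                                 element = "snrna_unit",
                                 copy_count = tandem_copies,
                                 strand = array_strand,
                                 stringsAsFactors = FALSE)
    })
  }
  list(contigs = contigs, truth = truth, array_truth = array_truth)
}

#' Write a full synthetic scenario to disk
#'
#' Emits `panel.fa`, `panel.tsv`, `ngs.fa`, `flreads.fa`, `contigs.fa`,
#' `truth.tsv` and `scenario.json` under `out_dir`; byte-identical for a
#' fixed (seed, scenario).
#'
#' @param out_dir output directory (created if needed).
#' @param scenario `"easy"`, `"paperlike"`, or a scenario list.
#' @param seed integer seed.
#' @param n_genes panel size, default 60.
#' @param length_range panel protein lengths.
#' @return invisibly, the generated objects.
#' @export
synth_make <- function(out_dir, scenario = "easy", seed = 1, n_genes = 60,
                       length_range = c(100, 250)) {
  sc <- if (is.character(scenario)) {
    switch(scenario, easy = scenario_easy(), paperlike = scenario_paperlike(),
           stop("unknown scenario: ", scenario))
  } else scenario
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_panel(n_genes, length_range, seed)
  tr <- make_transcriptome(panel, sc, seed)
  present <- tr$truth$panel_id[tr$truth$present]
  intron_table <- stats::setNames(
    rep_len(0:3, length.out = min(5, length(present))),
    utils::head(present, 5))
  gen <- make_genome(panel, intron_table,
                     snrna_unit = substr(back_translate(
                       panel$sequences[[1]], stop = FALSE), 1, 150),
                     tandem_copies = 4, seed = seed)
  write_fasta(panel$sequences, file.path(out_dir, "panel.fa"), "AA")
  utils::write.table(panel$entries, file.path(out_dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(tr$ngs, file.path(out_dir, "ngs.fa"))
  write_fasta(tr$fl, file.path(out_dir, "flreads.fa"))
  write_fasta(gen$contigs, file.path(out_dir, "contigs.fa"))
  utils::write.table(tr$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(sc, list(seed = seed, n_genes = n_genes)),
                       file.path(out_dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(panel = panel, transcriptome = tr, genome = gen,
                 scenario = sc))
}
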