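# Readers/writers for the pipeline's plain-text formats. TSVs carry a header
# row and use '.' for missing values; FASTA is wrapped at 80 columns; JSON
# summaries are pretty-printed with stable key order for diffability.

#' Write / read a TSV with '.' as the missing-value marker
#'
#' @param df `data.frame` to write.
#' @param path File path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` returns a
#'   `data.frame`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Write / read transcript sequences as FASTA
#'
#' Record ids are gene ids; sequences are wrapped at 80 columns.
#'
#' @param genes `data.frame` with `gene_id` and `transcript_seq`.
#' @param path File path.
#' @export
write_gene_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(genes$transcript_seq)
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' @rdname write_gene_fasta
#' @export
read_gene_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(gene_id = names(x), transcript_seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Load and validate gene records from FASTA + annotation + counts
#'
#' Cross-references transcript sequences (FASTA, record id = gene id), the
#' annotation TSV (`gene_id`, `cds_end`) and the counts/RPKM TSV (`gene_id`,
#' `mrna_rpkm`, `ribo_cds_rpkm`, `ribo_region1_rpkm`). When several FASTA
#' records share a gene id, the longest transcript is kept (ties: first
#' record). Records violating the gene invariants are dropped with a reason
#' code rather than silently skipped.
#'
#' Reason codes: `no_annotation`, `no_counts`, `cds_end_out_of_range`,
#' `bad_stop` (codon at `cds_end` is not a stop codon), `negative_rpkm`,
#' `non_acgt`.
#'
#' @param fasta_path,annot_path,counts_path Input file paths.
#' @return List with `genes` (validated gene table) and `report` (named drop
#'   counts plus `n_kept`).
#' @export
load_genes <- function(fasta_path, annot_path, counts_path) {
  fa <- read_gene_fasta(fasta_path)
  annot <- read_tsv(annot_path)
  counts <- read_tsv(counts_path)
  stopifnot(all(c("gene_id", "cds_end") %in% names(annot)),
            all(c("gene_id", "mrna_rpkm", "ribo_cds_rpkm",
                  "ribo_region1_rpkm") %in% names(counts)))
  # longest transcript per gene id, ties to the first record
  fa <- fa[order(-nchar(fa$transcript_seq)), ]
  fa <- fa[!duplicated(fa$gene_id), ]
  if (length(intersect(fa$gene_id, counts$gene_id)) == 0L)
    stop("no gene ids shared between FASTA and counts table", call. = FALSE)

  drop <- c(no_annotation = 0L, no_counts = 0L, cds_end_out_of_range = 0L,
            bad_stop = 0L, negative_rpkm = 0L, non_acgt = 0L)
  kept <- list()
  for (i in seq_len(nrow(fa))) {
    gid <- fa$gene_id[i]
    a <- annot[annot$gene_id == gid, ]
    cn <- counts[counts$gene_id == gid, ]
    reason <- NULL
    if (nrow(a) == 0L) reason <- "no_annotation"
    else if (nrow(cn) == 0L) reason <- "no_counts"
    else {
      seq <- fa$transcript_seq[i]
      ce <- a$cds_end[1L]
      if (grepl("[^ACGT]", seq)) reason <- "non_acgt"
      else if (is.na(ce) || ce < 3 || ce > nchar(seq)) reason <- "cds_end_out_of_range"
      else if (!substr(seq, ce - 2L, ce) %in% STOP_CODONS) reason <- "bad_stop"
      else {
        rp <- c(cn$mrna_rpkm[1L], cn$ribo_cds_rpkm[1L], cn$ribo_region1_rpkm[1L])
        if (any(rp < 0, na.rm = TRUE)) reason <- "negative_rpkm"
      }
    }
    if (!is.null(reason)) { drop[reason] <- drop[reason] + 1L; next }
    kept[[length(kept) + 1L]] <- data.frame(
      gene_id = gid, transcript_seq = fa$transcript_seq[i],
      cds_end = as.integer(a$cds_end[1L]),
      mrna_rpkm = cn$mrna_rpkm[1L], ribo_cds_rpkm = cn$ribo_cds_rpkm[1L],
      ribo_region1_rpkm = cn$ribo_region1_rpkm[1L],
      stringsAsFactors = FALSE)
  }
  genes <- if (length(kept)) do.call(rbind, kept) else NULL
  if (is.null(genes)) stop("no gene passed validation", call. = FALSE)
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  list(genes = genes, report = c(as.list(drop), n_kept = nrow(genes)))
}

#' Write a complete set of synthetic pipeline inputs
#'
#' Emits, under `dir`: `transcripts.fasta`, `annotation.tsv`, `counts.tsv`,
#' `rt_genes.txt`, `alignments.tsv` (gene_id / seq_a / seq_b / stop_col plus
#' region lengths) and `truth.json` — the exact input formats the analysis
#' stages consume.
#'
#' @param sim Output of [generate_genes()].
#' @param alignments Output of [generate_ortholog_pairs()] (optional).
#' @param rt_ids Read-through calls (optional).
#' @param truth The [synthetic_truth()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(sim, alignments = NULL, rt_ids = character(0),
                                   truth = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_fasta(sim$genes, file.path(dir, "transcripts.fasta"))
  write_tsv(sim$genes[, c("gene_id", "cds_end")], file.path(dir, "annotation.tsv"))
  write_tsv(sim$genes[, c("gene_id", "mrna_rpkm", "ribo_cds_rpkm",
                          "ribo_region1_rpkm")], file.path(dir, "counts.tsv"))
  writeLines(rt_ids, file.path(dir, "rt_genes.txt"))
  if (!is.null(alignments)) write_tsv(alignments, file.path(dir, "alignments.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Run the full synthetic read-through analysis pipeline
#'
#' Generates a ground-truthed synthetic study, then runs every analysis stage:
#' region extraction, per-gene rates, equal-total-RPKM binning with bootstrap
#' supergene rates and the bin-level Spearman correlation, the selection-
#' removed fraction, motif composition tests, interspecific conservation
#' (identity, codon positions, frame-shifting indels, length differences,
#' expression-matched controls) and hydrophobicity comparisons. All
#' randomness flows from `config$seed`.
#'
#' The conservation block also reports an `adaptive_verdict`: `TRUE` only when
#' read-through genes show BOTH excess region-1 conservation and a
#' frame-shifting-indel deficit (each one-tailed bootstrap P < 0.05) —
#' requiring multiple concordant signals before calling read-through adaptive.
#'
#' @param config List of settings; recognized fields (with defaults):
#'   `seed` (1), `truth` (a [synthetic_truth()]), `world` ("error"),
#'   `n_bins` (10), `n_boot` (1000), `n_shuffles` (10000),
#'   `run_conservation` (TRUE), `run_motifs` (TRUE), `run_hydrophobicity`
#'   (TRUE), `out_dir` (NULL: no files written).
#' @return A nested summary list; written as `summary.json` (plus all result
#'   tables) when `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1, truth = synthetic_truth(), world = "error",
    n_bins = 10, n_boot = 1000, n_shuffles = 10000,
    run_conservation = TRUE, run_motifs = TRUE, run_hydrophobicity = TRUE,
    out_dir = NULL), config)
  truth <- cfg$truth
  sim <- generate_genes(truth, seed = cfg$seed)
  rt_ids <- generate_rt_calls(truth, sim$genes)
  shifted <- apply_hydrophobicity_shift(
    sim$genes, sim$regions, rt_ids, shift = truth$hydrophobicity_shift,
    seed = derive_seed(cfg$seed, 11L))
  sim$genes <- shifted$genes
  sim$regions <- shifted$regions

  summary <- list(provenance = list(
    seed = cfg$seed, world = cfg$world, n_genes = truth$n_genes,
    n_bins = cfg$n_bins, n_boot = cfg$n_boot, n_shuffles = cfg$n_shuffles,
    package_version = as.character(utils::packageVersion("readthroughr"))))

  # rates
  bins <- bin_rate_table(sim$genes, n_bins = cfg$n_bins, n_boot = cfg$n_boot,
                         seed = derive_seed(cfg$seed, 21L))
  sc <- spearman_correlation(bins$median_expression, bins$supergene_rate)
  frac <- fraction_removed_by_selection(bins$supergene_rate[1L],
                                        bins$supergene_rate[nrow(bins)])
  summary$rates <- list(
    bin_rates = bins$supergene_rate, bin_sds = bins$supergene_rate_sd,
    spearman_rho = sc$rho, spearman_p = sc$p_value,
    rate_lowest_bin = bins$supergene_rate[1L],
    rate_highest_bin = bins$supergene_rate[nrow(bins)],
    fraction_removed_by_selection = frac,
    n_rt_calls = length(rt_ids))

  # motifs
  if (isTRUE(cfg$run_motifs)) {
    ctx <- stop_contexts(sim$genes)
    rep_tab <- motif_report(ctx, n_shuffles = cfg$n_shuffles, n_boot = cfg$n_boot,
                            seed = derive_seed(cfg$seed, 31L))
    summary$motifs <- list(
      report = rep_tab,
      mw_p_tgaca = expression_vs_motif_test(ctx, "TGACA")$p_value,
      mw_p_tgact = expression_vs_motif_test(ctx, "TGACT")$p_value,
      fisher_p_tga_top20 = tga_usage_top20_test(ctx)$p_value,
      n_excluded_short_utr = attr(ctx, "n_excluded"))
  }

  # conservation
  if (isTRUE(cfg$run_conservation)) {
    aln <- generate_ortholog_pairs(truth, sim$genes, sim$regions,
                                   seed = derive_seed(cfg$seed, 41L),
                                   world = cfg$world, rt_ids = rt_ids)
    ct <- conservation_table(aln)
    pg <- ct$per_gene
    is_rt <- pg$gene_id %in% rt_ids
    id1_rt <- pg$identity_region1[is_rt]; id1_non <- pg$identity_region1[!is_rt]
    p_excess <- bootstrap_group_p(id1_rt, id1_non, tail = "greater",
                                  n_boot = cfg$n_boot,
                                  seed = derive_seed(cfg$seed, 42L))
    ind <- ct$indels[ct$indels$region == 1L, , drop = FALSE]
    # per-gene event lists: genes are the bootstrap unit, the frameshift
    # fraction is computed from each resample's pooled events
    fs_by_gene <- function(ids) lapply(ids, function(g)
      as.numeric(ind$length_nt[ind$gene_id == g] %% 3L != 0L))
    fs_rt <- fs_by_gene(pg$gene_id[is_rt])
    fs_non <- fs_by_gene(pg$gene_id[!is_rt])
    p_fs_deficit <- if (sum(lengths(fs_rt)) >= 2 && sum(lengths(fs_non)) >= 2)
      bootstrap_group_p(fs_rt, fs_non, tail = "less",
                        n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, 43L))
    else NA_real_
    ld <- length_difference(pg$len_a_region1, pg$len_b_region1)
    keep_len <- !pg$truncated_at_cap
    mw_len <- if (sum(is_rt & keep_len) >= 2 && sum(!is_rt & keep_len) >= 2)
      stats::wilcox.test(ld$relative[is_rt & keep_len],
                         ld$relative[!is_rt & keep_len], exact = FALSE)$p.value
    else NA_real_
    truth_tab <- sim$truth_table
    expr <- truth_tab$expression[match(pg$gene_id, truth_tab$gene_id)]
    emc <- expression_matched_controls(data.frame(
      gene_id = pg$gene_id, expression = expr, is_rt = is_rt,
      value = pg$identity_region1, stringsAsFactors = FALSE))
    cp_p <- codon_position_bootstrap_p(pg$identity_pos12_r1[is_rt],
                                       pg$identity_pos3_r1[is_rt],
                                       n_boot = cfg$n_boot,
                                       seed = derive_seed(cfg$seed, 44L))
    summary$conservation <- list(
      n_alignments = nrow(aln), n_qc_fail = ct$n_qc_fail,
      mean_identity_region1_rt = mean(id1_rt, na.rm = TRUE),
      mean_identity_region1_nonrt = mean(id1_non, na.rm = TRUE),
      mean_identity_region2_rt = mean(pg$identity_region2[is_rt], na.rm = TRUE),
      mean_identity_region2_nonrt = mean(pg$identity_region2[!is_rt], na.rm = TRUE),
      p_region1_excess_conservation = p_excess,
      frameshift_fraction_rt = frameshift_fraction(ind[ind$gene_id %in% rt_ids, ]),
      frameshift_fraction_nonrt = frameshift_fraction(ind[!ind$gene_id %in% rt_ids, ]),
      p_frameshift_deficit = p_fs_deficit,
      mean_abs_lendiff_rt = mean(ld$absolute_nt[is_rt & keep_len], na.rm = TRUE),
      mean_abs_lendiff_nonrt = mean(ld$absolute_nt[!is_rt & keep_len], na.rm = TRUE),
      mw_p_relative_lendiff = mw_len,
      codon_position_p_rt = cp_p,
      matched_control_p = emc$p_value,
      adaptive_verdict = isTRUE(p_excess < 0.05) && isTRUE(p_fs_deficit < 0.05))
    per_gene_conservation <- pg
  }

  # hydrophobicity
  if (isTRUE(cfg$run_hydrophobicity)) {
    prof <- peptide_profiles(sim$genes, sim$regions)
    hydro <- lapply(c(cds_tail = "cds_tail", region1 = "region1",
                      region2 = "region2"), function(src) {
      group_hydrophobicity_comparison(prof, rt_ids, src, n_boot = cfg$n_boot,
                                      seed = derive_seed(cfg$seed, 51L + match(
                                        src, c("cds_tail", "region1", "region2"))))
    })
    summary$hydrophobicity <- hydro
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_synthetic_inputs(sim, rt_ids = rt_ids, truth = truth, dir = cfg$out_dir)
    write_tsv(sim$regions[, setdiff(names(sim$regions),
                                    c("region1_seq", "region2_seq"))],
              file.path(cfg$out_dir, "regions.tsv"))
    write_tsv(bins, file.path(cfg$out_dir, "bins.tsv"))
    if (isTRUE(cfg$run_motifs))
      write_tsv(summary$motifs$report, file.path(cfg$out_dir, "motif_report.tsv"))
    if (isTRUE(cfg$run_conservation))
      write_tsv(per_gene_conservation, file.path(cfg$out_dir, "conservation.tsv"))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  summary
}
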