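HYDROPHOBIC_AA <- c("G", "A", "V", "I", "L", "M", "F", "Y", "W")

#' Translate a DNA segment in the standard genetic code
#'
#' A trailing partial codon (as left by a capped region) is dropped. An
#' internal stop codon is an error: regions are delineated so that they cannot
#' contain one, so hitting one signals corrupt input upstream.
#'
#' @param dna DNA string (A/C/G/T); may be empty.
#' @return Amino-acid string (one-letter code).
#' @examples
#' translate_dna("ATGGGT")  # "MG"
#' @export
translate_dna <- function(dna) {
  stopifnot(length(dna) == 1L)
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n == 0L) return("")
  dna <- substr(dna, 1L, n)
  check_dna(dna)
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                            no.init.codon = TRUE))
  if (grepl("*", pep, fixed = TRUE))
    stop("internal stop codon in segment expected to be stop-free", call. = FALSE)
  pep
}

#' Fraction of hydrophobic residues in a peptide
#'
#' The hydrophobic set is the 9-residue membership rule G, A, V, I, L, M, F,
#' Y, W.
#'
#' @param peptide Amino-acid string (one-letter code).
#' @return Fraction in `[0, 1]`; `NA` for an empty peptide.
#' @examples
#' hydrophobic_fraction("GAVILMFYW")  # 1
#' @export
hydrophobic_fraction <- function(peptide) {
  stopifnot(length(peptide) == 1L)
  if (nchar(peptide) == 0L) return(NA_real_)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  mean(chars %in% HYDROPHOBIC_AA)
}

#' Peptide profiles: CDS tail, region-1 and region-2 extensions
#'
#' For every gene, conceptually translates (i) the last 16 codons of the
#' coding region before the canonical stop, (ii) region 1 and (iii) region 2,
#' and records each peptide's hydrophobic fraction. Proteins shorter than 16
#' residues use the whole protein (flagged `short_cds`); genes with an absent
#' region yield no row for that source. Capped regions are included and
#' flagged.
#'
#' @param genes Gene table (`gene_id`, `transcript_seq`, `cds_end`).
#' @param regions Output of [extract_regions_table()] for the same genes.
#' @param tail_codons Number of terminal CDS codons (default 16).
#' @return `data.frame` with `gene_id`, `source` (`cds_tail` / `region1` /
#'   `region2`), `peptide`, `hydrophobic_fraction`, `short_cds`,
#'   `truncated_at_cap`.
#' @export
peptide_profiles <- function(genes, regions, tail_codons = 16) {
  stopifnot(all(genes$gene_id == regions$gene_id))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]; r <- regions[i, ]
    cds_len_codons <- (g$cds_end - 3L) %/% 3L  # codons before the stop
    use <- min(tail_codons, cds_len_codons)
    tail_seq <- substr(g$transcript_seq, g$cds_end - 3L - use * 3L + 1L, g$cds_end - 3L)
    segs <- list(cds_tail = tail_seq, region1 = r$region1_seq, region2 = r$region2_seq)
    for (src in names(segs)) {
      pep <- translate_dna(segs[[src]])
      if (nchar(pep) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, source = src, peptide = pep,
        hydrophobic_fraction = hydrophobic_fraction(pep),
        short_cds = use < tail_codons,
        truncated_at_cap = r$truncated_at_cap,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare hydrophobicity between read-through and non-read-through genes
#'
#' Group means are unweighted means of per-gene hydrophobic fractions
#' (bootstrap is over genes, matching the error-bar construction of the
#' profile plots); the one-tailed P tests the alternative that read-through
#' genes are LESS hydrophobic, via [bootstrap_group_p()].
#'
#' @param profiles Output of [peptide_profiles()].
#' @param rt_ids Character vector of read-through gene ids.
#' @param source One of `"cds_tail"`, `"region1"`, `"region2"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional seed.
#' @return List with `mean_rt`, `mean_nonrt`, `se_rt`, `se_nonrt`,
#'   `one_tailed_p`, `n_rt`, `n_nonrt`.
#' @export
group_hydrophobicity_comparison <- function(profiles, rt_ids, source,
                                            n_boot = 1000, seed = NULL) {
  source <- match.arg(source, c("cds_tail", "region1", "region2"))
  p <- profiles[profiles$source == source, , drop = FALSE]
  rt <- p$hydrophobic_fraction[p$gene_id %in% rt_ids]
  nonrt <- p$hydrophobic_fraction[!p$gene_id %in% rt_ids]
  stopifnot(length(rt) >= 2, length(nonrt) >= 2)
  boot_se <- function(v, s) with_seed(s, {
    stats::sd(vapply(seq_len(n_boot), function(b)
      mean(v[sample.int(length(v), length(v), replace = TRUE)]), numeric(1)))
  })
  list(
    mean_rt = mean(rt), mean_nonrt = mean(nonrt),
    se_rt = boot_se(rt, derive_seed(seed, 1L)),
    se_nonrt = boot_se(nonrt, derive_seed(seed, 2L)),
    one_tailed_p = bootstrap_group_p(rt, nonrt, tail = "less",
                                     n_boot = n_boot, seed = derive_seed(seed, 3L)),
    n_rt = length(rt), n_nonrt = length(nonrt)
  )
}
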