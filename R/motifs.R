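#' Stop-codon contexts for a gene table
#'
#' Extracts, per gene, the canonical stop codon and the two nucleotides
#' immediately downstream — the three components of the read-through motifs
#' TGACA and TGACT — plus the gene's expression on the log2(RPKM + 1) scale.
#' Genes whose 3'UTR is shorter than 2 nt cannot carry a full context and are
#' dropped (count reported via the `n_excluded` attribute).
#'
#' @param genes `data.frame` with `gene_id`, `transcript_seq`, `cds_end` and
#'   `mrna_rpkm`.
#' @return `data.frame` with `gene_id`, `stop_codon`, `plus1`, `plus2`,
#'   `expression`.
#' @export
stop_contexts <- function(genes) {
  stopifnot(all(c("gene_id", "transcript_seq", "cds_end", "mrna_rpkm") %in% names(genes)))
  utr_len <- nchar(genes$transcript_seq) - genes$cds_end
  keep <- utr_len >= 2
  g <- genes[keep, , drop = FALSE]
  out <- data.frame(
    gene_id = g$gene_id,
    stop_codon = substr(g$transcript_seq, g$cds_end - 2L, g$cds_end),
    plus1 = substr(g$transcript_seq, g$cds_end + 1L, g$cds_end + 1L),
    plus2 = substr(g$transcript_seq, g$cds_end + 2L, g$cds_end + 2L),
    expression = log2(g$mrna_rpkm + 1),
    stringsAsFactors = FALSE
  )
  bad <- !out$stop_codon %in% STOP_CODONS
  if (any(bad)) stop(sprintf("gene %s: codon at cds_end is not a stop codon",
                             out$gene_id[which(bad)[1L]]), call. = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Does a stop-codon context carry a read-through motif?
#'
#' The motifs TGACA and TGACT (stop codon underlined in the field's notation)
#' require the TGA stop codon, a C at +1 and the motif's fifth base at +2.
#' Vectorized over contexts.
#'
#' @param stop_codon,plus1,plus2 Context components (character vectors).
#' @param motif `"TGACA"` or `"TGACT"`.
#' @return Logical vector.
#' @export
motif_present <- function(stop_codon, plus1, plus2, motif) {
  motif <- match.arg(motif, c("TGACA", "TGACT"))
  stop_codon == "TGA" & plus1 == "C" & plus2 == substr(motif, 5, 5)
}

#' Split contexts into expression tertiles of equal gene counts
#'
#' Genes are ranked by expression (ties broken by `gene_id`) and divided into
#' three bins of equal size; when the count is not divisible by 3 the extra
#' genes go to the lower bins.
#'
#' @param contexts Output of [stop_contexts()].
#' @return The input with an integer `bin` column (1 = low, 3 = high
#'   expression). Degenerate input (all expressions equal) is still binned; a
#'   `degenerate` attribute flags it.
#' @export
tertile_bins <- function(contexts) {
  n <- nrow(contexts)
  stopifnot(n >= 3)
  ord <- order(contexts$expression, contexts$gene_id)
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- contexts[ord, , drop = FALSE]
  out$bin <- rep(1:3, times = sizes)
  rownames(out) <- NULL
  attr(out, "degenerate") <- stats::sd(contexts$expression) == 0
  out
}

#' Expected motif frequency from component frequencies
#'
#' The frequency expected if the three motif components combined independently:
#' the product of the within-bin frequencies of (stop codon == TGA),
#' (+1 == C) and (+2 == motif's fifth base).
#'
#' @param contexts Contexts of one expression bin.
#' @param motif `"TGACA"` or `"TGACT"`.
#' @return Expected frequency in `[0, 1]`.
#' @export
expected_motif_frequency <- function(contexts, motif) {
  motif <- match.arg(motif, c("TGACA", "TGACT"))
  stopifnot(nrow(contexts) > 0)
  mean(contexts$stop_codon == "TGA") *
    mean(contexts$plus1 == "C") *
    mean(contexts$plus2 == substr(motif, 5, 5))
}

#' Component-shuffling test for motif underrepresentation
#'
#' Each shuffle independently permutes the stop-codon column, the +1 column and
#' the +2 column across the bin's genes (a permutation per column, so component
#' margins are preserved exactly), then counts genes carrying the motif.
#' `p_deficit` is the fraction of shuffles whose motif count is less than or
#' equal to the observed count — small when the observed combinatorial use of
#' the components is deficient relative to independence.
#'
#' @param contexts Contexts of one expression bin (>= 2 genes).
#' @param motif `"TGACA"` or `"TGACT"`.
#' @param n_shuffles Number of shuffles (default 10000).
#' @param seed Optional seed (deterministic result).
#' @return List with `observed_count`, `expected_count` (mean over shuffles)
#'   and `p_deficit`.
#' @export
shuffle_test <- function(contexts, motif, n_shuffles = 10000, seed = NULL) {
  motif <- match.arg(motif, c("TGACA", "TGACT"))
  n <- nrow(contexts)
  stopifnot(n >= 2)
  is_tga <- contexts$stop_codon == "TGA"
  is_c <- contexts$plus1 == "C"
  is_b5 <- contexts$plus2 == substr(motif, 5, 5)
  observed <- sum(is_tga & is_c & is_b5)
  counts <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      sum(is_tga[sample.int(n)] & is_c[sample.int(n)] & is_b5[sample.int(n)])
    }, numeric(1))
  })
  list(observed_count = observed,
       expected_count = mean(counts),
       p_deficit = mean(counts <= observed))
}

#' Mann-Whitney U test of expression between motif carriers and non-carriers
#'
#' @param contexts Output of [stop_contexts()] (whole genome, not one bin).
#' @param motif `"TGACA"` or `"TGACT"`.
#' @return List with `p_value` (two-sided, tie-corrected), `n_carrier`,
#'   `n_noncarrier`, `U`. `p_value` is `NA` when either group is empty.
#' @export
expression_vs_motif_test <- function(contexts, motif) {
  carrier <- motif_present(contexts$stop_codon, contexts$plus1, contexts$plus2, motif)
  x <- contexts$expression[carrier]
  y <- contexts$expression[!carrier]
  if (length(x) == 0L || length(y) == 0L)
    return(list(p_value = NA_real_, n_carrier = length(x),
                n_noncarrier = length(y), U = NA_real_))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  list(p_value = wt$p.value, n_carrier = length(x), n_noncarrier = length(y),
       U = unname(wt$statistic))
}

#' Fisher's exact test of TGA usage in the most highly expressed genes
#'
#' Builds the 2x2 table (top 20% by expression vs the rest) x (TGA vs other
#' stop codon) and applies the two-sided exact hypergeometric test.
#'
#' @param contexts Output of [stop_contexts()].
#' @param top_fraction Fraction of genes forming the highly expressed group
#'   (default 0.2).
#' @return List with `p_value`, `odds_ratio` (sample OR, cross-product), and
#'   the 2x2 `table`.
#' @export
tga_usage_top20_test <- function(contexts, top_fraction = 0.2) {
  n <- nrow(contexts)
  stopifnot(n >= 5)
  ord <- order(contexts$expression, contexts$gene_id, decreasing = TRUE)
  n_top <- max(1L, round(top_fraction * n))
  top <- logical(n)
  top[ord[seq_len(n_top)]] <- TRUE
  tga <- contexts$stop_codon == "TGA"
  tab <- matrix(c(sum(top & tga), sum(top & !tga),
                  sum(!top & tga), sum(!top & !tga)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("top20", "rest"),
                                stop = c("TGA", "other")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = ft$p.value, odds_ratio = or, table = tab)
}

#' Bootstrap SD of a within-bin motif frequency
#'
#' Resamples the bin's genes with replacement and returns the standard
#' deviation of the motif carrier frequency across resamples.
#'
#' @inheritParams shuffle_test
#' @param n_boot Number of resamples (default 1000).
#' @return Bootstrap SD.
#' @export
bootstrap_motif_freq_sd <- function(contexts, motif, n_boot = 1000, seed = NULL) {
  n <- nrow(contexts)
  stopifnot(n >= 2)
  carrier <- motif_present(contexts$stop_codon, contexts$plus1, contexts$plus2, motif)
  freqs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) mean(carrier[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  stats::sd(freqs)
}

#' Per-bin motif report
#'
#' For each expression tertile and each read-through motif: observed carrier
#' frequency, bootstrap SD, expected frequency from component independence,
#' and the shuffle-deficit P. Component frequencies (TGA, +1 C, +2 A/T pooled)
#' are reported alongside.
#'
#' @param contexts Output of [stop_contexts()].
#' @param n_shuffles Shuffles per bin/motif (default 10000).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Master seed; per-bin/motif streams are derived from it.
#' @return `data.frame` with one row per bin x motif.
#' @export
motif_report <- function(contexts, n_shuffles = 10000, n_boot = 1000, seed = NULL) {
  binned <- tertile_bins(contexts)
  rows <- list()
  for (b in 1:3) {
    ctx <- binned[binned$bin == b, , drop = FALSE]
    for (m in c("TGACA", "TGACT")) {
      idx <- b * 10L + match(m, c("TGACA", "TGACT"))
      st <- shuffle_test(ctx, m, n_shuffles = n_shuffles,
                         seed = derive_seed(seed, idx))
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, motif = m, n_genes = nrow(ctx),
        observed_freq = st$observed_count / nrow(ctx),
        boot_sd = bootstrap_motif_freq_sd(ctx, m, n_boot = n_boot,
                                          seed = derive_seed(seed, idx + 100L)),
        expected_freq = expected_motif_frequency(ctx, m),
        p_deficit = st$p_deficit,
        freq_tga = mean(ctx$stop_codon == "TGA"),
        freq_plus1_c = mean(ctx$plus1 == "C"),
        freq_plus2_at = mean(ctx$plus2 %in% c("A", "T")),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
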