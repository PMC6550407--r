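# Ground-truthed synthetic inputs emulating a ribosome-profiling read-through
# study: log-normal expression, Poisson-sampled mRNA/ribo counts with an
# expression-dependent true read-through rate, stop-codon contexts with
# expression-tertile-dependent component frequencies, and pairwise ortholog
# alignments with controllable substitution/indel processes.

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
})

codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Ground-truth parameter set for the synthetic study
#'
#' Defaults emulate the scale of a budding-yeast ribo-seq/mRNA-seq read-through
#' study: log-normal mRNA abundance, a true read-through rate declining with
#' expression as `r(e) = r0 * (1 + e)^(-b)` (so the rate is bounded by `r0`),
#' stop-codon component frequencies that shift away from TGA/C with rising
#' expression, uniform-ACGT 3'UTRs (in-frame stop probability 3/64 per codon,
#' hence region-1 lengths on the observed tens-of-nt scale), and
#' substitution/indel divergence typical of sister species.
#'
#' @param n_genes Number of genes (default 3000).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of mRNA
#'   RPKM (defaults 2 and 1.5).
#' @param r0 Intrinsic (unselected) read-through rate (default 0.04).
#' @param b Expression-decay exponent of the rate function (default 0.2;
#'   b = 0 gives a constant-rate null world).
#' @param motif_component_probs List of three tertile-level lists, each with
#'   `stop` (probabilities of TAA/TAG/TGA), `plus1` and `plus2`
#'   (probabilities of A/C/G/T).
#' @param library_size_mrna,library_size_ribo Mapped-read totals (default 2e7).
#' @param translation_factor Ribo-seq coverage multiplier relative to mRNA
#'   abundance (default 2).
#' @param cds_len_range,utr_len_range Length ranges in nt (CDS drawn as whole
#'   codons).
#' @param substitution_rate Per-site substitution probability between the
#'   species pair (default 0.10).
#' @param indel_rate Per-site probability of starting an indel (default 0.01).
#' @param indel_geom_p Geometric length parameter; indel length is
#'   `1 + rgeom(indel_geom_p)`, mean 3 at the default 1/3.
#' @param region1_purifying_factor Multiplier (< 1) on region-1 substitution
#'   rates of read-through genes in the adaptive world (default 0.5); indels
#'   there are forced in-frame with probability `1 - factor`.
#' @param hydrophobicity_shift Reduction in region-1 hydrophobic fraction of
#'   read-through genes (default 0.1; 0 disables).
#' @param rt_threshold Region-1 ribo read count that must be exceeded for a
#'   read-through call (default 4).
#' @param cap_nt Downstream region cap (default 300).
#' @param ortholog_upstream_nt Aligned flank upstream of the stop (default 50).
#' @return A `synthetic_truth` list (validated).
#' @export
synthetic_truth <- function(n_genes = 3000,
                            expression_meanlog = 2, expression_sdlog = 1.5,
                            r0 = 0.04, b = 0.2,
                            motif_component_probs = default_motif_probs(),
                            library_size_mrna = 2e7, library_size_ribo = 2e7,
                            translation_factor = 2,
                            cds_len_range = c(300, 3000),
                            utr_len_range = c(60, 400),
                            substitution_rate = 0.10,
                            indel_rate = 0.01, indel_geom_p = 1 / 3,
                            region1_purifying_factor = 0.5,
                            hydrophobicity_shift = 0.1,
                            rt_threshold = 4,
                            cap_nt = 300, ortholog_upstream_nt = 50) {
  truth <- list(
    n_genes = n_genes, expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog, r0 = r0, b = b,
    motif_component_probs = motif_component_probs,
    library_size_mrna = library_size_mrna, library_size_ribo = library_size_ribo,
    translation_factor = translation_factor,
    cds_len_range = cds_len_range, utr_len_range = utr_len_range,
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    indel_geom_p = indel_geom_p,
    region1_purifying_factor = region1_purifying_factor,
    hydrophobicity_shift = hydrophobicity_shift,
    rt_threshold = rt_threshold, cap_nt = cap_nt,
    ortholog_upstream_nt = ortholog_upstream_nt)
  stopifnot(n_genes >= 10, r0 >= 0, r0 <= 1, b >= 0,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate < 1,
            indel_geom_p > 0, indel_geom_p <= 1,
            region1_purifying_factor > 0, region1_purifying_factor <= 1,
            rt_threshold >= 0, cap_nt >= 3)
  for (tp in motif_component_probs) {
    stopifnot(abs(sum(tp$stop) - 1) < 1e-8, abs(sum(tp$plus1) - 1) < 1e-8,
              abs(sum(tp$plus2) - 1) < 1e-8)
  }
  class(truth) <- "synthetic_truth"
  truth
}

#' @rdname synthetic_truth
#' @export
default_motif_probs <- function() {
  list(
    low = list(stop = c(TAA = 0.45, TAG = 0.23, TGA = 0.32),
               plus1 = c(A = 0.38, C = 0.16, G = 0.16, T = 0.30),
               plus2 = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)),
    medium = list(stop = c(TAA = 0.48, TAG = 0.23, TGA = 0.29),
                  plus1 = c(A = 0.39, C = 0.14, G = 0.17, T = 0.30),
                  plus2 = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)),
    high = list(stop = c(TAA = 0.52, TAG = 0.23, TGA = 0.25),
                plus1 = c(A = 0.40, C = 0.11, G = 0.19, T = 0.30),
                plus2 = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30))
  )
}

true_rate <- function(truth, expression) {
  truth$r0 * (1 + expression)^(-truth$b)
}

#' Generate a synthetic gene set with ground truth
#'
#' Draws per-gene expression, builds transcripts (stop-free CDS, stop-codon
#' context from the expression tertile's component probabilities, uniform-ACGT
#' 3'UTR), samples mRNA and ribo-seq counts from Poisson distributions whose
#' region-1 intensity follows the true read-through rate, and computes RPKMs.
#' RNG streams are split per stage, so downstream generator stages never
#' perturb gene-level draws.
#'
#' @param truth A [synthetic_truth()] object.
#' @param seed Master seed (integer); the output is deterministic given it.
#' @return List with `genes` (gene table: sequences, counts, RPKMs), `regions`
#'   (from [extract_regions_table()]) and `truth_table` (per-gene true
#'   expression, rate, tertile and Poisson intensities).
#' @export
generate_genes <- function(truth, seed = 1) {
  n <- truth$n_genes
  expression <- with_seed(derive_seed(seed, 1L),
                          stats::rlnorm(n, truth$expression_meanlog,
                                        truth$expression_sdlog))
  rate <- true_rate(truth, expression)
  if (any(rate > 1)) stop("infeasible config: true rate exceeds 1", call. = FALSE)
  tert <- findInterval(rank(expression, ties.method = "first"),
                       c(1, n / 3 + 1, 2 * n / 3 + 1))
  gene_id <- sprintf("g%04d", seq_len(n))

  built <- with_seed(derive_seed(seed, 2L), {
    lapply(seq_len(n), function(i) {
      tp <- truth$motif_component_probs[[tert[i]]]
      n_codons <- sample(seq(truth$cds_len_range[1] %/% 3,
                             truth$cds_len_range[2] %/% 3), 1L)
      body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
      stop_codon <- sample(names(tp$stop), 1L, prob = tp$stop)
      utr_len <- sample(truth$utr_len_range[1]:truth$utr_len_range[2], 1L)
      utr <- c(sample(names(tp$plus1), 1L, prob = tp$plus1),
               sample(names(tp$plus2), 1L, prob = tp$plus2),
               sample(c("A", "C", "G", "T"), utr_len - 2L, replace = TRUE))
      list(seq = paste0("ATG", paste(body, collapse = ""), stop_codon,
                        paste(utr, collapse = "")),
           cds_end = n_codons * 3L)
    })
  })
  genes <- data.frame(
    gene_id = gene_id,
    transcript_seq = vapply(built, `[[`, character(1), "seq"),
    cds_end = vapply(built, `[[`, integer(1), "cds_end"),
    mrna_rpkm = NA_real_, ribo_cds_rpkm = NA_real_,
    ribo_region1_rpkm = NA_real_,
    stringsAsFactors = FALSE)

  regions <- extract_regions_table(genes, cap_nt = truth$cap_nt)
  len1 <- pmax(0L, regions$region1_end - regions$region1_start + 1L)
  cds_len <- genes$cds_end

  lambda_mrna <- expression * cds_len / 1e3 * truth$library_size_mrna / 1e6
  lambda_ribo_cds <- expression * truth$translation_factor *
    cds_len / 1e3 * truth$library_size_ribo / 1e6
  lambda_ribo_r1 <- lambda_ribo_cds * rate * len1 / cds_len

  counts <- with_seed(derive_seed(seed, 3L), {
    list(mrna = stats::rpois(n, lambda_mrna),
         ribo_cds = stats::rpois(n, lambda_ribo_cds),
         ribo_r1 = stats::rpois(n, lambda_ribo_r1))
  })
  genes$mrna_count <- counts$mrna
  genes$ribo_cds_count <- counts$ribo_cds
  genes$ribo_region1_count <- counts$ribo_r1
  genes$region1_len <- len1
  genes$mrna_rpkm <- rpkm(counts$mrna, cds_len, truth$library_size_mrna)
  genes$ribo_cds_rpkm <- rpkm(counts$ribo_cds, cds_len, truth$library_size_ribo)
  genes$ribo_region1_rpkm <- ifelse(
    len1 > 0, rpkm(counts$ribo_r1, pmax(len1, 1L), truth$library_size_ribo),
    NA_real_)

  truth_table <- data.frame(
    gene_id = gene_id, expression = expression, true_rate = rate,
    tertile = tert, lambda_mrna = lambda_mrna,
    lambda_ribo_cds = lambda_ribo_cds, lambda_ribo_region1 = lambda_ribo_r1,
    region1_len = len1, stringsAsFactors = FALSE)
  list(genes = genes, regions = regions, truth_table = truth_table)
}

#' Call read-through genes with the detection bias of ribosome profiling
#'
#' A gene is called read-through iff its region-1 ribo-seq read count exceeds
#' `truth$rt_threshold`. Because expected region-1 counts scale with
#' expression and region-1 length, the call set reproduces the detection bias
#' of real studies: calls enrich for highly expressed genes with long
#' region 1.
#'
#' @param truth A [synthetic_truth()] object.
#' @param genes Gene table from [generate_genes()].
#' @return Character vector of called gene ids.
#' @export
generate_rt_calls <- function(truth, genes) {
  stopifnot("ribo_region1_count" %in% names(genes))
  genes$gene_id[genes$ribo_region1_count > truth$rt_threshold]
}

#' Lower the region-1 hydrophobicity of selected genes
#'
#' Rewrites region-1 codons of the given genes, replacing each
#' hydrophobic-encoding codon by a random hydrophilic sense codon with the
#' probability that reduces the expected hydrophobic fraction by `shift`
#' (baseline fraction 27/61 under uniform sense-codon usage). The first
#' region-1 codon is left untouched so the stop-codon context (+1/+2 bases)
#' is preserved; replacement codons are sense codons, so region boundaries
#' never move.
#'
#' @param genes Gene table.
#' @param regions Matching region table.
#' @param target_ids Genes to modify (typically the read-through calls).
#' @param shift Target reduction in hydrophobic fraction (default 0.1).
#' @param seed Optional seed.
#' @return List with the modified `genes` table and the `regions` table with
#'   refreshed `region1_seq` (coordinates never move).
#' @export
apply_hydrophobicity_shift <- function(genes, regions, target_ids, shift = 0.1,
                                       seed = NULL) {
  if (shift <= 0 || length(target_ids) == 0L)
    return(list(genes = genes, regions = regions))
  hydro_codons <- SENSE_CODONS[codon_aa(SENSE_CODONS) %in% HYDROPHOBIC_AA]
  philic_codons <- setdiff(SENSE_CODONS, hydro_codons)
  f0 <- length(hydro_codons) / length(SENSE_CODONS)
  q <- min(1, shift / f0)
  with_seed(seed, {
    for (i in which(genes$gene_id %in% target_ids)) {
      j <- match(genes$gene_id[i], regions$gene_id)
      r <- regions[j, ]
      len1 <- r$region1_end - r$region1_start + 1L
      if (is.na(len1) || len1 < 6L) next
      n_codons <- len1 %/% 3L
      seq <- genes$transcript_seq[i]
      for (k in 2:n_codons) {           # codon 1 carries the +1/+2 context
        s <- r$region1_start + (k - 1L) * 3L
        codon <- substr(seq, s, s + 2L)
        if (codon %in% hydro_codons && stats::runif(1) < q) {
          substr(seq, s, s + 2L) <- sample(philic_codons, 1L)
        }
      }
      genes$transcript_seq[i] <- seq
      regions$region1_seq[j] <- substr(seq, r$region1_start, r$region1_end)
    }
    list(genes = genes, regions = regions)
  })
}

#' Generate pairwise ortholog alignments with known divergence
#'
#' Derives a second species from each gene's stop-codon neighborhood (50 nt
#' upstream of the stop through at most `cap_nt` downstream) by i.i.d.
#' substitutions (uniform among the three alternative bases) and indels with
#' geometric lengths, emitted as a gapped pairwise alignment. Under the
#' `"error"` world the same rates apply everywhere. Under the `"adaptive"`
#' world, region 1 of the genes in `rt_ids` evolves under purifying
#' constraint: its substitution rate is multiplied by
#' `region1_purifying_factor` and indels starting there are forced to
#' multiples of 3 with probability `1 - region1_purifying_factor`.
#'
#' @param truth A [synthetic_truth()] object.
#' @param genes,regions Output of [generate_genes()].
#' @param seed Master seed.
#' @param world `"error"` or `"adaptive"`.
#' @param rt_ids Read-through gene ids (needed for the adaptive world).
#' @return `data.frame` with `gene_id`, `seq_a`, `seq_b`, `stop_col`,
#'   `region1_len`, `region2_len`, `truncated_at_cap` — the input expected by
#'   [conservation_table()].
#' @export
generate_ortholog_pairs <- function(truth, genes, regions, seed = 1,
                                    world = c("error", "adaptive"),
                                    rt_ids = character(0)) {
  world <- match.arg(world)
  stopifnot(all(genes$gene_id == regions$gene_id))
  up <- truth$ortholog_upstream_nt
  bases <- c("A", "C", "G", "T")
  rows <- with_seed(derive_seed(seed, 7L), {
    lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]; r <- regions[i, ]
      stop_start <- g$cds_end - 2L
      if (stop_start - up < 1L) return(NULL)
      win_end <- min(nchar(g$transcript_seq), g$cds_end + truth$cap_nt)
      a <- strsplit(substr(g$transcript_seq, stop_start - up, win_end),
                    "", fixed = TRUE)[[1]]
      n_a <- length(a)
      len1 <- max(0L, r$region1_end - r$region1_start + 1L)
      len2 <- if (is.na(r$region2_start)) NA_integer_ else
        max(0L, r$region2_end - r$region2_start + 1L)
      # per-site rates; window positions up+1..up+3 are the stop codon,
      # region 1 occupies the next len1 positions
      is_rt <- world == "adaptive" && g$gene_id %in% rt_ids
      sub_rate <- rep(truth$substitution_rate, n_a)
      force_prob <- rep(0, n_a)
      if (is_rt && len1 > 0L) {
        r1_pos <- up + 3L + seq_len(len1)
        sub_rate[r1_pos] <- sub_rate[r1_pos] * truth$region1_purifying_factor
        force_prob[r1_pos] <- 1 - truth$region1_purifying_factor
      }
      # substitutions
      b <- a
      mut <- stats::runif(n_a) < sub_rate
      if (any(mut)) {
        b[mut] <- vapply(which(mut), function(p)
          sample(setdiff(bases, a[p]), 1L), character(1))
      }
      # deletions in species B: gap runs over A positions
      deleted <- rep(FALSE, n_a)
      p <- 1L
      while (p <= n_a) {
        if (stats::runif(1) < truth$indel_rate) {
          L <- 1L + stats::rgeom(1L, truth$indel_geom_p)
          if (stats::runif(1) < force_prob[p]) L <- as.integer(ceiling(L / 3) * 3)
          deleted[p:min(n_a, p + L - 1L)] <- TRUE
          p <- p + L
        }
        p <- p + 1L
      }
      # insertions in species B after each A position
      ins_len <- integer(n_a)
      ins_seq <- vector("list", n_a)
      hit <- which(stats::runif(n_a) < truth$indel_rate)
      for (p in hit) {
        L <- 1L + stats::rgeom(1L, truth$indel_geom_p)
        if (stats::runif(1) < force_prob[min(p + 1L, n_a)])
          L <- as.integer(ceiling(L / 3) * 3)
        ins_len[p] <- L
        ins_seq[[p]] <- sample(bases, L, replace = TRUE)
      }
      b[deleted] <- "-"
      a_cols <- character(0); b_cols <- character(0)
      if (sum(ins_len) == 0L) {
        a_cols <- a; b_cols <- b
        stop_col <- up + 1L
      } else {
        a_parts <- vector("list", n_a); b_parts <- vector("list", n_a)
        for (p in seq_len(n_a)) {
          if (ins_len[p] > 0L) {
            a_parts[[p]] <- c(a[p], rep("-", ins_len[p]))
            b_parts[[p]] <- c(b[p], ins_seq[[p]])
          } else {
            a_parts[[p]] <- a[p]; b_parts[[p]] <- b[p]
          }
        }
        a_cols <- unlist(a_parts); b_cols <- unlist(b_parts)
        stop_col <- up + sum(ins_len[seq_len(up)]) + 1L
      }
      data.frame(gene_id = g$gene_id,
                 seq_a = paste(a_cols, collapse = ""),
                 seq_b = paste(b_cols, collapse = ""),
                 stop_col = stop_col,
                 region1_len = len1, region2_len = len2,
                 truncated_at_cap = r$truncated_at_cap,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
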