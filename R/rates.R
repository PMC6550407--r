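#' Reads per kilobase per million mapped reads (RPKM)
#'
#' @param count Read count(s) for the feature (nonnegative).
#' @param length_nt Feature length(s) in nucleotides (>= 1).
#' @param total_mapped_reads Library size (>= 1).
#' @return RPKM value(s): `count / (length_nt/1e3) / (total_mapped_reads/1e6)`.
#' @examples
#' rpkm(37, 250, 2e6)  # 74
#' @export
rpkm <- function(count, length_nt, total_mapped_reads) {
  if (any(length_nt < 1, na.rm = TRUE)) stop("length_nt must be >= 1", call. = FALSE)
  if (any(total_mapped_reads < 1, na.rm = TRUE)) stop("total_mapped_reads must be >= 1", call. = FALSE)
  count / (length_nt / 1e3) / (total_mapped_reads / 1e6)
}

#' Per-gene stop-codon read-through rate
#'
#' The read-through rate of a gene is the ribosome-profiling RPKM of region 1
#' (between the canonical and the second in-frame stop codon) relative to that
#' of the coding region. Vectorized; `NA` where the CDS RPKM is 0 or either
#' input is missing.
#'
#' @param ribo_region1_rpkm Ribo-seq RPKM of region 1.
#' @param ribo_cds_rpkm Ribo-seq RPKM of the coding region.
#' @return Numeric vector of rates.
#' @export
gene_readthrough_rate <- function(ribo_region1_rpkm, ribo_cds_rpkm) {
  out <- ribo_region1_rpkm / ribo_cds_rpkm
  out[!is.na(ribo_cds_rpkm) & ribo_cds_rpkm == 0] <- NA_real_
  out
}

#' Bin genes so every bin carries the same total mRNA expression
#'
#' Genes are ranked by mRNA-seq RPKM of the coding region (ascending, ties
#' broken by `gene_id`) and assigned greedily, in rank order, to `n_bins` bins
#' whose cumulative-RPKM boundaries are at `k/n_bins` of the grand total. A
#' gene is never split, so bin totals agree only up to one gene's RPKM. Equal
#' total expression across bins removes the detection bias that makes
#' read-through observable only in well-expressed genes.
#'
#' @param genes `data.frame` with columns `gene_id` and `mrna_rpkm`.
#' @param n_bins Number of bins (default 10).
#' @return The input rows (reordered by expression rank) with an integer
#'   `bin` column, 1 = lowest expression.
#' @export
bin_by_equal_total_rpkm <- function(genes, n_bins = 10) {
  stopifnot(all(c("gene_id", "mrna_rpkm") %in% names(genes)), n_bins >= 2)
  if (any(is.na(genes$mrna_rpkm)) || any(genes$mrna_rpkm < 0))
    stop("mrna_rpkm must be nonnegative and non-missing", call. = FALSE)
  if (sum(genes$mrna_rpkm > 0) < n_bins)
    stop("fewer genes with positive mrna_rpkm than bins", call. = FALSE)
  ord <- order(genes$mrna_rpkm, genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  cum <- cumsum(g$mrna_rpkm)
  step <- cum[length(cum)] / n_bins
  # a gene belongs to the bin its cumulative-RPKM midpoint falls in, so a
  # boundary gene joins whichever side keeps bin totals closer to the ideal
  # total/n_bins; each bin's total then deviates by at most one gene's RPKM
  mid <- cum - g$mrna_rpkm / 2
  bin <- pmax(1L, pmin(as.integer(floor(mid / step)) + 1L, n_bins))
  g$bin <- cummax(bin)  # guard against numeric jitter breaking monotonicity
  rownames(g) <- NULL
  g
}

#' Bin-level ("supergene") read-through rate
#'
#' Total region-1 ribo-seq RPKM over total CDS ribo-seq RPKM across a set of
#' genes — the rate obtained by treating the whole bin as a single gene, NOT
#' the mean of per-gene rates. Genes with missing region-1 RPKM contribute 0
#' to the numerator; genes with 0 (or missing) CDS RPKM contribute to neither
#' sum.
#'
#' @param ribo_region1_rpkm,ribo_cds_rpkm Numeric vectors over the bin's genes.
#' @return The supergene rate, or `NA` if the denominator is 0.
#' @export
supergene_rate <- function(ribo_region1_rpkm, ribo_cds_rpkm) {
  stopifnot(length(ribo_region1_rpkm) == length(ribo_cds_rpkm))
  keep <- !is.na(ribo_cds_rpkm) & ribo_cds_rpkm > 0
  den <- sum(ribo_cds_rpkm[keep])
  if (!is.finite(den) || den == 0) return(NA_real_)
  num <- sum(ifelse(is.na(ribo_region1_rpkm[keep]), 0, ribo_region1_rpkm[keep]))
  num / den
}

#' Bootstrap standard deviation of a supergene rate
#'
#' Resamples the bin's genes with replacement (bin size preserved) `n_boot`
#' times and returns the standard deviation of the supergene rate across
#' resamples.
#'
#' @inheritParams supergene_rate
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional seed; the result is deterministic given a seed.
#' @return Bootstrap SD (0 for a bin of identical genes).
#' @export
bootstrap_supergene_sd <- function(ribo_region1_rpkm, ribo_cds_rpkm,
                                   n_boot = 1000, seed = NULL) {
  n <- length(ribo_cds_rpkm)
  stopifnot(n >= 2, length(ribo_region1_rpkm) == n)
  rates <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      supergene_rate(ribo_region1_rpkm[idx], ribo_cds_rpkm[idx])
    }, numeric(1))
  })
  stats::sd(rates[is.finite(rates)])
}

#' Spearman rank correlation with an honest small-sample P-value
#'
#' Average ranks are used for ties. The two-tailed P-value uses the exhaustive
#' permutation distribution for n < 10 and the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` for n >= 10.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return List with elements `rho` and `p_value` (`rho` is `NA` for constant
#'   input).
#' @export
spearman_correlation <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    perms <- all_permutations(n)
    s <- matrix(ry[perms], nrow = nrow(perms)) %*% rx  # sum_i rx[i]*ry[perm[i]]
    rho_perm <- (s / n - mean(rx) * mean(ry)) / (sd_pop(rx) * sd_pop(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = min(p, 1))
}

# population sd (divisor n), used by the permutation rho above
sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
all_permutations <- function(n) {
  stopifnot(n <= 9)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

#' Fraction of read-through removed by natural selection
#'
#' Read-through in lowly expressed genes is essentially unselected, so the
#' lowest bin's rate approximates the intrinsic error rate; the highest bin's
#' rate is what survives selective minimization. Their normalized difference
#' estimates the fraction of read-through that selection has removed from
#' highly expressed genes.
#'
#' @param rate_lowest_bin Supergene rate of the lowest-expression bin (> 0).
#' @param rate_highest_bin Supergene rate of the highest-expression bin.
#' @return `(rate_lowest_bin - rate_highest_bin) / rate_lowest_bin`.
#' @examples
#' fraction_removed_by_selection(0.0398, 0.0111)   # 0.721
#' @export
fraction_removed_by_selection <- function(rate_lowest_bin, rate_highest_bin) {
  if (!is.finite(rate_lowest_bin) || rate_lowest_bin <= 0)
    stop("rate_lowest_bin must be positive", call. = FALSE)
  (rate_lowest_bin - rate_highest_bin) / rate_lowest_bin
}

#' Summarize expression bins: supergene rates, bootstrap SDs, medians
#'
#' Convenience wrapper running [bin_by_equal_total_rpkm()], then
#' [supergene_rate()] and [bootstrap_supergene_sd()] per bin. Per-bin bootstrap
#' seeds are derived from the master seed and the bin index, so adding a bin
#' does not perturb the others.
#'
#' @param genes `data.frame` with `gene_id`, `mrna_rpkm`, `ribo_cds_rpkm`,
#'   `ribo_region1_rpkm`.
#' @param n_bins Number of equal-total-RPKM bins (default 10).
#' @param n_boot Bootstrap resamples per bin (default 1000).
#' @param seed Master seed.
#' @return `data.frame` with one row per bin: `bin`, `n_genes`,
#'   `median_expression`, `total_mrna_rpkm`, `supergene_rate`,
#'   `supergene_rate_sd`.
#' @export
bin_rate_table <- function(genes, n_bins = 10, n_boot = 1000, seed = NULL) {
  binned <- bin_by_equal_total_rpkm(genes, n_bins = n_bins)
  rows <- lapply(sort(unique(binned$bin)), function(b) {
    g <- binned[binned$bin == b, , drop = FALSE]
    data.frame(
      bin = b,
      n_genes = nrow(g),
      median_expression = stats::median(g$mrna_rpkm),
      total_mrna_rpkm = sum(g$mrna_rpkm),
      supergene_rate = supergene_rate(g$ribo_region1_rpkm, g$ribo_cds_rpkm),
      # a singleton bin resamples to itself, so its bootstrap SD is exactly 0
      supergene_rate_sd = if (nrow(g) < 2) 0 else bootstrap_supergene_sd(
        g$ribo_region1_rpkm, g$ribo_cds_rpkm,
        n_boot = n_boot, seed = derive_seed(seed, b))
    )
  })
  do.call(rbind, rows)
}
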