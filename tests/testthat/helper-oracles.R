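# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops and enumeration only.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# scan every in-frame codon by hand (1-based start positions)
oracle_inframe_stops <- function(seq, frame_offset) {
  chars <- strsplit(seq, "")[[1]]
  out <- integer(0)
  p <- frame_offset + 1L
  while (p + 2L <= length(chars)) {
    codon <- paste(chars[p:(p + 2L)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) out <- c(out, p)
    p <- p + 3L
  }
  out
}

# regions by explicit scan: returns list(r1 = c(start, end), r2 or NULL,
# truncated); same conventions as the package (1-based inclusive, exclusive
# of stop codons)
oracle_regions <- function(seq, cds_end, cap_nt = 300) {
  win_end <- min(nchar(seq), cds_end + cap_nt)
  stops <- oracle_inframe_stops(substr(seq, cds_end + 1L, win_end), 0L) + cds_end
  if (length(stops) == 0L) {
    return(list(r1 = c(cds_end + 1L, win_end), r2 = NULL, truncated = TRUE))
  }
  r1 <- c(cds_end + 1L, stops[1L] - 1L)
  if (length(stops) >= 2L) {
    list(r1 = r1, r2 = c(stops[1L] + 3L, stops[2L] - 1L), truncated = FALSE)
  } else {
    r2s <- stops[1L] + 3L
    if (r2s > win_end) list(r1 = r1, r2 = NULL, truncated = TRUE)
    else list(r1 = r1, r2 = c(r2s, win_end), truncated = TRUE)
  }
}

# identity by explicit per-column loop
oracle_identity <- function(a, b, cols) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  m <- 0L; tot <- 0L
  for (j in cols) {
    if (ac[j] != "-" && bc[j] != "-") {
      tot <- tot + 1L
      if (ac[j] == bc[j]) m <- m + 1L
    }
  }
  if (tot == 0L) NA_real_ else m / tot
}

# maximal gap runs by explicit walk over one sequence; returns lengths of runs
# whose first column is in cols
oracle_gap_runs <- function(s, cols) {
  ch <- strsplit(s, "")[[1]]
  lens <- integer(0)
  j <- 1L
  while (j <= length(ch)) {
    if (ch[j] == "-") {
      k <- j
      while (k <= length(ch) && ch[k] == "-") k <- k + 1L
      if (j %in% cols) lens <- c(lens, k - j)
      j <- k
    } else j <- j + 1L
  }
  lens
}

# rank-then-Pearson Spearman rho
oracle_spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

# all-pairs Mann-Whitney U for group x vs y (ties count 1/2)
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) u <- u + 1
    else if (xi == yi) u <- u + 0.5
  }
  u
}

# two-sided Fisher exact P by full enumeration over tables with fixed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) stats::dhyper(k, c1, n - c1, r1), numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random gapped alignment pair with no gap-in-both columns
random_alignment <- function(ncol, gap_prob = 0.1) {
  a <- character(ncol); b <- character(ncol)
  for (j in seq_len(ncol)) {
    r <- stats::runif(1)
    if (r < gap_prob) { a[j] <- "-"; b[j] <- sample(c("A", "C", "G", "T"), 1) }
    else if (r < 2 * gap_prob) { b[j] <- "-"; a[j] <- sample(c("A", "C", "G", "T"), 1) }
    else { a[j] <- sample(c("A", "C", "G", "T"), 1); b[j] <- sample(c("A", "C", "G", "T"), 1) }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# stop-codon contexts with independent components (a matched null for the
# component-shuffle test)
draw_null_contexts <- function(n, seed,
                               p_stop = c(TAA = 0.45, TAG = 0.23, TGA = 0.32),
                               p1 = c(A = 0.38, C = 0.16, G = 0.16, T = 0.30),
                               p2 = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)) {
  set.seed(seed)
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    stop_codon = sample(names(p_stop), n, TRUE, p_stop),
    plus1 = sample(names(p1), n, TRUE, p1),
    plus2 = sample(names(p2), n, TRUE, p2),
    expression = stats::runif(n),
    stringsAsFactors = FALSE)
}

# codon-table translation by direct lookup (independent of the package path)
oracle_translate <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3
  paste(vapply(seq_len(n), function(i)
    unname(gc[substr(dna, 3 * i - 2, 3 * i)]), character(1)), collapse = "")
}

# a random synthetic transcript: stop-free CDS + arbitrary UTR
random_transcript <- function(min_codons = 3, max_codons = 40,
                              min_utr = 0, max_utr = 120) {
  sense <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                         paste0), c("A","C","G","T"), paste0)),
                   c("TAA", "TAG", "TGA"))
  n_cod <- sample(min_codons:max_codons, 1)
  utr_len <- sample(min_utr:max_utr, 1)
  seq <- paste0(paste(sample(sense, n_cod, replace = TRUE), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1),
                random_dna(utr_len))
  list(seq = seq, cds_end = (n_cod + 1L) * 3L)
}
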