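# Pairwise ortholog alignments are handled as plain gapped strings over
# {A,C,G,T,-} plus the 1-based alignment column of the first base of the
# reference species' canonical stop codon (`stop_col`). The reference species
# ("A") is the one whose transcript defined region 1 and region 2.

aln_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# columns occupied by reference-species residues, in residue order
a_residue_cols <- function(a) which(a != "-")

#' Map reference-species region lengths to alignment columns
#'
#' Region 1 starts immediately after the reference stop codon and spans
#' `region1_len` reference residues; region 2 starts after the following
#' (second) stop codon and spans `region2_len` residues. Regions extending
#' past the aligned window are clipped.
#'
#' @param seq_a Gapped reference sequence.
#' @param stop_col Alignment column of the first base of the reference stop
#'   codon.
#' @param region1_len,region2_len Region lengths in reference nucleotides
#'   (`region2_len` may be `NA` for an absent region 2).
#' @return List with integer column vectors `region1` and `region2`.
#' @export
alignment_region_cols <- function(seq_a, stop_col, region1_len, region2_len = NA) {
  a <- aln_chars(seq_a)
  cols <- a_residue_cols(a)
  stop_idx <- match(stop_col, cols)
  if (is.na(stop_idx)) stop("stop_col is a gap column in the reference sequence",
                            call. = FALSE)
  r1_idx <- stop_idx + 3L + seq_len(max(0L, region1_len))
  r1_idx <- r1_idx[r1_idx <= length(cols)]
  r2 <- integer(0)
  if (!is.na(region2_len) && region2_len > 0) {
    r2_idx <- stop_idx + 3L + region1_len + 3L + seq_len(region2_len)
    r2_idx <- r2_idx[r2_idx <= length(cols)]
    r2 <- cols[r2_idx]
  }
  list(region1 = cols[r1_idx], region2 = r2)
}

#' Quality control for a pairwise stop-codon-neighborhood alignment
#'
#' An alignment passes when (a) the three columns of the reference stop codon
#' are contiguous and gap-free in both species and the non-reference bases
#' there form a stop codon (not necessarily the same one), and (b) sequence
#' identity over the 36 alignment columns immediately upstream of the stop
#' codon is at least `min_identity`, with gapped columns counted as
#' mismatches.
#'
#' @param seq_a,seq_b Gapped aligned sequences (equal length).
#' @param stop_col Column of the first reference stop base.
#' @param min_identity Identity threshold for the upstream window (default
#'   0.88).
#' @param window Upstream window width in columns (default 36).
#' @return `TRUE`/`FALSE`, with a `reason` attribute on failure.
#' @export
qc_alignment <- function(seq_a, seq_b, stop_col, min_identity = 0.88, window = 36) {
  a <- aln_chars(seq_a); b <- aln_chars(seq_b)
  stopifnot(length(a) == length(b))
  if (is.na(stop_col) || stop_col < 1 || stop_col + 2 > length(a))
    stop("stop_col unset or outside the alignment", call. = FALSE)
  fail <- function(reason) structure(FALSE, reason = reason)
  sc <- stop_col:(stop_col + 2L)
  if (any(a[sc] == "-")) return(fail("stop_gap_ref"))
  if (paste(a[sc], collapse = "") %in% STOP_CODONS == FALSE)
    return(fail("ref_not_stop"))
  if (any(b[sc] == "-")) return(fail("stop_gap_other"))
  if (!paste(b[sc], collapse = "") %in% STOP_CODONS) return(fail("other_not_stop"))
  if (stop_col <= window) return(fail("short_flank"))
  win <- (stop_col - window):(stop_col - 1L)
  ident <- sum(a[win] == b[win] & a[win] != "-") / window
  if (ident < min_identity) return(fail("low_flank_identity"))
  TRUE
}

#' Percent identity at aligned non-gapped sites
#'
#' @param seq_a,seq_b Gapped aligned sequences.
#' @param cols Alignment columns to consider.
#' @return Matches / (matches + mismatches) over columns where neither species
#'   has a gap; `NA` when no such column exists.
#' @export
percent_identity <- function(seq_a, seq_b, cols) {
  if (length(cols) == 0L) return(NA_real_)
  a <- aln_chars(seq_a)[cols]; b <- aln_chars(seq_b)[cols]
  ok <- a != "-" & b != "-"
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Identity at first-two vs third codon positions
#'
#' The reading frame is anchored at the first reference residue of the region
#' (codon phase 0) and tracked along reference residues, so gaps in the other
#' species do not shift the frame. Identity is computed over non-gapped
#' columns, separately for codon positions {1,2} and {3}. Under protein-level
#' constraint the first two positions should be the more conserved.
#'
#' @inheritParams percent_identity
#' @return List with `identity_pos12` and `identity_pos3` (`NA` when the
#'   region is shorter than one codon or has no usable site in a class).
#' @export
codon_position_identity <- function(seq_a, seq_b, cols) {
  if (length(cols) < 3L) return(list(identity_pos12 = NA_real_, identity_pos3 = NA_real_))
  a <- aln_chars(seq_a); b <- aln_chars(seq_b)
  a_res <- a[cols] != "-"
  phase <- integer(length(cols))         # 1,2,3 on reference residues; 0 at ref-gap cols
  phase[a_res] <- ((seq_len(sum(a_res)) - 1L) %% 3L) + 1L
  ok <- a_res & b[cols] != "-"
  match_ok <- a[cols] == b[cols]
  p12 <- ok & phase %in% c(1L, 2L)
  p3 <- ok & phase == 3L
  list(
    identity_pos12 = if (any(p12)) mean(match_ok[p12]) else NA_real_,
    identity_pos3 = if (any(p3)) mean(match_ok[p3]) else NA_real_
  )
}

#' Indel events within a column range
#'
#' A maximal run of gap characters in one species is one event; runs in the
#' two species are separate events even when adjacent. An event is assigned to
#' `cols` (and reported) when its first gap column falls inside `cols`, so an
#' event straddling a region boundary belongs to the region where it starts.
#'
#' @inheritParams percent_identity
#' @return `data.frame` with columns `species_with_gap` ("A"/"B"),
#'   `start_col`, `length_nt`, `frameshift` (length not a multiple of 3).
#' @export
indel_events <- function(seq_a, seq_b, cols) {
  a <- aln_chars(seq_a); b <- aln_chars(seq_b)
  one <- function(x, label) {
    r <- rle(x == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts %in% cols
    data.frame(species_with_gap = rep(label, sum(keep)),
               start_col = starts[keep], length_nt = r$lengths[keep],
               stringsAsFactors = FALSE)
  }
  ev <- rbind(one(a, "A"), one(b, "B"))
  ev$frameshift <- ev$length_nt %% 3L != 0L
  ev[order(ev$start_col), , drop = FALSE]
}

#' Fraction of indel events that shift the reading frame
#'
#' @param events `data.frame` from [indel_events()] (possibly row-bound over
#'   genes).
#' @return Proportion of events whose length is not a multiple of 3; `NA` for
#'   zero events.
#' @export
frameshift_fraction <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(NA_real_)
  mean(events$length_nt %% 3L != 0L)
}

#' Absolute and relative interspecific length difference
#'
#' @param len_a,len_b Orthologous region lengths (nt) in the two species.
#' @return List of vectors `absolute_nt` (`|L_A - L_B|`) and `relative`
#'   (`|L_A - L_B| / (L_A + L_B)`, `NA` when both lengths are 0).
#' @export
length_difference <- function(len_a, len_b) {
  absdiff <- abs(len_a - len_b)
  total <- len_a + len_b
  rel <- ifelse(total > 0, absdiff / total, NA_real_)
  list(absolute_nt = absdiff, relative = rel)
}

#' One-tailed bootstrap P-value for a two-group comparison
#'
#' Both groups are independently resampled with replacement `n_boot` times and
#' the statistic difference `stat(group1*) - stat(group2*)` recorded. The
#' P-value is the fraction of replicates contradicting the alternative: for
#' `tail = "greater"` (alternative group1 > group2) replicates with difference
#' <= 0, for `tail = "less"` those with difference >= 0. Ties count against
#' the strict alternative, so two identical constant groups give P = 1.
#'
#' @param values_group1,values_group2 Numeric vectors (NAs dropped; >= 2 values
#'   each), or lists of per-gene value vectors — then genes are the resampling
#'   unit and the statistic is applied to the pooled values of each resample
#'   (as when a per-group fraction is computed from pooled indel events but
#'   uncertainty comes from bootstrapping genes).
#' @param statistic Summary function (default `mean`).
#' @param n_boot Number of replicates (default 1000).
#' @param tail `"greater"` or `"less"` — direction of the alternative for
#'   group 1 relative to group 2.
#' @param seed Optional seed.
#' @return One-tailed bootstrap P-value. Replicates where the statistic is
#'   undefined in either group (e.g. no pooled events) are dropped.
#' @export
bootstrap_group_p <- function(values_group1, values_group2, statistic = mean,
                              n_boot = 1000, tail = c("greater", "less"),
                              seed = NULL) {
  tail <- match.arg(tail)
  prep <- function(v) {
    if (is.list(v)) lapply(v, function(x) x[!is.na(x)])
    else v[!is.na(v)]
  }
  v1 <- prep(values_group1); v2 <- prep(values_group2)
  stopifnot(length(v1) >= 2, length(v2) >= 2)
  stat_of <- function(v, idx) {
    pooled <- if (is.list(v)) unlist(v[idx], use.names = FALSE) else v[idx]
    if (length(pooled) == 0L) NA_real_ else statistic(pooled)
  }
  n1 <- length(v1); n2 <- length(v2)
  d <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      stat_of(v1, sample.int(n1, n1, replace = TRUE)) -
        stat_of(v2, sample.int(n2, n2, replace = TRUE))
    }, numeric(1))
  })
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_real_)
  if (tail == "greater") mean(d <= 0) else mean(d >= 0)
}

#' Bootstrap P for the codon-position conservation contrast
#'
#' Resamples genes `n_boot` times and reports the fraction of bootstrap
#' samples in which the mean identity at first-two codon positions is less
#' than or equal to the mean identity at third positions — the probability
#' that the protein-level-constraint signature is absent.
#'
#' @param identity_pos12,identity_pos3 Per-gene identities (paired; genes with
#'   an `NA` in either are dropped).
#' @param n_boot Number of resamples (default 1000).
#' @param seed Optional seed.
#' @return Bootstrap P-value.
#' @export
codon_position_bootstrap_p <- function(identity_pos12, identity_pos3,
                                       n_boot = 1000, seed = NULL) {
  ok <- !is.na(identity_pos12) & !is.na(identity_pos3)
  x12 <- identity_pos12[ok]; x3 <- identity_pos3[ok]
  n <- length(x12)
  stopifnot(n >= 2)
  with_seed(seed, {
    hits <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      mean(x12[idx]) <= mean(x3[idx])
    }, logical(1))
    mean(hits)
  })
}

#' Expression-matched controls for read-through genes
#'
#' Ranks all genes by expression; for each read-through (rt) gene picks the
#' nearest non-rt gene below and above it in the ranking, averages their
#' conservation values as the matched control, and runs a paired two-tailed
#' t-test of rt vs control values. Edge genes use the single available
#' neighbor; rt genes with no valid neighbor (or missing value) are dropped
#' and counted. A non-rt gene may serve as control for several rt genes; the
#' pairing is returned for audit.
#'
#' @param df `data.frame` with columns `gene_id`, `expression`, `is_rt`
#'   (logical) and `value` (the per-gene conservation measure).
#' @return List with `pairs` (`gene_id`, `rt_value`, `control_value`,
#'   `control_ids`), `p_value`, `n_dropped`.
#' @export
expression_matched_controls <- function(df) {
  stopifnot(all(c("gene_id", "expression", "is_rt", "value") %in% names(df)))
  ord <- order(df$expression, df$gene_id)
  d <- df[ord, , drop = FALSE]
  ctrl_ok <- !d$is_rt & !is.na(d$value)
  rt_rows <- which(d$is_rt & !is.na(d$value))
  pairs <- list(); n_dropped <- 0L
  for (i in rt_rows) {
    below <- which(ctrl_ok[seq_len(i - 1L)])
    below <- if (length(below)) max(below) else NA_integer_
    above_cand <- which(ctrl_ok) ; above_cand <- above_cand[above_cand > i]
    above <- if (length(above_cand)) min(above_cand) else NA_integer_
    nb <- c(below, above)
    nb <- nb[!is.na(nb)]
    if (length(nb) == 0L) { n_dropped <- n_dropped + 1L; next }
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_id = d$gene_id[i], rt_value = d$value[i],
      control_value = mean(d$value[nb]),
      control_ids = paste(d$gene_id[nb], collapse = ","),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_id = character(0), rt_value = numeric(0),
               control_value = numeric(0), control_ids = character(0))
  p <- if (nrow(pairs) >= 2 && stats::sd(pairs$rt_value - pairs$control_value) > 0)
    stats::t.test(pairs$rt_value, pairs$control_value, paired = TRUE)$p.value
  else if (nrow(pairs) >= 2) 1
  else NA_real_
  list(pairs = pairs, p_value = p, n_dropped = n_dropped)
}

#' Per-gene conservation table for a set of ortholog alignments
#'
#' Applies QC, then computes per gene and per region: percent identity,
#' codon-position identities, indel events, and region lengths in both
#' species (reference length from the annotation, other-species length as the
#' count of its residues within the region's columns).
#'
#' @param alignments `data.frame` with columns `gene_id`, `seq_a`, `seq_b`,
#'   `stop_col`, `region1_len`, `region2_len` (reference-species region
#'   lengths in nt; `region2_len` may be NA), and optionally
#'   `truncated_at_cap`.
#' @param min_identity,window QC parameters (see [qc_alignment()]).
#' @return List with `per_gene` (one row per QC-passing gene) and `indels`
#'   (one row per indel event, with `gene_id` and `region`), plus `n_qc_fail`.
#' @export
conservation_table <- function(alignments, min_identity = 0.88, window = 36) {
  need <- c("gene_id", "seq_a", "seq_b", "stop_col", "region1_len", "region2_len")
  stopifnot(all(need %in% names(alignments)))
  per_gene <- list(); indels <- list(); n_fail <- 0L
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    qc <- tryCatch(qc_alignment(al$seq_a, al$seq_b, al$stop_col,
                                min_identity = min_identity, window = window),
                   error = function(e) FALSE)
    if (!isTRUE(qc)) { n_fail <- n_fail + 1L; next }
    rc <- alignment_region_cols(al$seq_a, al$stop_col, al$region1_len, al$region2_len)
    cp1 <- codon_position_identity(al$seq_a, al$seq_b, rc$region1)
    b <- aln_chars(al$seq_b)
    len_b1 <- sum(b[rc$region1] != "-")
    len_b2 <- if (length(rc$region2)) sum(b[rc$region2] != "-") else NA_integer_
    per_gene[[length(per_gene) + 1L]] <- data.frame(
      gene_id = al$gene_id,
      identity_region1 = percent_identity(al$seq_a, al$seq_b, rc$region1),
      identity_region2 = percent_identity(al$seq_a, al$seq_b, rc$region2),
      identity_pos12_r1 = cp1$identity_pos12,
      identity_pos3_r1 = cp1$identity_pos3,
      len_a_region1 = al$region1_len, len_b_region1 = len_b1,
      len_a_region2 = al$region2_len, len_b_region2 = len_b2,
      truncated_at_cap = if ("truncated_at_cap" %in% names(al)) al$truncated_at_cap else FALSE,
      stringsAsFactors = FALSE)
    for (reg in c(1L, 2L)) {
      cols <- if (reg == 1L) rc$region1 else rc$region2
      if (length(cols) == 0L) next
      ev <- indel_events(al$seq_a, al$seq_b, cols)
      if (nrow(ev)) {
        ev$gene_id <- al$gene_id; ev$region <- reg
        indels[[length(indels) + 1L]] <- ev
      }
    }
  }
  list(
    per_gene = if (length(per_gene)) do.call(rbind, per_gene) else NULL,
    indels = if (length(indels)) do.call(rbind, indels) else
      data.frame(species_with_gap = character(0), start_col = integer(0),
                 length_nt = integer(0), frameshift = logical(0),
                 gene_id = character(0), region = integer(0)),
    n_qc_fail = n_fail
  )
}
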