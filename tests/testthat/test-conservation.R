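# helper: build an ungapped alignment with a 50-nt flank, a TGA stop, and a
# downstream region; substitutions/gaps are then edited in by tests
base_pair <- function(flank = 50, down = 60) {
  a <- paste0(strrep("ACGTG", flank / 5), "TGA", strrep("ACT", down / 3))
  list(seq_a = a, seq_b = a, stop_col = flank + 1)
}

test_that("alignment QC enforces stop integrity and the 36-column 88% rule", {
  p <- base_pair()
  expect_true(qc_alignment(p$seq_a, p$seq_b, p$stop_col))

  # 4 mismatches in the 36-column window (32/36 = 88.9%) still passes,
  # 5 (31/36 = 86.1%) fails
  mism <- function(seq, cols) {
    ch <- strsplit(seq, "")[[1]]
    ch[cols] <- ifelse(ch[cols] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  win <- (p$stop_col - 36):(p$stop_col - 1)
  expect_true(qc_alignment(p$seq_a, mism(p$seq_b, win[1:4]), p$stop_col))
  expect_false(qc_alignment(p$seq_a, mism(p$seq_b, win[1:5]), p$stop_col))

  # stop codon aligned against a gap fails regardless of identity
  ch <- strsplit(p$seq_b, "")[[1]]
  ch[p$stop_col] <- "-"
  expect_false(qc_alignment(p$seq_a, paste(ch, collapse = ""), p$stop_col))
  # the other species may use a DIFFERENT stop codon
  ch <- strsplit(p$seq_b, "")[[1]]
  ch[p$stop_col + 1] <- "A"    # TGA -> TAA
  expect_true(qc_alignment(p$seq_a, paste(ch, collapse = ""), p$stop_col))
  # ...but a non-stop there fails
  ch[p$stop_col] <- "C"
  expect_false(qc_alignment(p$seq_a, paste(ch, collapse = ""), p$stop_col))
  expect_error(qc_alignment(p$seq_a, p$seq_b, NA), "stop_col")
})

test_that("percent identity counts only non-gapped columns", {
  expect_equal(percent_identity("AC-GT", "AG-GA", 1:5), 2 / 4)
  expect_equal(percent_identity("ACGT", "ACGT", 1:4), 1)
  expect_true(is.na(percent_identity("--AA", "AA--", 1:2)))
  set.seed(17)
  for (i in 1:150) {
    al <- random_alignment(sample(10:60, 1))
    cols <- sort(sample(seq_len(nchar(al$a)), sample(3:10, 1)))
    expect_equal(percent_identity(al$a, al$b, cols),
                 oracle_identity(al$a, al$b, cols))
  }
})

test_that("codon-position identity tracks frame on the reference species", {
  # mismatches only at every third reference base
  a <- "AAAAAAAAAAAA"
  b <- "AACAACAACAAC"
  r <- codon_position_identity(a, b, 1:12)
  expect_equal(r$identity_pos12, 1)
  expect_equal(r$identity_pos3, 0)
  r2 <- codon_position_identity(a, a, 1:12)
  expect_equal(unlist(r2), c(identity_pos12 = 1, identity_pos3 = 1))
  # a gap in the reference does not advance the frame
  a3 <- "AA-AAAA"
  b3 <- "AACAAAC"   # mismatches under ref-gap col 3 (ignored) and col 7 (pos 3)
  r3 <- codon_position_identity(a3, b3, 1:7)
  expect_equal(r3$identity_pos12, 1)
  expect_equal(r3$identity_pos3, 1 / 2)
  expect_true(is.na(codon_position_identity("AC", "AC", 1:2)$identity_pos12))

  # brute-force per-column classification oracle on random alignments
  set.seed(23)
  for (i in 1:100) {
    al <- random_alignment(30)
    cols <- 1:30
    ac <- strsplit(al$a, "")[[1]]; bc <- strsplit(al$b, "")[[1]]
    phase <- 0; m12 <- c(); m3 <- c()
    for (j in cols) {
      if (ac[j] == "-") next
      phase <- phase + 1
      if (bc[j] == "-") next
      if ((phase - 1) %% 3 < 2) m12 <- c(m12, ac[j] == bc[j])
      else m3 <- c(m3, ac[j] == bc[j])
    }
    got <- codon_position_identity(al$a, al$b, cols)
    expect_equal(got$identity_pos12,
                 if (length(m12)) mean(m12) else NA_real_)
    expect_equal(got$identity_pos3,
                 if (length(m3)) mean(m3) else NA_real_)
  }
})

test_that("indel events are maximal per-sequence gap runs with frameshift flags", {
  ev <- indel_events("AAAAAAA", "AAAAAAA", 1:7)
  expect_equal(nrow(ev), 0L)
  expect_true(is.na(frameshift_fraction(ev)))

  ev <- indel_events("A---AAA", "AAAAAAA", 1:7)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length_nt, 3L)
  expect_false(ev$frameshift)

  # one 3-nt and one 1-nt gap: frameshift fraction 1/2
  ev <- indel_events("A---AAAA", "AAAAAA-A", 1:8)
  expect_equal(frameshift_fraction(ev), 0.5)
  # classification invariant under swapping species
  ev_sw <- indel_events("AAAAAA-A", "A---AAAA", 1:8)
  expect_equal(sort(ev_sw$length_nt), sort(ev$length_nt))
  # events are assigned by their first gap column
  ev2 <- indel_events("AA--AAAA", "AAAAAAAA", 3:8)
  expect_equal(nrow(ev2), 1L)
  expect_equal(indel_events("AA--AAAA", "AAAAAAAA", 4:8) |> nrow(), 0L)

  # run-length oracle on random gapped pairs
  set.seed(29)
  for (i in 1:100) {
    al <- random_alignment(sample(15:50, 1), gap_prob = 0.2)
    cols <- seq_len(nchar(al$a))
    got <- sort(indel_events(al$a, al$b, cols)$length_nt)
    want <- sort(c(oracle_gap_runs(al$a, cols), oracle_gap_runs(al$b, cols)))
    expect_equal(got, as.integer(want))
  }
})

test_that("length differences follow |La-Lb| and |La-Lb|/(La+Lb)", {
  r <- length_difference(60, 60)
  expect_equal(r$absolute_nt, 0); expect_equal(r$relative, 0)
  r <- length_difference(60, 30)
  expect_equal(r$absolute_nt, 30); expect_equal(r$relative, 1 / 3)
  expect_equal(length_difference(30, 60)$relative, 1 / 3)   # symmetric
  expect_true(is.na(length_difference(0, 0)$relative))
  set.seed(31)
  la <- sample(0:100, 50, TRUE); lb <- sample(0:100, 50, TRUE)
  rel <- length_difference(la, lb)$relative
  expect_true(all(rel[!is.na(rel)] <= 1))
})

test_that("bootstrap group P is directional, tie-conservative and powerful", {
  expect_equal(bootstrap_group_p(rep(2, 5), rep(2, 5), n_boot = 200, seed = 1), 1)
  set.seed(41)
  g1 <- rnorm(50, 1, 0.01); g2 <- rnorm(50, 0, 0.01)
  expect_equal(bootstrap_group_p(g1, g2, tail = "greater",
                                 n_boot = 500, seed = 2), 0)
  expect_equal(bootstrap_group_p(g1, g2, tail = "less",
                                 n_boot = 500, seed = 2), 1)
  expect_identical(bootstrap_group_p(g1, g2, n_boot = 100, seed = 3),
                   bootstrap_group_p(g1, g2, n_boot = 100, seed = 3))
  # list input: genes are the resampling unit for pooled statistics
  ev1 <- list(c(1, 1), numeric(0), 1)   # frameshift indicators per gene
  ev2 <- list(c(0, 0), 0, c(0, 1))
  p <- bootstrap_group_p(ev1, ev2, tail = "greater", n_boot = 300, seed = 4)
  expect_lt(p, 0.1)
})

test_that("codon-position bootstrap P counts samples without the constraint signature", {
  expect_equal(codon_position_bootstrap_p(rep(1, 10), rep(0, 10),
                                          n_boot = 200, seed = 1), 0)
  expect_equal(codon_position_bootstrap_p(rep(0.7, 10), rep(0.7, 10),
                                          n_boot = 200, seed = 1), 1)  # ties count
  set.seed(43)
  weak <- codon_position_bootstrap_p(runif(40, 0.80, 0.90), runif(40, 0.78, 0.88),
                                     n_boot = 500, seed = 2)
  strong <- codon_position_bootstrap_p(runif(40, 0.90, 1.00), runif(40, 0.70, 0.80),
                                       n_boot = 500, seed = 2)
  expect_lt(strong, weak)   # P shrinks with effect size
})

test_that("expression-matched controls pair each rt gene with flanking non-rt genes", {
  df <- data.frame(
    gene_id = sprintf("g%02d", 1:9),
    expression = 1:9,
    is_rt = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    value = c(0.5, 0.6, 0.7, 0.5, 0.6, 0.7, 0.5, 0.6, 0.7))
  res <- expression_matched_controls(df)
  expect_equal(nrow(res$pairs), 3L)
  expect_equal(res$pairs$control_value, c(0.6, 0.6, 0.6))  # means of flanks
  expect_equal(res$pairs$rt_value, c(0.6, 0.6, 0.6))
  expect_equal(res$p_value, 1)                             # rt == control
  # strong uniform shift: tiny paired-t P
  set.seed(47)
  n <- 61
  df2 <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    expression = 1:n,
    is_rt = rep(c(FALSE, TRUE), length.out = n),
    value = 0.5 + 0.001 * rnorm(n))
  df2$value[df2$is_rt] <- df2$value[df2$is_rt] + 0.1
  res2 <- expression_matched_controls(df2)
  expect_lt(res2$p_value, 1e-10)
  # edge rt gene uses its single available neighbor
  df3 <- data.frame(gene_id = c("a", "b", "c"), expression = 1:3,
                    is_rt = c(TRUE, FALSE, TRUE), value = c(0.4, 0.5, 0.6))
  res3 <- expression_matched_controls(df3)
  expect_equal(res3$pairs$control_value, c(0.5, 0.5))
})

test_that("conservation_table integrates QC, identity and indels per gene", {
  p <- base_pair(down = 30)
  aln <- data.frame(gene_id = c("gA", "gB"),
                    seq_a = p$seq_a, seq_b = p$seq_b,
                    stop_col = p$stop_col,
                    region1_len = 12, region2_len = 9,
                    truncated_at_cap = FALSE, stringsAsFactors = FALSE)
  # gB: break its QC window badly
  ch <- strsplit(p$seq_b, "")[[1]]
  ch[(p$stop_col - 36):(p$stop_col - 25)] <- "T"
  aln$seq_b[2] <- paste(ch, collapse = "")
  ct <- conservation_table(aln)
  expect_equal(ct$n_qc_fail, 1L)
  expect_equal(ct$per_gene$gene_id, "gA")
  expect_equal(ct$per_gene$identity_region1, 1)
  expect_equal(ct$per_gene$len_b_region1, 12)
})
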