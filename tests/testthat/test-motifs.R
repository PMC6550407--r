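make_genes_from_contexts <- function(ctx) {
  # embed each context in a minimal transcript so stop_contexts() can recover it
  data.frame(
    gene_id = ctx$gene_id,
    transcript_seq = paste0("ATGGCC", ctx$stop_codon, ctx$plus1, ctx$plus2, "ACGT"),
    cds_end = 9L,
    mrna_rpkm = 2^ctx$expression - 1,
    stringsAsFactors = FALSE)
}

test_that("stop_contexts recovers components and excludes ultra-short 3'UTRs", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"),
    transcript_seq = c("ATGTGACA",      # UTR "CA": full context
                       "ATGTAAC",       # UTR "C": too short
                       "ATGTAGGT"),
    cds_end = c(6L, 6L, 6L),
    mrna_rpkm = c(3, 1, 0),
    stringsAsFactors = FALSE)
  ctx <- stop_contexts(genes)
  expect_equal(ctx$gene_id, c("a", "c"))
  expect_equal(ctx$stop_codon, c("TGA", "TAG"))
  expect_equal(ctx$plus1, c("C", "G"))
  expect_equal(ctx$plus2, c("A", "T"))
  expect_equal(ctx$expression, log2(c(3, 0) + 1))
  expect_equal(attr(ctx, "n_excluded"), 1L)
})

test_that("motif_present requires TGA, C and the motif's fifth base", {
  expect_true(motif_present("TGA", "C", "A", "TGACA"))
  expect_false(motif_present("TAA", "C", "A", "TGACA"))
  expect_false(motif_present("TGA", "C", "T", "TGACA"))
  expect_true(motif_present("TGA", "C", "T", "TGACT"))
  expect_false(motif_present("TGA", "G", "A", "TGACA"))
})

test_that("tertile bins are equal-sized with the remainder in lower bins", {
  ctx9 <- draw_null_contexts(9, 1)
  expect_equal(as.integer(table(tertile_bins(ctx9)$bin)), c(3L, 3L, 3L))
  ctx10 <- draw_null_contexts(10, 2)
  expect_equal(as.integer(table(tertile_bins(ctx10)$bin)), c(4L, 3L, 3L))
  # binning is by ascending expression
  b <- tertile_bins(ctx10)
  expect_true(max(b$expression[b$bin == 1]) <= min(b$expression[b$bin == 3]))
  # degenerate expression still bins, flagged
  ctx10$expression <- 1
  expect_true(attr(tertile_bins(ctx10), "degenerate"))
})

test_that("expected motif frequency is the product of component frequencies", {
  ctx <- data.frame(gene_id = c("a", "b"), stop_codon = c("TGA", "TGA"),
                    plus1 = c("C", "C"), plus2 = c("A", "A"),
                    expression = c(1, 2))
  expect_equal(expected_motif_frequency(ctx, "TGACA"), 1)
  ctx2 <- data.frame(gene_id = letters[1:4],
                     stop_codon = c("TGA", "TGA", "TAA", "TAA"),
                     plus1 = c("C", "G", "C", "G"),
                     plus2 = c("A", "T", "A", "T"),
                     expression = 1:4)
  expect_equal(expected_motif_frequency(ctx2, "TGACA"), 0.5 * 0.5 * 0.5)
  # agreement with the shuffle-distribution mean within Monte-Carlo error
  ctx3 <- draw_null_contexts(400, 31)
  st <- shuffle_test(ctx3, "TGACA", n_shuffles = 20000, seed = 32)
  exp_count <- expected_motif_frequency(ctx3, "TGACA") * nrow(ctx3)
  expect_lt(abs(st$expected_count - exp_count), 3 * sqrt(max(exp_count, 1)) / sqrt(200))
})

test_that("component shuffling preserves margins and is seed-deterministic", {
  ctx <- draw_null_contexts(200, 21)
  a <- shuffle_test(ctx, "TGACT", n_shuffles = 200, seed = 5)
  b <- shuffle_test(ctx, "TGACT", n_shuffles = 200, seed = 5)
  expect_identical(a, b)
  # identical-component bin: every shuffle reproduces the observed count
  ctx_const <- data.frame(gene_id = c("a", "b", "c"),
                          stop_codon = "TGA", plus1 = "C", plus2 = "A",
                          expression = 1:3)
  st <- shuffle_test(ctx_const, "TGACA", n_shuffles = 50, seed = 1)
  expect_equal(st$p_deficit, 1)
  expect_equal(st$observed_count, 3L)
  expect_equal(st$expected_count, 3)
})

test_that("shuffle deficit P drops under negative component coupling", {
  # build a bin where TGA stops avoid C at +1 far more than independence allows
  set.seed(77)
  n <- 600
  stopc <- sample(c("TAA", "TGA"), n, TRUE, c(0.5, 0.5))
  plus1 <- ifelse(stopc == "TGA",
                  sample(c("A", "C"), n, TRUE, c(0.95, 0.05)),
                  sample(c("A", "C"), n, TRUE, c(0.5, 0.5)))
  coupled <- data.frame(gene_id = sprintf("g%03d", 1:n), stop_codon = stopc,
                        plus1 = plus1, plus2 = "A", expression = runif(n))
  p_coupled <- shuffle_test(coupled, "TGACA", n_shuffles = 1000, seed = 2)$p_deficit
  p_null <- shuffle_test(draw_null_contexts(n, 78), "TGACA",
                         n_shuffles = 1000, seed = 2)$p_deficit
  expect_lt(p_coupled, 0.05)
  expect_gt(p_null, 0.05)
})

test_that("Mann-Whitney expression comparison matches the all-pairs U oracle", {
  set.seed(55)
  for (i in 1:60) {
    nx <- sample(3:12, 1); ny <- sample(3:12, 1)
    ctx <- data.frame(
      gene_id = sprintf("g%02d", seq_len(nx + ny)),
      stop_codon = c(rep("TGA", nx), rep("TAA", ny)),
      plus1 = c(rep("C", nx), rep("A", ny)),
      plus2 = c(rep("A", nx), rep("G", ny)),
      expression = sample(1:6, nx + ny, replace = TRUE))
    res <- expression_vs_motif_test(ctx, "TGACA")
    carriers <- ctx$expression[1:nx]
    rest <- ctx$expression[(nx + 1):(nx + ny)]
    expect_equal(res$U, oracle_u_statistic(carriers, rest))
  }
  # separated groups give a tiny P, identical groups a large one
  ctx_sep <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    stop_codon = rep(c("TGA", "TAA"), each = 20),
    plus1 = rep(c("C", "A"), each = 20),
    plus2 = rep(c("A", "G"), each = 20),
    expression = c(rnorm(20, 10, 0.1), rnorm(20, 0, 0.1)))
  expect_lt(expression_vs_motif_test(ctx_sep, "TGACA")$p_value, 1e-6)
  ctx_same <- ctx_sep
  ctx_same$expression <- rep(c(1, 2), 20)
  expect_gt(expression_vs_motif_test(ctx_same, "TGACA")$p_value, 0.5)
})

test_that("top-20% TGA usage test matches exact hypergeometric enumeration", {
  set.seed(66)
  for (i in 1:60) {
    n <- sample(20:80, 1)
    ctx <- draw_null_contexts(n, 1000 + i)
    res <- tga_usage_top20_test(ctx)
    expect_equal(res$p_value, oracle_fisher_p(res$table), tolerance = 1e-9)
  }
  # symmetric table: OR 1, P 1
  ctx <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    stop_codon = rep(c("TGA", "TAA", "TGA", "TAA"), 10),
                    plus1 = "A", plus2 = "A",
                    expression = rep(1:40))
  res <- tga_usage_top20_test(ctx, top_fraction = 0.5)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
})

test_that("bootstrap motif-frequency SD approximates the binomial closed form", {
  set.seed(99)
  ctx <- draw_null_contexts(500, 3)
  sd_boot <- bootstrap_motif_freq_sd(ctx, "TGACA", n_boot = 2000, seed = 4)
  f <- mean(motif_present(ctx$stop_codon, ctx$plus1, ctx$plus2, "TGACA"))
  sd_theory <- sqrt(f * (1 - f) / nrow(ctx))
  expect_lt(abs(sd_boot - sd_theory) / sd_theory, 0.25)
  expect_identical(bootstrap_motif_freq_sd(ctx, "TGACA", n_boot = 100, seed = 8),
                   bootstrap_motif_freq_sd(ctx, "TGACA", n_boot = 100, seed = 8))
  ctx_all <- data.frame(gene_id = c("a", "b"), stop_codon = "TGA",
                        plus1 = "C", plus2 = "A", expression = 1:2)
  expect_equal(bootstrap_motif_freq_sd(ctx_all, "TGACA", n_boot = 50, seed = 1), 0)
})
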