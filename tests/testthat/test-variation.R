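# Top-hit identity, decile binning, per-bin composition and per-category
# correlation.

test_that("top-hit search returns the best background match", {
  set.seed(30)
  bg <- setNames(vapply(rep(60, 20), random_protein_str, character(1)),
                 paste0("b", 1:20))
  q <- c(q1 = unname(bg[3]))
  r <- top_hit_identity(q, bg)
  expect_equal(r$top_hit_identity, 100)
  expect_identical(r$top_hit, "b3")
  # empty background: no hit for any query
  r0 <- top_hit_identity(q, character(0))
  expect_true(is.na(r0$top_hit_identity))
  # a poly-W query shares no 4-mer with a W-free background
  r1 <- top_hit_identity(c(q2 = strrep("W", 50)), bg["b1"])
  expect_true(is.na(r1$top_hit_identity))
})

test_that("top-hit identity recovers a planted 12% protein divergence", {
  set.seed(31)
  cds <- random_cds(150)
  mut <- mutate_gene(cds, 0.12)
  q <- c(q1 = translate_cds(mut))
  bg <- c(b1 = translate_cds(cds))
  r <- top_hit_identity(q, bg)
  expect_lt(abs(r$top_hit_identity - 88), 1)
})

test_that("the calibrated score threshold rejects shuffled proteins", {
  set.seed(32)
  prots <- vapply(rep(80, 40), random_protein_str, character(1))
  thr <- calibrate_score_threshold(prots, n = 150, q = 0.99)
  expect_true(is.finite(thr))
  # a true homolog pair scores far above the random-pair threshold
  cds <- random_cds(80)
  s <- global_protein_identity(translate_cds(cds),
                               translate_cds(mutate_gene(cds, 0.1)))$score
  expect_gt(s, thr)
})

test_that("rank_into_bins partitions with near-equal sizes, larger first", {
  mk <- function(n) data.frame(gene_id = sprintf("g%03d", 1:n),
                               top_hit_identity = seq(99, by = -0.5,
                                                      length.out = n))
  b20 <- rank_into_bins(mk(20))
  expect_identical(as.integer(table(b20$bin_index)), rep(2L, 10))
  b23 <- rank_into_bins(mk(23))
  expect_identical(as.integer(table(b23$bin_index)),
                   c(3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
  # bin 1 holds the least dissimilar (highest identity) genes
  expect_true(all(b23$dissimilarity[b23$bin_index == 1] <=
                    min(b23$dissimilarity[b23$bin_index == 10])))
  # all-equal dissimilarities: deterministic binning by gene_id order
  eq <- data.frame(gene_id = sprintf("g%03d", 20:1), top_hit_identity = 90)
  be <- rank_into_bins(eq)
  expect_identical(be$gene_id, sprintf("g%03d", 1:20))
  expect_error(rank_into_bins(mk(9)), "at least 10")
})

test_that("per-bin category proportions are normalised, zeros recorded", {
  binned <- data.frame(
    gene_id = paste0("g", 1:8),
    dissimilarity = c(1, 2, 3, 4, 11, 12, 13, 14),
    bin_index = rep(1:2, each = 4),
    category = c("X", "X", "M", "M", "X", "X", "X", "X"))
  p <- category_bin_profile(binned)
  expect_equal(p$profile["X", "bin1"], 0.5)
  expect_equal(p$profile["M", "bin1"], 0.5)
  expect_equal(p$profile["M", "bin2"], 0)   # absent category recorded as 0
  expect_equal(unname(colSums(p$profile)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(p$mean_dissimilarity), c(2.5, 12.5))
})

test_that("category correlation matches the closed-form oracle to 1e-12", {
  set.seed(33)
  md <- sort(runif(10, 5, 40))
  y <- 0.1 + 0.004 * md + rnorm(10, sd = 0.01)
  profile <- rbind(A = y, B = 1 - y)
  got <- category_correlation(profile, md)
  # closed form: r from the covariance formula, p from the t statistic
  n <- 10
  r_oracle <- sum((md - mean(md)) * (y - mean(y))) /
    sqrt(sum((md - mean(md))^2) * sum((y - mean(y))^2))
  t_stat <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_stat), df = n - 2)
  expect_equal(got$pearson_r[got$category == "A"], r_oracle,
               tolerance = 1e-12)
  expect_equal(got$p_value[got$category == "A"], p_oracle,
               tolerance = 1e-12)
  expect_equal(got$pearson_r[got$category == "B"], -r_oracle,
               tolerance = 1e-12)
})

test_that("exact linear profiles give r = 1; constant rows are flagged", {
  md <- c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50)
  profile <- rbind(L = md / 100, K = 0.5 - md / 100, Z = rep(0.5, 10))
  got <- category_correlation(profile, md)
  expect_equal(got$pearson_r[got$category == "L"], 1)
  expect_true(got$significant[got$category == "L"])
  expect_true(is.na(got$pearson_r[got$category == "Z"]))
  expect_match(got$note[got$category == "Z"], "zero variance")
  expect_error(category_correlation(profile[, 1:2], md[1:2]), "3 bins")
})

test_that("a doubled divergence class yields a positive significant trend", {
  cl <- simulate_clade(clade_config(
    n_focal = 1, n_background = 1, n_core_genes = 600,
    gene_length_codons = c(50L, 80L), ani_targets = 0.08,
    unique_genes_per_focal = 0,
    core_category_weights = c(X = 1, C = 1, E = 1, G = 1, J = 1, K = 1,
                              M = 1, O = 1, P = 1, T = 1),
    divergence_class_by_category = c(X = 2), annotated_fraction = 1,
    seed = 34))
  va <- variation_analysis(cl$genes, "F01", "B01")
  x <- va$correlations[va$correlations$category == "X", ]
  expect_gt(x$pearson_r, 0)
  expect_lt(x$p_value, 0.01)
  expect_true(x$significant)
  # binning is a partition with near-equal sizes
  sizes <- table(va$binned$bin_index)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(anyDuplicated(va$binned$gene_id), 0L)
  # per-bin normalisation holds
  expect_equal(unname(colSums(va$profile)), rep(1, 10), tolerance = 1e-9)
})
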