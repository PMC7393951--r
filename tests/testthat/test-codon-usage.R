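# Wright's ENC, GC3 and the expected ENC-GC3 null curve.

test_that("count_codons keys counts by family with the stated exclusions", {
  cc <- count_codons("ATGAAAAAGTAA")
  expect_equal(cc$K[["AAA"]], 1L)
  expect_equal(cc$K[["AAG"]], 1L)
  expect_false(any(c("M", "W") %in% names(cc)))
  # ambiguous codon skipped entirely
  cc2 <- count_codons("ATGNNGTAA")
  expect_true(all(vapply(cc2, sum, integer(1)) == 0L))
  # Met + Trp only: every family empty
  cc3 <- count_codons("ATGTGGTAA")
  expect_true(all(vapply(cc3, sum, integer(1)) == 0L))
  expect_error(count_codons("ATGTAAAAATAA"), "internal stop")
})

test_that("family homozygosity follows the F-hat formula", {
  expect_equal(family_homozygosity(c(AAA = 5L, AAG = 0L)), 1)
  expect_equal(family_homozygosity(c(AAA = 3L, AAG = 3L)), 0.4)
  expect_true(is.na(family_homozygosity(c(AAA = 1L, AAG = 0L))))
  # two codons at (1,1): F-hat = 0 -> undefined
  expect_true(is.na(family_homozygosity(c(AAA = 1L, AAG = 1L))))
})

test_that("ENC attains its printed bounds at the extremes", {
  fams <- codon_families()
  deg <- fams[!(names(fams) %in% c("M", "W"))]
  # one codon exclusively used per amino acid, each seen 5 times -> 20
  cds_min <- paste0(paste(vapply(deg, function(x)
    strrep(x[1], 5), character(1)), collapse = ""), "TAA")
  expect_identical(enc(cds_min), 20)
  # every synonymous codon exactly 12 times -> truncated to 61
  cds_max <- paste0(paste(vapply(deg, function(x)
    paste(rep(x, each = 12), collapse = ""), character(1)), collapse = ""),
    "TAA")
  expect_identical(enc(cds_max), 61)
})

test_that("ENC matches the step-by-step Wright oracle on random CDS", {
  set.seed(40)
  for (r in 1:25) {
    cds <- random_cds(300)
    expect_equal(enc(cds), oracle_enc(cds), tolerance = 1e-9)
  }
})

test_that("ENC is undefined without usable families, in [20, 61] otherwise", {
  expect_true(is.na(enc("ATGTGGTAA")))
  set.seed(41)
  for (r in 1:20) {
    v <- enc(random_cds(sample(c(30, 100, 400), 1)))
    if (!is.na(v)) {
      expect_gte(v, 20)
      expect_lte(v, 61)
    }
  }
})

test_that("gc3 counts third positions over sense codons", {
  expect_equal(gc3("ATGAAA"), 0.5)   # third positions G, A
  expect_equal(gc3("AAATTTTAA"), 0)  # stop excluded
  expect_equal(gc3("AAGTTCGGC"), 1)
  expect_true(is.na(gc3("")))
})

test_that("the expected ENC curve follows the null formula", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1), 32)
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
  # algebraic symmetry of the formula about s = 0.5
  s <- seq(0, 1, 0.05)
  expect_equal(expected_enc(s) - s, expected_enc(1 - s) - (1 - s))
})

test_that("stronger codon bias never increases ENC", {
  set.seed(42)
  prot <- random_protein_str(1500)
  prev <- Inf
  for (s in c(0, 0.25, 0.5, 0.75, 1)) {
    set.seed(100)  # same RNG stream per strength: paired comparison
    cds <- paste0(hadalsig:::biased_backtranslate(prot, s), "TAA")
    v <- enc(cds)
    expect_lte(v, prev + 1e-9)
    prev <- v
  }
})

test_that("enc_gc3_table classifies genes against the null curve", {
  set.seed(43)
  cds <- setNames(vapply(rep(200, 5), random_cds, character(1)),
                  paste0("g", 1:5))
  tab <- enc_gc3_table(cds, setNames(c("X", "M", NA, "K", "X"), names(cds)))
  expect_identical(tab$gene_id, names(cds))
  expect_identical(tab$below_curve,
                   !is.na(tab$enc) & tab$enc < tab$expected_enc)
})

test_that("unique genes with weaker bias average a higher ENC", {
  cl <- small_clade(seed = 44, codon_bias_strength = 0.8,
                    unique_codon_bias_strength = 0.05,
                    unique_genes_per_focal = 12, annotated_fraction = 1)
  genes <- cl$genes[cl$genes$genome_id %in% c("F01", "F02"), ]
  tab <- enc_gc3_table(setNames(genes$cds, genes$gene_id),
                       setNames(genes$category, genes$gene_id))
  cmp <- enc_comparison(tab, cl$truth$unique_gene_ids)
  uniq_mean <- mean(tab$enc[tab$gene_id %in% cl$truth$unique_gene_ids],
                    na.rm = TRUE)
  all_mean <- mean(tab$enc, na.rm = TRUE)
  expect_gt(uniq_mean, all_mean)
  pc <- cmp$per_category
  have_both <- !is.na(pc$mean_enc_unique) & pc$n_unique >= 2
  expect_gt(mean(pc$mean_enc_unique[have_both] >
                   pc$mean_enc_all[have_both]), 0.5)
  # identical sets give identical means
  cmp2 <- enc_comparison(tab, tab$gene_id)
  expect_equal(cmp2$per_category$mean_enc_unique,
               cmp2$per_category$mean_enc_all)
})

test_that("below-curve classification separates biased from unbiased genes", {
  # with uniform synonymous usage the true ENC (61) sits above the curve
  # (<= 60.5), so only sampling noise puts genes below it; under strong
  # bias every gene falls well below.  The informative check is the
  # contrast between the two regimes.
  set.seed(45)
  below_at <- function(strength) mean(replicate(20, {
    prot <- random_protein_str(500)
    cds <- paste0(hadalsig:::biased_backtranslate(prot, strength), "TAA")
    enc(cds) < expected_enc(gc3(cds))
  }))
  f0 <- below_at(0)
  f8 <- below_at(0.8)
  expect_lte(f0, 0.3)
  expect_equal(f8, 1)
  expect_gt(f8 - f0, 0.5)
})
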