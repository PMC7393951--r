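# Protein alignment, RBH ortholog clustering, unique clusters and
# functional composition.

test_that("global protein identity matches a textbook DP oracle", {
  # the classic pair, plus random pairs
  got <- global_protein_identity("HEAGAWGHEE", "PAWHEAE")
  want <- oracle_nw("HEAGAWGHEE", "PAWHEAE")
  expect_equal(got$score, want$score)
  expect_equal(got$identity, want$identity)

  expect_identical(global_protein_identity("MKVLW", "MKVLW")$identity, 100)
  expect_error(global_protein_identity("", "MKV"), "empty")

  set.seed(20)
  for (r in 1:10) {
    a <- random_protein_str(sample(20:60, 1))
    b <- random_protein_str(sample(20:60, 1))
    got <- global_protein_identity(a, b)
    want <- oracle_nw(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$identity, want$identity)
    # symmetry of identity
    expect_equal(global_protein_identity(b, a)$identity, got$identity)
  }
})

test_that("score-only batch equals the full alignment scores", {
  set.seed(21)
  qs <- vapply(rep(40, 15), random_protein_str, character(1))
  ss <- vapply(rep(40, 15), random_protein_str, character(1))
  pairs <- cbind(rep(1:15, each = 3), sample(1:15, 45, replace = TRUE))
  sc <- score_protein_pairs(qs, ss, pairs)
  full <- align_proteins(qs[pairs[, 1]], ss[pairs[, 2]])
  expect_equal(sc, full$score)
})

test_that("RBH edges appear for identical genes and not for strangers", {
  prot <- random_protein_str(50)
  proteomes <- list(gA = c(a1 = prot), gB = c(b1 = prot))
  e <- build_rbh_graph(proteomes)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$gene_a, e$gene_b), c("a1", "b1"))
  expect_equal(e$identity, 100)

  set.seed(22)
  # poly-W query shares no 4-mer with a W-free partner: no candidates
  proteomes2 <- list(gA = c(a1 = strrep("W", 40)),
                     gB = c(b1 = paste(rep("MKEL", 10), collapse = "")))
  expect_identical(nrow(build_rbh_graph(proteomes2)), 0L)
  expect_error(build_rbh_graph(proteomes2[1]), "two genomes")
})

test_that("cluster_genes forms the transitive-closure partition", {
  tab <- data.frame(gene_id = letters[1:5], genome_id = "g",
                    category = NA_character_)
  cl0 <- cluster_genes(data.frame(gene_a = character(0),
                                  gene_b = character(0)), tab)
  expect_identical(length(unique(cl0$cluster_id)), 5L)
  cl1 <- cluster_genes(data.frame(gene_a = c("a", "b"),
                                  gene_b = c("b", "c")), tab)
  expect_identical(length(unique(cl1$cluster_id[cl1$gene_id %in%
                                                  c("a", "b", "c")])), 1L)
  expect_identical(length(unique(cl1$cluster_id)), 3L)
  # membership is a partition of the input genes
  expect_setequal(cl1$gene_id, tab$gene_id)
  expect_identical(anyDuplicated(cl1$gene_id), 0L)
  expect_error(cluster_genes(data.frame(gene_a = "zz", gene_b = "a"), tab),
               "unknown gene")
})

test_that("clustering recovers the planted families exactly", {
  cl <- small_clade(seed = 11)
  pan <- pangenome_analysis(cl$genes, c("F01", "F02"))
  norm <- function(l) sort(vapply(l, function(x)
    paste(sort(x), collapse = ","), character(1)), method = "radix")
  got <- norm(split(pan$membership$gene_id, pan$membership$cluster_id))
  want <- norm(split(names(cl$truth$family_of_gene),
                     unname(cl$truth$family_of_gene)))
  expect_identical(unname(got), unname(want))
})

test_that("majority-rule category assignment breaks ties lexicographically", {
  expect_identical(assign_cluster_category(c("X", "X", "M")), "X")
  expect_identical(assign_cluster_category(c("M", "X")), "M")
  expect_identical(assign_cluster_category(c(NA, NA)), NA_character_)
  expect_identical(assign_cluster_category(character(0)), NA_character_)
})

test_that("unique-cluster detection has precision and recall >= 0.9", {
  cl <- small_clade(seed = 23)
  pan <- pangenome_analysis(cl$genes, c("F01", "F02"))
  truth_cl <- unique(pan$membership$cluster_id[
    pan$membership$gene_id %in% cl$truth$unique_gene_ids])
  found <- pan$clusters$cluster_id[pan$clusters$unique_to_focal]
  precision <- mean(found %in% truth_cl)
  recall <- mean(truth_cl %in% found)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # a cluster spanning focal and background genomes is never unique
  mixed <- pan$clusters$cluster_id[!pan$clusters$unique_to_focal]
  genomes_of <- split(pan$membership$genome_id, pan$membership$cluster_id)
  expect_true(all(vapply(genomes_of[mixed], function(g)
    any(g %in% c("B01", "B02")), logical(1))))
})

test_that("functional composition excludes unannotated clusters", {
  clusters <- data.frame(
    cluster_id = paste0("GC", 1:7),
    n_genes = 1L, n_genomes = 1L,
    category = c("X", "X", "M", "X", "M", "K", NA),
    unique_to_focal = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  comp <- functional_composition(clusters)
  tab <- comp$table
  expect_equal(tab$unique_proportion[tab$category == "X"], 2 / 3)
  expect_equal(tab$unique_proportion[tab$category == "M"], 1 / 3)
  expect_equal(sum(tab$unique_proportion), 1, tolerance = 1e-9)
  expect_equal(sum(tab$total_proportion), 1, tolerance = 1e-9)
  expect_equal(unname(comp$annotated_fraction["unique"]), 3 / 4)
  # no annotated clusters at all -> explicit empty table
  none <- clusters; none$category <- NA_character_
  expect_identical(nrow(functional_composition(none)$table), 0L)
})

test_that("a planted category enrichment shows up in the composition", {
  cl <- small_clade(seed = 24, unique_genes_per_focal = 15,
                    unique_category_weights = c(X = 6, M = 1, K = 1),
                    annotated_fraction = 0.9)
  pan <- pangenome_analysis(cl$genes, c("F01", "F02"))
  tab <- pan$composition$table
  x <- tab[tab$category == "X", ]
  expect_gt(x$unique_proportion, x$total_proportion)
})

test_that("marker density comparison runs a two-sided rank-sum test", {
  # no private genes, so all four genomes have identical lengths and the
  # shared marker families give identical densities -> maximal p
  cl <- small_clade(seed = 25, unique_genes_per_focal = 0)
  tab <- cl$genes
  markers <- tab$gene_id[grepl("fam000[1-5]$", tab$gene_id)]
  r <- marker_density_compare(cl$genomes, tab, markers)
  expect_true(r$p_value > 0.99)
  expect_identical(nrow(r$densities), 4L)
  one <- cl$genomes[c(1, 3, 4)]
  expect_error(marker_density_compare(one, tab, markers),
               "two genomes per group")
})

test_that("the marker-density comparison holds its nominal type-I error", {
  set.seed(26)
  # 10 focal + 10 background genomes; marker densities drawn from the same
  # distribution via per-genome marker counts and jittered genome lengths
  mk_genome <- function(id, role) {
    structure(list(genome_id = id,
                   contigs = c(c1 = "ACGT"),
                   role = role,
                   genome_length_bp = round(runif(1, 9e5, 1.1e6))),
              class = "genome_record")
  }
  n_rep <- 1000
  rej <- 0
  for (r in seq_len(n_rep)) {
    genomes <- c(lapply(sprintf("F%02d", 1:10), mk_genome, role = "focal"),
                 lapply(sprintf("B%02d", 1:10), mk_genome,
                        role = "background"))
    ids <- vapply(genomes, `[[`, "", "genome_id")
    counts <- rpois(20, 40)
    tab <- data.frame(gene_id = sprintf("g%04d", seq_len(sum(counts))),
                      genome_id = rep(ids, counts))
    res <- marker_density_compare(genomes, tab, tab$gene_id)
    if (res$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})
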