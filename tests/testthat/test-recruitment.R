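# BLAST tabular parsing, hit filtering, competitive assignment, the
# internal mapper, RPKG and depth-profile clustering.

blast_row <- function(qid, sid, pident, qstart, qend,
                      evalue = 1e-20, bitscore = 200) {
  paste(qid, sid, pident, abs(qend - qstart) + 1, 0, 0, qstart, qend,
        1, abs(qend - qstart) + 1, format(evalue), bitscore, sep = "\t")
}

test_that("parse_blast_tab computes coverage and resolves genomes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(blast_row("r1", "c1", 99.0, 1, 100),
               blast_row("r2", "c2", 97.5, 100, 21)), f)  # minus-strand span
  hits <- parse_blast_tab(f, read_lengths = c(r1 = 100L, r2 = 100L),
                          contig_map = c(c1 = "gA", c2 = "gB"))
  expect_equal(hits$query_coverage, c(100, 80))
  expect_identical(hits$genome_id, c("gA", "gB"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_identical(nrow(parse_blast_tab(empty, c(r1 = 100L),
                                        c(c1 = "gA"))), 0L)
  writeLines(blast_row("r1", "cX", 99, 1, 100), f)
  expect_error(parse_blast_tab(f, c(r1 = 100L), c(c1 = "gA")),
               "unknown contig")
})

test_that("hit filtering is inclusive at every boundary", {
  hits <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                     genome_id = "g",
                     identity = c(94.9, 95.0, 99, 99),
                     query_coverage = c(90, 80.0, 79.9, 90),
                     evalue = c(1e-9, 1e-6, 1e-9, 2e-5),
                     score = 100)
  kept <- filter_hits(hits)
  expect_identical(kept$read_id, "r2")
  # hits without an E-value (internal mapper) pass the E-value gate
  hits$evalue <- NA_real_
  expect_identical(filter_hits(hits)$read_id, c("r2", "r4"))
  expect_identical(nrow(filter_hits(hits[0, ])), 0L)
})

test_that("competitive assignment picks identity, then score, then id", {
  hits <- data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r3", "r3"),
    genome_id = c("gA", "gB", "gA", "gB", "gB", "gA"),
    identity = c(99, 97, 99, 99, 98, 98),
    query_coverage = 100,
    score = c(180, 190, 180, 190, 150, 150))
  asg <- competitive_assign(hits)
  expect_identical(unname(asg[c("r1", "r2", "r3")]), c("gA", "gB", "gA"))
})

test_that("competitive assignment equals a brute-force scan on random tables", {
  set.seed(50)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    hits <- data.frame(
      read_id = sprintf("r%02d", sample(8, n, replace = TRUE)),
      genome_id = sprintf("g%s", sample(LETTERS[1:4], n, replace = TRUE)),
      identity = round(runif(n, 90, 100), sample(0:1, 1)),
      query_coverage = 100,
      score = sample(50:60, n, replace = TRUE))
    hits <- hits[!duplicated(hits[c("read_id", "genome_id")]), ]
    got <- competitive_assign(hits)
    want <- oracle_competitive(hits)
    expect_identical(got[order(names(got))], want[order(names(want))])
  }
})

test_that("the internal mapper hits only genomes containing the read", {
  cl <- small_clade(seed = 51)
  g <- cl$genomes[["F01"]]
  set.seed(52)
  unrelated <- genome_record("R00", c(c1 = paste(
    sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")))
  read <- substr(g$contigs[[1]], 1001, 1150)
  hits <- map_reads_simple(c(read1 = read), list(g, unrelated))
  expect_identical(hits$genome_id, "F01")
  expect_equal(hits$identity, 100)
  expect_equal(hits$query_coverage, 100)
  # a read from a region shared verbatim by two genomes hits both equally
  twin <- genome_record("A00", g$contigs)  # same sequence, smaller id
  hits2 <- map_reads_simple(c(read1 = read), list(g, twin))
  expect_equal(nrow(hits2), 2L)
  expect_equal(unique(hits2$identity), 100)
  asg <- competitive_assign(hits2)
  expect_identical(unname(asg), "A00")  # lexicographic tie-break
  # minus-strand reads map too
  hits3 <- map_reads_simple(c(read1 = revcomp(read)), list(g))
  expect_equal(hits3$identity, 100)
  expect_error(map_reads_simple(c(r = "ACGT"), list(g)), "seed length")
})

test_that("reads at 1% error usually retain an exact 21-mer seed", {
  cl <- small_clade(seed = 53)
  ab <- setNames(c(1, 0, 0, 0), names(cl$genomes))
  rs <- simulate_reads(cl$genomes, ab, n_reads = 500, read_length_bp = 150,
                       error_rate = 0.01, seed = 54)
  hits <- map_reads_simple(rs$reads, cl$genomes["F01"])
  expect_gte(length(unique(hits$read_id)) / 500, 0.95)
})

test_that("RPKG follows (Rx/MG)/Gx and its scaling laws", {
  expect_equal(rpkg(200, 1e6, 2e9), 0.1)
  expect_equal(rpkg(0, 1e6, 2e9), 0)
  expect_equal(rpkg(200, 1e6, 4e9), 0.05)  # doubling metagenome halves it
  expect_equal(rpkg(200, 2e6, 2e9), 0.05)  # doubling genome halves it
  expect_error(rpkg(1, 0, 1e9), "genome size")
  expect_error(rpkg(1, 1e6, 0), "metagenome size")
})

test_that("Z-normalisation centres and scales every non-constant row", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 5))
  z <- znormalize(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(unname(rowMeans(z)), rep(0, 3))
  expect_equal(apply(z[c("a", "c"), ], 1, sd), c(a = 1, c = 1))
  expect_error(znormalize(m[, 1, drop = FALSE]), "two samples")
})

test_that("profile clustering matches a brute-force complete-linkage oracle", {
  # two identical rows merge at height zero
  m0 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 1, 0, 2))
  cl0 <- cluster_profiles(m0)
  expect_equal(min(cl0$hclust$height), 0)
  # an outlier row joins last
  m1 <- rbind(a = c(0, 0, 0, 0), b = c(0.1, 0, 0, 0), c = c(50, 60, 70, 80))
  cl1 <- cluster_profiles(m1)
  expect_equal(max(cl1$hclust$height),
               max(dist(m1)))  # outlier merge = full-span complete linkage
  expect_match(cl1$newick, "^\\(")
  set.seed(55)
  for (r in 1:10) {
    m <- matrix(rnorm(24), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
    got <- sort(cluster_profiles(m)$hclust$height)
    want <- sort(oracle_complete_linkage_heights(m))
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(cluster_profiles(m0[1, , drop = FALSE]), "two genomes")
})

test_that("no read is assigned to a genome it cannot have come from", {
  # genomes >= 10% diverged from each other; 95% identity filter in force
  cl <- simulate_clade(clade_config(
    n_focal = 2, n_background = 2, n_core_genes = 25,
    gene_length_codons = c(80L, 80L), ani_targets = 0.06,
    unique_genes_per_focal = 0, seed = 56))
  ab <- setNames(rep(0.25, 4), names(cl$genomes))
  rs <- simulate_reads(cl$genomes, ab, n_reads = 2000, seed = 57)
  asg <- competitive_assign(filter_hits(map_reads_simple(rs$reads,
                                                         cl$genomes)))
  origin <- setNames(rs$origins$genome_id, rs$origins$read_id)
  expect_true(all(asg == origin[names(asg)]))
  # conservation: each read contributes at most once
  expect_lte(length(asg), length(rs$reads))
})
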