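# Ortholog gene-cluster inference by reciprocal best hits (RBH) plus
# connected components, majority-rule cluster annotation, focal-unique
# cluster detection, and functional-composition comparison of the unique
# pool against the total annotated pool.

#' Build the reciprocal-best-hit graph over per-genome proteomes
#'
#' Candidate pairs must share at least one exact protein `kmer_prefilter`-mer;
#' candidates are globally aligned (BLOSUM62, affine 11/1) and an edge is
#' drawn between genes of different genomes iff each is the other's
#' best-scoring hit in the partner genome and the pair passes the identity
#' and shorter-sequence coverage thresholds.  Within-genome pairs above
#' `paralog_identity` are bridged so recently duplicated copies join one
#' cluster.
#'
#' @param proteomes Named list (genome id -> named character vector of
#'   proteins, names are gene ids).
#' @param min_identity Minimum percent identity for an RBH edge.
#' @param min_shorter_coverage Minimum fraction of the shorter protein
#'   covered by residue-to-residue alignment columns.
#' @param kmer_prefilter Protein word length of the seeding prefilter.
#' @param paralog_identity Within-genome bridging threshold (percent).
#' @return data.frame edge list: gene_a, gene_b, identity, score.
#' @export
build_rbh_graph <- function(proteomes, min_identity = 30,
                            min_shorter_coverage = 0.5,
                            kmer_prefilter = 4L, paralog_identity = 70) {
  if (length(proteomes) < 2L) stop("need at least two genomes")
  gids <- names(proteomes)
  edges <- list()
  for (i in seq_along(proteomes)) {
    for (j in seq_along(proteomes)) {
      if (j <= i) next
      pa <- proteomes[[i]]; pb <- proteomes[[j]]
      cand <- shared_kmer_pairs(pa, pb, k = kmer_prefilter)
      if (!nrow(cand)) next
      sc <- score_protein_pairs(pa, pb, cand)
      # best-scoring hit of each query in the partner genome, and vice versa
      best_a <- tapply(seq_len(nrow(cand)), cand[, 1L],
                       function(r) r[which.max(sc[r])])
      best_b <- tapply(seq_len(nrow(cand)), cand[, 2L],
                       function(r) r[which.max(sc[r])])
      rbh <- intersect(unlist(best_a), unlist(best_b))
      if (!length(rbh)) next
      # identity/coverage thresholds are checked on the mutual best pairs
      aln <- align_proteins(pa[cand[rbh, 1L]], pb[cand[rbh, 2L]])
      cov <- aln$nboth / pmin(nchar(pa[cand[rbh, 1L]]),
                              nchar(pb[cand[rbh, 2L]]))
      ok <- aln$identity >= min_identity & cov >= min_shorter_coverage
      if (any(ok))
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = names(pa)[cand[rbh[ok], 1L]],
          gene_b = names(pb)[cand[rbh[ok], 2L]],
          identity = aln$identity[ok], score = aln$score[ok],
          stringsAsFactors = FALSE)
    }
    # within-genome paralog bridging
    pa <- proteomes[[i]]
    if (length(pa) >= 2L) {
      cand <- shared_kmer_pairs(pa, pa, k = kmer_prefilter)
      cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
      if (nrow(cand)) {
        # cheap score screen first; identity needs the full alignment
        sc <- score_protein_pairs(pa, pa, cand)
        keep <- sc > 0
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand)) {
        aln <- align_proteins(pa[cand[, 1L]], pa[cand[, 2L]])
        ok <- aln$identity > paralog_identity
        if (any(ok))
          edges[[length(edges) + 1L]] <- data.frame(
            gene_a = names(pa)[cand[ok, 1L]],
            gene_b = names(pa)[cand[ok, 2L]],
            identity = aln$identity[ok], score = aln$score[ok],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), score = numeric(0)))
  do.call(rbind, edges)
}

#' Cluster genes into ortholog groups (connected components)
#'
#' Connected components of the RBH graph; genes with no edge become
#' singleton clusters.  The clusters partition the gene set.
#'
#' @param edges Edge list data.frame (`gene_a`, `gene_b`) as from
#'   [build_rbh_graph()]; may have zero rows.
#' @param gene_table Gene table covering all genes (`gene_id`,
#'   `genome_id`, `category`).
#' @return data.frame: cluster_id, gene_id, genome_id, category; cluster
#'   ids are `GC0001`-style, ordered by first member gene.
#' @export
cluster_genes <- function(edges, gene_table) {
  ids <- gene_table$gene_id
  unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), ids)
  if (length(unknown)) stop("edge references unknown gene: ", unknown[1L])
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$gene_a, ids),
                                    match(edges$gene_b, ids)))
  comp <- igraph::components(g)$membership
  # stable cluster numbering by first gene appearance
  first <- !duplicated(comp)
  renum <- stats::setNames(seq_len(sum(first)), comp[first])
  cl <- renum[as.character(comp)]
  data.frame(cluster_id = sprintf("GC%04d", cl),
             gene_id = ids,
             genome_id = gene_table$genome_id,
             category = gene_table$category,
             stringsAsFactors = FALSE)
}

#' Majority-rule category of one gene cluster
#'
#' The category most frequent among the cluster's annotated members; ties
#' are broken by the lexicographically smallest letter (a deterministic
#' stand-in for an arbitrary choice); `NA` when no member is annotated.
#'
#' @param categories Member category letters (may contain `NA`).
#' @return Single category letter or `NA_character_`.
#' @export
assign_cluster_category <- function(categories) {
  categories <- categories[!is.na(categories)]
  if (!length(categories)) return(NA_character_)
  tab <- table(categories)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1L]
}

#' Summarise clusters: majority category and focal-unique flag
#'
#' @param membership Cluster membership data.frame from [cluster_genes()].
#' @param focal_ids Focal genome ids; every other genome id present is
#'   treated as background.
#' @return data.frame of class `gene_clusters`: cluster_id, n_genes,
#'   n_genomes, category, unique_to_focal.
#' @export
summarise_clusters <- function(membership, focal_ids) {
  sp <- split(membership, membership$cluster_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    cluster_id = d$cluster_id[1L],
    n_genes = nrow(d),
    n_genomes = length(unique(d$genome_id)),
    category = assign_cluster_category(d$category),
    unique_to_focal = all(d$genome_id %in% focal_ids),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("gene_clusters", "data.frame")
  out
}

#' Flag clusters unique to the focal genomes
#'
#' @param clusters `gene_clusters` data.frame (from
#'   [summarise_clusters()]) or raw membership; recomputed flag returned.
#' @param membership Cluster membership data.frame.
#' @param focal_ids Focal genome ids.
#' @return The clusters table with `unique_to_focal` set iff no member
#'   genome is background.
#' @export
unique_clusters <- function(clusters, membership, focal_ids) {
  by_cl <- split(membership$genome_id, membership$cluster_id)
  flag <- vapply(by_cl, function(g) all(g %in% focal_ids), logical(1))
  clusters$unique_to_focal <- unname(flag[clusters$cluster_id])
  clusters
}

#' Functional composition of the unique pool vs the total pool
#'
#' Category proportions among annotated clusters only (unannotated
#' clusters are excluded from both denominators), for the focal-unique
#' subset and for the full cluster pool.
#'
#' @param clusters `gene_clusters` data.frame with `category` and
#'   `unique_to_focal`.
#' @return List of class `composition_table`: `table` (data.frame:
#'   category, unique_proportion, total_proportion, n_unique, n_total)
#'   and `annotated_fraction` (named: unique, total).  With no annotated
#'   clusters at all, `table` has zero rows.
#' @export
functional_composition <- function(clusters) {
  ann <- clusters[!is.na(clusters$category), ]
  uniq <- ann[ann$unique_to_focal, ]
  if (!nrow(ann)) {
    return(structure(list(
      table = data.frame(category = character(0),
                         unique_proportion = numeric(0),
                         total_proportion = numeric(0),
                         n_unique = integer(0), n_total = integer(0)),
      annotated_fraction = c(unique = NA_real_, total = NA_real_)),
      class = "composition_table"))
  }
  cats <- sort(unique(ann$category))
  n_tot <- table(factor(ann$category, levels = cats))
  n_unq <- table(factor(uniq$category, levels = cats))
  tab <- data.frame(
    category = cats,
    unique_proportion = if (nrow(uniq)) as.numeric(n_unq / nrow(uniq))
                        else NA_real_,
    total_proportion = as.numeric(n_tot / nrow(ann)),
    n_unique = as.integer(n_unq),
    n_total = as.integer(n_tot),
    stringsAsFactors = FALSE)
  u_all <- clusters$unique_to_focal
  structure(list(
    table = tab,
    annotated_fraction = c(
      unique = if (any(u_all)) mean(!is.na(clusters$category[u_all]))
               else NA_real_,
      total = mean(!is.na(clusters$category)))),
    class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Functional composition (annotated clusters only)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("annotated fraction: unique %.3f, total %.3f\n",
              x$annotated_fraction["unique"], x$annotated_fraction["total"]))
  invisible(x)
}

#' Compare marker-gene coding density between focal and background genomes
#'
#' Density is marker genes per Mb of genome; groups are compared with a
#' two-sided Mann-Whitney U (Wilcoxon rank-sum) test, the standard check
#' that e.g. CAZyme density does not differ between trench SAGs and their
#' surface relatives.
#'
#' @param genomes List of `genome_record` (both roles present, at least
#'   two genomes per role).
#' @param gene_table Gene table with `gene_id` and `genome_id`.
#' @param marker_gene_ids Gene ids of the marker subset.
#' @return List: `densities` (data.frame genome_id, role, n_markers,
#'   density_per_mb), `p_value`, `statistic`.
#' @export
marker_density_compare <- function(genomes, gene_table, marker_gene_ids) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  roles <- vapply(genomes, `[[`, "", "role")
  if (sum(roles == "focal") < 2L || sum(roles == "background") < 2L)
    stop("need at least two genomes per group")
  markers <- gene_table[gene_table$gene_id %in% marker_gene_ids, ]
  n_mark <- vapply(ids, function(g) sum(markers$genome_id == g), integer(1))
  mb <- vapply(genomes, `[[`, 0, "genome_length_bp") / 1e6
  dens <- n_mark / mb
  wt <- suppressWarnings(wilcox.test(dens[roles == "focal"],
                                     dens[roles == "background"],
                                     alternative = "two.sided"))
  # fully tied samples: no evidence of a difference, maximal p
  if (is.nan(wt$p.value)) wt$p.value <- 1
  list(densities = data.frame(genome_id = ids, role = roles,
                              n_markers = n_mark,
                              density_per_mb = unname(dens),
                              stringsAsFactors = FALSE, row.names = NULL),
       p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' Full pangenome analysis convenience wrapper
#'
#' Runs RBH graph construction, clustering, summarisation, unique-cluster
#' flagging and functional composition in one call.
#'
#' @param gene_table Gene table with `gene_id`, `genome_id`, `protein`,
#'   `category`.
#' @param focal_ids Focal genome ids.
#' @param ... Passed to [build_rbh_graph()].
#' @return List: `membership`, `clusters`, `composition`, `edges`.
#' @export
pangenome_analysis <- function(gene_table, focal_ids, ...) {
  proteomes <- lapply(split(gene_table, gene_table$genome_id), function(d)
    stats::setNames(d$protein, d$gene_id))
  edges <- build_rbh_graph(proteomes, ...)
  membership <- cluster_genes(edges, gene_table)
  clusters <- summarise_clusters(membership, focal_ids)
  list(membership = membership, clusters = clusters,
       composition = functional_composition(clusters), edges = edges)
}
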