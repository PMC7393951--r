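# Rank-decile amino-acid-variation profiling: per-gene top-hit identity of
# focal proteins against background proteomes, decile binning by
# dissimilarity (100 - identity), per-category composition per bin, and
# per-category Pearson correlation of composition with mean dissimilarity.

#' Best-hit identity of focal proteins against background proteomes
#'
#' Candidates must share at least one exact protein 4-mer with the query;
#' all candidates are globally aligned (BLOSUM62, affine 11/1) and the
#' best-scoring alignment wins.  A query whose best score falls below
#' `min_score` — the raw-score stand-in for a search E-value cutoff, see
#' [calibrate_score_threshold()] — gets no hit (`NA`).
#'
#' @param queries Named character vector of query proteins.
#' @param background Named character vector of background proteins (all
#'   background genomes pooled).
#' @param min_score Minimum accepted alignment score.
#' @param kmer_prefilter Protein word length for candidate seeding.
#' @return data.frame: gene_id, top_hit_identity (percent or `NA`),
#'   top_hit (subject gene id or `NA`), score.
#' @export
top_hit_identity <- function(queries, background, min_score = 50,
                             kmer_prefilter = 4L) {
  out <- data.frame(gene_id = names(queries),
                    top_hit_identity = NA_real_,
                    top_hit = NA_character_,
                    score = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(background) || !length(queries)) return(out)
  cand <- shared_kmer_pairs(queries, background, k = kmer_prefilter)
  if (!nrow(cand)) return(out)
  sc <- score_protein_pairs(queries, background, cand)
  best <- tapply(seq_len(nrow(cand)), cand[, 1L],
                 function(r) r[which.max(sc[r])])
  bi <- unlist(best)
  qi <- as.integer(names(best))
  keep <- sc[bi] >= min_score
  bi <- bi[keep]; qi <- qi[keep]
  if (!length(bi)) return(out)
  # full alignment (for identity) only on each query's best-scoring hit
  aln <- align_proteins(queries[cand[bi, 1L]], background[cand[bi, 2L]])
  out$top_hit_identity[qi] <- aln$identity
  out$top_hit[qi] <- names(background)[cand[bi, 2L]]
  out$score[qi] <- aln$score
  out
}

#' Calibrate the alignment-score acceptance threshold
#'
#' Aligns residue-shuffled query/subject pairs and returns the score
#' quantile below which random (non-homologous) proteins fall, so that
#' unrelated sequences pass the threshold at most `1 - q` of the time.
#'
#' @param proteins Character vector of proteins to shuffle.
#' @param n Number of shuffled pairs to align.
#' @param q Quantile (default 0.99: random pairs pass < 1% of the time).
#' @return Numeric score threshold.
#' @export
calibrate_score_threshold <- function(proteins, n = 200L, q = 0.99) {
  if (length(proteins) < 2L) stop("need at least two proteins")
  shuffle <- function(s) paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]),
                               collapse = "")
  pick <- matrix(sample(length(proteins), 2L * n, replace = TRUE), ncol = 2)
  a <- vapply(proteins[pick[, 1L]], shuffle, character(1), USE.NAMES = FALSE)
  b <- vapply(proteins[pick[, 2L]], shuffle, character(1), USE.NAMES = FALSE)
  aln <- align_proteins(a, b)
  unname(stats::quantile(aln$score, q))
}

#' Rank genes by dissimilarity and divide them into equal bins
#'
#' Records are sorted ascending by dissimilarity (`100 - identity`), ties
#' broken by `gene_id`, and split into `n_bins` contiguous intervals whose
#' sizes differ by at most one (larger bins first); bin 1 holds the least
#' dissimilar genes.  Records without an accepted hit are excluded before
#' ranking.
#'
#' @param records data.frame with `gene_id` and `top_hit_identity` (as
#'   from [top_hit_identity()]), plus any annotation columns.
#' @param n_bins Number of intervals.
#' @return The ranked records with `dissimilarity` and `bin_index`
#'   columns.
#' @export
rank_into_bins <- function(records, n_bins = 10L) {
  rec <- records[!is.na(records$top_hit_identity), , drop = FALSE]
  if (nrow(rec) < n_bins)
    stop("need at least ", n_bins, " genes with hits to form ", n_bins,
         " bins (have ", nrow(rec), ")")
  rec$dissimilarity <- 100 - rec$top_hit_identity
  rec <- rec[order(rec$dissimilarity, rec$gene_id), , drop = FALSE]
  n <- nrow(rec)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + rep(c(1L, 0L), c(extra, n_bins - extra))
  rec$bin_index <- rep(seq_len(n_bins), sizes)
  rownames(rec) <- NULL
  rec
}

#' Category composition and mean dissimilarity per bin
#'
#' @param binned Output of [rank_into_bins()] with a `category` column.
#' @return List: `profile` (matrix category x bin of within-bin relative
#'   abundance among annotated genes; each column sums to 1),
#'   `mean_dissimilarity` (per bin, over all the bin's records),
#'   `bin_sizes`.
#' @export
category_bin_profile <- function(binned) {
  n_bins <- max(binned$bin_index)
  bins <- factor(binned$bin_index, levels = seq_len(n_bins))
  ann <- !is.na(binned$category)
  cats <- sort(unique(binned$category[ann]))
  counts <- table(factor(binned$category[ann], levels = cats), bins[ann])
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("bin without annotated genes; cannot form composition profile")
  profile <- sweep(unclass(counts), 2, totals, "/")
  dimnames(profile) <- list(cats, paste0("bin", seq_len(n_bins)))
  md <- tapply(binned$dissimilarity, bins, mean)
  list(profile = profile,
       mean_dissimilarity = stats::setNames(as.numeric(md),
                                            colnames(profile)),
       bin_sizes = stats::setNames(as.integer(table(bins)),
                                   colnames(profile)))
}

#' Per-category Pearson correlation with mean bin dissimilarity
#'
#' For each category, Pearson r between its per-bin relative abundance and
#' the per-bin mean dissimilarity, with a two-sided p-value from the t
#' statistic on n - 2 degrees of freedom; the significance flag is
#' `p < p_cutoff`.  Zero-variance composition rows are undefined and
#' flagged with a reason.
#'
#' @param profile Category x bin matrix from [category_bin_profile()].
#' @param mean_dissimilarity Per-bin mean dissimilarities.
#' @param p_cutoff Significance cutoff (default 0.01).
#' @return data.frame: category, pearson_r, p_value, significant, note.
#' @export
category_correlation <- function(profile, mean_dissimilarity,
                                 p_cutoff = 0.01) {
  if (ncol(profile) < 3L) stop("need at least 3 bins")
  out <- data.frame(category = rownames(profile),
                    pearson_r = NA_real_, p_value = NA_real_,
                    significant = FALSE, note = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(profile))) {
    y <- profile[i, ]
    if (stats::sd(y) == 0 || stats::sd(mean_dissimilarity) == 0) {
      out$note[i] <- "zero variance; correlation undefined"
      next
    }
    ct <- cor.test(mean_dissimilarity, y, method = "pearson",
                   alternative = "two.sided")
    out$pearson_r[i] <- unname(ct$estimate)
    out$p_value[i] <- ct$p.value
    out$significant[i] <- ct$p.value < p_cutoff
  }
  out
}

#' Full variation analysis convenience wrapper
#'
#' Runs top-hit search, decile binning, per-bin composition and
#' per-category correlation for annotated focal genes against the pooled
#' background proteomes.
#'
#' @param gene_table Gene table with `gene_id`, `genome_id`, `protein`,
#'   `category`.
#' @param focal_ids,background_ids Genome id vectors.
#' @param min_score Alignment-score acceptance threshold.
#' @param n_bins Number of rank intervals.
#' @param p_cutoff Correlation significance cutoff.
#' @return List: `records`, `binned`, `profile`, `mean_dissimilarity`,
#'   `correlations`.
#' @export
variation_analysis <- function(gene_table, focal_ids, background_ids,
                               min_score = 50, n_bins = 10L,
                               p_cutoff = 0.01) {
  q <- gene_table[gene_table$genome_id %in% focal_ids &
                    !is.na(gene_table$category), ]
  b <- gene_table[gene_table$genome_id %in% background_ids, ]
  rec <- top_hit_identity(stats::setNames(q$protein, q$gene_id),
                          stats::setNames(b$protein, b$gene_id),
                          min_score = min_score)
  rec$category <- q$category[match(rec$gene_id, q$gene_id)]
  binned <- rank_into_bins(rec, n_bins = n_bins)
  prof <- category_bin_profile(binned)
  corr <- category_correlation(prof$profile, prof$mean_dissimilarity,
                               p_cutoff = p_cutoff)
  list(records = rec, binned = binned, profile = prof$profile,
       mean_dissimilarity = prof$mean_dissimilarity, correlations = corr)
}
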