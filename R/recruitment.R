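# Competitive metagenomic read recruitment, RPKG abundance, Z-normalised
# depth profiles and hierarchical clustering of genomes by vertical
# distribution.
#
# Hits can come from an external BLAST tabular file (outfmt 6) or from the
# internal exact-k-mer/ungapped mapper; after filtering (evalue <= 1e-5,
# identity >= 95, query coverage >= 80 by default) each read is recruited
# only by the genome with which it has the highest identity.

#' Parse a 12-column BLAST tabular (outfmt 6) hit file
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore.  Query coverage is computed as
#' `100 * (|qend - qstart| + 1) / read length`; the subject genome is
#' resolved from the subject (contig) id through `contig_map`.
#'
#' @param path Path to the tabular file (no header).
#' @param read_lengths Named integer vector: read id -> length.
#' @param contig_map Named character vector: contig id -> genome id.
#' @return data.frame of hits: read_id, genome_id, identity,
#'   query_coverage, evalue, alignment_length, score.
#' @export
parse_blast_tab <- function(path, read_lengths, contig_map) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0)
    return(data.frame(read_id = character(0), genome_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      evalue = numeric(0), alignment_length = integer(0),
                      score = numeric(0)))
  tab <- tryCatch(
    read.delim(path, header = FALSE, col.names = cols,
               stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("malformed BLAST tabular file: ",
                             conditionMessage(e)))
  if (ncol(tab) != 12L) stop("expected 12 BLAST tabular columns")
  num_ok <- vapply(tab[c("pident", "qstart", "qend", "evalue")],
                   is.numeric, logical(1))
  if (!all(num_ok)) {
    bad <- which(!stats::complete.cases(
      suppressWarnings(vapply(tab[c("pident", "qstart", "qend")],
                              as.numeric, numeric(nrow(tab))))))[1L]
    stop("malformed BLAST tabular row at line ", bad)
  }
  genome <- unname(contig_map[tab$sseqid])
  if (anyNA(genome))
    stop("unknown contig in hits: ", tab$sseqid[is.na(genome)][1L])
  rl <- unname(read_lengths[tab$qseqid])
  if (anyNA(rl))
    stop("hit for unknown read: ", tab$qseqid[is.na(rl)][1L])
  data.frame(read_id = tab$qseqid, genome_id = genome,
             identity = tab$pident,
             query_coverage = 100 * (abs(tab$qend - tab$qstart) + 1) / rl,
             evalue = tab$evalue,
             alignment_length = tab$length,
             score = tab$bitscore,
             stringsAsFactors = FALSE)
}

#' Filter recruitment hits at the standard thresholds
#'
#' Keeps hits with `evalue <= max_evalue` (hits lacking an E-value, e.g.
#' from the internal mapper, pass), `identity >= min_identity` and
#' `query_coverage >= min_coverage` — all thresholds inclusive.
#'
#' @param hits Hit data.frame (see [parse_blast_tab()]).
#' @param max_evalue,min_identity,min_coverage Thresholds.
#' @return The filtered hits.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_identity = 95.0,
                        min_coverage = 80.0) {
  ev_ok <- if ("evalue" %in% names(hits))
    is.na(hits$evalue) | hits$evalue <= max_evalue else TRUE
  keep <- ev_ok & hits$identity >= min_identity &
    hits$query_coverage >= min_coverage
  hits[keep, , drop = FALSE]
}

#' Competitively assign each read to a single genome
#'
#' Per read, the genome of the highest-identity hit wins; ties are broken
#' by higher score, then by lexicographically smallest genome id, so
#' assignment is deterministic.
#'
#' @param hits Filtered hit data.frame with `read_id`, `genome_id`,
#'   `identity`, `score`.
#' @return Named character vector: read id -> genome id.
#' @export
competitive_assign <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$read_id, -hits$identity, -hits$score, hits$genome_id)
  h <- hits[ord, ]
  first <- !duplicated(h$read_id)
  stats::setNames(h$genome_id[first], h$read_id[first])
}

#' Internal competitive mapper: exact k-mer seeding, ungapped extension
#'
#' Maps each read against every genome on both strands: candidate
#' placements are located by exact shared k-mers, the full read is
#' compared ungapped at each placement (full-length placement inside a
#' contig required), identity is computed over the read length, and
#' coverage is 100 for any seeded hit.  Reads with no seed in a genome get
#' no hit for it.
#'
#' @param reads Named character vector of read sequences.
#' @param genomes List of `genome_record`.
#' @param k Seed length (reads must be at least `k` long).
#' @return Hit data.frame: read_id, genome_id, identity, query_coverage,
#'   evalue (`NA`), alignment_length, score (match count).
#' @export
map_reads_simple <- function(reads, genomes, k = 21L) {
  if (any(nchar(reads) < k)) stop("read shorter than the seed length k")
  rows <- list()
  for (g in genomes) {
    best_id <- rep(NA_real_, length(reads))
    best_match <- rep(NA_real_, length(reads))
    for (contig in g$contigs) {
      m <- cpp_seed_extend(reads, contig, as.integer(k), 1.0)
      better <- !is.na(m[, "identity"]) &
        (is.na(best_id) | m[, "identity"] > best_id)
      best_id[better] <- m[better, "identity"]
      best_match[better] <- m[better, "matches"]
    }
    hit <- !is.na(best_id)
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(reads)[hit], genome_id = g$genome_id,
        identity = best_id[hit], query_coverage = 100,
        evalue = NA_real_,
        alignment_length = nchar(reads[hit]),
        score = best_match[hit],
        stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(read_id = character(0), genome_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      evalue = numeric(0), alignment_length = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RPKG: reads recruited per kilobase of genome per gigabase of metagenome
#'
#' `RPKG = (Rx / MG) / Gx` with Rx the reads assigned to the genome, MG
#' the metagenome size in gigabases and Gx the genome size in kilobases.
#'
#' @param n_reads Reads assigned to the genome (Rx).
#' @param genome_length_bp Genome size in bp (> 0).
#' @param metagenome_size_bp Metagenome size in bp (> 0).
#' @return RPKG value (vectorised).
#' @export
rpkg <- function(n_reads, genome_length_bp, metagenome_size_bp) {
  if (any(genome_length_bp <= 0)) stop("genome size must be > 0")
  if (any(metagenome_size_bp <= 0)) stop("metagenome size must be > 0")
  (n_reads / (metagenome_size_bp / 1e9)) / (genome_length_bp / 1e3)
}

#' Genome x sample RPKG matrix from per-sample assignments
#'
#' @param assignments Named list: sample id -> named character vector of
#'   read -> genome assignments (from [competitive_assign()]).
#' @param genomes List of `genome_record`.
#' @param samples Sample metadata data.frame (`sample_id`,
#'   `metagenome_size_bp`).
#' @return Numeric matrix genomes x samples of RPKG values.
#' @export
rpkg_matrix <- function(assignments, genomes, samples) {
  gids <- vapply(genomes, `[[`, "", "genome_id")
  glen <- vapply(genomes, `[[`, 0, "genome_length_bp")
  m <- matrix(0, length(gids), nrow(samples),
              dimnames = list(gids, samples$sample_id))
  for (si in seq_len(nrow(samples))) {
    asg <- assignments[[samples$sample_id[si]]]
    counts <- table(factor(asg, levels = gids))
    m[, si] <- rpkg(as.numeric(counts), glen,
                    samples$metagenome_size_bp[si])
  }
  m
}

#' Z-normalise a genome x sample profile matrix by row
#'
#' Each genome row is centred and scaled by its sample standard deviation
#' (n - 1 denominator); constant rows map to all zeros.
#'
#' @param m Numeric matrix with at least two columns.
#' @return Matrix of the same shape.
#' @export
znormalize <- function(m) {
  if (ncol(m) < 2L) stop("need at least two samples per profile")
  t(apply(m, 1L, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}

#' Hierarchically cluster genomes by their vertical distribution profiles
#'
#' Agglomerative clustering of Z-normalised profile rows (Euclidean
#' distance, complete linkage by default), with rows pre-sorted by genome
#' id so the leaf order is deterministic.  The dendrogram is also returned
#' serialised as Newick.
#'
#' @param z Genome x sample matrix (typically from [znormalize()]).
#' @param method Agglomeration method for [stats::hclust()].
#' @return List: `hclust`, `leaf_order` (genome ids), `newick`.
#' @export
cluster_profiles <- function(z, method = "complete") {
  if (nrow(z) < 2L) stop("need at least two genomes to cluster")
  z <- z[order(rownames(z)), , drop = FALSE]
  hc <- hclust(dist(z, method = "euclidean"), method = method)
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       leaf_order = rownames(z)[hc$order],
       newick = ape::write.tree(phy))
}

#' Per-sample competitive recruitment of simulated or real reads
#'
#' Maps each sample's reads with [map_reads_simple()] (or accepts
#' pre-parsed hits), filters at the standard thresholds and competitively
#' assigns reads.
#'
#' @param reads_by_sample Named list: sample id -> named read vector.
#' @param genomes List of `genome_record`.
#' @param k Seed length for the internal mapper.
#' @param max_evalue,min_identity,min_coverage Filter thresholds.
#' @return Named list of assignment vectors per sample.
#' @export
recruit_samples <- function(reads_by_sample, genomes, k = 21L,
                            max_evalue = 1e-5, min_identity = 95.0,
                            min_coverage = 80.0) {
  lapply(reads_by_sample, function(reads) {
    hits <- map_reads_simple(reads, genomes, k = k)
    hits <- filter_hits(hits, max_evalue, min_identity, min_coverage)
    competitive_assign(hits)
  })
}
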