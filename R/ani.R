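# Fragment-based average nucleotide identity (ANI) and selection of
# "closely related" background genomes at the >95% threshold.
#
# The classic fragment method: each genome is cut into consecutive
# non-overlapping 1020-bp-style windows (1000 bp here), each fragment is
# searched against the partner genome by exact k-mer seeding plus ungapped
# extension on both strands, and ANI is the mean identity over fragments
# with an accepted hit (aligned fraction >= 0.7, identity >= 30%),
# averaged over both directions.

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Windows are taken per contig; a terminal remainder shorter than
#' `fragment_len` is discarded.
#'
#' @param genome A `genome_record`.
#' @param fragment_len Window length in bp (>= 100).
#' @return Character vector of fragment sequences.
#' @export
fragment_genome <- function(genome, fragment_len = 1000L) {
  if (fragment_len < 100L) stop("fragment_len must be >= 100")
  frags <- lapply(genome$contigs, function(s) {
    n_win <- nchar(s) %/% fragment_len
    if (n_win == 0L) return(character(0))
    starts <- (seq_len(n_win) - 1L) * fragment_len + 1L
    substring(s, starts, starts + fragment_len - 1L)
  })
  unlist(frags, use.names = FALSE)
}

#' Best identity of one fragment (or many) against a target genome
#'
#' Candidate loci are located by exact shared k-mers on both strands and
#' extended without gaps over the fragment; the best hit is reported.
#' Hits with aligned fraction < `min_aligned_frac` or identity <
#' `min_identity` are rejected (no-hit, `NA`).
#'
#' @param fragments Character vector of fragment sequences.
#' @param target A `genome_record`.
#' @param k Seed k-mer length.
#' @param min_aligned_frac Minimum fraction of the fragment aligned.
#' @param min_identity Minimum percent identity to accept.
#' @return data.frame with `identity` and `aligned_frac` per fragment
#'   (`NA` for no-hit).
#' @export
best_fragment_identity <- function(fragments, target, k = 15L,
                                   min_aligned_frac = 0.7,
                                   min_identity = 30) {
  best_id <- rep(NA_real_, length(fragments))
  best_fr <- rep(NA_real_, length(fragments))
  for (contig in target$contigs) {
    m <- cpp_seed_extend(fragments, contig, as.integer(k), min_aligned_frac)
    better <- !is.na(m[, "identity"]) &
      (is.na(best_id) | m[, "identity"] > best_id)
    best_id[better] <- m[better, "identity"]
    best_fr[better] <- m[better, "aligned_frac"]
  }
  reject <- !is.na(best_id) & best_id < min_identity
  best_id[reject] <- NA_real_
  best_fr[reject] <- NA_real_
  data.frame(identity = best_id, aligned_frac = best_fr)
}

#' Average nucleotide identity between two genomes
#'
#' Mean best-fragment identity of `genome_a`'s fragments against
#' `genome_b`; by default the symmetric version (mean of both directions)
#' is reported.
#'
#' @param genome_a,genome_b `genome_record` objects.
#' @param fragment_len Fragment window length (bp).
#' @param k Seed k-mer length.
#' @param symmetric Average both directions (default) or use a->b only.
#' @return List of class `ani_result`: `genome_a`, `genome_b`,
#'   `ani_percent` (`NA` when no fragment aligned), `n_fragments_used`,
#'   `coverage_fraction` (fraction of query fragments with an accepted
#'   hit).
#' @export
ani <- function(genome_a, genome_b, fragment_len = 1000L, k = 15L,
                symmetric = TRUE) {
  one_way <- function(qa, qb) {
    frags <- fragment_genome(qa, fragment_len)
    if (!length(frags))
      return(list(mean = NA_real_, used = 0L, total = 0L))
    hits <- best_fragment_identity(frags, qb, k = k)
    ok <- !is.na(hits$identity)
    list(mean = if (any(ok)) mean(hits$identity[ok]) else NA_real_,
         used = sum(ok), total = length(frags))
  }
  ab <- one_way(genome_a, genome_b)
  if (symmetric) {
    ba <- one_way(genome_b, genome_a)
    vals <- c(ab$mean, ba$mean)
    est <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    used <- ab$used + ba$used
    cov <- if (ab$total + ba$total > 0)
      (ab$used + ba$used) / (ab$total + ba$total) else 0
  } else {
    est <- ab$mean
    used <- ab$used
    cov <- if (ab$total > 0) ab$used / ab$total else 0
  }
  structure(list(genome_a = genome_a$genome_id,
                 genome_b = genome_b$genome_id,
                 ani_percent = est, n_fragments_used = used,
                 coverage_fraction = cov), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ANI %s vs %s: %s%% (%d fragments, coverage %.2f)>\n",
              x$genome_a, x$genome_b,
              if (is.na(x$ani_percent)) "no estimate"
              else sprintf("%.2f", x$ani_percent),
              x$n_fragments_used, x$coverage_fraction))
  invisible(x)
}

#' All-pairs ANI table for a set of genomes
#'
#' @param genomes List of `genome_record`.
#' @param ... Passed on to [ani()].
#' @return data.frame: genome_a, genome_b, ani_percent, n_fragments_used,
#'   coverage_fraction, one row per unordered pair.
#' @export
ani_matrix <- function(genomes, ...) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  rows <- list()
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (j <= i) next
      r <- ani(genomes[[i]], genomes[[j]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = ids[i], genome_b = ids[j],
        ani_percent = r$ani_percent,
        n_fragments_used = r$n_fragments_used,
        coverage_fraction = r$coverage_fraction,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select background genomes closely related to the focal set
#'
#' A background genome is selected iff its ANI to at least one focal
#' genome is strictly greater than `threshold` (the same-species style
#' >95% rule used to pick reference relatives).
#'
#' @param ani_table data.frame as from [ani_matrix()] covering every
#'   focal x background pair.
#' @param focal_ids,background_ids Genome id vectors.
#' @param threshold ANI threshold in percent (strict >).
#' @return Character vector of selected background ids.
#' @export
select_close_relatives <- function(ani_table, focal_ids, background_ids,
                                   threshold = 95.0) {
  if (!length(background_ids)) return(character(0))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(ani_table$genome_a, ani_table$genome_b)
  sel <- character(0)
  for (b in background_ids) {
    vals <- numeric(0)
    for (f in focal_ids) {
      i <- match(key(f, b), have)
      if (is.na(i)) stop("missing ANI pair: ", f, " vs ", b)
      vals <- c(vals, ani_table$ani_percent[i])
    }
    if (any(!is.na(vals) & vals > threshold)) sel <- c(sel, b)
  }
  sel
}
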