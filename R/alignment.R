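# Global protein alignment (Needleman-Wunsch with affine gaps, BLOSUM62,
# gap open 11 / extend 1 — common protein-search defaults).  The dynamic
# programme runs in compiled code; these wrappers batch pairs.

#' Batch global protein alignment
#'
#' @param a,b Equal-length character vectors; pair `i` aligns `a[i]` to
#'   `b[i]`.
#' @param gap_open,gap_ext Affine gap penalties (a gap of length L costs
#'   `gap_open + gap_ext * L`).
#' @return data.frame: score, identity (percent of alignment columns,
#'   gaps included, that are identical residue pairs), ncols, nmatch,
#'   nboth (columns aligning residue to residue).
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_ext = 1) {
  if (length(a) != length(b)) stop("a and b must pair up")
  if (!length(a))
    return(data.frame(score = numeric(0), identity = numeric(0),
                      ncols = numeric(0), nmatch = numeric(0),
                      nboth = numeric(0)))
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty protein sequence")
  sub <- blosum62()
  m <- cpp_nw_batch(a, b, sub, rownames(sub), gap_open, gap_ext)
  as.data.frame(m)
}

#' Global percent identity between two proteins
#'
#' Identity is `matches / alignment columns` with gap columns included in
#' the denominator.
#'
#' @param protein_a,protein_b Amino-acid sequences.
#' @param gap_open,gap_ext Affine gap penalties.
#' @return List with `identity` (percent) and `score`.
#' @export
global_protein_identity <- function(protein_a, protein_b,
                                    gap_open = 11, gap_ext = 1) {
  r <- align_proteins(protein_a, protein_b, gap_open, gap_ext)
  list(identity = r$identity[1L], score = r$score[1L])
}

#' Score-only global alignment over candidate index pairs
#'
#' Fast path for best-hit searches: computes only the optimal global
#' alignment score (same scoring scheme as [align_proteins()]) for each
#' (query index, subject index) pair, encoding every sequence once.
#'
#' @param qs,ss Query and subject sequence pools.
#' @param pairs Two-column integer matrix of 1-based (query, subject)
#'   indices, e.g. from [shared_kmer_pairs()].
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Numeric vector of scores, one per pair row.
#' @export
score_protein_pairs <- function(qs, ss, pairs, gap_open = 11, gap_ext = 1) {
  if (!nrow(pairs)) return(numeric(0))
  sub <- blosum62()
  cpp_nw_score_pairs(qs, ss, as.integer(pairs[, 1L]),
                     as.integer(pairs[, 2L]), sub, rownames(sub),
                     gap_open, gap_ext)
}

#' Shared k-mer candidate pairs between two protein sets
#'
#' Returns index pairs (i, j) of proteins sharing at least one exact
#' k-mer — the seeding prefilter used before alignment in the RBH and
#' top-hit searches.
#'
#' @param qs,ss Character vectors of protein sequences.
#' @param k Word length.
#' @return Two-column integer matrix of (query index, subject index).
#' @export
shared_kmer_pairs <- function(qs, ss, k = 4L) {
  kmers <- function(seqs) {
    nk <- pmax(0L, nchar(seqs) - k + 1L)
    words <- unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      substring(s, 1:(n - k + 1L), k:n)
    }), use.names = FALSE)
    list(idx = rep(seq_along(seqs), nk), words = words)
  }
  qk <- kmers(qs)
  sk <- kmers(ss)
  vocab <- unique(sk$words)
  scode <- match(sk$words, vocab)
  qcode <- match(qk$words, vocab)
  # group subject indices by word code
  tab <- tabulate(scode, nbins = length(vocab))
  sidx_sorted <- sk$idx[order(scode)]
  starts <- cumsum(c(1L, tab))[seq_along(tab)]
  ok <- !is.na(qcode)
  if (!any(ok))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("query", "subject"))))
  nrep <- tab[qcode[ok]]
  qcol <- rep(qk$idx[ok], nrep)
  scol <- sidx_sorted[sequence(nrep, from = starts[qcode[ok]])]
  key <- (qcol - 1) * length(ss) + scol
  keep <- !duplicated(key)
  ord <- order(key[keep])
  cbind(query = qcol[keep][ord], subject = scol[keep][ord])
}
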