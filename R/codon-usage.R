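# Wright's effective number of codons (ENC), GC3, and the expected
# ENC-GC3 curve under random (mutation-driven) codon usage.
#
# ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk is the mean codon
# homozygosity F-hat over the amino-acid families of degeneracy class k
# (2-fold: 9 families; 3-fold: Ile; 4-fold: 5 families; 6-fold: Leu, Ser,
# Arg, treated as one 6-fold class as CodonW does).  ENC ranges from 20
# (one codon used exclusively per amino acid) to 61 (all synonymous codons
# used equally likely); finite-sample values above 61 are truncated to 61.

#' Degeneracy class of each amino-acid family
#' @noRd
degeneracy_classes <- function() {
  if (is.null(.hadalsig_cache$degeneracy)) {
    fams <- codon_families()
    sizes <- lengths(fams)
    .hadalsig_cache$degeneracy <- sizes[!(names(sizes) %in% c("M", "W"))]
  }
  .hadalsig_cache$degeneracy
}

#' Count synonymous codon usage of a coding sequence
#'
#' Counts codons per amino-acid family, excluding the single-codon families
#' Met and Trp and any stop codon.  A trailing stop codon is stripped;
#' codons containing a non-ACGT base are skipped; an internal stop codon is
#' an error.
#'
#' @param cds Coding sequence, length divisible by 3.
#' @return Object of class `codon_counts`: named list amino acid ->
#'   named integer vector of codon counts.
#' @export
count_codons <- function(cds) {
  codons <- split_codons(toupper(cds))
  tab <- codon_table()
  aa <- unname(tab[codons])
  n <- length(aa)
  if (n > 0L && !is.na(aa[n]) && aa[n] == "*") {
    aa <- aa[-n]; codons <- codons[-n]
  }
  stops <- which(!is.na(aa) & aa == "*")
  if (length(stops)) stop("internal stop codon at codon position ", stops[1L])
  keep <- !is.na(aa) & !(aa %in% c("M", "W"))
  aa <- aa[keep]; codons <- codons[keep]
  fams <- codon_families()
  out <- lapply(names(degeneracy_classes()), function(a) {
    counts <- table(factor(codons[aa == a], levels = fams[[a]]))
    stats::setNames(as.integer(counts), names(counts))
  })
  names(out) <- names(degeneracy_classes())
  structure(out, class = "codon_counts")
}

#' Codon homozygosity F-hat of one synonymous family
#'
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` with `p_i = count_i / n`;
#' undefined (`NA`) when the family was observed fewer than twice or when
#' the estimate is non-positive.
#'
#' @param counts Integer vector of codon counts for one family.
#' @return F-hat, or `NA_real_` when undefined.
#' @export
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  p <- counts / n
  f <- (n * sum(p^2) - 1) / (n - 1)
  if (f <= 0) NA_real_ else f
}

#' Wright's effective number of codons
#'
#' See the file header for the formula and conventions.  If the 3-fold
#' class (Ile) is undefined it is imputed as `(F2 + F4) / 2` (Wright's
#' rule); if any other degeneracy class has no defined family the result
#' is undefined (`NA`).  Raw values above 61 are truncated to 61.
#'
#' @param x A `codon_counts` object (or a CDS string, which is counted
#'   first).
#' @return ENC in \[20, 61\], or `NA_real_` when undefined.
#' @export
enc <- function(x) {
  if (is.character(x)) x <- count_codons(x)
  stopifnot(inherits(x, "codon_counts"))
  deg <- degeneracy_classes()
  fhat <- vapply(x, family_homozygosity, numeric(1))
  fbar <- function(k) {
    v <- fhat[deg == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  f2 <- fbar(2L); f3 <- fbar(3L); f4 <- fbar(4L); f6 <- fbar(6L)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(val, 61)
}

#' GC content of third codon positions
#'
#' Fraction of sense-codon third positions that are G or C; the trailing
#' stop codon is excluded and codons whose third base is not A/C/G/T are
#' skipped.
#'
#' @param cds Coding sequence.
#' @return Fraction in \[0, 1\], or `NA_real_` with zero countable codons.
#' @export
gc3 <- function(cds) {
  codons <- split_codons(toupper(cds))
  tab <- codon_table()
  aa <- unname(tab[codons])
  n <- length(aa)
  if (n > 0L && !is.na(aa[n]) && aa[n] == "*") codons <- codons[-n]
  third <- substr(codons, 3L, 3L)
  third <- third[third %in% c("A", "C", "G", "T")]
  if (!length(third)) return(NA_real_)
  mean(third %in% c("G", "C"))
}

#' Expected ENC under random codon usage at a given GC3
#'
#' The null curve `ENC = 2 + s + 29 / (s^2 + (1 - s)^2)` for GC3 = s:
#' the ENC a gene would show if codon usage were driven by base
#' composition alone.  Genes lying below the curve show selected codon
#' bias.
#'
#' @param s GC3 fraction in \[0, 1\].
#' @return Expected ENC (vectorised over `s`).
#' @export
expected_enc <- function(s) {
  if (any(s < 0 | s > 1)) stop("GC3 must be in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Per-gene ENC/GC3 table with below-curve classification
#'
#' @param cds Named character vector of coding sequences.
#' @param categories Optional named (by gene id) category letters.
#' @return data.frame: gene_id, category, enc, gc3, expected_enc,
#'   below_curve.
#' @export
enc_gc3_table <- function(cds, categories = NULL) {
  enc_v <- vapply(cds, enc, numeric(1), USE.NAMES = FALSE)
  gc3_v <- vapply(cds, gc3, numeric(1), USE.NAMES = FALSE)
  exp_v <- ifelse(is.na(gc3_v), NA_real_, expected_enc(pmin(1, pmax(0, gc3_v))))
  data.frame(
    gene_id = names(cds),
    category = if (is.null(categories)) NA_character_
               else unname(categories[names(cds)]),
    enc = enc_v, gc3 = gc3_v, expected_enc = exp_v,
    below_curve = !is.na(enc_v) & !is.na(exp_v) & enc_v < exp_v,
    stringsAsFactors = FALSE)
}

#' Compare codon usage of a unique-gene set against the full gene set
#'
#' Per-category mean ENC for the focal-unique genes and for all genes,
#' plus the below-curve fraction of each set; genes with undefined ENC are
#' excluded from means and counted.
#'
#' @param tab An [enc_gc3_table()] for all genes.
#' @param unique_gene_ids Gene ids of the focal-unique set.
#' @return List with `per_category` (data.frame: category,
#'   mean_enc_unique, n_unique, mean_enc_all, n_all), `below_curve_fraction`
#'   (named: unique, all) and `n_undefined` (named: unique, all).
#' @export
enc_comparison <- function(tab, unique_gene_ids) {
  if (!nrow(tab)) stop("empty gene table")
  uniq <- tab[tab$gene_id %in% unique_gene_ids, ]
  if (!nrow(uniq)) stop("unique gene set is empty")
  summarise <- function(d) {
    ok <- !is.na(d$enc) & !is.na(d$category)
    agg <- if (any(ok))
      stats::aggregate(enc ~ category, data = d[ok, ], FUN = mean)
    else data.frame(category = character(0), enc = numeric(0))
    cnt <- table(d$category[ok])
    list(agg = agg, cnt = cnt,
         below = mean(d$below_curve[!is.na(d$enc)]),
         undef = sum(is.na(d$enc)))
  }
  su <- summarise(uniq); sa <- summarise(tab)
  cats <- sort(union(su$agg$category, sa$agg$category))
  per_cat <- data.frame(
    category = cats,
    mean_enc_unique = su$agg$enc[match(cats, su$agg$category)],
    n_unique = as.integer(su$cnt[cats]),
    mean_enc_all = sa$agg$enc[match(cats, sa$agg$category)],
    n_all = as.integer(sa$cnt[cats]),
    stringsAsFactors = FALSE)
  per_cat$n_unique[is.na(per_cat$n_unique)] <- 0L
  per_cat$n_all[is.na(per_cat$n_all)] <- 0L
  list(per_category = per_cat,
       below_curve_fraction = c(unique = su$below, all = sa$below),
       n_undefined = c(unique = su$undef, all = sa$undef))
}
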