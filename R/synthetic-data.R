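# Seeded generator for a synthetic clade of focal ("hadal SAG") and
# background ("surface relative") genomes, plus depth-structured
# metagenomic reads, with full ground truth.  Evolution is
# substitution-only (no indels or rearrangements) so that nucleotide and
# amino-acid divergence oracles are exact Hamming counts.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

#' Synonymous codon families of the standard genetic code
#'
#' @return Named list: amino acid -> character vector of its codons
#'   (stop codons excluded).
#' @export
codon_families <- function() {
  if (is.null(.hadalsig_cache$codon_families)) {
    tab <- codon_table()
    sense <- tab[tab != "*"]
    .hadalsig_cache$codon_families <- split(names(sense), unname(sense))
  }
  .hadalsig_cache$codon_families
}

#' Per-family codon weights used by the biased back-translator
#'
#' Zipf-like weights over each amino acid's synonymous codons.  Codons are
#' ranked GC-ending first (then alphabetically) and codon rank r gets
#' weight r^(-6 * strength), so strength 0 is uniform synonymous usage and
#' strength near 1 concentrates usage on one (GC-ending) codon per family,
#' driving ENC down and GC3 up the way translational selection does.
#'
#' @param strength Codon bias strength in \[0, 1\].
#' @return Named list: amino acid -> named numeric weight vector.
#' @export
codon_bias_weights <- function(strength) {
  stopifnot(strength >= 0, strength <= 1)
  fams <- codon_families()
  lapply(fams, function(cods) {
    gc_end <- substr(cods, 3L, 3L) %in% c("G", "C")
    ord <- order(!gc_end, cods)
    cods <- cods[ord]
    w <- (seq_along(cods))^(-6 * strength)
    stats::setNames(w / sum(w), cods)
  })
}

#' Back-translate proteins with biased synonymous codon usage
#'
#' Vectorised over genes: synonymous codons for all occurrences of each
#' amino acid across all proteins are drawn in one call.
#' @noRd
biased_backtranslate <- function(proteins, strength) {
  wts <- codon_bias_weights(strength)
  aas <- strsplit(proteins, "", fixed = TRUE)
  lens <- lengths(aas)
  flat <- unlist(aas, use.names = FALSE)
  codons <- character(length(flat))
  for (a in unique(flat)) {
    w <- wts[[a]]
    if (is.null(w)) stop("cannot back-translate residue: ", a)
    idx <- which(flat == a)
    codons[idx] <- if (length(w) == 1L) names(w) else
      sample(names(w), length(idx), replace = TRUE, prob = w)
  }
  ends <- cumsum(lens)
  vapply(seq_along(proteins), function(i)
    paste(codons[(ends[i] - lens[i] + 1L):ends[i]], collapse = ""),
    character(1))
}

#' Single-nucleotide neighbours of a codon, split by effect
#' @noRd
codon_neighbours <- function() {
  if (!is.null(.hadalsig_cache$codon_neighbours))
    return(.hadalsig_cache$codon_neighbours)
  tab <- codon_table()
  bases <- c("A", "C", "G", "T")
  res <- lapply(names(tab), function(cod) {
    aa <- tab[[cod]]
    syn <- character(0); nonsyn <- character(0)
    for (p in 1:3) for (b in bases) {
      if (b == substr(cod, p, p)) next
      alt <- cod
      substr(alt, p, p) <- b
      alt_aa <- tab[[alt]]
      if (alt_aa == "*") next
      if (alt_aa == aa) syn <- c(syn, alt) else nonsyn <- c(nonsyn, alt)
    }
    list(syn = syn, nonsyn = nonsyn)
  })
  names(res) <- names(tab)
  .hadalsig_cache$codon_neighbours <- res
  .hadalsig_cache$nb_nonsyn_n <- vapply(res, function(x)
    length(x$nonsyn), integer(1))
  .hadalsig_cache$nb_syn_n <- vapply(res, function(x)
    length(x$syn), integer(1))
  res
}

#' Draw one random element from each list entry (vectorised)
#' @noRd
pick_one <- function(lst) {
  n <- lengths(lst)
  ri <- ceiling(runif(length(lst)) * n)
  unlist(Map(`[`, lst, ri), use.names = FALSE)
}

#' Mutate a coding sequence to a target amino-acid divergence
#'
#' Applies single-nucleotide nonsynonymous substitutions at
#' `round(target_aa_divergence * L)` distinct codon positions (L = protein
#' length) so the realised protein Hamming divergence is within one residue
#' of the target count, plus independent single-nucleotide synonymous
#' substitutions at rate `syn_rate` per remaining codon.  Never creates an
#' internal stop codon; a trailing stop codon, if present, is preserved
#' unchanged.  Uses the current R RNG stream (seed with [set.seed()]).
#'
#' @param cds Coding sequence (with or without trailing stop codon).
#' @param target_aa_divergence Fraction in \[0, 0.5\].
#' @param syn_rate Per-codon probability of a synonymous substitution at
#'   codon positions not already mutated nonsynonymously.
#' @return Mutated CDS of identical length.
#' @export
mutate_gene <- function(cds, target_aa_divergence, syn_rate = 0) {
  if (target_aa_divergence < 0 || target_aa_divergence > 0.5)
    stop("target_aa_divergence must be in [0, 0.5]")
  codons <- split_codons(toupper(cds))
  tab <- codon_table()
  has_stop <- length(codons) > 0L && tab[[codons[length(codons)]]] == "*"
  n_sense <- length(codons) - as.integer(has_stop)
  n_target <- round(target_aa_divergence * n_sense)
  mutate_gene_counts(cds, n_nonsyn = n_target,
                     n_syn = if (n_sense > n_target)
                       rbinom(1L, n_sense - n_target, min(1, syn_rate))
                     else 0L)$cds
}

#' Mutate with exact nonsynonymous / synonymous substitution counts
#'
#' Deterministic-count workhorse behind [mutate_gene()]: `n_nonsyn` codon
#' positions receive one nonsynonymous single-nucleotide change each and
#' `n_syn` further positions one synonymous change each, all at distinct
#' codons, so nucleotide Hamming distance is exactly `n_nonsyn + n_syn`
#' (synonymous capacity permitting) and protein Hamming distance exactly
#' `n_nonsyn`.
#'
#' @param cds Coding sequence.
#' @param n_nonsyn Number of nonsynonymous substitutions.
#' @param n_syn Number of synonymous substitutions requested.
#' @return List with `cds` (mutated sequence), `n_nonsyn`, `n_syn`
#'   (realised counts).
#' @export
mutate_gene_counts <- function(cds, n_nonsyn, n_syn = 0L) {
  codons <- split_codons(toupper(cds))
  tab <- codon_table()
  nb <- codon_neighbours()
  n <- length(codons)
  has_stop <- n > 0L && tab[[codons[n]]] == "*"
  sense_idx <- seq_len(n - as.integer(has_stop))
  # keep an initial ATG fixed, as a start codon would be
  if (length(sense_idx) && codons[1L] == "ATG") sense_idx <- sense_idx[-1L]
  nbn <- .hadalsig_cache$nb_nonsyn_n
  nbs <- .hadalsig_cache$nb_syn_n
  eligible_ns <- sense_idx[nbn[codons[sense_idx]] > 0L]
  if (n_nonsyn > length(eligible_ns))
    stop("requested ", n_nonsyn, " nonsynonymous changes but only ",
         length(eligible_ns), " mutable codons")
  ns_pos <- if (n_nonsyn > 0L) sample(eligible_ns, n_nonsyn) else integer(0)
  if (length(ns_pos))
    codons[ns_pos] <- pick_one(lapply(nb[codons[ns_pos]], `[[`, "nonsyn"))
  syn_pool <- setdiff(sense_idx, ns_pos)
  syn_pool <- syn_pool[nbs[codons[syn_pool]] > 0L]
  n_syn_real <- min(n_syn, length(syn_pool))
  syn_pos <- if (n_syn_real > 0L) sample(syn_pool, n_syn_real) else integer(0)
  if (length(syn_pos))
    codons[syn_pos] <- pick_one(lapply(nb[codons[syn_pos]], `[[`, "syn"))
  list(cds = paste(codons, collapse = ""),
       n_nonsyn = length(ns_pos), n_syn = n_syn_real)
}

#' Configuration for the synthetic clade generator
#'
#' Collects and validates every tunable of [simulate_clade()].  Defaults
#' describe a small but realistic study clade: a handful of focal SAGs and
#' background relatives at ~95% ANI to a common ancestor, a few hundred
#' shared single-copy gene families, focal-private gene content enriched in
#' mobilome (X) and envelope-biogenesis (M) categories, and moderate codon
#' bias in the core.
#'
#' @param n_focal,n_background Number of focal / background genomes.
#' @param n_core_genes Shared single-copy gene families in the clade core.
#' @param gene_length_codons Length range (codons, excluding start/stop)
#'   genes are drawn from.
#' @param ani_targets Per-genome nucleotide divergence fraction from the
#'   clade ancestor (focal genomes first, then background).  Scalar values
#'   are recycled.  Must lie in \[0, 0.35\].
#' @param unique_genes_per_focal Focal-private genes planted per focal
#'   genome (absent from every other genome).
#' @param unique_category_weights Named sampling weights over one-letter
#'   categories for the planted unique genes.
#' @param core_category_weights Named sampling weights for core-gene
#'   categories (default: uniform over 18 common categories).
#' @param divergence_class_by_category Named multipliers applied to a
#'   genome's base amino-acid divergence for genes of that category
#'   (unlisted categories get 1).
#' @param aa_divergence_base Per-genome base amino-acid divergence
#'   fraction; default `NULL` uses each genome's `ani_target`.
#' @param codon_bias_strength Core-gene codon bias in \[0, 1\]
#'   (see [codon_bias_weights()]).
#' @param unique_codon_bias_strength Bias for planted unique genes
#'   (default: same as core).
#' @param annotated_fraction Fraction of gene families carrying a category
#'   annotation (the rest are unannotated, as in real COG tables).
#' @param spacer_length_bp Intergenic spacer length.
#' @param sample_depths Water-column depths (m) of the simulated
#'   metagenome samples.
#' @param focal_depth_gain Log-abundance slope with depth: focal genomes
#'   increase, background genomes decrease at this rate.
#' @param abundance_noise_sd Lognormal noise sd on abundances.
#' @param seed Integer seed; required, the whole simulation is
#'   deterministic given it.
#' @return A validated list of class `clade_config`.
#' @export
clade_config <- function(n_focal = 3L, n_background = 3L,
                         n_core_genes = 120L,
                         gene_length_codons = c(80L, 250L),
                         ani_targets = 0.02,
                         unique_genes_per_focal = 12L,
                         unique_category_weights = c(X = 3, M = 2, K = 2,
                                                     P = 1, L = 1, R = 1,
                                                     S = 1),
                         core_category_weights = NULL,
                         divergence_class_by_category = NULL,
                         aa_divergence_base = NULL,
                         codon_bias_strength = 0.5,
                         unique_codon_bias_strength = NULL,
                         annotated_fraction = 0.7,
                         spacer_length_bp = 150L,
                         sample_depths = c(0, 2000, 4000, 6000, 9000),
                         focal_depth_gain = 1.5,
                         abundance_noise_sd = 0.3,
                         seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("clade_config requires an integer seed")
  # accept YAML-style nested lists for vector-valued fields
  gene_length_codons <- as.integer(unlist(gene_length_codons))
  ani_targets <- as.numeric(unlist(ani_targets))
  sample_depths <- as.numeric(unlist(sample_depths))
  unique_category_weights <- unlist(unique_category_weights)
  if (!is.null(core_category_weights))
    core_category_weights <- unlist(core_category_weights)
  if (!is.null(divergence_class_by_category))
    divergence_class_by_category <- unlist(divergence_class_by_category)
  n_genomes <- n_focal + n_background
  if (length(ani_targets) == 1L) ani_targets <- rep(ani_targets, n_genomes)
  if (length(ani_targets) != n_genomes)
    stop("ani_targets must have length n_focal + n_background (or 1)")
  if (any(ani_targets < 0 | ani_targets > 0.35))
    stop("infeasible divergence: ani_targets must lie in [0, 0.35]")
  if (is.null(core_category_weights)) {
    core_category_weights <- stats::setNames(
      rep(1, 18), c("C","E","G","H","I","J","K","L","M","N","O","P","Q",
                    "R","S","T","U","V"))
  }
  if (is.null(divergence_class_by_category))
    divergence_class_by_category <- numeric(0)
  if (any(unique_category_weights < 0) || !any(unique_category_weights > 0))
    stop("unique_category_weights must be nonnegative with one positive")
  if (length(divergence_class_by_category)) {
    base <- if (is.null(aa_divergence_base)) max(ani_targets)
            else max(aa_divergence_base)
    if (max(divergence_class_by_category) * base > 0.5)
      stop("divergence multipliers push amino-acid divergence above 0.5")
  }
  if (is.null(unique_codon_bias_strength))
    unique_codon_bias_strength <- codon_bias_strength
  structure(list(
    n_focal = as.integer(n_focal), n_background = as.integer(n_background),
    n_core_genes = as.integer(n_core_genes),
    gene_length_codons = as.integer(gene_length_codons),
    ani_targets = ani_targets,
    unique_genes_per_focal = as.integer(unique_genes_per_focal),
    unique_category_weights = unique_category_weights,
    core_category_weights = core_category_weights,
    divergence_class_by_category = divergence_class_by_category,
    aa_divergence_base = aa_divergence_base,
    codon_bias_strength = codon_bias_strength,
    unique_codon_bias_strength = unique_codon_bias_strength,
    annotated_fraction = annotated_fraction,
    spacer_length_bp = as.integer(spacer_length_bp),
    sample_depths = sample_depths,
    focal_depth_gain = focal_depth_gain,
    abundance_noise_sd = abundance_noise_sd,
    seed = as.integer(seed)), class = "clade_config")
}

#' @noRd
random_protein <- function(n_codons) {
  paste0("M", paste(sample(AA20, n_codons - 1L, replace = TRUE),
                    collapse = ""))
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a clade of focal and background genomes with ground truth
#'
#' Builds a clade ancestor from `n_core_genes` protein-coding genes
#' (back-translated with the configured codon bias), then derives each
#' genome by codon-aware point substitutions: nonsynonymous changes sized
#' by the genome's base amino-acid divergence times its category's
#' multiplier, synonymous changes and intergenic substitutions topped up so
#' the genome's realised nucleotide divergence from the ancestor lands on
#' its `ani_target`.  Focal genomes additionally receive private genes
#' drawn with `unique_category_weights`.  Entirely deterministic given
#' `config$seed`.
#'
#' @param config A [clade_config()].
#' @return Object of class `hadal_clade`: list with `genomes` (list of
#'   `genome_record`), `genes` (gene table with cds/protein/category),
#'   `annotations`, `samples`, and `truth` (family map, unique gene ids,
#'   planted per-gene amino-acid divergence, realised per-genome nucleotide
#'   divergence, genome x sample abundance matrix, ancestor sequences).
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "clade_config"))
  set.seed(config$seed)
  cf <- config
  n_genomes <- cf$n_focal + cf$n_background
  genome_ids <- c(sprintf("F%02d", seq_len(cf$n_focal)),
                  sprintf("B%02d", seq_len(cf$n_background)))
  roles <- rep(c("focal", "background"), c(cf$n_focal, cf$n_background))

  # --- ancestor ---
  fam_ids <- sprintf("fam%04d", seq_len(cf$n_core_genes))
  lens <- sample(seq(cf$gene_length_codons[1], cf$gene_length_codons[2]),
                 cf$n_core_genes, replace = TRUE)
  ccat <- cf$core_category_weights
  fam_category <- sample(names(ccat), cf$n_core_genes, replace = TRUE,
                         prob = ccat)
  fam_annotated <- runif(cf$n_core_genes) < cf$annotated_fraction
  fam_strand <- sample(c("+", "-"), cf$n_core_genes, replace = TRUE,
                       prob = c(0.6, 0.4))
  anc_protein <- vapply(lens, random_protein, character(1))
  anc_cds <- paste0(biased_backtranslate(anc_protein,
                                         cf$codon_bias_strength), "TAA")
  anc_spacers <- vapply(rep(cf$spacer_length_bp, cf$n_core_genes + 1L),
                        random_dna, character(1))

  mults <- cf$divergence_class_by_category
  mult_of <- function(cat) {
    if (!is.na(cat) && cat %in% names(mults)) mults[[cat]] else 1
  }

  genomes <- vector("list", n_genomes)
  gene_rows <- list()
  div_rows <- list()
  nt_div <- numeric(n_genomes)

  for (gi in seq_len(n_genomes)) {
    gid <- genome_ids[gi]
    d <- cf$ani_targets[gi]
    aa_base <- if (is.null(cf$aa_divergence_base)) d else
      rep(cf$aa_divergence_base, n_genomes)[gi]
    cds_g <- character(cf$n_core_genes)
    aa_div_g <- numeric(cf$n_core_genes)
    subs_in_genes <- 0L
    for (fi in seq_len(cf$n_core_genes)) {
      L <- lens[fi]
      target_aa <- min(0.5, aa_base * mult_of(fam_category[fi]))
      n_nonsyn <- round(target_aa * L)
      gene_nt_target <- round(d * 3 * (L + 2L))
      n_syn <- max(0L, gene_nt_target - n_nonsyn)
      mut <- mutate_gene_counts(anc_cds[fi], n_nonsyn, n_syn)
      cds_g[fi] <- mut$cds
      aa_div_g[fi] <- mut$n_nonsyn / L
      subs_in_genes <- subs_in_genes + mut$n_nonsyn + mut$n_syn
    }
    div_rows[[gi]] <- data.frame(
      genome_id = gid, gene_id = paste0(gid, "_", fam_ids),
      family = fam_ids, category = fam_category,
      aa_divergence = aa_div_g, n_codons = lens,
      stringsAsFactors = FALSE)
    # top up / trim substitutions in the intergenic spacers so the
    # genome-wide realised divergence hits the ani_target
    gene_bp <- sum(nchar(cds_g))
    spacer_bp <- sum(nchar(anc_spacers))
    total_target <- round(d * (gene_bp + spacer_bp))
    remainder <- max(0L, total_target - subs_in_genes)
    spacers_g <- anc_spacers
    if (remainder > 0L) {
      pos <- sample(spacer_bp, min(remainder, spacer_bp))
      flat <- strsplit(paste(spacers_g, collapse = ""), "", fixed = TRUE)[[1L]]
      for (p in pos) {
        flat[p] <- sample(setdiff(c("A", "C", "G", "T"), flat[p]), 1L)
      }
      flat <- paste(flat, collapse = "")
      starts <- cumsum(c(1L, nchar(anc_spacers)))
      spacers_g <- substring(flat, starts[-length(starts)],
                             starts[-1L] - 1L)
    }
    # focal-private genes
    n_uniq <- if (roles[gi] == "focal") cf$unique_genes_per_focal else 0L
    uniq_cds <- character(n_uniq); uniq_len <- integer(n_uniq)
    uniq_cat <- character(n_uniq)
    if (n_uniq > 0L) {
      uw <- cf$unique_category_weights
      uniq_cat <- sample(names(uw), n_uniq, replace = TRUE, prob = uw)
      uniq_len <- sample(seq(cf$gene_length_codons[1],
                             cf$gene_length_codons[2]), n_uniq,
                         replace = TRUE)
      uniq_cds <- paste0(biased_backtranslate(
        vapply(uniq_len, random_protein, character(1)),
        cf$unique_codon_bias_strength), "TAA")
    }
    uniq_spacers <- vapply(rep(cf$spacer_length_bp, n_uniq), random_dna,
                           character(1))
    uniq_strand <- if (n_uniq > 0L)
      sample(c("+", "-"), n_uniq, replace = TRUE) else character(0)

    # assemble the single contig: spacer-gene interleave, then private genes
    contig_id <- paste0(gid, "_c1")
    placed <- cds_g
    if (any(fam_strand == "-"))
      placed[fam_strand == "-"] <- revcomp(cds_g[fam_strand == "-"])
    core_parts <- c(rbind(spacers_g[seq_len(cf$n_core_genes)], placed))
    core_parts <- c(core_parts, spacers_g[cf$n_core_genes + 1L])
    placed_u <- uniq_cds
    if (n_uniq > 0L && any(uniq_strand == "-"))
      placed_u[uniq_strand == "-"] <- revcomp(uniq_cds[uniq_strand == "-"])
    parts <- c(core_parts,
               if (n_uniq > 0L) c(rbind(placed_u, uniq_spacers)))
    ends <- cumsum(nchar(parts))
    starts <- ends - nchar(parts) + 1L
    core_gene_part <- 2L * seq_len(cf$n_core_genes)  # genes sit after spacers
    uniq_gene_part <- if (n_uniq > 0L)
      length(core_parts) + 2L * seq_len(n_uniq) - 1L else integer(0)
    gene_rows[[gi]] <- data.frame(
      gene_id = c(paste0(gid, "_", fam_ids),
                  if (n_uniq > 0L) sprintf("%s_u%03d", gid, seq_len(n_uniq))),
      genome_id = gid, contig_id = contig_id,
      start = c(starts[core_gene_part], starts[uniq_gene_part]),
      end = c(ends[core_gene_part], ends[uniq_gene_part]),
      strand = c(fam_strand, uniq_strand),
      category = c(ifelse(fam_annotated, fam_category, NA_character_),
                   if (n_uniq > 0L)
                     ifelse(runif(n_uniq) < cf$annotated_fraction,
                            uniq_cat, NA_character_)),
      cds = c(cds_g, uniq_cds),
      stringsAsFactors = FALSE)
    contig <- paste(parts, collapse = "")
    genomes[[gi]] <- genome_record(gid, stats::setNames(contig, contig_id),
                                   role = roles[gi])
    # realised divergence over the ancestral (core) span
    anc_placed <- anc_cds
    if (any(fam_strand == "-"))
      anc_placed[fam_strand == "-"] <- revcomp(anc_cds[fam_strand == "-"])
    anc_core <- paste(c(c(rbind(anc_spacers[seq_len(cf$n_core_genes)],
                                anc_placed)),
                        anc_spacers[cf$n_core_genes + 1L]), collapse = "")
    core_span <- substr(contig, 1L, nchar(anc_core))
    nt_div[gi] <- hamming(core_span, anc_core) / nchar(anc_core)
  }

  genes <- do.call(rbind, gene_rows)
  genes$protein <- translate_batch(genes$cds)
  div_tab <- do.call(rbind, div_rows)

  family_of_gene <- stats::setNames(
    ifelse(grepl("_u\\d+$", genes$gene_id),
           paste0("uniq_", genes$gene_id),
           sub("^[FB]\\d+_", "", genes$gene_id)),
    genes$gene_id)
  unique_gene_ids <- genes$gene_id[grepl("_u\\d+$", genes$gene_id)]

  abundance <- simulate_abundance(genome_ids, roles, cf$sample_depths,
                                  cf$focal_depth_gain, cf$abundance_noise_sd)
  samples <- data.frame(
    sample_id = colnames(abundance),
    depth_m = cf$sample_depths,
    size_fraction = "free_living",
    metagenome_size_bp = 2e9,
    stringsAsFactors = FALSE)

  structure(list(
    genomes = stats::setNames(genomes, genome_ids),
    genes = genes,
    annotations = data.frame(gene_id = genes$gene_id,
                             category = genes$category,
                             stringsAsFactors = FALSE),
    samples = samples,
    truth = list(family_of_gene = family_of_gene,
                 unique_gene_ids = unique_gene_ids,
                 planted_divergence = div_tab,
                 nt_divergence = stats::setNames(nt_div, genome_ids),
                 abundance = abundance,
                 ancestor = list(cds = stats::setNames(anc_cds, fam_ids),
                                 protein = stats::setNames(anc_protein,
                                                           fam_ids))),
    config = cf), class = "hadal_clade")
}

#' @export
print.hadal_clade <- function(x, ...) {
  cat(sprintf(paste0("<synthetic clade: %d focal + %d background genomes, ",
                     "%d genes (%d focal-private), %d samples>\n"),
              x$config$n_focal, x$config$n_background, nrow(x$genes),
              length(x$truth$unique_gene_ids), nrow(x$samples)))
  invisible(x)
}

#' Hamming distance between equal-length strings
#' @param a,b Strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  sum(charToRaw(a) != charToRaw(b))
}

#' Depth-structured relative abundances
#'
#' Log-linear abundance model: focal genomes gain, background genomes lose
#' `depth_gain` log-units across the depth range, with lognormal noise;
#' each sample column is normalised to sum to one.
#'
#' @param genome_ids,roles Genome ids and their focal/background roles.
#' @param depths Sample depths (m).
#' @param depth_gain Log-slope magnitude.
#' @param noise_sd Lognormal noise sd.
#' @return Matrix genomes x samples, columns summing to 1.
#' @export
simulate_abundance <- function(genome_ids, roles, depths,
                               depth_gain = 1.5, noise_sd = 0.3) {
  z <- (depths - mean(range(depths))) / (diff(range(depths)) / 2)
  slope <- ifelse(roles == "focal", depth_gain, -depth_gain)
  w <- exp(outer(slope, z) + rnorm(length(genome_ids) * length(depths),
                                   sd = noise_sd))
  ab <- sweep(w, 2, colSums(w), "/")
  dimnames(ab) <- list(genome_ids, sprintf("S%02d_%dm", seq_along(depths),
                                           round(depths)))
  ab
}

#' Simulate metagenomic reads from a community of genomes
#'
#' Reads are drawn genome-proportionally to `abundance * genome length`
#' (length-weighted, so RPKG — which divides by genome length — recovers the
#' configured relative abundances), with uniform start positions, random
#' strand, and independent per-base substitution errors.
#'
#' @param genomes List of `genome_record`.
#' @param abundance Named relative abundances over the genomes (sums to 1).
#' @param n_reads Number of reads (> 0).
#' @param read_length_bp Read length; no contig may be shorter.
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional integer seed (set for standalone determinism).
#' @return List with `reads` (named character vector) and `origins`
#'   (data.frame read_id, genome_id, contig_id, start, strand).
#' @export
simulate_reads <- function(genomes, abundance, n_reads,
                           read_length_bp = 150L, error_rate = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_reads <= 0L) stop("n_reads must be positive")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  names(genomes) <- ids
  abundance <- abundance[ids]
  if (abs(sum(abundance) - 1) > 1e-6)
    stop("abundances must sum to 1")
  lens <- vapply(genomes, `[[`, 0, "genome_length_bp")
  min_contig <- min(unlist(lapply(genomes, function(g) nchar(g$contigs))))
  if (read_length_bp > min_contig)
    stop("read_length_bp exceeds the shortest contig")
  p <- abundance * lens
  p <- p / sum(p)
  origin_genome <- sample(ids, n_reads, replace = TRUE, prob = p)
  read_ids <- sprintf("read%06d", seq_len(n_reads))
  reads <- character(n_reads)
  contig_ids <- character(n_reads)
  starts <- integer(n_reads)
  strands <- character(n_reads)
  for (gid in ids) {
    sel <- which(origin_genome == gid)
    if (!length(sel)) next
    g <- genomes[[gid]]
    clens <- nchar(g$contigs)
    cidx <- sample.int(length(clens), length(sel), replace = TRUE,
                       prob = clens)
    st <- floor(runif(length(sel)) * (clens[cidx] - read_length_bp + 1)) + 1L
    sq <- substring(g$contigs[cidx], st, st + read_length_bp - 1L)
    rs <- sample(c("+", "-"), length(sel), replace = TRUE)
    sq[rs == "-"] <- revcomp(sq[rs == "-"])
    reads[sel] <- sq
    contig_ids[sel] <- names(g$contigs)[cidx]
    starts[sel] <- st
    strands[sel] <- rs
  }
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_length_bp, error_rate)
    for (i in which(n_err > 0L)) {
      r <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      pos <- sample.int(read_length_bp, n_err[i])
      for (p2 in pos)
        r[p2] <- sample(setdiff(c("A", "C", "G", "T"), r[p2]), 1L)
      reads[i] <- paste(r, collapse = "")
    }
  }
  list(reads = stats::setNames(reads, read_ids),
       origins = data.frame(read_id = read_ids, genome_id = origin_genome,
                            contig_id = contig_ids, start = starts,
                            strand = strands, stringsAsFactors = FALSE))
}

#' Write a simulated clade to disk as plain-text pipeline inputs
#'
#' Writes per-genome FASTA, CDS and protein FASTA, the gene table TSV, the
#' annotation TSV, sample metadata TSV and ground-truth TSVs under `dir`.
#'
#' @param clade A `hadal_clade` from [simulate_clade()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contigs <- unlist(lapply(clade$genomes, `[[`, "contigs"))
  names(contigs) <- unlist(lapply(clade$genomes, function(g)
    names(g$contigs)))
  write_fasta(contigs, file.path(dir, "genomes.fna"))
  write_fasta(stats::setNames(clade$genes$cds, clade$genes$gene_id),
              file.path(dir, "cds.fna"))
  write_fasta(stats::setNames(clade$genes$protein, clade$genes$gene_id),
              file.path(dir, "proteins.faa"))
  write_tsv(clade$genes[, c("gene_id", "genome_id", "contig_id", "start",
                            "end", "strand", "category")],
            file.path(dir, "genes.tsv"))
  write_tsv(clade$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(clade$samples, file.path(dir, "samples.tsv"))
  write_tsv(data.frame(gene_id = names(clade$truth$family_of_gene),
                       family = unname(clade$truth$family_of_gene),
                       unique = names(clade$truth$family_of_gene) %in%
                         clade$truth$unique_gene_ids),
            file.path(dir, "truth_families.tsv"))
  write_tsv(clade$truth$planted_divergence,
            file.path(dir, "truth_divergence.tsv"))
  ab <- data.frame(genome_id = rownames(clade$truth$abundance),
                   clade$truth$abundance, check.names = FALSE)
  write_tsv(ab, file.path(dir, "truth_abundance.tsv"))
  invisible(dir)
}
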