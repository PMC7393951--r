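# Domain types and format I/O shared by every pipeline stage.
#
# Genomes, genes and samples are held in plain data structures:
#   * genome: list(genome_id, contigs = named character vector,
#              role = "focal"/"background", genome_length_bp)
#   * gene table: data.frame(gene_id, genome_id, contig_id, start, end,
#              strand, cds, protein, category)
#   * sample metadata: data.frame(sample_id, depth_m, size_fraction,
#              metagenome_size_bp)
# Coordinates are 1-based inclusive on the forward strand; strand "-" means
# the CDS is the reverse complement of the contig slice.

#' The fixed one-letter functional category vocabulary
#'
#' The 26 single-letter COG functional categories (A-Z) used for gene and
#' gene-cluster annotation throughout the package (e.g. M = cell
#' wall/membrane/envelope biogenesis, X = mobilome: prophages, transposons).
#'
#' @return Character vector of the 26 category letters.
#' @export
cog_categories <- function() LETTERS

#' Read a FASTA file
#'
#' Thin wrapper around Biostrings FASTA parsing with the package's
#' conventions: record order preserved, sequences uppercased, and (for
#' nucleotide mode) U mapped to T.  Duplicate or empty record ids are
#' errors.
#'
#' @param path Path to a FASTA file.
#' @param type `"nucleotide"` (default; U is mapped to T) or `"protein"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- names(set)
  # Biostrings keeps the full header; the id is the first whitespace token
  ids <- sub("\\s.*$", "", ids)
  if (length(ids) && any(!nzchar(ids)))
    stop("FASTA format error: empty id line in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  if (type == "nucleotide") seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' @noRd
codon_table <- function() {
  if (is.null(.hadalsig_cache$codon_table)) {
    gc <- Biostrings::GENETIC_CODE  # standard code, names are DNA codons
    .hadalsig_cache$codon_table <- gc
  }
  .hadalsig_cache$codon_table
}

#' Split a CDS string into codons
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") not divisible by 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Standard bacterial/plastid-style translation of a CDS: ATG and every
#' other sense codon translate by the standard genetic code, a trailing stop
#' codon is stripped, and codons containing any non-ACGT base translate to
#' `X`.  An internal stop codon is an error (the simulator never produces
#' one and real gene calls should not contain one).
#'
#' @param cds Nucleotide coding sequence (A/C/G/T/N), length divisible by 3.
#' @return Amino-acid sequence, stop excluded.
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) == 0L) return("")
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"  # any codon with a non-ACGT base
  n <- length(aa)
  if (aa[n] == "*") {
    aa <- aa[-n]
    codons <- codons[-n]
  }
  stops <- which(aa == "*")
  if (length(stops))
    stop("internal stop codon at codon position ", stops[1L])
  paste(aa, collapse = "")
}

#' Reverse complement of nucleotide sequences
#'
#' @param x Character vector of nucleotide strings (A/C/G/T/N,
#'   case-insensitive).
#' @return Reverse complements, uppercased.
#' @export
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(x)))))
}

#' Batch translation of clean coding sequences
#'
#' Fast path used by the simulator: behaviourally identical to
#' [translate_cds()] on valid CDS input (trailing stop stripped, fuzzy
#' codons to X, internal stop is an error).
#' @noRd
translate_batch <- function(cds) {
  if (!length(cds)) return(character(0))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(toupper(cds)), if.fuzzy.codon = "X")))
  aa <- sub("\\*$", "", aa)
  bad <- grep("*", aa, fixed = TRUE)
  if (length(bad))
    stop("internal stop codon in CDS ", bad[1L])
  unname(aa)
}

#' Construct a genome record
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param role `"focal"` (trench SAG) or `"background"` (reference relative).
#' @return A list of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, role = c("focal", "background")) {
  role <- match.arg(role)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contig ids must be unique and non-empty")
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig ", names(contigs)[bad][1L], " contains non-ACGTN characters")
  len <- sum(nchar(contigs))
  if (len <= 0L) stop("genome must contain sequence")
  structure(list(genome_id = genome_id, contigs = contigs, role = role,
                 genome_length_bp = len),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome %s (%s): %d contig(s), %s bp>\n", x$genome_id,
              x$role, length(x$contigs),
              format(x$genome_length_bp, big.mark = ",")))
  invisible(x)
}

#' Load a gene table and join coding sequences from the genome
#'
#' Reads a tab-delimited gene table (columns `gene_id`, `genome_id`,
#' `contig_id`, `start`, `end`, `strand`, and optionally `category`),
#' extracts each CDS from the corresponding genome contig (reverse
#' complemented for strand `-`), and verifies that it translates.
#'
#' @param path Path to the TSV gene table.
#' @param genomes List of `genome_record` objects covering every
#'   `genome_id` in the table.
#' @param annotations Optional data.frame with columns `gene_id`,
#'   `category` used to fill/override categories.
#' @return Gene table data.frame with `cds` and `protein` columns added.
#' @export
load_gene_table <- function(path, genomes, annotations = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"category" %in% names(tab)) tab$category <- NA_character_
  tab$category[!is.na(tab$category) & !nzchar(tab$category)] <- NA_character_
  if (!is.null(annotations)) {
    idx <- match(tab$gene_id, annotations$gene_id)
    hit <- !is.na(idx)
    tab$category[hit] <- annotations$category[idx[hit]]
  }
  validate_gene_table(tab, genomes)
}

#' Validate a gene table against genomes; extract and translate each CDS
#'
#' @param tab Gene table data.frame (see [load_gene_table()]).
#' @param genomes List of `genome_record` objects.
#' @return The table with verified `cds` and `protein` columns.
#' @export
validate_gene_table <- function(tab, genomes) {
  gmap <- stats::setNames(genomes, vapply(genomes, `[[`, "", "genome_id"))
  bad_cat <- !is.na(tab$category) & !(tab$category %in% cog_categories())
  if (any(bad_cat))
    stop("unknown category letter: ", tab$category[bad_cat][1L])
  if (any(!(tab$strand %in% c("+", "-"))))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id: ", tab$gene_id[duplicated(tab$gene_id)][1L])
  cds <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- gmap[[tab$genome_id[i]]]
    if (is.null(g)) stop("unknown genome: ", tab$genome_id[i])
    contig <- unname(g$contigs[tab$contig_id[i]])
    if (is.na(contig))
      stop("gene ", tab$gene_id[i], " references absent contig ",
           tab$contig_id[i])
    if (tab$end[i] < tab$start[i])
      stop("gene ", tab$gene_id[i], ": end < start")
    if (tab$start[i] < 1L || tab$end[i] > nchar(contig))
      stop("gene ", tab$gene_id[i], ": coordinates outside contig")
    s <- substr(contig, tab$start[i], tab$end[i])
    if (tab$strand[i] == "-") s <- revcomp(s)
    cds[i] <- s
  }
  tab$cds <- cds
  tab$protein <- vapply(cds, translate_cds, character(1), USE.NAMES = FALSE)
  tab
}

#' Read a gene functional-annotation table (gene_id, category)
#'
#' @param path TSV path with header columns `gene_id`, `category`.
#' @return data.frame with validated one-letter categories.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "category") %in% names(tab)))
    stop("annotation table needs columns gene_id, category")
  bad <- !is.na(tab$category) & !(tab$category %in% cog_categories())
  if (any(bad)) stop("unknown category letter: ", tab$category[bad][1L])
  tab
}

#' Read sample metadata
#'
#' @param path TSV path with columns `sample_id`, `depth_m`,
#'   `size_fraction` (`free_living` or `particle_associated`) and
#'   `metagenome_size_bp`.
#' @return Validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "depth_m", "size_fraction", "metagenome_size_bp")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!(tab$size_fraction %in% c("free_living", "particle_associated"))))
    stop("size_fraction must be free_living or particle_associated")
  if (any(tab$metagenome_size_bp <= 0)) stop("metagenome_size_bp must be > 0")
  tab
}

#' Write a data.frame as an unquoted TSV with header
#' @param tab data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
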