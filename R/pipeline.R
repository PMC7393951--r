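# End-to-end orchestration: simulate -> ANI -> relative selection ->
# pangenome -> variation -> codon usage -> recruitment, with a YAML
# config, seeded determinism, TSV outputs and a run manifest.

#' Pipeline configuration
#'
#' Builds (and validates) the full pipeline configuration.  All analysis
#' thresholds default to the standard values: ANI relative-selection
#' threshold 95%, recruitment identity 95% / coverage 80% / E-value 1e-5,
#' ten variation bins, correlation cutoff p < 0.01.
#'
#' @param path Optional YAML file; entries override defaults.  Top-level
#'   keys mirror the arguments below, with a `clade` section passed to
#'   [clade_config()].
#' @param seed Integer seed, required when simulation is enabled.
#' @param out_dir Output directory.
#' @param clade Named list of [clade_config()] overrides.
#' @param ani_threshold,ani_fragment_len Relative-selection threshold (%)
#'   and ANI fragment length (bp).
#' @param identity,coverage,evalue Recruitment filter thresholds.
#' @param n_bins,p_cutoff Variation-analysis parameters.
#' @param n_reads_per_sample,read_length,read_error_rate Read-simulation
#'   parameters.
#' @param min_score Variation top-hit score threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, seed = NULL, out_dir = "hadalsig_out",
                            clade = list(), ani_threshold = 95,
                            ani_fragment_len = 1000L, identity = 95,
                            coverage = 80, evalue = 1e-5, n_bins = 10L,
                            p_cutoff = 0.01, n_reads_per_sample = 20000L,
                            read_length = 150L, read_error_rate = 0.005,
                            min_score = 50) {
  cfg <- list(seed = seed, out_dir = out_dir, clade = clade,
              ani_threshold = ani_threshold,
              ani_fragment_len = as.integer(ani_fragment_len),
              identity = identity, coverage = coverage, evalue = evalue,
              n_bins = as.integer(n_bins), p_cutoff = p_cutoff,
              n_reads_per_sample = as.integer(n_reads_per_sample),
              read_length = as.integer(read_length),
              read_error_rate = read_error_rate, min_score = min_score)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    for (k in names(y)) cfg[[k]] <- y[[k]]
  }
  if (is.null(cfg$seed))
    stop("pipeline_config: a seed is required for the simulation stages")
  stopifnot(cfg$ani_threshold > 0, cfg$ani_threshold <= 100,
            cfg$identity >= 0, cfg$identity <= 100,
            cfg$coverage >= 0, cfg$coverage <= 100,
            cfg$evalue > 0, cfg$n_bins >= 2L,
            cfg$p_cutoff > 0, cfg$p_cutoff < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated clade
#'
#' Executes simulate -> ANI -> close-relative selection -> pangenome ->
#' variation -> codon usage -> recruitment, writes every stage's TSV
#' outputs plus a JSON run manifest (seed, thresholds, input checksums)
#' under `config$out_dir`, and returns the in-memory results.  Outputs are
#' byte-identical across reruns with the same config and seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `hadalsig_run` with elements `clade`,
#'   `ani_table`, `selected_relatives`, `pangenome`, `variation`, `codon`,
#'   `recruitment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---
  clade <- stage("simulate", {
    cl_args <- config$clade
    cl_args$seed <- config$seed
    cl <- simulate_clade(do.call(clade_config, cl_args))
    write_clade(cl, file.path(out, "clade"))
    cl
  })
  genomes <- clade$genomes
  focal_ids <- names(genomes)[vapply(genomes, `[[`, "", "role") == "focal"]
  background_ids <- setdiff(names(genomes), focal_ids)

  # --- ANI + relative selection ---
  ani_table <- stage("ani", ani_matrix(genomes,
                                       fragment_len = config$ani_fragment_len))
  write_tsv(ani_table, file.path(out, "ani.tsv"))
  selected <- stage("select_relatives",
                    select_close_relatives(ani_table, focal_ids,
                                           background_ids,
                                           threshold = config$ani_threshold))
  writeLines(selected, file.path(out, "close_relatives.txt"))
  kept_ids <- c(focal_ids, selected)
  kept_genes <- clade$genes[clade$genes$genome_id %in% kept_ids, ]

  # --- pangenome ---
  pan <- stage("pangenome", pangenome_analysis(kept_genes, focal_ids))
  write_tsv(merge(pan$membership,
                  pan$clusters[, c("cluster_id", "unique_to_focal")],
                  by = "cluster_id"),
            file.path(out, "clusters.tsv"))
  write_tsv(pan$composition$table, file.path(out, "composition.tsv"))

  # --- variation ---
  variation <- stage("variation",
                     variation_analysis(kept_genes, focal_ids, selected,
                                        min_score = config$min_score,
                                        n_bins = config$n_bins,
                                        p_cutoff = config$p_cutoff))
  write_tsv(variation$binned, file.path(out, "variation_records.tsv"))
  write_tsv(data.frame(category = rownames(variation$profile),
                       variation$profile, check.names = FALSE),
            file.path(out, "variation_profile.tsv"))
  write_tsv(variation$correlations, file.path(out, "variation_correlations.tsv"))

  # --- codon usage ---
  codon <- stage("codon", {
    focal_genes <- clade$genes[clade$genes$genome_id %in% focal_ids, ]
    tab <- enc_gc3_table(stats::setNames(focal_genes$cds,
                                         focal_genes$gene_id),
                         stats::setNames(focal_genes$category,
                                         focal_genes$gene_id))
    cmp <- enc_comparison(tab, clade$truth$unique_gene_ids)
    list(table = tab, comparison = cmp)
  })
  write_tsv(codon$table, file.path(out, "enc_gc3.tsv"))
  write_tsv(codon$comparison$per_category, file.path(out, "enc_comparison.tsv"))

  # --- recruitment ---
  recruitment <- stage("recruit", {
    reads_by_sample <- lapply(seq_len(nrow(clade$samples)), function(si) {
      simulate_reads(genomes, clade$truth$abundance[, si],
                     n_reads = config$n_reads_per_sample,
                     read_length_bp = config$read_length,
                     error_rate = config$read_error_rate,
                     seed = config$seed + si)
    })
    names(reads_by_sample) <- clade$samples$sample_id
    asg <- recruit_samples(lapply(reads_by_sample, `[[`, "reads"), genomes,
                           max_evalue = config$evalue,
                           min_identity = config$identity,
                           min_coverage = config$coverage)
    m <- rpkg_matrix(asg, genomes, clade$samples)
    z <- znormalize(m)
    cl <- cluster_profiles(z)
    list(assignments = asg, rpkg = m, z = z, clustering = cl)
  })
  write_tsv(data.frame(genome_id = rownames(recruitment$rpkg),
                       recruitment$rpkg, check.names = FALSE),
            file.path(out, "rpkg.tsv"))
  write_tsv(data.frame(genome_id = rownames(recruitment$z),
                       recruitment$z, check.names = FALSE),
            file.path(out, "rpkg_z.tsv"))
  writeLines(recruitment$clustering$newick,
             file.path(out, "profile_dendrogram.nwk"))

  # --- manifest ---
  manifest <- list(
    package = "hadalsig",
    version = as.character(utils::packageVersion("hadalsig")),
    seed = config$seed,
    thresholds = config[c("ani_threshold", "ani_fragment_len", "identity",
                          "coverage", "evalue", "n_bins", "p_cutoff",
                          "min_score", "n_reads_per_sample", "read_length",
                          "read_error_rate")],
    n_genomes = length(genomes),
    input_checksums = vapply(
      list.files(file.path(out, "clade"), full.names = TRUE),
      function(f) as.character(tools::md5sum(f)), character(1)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(clade = clade, ani_table = ani_table,
                 selected_relatives = selected, pangenome = pan,
                 variation = variation, codon = codon,
                 recruitment = recruitment, manifest = manifest),
            class = "hadalsig_run")
}

#' @export
print.hadalsig_run <- function(x, ...) {
  cat("<hadalsig pipeline run>\n")
  cat("  genomes:", length(x$clade$genomes),
      "| close relatives selected:", length(x$selected_relatives), "\n")
  cat("  gene clusters:", nrow(x$pangenome$clusters),
      "| focal-unique:", sum(x$pangenome$clusters$unique_to_focal), "\n")
  sig <- x$variation$correlations
  sig <- sig$category[which(sig$significant & sig$pearson_r > 0)]
  cat("  categories with significant positive variation correlation:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
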