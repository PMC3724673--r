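# End-to-end orchestration: simulate -> profile -> analyze, with a run
# manifest (input hashes, row counts, versions, seeds) so cohort-scale
# runs are auditable and reproducible.

#' Read a key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that
#' parse as numbers are returned numeric; `true`/`false` become logical.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(paste0("malformed config line: ", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  out
}

write_manifest <- function(dir, stage, inputs, tables, counts, seed = NULL,
                           config = NULL, notes = character(0)) {
  hash_of <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(packageVersion("codonbias")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_hashes = hash_of(inputs),
    output_hashes = hash_of(tables),
    row_counts = counts,
    notes = notes
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a simulated cohort to disk
#'
#' Emits one multi-FASTA per genome under `out_dir/fasta/`, the taxonomy
#' TSV, the generative-truth TSV (with the true codon distributions as a
#' separate wide table), and a run manifest. Deterministic per seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(file.path(out_dir, "fasta"), recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  paths <- character(0)
  for (gid in unique(cohort$sequences$genome_id)) {
    p <- file.path(out_dir, "fasta", paste0(gid, ".fasta"))
    write_cds_fasta(cohort$sequences[cohort$sequences$genome_id == gid, ], p)
    paths <- c(paths, p)
  }
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  readr::write_tsv(cohort$taxonomy, tax_path, progress = FALSE)
  truth_flat <- cohort$truth[, setdiff(names(cohort$truth), "distribution")]
  truth_path <- file.path(out_dir, "truth.tsv")
  write_results_tsv(truth_flat, truth_path)
  dist_m <- do.call(rbind, cohort$truth$distribution)
  rownames(dist_m) <- cohort$truth$genome_id
  dist_path <- file.path(out_dir, "truth_distributions.tsv")
  write_results_tsv(dist_m, dist_path)
  write_manifest(out_dir, "simulate", character(0),
                 c(paths, tax_path, truth_path, dist_path),
                 list(genomes = nrow(cohort$taxonomy),
                      cds_records = nrow(cohort$sequences)),
                 seed = config$seed, config = unclass(config))
  invisible(cohort)
}

#' Profile a set of CDS FASTA files
#'
#' One profile row per replicon (or per genome with `by = "genome"`).
#' Replicons flagged as plasmids in the optional replicon metadata are
#' excluded with a logged count, since plasmid composition is analyzed
#' separately from chromosomes.
#'
#' @param fasta_paths Character vector of CDS FASTA files (one genome
#'   each), or a directory containing them.
#' @param out_dir Output directory.
#' @param replicon_metadata Optional TSV with columns `replicon_id` and
#'   `replicon_type`; rows with type `"plasmid"` are excluded.
#' @param by `"replicon"` or `"genome"` aggregation.
#' @param code NCBI genetic-code identifier.
#' @return Invisibly, the profiles tibble (also written as
#'   `profiles.tsv`).
#' @export
run_profile <- function(fasta_paths, out_dir, replicon_metadata = NULL,
                        by = "replicon", code = "11") {
  if (length(fasta_paths) == 1L && dir.exists(fasta_paths)) {
    fasta_paths <- sort(list.files(fasta_paths, pattern = "\\.(fa|fasta|fna)$",
                                   full.names = TRUE))
  }
  if (!length(fasta_paths)) abort("no FASTA inputs")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(fasta_paths, read_cds_fasta)
  cds <- bind_rows(sets)
  if (!is.null(replicon_metadata)) {
    meta <- readr::read_tsv(replicon_metadata, col_types = readr::cols(),
                            progress = FALSE)
    plasmids <- meta$replicon_id[tolower(meta$replicon_type) == "plasmid"]
    n_before <- length(unique(cds$replicon_id))
    cds <- cds[!(cds$replicon_id %in% plasmids), ]
    n_removed <- n_before - length(unique(cds$replicon_id))
    if (n_removed > 0) {
      inform(sprintf("excluded %d plasmid replicon(s)", n_removed))
    }
    if (nrow(cds) == 0L) abort("all replicons were excluded as plasmids")
  }
  profiles <- profile_cohort(cds, by = by, code = code)
  prof_path <- file.path(out_dir, "profiles.tsv")
  write_results_tsv(profiles, prof_path)
  write_manifest(out_dir, "profile", fasta_paths, prof_path,
                 list(genomes = length(unique(profiles$genome_id)),
                      replicons = nrow(profiles)))
  invisible(profiles)
}

#' Run the full statistical analysis bundle
#'
#' Executes every downstream stage on a profiles table: amino-acid and
#' codon correlation-matrix PCA with PC-vs-%AT and PC-vs-phylum
#' regressions, complete-linkage clustering with heatmap exports, the
#' %AT-on-codons linear model, the phylum ANOVA of AAUB, the AAUB~s(CUB)
#' GAM and its hierarchical random-slope GAMM with ML-based AIC
#' comparison, the KL GAMM, and the KL-vs-genome-size model. Stages whose
#' group-structure prerequisites fail (e.g. fewer than 2 phyla) are
#' skipped with an explicit notice recorded in the manifest.
#'
#' @param profiles Profiles tibble or path to `profiles.tsv`.
#' @param taxonomy Taxonomy tibble or path to the taxonomy TSV.
#' @param out_dir Output directory; one sub-directory per analysis.
#' @param min_phylum_size Size threshold for the AAUB phylum ranking.
#' @param k Spline basis dimension for GAM/GAMM stages.
#' @return Invisibly, a named list with every fitted object.
#' @export
run_analyze <- function(profiles, taxonomy, out_dir, min_phylum_size = 20,
                        k = 10) {
  if (is.character(profiles)) {
    profiles <- readr::read_tsv(profiles, col_types = readr::cols(), progress = FALSE)
  }
  if (is.character(taxonomy)) taxonomy <- read_taxonomy_table(taxonomy)
  missing_tax <- setdiff(profiles$genome_id, taxonomy$genome_id)
  if (length(missing_tax)) {
    abort(paste0("genomes missing from taxonomy: ",
                 paste(head(missing_tax, 5), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  notes <- character(0)
  results <- list()
  tax <- taxonomy[match(profiles$genome_id, taxonomy$genome_id), ]

  # --- multivariate -------------------------------------------------
  aa_m <- as.matrix(profiles[, paste0("aa_", cb_amino_acids)])
  rownames(aa_m) <- profiles$genome_id
  codon_m <- as.matrix(profiles[, paste0("codon_", cb_codons)])
  rownames(codon_m) <- profiles$genome_id
  mv_dir <- file.path(out_dir, "multivariate")
  dir.create(mv_dir, showWarnings = FALSE)
  if (nrow(profiles) >= 3) {
    results$pca_aa <- pca_correlation(aa_m, at = profiles$at_fraction)
    results$pca_codon <- pca_correlation(codon_m, at = profiles$at_fraction)
    write_results_tsv(results$pca_aa$scores, file.path(mv_dir, "pca_aa_scores.tsv"))
    write_results_tsv(results$pca_aa$loadings, file.path(mv_dir, "pca_aa_loadings.tsv"))
    write_results_tsv(tibble(component = seq_along(results$pca_aa$variance_fraction),
                             variance_fraction = results$pca_aa$variance_fraction),
                      file.path(mv_dir, "pca_aa_variance.tsv"))
    write_results_tsv(results$pca_codon$scores, file.path(mv_dir, "pca_codon_scores.tsv"))
    results$pc1_at <- regress_component_on_covariate(
      results$pca_aa$scores$PC1, profiles$at_fraction)
    results$pc2_phylum <- if (length(unique(tax$phylum)) >= 2) {
      regress_component_on_covariate(results$pca_aa$scores$PC2, tax$phylum)
    } else NULL
    write_results_tsv(bind_rows(
      mutate(results$pc1_at, model = "PC1_vs_at", .before = 1),
      if (!is.null(results$pc2_phylum)) {
        mutate(results$pc2_phylum, model = "PC2_vs_phylum", .before = 1)
      }
    ), file.path(mv_dir, "pc_regressions.tsv"))
  } else {
    notes <- c(notes, "PCA skipped: fewer than 3 genomes")
  }
  if (nrow(profiles) >= 2) {
    results$dendrogram <- cluster_genomes(aa_m)
    if (requireNamespace("ape", quietly = TRUE)) {
      dendrogram_newick(results$dendrogram, file.path(mv_dir, "aa_dendrogram.nwk"))
    }
    ann <- tibble(genome_id = profiles$genome_id,
                  at_fraction = profiles$at_fraction, phylum = tax$phylum)
    results$heatmap <- export_heatmap_inputs(aa_m, results$dendrogram, ann,
                                             dir = mv_dir)
  }

  # --- regression ---------------------------------------------------
  reg_dir <- file.path(out_dir, "models")
  dir.create(reg_dir, showWarnings = FALSE)
  if (nrow(profiles) > 66) {
    results$at_on_codons <- fit_at_on_codons(profiles)
    write_results_tsv(results$at_on_codons$coefficients,
                      file.path(reg_dir, "at_on_codons_coefficients.tsv"))
  } else {
    notes <- c(notes, "%AT-on-codons model skipped: needs > 66 genomes")
  }
  phyla_tab <- table(tax$phylum)
  if (length(phyla_tab) >= 2 && sum(phyla_tab >= 2) >= 2) {
    results$anova_phylum <- fit_anova_aaub_phylum(profiles, taxonomy,
                                                  min_genomes = min_phylum_size)
    write_results_tsv(results$anova_phylum$phylum_means,
                      file.path(reg_dir, "aaub_phylum_means.tsv"))
  } else {
    notes <- c(notes, "phylum ANOVA skipped: insufficient phyla")
  }
  if (nrow(profiles) > k + 2) {
    results$gam_aaub_cub <- fit_aaub_cub_gam(profiles, k = k)
  } else {
    notes <- c(notes, "GAM stage skipped: insufficient genomes for the spline basis")
  }
  enough_groups <- !is.null(results$gam_aaub_cub) && length(phyla_tab) >= 2 &&
    length(unique(paste(tax$phylum, tax$genus))) >= 2 && nrow(profiles) > 2 * k
  if (enough_groups) {
    results$gamm_aaub_cub <- fit_aaub_cub_gamm(profiles, taxonomy, k = k)
    results$aic_aaub <- compare_aic(results$gamm_aaub_cub, results$gam_aaub_cub,
                                    labels = c("random_effects", "fixed_only"))
    results$gamm_kl <- fit_kl_gamm(profiles, taxonomy, k = k)
    results$gam_kl <- fit_gam(profiles, "kl", smooth_terms = "at_fraction",
                              linear_terms = "aaub", k = k)
    results$aic_kl <- compare_aic(results$gamm_kl, results$gam_kl,
                                  labels = c("random_effects", "fixed_only"))
    if (nrow(profiles) >= 10 && var(profiles$genome_size) > 0) {
      results$kl_vs_size <- fit_kl_vs_size(profiles, taxonomy, k = k)
    }
    write_results_tsv(bind_rows(
      mutate(results$aic_aaub, comparison = "aaub_cub", .before = 1),
      mutate(results$aic_kl, comparison = "kl_model", .before = 1)
    ), file.path(reg_dir, "aic_comparisons.tsv"))
  } else {
    notes <- c(notes, "GAMM stages skipped: insufficient groups for random effects")
  }
  fits <- results[vapply(results, inherits, logical(1), what = "cb_fit")]
  if (length(fits)) {
    write_results_tsv(bind_rows(lapply(names(fits), function(nm) {
      mutate(glance(fits[[nm]]), model = nm, .before = 1)
    })), file.path(reg_dir, "model_summaries.tsv"))
    grids <- bind_rows(lapply(names(fits), function(nm) {
      g <- fits[[nm]]$smooth_estimates
      if (is.null(g)) NULL else mutate(g, model = nm, .before = 1)
    }))
    if (nrow(grids)) write_results_tsv(grids, file.path(reg_dir, "smooth_curves.tsv"))
  }
  for (nt in notes) inform(nt)
  tables <- list.files(out_dir, recursive = TRUE, full.names = TRUE,
                       pattern = "\\.(tsv|nwk)$")
  write_manifest(out_dir, "analyze", character(0), tables,
                 list(genomes = nrow(profiles)), notes = notes)
  invisible(results)
}
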