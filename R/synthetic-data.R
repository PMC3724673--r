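# Synthetic cohorts of genomes with the statistical structure the
# analyses assume: a nested phylum/genus/species taxonomy, a wide %AT
# gradient that is cluster-correlated within taxa, and codon-level bias
# produced by exponential tilting of the factorized null, which has a
# closed-form codon distribution and hence an exactly computable
# ("analytic") relative entropy for every genome.

#' Configuration for a synthetic cohort
#'
#' Defaults describe the study conditions every simulation-based check in
#' the package runs under: 30 phyla of 5 genera with 4 species each (600
#' genomes), phylum mean %AT uniform on 0.25-0.86 with genus- and
#' species-level Gaussian deviations, and a codon tilt whose strength
#' decreases linearly in %AT (so relative entropy falls as genomes become
#' AT-richer) with phylum- and genome-level jitter (so taxa share bias
#' beyond what %AT explains, and genomes at equal %AT still differ).
#'
#' @param n_phyla,genera_per_phylum,species_per_genus,n_per_species Cohort
#'   shape; one genome per strain.
#' @param at_range Range of phylum mean %AT (default `c(0.25, 0.86)`).
#' @param sigma_phylum,sigma_genus,sigma_species SDs of the nested %AT
#'   deviations added below the uniform phylum means.
#' @param bias_beta Maximum tilt strength (at the GC-rich end under the
#'   `"at_linear"` link; the constant tilt under `"constant"`).
#' @param bias_link `"at_linear"` (default): tilt decreases linearly from
#'   `bias_beta` at `at_range[1]` to 0 at `at_range[2]`; `"constant"`:
#'   tilt equals `bias_beta` everywhere.
#' @param bias_sd_phylum,bias_sd_genome SDs of phylum-level and
#'   genome-level Gaussian jitter added to the tilt strength.
#' @param n_codons_per_genome Expected codons per genome.
#' @param size_range Per-genome relative size multipliers, drawn uniformly,
#'   giving genome-size variation that is independent of the tilt.
#' @param pack_cds Pack simulated codons into start/stop-delimited CDS
#'   records (`TRUE`, I/O realism) or emit raw codon runs (`FALSE`, exact
#'   frequency arithmetic).
#' @param cds_codons Approximate codons per packed CDS record.
#' @param seed Integer seed; every draw derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_phyla = 30, genera_per_phylum = 5,
                          species_per_genus = 4, n_per_species = 1,
                          at_range = c(0.25, 0.86),
                          sigma_phylum = 0, sigma_genus = 0.03,
                          sigma_species = 0.015,
                          bias_beta = 1.5,
                          bias_link = c("at_linear", "constant"),
                          bias_sd_phylum = 0.10, bias_sd_genome = 0.05,
                          n_codons_per_genome = 20000,
                          size_range = c(0.7, 1.3),
                          pack_cds = TRUE, cds_codons = 300,
                          seed = 1) {
  bias_link <- match.arg(bias_link)
  stopifnot(
    n_phyla >= 1, genera_per_phylum >= 1, species_per_genus >= 1,
    n_per_species >= 1,
    length(at_range) == 2, at_range[1] > 0, at_range[2] < 1,
    at_range[1] < at_range[2],
    sigma_phylum >= 0, sigma_genus >= 0, sigma_species >= 0,
    bias_beta >= 0, bias_sd_phylum >= 0, bias_sd_genome >= 0,
    n_codons_per_genome >= 1,
    length(size_range) == 2, size_range[1] > 0,
    size_range[1] <= size_range[2]
  )
  structure(list(
    n_phyla = n_phyla, genera_per_phylum = genera_per_phylum,
    species_per_genus = species_per_genus, n_per_species = n_per_species,
    at_range = at_range, sigma_phylum = sigma_phylum,
    sigma_genus = sigma_genus, sigma_species = sigma_species,
    bias_beta = bias_beta, bias_link = bias_link,
    bias_sd_phylum = bias_sd_phylum, bias_sd_genome = bias_sd_genome,
    n_codons_per_genome = n_codons_per_genome, size_range = size_range,
    pack_cds = pack_cds, cds_codons = cds_codons, seed = as.integer(seed)
  ), class = "cohort_config")
}

clip_at <- function(x) pmin(pmax(x, 0.05), 0.95)

#' Simulate the nested taxonomy and per-genome true %AT
#'
#' Phylum mean %AT is drawn uniformly on `at_range` (plus optional
#' `sigma_phylum` jitter); genus and species effects are zero-mean normal
#' deviations with the configured SDs, so %AT is most similar within
#' species, then genera, then phyla — the structure the random-slope
#' models assume. Values are clipped to (0.05, 0.95).
#'
#' @param config A [cohort_config()].
#' @return Tibble: `genome_id`, `phylum`, `genus`, `species`, `strain`,
#'   `at_true`.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, simulate_taxonomy_impl(config))
}

simulate_taxonomy_impl <- function(config) {
  np <- config$n_phyla; ng <- config$genera_per_phylum
  ns <- config$species_per_genus; nr <- config$n_per_species
  phyla <- sprintf("Phylum%02d", seq_len(np))
  at_phylum <- runif(np, config$at_range[1], config$at_range[2]) +
    rnorm(np, 0, config$sigma_phylum)
  rows <- list()
  for (p in seq_len(np)) {
    for (g in seq_len(ng)) {
      at_genus <- at_phylum[p] + rnorm(1, 0, config$sigma_genus)
      for (s in seq_len(ns)) {
        at_species <- at_genus + rnorm(1, 0, config$sigma_species)
        for (r in seq_len(nr)) {
          rows[[length(rows) + 1L]] <- tibble(
            phylum = phyla[p],
            genus = sprintf("%s_G%02d", phyla[p], g),
            species = sprintf("%s_G%02d_S%02d", phyla[p], g, s),
            strain = sprintf("%s_G%02d_S%02d_T%02d", phyla[p], g, s, r),
            at_true = clip_at(at_species)
          )
        }
      }
    }
  }
  out <- bind_rows(rows)
  out$genome_id <- out$strain
  out[, c("genome_id", "phylum", "genus", "species", "strain", "at_true")]
}

#' Tilted codon distribution with analytic relative entropy
#'
#' Starts from the factorized distribution with marginals
#' `A = T = at_target/2`, `C = G = (1 - at_target)/2`, multiplies each
#' codon probability by `exp(bias_beta * w)` using the fixed
#' [codon_tilt_weights()], and renormalizes. At `bias_beta = 0` this is
#' exactly the factorized null (KL = 0); increasing `bias_beta` makes
#' codon usage progressively more biased. The analytic KL is computed
#' against the distribution's own pooled nucleotide marginals — precisely
#' what [relative_entropy_kl()] measures on simulated sequence.
#'
#' @param at_target Target %AT in (0, 1).
#' @param bias_beta Tilt strength, `>= 0`.
#' @return List: `freq` (named 64-vector), `nuc_freq` (pooled marginals),
#'   `kl` (bits), `at_realized`.
#' @export
build_codon_distribution <- function(at_target, bias_beta) {
  if (at_target <= 0 || at_target >= 1) abort("at_target must be in (0, 1)")
  if (bias_beta < 0) abort("bias_beta must be nonnegative")
  base_p <- c(A = at_target / 2, C = (1 - at_target) / 2,
              G = (1 - at_target) / 2, T = at_target / 2)
  b1 <- rep(1:4, each = 16); b2 <- rep(rep(1:4, each = 4), 4); b3 <- rep(1:4, 16)
  p0 <- base_p[b1] * base_p[b2] * base_p[b3]
  w <- codon_tilt_weights()
  p <- p0 * exp(bias_beta * w)
  p <- p / sum(p)
  names(p) <- cb_codons
  counts <- cb_codon_base_counts()
  q <- as.numeric(p %*% counts) / 3
  names(q) <- cb_bases
  list(freq = p, nuc_freq = q,
       kl = relative_entropy_kl(p, q),
       at_realized = unname(q["A"] + q["T"]))
}

# 64 x 4 matrix: occurrences of each base in each codon
cb_codon_base_counts <- function() {
  if (is.null(cb_cache$base_counts)) {
    m <- sapply(cb_bases, function(b) {
      vapply(strsplit(cb_codons, ""), function(x) sum(x == b), numeric(1))
    })
    rownames(m) <- cb_codons
    cb_cache$base_counts <- m
  }
  cb_cache$base_counts
}

#' Simulate one genome from a codon distribution
#'
#' Draws `n_codons` codons i.i.d. and packs them into CDS records of about
#' `cds_codons` codons, each prefixed with `ATG` and terminated with `TAA`
#' (packing off gives raw codon runs whose frequencies are exactly the
#' draws).
#'
#' @param distribution Named 64-vector of codon probabilities (or a
#'   [build_codon_distribution()] result).
#' @param n_codons Number of codons to draw.
#' @param genome_id Genome identifier.
#' @param seed Optional integer seed for this genome.
#' @param pack_cds Add start/stop codons and split into ~`cds_codons`
#'   records (default `TRUE`).
#' @param cds_codons Codons per packed record.
#' @return A [new_cds_set()] tibble.
#' @export
simulate_genome <- function(distribution, n_codons, genome_id = "genome",
                            seed = NULL, pack_cds = TRUE, cds_codons = 300) {
  if (is.list(distribution)) distribution <- distribution$freq
  if (length(distribution) != 64L || abs(sum(distribution) - 1) > 1e-9 ||
      any(distribution < 0)) {
    abort("distribution must be 64 nonnegative probabilities summing to 1")
  }
  if (n_codons < 1) abort("n_codons must be >= 1")
  draw <- function() sample.int(64L, n_codons, replace = TRUE, prob = distribution)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  codons <- cb_codons[idx]
  chunk <- ceiling(seq_along(codons) / cds_codons)
  parts <- vapply(split(codons, chunk), paste0, character(1), collapse = "")
  if (pack_cds) parts <- paste0("ATG", parts, "TAA")
  new_cds_set(genome_id, genome_id,
              sprintf("%s_cds%04d", genome_id, seq_along(parts)), parts)
}

# Realized tilt strength per genome: link(at) + phylum jitter + genome
# jitter, floored at 0.
realize_bias <- function(config, taxonomy) {
  link <- switch(config$bias_link,
    at_linear = function(at) {
      config$bias_beta * (config$at_range[2] - at) /
        (config$at_range[2] - config$at_range[1])
    },
    constant = function(at) rep(config$bias_beta, length(at))
  )
  phyla <- unique(taxonomy$phylum)
  dev_p <- setNames(rnorm(length(phyla), 0, config$bias_sd_phylum), phyla)
  beta <- link(taxonomy$at_true) + dev_p[taxonomy$phylum] +
    rnorm(nrow(taxonomy), 0, config$bias_sd_genome)
  pmax(unname(beta), 0)
}

#' Simulate a full cohort
#'
#' Composes [simulate_taxonomy()], [build_codon_distribution()] and
#' [simulate_genome()]: per-genome %AT from the nested taxonomy, tilt
#' strength from the configured %AT link plus phylum- and genome-level
#' jitter, sequences drawn i.i.d. from the tilted distribution. The
#' generative truth (target and realized %AT, realized tilt, analytic KL,
#' true distribution) is recorded for every genome.
#'
#' @param config A [cohort_config()].
#' @return List with `sequences` (one combined `cds_set` tibble),
#'   `taxonomy` (five-column table) and `truth` (tibble with per-genome
#'   `at_target`, `at_realized`, `bias_beta`, `kl_analytic`, `n_codons`
#'   and a `distribution` list-column).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tax <- simulate_taxonomy(config)
  withr::with_seed(config$seed + 1L, simulate_cohort_impl(config, tax))
}

simulate_cohort_impl <- function(config, tax) {
  beta <- realize_bias(config, tax)
  mult <- runif(nrow(tax), config$size_range[1], config$size_range[2])
  n_cod <- pmax(1L, as.integer(round(config$n_codons_per_genome * mult)))
  dists <- lapply(seq_len(nrow(tax)), function(i) {
    build_codon_distribution(tax$at_true[i], beta[i])
  })
  seqs <- lapply(seq_len(nrow(tax)), function(i) {
    simulate_genome(dists[[i]]$freq, n_cod[i], genome_id = tax$genome_id[i],
                    pack_cds = config$pack_cds, cds_codons = config$cds_codons)
  })
  truth <- tibble(
    genome_id = tax$genome_id,
    at_target = tax$at_true,
    at_realized = vapply(dists, function(d) d$at_realized, numeric(1)),
    bias_beta = beta,
    kl_analytic = vapply(dists, function(d) d$kl, numeric(1)),
    n_codons = n_cod,
    distribution = lapply(dists, function(d) d$freq)
  )
  list(sequences = bind_rows(seqs),
       taxonomy = tax[, c("genome_id", "phylum", "genus", "species", "strain")],
       truth = truth)
}

#' Simulate a cohort directly as composition profiles
#'
#' Draws each genome's codon counts from the multinomial implied by its
#' tilted distribution and computes the profile arithmetically from the
#' counts — the same quantities [profile_cohort()] computes from unpacked
#' simulated sequence, without materializing strings. Useful for
#' simulation studies with many replicate cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `profiles` (as from [profile_cohort()]), `taxonomy`
#'   and `truth`.
#' @export
simulate_cohort_profiles <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tax <- simulate_taxonomy(config)
  withr::with_seed(config$seed + 1L, {
    beta <- realize_bias(config, tax)
    mult <- runif(nrow(tax), config$size_range[1], config$size_range[2])
    n_cod <- pmax(1L, as.integer(round(config$n_codons_per_genome * mult)))
    dists <- lapply(seq_len(nrow(tax)), function(i) {
      build_codon_distribution(tax$at_true[i], beta[i])
    })
    profs <- lapply(seq_len(nrow(tax)), function(i) {
      counts <- rmultinom(1, n_cod[i], dists[[i]]$freq)[, 1]
      profile_from_codon_counts(setNames(counts, cb_codons), tax$genome_id[i])
    })
    truth <- tibble(
      genome_id = tax$genome_id,
      at_target = tax$at_true,
      at_realized = vapply(dists, function(d) d$at_realized, numeric(1)),
      bias_beta = beta,
      kl_analytic = vapply(dists, function(d) d$kl, numeric(1)),
      n_codons = n_cod,
      distribution = lapply(dists, function(d) d$freq)
    )
    list(profiles = bind_rows(profs),
         taxonomy = tax[, c("genome_id", "phylum", "genus", "species", "strain")],
         truth = truth)
  })
}

#' Composition profile from codon counts
#'
#' Computes the full profile row of [profile_genome()] from a vector of
#' codon counts: base frequencies are the pooled bases of the counted
#' codons, amino-acid frequencies come from translating each codon under
#' the given code (stop codons yield no residue). Identical to profiling
#' the corresponding unpacked sequence.
#'
#' @param counts Named integer 64-vector of codon counts.
#' @param genome_id,replicon_id Identifiers.
#' @param code NCBI genetic-code identifier.
#' @return One-row profile tibble.
#' @export
profile_from_codon_counts <- function(counts, genome_id,
                                      replicon_id = genome_id, code = "11") {
  counts <- counts[cb_codons]
  n <- sum(counts)
  if (n == 0) abort("no codon counts")
  cf <- setNames(as.numeric(counts) / n, cb_codons)
  base_m <- cb_codon_base_counts()
  nf <- setNames(as.numeric(counts %*% base_m) / (3 * n), cb_bases)
  aa_map <- genetic_code_table(code)
  keep <- aa_map != "*"
  aa_counts <- tapply(counts[keep], factor(aa_map[keep], levels = cb_amino_acids), sum)
  aa_counts[is.na(aa_counts)] <- 0
  n_res <- sum(aa_counts)
  af <- setNames(as.numeric(aa_counts) / n_res, cb_amino_acids)
  row <- tibble(
    genome_id = genome_id, replicon_id = replicon_id,
    at_fraction = unname(nf["A"] + nf["T"]),
    n_codons = as.integer(n), n_residues = as.integer(n_res),
    genome_size = as.integer(3 * n),
    aaub = usage_bias(af), cub = usage_bias(cf),
    kl = relative_entropy_kl(cf, nf)
  )
  freqs <- c(setNames(as.numeric(nf), paste0("nuc_", cb_bases)),
             setNames(as.numeric(cf), paste0("codon_", cb_codons)),
             setNames(as.numeric(af), paste0("aa_", cb_amino_acids)))
  dplyr::bind_cols(row, as_tibble(as.list(freqs)))
}
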