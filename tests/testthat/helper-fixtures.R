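# Shared fixtures and independent oracles, built in code at test time.

codons64 <- codonbias:::cb_codons
bases4 <- codonbias:::cb_bases
aa20 <- codonbias:::cb_amino_acids

write_fasta_file <- function(records, path = withr::local_tempfile(fileext = ".fasta",
                                                                   .local_envir = parent.frame())) {
  writeLines(paste0(">", names(records), "\n", unname(records)), path)
  path
}

# Minimal GenBank flat file with the given location strings over a sequence.
write_genbank_file <- function(sequence, cds_locations,
                               path = withr::local_tempfile(fileext = ".gb",
                                                            .local_envir = parent.frame())) {
  feat <- unlist(lapply(cds_locations, function(loc) {
    c(sprintf("     CDS             %s", loc),
      "                     /product=\"hypothetical protein\"")
  }))
  chunks <- substring(sequence, seq(1, nchar(sequence), 60),
                      pmin(seq(1, nchar(sequence), 60) + 59, nchar(sequence)))
  origin <- sprintf("%9d %s", seq(1, nchar(sequence), 60), tolower(chunks))
  writeLines(c(
    "LOCUS       TESTSEQ                 100 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    feat,
    "ORIGIN",
    origin,
    "//"
  ), path)
  path
}

# random proportion vector over k categories (strictly positive)
random_props <- function(k) {
  x <- rexp(k) + 1e-6
  x / sum(x)
}

# Two-pass mean/variance oracle for the usage-bias statistic.
usage_bias_oracle <- function(x) {
  mu <- mean(x)
  acc <- 0
  for (xi in x) acc <- acc + (xi - mu)^2
  sqrt(acc / (length(x) - 1))
}

# Term-by-term relative-entropy oracle (base 2), looping over all codons.
kl_oracle <- function(codon_freq, nuc_freq) {
  total <- 0
  for (i in seq_along(codons64)) {
    p <- codon_freq[[i]]
    if (p > 0) {
      b <- strsplit(codons64[i], "")[[1]]
      q <- nuc_freq[[b[1]]] * nuc_freq[[b[2]]] * nuc_freq[[b[3]]]
      total <- total + p * log2(p / q)
    }
  }
  total
}

# O(n^3) brute-force complete-linkage agglomeration; returns merge heights
# and the leaf partition at each merge.
complete_linkage_oracle <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# balanced taxonomy table for direct-response mixed-model simulations
make_balanced_taxonomy <- function(n_phyla, n_genera, n_species, n_per) {
  g <- expand.grid(r = seq_len(n_per), s = seq_len(n_species),
                   ge = seq_len(n_genera), p = seq_len(n_phyla))
  tibble::tibble(
    genome_id = sprintf("g%05d", seq_len(nrow(g))),
    phylum = sprintf("P%02d", g$p),
    genus = sprintf("P%02d_G%d", g$p, g$ge),
    species = sprintf("P%02d_G%d_S%d", g$p, g$ge, g$s),
    strain = sprintf("%s_T%d", sprintf("P%02d_G%d_S%d", g$p, g$ge, g$s), g$r)
  )
}

# small profile tibble straight from exact tilted distributions (no noise)
exact_profiles <- function(at, beta, ids = sprintf("g%02d", seq_along(at))) {
  rows <- lapply(seq_along(at), function(i) {
    d <- build_codon_distribution(at[i], beta[i])
    p <- profile_from_codon_counts(
      setNames(round(d$freq * 1e7), codons64), ids[i])
    p
  })
  dplyr::bind_rows(rows)
}
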