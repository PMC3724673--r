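# Per-genome composition profiles and the three bias statistics:
# AAUB/CUB (standard deviation of amino-acid / codon frequencies) and the
# Kullback-Leibler relative entropy of codon frequencies against the
# factorized (zeroth-order) null built from base composition.

split_codons <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq.int(1L, n, by = 3L)
  substring(sequence, starts, starts + 2L)
}

#' Codon frequencies of a CDS set
#'
#' Counts non-overlapping in-frame triplets over every CDS of the set and
#' normalizes by the total. Stop codons are ordinary categories among the
#' 64; triplets containing `N` are skipped (not redistributed).
#'
#' @param cds_set A [new_cds_set()] tibble.
#' @return Named numeric vector over the 64 codons (lexicographic order)
#'   with attributes `n_codons` (counted triplets) and `n_skipped`.
#' @export
codon_frequencies <- function(cds_set) {
  if (nrow(cds_set) == 0L) abort("cds_set is empty")
  codons <- unlist(lapply(cds_set$sequence, split_codons), use.names = FALSE)
  counts <- table(factor(codons, levels = cb_codons))
  n <- sum(counts)
  if (n == 0L) abort("no countable codons (all triplets contain N)")
  out <- as.numeric(counts) / n
  names(out) <- cb_codons
  attr(out, "n_codons") <- as.integer(n)
  attr(out, "n_skipped") <- length(codons) - as.integer(n)
  out
}

#' Nucleotide frequencies
#'
#' Base proportions over all positions of the counted codons of a CDS set
#' (`N` excluded), or over a whole replicon sequence when one is supplied.
#' These marginals define the factorized null for [relative_entropy_kl()].
#'
#' @param cds_set A [new_cds_set()] tibble, or `NULL` when `whole_sequence`
#'   is given.
#' @param whole_sequence Optional DNA string to use instead of the CDS.
#' @return Named numeric 4-vector over A, C, G, T.
#' @export
nucleotide_frequencies <- function(cds_set = NULL, whole_sequence = NULL) {
  if (!is.null(whole_sequence)) {
    chars <- strsplit(normalise_dna(whole_sequence), "")[[1]]
  } else {
    if (is.null(cds_set) || nrow(cds_set) == 0L) abort("cds_set is empty")
    codons <- unlist(lapply(cds_set$sequence, split_codons), use.names = FALSE)
    codons <- codons[!grepl("N", codons, fixed = TRUE)]
    chars <- unlist(strsplit(codons, ""), use.names = FALSE)
  }
  counts <- table(factor(chars, levels = cb_bases))
  n <- sum(counts)
  if (n == 0L) abort("no unambiguous bases to count")
  out <- as.numeric(counts) / n
  names(out) <- cb_bases
  out
}

#' Amino-acid frequencies of a protein set
#'
#' Proportions over the pooled residues of all proteins of a genome.
#'
#' @param proteins Character vector of amino-acid strings (20 standard
#'   one-letter codes), or a tibble with a `protein` column as returned by
#'   [translate_cds_set()].
#' @return Named numeric 20-vector (alphabetical one-letter order) with
#'   attribute `n_residues`.
#' @export
amino_acid_frequencies <- function(proteins) {
  if (is.data.frame(proteins)) proteins <- proteins$protein
  if (length(proteins) == 0L) abort("protein set is empty")
  chars <- unlist(strsplit(proteins, ""), use.names = FALSE)
  bad <- setdiff(unique(chars), cb_amino_acids)
  if (length(bad)) {
    abort(paste0("proteins contain non-standard symbols: ", paste(bad, collapse = "")))
  }
  counts <- table(factor(chars, levels = cb_amino_acids))
  n <- sum(counts)
  if (n == 0L) abort("zero residues")
  out <- as.numeric(counts) / n
  names(out) <- cb_amino_acids
  attr(out, "n_residues") <- as.integer(n)
  out
}

#' Genomic %AT of a sequence
#'
#' `(A + T) / (A + C + G + T)`; ambiguity codes are excluded from the
#' denominator.
#'
#' @param sequence DNA string with at least one unambiguous base.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' at_content("ATGC")  # 0.5
at_content <- function(sequence) {
  chars <- strsplit(normalise_dna(sequence), "")[[1]]
  n_at <- sum(chars %in% c("A", "T"))
  n_all <- sum(chars %in% cb_bases)
  if (n_all == 0L) abort("sequence contains no unambiguous bases")
  n_at / n_all
}

#' Usage bias of a frequency vector
#'
#' The empirical (sample) standard deviation of a vector of `k` category
#' proportions around their mean `1/k`. With `k = 20` amino-acid
#' frequencies this is AAUB; with `k = 64` codon frequencies, CUB. High
#' values mean a few categories dominate; a uniform vector scores 0.
#'
#' @param freqs Numeric vector of proportions summing to 1.
#' @return Nonnegative scalar, `sqrt(sum((x - 1/k)^2) / (k - 1))`.
#' @export
#' @examples
#' usage_bias(rep(1/20, 20))  # 0
usage_bias <- function(freqs) {
  k <- length(freqs)
  if (k < 2L) abort("need at least 2 categories")
  if (abs(sum(freqs) - 1) > 1e-9) abort("frequencies must sum to 1")
  if (any(freqs < 0)) abort("frequencies must be nonnegative")
  mu <- 1 / k
  sqrt(sum((freqs - mu)^2) / (k - 1))
}

#' Relative entropy of codon frequencies against the factorized null
#'
#' Kullback-Leibler divergence of the observed codon distribution
#' `F(XYZ)` from the zeroth-order expectation `F(X) F(Y) F(Z)` built from
#' the genomic base frequencies:
#' `KL = sum F(XYZ) * log2(F(XYZ) / (F(X) F(Y) F(Z)))`.
#' Zero-frequency codons contribute 0. A value of 0 means codons look like
#' independent draws of single bases; larger values mean more codon-level
#' structure than base composition alone explains.
#'
#' @param codon_freq Numeric 64-vector of codon proportions (lexicographic
#'   order, or named by codon).
#' @param nuc_freq Numeric 4-vector of base proportions over A, C, G, T.
#' @param units `"bits"` (log2, default) or `"nats"` (natural log).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' p <- setNames(rep(0, 64), codonbias:::cb_codons); p["AAA"] <- p["TTT"] <- 0.5
#' relative_entropy_kl(p, c(A = 0.5, C = 0, G = 0, T = 0.5))  # 2 bits
relative_entropy_kl <- function(codon_freq, nuc_freq, units = c("bits", "nats")) {
  units <- match.arg(units)
  if (length(codon_freq) != 64L) abort("codon_freq must have length 64")
  if (length(nuc_freq) != 4L) abort("nuc_freq must have length 4")
  if (abs(sum(codon_freq) - 1) > 1e-9) abort("codon_freq must sum to 1")
  if (abs(sum(nuc_freq) - 1) > 1e-9) abort("nuc_freq must sum to 1")
  if (!is.null(names(codon_freq))) codon_freq <- codon_freq[cb_codons]
  if (!is.null(names(nuc_freq))) nuc_freq <- nuc_freq[cb_bases]
  b1 <- rep(rep(1:4, each = 16), 1)
  b2 <- rep(rep(1:4, each = 4), 4)
  b3 <- rep(1:4, 16)
  q <- nuc_freq[b1] * nuc_freq[b2] * nuc_freq[b3]
  pos <- codon_freq > 0
  if (any(pos & q == 0)) {
    abort("infinite divergence: observed codon has a zero-probability factorized expectation")
  }
  kl <- sum(codon_freq[pos] * log(codon_freq[pos] / q[pos]))
  if (units == "bits") kl <- kl / log(2)
  if (kl < 0 && kl > -1e-12) kl <- 0
  kl
}

#' Profile one genome (or replicon)
#'
#' Computes the full composition profile and the three bias statistics for
#' a CDS set: nucleotide, codon and amino-acid frequencies, genomic %AT,
#' AAUB, CUB and KL relative entropy. By default the null-model base
#' frequencies and %AT come from the counted codons themselves, which
#' guarantees a finite KL; supply `whole_sequence` (and
#' `marginals = "whole"`) to use whole-replicon base composition instead.
#'
#' @param cds_set A [new_cds_set()] tibble (one genome/replicon).
#' @param whole_sequence Optional whole-replicon DNA string.
#' @param marginals `"cds"` (default) or `"whole"`: source of the base
#'   frequencies used for %AT and the factorized null.
#' @param code NCBI genetic-code identifier for translation.
#' @return A one-row tibble: `genome_id`, `replicon_id`, `at_fraction`,
#'   `n_codons`, `n_residues`, `genome_size`, `aaub`, `cub`, `kl`, then the
#'   4 base frequencies (`nuc_A`...), 64 codon frequencies (`codon_AAA`...)
#'   and 20 amino-acid frequencies (`aa_A`...).
#' @export
profile_genome <- function(cds_set, whole_sequence = NULL,
                           marginals = c("cds", "whole"), code = "11") {
  marginals <- match.arg(marginals)
  if (nrow(cds_set) == 0L) abort("cds_set is empty")
  if (marginals == "whole" && is.null(whole_sequence)) {
    abort("marginals = \"whole\" requires whole_sequence")
  }
  cf <- codon_frequencies(cds_set)
  nf <- if (marginals == "whole") {
    nucleotide_frequencies(whole_sequence = whole_sequence)
  } else {
    nucleotide_frequencies(cds_set)
  }
  prot <- translate_cds_set(cds_set, code = code)
  af <- amino_acid_frequencies(prot)
  at <- if (!is.null(whole_sequence)) {
    at_content(whole_sequence)
  } else {
    unname(nf["A"] + nf["T"])
  }
  genome_size <- if (!is.null(whole_sequence)) {
    nchar(whole_sequence)
  } else {
    sum(nchar(cds_set$sequence))
  }
  row <- tibble(
    genome_id = cds_set$genome_id[1],
    replicon_id = cds_set$replicon_id[1],
    at_fraction = at,
    n_codons = attr(cf, "n_codons"),
    n_residues = attr(af, "n_residues"),
    genome_size = as.integer(genome_size),
    aaub = usage_bias(af),
    cub = usage_bias(cf),
    kl = relative_entropy_kl(cf, nf)
  )
  freqs <- c(setNames(as.numeric(nf), paste0("nuc_", cb_bases)),
             setNames(as.numeric(cf), paste0("codon_", cb_codons)),
             setNames(as.numeric(af), paste0("aa_", cb_amino_acids)))
  dplyr::bind_cols(row, as_tibble(as.list(freqs)))
}

#' Profile a cohort of genomes
#'
#' Applies [profile_genome()] to every genome (or replicon) of a combined
#' CDS table and binds the rows.
#'
#' @param cds A `cds_set` tibble possibly covering many genomes, or a list
#'   of such tibbles.
#' @param by `"replicon"` (default) profiles each replicon separately;
#'   `"genome"` merges the replicons of a genome before profiling.
#' @inheritParams profile_genome
#' @return Tibble with one row per replicon (or genome).
#' @export
profile_cohort <- function(cds, by = c("replicon", "genome"), code = "11") {
  by <- match.arg(by)
  if (is.data.frame(cds)) cds <- list(cds)
  all_cds <- dplyr::bind_rows(cds)
  key <- if (by == "replicon") {
    paste(all_cds$genome_id, all_cds$replicon_id, sep = "\r")
  } else {
    all_cds$genome_id
  }
  parts <- split(seq_len(nrow(all_cds)), key)
  rows <- lapply(parts, function(idx) {
    profile_genome(validate_cds_set(all_cds[idx, ]), code = code)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$genome_id, out$replicon_id), ]
}
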