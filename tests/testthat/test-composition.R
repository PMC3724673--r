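test_that("codon frequencies count in-frame triplets with N skipping", {
  cs <- new_cds_set("g", "g", "c1", "AAATTT")
  cf <- codon_frequencies(cs)
  expect_equal(unname(cf["AAA"]), 0.5)
  expect_equal(unname(cf["TTT"]), 0.5)
  expect_equal(sum(cf), 1)
  expect_equal(attr(cf, "n_codons"), 2L)

  cs2 <- new_cds_set("g", "g", "c1", "AAANNNTTT")
  cf2 <- codon_frequencies(cs2)
  expect_equal(attr(cf2, "n_codons"), 2L)
  expect_equal(attr(cf2, "n_skipped"), 1L)
  expect_equal(unname(cf2["AAA"]), 0.5)

  cs3 <- new_cds_set("g", "g", c("c1", "c2"), c("AAA", "AAA"))
  expect_equal(unname(codon_frequencies(cs3)["AAA"]), 1)
})

test_that("nucleotide frequencies come from counted codons or whole sequence", {
  cs <- new_cds_set("g", "g", "c1", "AAATTT")
  expect_equal(nucleotide_frequencies(cs),
               c(A = 0.5, C = 0, G = 0, T = 0.5))
  cs2 <- new_cds_set("g", "g", "c1", strrep("ACGT", 3))
  expect_equal(nucleotide_frequencies(cs2), c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(nucleotide_frequencies(whole_sequence = "GGGG"),
               c(A = 0, C = 0, G = 1, T = 0))
})

test_that("amino-acid frequencies pool residues across proteins", {
  f <- amino_acid_frequencies(c("KK", "AA"))
  expect_equal(unname(f["K"]), 0.5)
  expect_equal(unname(f["A"]), 0.5)
  expect_equal(attr(f, "n_residues"), 4L)
  f2 <- amino_acid_frequencies(paste(aa20, collapse = ""))
  expect_equal(as.numeric(f2), rep(0.05, 20))
  expect_equal(unname(amino_acid_frequencies("M")["M"]), 1)
  expect_error(amino_acid_frequencies("KX"), "non-standard")
})

test_that("%AT excludes ambiguity codes from the denominator", {
  expect_equal(at_content("AAATTT"), 1)
  expect_equal(at_content("GGCC"), 0)
  expect_equal(at_content("ATGC"), 0.5)
  expect_equal(at_content("ATNN"), 1)
  expect_error(at_content("NNN"), "no unambiguous")
})

test_that("usage bias matches hand evaluation and brute-force oracle", {
  expect_equal(usage_bias(rep(1 / 20, 20)), 0)
  expect_equal(usage_bias(rep(1 / 64, 64)), 0)
  x <- c(0.5, 0.5, rep(0, 18))
  expect_equal(usage_bias(x), sqrt(0.45 / 19), tolerance = 1e-12)
  expect_equal(usage_bias(x), usage_bias_oracle(x), tolerance = 1e-12)

  set.seed(42)
  for (k in c(20, 64)) {
    for (i in 1:50) {
      p <- random_props(k)
      expect_equal(usage_bias(p), usage_bias_oracle(p), tolerance = 1e-12)
      # label-permutation invariance
      expect_equal(usage_bias(sample(p)), usage_bias(p), tolerance = 1e-12)
    }
  }
  expect_error(usage_bias(c(0.5, 0.4)), "sum to 1")
})

test_that("relative entropy matches the worked case and brute-force sum", {
  p <- setNames(rep(0, 64), codons64)
  p["AAA"] <- p["TTT"] <- 0.5
  q <- c(A = 0.5, C = 0, G = 0, T = 0.5)
  expect_equal(relative_entropy_kl(p, q), 2)

  expect_equal(relative_entropy_kl(rep(1 / 64, 64), rep(0.25, 4)), 0)

  set.seed(7)
  for (i in 1:50) {
    cf <- random_props(64)
    names(cf) <- codons64
    nf <- setNames(as.numeric(cf %*% codonbias:::cb_codon_base_counts()) / 3, bases4)
    kl <- relative_entropy_kl(cf, nf)
    expect_equal(kl, kl_oracle(cf, nf), tolerance = 1e-12)
    expect_gte(kl, 0)  # Gibbs inequality
  }

  # exact factorization -> 0 at any marginals
  nf <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  fac <- as.vector(outer(outer(nf, nf), nf))
  b1 <- rep(1:4, each = 16); b2 <- rep(rep(1:4, each = 4), 4); b3 <- rep(1:4, 16)
  fac <- nf[b1] * nf[b2] * nf[b3]
  names(fac) <- codons64
  expect_equal(relative_entropy_kl(fac, nf), 0, tolerance = 1e-12)

  # observed codon with zero-probability expectation is an error
  p2 <- setNames(rep(0, 64), codons64)
  p2["GGG"] <- 1
  expect_error(relative_entropy_kl(p2, c(A = 0.5, C = 0, G = 0, T = 0.5)),
               "infinite divergence")

  # nats are bits times log(2)
  expect_equal(relative_entropy_kl(p, q, units = "nats"), 2 * log(2))
})

test_that("profile_genome composes the single-purpose statistics", {
  cs <- new_cds_set("g1", "g1", "c1", "AAATTT")
  prof <- profile_genome(cs)
  expect_equal(prof$at_fraction, 1)
  expect_equal(prof$kl, 2)
  expect_equal(prof$cub, usage_bias(codon_frequencies(cs)))
  expect_equal(prof$aaub, usage_bias(amino_acid_frequencies(translate_cds_set(cs))))
  expect_equal(ncol(prof), 9 + 4 + 64 + 20)

  expect_error(profile_genome(new_cds_set(character(0), character(0),
                                          character(0), character(0))),
               "empty")
})

test_that("counting matches a naive per-record recount oracle", {
  set.seed(13)
  for (rep in 1:10) {
    n_rec <- sample(1:4, 1)
    seqs <- vapply(seq_len(n_rec), function(i) {
      paste0(sample(codons64, sample(2:30, 1), replace = TRUE), collapse = "")
    }, character(1))
    cs <- new_cds_set("g", "g", paste0("c", seq_len(n_rec)), seqs)
    # naive oracle: loop records, walk codons one at a time
    tally <- setNames(rep(0, 64), codons64)
    for (s in seqs) {
      for (j in seq(1, nchar(s), 3)) {
        cod <- substr(s, j, j + 2)
        tally[cod] <- tally[cod] + 1
      }
    }
    cf <- codon_frequencies(cs)
    expect_equal(as.numeric(cf), as.numeric(tally / sum(tally)), tolerance = 1e-12)
  }
})

test_that("profiles from counts equal profiles from unpacked sequence", {
  set.seed(5)
  d <- build_codon_distribution(0.4, 1.2)
  counts <- rmultinom(1, 400, d$freq)[, 1]
  names(counts) <- codons64
  from_counts <- profile_from_codon_counts(counts, "x")
  seqstr <- paste0(rep(codons64, counts), collapse = "")
  from_seq <- profile_genome(new_cds_set("x", "x", "c1", seqstr))
  expect_equal(as.data.frame(from_counts[, -(1:2)]),
               as.data.frame(from_seq[, -(1:2)]), tolerance = 1e-12)
})

test_that("whole-sequence marginals mode changes the null model source", {
  cs <- new_cds_set("g", "g", "c1", "AAATTT")
  whole <- "AAATTTGGGCCC"
  prof <- profile_genome(cs, whole_sequence = whole, marginals = "whole")
  expect_equal(prof$at_fraction, 0.5)
  expect_equal(prof$genome_size, nchar(whole))
  expect_equal(prof$kl,
               relative_entropy_kl(codon_frequencies(cs),
                                   nucleotide_frequencies(whole_sequence = whole)))
})
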