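# Fixed category orderings used by every frequency vector in the package.
# Codons are lexicographic over A < C < G < T; amino acids are the 20
# standard residues in alphabetical one-letter order.

cb_bases <- c("A", "C", "G", "T")

cb_codons <- as.vector(t(outer(
  as.vector(t(outer(cb_bases, cb_bases, paste0))),
  cb_bases, paste0
)))

cb_amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Genetic code lookup for a translation table
#'
#' Returns the codon-to-amino-acid map for an NCBI translation table as a
#' named character vector over the 64 codons in lexicographic order; stop
#' codons are `"*"`. The default is table 11 (bacterial, archaeal and plant
#' plastid code), which shares its codon assignments with the standard code
#' and differs only in permitted initiation codons.
#'
#' @param code NCBI genetic-code identifier as a string (default `"11"`).
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code_table()[["ATG"]]  # "M"
genetic_code_table <- function(code = "11") {
  key <- paste0("code_", code)
  if (is.null(cb_cache[[key]])) {
    gc <- Biostrings::getGeneticCode(code)
    # Biostrings indexes by TCAG order; reindex to our lexicographic order
    out <- gc[cb_codons]
    names(out) <- cb_codons
    cb_cache[[key]] <- out
  }
  cb_cache[[key]]
}

# memo store for pure lookup tables derived from the genetic code
cb_cache <- new.env(parent = emptyenv())

# number of A or T bases in each codon (0..3)
cb_codon_at_count <- vapply(
  strsplit(cb_codons, ""),
  function(b) sum(b %in% c("A", "T")), integer(1)
)

#' Codon tilt weights for the synthetic-genome generator
#'
#' The cohort generator perturbs a factorized (zeroth-order) codon
#' distribution by exponential tilting with a fixed weight vector `w`:
#' codons get probability proportional to the factorized probability times
#' `exp(beta * w)`. The weights are deterministic and shipped with the
#' package so that analytic relative-entropy values are stable constants.
#'
#' Construction: codons encoding leucine or serine score +1, all other
#' codons 0, and the scores are then centred within groups of codons
#' sharing the same A+T count. Leucine and serine are abundant across the
#' whole prokaryotic %AT range and their six-codon families span all base
#' compositions, so tilting them upward makes amino-acid usage
#' progressively more biased (AAUB increases with `beta`) at every %AT.
#' Under a factorized distribution with A=T and C=G marginals, all codons
#' with equal A+T count are equiprobable, so the centring makes the tilt
#' orthogonal (to first order in `beta`) to genomic %AT: codon usage is
#' biased without displacing the base composition the cohort design
#' prescribes.
#'
#' @return Named numeric vector of length 64 (lexicographic codon order).
#' @export
#' @examples
#' w <- codon_tilt_weights()
#' tapply(w, sapply(strsplit(names(w), ""), function(b) sum(b %in% c("A","T"))), mean)
codon_tilt_weights <- function() {
  if (is.null(cb_cache$tilt_w)) {
    aa <- genetic_code_table("11")
    s <- as.numeric(aa %in% c("L", "S"))
    w <- s - ave(s, cb_codon_at_count)
    names(w) <- cb_codons
    cb_cache$tilt_w <- w
  }
  cb_cache$tilt_w
}

#' @importFrom stats ave
NULL
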