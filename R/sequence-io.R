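#' Coding-sequence sets
#'
#' A CDS set is a tibble with one row per coding sequence and columns
#' `genome_id`, `replicon_id`, `cds_id` and `sequence` (uppercase DNA over
#' A/C/G/T/N). All profiling functions accept this shape. Retained sequences
#' always have length a positive multiple of 3 and unique `cds_id` within
#' the set.
#'
#' @param genome_id,replicon_id,cds_id character vectors.
#' @param sequence character vector of DNA sequences.
#' @return A `cds_set` tibble.
#' @export
new_cds_set <- function(genome_id, replicon_id, cds_id, sequence) {
  sequence <- unname(normalise_dna(sequence))
  x <- tibble(
    genome_id = unname(as.character(genome_id)),
    replicon_id = unname(as.character(replicon_id)),
    cds_id = unname(as.character(cds_id)),
    sequence = sequence
  )
  validate_cds_set(x)
}

validate_cds_set <- function(x) {
  stopifnot(all(c("genome_id", "replicon_id", "cds_id", "sequence") %in% names(x)))
  len <- nchar(x$sequence)
  if (any(len == 0L | len %% 3L != 0L)) {
    abort("cds_set sequences must have positive length divisible by 3")
  }
  if (anyDuplicated(x$cds_id)) {
    abort("cds_ids must be unique within a cds_set")
  }
  bad <- grepl("[^ACGTN]", x$sequence)
  if (any(bad)) abort("cds_set sequences may only contain A, C, G, T, N")
  class(x) <- c("cds_set", class(tibble()))
  x
}

normalise_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Read coding sequences from a multi-FASTA file
#'
#' Each FASTA record is taken as one CDS/ORF. Sequences are uppercased and
#' RNA `U` is mapped to `T`. Records whose length is not a positive multiple
#' of 3 are dropped (a frame cannot be assumed for them); the number dropped
#' is reported via a message and stored in the `n_skipped` attribute.
#'
#' @param path Path to a nucleotide multi-FASTA file.
#' @param genome_id Genome identifier for all records; defaults to the file
#'   name without extension.
#' @param replicon_id Replicon identifier; defaults to `genome_id`.
#' @return A [new_cds_set()] tibble with attribute `n_skipped`.
#' @export
read_cds_fasta <- function(path, genome_id = NULL, replicon_id = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read FASTA file: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  replicon_id <- replicon_id %||% genome_id
  ids <- sub("\\s.*$", "", names(seqs))
  sequence <- normalise_dna(as.character(seqs))
  len <- nchar(sequence)
  keep <- len >= 3L & len %% 3L == 0L
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("%s: skipped %d record(s) whose length is not a positive multiple of 3",
                   basename(path), n_skipped))
  }
  if (!any(keep)) abort(paste0("no usable CDS records in ", path))
  out <- new_cds_set(genome_id, replicon_id, ids[keep], sequence[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Extract coding sequences from a GenBank flat file
#'
#' Parses the `FEATURES` table for `CDS` entries and the `ORIGIN` sequence
#' block, and assembles each CDS in genome order: `complement(...)`
#' locations are reverse-complemented, `join(...)` spans are concatenated in
#' feature order, and partial-end markers (`<`, `>`) are ignored. The same
#' length filter as [read_cds_fasta()] applies. No installed package in this
#' stack reads GenBank feature tables, so the (small, line-oriented) format
#' is parsed here directly.
#'
#' @param path Path to a GenBank flat file with CDS features.
#' @param genome_id Genome identifier; defaults to the LOCUS name.
#' @return A [new_cds_set()] tibble with attribute `n_skipped`.
#' @export
extract_cds_from_genbank <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read GenBank file: ", path))
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  locus <- if (length(locus_line)) strsplit(trimws(locus_line[1]), "\\s+")[[1]][2] else "genbank"
  genome_id <- genome_id %||% locus

  # ORIGIN block -> one uppercase sequence string
  o <- grep("^ORIGIN", lines)
  if (!length(o)) abort("GenBank file has no ORIGIN sequence block")
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > o[1]][1] else length(lines) + 1L
  seq_lines <- lines[(o[1] + 1L):(end - 1L)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  genome_seq <- gsub("U", "T", genome_seq)
  genome_seq <- gsub("[^ACGTN]", "N", genome_seq)

  # FEATURES table -> CDS location strings (continuation lines joined)
  f0 <- grep("^FEATURES", lines)
  if (!length(f0)) abort("GenBank file has no FEATURES table")
  feat <- lines[(f0[1] + 1L):(o[1] - 1L)]
  is_key <- grepl("^ {5}\\S", feat)
  locs <- character(0)
  i <- 1L
  while (i <= length(feat)) {
    if (is_key[i] && grepl("^ {5}CDS\\s", feat[i])) {
      loc <- trimws(sub("^ {5}CDS\\s+", "", feat[i]))
      j <- i + 1L
      while (j <= length(feat) && !is_key[j] && !grepl("^\\s+/", feat[j])) {
        loc <- paste0(loc, trimws(feat[j]))
        j <- j + 1L
      }
      locs <- c(locs, loc)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(locs)) abort(paste0("no CDS features in ", path))

  sequence <- vapply(locs, extract_location, character(1), genome = genome_seq)
  len <- nchar(sequence)
  keep <- len >= 3L & len %% 3L == 0L
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("%s: skipped %d CDS feature(s) whose length is not a positive multiple of 3",
                   basename(path), n_skipped))
  }
  if (!any(keep)) abort(paste0("no usable CDS features in ", path))
  out <- new_cds_set(genome_id, genome_id,
                     sprintf("%s_cds%04d", genome_id, which(keep)),
                     sequence[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

# Resolve a GenBank location string against the genome sequence.
extract_location <- function(loc, genome) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  rc <- FALSE
  while (grepl("^complement\\(", loc)) {
    rc <- !rc
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  parts <- vapply(spans, function(s) {
    s <- gsub("complement\\((.*)\\)", "\\1", s)
    se <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    if (length(se) == 1L) se <- c(se, se)
    substr(genome, se[1], se[2])
  }, character(1))
  out <- paste0(parts, collapse = "")
  if (rc) out <- reverse_complement(out)
  out
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence
#'
#' In-frame translation under an NCBI genetic code (default table 11,
#' bacteria/archaea). A terminal stop codon is dropped silently; internal
#' stop codons and codons containing `N` yield no residue (the position is
#' skipped and counted in the `n_skipped` attribute). The result contains
#' only the 20 standard one-letter codes.
#'
#' @param cds_sequence DNA string whose length is divisible by 3.
#' @param code NCBI genetic-code identifier (default `"11"`).
#' @return Amino-acid string with attribute `n_skipped`.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
translate_cds <- function(cds_sequence, code = "11") {
  cds_sequence <- normalise_dna(cds_sequence)
  n <- nchar(cds_sequence)
  if (n == 0L || n %% 3L != 0L) {
    abort("sequence length must be a positive multiple of 3")
  }
  tab <- genetic_code_table(code)
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds_sequence, starts, starts + 2L)
  aa <- unname(tab[codons])          # NA for codons containing N
  n_cod <- length(aa)
  if (!is.na(aa[n_cod]) && aa[n_cod] == "*") aa <- aa[-n_cod]
  skipped <- is.na(aa) | aa == "*"
  out <- paste0(aa[!skipped], collapse = "")
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Translate every CDS of a set into a protein set
#'
#' @param cds_set A [new_cds_set()] tibble.
#' @param code NCBI genetic-code identifier (default `"11"`).
#' @return Tibble with columns `genome_id`, `cds_id`, `protein`; zero-length
#'   translations (all-stop/ambiguous CDS) are dropped.
#' @export
translate_cds_set <- function(cds_set, code = "11") {
  prot <- vapply(cds_set$sequence, function(s) as.character(translate_cds(s, code)),
                 character(1), USE.NAMES = FALSE)
  out <- tibble(genome_id = cds_set$genome_id, cds_id = cds_set$cds_id,
                protein = prot)
  out[nchar(out$protein) > 0L, ]
}

#' Read a taxonomy table
#'
#' Reads a tab-separated table with header columns `genome_id`, `phylum`,
#' `genus`, `species`, `strain`. Rows with an empty phylum are excluded with
#' a warning (the hierarchical models require a phylum for every genome);
#' duplicated genome ids are an error.
#'
#' @param path Path to the TSV file.
#' @return Tibble with the five taxonomy columns.
#' @export
read_taxonomy_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("genome_id", "phylum", "genus", "species", "strain")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(paste0("taxonomy table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$genome_id)) {
    abort("taxonomy table contains duplicated genome_id values")
  }
  empty <- is.na(tab$phylum) | tab$phylum == ""
  if (any(empty)) {
    warn(sprintf("excluding %d genome(s) without a phylum assignment", sum(empty)))
    tab <- tab[!empty, ]
  }
  tab[, required]
}

#' Write a results table as TSV
#'
#' Floating-point values are written with 12 significant digits so that a
#' read-back reproduces the table to that precision. Matrices are written
#' with their row names as a leading `row_id` column.
#'
#' @param table Data frame, tibble or matrix with unique labels.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results_tsv <- function(table, path) {
  if (is.matrix(table)) {
    df <- as_tibble(table, rownames = "row_id")
  } else {
    df <- as_tibble(table)
  }
  if (anyDuplicated(names(df))) abort("column labels must be unique")
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a CDS set as multi-FASTA
#'
#' @param cds_set A [new_cds_set()] tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cds_fasta <- function(cds_set, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", cds_set$cds_id, "\n", cds_set$sequence), con)
  invisible(path)
}
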