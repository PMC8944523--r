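# Low-level codon/sequence helpers shared across modules.

.gfk_cache <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE DNAString DNAStringSet AAString
#'   AAStringSet reverseComplement translate
NULL

BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#' @noRd
all_codons <- function() {
  if (is.null(.gfk_cache$codons)) {
    .gfk_cache$codons <- as.vector(outer(
      outer(BASES, BASES, paste0), BASES, paste0))
  }
  .gfk_cache$codons
}

#' Translate a codon string vector to one-letter amino acids ("*" = stop)
#' @noRd
codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Split a CDS string into codons
#' @noRd
split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Reverse complement of a plain character DNA string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS character string; stops as "*"
#' @noRd
translate_cds <- function(cds, trim_stop = TRUE) {
  aa <- codon_aa(split_codons(cds))
  if (trim_stop && length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

#' Check a CDS is a complete, stop-free ORF (ends in stop, no internal stop)
#' @noRd
is_clean_orf <- function(cds) {
  if (nchar(cds) %% 3L != 0L) return(FALSE)
  aa <- codon_aa(split_codons(cds))
  n <- length(aa)
  n >= 2L && aa[n] == "*" && !any(aa[-n] == "*")
}

#' Back-translate a protein to a CDS using seeded random synonymous codons
#' @noRd
back_translate <- function(protein, add_stop = TRUE) {
  aa <- strsplit(protein, "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  picks <- vapply(aa, function(a) {
    cods <- by_aa[[a]]
    if (is.null(cods)) stop("cannot back-translate residue: ", a)
    cods[sample.int(length(cods), 1L)]
  }, character(1))
  stop_codon <- if (add_stop) by_aa[["*"]][sample.int(3L, 1L)] else ""
  paste0(paste(picks, collapse = ""), stop_codon)
}

#' Seeded random DNA of a given length
#' @noRd
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Seeded random protein of a given length (no stops)
#' @noRd
random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# IUPAC nucleotide code -> base set
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Realize an IUPAC consensus as one concrete sequence (first base per code)
#' @noRd
iupac_realize <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ","))
  paste(vapply(codes, function(k) IUPAC_SETS[[k]][1L], character(1)),
        collapse = "")
}

#' Validate an IUPAC consensus string
#' @noRd
check_iupac <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC code(s) in consensus '", consensus, "': ",
         paste(bad, collapse = ","))
  }
  invisible(TRUE)
}
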