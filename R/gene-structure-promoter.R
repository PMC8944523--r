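# Exon-intron structure summaries, promoter extraction and cis-regulatory
# element scanning.

#' Exon-intron structure of a gene model
#'
#' Decomposes the chosen transcript into an ordered 5'->3' segment list in
#' gene-local coordinates: UTR and CDS portions of each exon, with introns
#' as the gaps between consecutive exons on the coding strand.
#'
#' @param gene A gene model (element of [read_gene_models()]).
#' @param transcript_id Transcript to summarize; defaults to the longest
#'   ([select_longest_transcript()]).
#' @return List with `gene_id`, `transcript_id`, `exon_count`,
#'   `intron_count`, `utr_count` and `segments` (data frame: type in
#'   utr/cds/intron, start, end in gene-local 1-based coordinates).
#' @export
structure_summary <- function(gene, transcript_id = NULL) {
  if (is.null(transcript_id)) transcript_id <- select_longest_transcript(gene)
  tx <- gene$transcripts[[transcript_id]]
  if (is.null(tx)) stop("unknown transcript: ", transcript_id)
  exons <- tx$exons
  cdss <- tx$cds
  g2l <- if (gene$strand == "-") {
    function(pos) gene$end - pos + 1L
  } else {
    function(pos) pos - gene$start + 1L
  }
  # local coordinates, 5'->3'
  le <- data.frame(start = pmin(g2l(exons$start), g2l(exons$end)),
                   end = pmax(g2l(exons$start), g2l(exons$end)))
  le <- le[order(le$start), , drop = FALSE]
  if (nrow(le) > 1 && any(le$start[-1] <= le$end[-nrow(le)])) {
    stop("overlapping exons in ", gene$gene_id)
  }
  lc <- data.frame(start = pmin(g2l(cdss$start), g2l(cdss$end)),
                   end = pmax(g2l(cdss$start), g2l(cdss$end)))
  lc <- lc[order(lc$start), , drop = FALSE]
  segs <- list()
  for (i in seq_len(nrow(le))) {
    ex <- le[i, ]
    pos <- ex$start
    for (j in seq_len(nrow(lc))) {
      cd <- lc[j, ]
      if (cd$end < ex$start || cd$start > ex$end) next
      if (cd$start > pos) {
        segs[[length(segs) + 1]] <- data.frame(
          type = "utr", start = pos, end = cd$start - 1L)
      }
      segs[[length(segs) + 1]] <- data.frame(
        type = "cds", start = max(cd$start, ex$start),
        end = min(cd$end, ex$end))
      pos <- min(cd$end, ex$end) + 1L
    }
    if (pos <= ex$end) {
      segs[[length(segs) + 1]] <- data.frame(
        type = "utr", start = pos, end = ex$end)
    }
    if (i < nrow(le)) {
      segs[[length(segs) + 1]] <- data.frame(
        type = "intron", start = ex$end + 1L, end = le$start[i + 1] - 1L)
    }
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  list(gene_id = gene$gene_id, transcript_id = transcript_id,
       exon_count = nrow(le), intron_count = nrow(le) - 1L,
       utr_count = sum(segments$type == "utr"), segments = segments)
}

#' Extract the promoter window upstream of the translation start
#'
#' Returns the `length` bp immediately 5' of the first CDS base, reported
#' 5'->3' on the gene's coding strand (reverse-complemented for minus-strand
#' genes). Windows truncated by a chromosome end are returned shorter, with
#' a warning.
#'
#' @param genome A `DNAStringSet` (or named character vector) keyed by
#'   chromosome.
#' @param gene A gene model with CDS coordinates.
#' @param length Window length in bp (default 2000).
#' @param transcript_id Transcript whose CDS start anchors the window;
#'   defaults to the longest.
#' @return Promoter sequence as a character string, with attribute
#'   `"window"` giving the genomic interval used (1-based inclusive).
#' @export
extract_promoter <- function(genome, gene, length = 2000,
                             transcript_id = NULL) {
  if (is.null(transcript_id)) transcript_id <- select_longest_transcript(gene)
  tx <- gene$transcripts[[transcript_id]]
  if (is.null(tx) || nrow(tx$cds) == 0) {
    stop("gene ", gene$gene_id, " has no CDS")
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom <- genome[[gene$chromosome]]
  if (is.null(chrom)) stop("chromosome not in genome: ", gene$chromosome)
  clen <- Biostrings::nchar(chrom)
  if (gene$strand == "-") {
    cds_start <- max(tx$cds$end)
    lo <- cds_start + 1L
    hi <- min(clen, cds_start + length)
    if (hi - lo + 1L < length) {
      warning("promoter of ", gene$gene_id, " truncated to ",
              max(hi - lo + 1L, 0L), " bp by chromosome end")
    }
    if (hi < lo) return(structure("", window = c(NA, NA)))
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chrom, lo, hi)))
  } else {
    cds_start <- min(tx$cds$start)
    hi <- cds_start - 1L
    lo <- max(1L, cds_start - length)
    if (hi - lo + 1L < length) {
      warning("promoter of ", gene$gene_id, " truncated to ",
              max(hi - lo + 1L, 0L), " bp by chromosome end")
    }
    if (hi < lo) return(structure("", window = c(NA, NA)))
    seq <- as.character(Biostrings::subseq(chrom, lo, hi))
  }
  structure(seq, window = c(lo, hi))
}

#' Load a cis-regulatory element dictionary
#'
#' A TSV with columns `name`, `consensus` (IUPAC nucleotide codes) and
#' `category`. Every consensus is validated against the IUPAC alphabet at
#' load time. Without a path, the dictionary shipped with the package
#' (seeded with commonly reported stress/hormone/light elements) is used;
#' it is a plain editable file.
#'
#' @param path Optional TSV path.
#' @return Data frame: name, consensus, category.
#' @export
load_cis_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_elements.tsv", package = "genefamkit")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (!all(c("name", "consensus") %in% names(d))) {
    stop("dictionary needs 'name' and 'consensus' columns")
  }
  for (cs in d$consensus) check_iupac(cs)
  if (is.null(d$category)) d$category <- "other"
  d
}

#' Scan a promoter window for cis-regulatory elements
#'
#' Reports every IUPAC-compatible match of every dictionary element on both
#' strands of the window (strand scanning can be restricted). Overlapping
#' hits are all reported. Positions are 1-based offsets of the match start
#' within the window, 5'->3' on the gene's coding strand.
#'
#' @param promoter Promoter sequence (character) from [extract_promoter()].
#' @param dictionary Data frame from [load_cis_dictionary()].
#' @param member Optional member name recorded with each hit.
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Data frame of hits: member, element, position, strand, match.
#' @export
scan_cis_elements <- function(promoter, dictionary, member = NA_character_,
                              both_strands = TRUE) {
  if (nrow(dictionary) == 0) stop("empty cis-element dictionary")
  subj <- Biostrings::DNAString(promoter)
  out <- list()
  for (i in seq_len(nrow(dictionary))) {
    el <- dictionary$name[i]
    cons <- toupper(dictionary$consensus[i])
    fwd <- Biostrings::matchPattern(cons, subj, fixed = FALSE)
    if (length(fwd)) {
      out[[length(out) + 1]] <- data.frame(
        member = member, element = el,
        position = Biostrings::start(fwd), strand = "+",
        match = as.character(fwd), stringsAsFactors = FALSE)
    }
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cons)))
      rev <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
      if (length(rev)) {
        out[[length(out) + 1]] <- data.frame(
          member = member, element = el,
          position = Biostrings::start(rev), strand = "-",
          match = as.character(rev), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(member = character(), element = character(),
                      position = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$element, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-by-element count matrix from cis-element hits
#'
#' @param hits Hit table from [scan_cis_elements()] (rows for several
#'   members concatenated).
#' @param members Character vector of member names (matrix rows; zero rows
#'   kept for members without hits).
#' @param elements Optional element names for the columns; defaults to all
#'   elements present in `hits`.
#' @param min_total Optional threshold: keep only elements whose total
#'   count across members is strictly greater than this (e.g., 15).
#' @return Integer matrix, members x elements.
#' @export
element_count_matrix <- function(hits, members, elements = NULL,
                                 min_total = NULL) {
  if (is.null(elements)) elements <- sort(unique(hits$element))
  m <- matrix(0L, nrow = length(members), ncol = length(elements),
              dimnames = list(members, elements))
  if (nrow(hits)) {
    tb <- table(factor(hits$member, levels = members),
                factor(hits$element, levels = elements))
    m[] <- as.integer(tb)
  }
  if (!is.null(min_total)) {
    m <- m[, colSums(m) > min_total, drop = FALSE]
  }
  m
}
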