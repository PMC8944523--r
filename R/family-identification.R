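# Family-member nomination: gene-model parsing, transcript selection,
# CDS-length and truncation filters, PSSM domain scan, naming convention.

#' Read a species bundle (genome, annotation, CDS and protein FASTA)
#'
#' @param dir Directory containing `genome.fa`, `genes.gff3`, `cds.fa`,
#'   `protein.fa` (the layout written by [generate_bundle()]), or supply
#'   the four paths explicitly.
#' @return List with `genome` (DNAStringSet), `models` (named list of gene
#'   models, see [read_gene_models()]), `cds` and `protein` (named
#'   character vectors keyed by transcript id).
#' @export
read_bundle <- function(dir, genome = file.path(dir, "genome.fa"),
                        gff = file.path(dir, "genes.gff3"),
                        cds = file.path(dir, "cds.fa"),
                        protein = file.path(dir, "protein.fa")) {
  list(
    genome = Biostrings::readDNAStringSet(genome),
    models = read_gene_models(gff),
    cds = as.character(Biostrings::readDNAStringSet(cds)),
    protein = as.character(Biostrings::readAAStringSet(protein)))
}

#' Parse GFF3 annotation into gene models
#'
#' Consumes the gene -> mRNA -> exon/CDS dialect with ID/Parent attributes
#' (1-based inclusive coordinates). Exons and CDS are sorted 5'->3' on the
#' coding strand.
#'
#' @param gff Path to a GFF3 file.
#' @return Named list of gene models; each is a list with `gene_id`,
#'   `chromosome`, `strand`, `start`, `end` and `transcripts` (a named list
#'   with `transcript_id`, `cds_length`, `exons`, `cds`; the last two are
#'   data frames with `start`/`end`).
#' @export
read_gene_models <- function(gff) {
  gr <- rtracklayer::import(gff, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, character(1))
  genes <- which(type == "gene")
  mrnas <- which(type == "mRNA")
  parts <- which(type %in% c("exon", "CDS"))
  models <- list()
  for (gi in genes) {
    gid <- ids[gi]
    strand <- as.character(GenomicRanges::strand(gr)[gi])
    txs <- mrnas[parents[mrnas] == gid]
    tx_list <- list()
    for (ti in txs) {
      tid <- ids[ti]
      sub <- parts[parents[parts] == tid]
      seg <- data.frame(
        type = type[sub],
        start = GenomicRanges::start(gr)[sub],
        end = GenomicRanges::end(gr)[sub])
      exons <- seg[seg$type == "exon", c("start", "end")]
      cdss <- seg[seg$type == "CDS", c("start", "end")]
      dec <- strand == "-"
      exons <- exons[order(exons$start, decreasing = dec), , drop = FALSE]
      cdss <- cdss[order(cdss$start, decreasing = dec), , drop = FALSE]
      rownames(exons) <- rownames(cdss) <- NULL
      tx_list[[tid]] <- list(
        transcript_id = tid,
        cds_length = sum(cdss$end - cdss$start + 1L),
        exons = exons, cds = cdss)
    }
    models[[gid]] <- list(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(gr)[gi]),
      strand = strand,
      start = GenomicRanges::start(gr)[gi],
      end = GenomicRanges::end(gr)[gi],
      transcripts = tx_list)
  }
  models
}

#' Select the longest transcript of a gene model
#'
#' Returns the transcript maximizing CDS length; ties are broken by the
#' lexicographically smallest transcript id.
#'
#' @param gene A gene model (element of [read_gene_models()] output).
#' @return The selected transcript id.
#' @export
select_longest_transcript <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) == 0) stop("gene ", gene$gene_id, " has no transcripts")
  lens <- vapply(txs, function(t) t$cds_length, numeric(1))
  ids <- vapply(txs, function(t) t$transcript_id, character(1))
  ord <- order(-lens, ids)
  unname(ids[ord[1]])
}

#' Filter records by minimum CDS length
#'
#' @param records Data frame with a `cds_length` column (or a numeric
#'   vector of CDS lengths).
#' @param min_bp Minimum CDS length in bp; records shorter than this are
#'   eliminated (boundary inclusive: exactly `min_bp` survives).
#' @return The surviving records.
#' @export
filter_min_cds <- function(records, min_bp = 150) {
  if (is.data.frame(records)) {
    records[records$cds_length >= min_bp, , drop = FALSE]
  } else {
    records[records >= min_bp]
  }
}

#' Build a position-specific scoring model for a protein domain
#'
#' Either from an explicit PSSM (rows = 20 amino acids, columns =
#' positions) or from an amino-acid consensus with match/mismatch scores.
#'
#' @param name Model name (e.g., "GPX-like").
#' @param consensus Amino-acid consensus string (used when `pssm` absent).
#' @param pssm Optional explicit score matrix.
#' @param match,mismatch Per-position scores when building from consensus.
#' @param threshold Minimum best-window score for a complete hit; default
#'   one point per model position (half the consensus maximum).
#' @param completeness Fraction of the model length that must be present in
#'   the protein for the scan to proceed (default 0.8); shorter proteins
#'   are truncated and yield no hit.
#' @return A `domain_model` list.
#' @export
domain_model <- function(name, consensus = NULL, pssm = NULL,
                         match = 2, mismatch = -1,
                         threshold = NULL, completeness = 0.8) {
  if (is.null(pssm)) {
    if (is.null(consensus)) stop("supply consensus or pssm")
    aa <- strsplit(toupper(consensus), "")[[1]]
    if (!all(aa %in% AA20)) stop("consensus must use the 20-letter alphabet")
    pssm <- matrix(mismatch, nrow = length(AA20), ncol = length(aa),
                   dimnames = list(AA20, NULL))
    pssm[cbind(match(aa, AA20), seq_along(aa))] <- match
  }
  if (completeness <= 0 || completeness > 1) {
    stop("completeness fraction must be in (0, 1]")
  }
  if (is.null(threshold)) threshold <- ncol(pssm)
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(list(name = name, pssm = pssm, length = ncol(pssm),
                 threshold = threshold, completeness = completeness),
            class = "domain_model")
}

#' Scan a protein for the best ungapped domain window
#'
#' Slides the model over the sequence and scores each full-length window
#' with the PSSM (X and any non-standard letter score 0). A hit is
#' `complete` iff a full-length window fits in the sequence and its score
#' reaches the model threshold. A protein shorter than
#' `completeness * model length` is truncated: no hit is returned. A
#' protein between that bound and the model length is scored against the
#' best partial model placement and flagged incomplete.
#'
#' @param protein Amino-acid string.
#' @param model A [domain_model()].
#' @return List with `start`, `end` (1-based in the protein), `score` and
#'   `complete`, or `NULL` for truncated proteins.
#' @export
scan_domain <- function(protein, model) {
  L <- model$length
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  if (n < ceiling(L * model$completeness)) return(NULL)
  idx <- match(aa, rownames(model$pssm))   # NA for X / unknown -> scores 0
  if (n >= L) {
    starts <- seq_len(n - L + 1L)
    scores <- vapply(starts, function(s) {
      rows <- idx[s:(s + L - 1L)]
      pos <- which(!is.na(rows))
      sum(model$pssm[cbind(rows[pos], pos)])
    }, numeric(1))
    best <- which.max(scores)
    list(start = starts[best], end = starts[best] + L - 1L,
         score = scores[best], complete = scores[best] >= model$threshold)
  } else {
    # protein shorter than the model: best placement of the protein within
    # the model, reported as incomplete
    offsets <- 0:(L - n)
    scores <- vapply(offsets, function(o) {
      pos <- which(!is.na(idx))
      sum(model$pssm[cbind(idx[pos], pos + o)])
    }, numeric(1))
    best <- which.max(scores)
    list(start = 1L, end = n, score = scores[best], complete = FALSE)
  }
}

#' Extract a numeric chromosome token from a sequence name
#'
#' "chr2", "Chr02" or "2" map to "2"; anything else (unplaced scaffolds,
#' contigs) maps to the pseudo-chromosome "U".
#' @noRd
chromosome_token <- function(chromosome) {
  is_chr <- grepl("^(chr(omosome)?[ _.]?)?0*[0-9]+$", chromosome,
                  ignore.case = TRUE)
  num <- sub("^\\D*0*", "", chromosome)
  ifelse(is_chr, num, "U")
}

#' Assign family-member names by chromosome and position
#'
#' Names follow `<prefix><family><chromosome>.<ordinal>`: a three-letter
#' species prefix, a family label, the chromosome number and the ordinal of
#' the gene on that chromosome by ascending start coordinate (starting at
#' 1). Genes on unplaced scaffolds use the "U" pseudo-chromosome token.
#'
#' @param members Data frame with columns `gene_id`, `chromosome`, `start`.
#' @param prefix Three-letter species prefix (e.g., "Gso").
#' @param family Family label (e.g., "GPX").
#' @return `members` with `chr_label` and `name` columns added.
#' @export
assign_names <- function(members, prefix, family) {
  if (anyDuplicated(members$gene_id)) {
    stop("duplicate gene_ids in member table")
  }
  members$chr_label <- chromosome_token(members$chromosome)
  ord <- order(members$chr_label, members$start, members$gene_id)
  members <- members[ord, , drop = FALSE]
  ordinal <- stats::ave(seq_len(nrow(members)), members$chr_label,
                        FUN = seq_along)
  members$name <- paste0(prefix, family, members$chr_label, ".", ordinal)
  rownames(members) <- NULL
  members
}

#' Import externally produced domain hits
#'
#' Alternative entry point for hits from external domain scanners: a TSV
#' with columns `gene_id`, `start`, `end`, `score` (and optional
#' `complete`).
#'
#' @param path TSV path.
#' @return Data frame of hits keyed by gene id.
#' @export
import_domain_hits <- function(path) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "score")
  if (!all(need %in% names(hits))) {
    stop("domain-hit TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(hits$complete)) hits$complete <- TRUE
  hits
}

#' Identify and name family members in a species bundle
#'
#' Applies the three nomination filters in sequence: (1) the longest
#' transcript represents each locus, (2) CDS shorter than `min_cds` bp are
#' eliminated, (3) genes with truncated proteins (no terminal stop,
#' internal stop) or an incomplete domain are discarded. Survivors are
#' named by chromosome and position.
#'
#' @param bundle A bundle from [read_bundle()] (or an equivalent list).
#' @param model A [domain_model()]; ignored when `domain_hits` is given.
#' @param prefix Three-letter species prefix.
#' @param family Family label ("SOD", "GPX", ...).
#' @param min_cds Minimum CDS length in bp (default 150).
#' @param domain_hits Optional imported hit table from
#'   [import_domain_hits()], replacing the in-package PSSM scan.
#' @return Data frame of accepted members: gene_id, transcript_id,
#'   chromosome, chr_label, strand, start, end, cds_length, name, cds,
#'   protein, domain_start, domain_end, domain_score.
#' @export
identify_family <- function(bundle, model, prefix, family,
                            min_cds = 150, domain_hits = NULL) {
  models <- bundle$models
  rows <- lapply(models, function(g) {
    tid <- select_longest_transcript(g)
    tx <- g$transcripts[[tid]]
    data.frame(gene_id = g$gene_id, transcript_id = tid,
               chromosome = g$chromosome, strand = g$strand,
               start = g$start, end = g$end, cds_length = tx$cds_length,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- filter_min_cds(tab, min_bp = min_cds)
  if (nrow(tab) == 0) return(tab)
  tab$cds <- unname(bundle$cds[tab$transcript_id])
  tab$protein <- unname(bundle$protein[tab$transcript_id])
  if (anyNA(tab$cds) || anyNA(tab$protein)) {
    stop("CDS/protein FASTA missing entries for some transcripts")
  }
  clean <- vapply(tab$cds, is_clean_orf, logical(1))
  tab <- tab[clean, , drop = FALSE]
  if (nrow(tab) == 0) return(tab)
  if (is.null(domain_hits)) {
    hits <- lapply(tab$protein, scan_domain, model = model)
  } else {
    hits <- lapply(tab$gene_id, function(g) {
      h <- domain_hits[domain_hits$gene_id == g, , drop = FALSE]
      if (nrow(h) == 0) return(NULL)
      h <- h[which.max(h$score), ]
      list(start = h$start, end = h$end, score = h$score,
           complete = isTRUE(h$complete))
    })
  }
  ok <- vapply(hits, function(h) !is.null(h) && isTRUE(h$complete),
               logical(1))
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0) return(tab)
  tab$domain_start <- vapply(hits[ok], function(h) as.integer(h$start),
                             integer(1))
  tab$domain_end <- vapply(hits[ok], function(h) as.integer(h$end),
                           integer(1))
  tab$domain_score <- vapply(hits[ok], function(h) as.numeric(h$score),
                             numeric(1))
  assign_names(tab, prefix, family)
}
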