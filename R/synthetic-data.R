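# Synthetic species bundles with known ground truth: genome + GFF3 +
# CDS/protein FASTA, expression matrices and qPCR Ct tables emulating the
# statistical structure the downstream analysis assumes.

# Invented family domain consensus (GPX-like length scale); planted in
# every family gene, absent from decoys.
DEFAULT_DOMAIN_CONSENSUS <- paste0(
  "DFTVKDAKGNDVPLSQYKGKVLLIVNVASQCGLTNSNYTELSQLYEKYKNQGFEILAFPC")

#' Configuration for a synthetic species bundle
#'
#' @param seed Integer seed; a fixed seed makes the bundle byte-identical
#'   across runs.
#' @param n_chromosomes,chromosome_length Genome shape (bp). Chromosomes
#'   must be long enough to hold all genes with a 2000 bp upstream flank;
#'   infeasible layouts fail at generation time.
#' @param n_family_genes Total planted family members (pair members
#'   included).
#' @param n_decoy_genes Ordinary decoy genes without the domain.
#' @param n_multi_isoform_loci Family loci given a second, shorter
#'   transcript.
#' @param n_short_cds_decoys Decoys with CDS < 150 bp.
#' @param tandem_pairs,segmental_pairs Lists of c(ks, ka) target NG86
#'   divergences for planted duplicate pairs (all targets >= 0).
#' @param tandem_gap Decoy genes placed between tandem pair members
#'   (default 1; must be <= 5 for the pair to classify as tandem).
#' @param domain_consensus Amino-acid consensus planted in family genes.
#' @param promoter_elements Named integer vector: cis-element name ->
#'   copies planted in every family-gene promoter window.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chromosomes = 3,
                             chromosome_length = 150000,
                             n_family_genes = 6,
                             n_decoy_genes = 8,
                             n_multi_isoform_loci = 2,
                             n_short_cds_decoys = 2,
                             tandem_pairs = list(c(ks = 0.05, ka = 0.01)),
                             segmental_pairs = list(c(ks = 0.10, ka = 0.03)),
                             tandem_gap = 1,
                             domain_consensus = DEFAULT_DOMAIN_CONSENSUS,
                             promoter_elements = c(ABRE = 3,
                                                   "TGACG-motif" = 2)) {
  all_pairs <- c(tandem_pairs, segmental_pairs)
  for (p in all_pairs) {
    if (any(p < 0)) stop("target_ks and target_ka must be >= 0")
  }
  n_pair_members <- 2L * length(all_pairs)
  if (n_family_genes < n_pair_members) {
    stop("n_family_genes (", n_family_genes,
         ") smaller than the genes needed for the requested pairs (",
         n_pair_members, ")")
  }
  if (length(segmental_pairs) > 0 && n_chromosomes < 2) {
    stop("segmental pairs need at least 2 chromosomes")
  }
  structure(list(
    seed = seed, n_chromosomes = n_chromosomes,
    chromosome_length = chromosome_length,
    n_family_genes = n_family_genes, n_decoy_genes = n_decoy_genes,
    n_multi_isoform_loci = n_multi_isoform_loci,
    n_short_cds_decoys = n_short_cds_decoys,
    tandem_pairs = tandem_pairs, segmental_pairs = segmental_pairs,
    tandem_gap = tandem_gap, domain_consensus = domain_consensus,
    promoter_elements = promoter_elements), class = "synthetic_config")
}

#' Evolve a duplicate CDS to target NG86 divergences
#'
#' Applies point mutations with explicit synonymous/nonsynonymous fate
#' control so that the expected NG86 (Ks, Ka) estimates of the pair equal
#' the targets: the target rates are back-transformed through the
#' Jukes-Cantor correction to difference proportions, converted to mutation
#' counts via the sequence's potential site counts, and placed uniformly
#' over codons (at most one change per codon). No stop codons are
#' introduced and the reading frame is preserved.
#'
#' @param cds Coding sequence (length divisible by 3, no internal stops; a
#'   trailing stop codon is kept untouched).
#' @param target_ks,target_ka Target NG86 rates (>= 0, finite).
#' @param seed Optional seed for reproducibility.
#' @return The mutated CDS string.
#' @export
evolve_duplicate <- function(cds, target_ks, target_ka, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_ks < 0 || target_ka < 0) stop("targets must be >= 0")
  p_of <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  ps <- p_of(target_ks)
  pn <- p_of(target_ka)
  if (!is.finite(ps) || !is.finite(pn) || ps >= 0.75 || pn >= 0.75) {
    stop("target implies a difference proportion >= 3/4: ",
         "Jukes-Cantor correction undefined")
  }
  codons <- split_codons(cds)
  aa <- codon_aa(codons)
  has_stop <- length(aa) > 0 && aa[length(aa)] == "*"
  body <- if (has_stop) codons[-length(codons)] else codons
  if (any(codon_aa(body) == "*")) stop("internal stop codon in CDS")
  if (target_ks == 0 && target_ka == 0) return(cds)
  tab <- ng86_tables()
  S <- sum(tab$s_sites[match(body, tab$codons)])
  N <- 3 * length(body) - S
  # stochastic rounding keeps the expected counts equal to the targets
  sround <- function(x) floor(x) + (stats::runif(1) < x - floor(x))
  n_syn <- sround(ps * S)
  n_non <- sround(pn * N)
  # per-codon single-step options, stop codons excluded
  options_of <- function(codon) {
    a0 <- codon_aa(codon)
    syn <- list(); non <- list()
    s <- strsplit(codon, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(BASES, s[pos])) {
        s2 <- s; s2[pos] <- b
        cd2 <- paste(s2, collapse = "")
        a2 <- codon_aa(cd2)
        if (a2 == "*") next
        if (a2 == a0) syn[[length(syn) + 1]] <- cd2
        else non[[length(non) + 1]] <- cd2
      }
    }
    list(syn = unlist(syn), non = unlist(non))
  }
  opts <- lapply(body, options_of)
  can_syn <- vapply(opts, function(o) length(o$syn) > 0, logical(1))
  can_non <- vapply(opts, function(o) length(o$non) > 0, logical(1))
  perm <- sample.int(length(body))
  picked <- character(length(body))  # "", "syn", "non"
  ns <- 0L; nn <- 0L
  for (i in perm) {
    if (ns < n_syn && can_syn[i]) {
      picked[i] <- "syn"; ns <- ns + 1L
    } else if (nn < n_non && can_non[i]) {
      picked[i] <- "non"; nn <- nn + 1L
    }
    if (ns >= n_syn && nn >= n_non) break
  }
  if (ns < n_syn || nn < n_non) {
    stop("targets infeasible for this CDS: need ", n_syn, " synonymous and ",
         n_non, " nonsynonymous single-codon changes, found ", ns, "/", nn)
  }
  out <- body
  for (i in which(picked != "")) {
    pool <- if (picked[i] == "syn") opts[[i]]$syn else opts[[i]]$non
    out[i] <- pool[sample.int(length(pool), 1L)]
  }
  paste(c(out, if (has_stop) codons[length(codons)]), collapse = "")
}

# low-complexity backgrounds keep cis-element false positives at zero:
# promoters are AC-repeat filler (planted elements overwrite it), UTRs are
# CT-repeat filler; neither matches any shipped consensus on either strand
filler <- function(n, unit) {
  substr(paste(rep(unit, ceiling(n / nchar(unit))), collapse = ""), 1, n)
}

#' Generate a synthetic species bundle with ground truth
#'
#' Builds a genome FASTA, GFF3 annotation (gene -> mRNA -> exon/CDS with
#' ID/Parent attributes, 1-based inclusive) and CDS/protein FASTA in which
#' family genes carry the domain signature in frame, decoys lack it,
#' multi-isoform loci have two transcripts of different CDS length,
#' short-CDS decoys have CDS < 150 bp, duplicate pairs sit at controlled
#' NG86 divergence, and family promoters carry planted cis-elements at
#' recorded positions. Strands are mixed.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `cds.fa`, `protein.fa` and `ground_truth.json`.
#' @return Invisibly, a bundle list compatible with [read_bundle()]
#'   (`genome`, `models`, `cds`, `protein`) plus `gene_order` (full
#'   annotated gene order) and `truth` (the ground-truth record).
#' @export
generate_bundle <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  all_pairs <- c(config$tandem_pairs, config$segmental_pairs)
  pair_types <- c(rep("tandem", length(config$tandem_pairs)),
                  rep("segmental", length(config$segmental_pairs)))
  n_pairs <- length(all_pairs)
  n_singles <- config$n_family_genes - 2L * n_pairs

  make_family_protein <- function() {
    paste0("M", random_protein(sample(30:60, 1)),
           config$domain_consensus,
           random_protein(sample(30:60, 1)))
  }

  genes <- list()   # each: id, kind, protein, cds (with stop)
  add_gene <- function(id, kind, protein, cds) {
    genes[[id]] <<- list(id = id, kind = kind, protein = protein, cds = cds)
  }
  fam_counter <- 0L
  new_fam_id <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("FAMG%02d", fam_counter)
  }
  pair_truth <- list()
  for (k in seq_len(n_pairs)) {
    prot <- make_family_protein()
    cds_a <- back_translate(prot)
    targets <- all_pairs[[k]]
    ks <- unname(targets[1]); ka <- unname(targets[2])
    cds_b <- evolve_duplicate(cds_a, ks, ka)
    ida <- new_fam_id(); idb <- new_fam_id()
    add_gene(ida, "family", translate_cds(cds_a), cds_a)
    add_gene(idb, "family", translate_cds(cds_b), cds_b)
    pair_truth[[k]] <- list(a = ida, b = idb, type = pair_types[k],
                            target_ks = ks, target_ka = ka)
  }
  for (k in seq_len(n_singles)) {
    prot <- make_family_protein()
    cds <- back_translate(prot)
    add_gene(new_fam_id(), "family", prot, cds)
  }
  for (k in seq_len(config$n_decoy_genes)) {
    prot <- paste0("M", random_protein(sample(120:250, 1)))
    add_gene(sprintf("DECOY%02d", k), "decoy", prot, back_translate(prot))
  }
  for (k in seq_len(config$n_short_cds_decoys)) {
    prot <- paste0("M", random_protein(sample(25:40, 1)))  # CDS 81..126 bp
    add_gene(sprintf("SDEC%02d", k), "short_decoy", prot,
             back_translate(prot))
  }
  gene_ids <- names(genes)
  fam_ids <- gene_ids[vapply(genes, function(g) g$kind == "family",
                             logical(1))]
  multi_ids <- utils::head(fam_ids, config$n_multi_isoform_loci)

  # ---- chromosome layout (ordered gene lists per chromosome) ----
  chrom_lists <- rep(list(character(0)), config$n_chromosomes)
  decoy_queue <- gene_ids[vapply(genes, function(g) g$kind != "family",
                                 logical(1))]
  pop_decoys <- function(n) {
    take <- utils::head(decoy_queue, n)
    decoy_queue <<- decoy_queue[-seq_len(length(take))]
    take
  }
  rot <- 0L
  next_chrom <- function() {
    rot <<- rot + 1L
    ((rot - 1L) %% config$n_chromosomes) + 1L
  }
  ti <- 0L
  for (k in seq_len(n_pairs)) {
    pt <- pair_truth[[k]]
    if (pt$type == "tandem") {
      ch <- next_chrom()
      chrom_lists[[ch]] <- c(chrom_lists[[ch]], pt$a,
                             pop_decoys(config$tandem_gap), pt$b)
    } else {
      ch1 <- next_chrom()
      ch2 <- next_chrom()
      if (ch2 == ch1) ch2 <- (ch1 %% config$n_chromosomes) + 1L
      chrom_lists[[ch1]] <- c(chrom_lists[[ch1]], pt$a)
      chrom_lists[[ch2]] <- c(chrom_lists[[ch2]], pt$b)
    }
  }
  placed <- unlist(chrom_lists)
  for (id in setdiff(gene_ids, placed)) {
    ch <- next_chrom()
    chrom_lists[[ch]] <- c(chrom_lists[[ch]], id)
  }

  # ---- per-gene structure and region assembly ----
  promoter_len <- 2000L
  plant_elements <- function() {
    # returns list(promoter_string, plants = data.frame(element, region_pos))
    prom <- filler(promoter_len, "AC")
    plants <- list()
    pos <- 300L
    for (el in names(config$promoter_elements)) {
      cnt <- config$promoter_elements[[el]]
      dict <- load_cis_dictionary()
      cons <- dict$consensus[dict$name == el]
      if (!length(cons)) stop("promoter element not in dictionary: ", el)
      inst <- iupac_realize(cons)
      for (r in seq_len(cnt)) {
        substr(prom, pos, pos + nchar(inst) - 1L) <- inst
        plants[[length(plants) + 1]] <- data.frame(
          element = el, region_pos = pos, stringsAsFactors = FALSE)
        pos <- pos + nchar(inst) + 25L
      }
    }
    list(promoter = prom,
         plants = if (length(plants)) do.call(rbind, plants) else
           data.frame(element = character(), region_pos = integer()))
  }

  build_locus <- function(g) {
    cds <- g$cds
    ncod <- nchar(cds) / 3
    n_exons <- if (g$kind == "short_decoy") 1L else sample(2:6, 1)
    n_exons <- min(n_exons, max(1L, floor(ncod / 2)))
    # codon-aligned CDS chunks
    if (n_exons == 1L) {
      cuts <- integer(0)
    } else {
      cuts <- sort(sample(seq_len(ncod - 1), n_exons - 1)) * 3L
    }
    bounds <- c(0L, cuts, nchar(cds))
    chunks <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
    utr5 <- filler(sample(60:150, 1), "CT")
    utr3 <- filler(sample(60:150, 1), "CT")
    introns <- if (n_exons > 1) {
      vapply(seq_len(n_exons - 1), function(i) {
        paste0("GT", random_dna(sample(80:250, 1)), "AG")
      }, character(1))
    } else character(0)
    # assemble gene body and record local coordinates
    body <- ""
    exon_loc <- list(); cds_loc <- list()
    pos <- 0L
    append_seg <- function(s) {
      body <<- paste0(body, s)
      old <- pos
      pos <<- pos + nchar(s)
      c(old + 1L, pos)
    }
    for (i in seq_len(n_exons)) {
      ex_start <- pos + 1L
      if (i == 1L) append_seg(utr5)
      cl <- append_seg(chunks[i])
      cds_loc[[i]] <- cl
      if (i == n_exons) append_seg(utr3)
      exon_loc[[i]] <- c(ex_start, pos)
      if (i < n_exons) append_seg(introns[i])
    }
    if (g$kind == "family") {
      pe <- plant_elements()
      promoter <- pe$promoter
      plants <- pe$plants
      plants$window_pos <- plants$region_pos - nchar(utr5)
    } else {
      promoter <- filler(promoter_len, "AC")
      plants <- data.frame(element = character(), region_pos = integer(),
                           window_pos = integer())
    }
    list(region = paste0(promoter, body),
         body_len = nchar(body),
         exon_loc = exon_loc, cds_loc = cds_loc,
         utr5_len = nchar(utr5),
         n_exons = n_exons, plants = plants)
  }

  loci <- lapply(genes, build_locus)

  # ---- place regions on chromosomes, build genome and annotation ----
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genome_seqs <- character(config$n_chromosomes)
  ann <- list()      # GFF3 feature rows
  cds_fa <- character(0)
  prot_fa <- character(0)
  gene_meta <- list()
  strand_pool <- c("+", "-")
  gcount <- 0L

  for (ci in seq_len(config$n_chromosomes)) {
    cursor <- 200L
    pieces <- list()
    last_end <- 0L
    for (gid in chrom_lists[[ci]]) {
      g <- genes[[gid]]
      lc <- loci[[gid]]
      region_len <- nchar(lc$region)
      gcount <- gcount + 1L
      strand <- if (gcount <= 2L) strand_pool[gcount] else
        sample(strand_pool, 1)
      slot_start <- cursor
      slot_end <- slot_start + region_len - 1L
      if (slot_end > config$chromosome_length - 200L) {
        stop("config infeasible: genes do not fit on ", chrom_names[ci],
             " (need > ", slot_end, " bp of ", config$chromosome_length, ")")
      }
      # local (region, 5'->3') to genomic coordinates
      l2g <- if (strand == "+") {
        function(l) slot_start + l - 1L
      } else {
        function(l) slot_end - l + 1L
      }
      body_lo <- promoter_len + 1L
      body_hi <- region_len
      gstart <- min(l2g(body_lo), l2g(body_hi))
      gend <- max(l2g(body_lo), l2g(body_hi))
      seg <- if (strand == "+") lc$region else revcomp(lc$region)
      pieces[[length(pieces) + 1]] <- random_dna(slot_start - last_end - 1L)
      pieces[[length(pieces) + 1]] <- seg
      last_end <- slot_end
      cursor <- slot_end + sample(300:800, 1)

      tid1 <- paste0(gid, ".t1")
      ann[[length(ann) + 1]] <- data.frame(
        seqnames = chrom_names[ci], start = gstart, end = gend,
        strand = strand, type = "gene", ID = gid, Parent = NA_character_,
        phase = NA_integer_, stringsAsFactors = FALSE)
      add_tx <- function(tid, exon_loc, cds_loc) {
        exs <- do.call(rbind, lapply(exon_loc, function(e) {
          gg <- sort(c(l2g(e[1] + promoter_len), l2g(e[2] + promoter_len)))
          data.frame(start = gg[1], end = gg[2])
        }))
        ann[[length(ann) + 1]] <<- data.frame(
          seqnames = chrom_names[ci], start = min(exs$start),
          end = max(exs$end), strand = strand, type = "mRNA", ID = tid,
          Parent = gid, phase = NA_integer_, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(exs))) {
          ann[[length(ann) + 1]] <<- data.frame(
            seqnames = chrom_names[ci], start = exs$start[r],
            end = exs$end[r], strand = strand, type = "exon",
            ID = NA_character_, Parent = tid, phase = NA_integer_,
            stringsAsFactors = FALSE)
        }
        cum <- 0L
        for (r in seq_along(cds_loc)) {
          e <- cds_loc[[r]]
          gg <- sort(c(l2g(e[1] + promoter_len), l2g(e[2] + promoter_len)))
          ann[[length(ann) + 1]] <<- data.frame(
            seqnames = chrom_names[ci], start = gg[1], end = gg[2],
            strand = strand, type = "CDS", ID = NA_character_, Parent = tid,
            phase = (3L - cum %% 3L) %% 3L, stringsAsFactors = FALSE)
          cum <- cum + (e[2] - e[1] + 1L)
        }
      }
      add_tx(tid1, lc$exon_loc, lc$cds_loc)
      cds_fa[tid1] <- g$cds
      prot_fa[tid1] <- g$protein
      if (gid %in% multi_ids && lc$n_exons >= 2L) {
        # second, shorter isoform: drops the last exon
        tid2 <- paste0(gid, ".t2")
        ex2 <- lc$exon_loc[-lc$n_exons]
        cd2 <- lc$cds_loc[-lc$n_exons]
        # last retained exon has no 3' UTR; close it at the CDS end
        ex2[[length(ex2)]] <- c(ex2[[length(ex2)]][1],
                                cd2[[length(cd2)]][2])
        add_tx(tid2, ex2, cd2)
        cds2 <- paste(substring(g$cds,
                                cumsum(c(0, vapply(cd2, function(e)
                                  e[2] - e[1] + 1, numeric(1))))[
                                    seq_along(cd2)] + 1,
                                cumsum(vapply(cd2, function(e)
                                  e[2] - e[1] + 1, numeric(1)))),
                      collapse = "")
        cds_fa[tid2] <- cds2
        prot_fa[tid2] <- translate_cds(cds2)
      }
      gene_meta[[gid]] <- list(id = gid, kind = g$kind,
                               chromosome = chrom_names[ci],
                               start = gstart, end = gend, strand = strand,
                               n_exons = lc$n_exons,
                               n_introns = lc$n_exons - 1L,
                               plants = lc$plants)
    }
    pieces[[length(pieces) + 1]] <-
      random_dna(config$chromosome_length - last_end)
    genome_seqs[ci] <- paste(unlist(pieces), collapse = "")
  }
  names(genome_seqs) <- chrom_names

  ann_df <- do.call(rbind, ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann_df$seqnames,
    ranges = IRanges::IRanges(ann_df$start, ann_df$end),
    strand = ann_df$strand)
  gr$type <- ann_df$type
  gr$ID <- ann_df$ID
  gr$Parent <- ifelse(is.na(ann_df$Parent), NA_character_, ann_df$Parent)
  gr$phase <- ann_df$phase

  gene_order <- do.call(rbind, lapply(gene_meta, function(m) {
    data.frame(id = m$id, kind = m$kind, chromosome = m$chromosome,
               start = m$start, end = m$end, strand = m$strand,
               n_introns = m$n_introns, stringsAsFactors = FALSE)
  }))
  rownames(gene_order) <- NULL

  plants_all <- do.call(rbind, lapply(gene_meta, function(m) {
    if (nrow(m$plants) == 0) return(NULL)
    cbind(data.frame(gene_id = m$id, stringsAsFactors = FALSE), m$plants)
  }))
  if (is.null(plants_all)) {
    plants_all <- data.frame(gene_id = character(), element = character(),
                             region_pos = integer(), window_pos = integer())
  }

  truth <- list(
    family_gene_ids = fam_ids,
    duplicate_pairs = pair_truth,
    multi_isoform_ids = multi_ids,
    short_cds_decoy_ids = gene_ids[vapply(genes, function(g)
      g$kind == "short_decoy", logical(1))],
    promoter_plants = plants_all,
    intron_counts = stats::setNames(gene_order$n_introns, gene_order$id))

  genome <- Biostrings::DNAStringSet(genome_seqs)
  bundle <- list(genome = genome, gff = gr,
                 cds = cds_fa, protein = prot_fa,
                 gene_order = gene_order, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
    rtracklayer::export(gr, file.path(out_dir, "genes.gff3"),
                        format = "gff3")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds_fa),
                                file.path(out_dir, "cds.fa"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot_fa),
                                file.path(out_dir, "protein.fa"))
    jsonlite::write_json(
      list(family_gene_ids = truth$family_gene_ids,
           duplicate_pairs = truth$duplicate_pairs,
           multi_isoform_ids = truth$multi_isoform_ids,
           short_cds_decoy_ids = truth$short_cds_decoy_ids,
           promoter_plants = truth$promoter_plants,
           intron_counts = as.list(truth$intron_counts)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
  }
  # parsed gene models for direct downstream use
  tmp_gff <- tempfile(fileext = ".gff3")
  rtracklayer::export(gr, tmp_gff, format = "gff3")
  bundle$models <- read_gene_models(tmp_gff)
  unlink(tmp_gff)
  invisible(bundle)
}

#' Synthetic FPKM expression matrix with planted tissue effects
#'
#' @param genes Gene names (or a count).
#' @param tissues Tissue names.
#' @param effects Data frame with columns `gene`, `tissue`, `fold`
#'   (multiplicative fold-change > 0 applied to that cell).
#' @param noise_sd Lognormal noise sd in log2 units (0 = exact folds).
#' @param seed Optional seed.
#' @param base_range FPKM baseline range per gene.
#' @return FPKM matrix, genes x tissues (non-negative).
#' @export
generate_expression <- function(genes, tissues, effects = NULL,
                                noise_sd = 0, seed = NULL,
                                base_range = c(5, 100)) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("gene%02d", seq_len(genes))
  }
  if (!is.null(effects) && nrow(effects) > 0 && any(effects$fold <= 0)) {
    stop("fold-changes must be positive")
  }
  base <- stats::runif(length(genes), base_range[1], base_range[2])
  m <- matrix(rep(base, length(tissues)), nrow = length(genes),
              dimnames = list(genes, tissues))
  if (!is.null(effects)) {
    for (r in seq_len(nrow(effects))) {
      m[effects$gene[r], effects$tissue[r]] <-
        m[effects$gene[r], effects$tissue[r]] * effects$fold[r]
    }
  }
  if (noise_sd > 0) {
    m <- m * 2^matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  }
  m
}

#' Synthetic qPCR Ct table with planted ddCt effects
#'
#' Emulates a stress-treatment time-course design: a reference gene plus
#' target genes measured over treatments and timepoints with `n_bio`
#' biological and `n_tech` technical replicates. A planted effect e for
#' (gene, treatment, timepoint) shifts the target Ct by e relative to the
#' timepoint-0 calibrator, so downstream 2^-ddCt recovers 2^-e exactly
#' when `sd = 0`.
#'
#' @param genes Target gene names.
#' @param treatments,timepoints Design factors (timepoint 0 is the
#'   calibrator and always included).
#' @param ddct_effects Data frame: gene, treatment, timepoint, effect.
#' @param sd Technical noise sd in Ct units.
#' @param n_bio,n_tech Replicate counts (default 3 biological x 3
#'   technical).
#' @param reference Reference gene name (must be non-empty).
#' @param seed Optional seed.
#' @return Long-format data frame: gene, treatment, timepoint, bio_rep,
#'   tech_rep, ct.
#' @export
generate_qpcr <- function(genes, treatments = c("H2O2", "NaCl", "PEG"),
                          timepoints = c(0, 3, 6, 12),
                          ddct_effects = NULL, sd = 0,
                          n_bio = 3, n_tech = 3,
                          reference = "GsoActin-11", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference) || !nzchar(reference)) {
    stop("design must include a reference gene")
  }
  if (!0 %in% timepoints) timepoints <- c(0, timepoints)
  effect_of <- function(g, tr, tp) {
    if (is.null(ddct_effects) || tp == 0) return(0)
    hit <- ddct_effects$gene == g & ddct_effects$treatment == tr &
      ddct_effects$timepoint == tp
    if (any(hit)) ddct_effects$effect[which(hit)[1]] else 0
  }
  base_dct <- stats::setNames(2 + 0.5 * seq_along(genes), genes)
  rows <- list()
  for (tr in treatments) {
    for (tp in sort(timepoints)) {
      for (b in seq_len(n_bio)) {
        ct_ref <- 20 + 0.3 * (b - 1)
        rows[[length(rows) + 1]] <- data.frame(
          gene = reference, treatment = tr, timepoint = tp, bio_rep = b,
          tech_rep = seq_len(n_tech),
          ct = ct_ref + stats::rnorm(n_tech, 0, sd),
          stringsAsFactors = FALSE)
        for (g in genes) {
          ct_t <- ct_ref + base_dct[[g]] + effect_of(g, tr, tp)
          rows[[length(rows) + 1]] <- data.frame(
            gene = g, treatment = tr, timepoint = tp, bio_rep = b,
            tech_rep = seq_len(n_tech),
            ct = ct_t + stats::rnorm(n_tech, 0, sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
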