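# End-to-end orchestration: identify -> properties -> phylogeny ->
# structure/promoters -> duplication/evolution -> expression, with TSV
# outputs and a machine-readable JSON report.

#' Run the full gene-family characterization pipeline
#'
#' Executes every stage for each species bundle and emits per-stage TSVs,
#' a Newick tree and a JSON summary. The run is deterministic under a
#' fixed seed.
#'
#' @param species List of species entries: each a list with `prefix` (a
#'   unique 3-letter species code) and either `dir` (a bundle directory
#'   for [read_bundle()]) or `bundle` (an in-memory bundle, e.g. from
#'   [generate_bundle()]).
#' @param family Family label used in member names (e.g., "GPX").
#' @param model A [domain_model()] describing the family signature.
#' @param out_dir Optional output directory for TSV/Newick/JSON artifacts.
#' @param min_cds Minimum CDS length (bp).
#' @param identity_filter Pre-phylogeny identity threshold (percent).
#' @param duplication_identity Duplicate-detection threshold (percent,
#'   strict).
#' @param tandem_gap Maximum intervening genes for tandem pairs.
#' @param lambda Synonymous substitution rate per site per year.
#' @param bootstrap Bootstrap replicate count (0 disables supports).
#' @param promoter_length Promoter window length (bp).
#' @param neutral_band Neutral Ka/Ks band.
#' @param dictionary Cis-element dictionary (default: shipped file).
#' @param fpkm Optional FPKM matrix (genes x tissues) for the expression
#'   stage.
#' @param qpcr Optional long-format qPCR Ct table.
#' @param qpcr_reference Reference gene for the qPCR stage.
#' @param alpha Significance level for Duncan groupings.
#' @param seed Seed controlling bootstrap resampling and the synteny null.
#' @return A report list (also written as `report.json` when `out_dir` is
#'   set) with per-species member tables, counts, trees (Newick strings),
#'   duplicate pairs, cis-element matrices and orthologue pairs.
#' @export
run_pipeline <- function(species, family, model, out_dir = NULL,
                         min_cds = 150, identity_filter = 50,
                         duplication_identity = 90, tandem_gap = 5,
                         lambda = 6.1e-9, bootstrap = 1000,
                         promoter_length = 2000,
                         neutral_band = c(0.95, 1.05),
                         dictionary = NULL,
                         fpkm = NULL, qpcr = NULL,
                         qpcr_reference = "GsoActin-11", alpha = 0.05,
                         seed = 1) {
  prefixes <- vapply(species, function(s) s$prefix, character(1))
  if (anyDuplicated(prefixes)) stop("species prefixes must be unique")
  stopifnot(min_cds > 0, identity_filter >= 0, duplication_identity > 0,
            tandem_gap >= 0, lambda > 0, promoter_length > 0)
  if (is.null(dictionary)) dictionary <- load_cis_dictionary()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  emit <- function(x, file) {
    if (!is.null(out_dir)) {
      utils::write.table(x, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(species = list())
  all_members <- list()

  for (sp in species) {
    pre <- sp$prefix
    bundle <- stage(paste0(pre, ":load"), {
      if (!is.null(sp$bundle)) sp$bundle else read_bundle(sp$dir)
    })
    members <- stage(paste0(pre, ":identify"), {
      identify_family(bundle, model, pre, family, min_cds = min_cds)
    })
    if (nrow(members) == 0) stop("no family members identified for ", pre)
    emit(members[, setdiff(names(members), c("cds", "protein"))],
         paste0(pre, "_members.tsv"))
    props <- stage(paste0(pre, ":props"), protein_properties(members))
    emit(props, paste0(pre, "_props.tsv"))

    structures <- stage(paste0(pre, ":structure"), {
      do.call(rbind, lapply(members$gene_id, function(g) {
        s <- structure_summary(bundle$models[[g]])
        data.frame(gene_id = g, exon_count = s$exon_count,
                   intron_count = s$intron_count, stringsAsFactors = FALSE)
      }))
    })
    emit(structures, paste0(pre, "_structures.tsv"))

    hits <- stage(paste0(pre, ":promoters"), {
      do.call(rbind, lapply(seq_len(nrow(members)), function(i) {
        prom <- suppressWarnings(extract_promoter(
          bundle$genome, bundle$models[[members$gene_id[i]]],
          length = promoter_length))
        scan_cis_elements(prom, dictionary, member = members$name[i])
      }))
    })
    emit(hits, paste0(pre, "_promoter_hits.tsv"))
    cis_mat <- element_count_matrix(hits, members$name,
                                    elements = dictionary$name)
    emit(cbind(member = rownames(cis_mat), as.data.frame(cis_mat)),
         paste0(pre, "_cis_matrix.tsv"))

    gene_order <- if (!is.null(bundle$gene_order)) bundle$gene_order else {
      do.call(rbind, lapply(bundle$models, function(m) {
        data.frame(id = m$gene_id, chromosome = m$chromosome,
                   start = m$start, stringsAsFactors = FALSE)
      }))
    }
    pairs <- stage(paste0(pre, ":evolve"), {
      duplicate_pair_table(members, gene_order,
                           identity_threshold = duplication_identity,
                           max_gap = tandem_gap, lambda = lambda,
                           neutral_band = neutral_band)
    })
    emit(pairs, paste0(pre, "_pairs.tsv"))

    chrom_counts <- table(members$chr_label)
    report$species[[pre]] <- list(
      n_members = nrow(members),
      per_chromosome = as.list(chrom_counts),
      members = members$name,
      duplicate_pairs = pairs,
      structures = structures)
    all_members[[pre]] <- members
  }

  # phylogeny over the pooled members of all species
  pooled <- do.call(rbind, lapply(all_members, function(m)
    m[, c("name", "protein")]))
  seqs <- stats::setNames(pooled$protein, pooled$name)
  tree_nwk <- NA_character_
  if (length(seqs) >= 4) {
    phylo <- stage("phylo", {
      kept <- filter_by_identity(seqs, threshold = identity_filter)
      msa <- progressive_align(kept)
      if (bootstrap > 0) {
        bootstrap_support(msa, replicates = bootstrap, seed = seed)
      } else {
        neighbor_joining(poisson_distance(msa))
      }
    })
    tree_nwk <- ape::write.tree(phylo)
    if (!is.null(out_dir)) {
      writeLines(tree_nwk, file.path(out_dir, "tree.nwk"))
    }
  }
  report$tree <- tree_nwk

  # cross-species orthologue pairs (100% identity) and synteny links
  if (length(all_members) >= 2) {
    prefs <- names(all_members)
    orth <- list()
    links <- list()
    for (i in seq_len(length(prefs) - 1)) {
      for (j in (i + 1):length(prefs)) {
        qa <- stats::setNames(all_members[[i]]$protein,
                              all_members[[i]]$name)
        sb <- stats::setNames(all_members[[j]]$protein,
                              all_members[[j]]$name)
        ln <- synteny_links(qa, sb, seed = seed)
        links[[length(links) + 1]] <- ln
        if (nrow(ln)) {
          o <- ln[ln$identity >= 100, c("query", "subject"), drop = FALSE]
          if (nrow(o)) orth[[length(orth) + 1]] <- o
        }
      }
    }
    links <- if (length(links)) do.call(rbind, links) else NULL
    orth <- if (length(orth)) do.call(rbind, orth) else
      data.frame(query = character(), subject = character())
    if (!is.null(links)) emit(links, "synteny_links.tsv")
    report$orthologue_pairs <- orth
    report$n_orthologue_pairs <- nrow(orth)
  }

  if (!is.null(fpkm)) {
    hm <- stage("expression", heatmap_matrix(fpkm))
    emit(cbind(gene = rownames(hm), as.data.frame(hm)),
         "expression_heatmap.tsv")
    report$tissue_profiles <- tissue_profile_report(fpkm)
  }
  if (!is.null(qpcr)) {
    qres <- stage("qpcr", {
      targets <- setdiff(unique(qpcr$gene), qpcr_reference)
      do.call(rbind, lapply(targets, function(g) {
        cbind(gene = g,
              relative_expression(qpcr, g, qpcr_reference))
      }))
    })
    emit(qres, "qpcr_results.tsv")
    report$qpcr <- qres
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(n_species = length(species),
           species = lapply(report$species, function(s) {
             list(n_members = s$n_members,
                  per_chromosome = s$per_chromosome,
                  members = s$members,
                  duplicate_pairs = s$duplicate_pairs)
           }),
           n_orthologue_pairs = report$n_orthologue_pairs,
           tree = report$tree),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(report)
}
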