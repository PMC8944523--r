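# Synthetic bundle generator: determinism, ground-truth plumbing,
# controlled-divergence evolution, expression and qPCR emulation.

test_that("fixed seed reproduces byte-identical bundle files", {
  cfg <- synthetic_config(seed = 11, n_family_genes = 4,
                          n_decoy_genes = 4, n_multi_isoform_loci = 1,
                          n_short_cds_decoys = 1,
                          tandem_pairs = list(c(0.05, 0.01)),
                          segmental_pairs = list())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_bundle(cfg, out_dir = d1)
  generate_bundle(cfg, out_dir = d2)
  files <- c("genome.fa", "genes.gff3", "cds.fa", "protein.fa",
             "ground_truth.json")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("zero family genes yields a decoy-only bundle", {
  cfg <- synthetic_config(seed = 2, n_family_genes = 0, n_decoy_genes = 3,
                          n_multi_isoform_loci = 0, n_short_cds_decoys = 1,
                          tandem_pairs = list(), segmental_pairs = list())
  b <- generate_bundle(cfg)
  expect_length(b$truth$family_gene_ids, 0)
  expect_true(all(grepl("^(DECOY|SDEC)", names(b$models))))
  mem <- identify_family(b, default_model(), "Gso", "GPX")
  expect_equal(nrow(mem), 0)
})

test_that("bundle structure honours the configured gene classes", {
  b <- fixture_bundle()
  truth <- b$truth
  # multi-isoform loci have two transcripts with different CDS lengths
  for (g in truth$multi_isoform_ids) {
    txs <- b$models[[g]]$transcripts
    expect_gte(length(txs), 2)
    lens <- vapply(txs, function(t) t$cds_length, numeric(1))
    expect_gt(max(lens), min(lens))
  }
  # short decoys have CDS < 150 bp
  for (g in truth$short_cds_decoy_ids) {
    lens <- vapply(b$models[[g]]$transcripts, function(t) t$cds_length,
                   numeric(1))
    expect_lt(max(lens), 150)
  }
  # strands mixed, coordinates GFF3-consistent
  expect_setequal(unique(b$gene_order$strand), c("+", "-"))
  expect_true(all(b$gene_order$start >= 1))
  expect_true(all(b$gene_order$end > b$gene_order$start))
})

test_that("infeasible layouts fail explicitly", {
  cfg <- synthetic_config(seed = 1, chromosome_length = 8000,
                          n_chromosomes = 2,
                          segmental_pairs = list(c(0.1, 0.03)))
  expect_error(generate_bundle(cfg), "do not fit")
})

test_that("evolve_duplicate respects trivial and degenerate targets", {
  set.seed(5)
  cds <- genefamkit:::back_translate(
    paste(sample(genefamkit:::AA20, 100, replace = TRUE), collapse = ""))
  expect_identical(evolve_duplicate(cds, 0, 0), cds)
  expect_error(evolve_duplicate(cds, Inf, 0.01), "undefined")
  expect_error(evolve_duplicate(cds, -0.1, 0), ">= 0")
  mut <- evolve_duplicate(cds, 0.05, 0.01, seed = 3)
  expect_equal(nchar(mut), nchar(cds))
  expect_true(genefamkit:::is_clean_orf(mut))
})

test_that("mean NG86 estimates recover evolution targets within 15%", {
  set.seed(9)
  prot <- paste(sample(genefamkit:::AA20, 500, replace = TRUE),
                collapse = "")
  cds <- genefamkit:::back_translate(prot)
  est <- vapply(1:60, function(i) {
    mut <- evolve_duplicate(cds, 0.05, 0.01, seed = i)
    kk <- ng86_ka_ks(codon_align(cds, mut))
    c(kk$ks, kk$ka)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) / 0.05 - 1), 0.15)
  expect_lt(abs(mean(est[2, ]) / 0.01 - 1), 0.15)
})

test_that("expression generator plants exact fold-changes at zero noise", {
  eff <- data.frame(gene = "gene03", tissue = "leaf", fold = 8)
  m <- generate_expression(5, c("root", "leaf", "seed"), effects = eff,
                           noise_sd = 0, seed = 4)
  expect_true(all(m >= 0))
  expect_equal(m["gene03", "leaf"] / m["gene03", "root"], 8)
  # detected as the max mean-centered value in the leaf column
  hm <- heatmap_matrix(m)
  expect_equal(rownames(hm)[which.max(hm[, "leaf"])], "gene03")
  m2 <- generate_expression(5, c("root", "leaf", "seed"), effects = eff,
                            noise_sd = 0, seed = 4)
  expect_identical(m, m2)
  expect_error(generate_expression(
    5, "root", effects = data.frame(gene = "gene01", tissue = "root",
                                    fold = -2)), "positive")
})

test_that("qPCR generator round-trips planted ddCt effects", {
  eff <- data.frame(gene = c("g1", "g1"),
                    treatment = c("NaCl", "H2O2"),
                    timepoint = c(12, 6), effect = c(-1, 0))
  q <- generate_qpcr("g1", ddct_effects = eff, sd = 0, seed = 2)
  rel <- relative_expression(q, "g1", "GsoActin-11")
  expect_equal(rel$mean_rel_expr[rel$treatment == "NaCl" &
                                   rel$timepoint == 12], 2)
  expect_equal(rel$mean_rel_expr[rel$treatment == "H2O2" &
                                   rel$timepoint == 6], 1)
  expect_error(generate_qpcr("g1", reference = ""), "reference")
})
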