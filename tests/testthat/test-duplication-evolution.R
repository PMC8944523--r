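# Duplicate detection/classification, NG86 Ka/Ks, selection and dating.

test_that("duplicate detection uses a strict >90% identity rule", {
  prot <- paste(rep("MKLVVFACDE", 10), collapse = "")  # 100 aa
  # 10 mismatches -> exactly 90% identity: must NOT be reported
  at90 <- paste0(strrep("W", 10), substr(prot, 11, 100))
  pairs <- detect_duplicates(c(a = prot, b = at90))
  expect_equal(nrow(pairs), 0)
  # 9 mismatches -> 91%: reported
  at91 <- paste0(strrep("W", 9), substr(prot, 10, 100))
  pairs2 <- detect_duplicates(c(a = prot, b = at91))
  expect_equal(nrow(pairs2), 1)
  expect_equal(pairs2$identity, 91)
  # identical paralogs at 100%
  pairs3 <- detect_duplicates(c(a = prot, b = prot))
  expect_equal(pairs3$identity, 100)
})

test_that("tandem/segmental classification follows the 5-gene rule", {
  mk_order <- function(n, chrom = "chr1") {
    data.frame(id = paste0(chrom, "_g", seq_len(n)), chromosome = chrom,
               start = seq_len(n) * 1000)
  }
  ord <- mk_order(10)
  # 3 intervening genes -> tandem
  expect_equal(classify_duplication("chr1_g1", "chr1_g5", ord), "tandem")
  # exactly 5 intervening -> tandem; 6 -> segmental
  expect_equal(classify_duplication("chr1_g1", "chr1_g7", ord), "tandem")
  expect_equal(classify_duplication("chr1_g1", "chr1_g8", ord), "segmental")
  # different chromosomes -> segmental
  ord2 <- rbind(ord, mk_order(3, "chr2"))
  expect_equal(classify_duplication("chr1_g1", "chr2_g1", ord2),
               "segmental")
  expect_equal(classify_duplication("chr1_g1", "missing", ord), "unknown")
})

test_that("codon alignment propagates protein gaps and rejects frameshifts", {
  cds <- "ATGAAATTTGGGCCCTAA"
  aln <- codon_align(cds, cds)
  expect_identical(aln$a, aln$b)
  expect_false(any(grepl("-", aln$a)))
  # whole-codon deletion -> one 3-bp gap, gapped column dropped
  del <- "ATGAAAGGGCCCTAA"
  aln2 <- codon_align(cds, del)
  expect_equal(length(aln2$a), 4)          # 5 codons minus the gapped one
  expect_equal(sum(strsplit(aln2$prot_b, "")[[1]] == "-"), 1)
  expect_error(codon_align("ATGAAATT", cds), "divisible")
  expect_error(codon_align("ATGTAAAAATTT", cds), "internal stop")
})

test_that("NG86 handles pure synonymous and nonsynonymous single changes", {
  base <- strrep("ATGAAACCCGGGTTTCAT", 2)  # 12 codons
  syn <- sub("TTT", "TTC", base)           # F -> F
  kk <- ng86_ka_ks(codon_align(paste0(base, "TAA"), paste0(syn, "TAA")))
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
  non <- sub("AAA", "GAA", base)           # K -> E
  kk2 <- ng86_ka_ks(codon_align(paste0(base, "TAA"), paste0(non, "TAA")))
  expect_equal(kk2$ks, 0)
  expect_gt(kk2$ka, 0)
  ident <- ng86_ka_ks(codon_align(paste0(base, "TAA"), paste0(base, "TAA")))
  expect_equal(c(ident$ka, ident$ks), c(0, 0))
})

test_that("NG86 is symmetric and dominates uncorrected proportions", {
  set.seed(10)
  prot <- paste(sample(genefamkit:::AA20, 120, replace = TRUE),
                collapse = "")
  a <- genefamkit:::back_translate(prot)
  b <- evolve_duplicate(a, 0.08, 0.03, seed = 2)
  ab <- ng86_ka_ks(codon_align(a, b))
  ba <- ng86_ka_ks(codon_align(b, a))
  expect_equal(ab$ks, ba$ks)
  expect_equal(ab$ka, ba$ka)
  expect_gte(ab$ks, ab$ps)
  expect_gte(ab$ka, ab$pn)
})

test_that("NG86 matches the pathway-enumeration oracle on codon pairs", {
  # sampled 1- and 2-difference sense-codon pairs; the exhaustive sweep
  # over every such pair runs in the acceptance suite
  sense <- sense_codons()
  set.seed(11)
  # shared context codons keep the difference proportions inside the
  # Jukes-Cantor domain even for doubly-synonymous codon pairs
  pad <- c("ATG", "GGG", "CCC", "GCT")
  for (rep in 1:60) {
    a <- sample(sense, 1)
    s <- strsplit(a, "")[[1]]
    npos <- sample(1:2, 1)
    pos <- sample(1:3, npos)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    b <- paste(s, collapse = "")
    if (!(b %in% sense)) next
    ca <- c(pad, a); cb <- c(pad, b)
    mine <- ng86_ka_ks(list(a = ca, b = cb))
    orac <- oracle_ng86(ca, cb)
    expect_equal(mine$S, orac$S, tolerance = 1e-12)
    expect_equal(mine$sd, orac$sd, tolerance = 1e-12)
    expect_equal(mine$nd, orac$nd, tolerance = 1e-12)
    expect_equal(mine$ks, orac$ks, tolerance = 1e-12)
    expect_equal(mine$ka, orac$ka, tolerance = 1e-12)
  }
})

test_that("selection classes follow the neutral band and degenerate rules", {
  expect_equal(classify_selection(ratio = 1.298)$class, "positive")
  expect_equal(classify_selection(ratio = 0.656)$class, "purifying")
  expect_equal(classify_selection(ratio = 0.970)$class, "neutral")
  expect_equal(classify_selection(ratio = 1.051)$class, "positive")
  expect_equal(classify_selection(ratio = 0.941)$class, "purifying")
  deg <- classify_selection(ka = 0.033, ks = 0)
  expect_equal(deg$class, "purifying")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$ratio))
  expect_equal(classify_selection(ka = 0, ks = 0)$class, "identical")
})

test_that("divergence dating applies T = Ks / (2 lambda)", {
  expect_equal(divergence_time(0.051), 4.18)
  expect_equal(divergence_time(0.122), 10.00)
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.1, lambda = 1e-8), 5)
  expect_error(divergence_time(-0.01), "negative")
})

test_that("synthetic pairs are detected with correct types and dates", {
  b <- fixture_bundle()
  mem <- identify_family(b, default_model(), "Gso", "GPX")
  pairs <- duplicate_pair_table(mem, b$gene_order)
  truth <- b$truth$duplicate_pairs
  expect_equal(nrow(pairs), length(truth))
  id_of <- stats::setNames(mem$name, mem$gene_id)
  for (pt in truth) {
    row <- pairs[(pairs$a == id_of[[pt$a]] & pairs$b == id_of[[pt$b]]) |
                   (pairs$a == id_of[[pt$b]] & pairs$b == id_of[[pt$a]]), ]
    expect_equal(nrow(row), 1)
    expect_equal(row$type, pt$type)
    expect_gt(row$identity, 90)
    expect_equal(row$time_mya, divergence_time(row$ks))
  }
})

test_that("synteny links keep near-identical proteins and drop noise", {
  b <- fixture_bundle()
  mem <- identify_family(b, default_model(), "Gso", "GPX")
  fam <- stats::setNames(mem$protein, paste0("q_", mem$name))
  fam2 <- stats::setNames(mem$protein, paste0("s_", mem$name))
  links <- synteny_links(fam, fam2, seed = 5)
  self <- links[sub("^q_", "", links$query) == sub("^s_", "", links$subject), ]
  expect_equal(nrow(self), nrow(mem))
  expect_true(all(self$bin == ">90"))
  # random decoys produce no significant links
  set.seed(12)
  rnd1 <- stats::setNames(replicate(3, paste(
    sample(genefamkit:::AA20, 150, replace = TRUE), collapse = "")),
    paste0("r", 1:3))
  rnd2 <- stats::setNames(replicate(3, paste(
    sample(genefamkit:::AA20, 150, replace = TRUE), collapse = "")),
    paste0("u", 1:3))
  expect_equal(nrow(synteny_links(rnd1, rnd2, seed = 5)), 0)
})
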