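# Exon-intron summaries, promoter windows and cis-element scanning.

test_that("structure summary counts exons, introns and UTRs", {
  exons <- data.frame(start = c(1001, 1501, 2201), end = c(1200, 1700, 2500))
  cds <- data.frame(start = c(1101, 1501, 2201), end = c(1200, 1700, 2300))
  g <- toy_gene(exons = exons, cds = cds)
  s <- structure_summary(g)
  expect_equal(s$exon_count, 3)
  expect_equal(s$intron_count, 2)
  expect_equal(s$utr_count, 2)
  expect_true(all(diff(s$segments$start) > 0))
  # one exon -> no introns
  g1 <- toy_gene(exons = data.frame(start = 100, end = 400),
                 cds = data.frame(start = 150, end = 350))
  expect_equal(structure_summary(g1)$intron_count, 0)
  # overlapping exons are an error
  bad <- toy_gene(exons = data.frame(start = c(100, 150), end = c(200, 250)),
                  cds = data.frame(start = 100, end = 250))
  expect_error(structure_summary(bad), "overlapping")
})

test_that("synthetic intron counts match ground truth", {
  b <- fixture_bundle()
  for (g in b$truth$family_gene_ids) {
    s <- structure_summary(b$models[[g]])
    expect_equal(s$intron_count, unname(b$truth$intron_counts[[g]]),
                 info = g)
  }
})

test_that("promoter window arithmetic is exact on both strands", {
  set.seed(6)
  chrom <- genefamkit:::random_dna(6000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  plus <- toy_gene(strand = "+",
                   exons = data.frame(start = 4900, end = 5600),
                   cds = data.frame(start = 5000, end = 5500))
  p <- extract_promoter(genome, plus)
  expect_equal(attr(p, "window"), c(3000, 4999))
  expect_equal(p, substr(chrom, 3000, 4999), ignore_attr = TRUE)
  minus <- toy_gene(strand = "-",
                    exons = data.frame(start = 2400, end = 3100),
                    cds = data.frame(start = 2500, end = 3000))
  m <- extract_promoter(genome, minus)
  expect_equal(attr(m, "window"), c(3001, 5000))
  expect_equal(m, genefamkit:::revcomp(substr(chrom, 3001, 5000)),
               ignore_attr = TRUE)
  # strand symmetry: a minus-strand gene equals the plus-strand extraction
  # on the reverse-complemented chromosome
  rc_chrom <- genefamkit:::revcomp(chrom)
  L <- nchar(chrom)
  flip <- function(pos) L - pos + 1
  plus_on_rc <- toy_gene(strand = "+",
                         exons = data.frame(start = flip(3100),
                                            end = flip(2400)),
                         cds = data.frame(start = flip(3000),
                                          end = flip(2500)))
  p2 <- extract_promoter(Biostrings::DNAStringSet(c(chr1 = rc_chrom)),
                         plus_on_rc)
  expect_equal(as.character(m), as.character(p2))
  # truncation at the chromosome start
  near <- toy_gene(strand = "+",
                   exons = data.frame(start = 1400, end = 1800),
                   cds = data.frame(start = 1500, end = 1700))
  expect_warning(pt <- extract_promoter(genome, near), "truncated")
  expect_equal(nchar(pt), 1499)
  expect_equal(attr(pt, "window"), c(1, 1499))
})

test_that("cis-element scanning finds direct and reverse-strand matches", {
  dict <- data.frame(name = c("TGACG-motif", "CGTCA-motif"),
                     consensus = c("TGACG", "CGTCA"),
                     category = "hormone")
  hits <- scan_cis_elements("AATGACGTT", dict)
  fw <- hits[hits$element == "TGACG-motif" & hits$strand == "+", ]
  expect_equal(fw$position, 3)
  # CGTCA is the reverse complement of TGACG: one minus-strand hit
  rc <- hits[hits$element == "CGTCA-motif" & hits$strand == "-", ]
  expect_equal(nrow(rc), 1)
  expect_equal(rc$position, 3)
  # IUPAC degeneracy
  dict2 <- data.frame(name = "MYC", consensus = "CANNTG", category = "s")
  h2 <- scan_cis_elements("GGCATATGGG", dict2, both_strands = FALSE)
  expect_equal(h2$position, 3)
})

test_that("dictionary validates IUPAC codes at load", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus\tcategory", "BAD\tACZTG\tstress"), tmp)
  expect_error(load_cis_dictionary(tmp), "IUPAC")
  good <- load_cis_dictionary()
  expect_true(all(c("ABRE", "TGACG-motif", "MYB", "MBS") %in% good$name))
})

test_that("planted promoter elements are recovered at recorded positions", {
  b <- fixture_bundle()
  dict <- load_cis_dictionary()
  plants <- b$truth$promoter_plants
  for (g in unique(plants$gene_id)) {
    prom <- extract_promoter(b$genome, b$models[[g]])
    hits <- scan_cis_elements(prom, dict, member = g)
    pg <- plants[plants$gene_id == g, ]
    for (el in unique(pg$element)) {
      got <- hits[hits$element == el & hits$strand == "+", "position"]
      expect_setequal(got, pg$window_pos[pg$element == el])
    }
  }
})

test_that("count matrix sums to the number of hits and filters by total", {
  members <- c("m1", "m2")
  hits <- data.frame(member = c("m1", "m1", "m2"),
                     element = c("ABRE", "ABRE", "MYB"),
                     position = c(1, 10, 5), strand = "+",
                     match = "x")
  m <- element_count_matrix(hits, members)
  expect_equal(sum(m), nrow(hits))
  expect_equal(m["m1", "ABRE"], 2L)
  empty <- element_count_matrix(hits[0, ], members, elements = "ABRE")
  expect_true(all(empty == 0))
  # threshold keeps only elements with totals strictly greater
  big <- data.frame(member = "m1", element = rep(c("A", "B"), c(20, 3)),
                    position = 1, strand = "+", match = "x")
  mf <- element_count_matrix(big, "m1", min_total = 15)
  expect_identical(colnames(mf), "A")
})
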