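# Alignment, distances, neighbor joining and bootstrap.

test_that("global alignment identity matches gapless enumeration on 3-mers", {
  # with gaps this costly the optimal global alignment of equal-length
  # short sequences is the diagonal, so identity = matches / length
  bases <- c("A", "C", "G", "T")
  set.seed(1)
  for (rep in 1:40) {
    a <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    b <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    expected <- 100 * sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]) / 3
    got <- global_align(a, b, type = "dna", gap_open = 25, gap_extend = 5)
    expect_equal(got$identity, expected, info = paste(a, b))
  }
})

test_that("global alignment basic examples and symmetry", {
  expect_equal(global_align("MKLV", "MKLV")$identity, 100)
  got <- global_align("AAAA", "AATT", type = "dna", gap_open = 25,
                      gap_extend = 5)
  expect_equal(got$identity, 50)
  ab <- global_align("MKLVVF", "MKLACDEF")$identity
  ba <- global_align("MKLACDEF", "MKLVVF")$identity
  expect_equal(ab, ba)
})

test_that("identity filter drops only sequences far from every other", {
  two <- c(a = "MKLVVFACDE", b = "MKLVVFACDE")
  expect_identical(filter_by_identity(two), two)
  one <- two[1]
  expect_identical(filter_by_identity(one), one)
  fam <- c(x = "MKLVVFACDEMKLVVFACDE", y = "MKLVVFACDEMKLVVFACDD",
           z = "WWHHGGPPRRSSNNQQTTYY")
  kept <- filter_by_identity(fam, threshold = 50)
  expect_setequal(names(kept), c("x", "y"))
  expect_length(filter_by_identity(fam, threshold = 0), 3)
})

test_that("progressive alignment handles identity and single indels", {
  same <- c(a = "MKLVVFACDE", b = "MKLVVFACDE", c = "MKLVVFACDE")
  msa <- progressive_align(same)
  expect_identical(unname(msa), unname(same))  # gap-free
  indel <- c(a = "MKLVVFACDE", b = "MKLVVFACDE", c = "MKLVVACDE")
  msa2 <- progressive_align(indel)
  expect_equal(length(unique(nchar(msa2))), 1)
  expect_equal(sum(strsplit(msa2[["c"]], "")[[1]] == "-"), 1)
  gsub_g <- function(x) gsub("-", "", x)
  expect_identical(vapply(msa2, gsub_g, character(1))[names(indel)], indel)
  # input order irrelevant for identical sequences
  msa3 <- progressive_align(same[c(2, 3, 1)])
  expect_identical(sort(names(msa3)), sort(names(same)))
  expect_equal(unique(nchar(msa3)), 10L)
})

test_that("Poisson distance matches the closed form and dominates p", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  expect_equal(poisson_distance(msa)["a", "b"], 0)
  msa2 <- c(a = "AAAAAAAAAA", b = "AAAAACCCCC")
  expect_equal(poisson_distance(msa2)["a", "b"], -log(0.5))
  msa3 <- c(a = "AAAAAAAAAA", b = "CAAAAAAAAA")
  expect_equal(poisson_distance(msa3)["a", "b"], -log(0.9))
  # pairwise deletion and domination over p-distance
  set.seed(2)
  aas <- genefamkit:::AA20
  for (rep in 1:10) {
    r1 <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    r2 <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    m <- c(x = r1, y = r2)
    d <- poisson_distance(m)["x", "y"]
    p <- mean(strsplit(r1, "")[[1]] != strsplit(r2, "")[[1]])
    if (p < 1) expect_gte(d, p)
  }
  expect_warning(poisson_distance(c(a = "AAAA", b = "CCCC")), ">= 1")
})

test_that("3-taxon NJ solves the closed-form star lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["a", "b"], 3)
  expect_equal(cp["a", "c"], 4)
  expect_equal(cp["b", "c"], 5)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees exactly (n <= 8)", {
  skip_if_not_installed("phangorn")
  set.seed(4)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1)))
      dm <- ape::cophenetic.phylo(tr)
      my <- neighbor_joining(dm)
      expect_equal(phangorn::RF.dist(ape::unroot(my), tr), 0)
      cp <- ape::cophenetic.phylo(my)[rownames(dm), colnames(dm)]
      expect_lt(max(abs(cp - dm)), 1e-8)
      # taxon order must not change the unrooted topology
      perm <- sample(n)
      my2 <- neighbor_joining(dm[perm, perm])
      expect_equal(phangorn::RF.dist(ape::unroot(my2), tr), 0)
    }
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 7
    tr <- ape::unroot(ape::rtree(n))
    dm <- ape::cophenetic.phylo(tr)
    noise <- matrix(stats::runif(n * n, 0, 0.02), n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dmn <- dm + noise
    skip_if_not_installed("phangorn")
    expect_equal(phangorn::RF.dist(ape::unroot(neighbor_joining(dmn)),
                                   ape::unroot(ape::nj(dmn))), 0)
  }
})

test_that("bootstrap supports are deterministic, bounded, and saturate", {
  msa <- c(a = "KKKKKKKKKKAA", b = "KKKKKKKKKKAA",
           c = "RRRRRRRRRRAA", d = "RRRRRRRRRRAA")
  bt <- bootstrap_support(msa, replicates = 50, seed = 3)
  sup <- attr(bt, "supports")
  expect_true(all(sup >= 0 & sup <= 100))
  expect_equal(unname(sup[["c|d"]]), 100)
  bt2 <- bootstrap_support(msa, replicates = 50, seed = 3)
  expect_identical(attr(bt2, "supports"), sup)
  # replicates = 0: tree without supports
  bt0 <- bootstrap_support(msa, replicates = 0)
  expect_true(all(bt0$node.label == ""))
  # column order of the MSA does not change supports
  perm_cols <- function(s, idx) paste(strsplit(s, "")[[1]][idx],
                                      collapse = "")
  idx <- c(7:12, 1:6)
  msa_p <- vapply(msa, perm_cols, character(1), idx = idx)
  btp <- bootstrap_support(msa_p, replicates = 50, seed = 3)
  expect_identical(attr(btp, "supports"), sup)
})
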