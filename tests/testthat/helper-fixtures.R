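# Shared fixtures and independent oracles for the test suite.

default_model <- function() {
  domain_model("FAM", consensus = genefamkit:::DEFAULT_DOMAIN_CONSENSUS)
}

# one default bundle per session, reused across test files
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_bundle(synthetic_config(seed = 7))
    cache
  }
})

# Independent brute-force Nei-Gojobori oracle for a pair of codon vectors.
# Recursive pathway enumeration, written without the package's lookup
# tables: synonymous sites counted by direct mutation of each position,
# differences averaged over all orderings of the differing positions,
# pathways through stops dropped (all-blocked pairs fall back to counting
# stop steps as nonsynonymous).
oracle_ng86 <- function(codons_a, codons_b) {
  gc <- Biostrings::GENETIC_CODE
  aa_of <- function(cd) unname(gc[cd])
  syn_sites_codon <- function(cd) {
    ref <- aa_of(cd)
    total <- 0
    for (p in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (substr(cd, p, p) == nt) next
        alt <- cd
        substr(alt, p, p) <- nt
        if (aa_of(alt) != "*" && aa_of(alt) == ref) total <- total + 1 / 3
      }
    }
    total
  }
  paths <- function(cur, target, remaining) {
    # returns matrix with rows (sd, nd, blocked) over all orderings
    if (!length(remaining)) return(matrix(c(0, 0, 0), nrow = 3))
    out <- NULL
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      step_syn <- aa_of(nxt) != "*" && aa_of(nxt) == aa_of(cur)
      step_blocked <- aa_of(nxt) == "*" && length(remaining) > 1
      rest <- paths(nxt, target, setdiff(remaining, p))
      rest[1, ] <- rest[1, ] + as.numeric(step_syn)
      rest[2, ] <- rest[2, ] + as.numeric(!step_syn)
      rest[3, ] <- pmax(rest[3, ], as.numeric(step_blocked))
      out <- cbind(out, rest)
    }
    out
  }
  S <- 0; sd <- 0; nd <- 0
  for (k in seq_along(codons_a)) {
    a <- codons_a[k]; b <- codons_b[k]
    S <- S + (syn_sites_codon(a) + syn_sites_codon(b)) / 2
    diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(diffs)) {
      pw <- paths(a, b, diffs)
      ok <- pw[3, ] == 0
      use <- if (any(ok)) pw[, ok, drop = FALSE] else pw
      sd <- sd + mean(use[1, ])
      nd <- nd + mean(use[2, ])
    }
  }
  N <- 3 * length(codons_a) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd,
       ks = jc(if (S > 0) sd / S else 0),
       ka = jc(if (N > 0) nd / N else 0))
}

# all sense codons
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# hand-built single-transcript gene model for coordinate tests
toy_gene <- function(gene_id = "g1", chromosome = "chr1", strand = "+",
                     exons, cds) {
  list(gene_id = gene_id, chromosome = chromosome, strand = strand,
       start = min(exons$start), end = max(exons$end),
       transcripts = list(t1 = list(
         transcript_id = "t1",
         cds_length = sum(cds$end - cds$start + 1L),
         exons = exons, cds = cds)))
}
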