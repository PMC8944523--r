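# Nei-Gojobori (1986) synonymous/nonsynonymous rate estimation.
#
# Site counting: at each codon position the synonymous fraction is the
# proportion of the 3 alternative nucleotides whose substitution leaves the
# amino acid unchanged; changes creating a stop codon count as
# nonsynonymous. Observed differences between two codons are partitioned by
# averaging over all minimal mutational pathways (permutations of the
# differing positions) with equal weights, excluding pathways that pass
# through a stop codon; if every pathway is blocked the stop-containing
# pathways are used with stop steps counted as nonsynonymous.

#' Per-codon synonymous site counts and pairwise pathway difference tables
#'
#' Memoized 64-codon tables: `s_sites[codon]` = number of synonymous sites
#' (0..3), `SD[a, b]` / `ND[a, b]` = pathway-averaged synonymous and
#' nonsynonymous difference counts between codons `a` and `b`.
#' @noRd
ng86_tables <- function() {
  if (!is.null(.gfk_cache$ng86)) return(.gfk_cache$ng86)
  codons <- all_codons()
  aa <- codon_aa(codons)
  n <- length(codons)

  mutate1 <- function(codon, pos, base) {
    s <- strsplit(codon, "")[[1]]
    s[pos] <- base
    paste(s, collapse = "")
  }

  s_sites <- vapply(codons, function(cd) {
    a0 <- codon_aa(cd)
    if (a0 == "*") return(NA_real_)
    tot <- 0
    for (pos in 1:3) {
      cur <- substr(cd, pos, pos)
      alts <- setdiff(BASES, cur)
      syn <- vapply(alts, function(b) {
        a1 <- codon_aa(mutate1(cd, pos, b))
        a1 != "*" && a1 == a0
      }, logical(1))
      tot <- tot + sum(syn) / 3
    }
    tot
  }, numeric(1))

  # pathway-averaged differences
  SD <- matrix(0, n, n, dimnames = list(codons, codons))
  ND <- matrix(0, n, n, dimnames = list(codons, codons))
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

  path_counts <- function(a, b, diff_pos, order) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (k in seq_along(order)) {
      pos <- diff_pos[order[k]]
      nxt <- mutate1(cur, pos, substr(b, pos, pos))
      aa_cur <- codon_aa(cur); aa_nxt <- codon_aa(nxt)
      if (aa_nxt == "*" && k < length(order)) blocked <- TRUE
      if (aa_cur == aa_nxt && aa_nxt != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }

  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    for (j in seq_len(n)) {
      if (aa[j] == "*" || i == j) next
      a <- codons[i]; b <- codons[j]
      diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      k <- length(diff_pos)
      if (k == 1L) {
        res <- path_counts(a, b, diff_pos, 1L)
        SD[i, j] <- res["sd"]; ND[i, j] <- res["nd"]
      } else {
        perms <- if (k == 2L) perms2 else perms3
        mat <- vapply(perms, function(p) path_counts(a, b, diff_pos, p),
                      numeric(3))
        ok <- mat["blocked", ] == 0
        use <- if (any(ok)) mat[, ok, drop = FALSE] else mat
        SD[i, j] <- mean(use["sd", ]); ND[i, j] <- mean(use["nd", ])
      }
    }
  }
  .gfk_cache$ng86 <- list(codons = codons, s_sites = s_sites, SD = SD, ND = ND)
  .gfk_cache$ng86
}

#' Nei-Gojobori Ka/Ks from a pairwise codon alignment
#'
#' Estimates synonymous (Ks) and nonsynonymous (Ka) substitution rates per
#' site between two aligned coding sequences using Nei-Gojobori counting
#' with equal pathway weights and the Jukes-Cantor correction
#' d = -(3/4) log(1 - (4/3) p).
#'
#' @param aln A codon alignment as returned by [codon_align()]: a list with
#'   character vectors `a` and `b` of equal length holding aligned codons
#'   (gap-containing codon columns already removed), or two CDS strings of
#'   equal length passed as `aln = list(a=, b=)`.
#' @return A list with elements `ka`, `ks`, `ratio` (Ka/Ks; `NA` when Ks is
#'   0), `S`, `N` (potential sites), `sd`, `nd` (observed differences),
#'   `ps`, `pn` (uncorrected proportions).
#' @details Fails explicitly when a difference proportion reaches 3/4, where
#'   the Jukes-Cantor correction is undefined.
#' @export
#' @examples
#' aln <- codon_align("ATGTTTAAACCC", "ATGTTCAAACCC")
#' ng86_ka_ks(aln)
ng86_ka_ks <- function(aln) {
  a <- aln$a
  b <- aln$b
  if (length(a) == 1L && nchar(a[1]) > 3L) a <- split_codons(a)
  if (length(b) == 1L && nchar(b[1]) > 3L) b <- split_codons(b)
  if (length(a) != length(b)) stop("codon vectors differ in length")
  if (length(a) < 1L) stop("need at least one comparable codon column")
  tab <- ng86_tables()
  ia <- match(a, tab$codons)
  ib <- match(b, tab$codons)
  if (anyNA(ia) || anyNA(ib)) stop("non-ACGT codon in alignment")
  if (any(codon_aa(a) == "*") || any(codon_aa(b) == "*")) {
    stop("stop codon inside alignment")
  }
  S <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  N <- 3 * length(a) - S
  idx <- cbind(ia, ib)
  sd <- sum(tab$SD[idx])
  nd <- sum(tab$ND[idx])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p, what) {
    if (p >= 0.75) {
      stop("proportion of ", what, " differences (", signif(p, 4),
           ") >= 3/4: Jukes-Cantor correction undefined")
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps, "synonymous")
  ka <- jc(pn, "nonsynonymous")
  list(ka = ka, ks = ks,
       ratio = if (ks > 0) ka / ks else NA_real_,
       S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn)
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Translates both CDS, aligns the proteins globally, propagates the gaps
#' back onto the codons, and removes codon columns containing a gap.
#'
#' @param cds_a,cds_b CDS strings; length divisible by 3, translatable with
#'   no internal stop (a trailing stop codon is trimmed).
#' @return List with aligned codon vectors `a` and `b` (equal length, no
#'   gaps) and the aligned protein strings `prot_a`, `prot_b`.
#' @export
codon_align <- function(cds_a, cds_b) {
  trim <- function(cds) {
    codons <- split_codons(cds)
    aa <- codon_aa(codons)
    if (length(aa) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) stop("internal stop codon: CDS not translatable")
    list(codons = codons, protein = paste(aa, collapse = ""))
  }
  ta <- trim(cds_a)
  tb <- trim(cds_b)
  aln <- global_align(ta$protein, tb$protein, type = "protein")
  ga <- strsplit(aln$aligned_a, "")[[1]]
  gb <- strsplit(aln$aligned_b, "")[[1]]
  ca <- cb <- character(length(ga))
  i <- j <- 0L
  for (k in seq_along(ga)) {
    if (ga[k] != "-") { i <- i + 1L; ca[k] <- ta$codons[i] } else ca[k] <- "---"
    if (gb[k] != "-") { j <- j + 1L; cb[k] <- tb$codons[j] } else cb[k] <- "---"
  }
  keep <- ca != "---" & cb != "---"
  list(a = ca[keep], b = cb[keep],
       prot_a = aln$aligned_a, prot_b = aln$aligned_b)
}
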