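# Pairwise/progressive alignment, Poisson-corrected distances,
# neighbor-joining and bootstrap support.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings) with affine gap
#' penalties. Identity is 100 * matching columns / total alignment columns,
#' gap columns included in the denominator.
#'
#' @param a,b Sequences (plain character strings).
#' @param type "protein" (default, BLOSUM62) or "dna" (match/mismatch
#'   scores).
#' @param substitution_matrix Optional explicit substitution matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param match,mismatch Scores used for `type = "dna"` when no matrix is
#'   given.
#' @return List with `aligned_a`, `aligned_b` (gapped strings), `identity`
#'   (percent) and `score`.
#' @export
global_align <- function(a, b, type = c("protein", "dna"),
                         substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 0.5,
                         match = 1, mismatch = -1) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (is.null(substitution_matrix)) {
    if (type == "protein") {
      substitution_matrix <- "BLOSUM62"
    } else {
      substitution_matrix <- Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch, baseOnly = TRUE)
    }
  }
  cls <- if (type == "protein") Biostrings::AAString else Biostrings::DNAString
  aln <- Biostrings::pairwiseAlignment(
    cls(a), cls(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  ident <- 100 * sum(ca == cb & ca != "-") / length(ca)
  list(aligned_a = pa, aligned_b = pb, identity = ident,
       score = Biostrings::score(aln))
}

#' Pairwise identity matrix over a set of sequences
#'
#' @param seqs Named character vector of unaligned sequences.
#' @inheritParams global_align
#' @return Symmetric percent-identity matrix (diagonal 100).
#' @export
pairwise_identity <- function(seqs, type = "protein", ...) {
  n <- length(seqs)
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- global_align(seqs[[i]], seqs[[j]], type = type, ...)$identity
      m[i, j] <- m[j, i] <- id
    }
  }
  m
}

#' Filter sequences by maximum pairwise identity
#'
#' A sequence is retained iff its highest identity to any other input
#' sequence is at least `threshold` percent; sequences below it (too
#' diverged from every other candidate) are dropped. A singleton input is
#' always retained.
#'
#' @param seqs Named character vector.
#' @param threshold Percent identity cutoff (default 50).
#' @param identity_matrix Optional precomputed matrix from
#'   [pairwise_identity()].
#' @return The retained subset of `seqs`.
#' @export
filter_by_identity <- function(seqs, threshold = 50, identity_matrix = NULL,
                               type = "protein") {
  if (length(seqs) == 0) return(seqs)
  if (length(seqs) == 1) return(seqs)
  if (is.null(identity_matrix)) {
    identity_matrix <- pairwise_identity(seqs, type = type)
  }
  m <- identity_matrix
  diag(m) <- -Inf
  keep <- apply(m, 1, max) >= threshold
  seqs[keep]
}

#' Progressive multiple sequence alignment
#'
#' A deterministic progressive aligner: a UPGMA guide tree built from
#' pairwise identity distances fixes the addition order, and each sequence
#' is aligned to the consensus of the running profile with gaps propagated
#' to all existing rows (once a gap, always a gap).
#'
#' @param seqs Named character vector of (unaligned) sequences.
#' @param type "protein" or "dna".
#' @return Named character vector of aligned rows (equal length, gap "-"),
#'   in the input order.
#' @export
progressive_align <- function(seqs, type = "protein") {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 0) return(seqs)
  if (n == 1) return(seqs)
  ord <- if (n == 2) {
    1:2
  } else {
    idm <- pairwise_identity(seqs, type = type)
    hc <- stats::hclust(stats::as.dist(100 - idm), method = "average")
    hc$order
  }
  rows <- matrix(strsplit(seqs[[ord[1]]], "")[[1]], nrow = 1)
  row_names <- names(seqs)[ord[1]]
  consensus_of <- function(rows) {
    apply(rows, 2, function(col) {
      col <- col[col != "-"]
      if (!length(col)) return(NA_character_)
      tab <- sort(table(col), decreasing = TRUE)
      cands <- names(tab)[tab == tab[1]]
      sort(cands)[1]
    })
  }
  for (k in ord[-1]) {
    cons <- consensus_of(rows)
    cons_str <- paste(cons, collapse = "")
    aln <- global_align(cons_str, seqs[[k]], type = type)
    ac <- strsplit(aln$aligned_a, "")[[1]]
    as_ <- strsplit(aln$aligned_b, "")[[1]]
    new_rows <- matrix("-", nrow = nrow(rows) + 1, ncol = length(ac))
    p <- 0L
    for (col in seq_along(ac)) {
      if (ac[col] != "-") {
        p <- p + 1L
        new_rows[seq_len(nrow(rows)), col] <- rows[, p]
      }
      new_rows[nrow(new_rows), col] <- as_[col]
    }
    rows <- new_rows
    row_names <- c(row_names, names(seqs)[k])
  }
  out <- apply(rows, 1, paste, collapse = "")
  names(out) <- row_names
  out[names(seqs)]
}

#' Poisson-corrected amino-acid distance matrix
#'
#' Pairwise-deletion p-distance over columns where neither row is gapped,
#' corrected as d = -log(1 - p).
#'
#' @param msa Named character vector of aligned rows (equal length).
#' @return Symmetric distance matrix; a pair with p >= 1 or no comparable
#'   column gets `NA` with a warning.
#' @export
poisson_distance <- function(msa) {
  n <- length(msa)
  if (n < 2) stop("need at least two aligned rows")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("rows differ in length: not an MSA")
  chars <- do.call(rbind, strsplit(msa, ""))
  nm <- names(msa)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0) {
        warning("no comparable columns for pair ", nm[i], "/", nm[j])
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / nc
      if (p >= 1) {
        warning("p-distance >= 1 for pair ", nm[i], "/", nm[j])
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimizing the
#' Q-criterion, with ties broken by the lexicographically smallest pair of
#' cluster names. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling edge.
#'
#' @param dm Symmetric distance matrix with row/column names (or a `dist`).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(dm)) stop("distance matrix contains NA")
  D <- dm
  reps <- rownames(D)            # newick fragments
  keys <- rownames(D)            # tie-break names
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      k <- sort(c(keys[ij[1]], keys[ij[2]]))
      paste(k, collapse = "\r")
    })
    best <- cand[order(pair_key)[1], ]
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newrep <- paste0("(", reps[i], ":", fmt(li), ",", reps[j], ":", fmt(lj), ")")
    newkey <- min(keys[i], keys[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, new = dnew), new = c(dnew, 0))
    reps <- c(reps[-c(i, j)], newrep)
    keys <- c(keys[-c(i, j)], newkey)
    rownames(D) <- colnames(D) <- keys
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- paste0("(", reps[1], ":", fmt(l1), ",", reps[2], ":", fmt(l2), ",",
                reps[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Canonical bipartition keys of an unrooted tree
#'
#' One key per internal edge: the tip set on the side not containing the
#' alphabetically first tip, sorted and collapsed. Trivial splits excluded.
#' @noRd
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- ntip + 1L
  keys <- character(0)
  nodes <- integer(0)
  for (v in seq_len(tree$Nnode) + ntip) {
    if (v == root) next
    side <- desc[[v]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, v)
  }
  list(keys = keys, nodes = nodes, desc = desc, root = root)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples MSA columns with replacement, rebuilds the Poisson-distance NJ
#' tree for each replicate, and reports for every internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition.
#'
#' @param msa Named character vector of aligned rows (>= 4).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @return The NJ tree (`ape::phylo`) with internal `node.label` set to the
#'   support percentages (root label empty), plus attribute `"supports"`
#'   naming each bipartition.
#' @export
bootstrap_support <- function(msa, replicates = 1000, seed = NULL) {
  if (length(msa) < 4) stop("bootstrap needs an MSA with at least 4 rows")
  if (!is.null(seed)) set.seed(seed)
  tree <- neighbor_joining(poisson_distance(msa))
  sp <- tree_splits(tree)
  if (replicates < 1) {
    tree$node.label <- rep("", tree$Nnode)
    return(tree)
  }
  counts <- stats::setNames(numeric(length(sp$keys)), sp$keys)
  chars <- do.call(rbind, strsplit(msa, ""))
  ncol_msa <- ncol(chars)
  used <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol_msa, ncol_msa, replace = TRUE)
    rep_msa <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rep_msa) <- names(msa)
    dmb <- suppressWarnings(poisson_distance(rep_msa))
    if (anyNA(dmb)) next
    trb <- neighbor_joining(dmb)
    used <- used + 1L
    kb <- tree_splits(trb)$keys
    hit <- sp$keys %in% kb
    counts[hit] <- counts[hit] + 1
  }
  if (used == 0L) stop("all bootstrap replicates failed (undefined distances)")
  support <- round(100 * counts / used)
  labs <- rep("", tree$Nnode)
  ntip <- length(tree$tip.label)
  labs[sp$nodes - ntip] <- as.character(support)
  tree$node.label <- labs
  attr(tree, "supports") <- support
  attr(tree, "replicates_used") <- used
  tree
}
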