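# Duplicate-pair detection and classification, selection inference and
# divergence dating, synteny link binning.

#' Detect candidate duplicate pairs by protein identity
#'
#' All unordered member pairs whose global-alignment protein identity is
#' strictly greater than the threshold (default 90 percent).
#'
#' @param members Data frame with `name` and `protein` columns, or a named
#'   character vector of protein sequences.
#' @param identity_threshold Percent identity; strictly-greater rule.
#' @return Data frame: a, b, identity.
#' @export
detect_duplicates <- function(members, identity_threshold = 90) {
  seqs <- if (is.data.frame(members)) {
    stats::setNames(members$protein, members$name)
  } else members
  out <- list()
  n <- length(seqs)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        id <- global_align(seqs[[i]], seqs[[j]])$identity
        if (id > identity_threshold) {
          out[[length(out) + 1]] <- data.frame(
            a = names(seqs)[i], b = names(seqs)[j], identity = id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a duplicate pair as tandem or segmental
#'
#' Tandem iff both genes sit on the same chromosome with at most
#' `max_gap` annotated genes between them in chromosome gene order;
#' otherwise (more intervening genes, or different chromosomes) segmental.
#'
#' @param member_a,member_b Gene ids (or member names present in
#'   `gene_order`).
#' @param gene_order Data frame of ALL annotated genes with columns `id`,
#'   `chromosome`, `start` (the full gene complement, not just family
#'   members).
#' @param max_gap Maximum intervening gene count for tandem (default 5).
#' @return "tandem", "segmental", or "unknown" when a member is unplaced.
#' @export
classify_duplication <- function(member_a, member_b, gene_order,
                                 max_gap = 5) {
  ia <- match(member_a, gene_order$id)
  ib <- match(member_b, gene_order$id)
  if (is.na(ia) || is.na(ib)) return("unknown")
  ca <- gene_order$chromosome[ia]
  cb <- gene_order$chromosome[ib]
  if (is.na(ca) || is.na(cb)) return("unknown")
  if (ca != cb) return("segmental")
  chr <- gene_order[gene_order$chromosome == ca, , drop = FALSE]
  chr <- chr[order(chr$start), , drop = FALSE]
  ra <- match(member_a, chr$id)
  rb <- match(member_b, chr$id)
  intervening <- abs(ra - rb) - 1L
  if (intervening <= max_gap) "tandem" else "segmental"
}

#' Classify the selection regime from Ka/Ks
#'
#' Purifying below the neutral band, neutral inside it, positive above it.
#' The default band [0.95, 1.05] treats ratios indistinguishable from 1 as
#' neutral. Degenerate cases: Ks = 0 with Ka > 0 has an undefined ratio and
#' is reported as purifying with `degenerate = TRUE` (no synonymous change
#' observed, so the ratio carries no positive-selection signal); Ka = Ks =
#' 0 is class "identical".
#'
#' @param ka,ks Nonsynonymous and synonymous rates (used when `ratio` is
#'   not given).
#' @param ratio Optional precomputed Ka/Ks (takes precedence, e.g. when
#'   classifying published ratio values).
#' @param neutral_band Two-element numeric band for neutrality.
#' @return List with `class` ("purifying", "neutral", "positive",
#'   "identical"), `ratio` (NA when undefined) and `degenerate`.
#' @export
classify_selection <- function(ka = NULL, ks = NULL, ratio = NULL,
                               neutral_band = c(0.95, 1.05)) {
  if (is.null(ratio)) {
    if (is.null(ka) || is.null(ks)) stop("supply ka and ks, or ratio")
    if (ks == 0 && ka == 0) {
      return(list(class = "identical", ratio = NA_real_, degenerate = TRUE))
    }
    if (ks == 0) {
      return(list(class = "purifying", ratio = NA_real_, degenerate = TRUE))
    }
    ratio <- ka / ks
  } else if (!is.null(ks) && ks == 0) {
    if (!is.null(ka) && ka == 0) {
      return(list(class = "identical", ratio = NA_real_, degenerate = TRUE))
    }
    return(list(class = "purifying", ratio = NA_real_, degenerate = TRUE))
  }
  cls <- if (ratio < neutral_band[1]) {
    "purifying"
  } else if (ratio <= neutral_band[2]) {
    "neutral"
  } else {
    "positive"
  }
  list(class = cls, ratio = ratio, degenerate = FALSE)
}

#' Divergence time from the synonymous rate
#'
#' T = Ks / (2 * lambda), in millions of years, with lambda the synonymous
#' substitution rate per site per year (default 6.1e-9, the soybean rate).
#'
#' @param ks Synonymous substitution rate (>= 0).
#' @param lambda Synonymous substitutions per site per year.
#' @param digits Decimals for the reported value (default 2; use NULL for
#'   the unrounded value).
#' @return Divergence time in Mya.
#' @export
#' @examples
#' divergence_time(0.051)  # 4.18 Mya
divergence_time <- function(ks, lambda = 6.1e-9, digits = 2) {
  if (any(ks < 0)) stop("negative Ks")
  t_mya <- ks / (2 * lambda) / 1e6
  if (is.null(digits)) t_mya else round(t_mya, digits)
}

#' Full evolutionary characterization of duplicate pairs
#'
#' For each detected pair: duplication type, codon-alignment NG86 Ka and
#' Ks, selection class and divergence time.
#'
#' @param members Member table from [identify_family()] (needs name,
#'   gene_id, cds, protein).
#' @param gene_order Full annotated gene order (see
#'   [classify_duplication()]).
#' @param identity_threshold Detection threshold (percent, strict).
#' @param max_gap Tandem gap rule.
#' @param lambda Synonymous rate per year for dating.
#' @param neutral_band Neutral Ka/Ks band.
#' @return Data frame with columns a, b, identity, type, ka, ks, ratio,
#'   selection, time_mya.
#' @export
duplicate_pair_table <- function(members, gene_order,
                                 identity_threshold = 90, max_gap = 5,
                                 lambda = 6.1e-9,
                                 neutral_band = c(0.95, 1.05)) {
  pairs <- detect_duplicates(members, identity_threshold)
  if (nrow(pairs) == 0) {
    return(cbind(pairs, data.frame(type = character(), ka = numeric(),
                                   ks = numeric(), ratio = numeric(),
                                   selection = character(),
                                   time_mya = numeric())))
  }
  idx <- stats::setNames(seq_len(nrow(members)), members$name)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$a[k]; b <- pairs$b[k]
    ga <- members$gene_id[idx[[a]]]
    gb <- members$gene_id[idx[[b]]]
    type <- classify_duplication(ga, gb, gene_order, max_gap)
    aln <- codon_align(members$cds[idx[[a]]], members$cds[idx[[b]]])
    kk <- ng86_ka_ks(aln)
    sel <- classify_selection(ka = kk$ka, ks = kk$ks,
                              neutral_band = neutral_band)
    data.frame(a = a, b = b, identity = pairs$identity[k], type = type,
               ka = kk$ka, ks = kk$ks, ratio = sel$ratio,
               selection = sel$class,
               time_mya = divergence_time(kk$ks, lambda),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-species synteny links with identity bins
#'
#' All-vs-all global protein alignments between a query and a subject
#' member set, with significance from a Gumbel (Karlin-Altschul-style)
#' model whose location/scale are fit on a shuffled-sequence score null at
#' startup. Retained links are binned by percent identity as <=50, <=70,
#' <=90, >90.
#'
#' @param query,subject Named character vectors of protein sequences (a
#'   self-comparison is skipped when a name appears in both).
#' @param e_value_max Retention threshold (default 1e-10).
#' @param n_null Number of shuffled pairs used to fit the null.
#' @param seed Seed for the shuffling.
#' @return Data frame: query, subject, identity, bin, score, e_value.
#' @export
synteny_links <- function(query, subject, e_value_max = 1e-10,
                          n_null = 50, seed = 1) {
  if (!length(query) || !length(subject)) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), bin = character(),
                      score = numeric(), e_value = numeric()))
  }
  set.seed(seed)
  shuffle <- function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }
  # score null: alignments of shuffled query/subject picks
  null_scores <- vapply(seq_len(n_null), function(i) {
    q <- shuffle(query[[sample.int(length(query), 1)]])
    s <- shuffle(subject[[sample.int(length(subject), 1)]])
    global_align(q, s)$score
  }, numeric(1))
  # Gumbel fit by method of moments
  beta <- stats::sd(null_scores) * sqrt(6) / pi
  if (beta <= 0) beta <- 1
  mu <- mean(null_scores) - 0.5772156649 * beta
  n_comp <- length(query) * length(subject)
  out <- list()
  for (qn in names(query)) {
    for (sn in names(subject)) {
      if (qn == sn) next
      aln <- global_align(query[[qn]], subject[[sn]])
      p <- 1 - exp(-exp(-(aln$score - mu) / beta))
      e <- n_comp * p
      if (e <= e_value_max) {
        id <- aln$identity
        bin <- if (id <= 50) "<=50" else if (id <= 70) "<=70"
               else if (id <= 90) "<=90" else ">90"
        out[[length(out) + 1]] <- data.frame(
          query = qn, subject = sn, identity = id, bin = bin,
          score = aln$score, e_value = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), bin = character(),
                      score = numeric(), e_value = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference Ka/Ks table for soybean SOD/GPX duplicate pairs
#'
#' Published NG86-style Ka, Ks, Ka/Ks ratios, duplication types, selection
#' labels and divergence times for 17 duplicated soybean (Glycine max /
#' Glycine soja) SOD and GPX paralog pairs, used to validate selection
#' classification and synonymous-rate dating.
#'
#' @return Data frame: pair, ka, ks, ratio, type, time_mya, selection.
#' @export
soybean_duplicate_reference <- function() {
  path <- system.file("extdata", "soybean_sod_gpx_duplicates.tsv",
                      package = "genefamkit")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
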