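# Expression-matrix transformation, 2^-ddCt relative expression, Duncan's
# multiple range test.

#' Heatmap-ready transformation of an FPKM matrix
#'
#' log2(FPKM + 1) followed by per-gene mean-centering (row mean subtracted),
#' the usual normalization for tissue-profile heatmaps.
#'
#' @param fpkm Numeric matrix, genes x tissues, values >= 0.
#' @return Transformed matrix of the same shape; every row mean is 0.
#' @export
heatmap_matrix <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("negative FPKM values")
  if (any(!is.finite(fpkm))) stop("non-finite FPKM values")
  lg <- log2(fpkm + 1)
  sweep(lg, 1, rowMeans(lg))
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged to one Ct per (gene, condition,
#' biological replicate); dCt = Ct_target - Ct_reference per biological
#' replicate; ddCt subtracts the mean calibrator dCt (same treatment at the
#' calibrator timepoint); relative expression is 2^-ddCt, summarized as
#' mean and sd over biological replicates.
#'
#' @param table qPCR long table: gene, treatment, timepoint, bio_rep,
#'   tech_rep, ct.
#' @param gene Target gene.
#' @param reference Reference (housekeeping) gene, e.g. an actin.
#' @param calibrator_timepoint Timepoint used as calibrator within each
#'   treatment (default 0).
#' @return Data frame: treatment, timepoint, mean_rel_expr, sd_rel_expr,
#'   n_bio.
#' @export
relative_expression <- function(table, gene, reference,
                                calibrator_timepoint = 0) {
  need <- c("gene", "treatment", "timepoint", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(table))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  collapse <- function(g) {
    sub <- table[table$gene == g, , drop = FALSE]
    stats::aggregate(ct ~ treatment + timepoint + bio_rep, data = sub,
                     FUN = mean)
  }
  tgt <- collapse(gene)
  ref <- collapse(reference)
  if (nrow(tgt) == 0) stop("no rows for target gene ", gene)
  if (nrow(ref) == 0) stop("no rows for reference gene ", reference)
  merged <- merge(tgt, ref, by = c("treatment", "timepoint", "bio_rep"),
                  suffixes = c("_target", "_ref"), all.x = TRUE)
  if (anyNA(merged$ct_ref)) {
    bad <- merged[is.na(merged$ct_ref), c("treatment", "timepoint",
                                          "bio_rep")]
    stop("missing reference Ct for cell(s): ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "))
  }
  merged$dct <- merged$ct_target - merged$ct_ref
  out <- list()
  for (tr in unique(merged$treatment)) {
    sub <- merged[merged$treatment == tr, , drop = FALSE]
    cal <- sub$dct[sub$timepoint == calibrator_timepoint]
    if (!length(cal)) {
      stop("no calibrator (timepoint ", calibrator_timepoint,
           ") rows for treatment ", tr)
    }
    cal_mean <- mean(cal)
    for (tp in sort(unique(sub$timepoint))) {
      rel <- 2^(-(sub$dct[sub$timepoint == tp] - cal_mean))
      out[[length(out) + 1]] <- data.frame(
        treatment = tr, timepoint = tp,
        mean_rel_expr = mean(rel),
        sd_rel_expr = if (length(rel) > 1) stats::sd(rel) else 0,
        n_bio = length(rel), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Duncan's multiple range test with letter groupings
#'
#' One-way ANOVA error variance and df, then for each span of p ordered
#' means the least significant range R_p = q(alpha_p, p, df) *
#' sqrt(MSE / n), with protection level alpha_p = 1 - (1 - alpha)^(p - 1)
#' and q the studentized-range quantile. A span of ordered means is
#' homogeneous iff its endpoint difference is below R_p (spans inside a
#' homogeneous span inherit homogeneity); letters mark the maximal
#' homogeneous spans, "a" attached to the largest mean.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   >= 2 values).
#' @param alpha Significance level (default 0.05).
#' @return Data frame sorted by descending mean: group, mean, n, letters;
#'   attributes `mse`, `df`, `alpha`. Unbalanced designs use the harmonic
#'   mean n (with a message).
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least two replicates")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(sizes)
  df_err <- N - k
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  mse <- sse / df_err
  if (length(unique(sizes)) > 1) {
    message("unbalanced groups: using harmonic mean n")
    n_eff <- k / sum(1 / sizes)
  } else {
    n_eff <- sizes[1]
  }
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se <- sqrt(mse / n_eff)
  # least significant ranges for spans of 2..k means
  rp <- c(NA_real_, vapply(2:k, function(p) {
    conf <- (1 - alpha)^(p - 1)
    if (se == 0) return(0)
    stats::qtukey(conf, p, df_err) * se
  }, numeric(1)))
  # homogeneity of ordered spans with Duncan's protection rule: a span is
  # homogeneous if its endpoint range is below R_p, and any span contained
  # in a homogeneous span is homogeneous too (tested widest-first)
  homog <- matrix(FALSE, k, k)
  for (i in seq_len(k)) homog[i, i] <- TRUE
  for (span in 2:k) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      homog[i, j] <- (m[i] - m[j]) < rp[span] ||
        (se == 0 && isTRUE(all.equal(m[i], m[j])))
    }
  }
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (homog[i, j]) {
        for (i2 in i:j) for (j2 in i2:j) homog[i2, j2] <- TRUE
      }
    }
  }
  # letters on maximal homogeneous spans
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homog[i, j + 1]) j <- j + 1
    spans[[i]] <- c(i, j)
  }
  maximal <- Filter(function(s) {
    !any(vapply(spans, function(t) {
      (t[1] < s[1] && t[2] >= s[2]) || (t[1] <= s[1] && t[2] > s[2])
    }, logical(1)))
  }, spans)
  maximal <- unique(maximal)
  letters_vec <- rep("", k)
  for (li in seq_along(maximal)) {
    s <- maximal[[li]]
    lt <- letters[(li - 1) %% 26 + 1]
    for (i in s[1]:s[2]) letters_vec[i] <- paste0(letters_vec[i], lt)
  }
  out <- data.frame(group = names(m), mean = unname(m),
                    n = unname(sizes[ord]), letters = letters_vec,
                    stringsAsFactors = FALSE)
  attr(out, "mse") <- mse
  attr(out, "df") <- df_err
  attr(out, "alpha") <- alpha
  out
}

#' Ranked tissue profiles with specificity flags
#'
#' Ranks tissues per gene by the transformed heatmap value and flags genes
#' whose top tissue exceeds the runner-up by at least `margin` (log2
#' units).
#'
#' @param matrix FPKM matrix, genes x tissues.
#' @param members Optional subset of gene names to report.
#' @param margin Flagging margin in log2 units (default 1, i.e. 2-fold).
#' @return Data frame: gene, top_tissue, top_value, second_value, flagged.
#' @export
tissue_profile_report <- function(matrix, members = NULL, margin = 1) {
  if (length(matrix) == 0 || nrow(matrix) == 0) {
    return(data.frame(gene = character(), top_tissue = character(),
                      top_value = numeric(), second_value = numeric(),
                      flagged = logical()))
  }
  hm <- heatmap_matrix(matrix)
  if (!is.null(members)) hm <- hm[rownames(hm) %in% members, , drop = FALSE]
  rows <- lapply(rownames(hm), function(g) {
    v <- sort(hm[g, ], decreasing = TRUE)
    data.frame(gene = g, top_tissue = names(v)[1], top_value = v[1],
               second_value = if (length(v) > 1) v[2] else NA_real_,
               flagged = length(v) > 1 && (v[1] - v[2]) >= margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
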