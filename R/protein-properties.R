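# Physicochemical protein properties: length, molecular weight,
# isoelectric point.

# Average (isotope-weighted) residue masses in Da; a residue is the amino
# acid minus one water, so a peptide mass is sum(residues) + one water.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# EMBOSS-style pKa values for the ionizable groups; swappable via the
# `pka` argument of isoelectric_point().
PKA_EMBOSS <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, reported in kDa. The
#' ambiguity code X contributes the mean residue mass; any other non-standard
#' letter is an error.
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @return Molecular weight in kDa.
#' @export
#' @examples
#' molecular_weight("G")   # glycine: 0.0750672 kDa
molecular_weight <- function(sequence) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  mean_mass <- mean(AA_RESIDUE_MASS)
  masses <- AA_RESIDUE_MASS[aa]
  masses[aa == "X"] <- mean_mass
  if (anyNA(masses)) {
    stop("unknown residue(s): ",
         paste(unique(aa[is.na(masses)]), collapse = ","))
  }
  (sum(masses) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R).
#'
#' @param sequence Amino-acid string.
#' @param pH pH value(s).
#' @param pka Named pKa vector (defaults to an EMBOSS-style table).
#' @return Net charge in elementary charges (vectorized over `pH`).
#' @export
protein_charge <- function(sequence, pH, pka = PKA_EMBOSS) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(aa, levels = c("C", "D", "E", "H", "K", "R", "Y")))
  pos_groups <- c(Nterm = 1, H = counts[["H"]], K = counts[["K"]],
                  R = counts[["R"]])
  neg_groups <- c(Cterm = 1, C = counts[["C"]], D = counts[["D"]],
                  E = counts[["E"]], Y = counts[["Y"]])
  vapply(pH, function(p) {
    pos <- sum(pos_groups / (1 + 10^(p - pka[names(pos_groups)])))
    neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - p)))
    pos - neg
  }, numeric(1))
}

#' Protein isoelectric point
#'
#' The pH at which the net charge crosses zero, found by bisection on
#' [0, 14] to a tolerance of 1e-4 pH units. The charge is strictly
#' decreasing in pH so the root is unique.
#'
#' @inheritParams protein_charge
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = PKA_EMBOSS, tol = 1e-4) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  lo <- 0; hi <- 14
  f_lo <- protein_charge(sequence, lo, pka)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- protein_charge(sequence, mid, pka)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Physicochemical property table for a set of family members
#'
#' @param members Data frame with columns `name` and `protein` (as returned
#'   by [identify_family()]), or a named character vector of protein
#'   sequences.
#' @param localization Optional named character vector of imported
#'   subcellular-localization annotations (free text, never computed here).
#' @return Data frame: name, length_aa, mw_kda, pi (and localization when
#'   supplied).
#' @export
protein_properties <- function(members, localization = NULL) {
  if (is.data.frame(members)) {
    seqs <- stats::setNames(members$protein, members$name)
  } else {
    seqs <- members
  }
  out <- data.frame(
    name = names(seqs),
    length_aa = nchar(seqs),
    mw_kda = vapply(seqs, molecular_weight, numeric(1)),
    pi = vapply(seqs, isoelectric_point, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(localization)) {
    out$localization <- unname(localization[out$name])
  }
  out
}
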