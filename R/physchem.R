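# Physicochemical profiling: length, average molecular weight, isoelectric
# point, aliphatic index, GRAVY and instability index. Composition-only
# quantities ignore the order of residues; the instability index is the one
# order-sensitive statistic. The ambiguity code X is excluded from the
# GRAVY / aliphatic-index / instability denominators and contributes the
# mean residue mass to the molecular weight.

aa_counts <- function(sequence) {
  chars <- seq_chars(sequence)
  table(factor(chars, levels = c(AA_ALPHABET, "X")))
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water. `X` residues contribute
#' the mean of the twenty standard residue masses, with a warning.
#'
#' @param sequence amino-acid sequence.
#' @return molecular weight in daltons.
#' @export
molecular_weight <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  cnt <- aa_counts(sequence)
  nx <- cnt[["X"]]
  if (nx > 0) warning("X residues assigned the mean residue mass")
  sum(cnt[AA_ALPHABET] * AA_MASS[AA_ALPHABET]) +
    nx * mean(AA_MASS) + WATER_MASS
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all scorable
#' residues.
#'
#' @param sequence amino-acid sequence.
#' @return mean hydropathy, in \[-4.5, 4.5\].
#' @export
gravy <- function(sequence) {
  chars <- seq_chars(sequence)
  chars <- chars[chars != "X"]
  if (length(chars) == 0) stop("no scorable residues")
  mean(KD_HYDROPATHY[chars])
}

#' Aliphatic index
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` where `X(aa)` is the mole
#' percent of the residue among scorable residues.
#'
#' @param sequence amino-acid sequence.
#' @return dimensionless aliphatic index.
#' @export
aliphatic_index <- function(sequence) {
  chars <- seq_chars(sequence)
  chars <- chars[chars != "X"]
  if (length(chars) == 0) stop("no scorable residues")
  mole <- 100 * table(factor(chars, levels = AA_ALPHABET)) / length(chars)
  unname(mole[["A"]] + 2.9 * mole[["V"]] + 3.9 * (mole[["I"]] + mole[["L"]]))
}

# Net charge at a given pH under a pKa set (Henderson-Hasselbalch sum over
# the termini and the D, E, C, Y, H, K, R side chains).
net_charge <- function(pH, counts, pka) {
  pos <- pka$positive
  neg <- pka$negative
  n_pos <- c(Nterm = 1, counts[intersect(names(pos), AA_ALPHABET)])
  n_neg <- c(Cterm = 1, counts[intersect(names(neg), AA_ALPHABET)])
  sum(n_pos / (1 + 10^(pH - pos[names(n_pos)]))) -
    sum(n_neg / (1 + 10^(pka$negative[names(n_neg)] - pH)))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge of the
#' peptide crosses zero, by bisection on \[0, 14\] to a tolerance of 1e-4.
#'
#' @param sequence amino-acid sequence.
#' @param pka_set `"bjellqvist"` (ExPASy-style, default) or `"emboss"`, or a
#'   list with `positive` / `negative` pKa vectors in the same shape as the
#'   entries of `PKA_SETS`.
#' @return isoelectric point in pH units (full precision; round to 2
#'   decimals for reporting).
#' @export
isoelectric_point <- function(sequence, pka_set = "bjellqvist") {
  if (!nzchar(sequence)) stop("empty sequence")
  pka <- if (is.character(pka_set)) {
    if (!pka_set %in% names(PKA_SETS)) {
      stop("unknown pKa set: ", pka_set)
    }
    PKA_SETS[[pka_set]]
  } else pka_set
  counts <- aa_counts(sequence)
  lo <- 0; hi <- 14
  f_lo <- net_charge(lo, counts, pka)
  f_hi <- net_charge(hi, counts, pka)
  if (f_lo < 0 || f_hi > 0) stop("charge curve does not bracket zero")
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(mid, counts, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index
#'
#' `(10 / L) *` sum of dipeptide instability weight values (Guruprasad et
#' al. 1990) over consecutive dipeptides. Dipeptides containing `X` are
#' skipped and `L` counts scorable residues only.
#'
#' @param sequence amino-acid sequence of length >= 2.
#' @return dimensionless instability index.
#' @export
instability_index <- function(sequence) {
  chars <- seq_chars(sequence)
  if (length(chars) < 2) stop("instability index needs length >= 2")
  diwv <- diwv_table()
  a <- chars[-length(chars)]
  b <- chars[-1]
  keep <- a != "X" & b != "X"
  len <- sum(chars != "X")
  if (len == 0) stop("no scorable residues")
  (10 / len) * sum(diwv[cbind(a[keep], b[keep])])
}

#' Full physicochemical profile of one protein
#'
#' @param sequence amino-acid sequence.
#' @param pka_set passed to [isoelectric_point()].
#' @return data.frame row with `length`, `mw` (Da), `pi`, `ai`, `gravy`,
#'   `instability`.
#' @export
physchem_profile <- function(sequence, pka_set = "bjellqvist") {
  data.frame(
    length = nchar(sequence),
    mw = molecular_weight(sequence),
    pi = isoelectric_point(sequence, pka_set),
    ai = aliphatic_index(sequence),
    gravy = gravy(sequence),
    instability = instability_index(sequence)
  )
}
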