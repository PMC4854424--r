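# Physicochemical constants used across the package. All scales are the
# standard published tables; DIWV is shipped as a CSV under inst/extdata.

#' Standard amino-acid alphabet
#'
#' The twenty proteinogenic residues in one-letter code.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue masses (Da), ExPASy convention; a free peptide adds one
# water (18.0153 Da).
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Ionizable-group pKa sets for isoelectric-point bisection. "bjellqvist" is
# the ExPASy-style set; "emboss" is the set used by the EMBOSS iep tool.
PKA_SETS <- list(
  bjellqvist = list(
    positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
    negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  ),
  emboss = list(
    positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
)

# Dipeptide instability weight values (Guruprasad et al. 1990), cached on
# first use from the CSV shipped with the package.
.wrky_env <- new.env(parent = emptyenv())

diwv_table <- function() {
  if (is.null(.wrky_env$diwv)) {
    path <- system.file("extdata", "diwv_guruprasad1990.csv",
                        package = "wrkycensus", mustWork = TRUE)
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    .wrky_env$diwv <- as.matrix(tab)
  }
  .wrky_env$diwv
}
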