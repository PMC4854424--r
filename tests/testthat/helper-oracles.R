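# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (enumeration / direct table lookup) and never call
# the implementation they check.

# Brute-force core scan: test every offset of every variant by direct
# substring comparison.
brute_force_cores <- function(sequence, variants = core_variants()) {
  n <- nchar(sequence)
  hits <- integer(0)
  for (v in variants) {
    w <- nchar(v)
    if (n < w) next
    for (off in 0:(n - w)) {
      if (substring(sequence, off + 1, off + w) == v) {
        hits <- c(hits, off)
      }
    }
  }
  sort(unique(hits))
}

# Direct DIWV lookup from the shipped CSV (no package code paths).
diwv_oracle <- local({
  tab <- NULL
  function(sequence) {
    if (is.null(tab)) {
      path <- system.file("extdata", "diwv_guruprasad1990.csv",
                          package = "wrkycensus")
      tab <<- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    }
    ch <- strsplit(sequence, "")[[1]]
    s <- 0
    for (i in seq_len(length(ch) - 1)) s <- s + tab[ch[i], ch[i + 1]]
    10 / length(ch) * s
  }
})

# Net-charge equation evaluated independently for the pI bisection check.
charge_oracle <- function(sequence, pH) {
  pos <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
  neg <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  ch <- strsplit(sequence, "")[[1]]
  cnt <- table(ch)
  n_of <- function(a) if (a %in% names(cnt)) cnt[[a]] else 0
  z <- 1 / (1 + 10^(pH - pos["Nterm"])) - 1 / (1 + 10^(neg["Cterm"] - pH))
  for (a in c("K", "R", "H")) z <- z + n_of(a) / (1 + 10^(pH - pos[a]))
  for (a in c("D", "E", "C", "Y")) z <- z - n_of(a) / (1 + 10^(neg[a] - pH))
  unname(z)
}

# Random additive distance matrix from a random binary tree with edge
# lengths bounded away from zero (unique generating topology).
random_additive_matrix <- function(n) {
  phy <- ape::rtree(n, rooted = FALSE)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.1, 2)
  list(tree = phy, D = ape::cophenetic.phylo(phy))
}

# Standard small synthetic family used by several files.
small_family <- function(seed = 7L, decoys = 4L) {
  groups <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "IV")
  spec <- family_spec(stats::setNames(rep(2L, 8), groups),
                      n_decoys = decoys, seed = seed)
  sim_proteins(spec)
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Random flank guaranteed motif-free (rejection against the brute-force
# scanner, not the package scanner).
random_flank <- function(len) {
  repeat {
    s <- random_protein(len)
    if (length(brute_force_cores(s)) == 0) return(s)
  }
}
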