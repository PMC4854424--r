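# Domain phylogeny: progressive multiple alignment (pairwise alignments
# feed a UPGMA guide tree, profiles merged in guide-tree order),
# p-distances, neighbor-joining via ape, and seeded bootstrap support.
# An exhaustive least-squares topology search over all unrooted leaf-
# labeled topologies (n <= ~7) is provided for validation.

blosum62 <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

# Column frequency matrix of a set of aligned rows (gaps excluded).
profile_freq <- function(rows) {
  L <- nchar(rows[1])
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  freq <- matrix(0, nrow = L, ncol = length(AA_ALPHABET),
                 dimnames = list(NULL, AA_ALPHABET))
  for (a in AA_ALPHABET) freq[, a] <- colSums(mat == a)
  freq
}

# Global profile-profile alignment with affine gaps. Returns the gap masks
# to apply to each profile. Deterministic tie-break: diagonal over
# gap-in-profile-2 over gap-in-profile-1.
profile_align <- function(rows1, rows2, gap_open = 10, gap_extend = 0.5,
                          submat = blosum62()) {
  f1 <- profile_freq(rows1)
  f2 <- profile_freq(rows2)
  n1 <- nrow(f1); n2 <- nrow(f2)
  B <- submat[AA_ALPHABET, AA_ALPHABET]
  S <- (f1 %*% B %*% t(f2)) / (length(rows1) * length(rows2))
  NEG <- -1e9
  M <- matrix(NEG, n1 + 1, n2 + 1); Xg <- M; Yg <- M
  pM <- matrix(0L, n1 + 1, n2 + 1); pX <- pM; pY <- pM
  M[1, 1] <- 0
  if (n1 > 0) {
    Xg[2:(n1 + 1), 1] <- -gap_open - (0:(n1 - 1)) * gap_extend
    pX[2:(n1 + 1), 1] <- c(1L, rep(2L, n1 - 1))
  }
  if (n2 > 0) {
    Yg[1, 2:(n2 + 1)] <- -gap_open - (0:(n2 - 1)) * gap_extend
    pY[1, 2:(n2 + 1)] <- c(1L, rep(3L, n2 - 1))
  }
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      prev <- c(M[i, j], Xg[i, j], Yg[i, j])
      k <- which.max(prev)
      M[i + 1, j + 1] <- prev[k] + S[i, j]
      pM[i + 1, j + 1] <- k
      ox <- c(M[i, j + 1] - gap_open, Xg[i, j + 1] - gap_extend)
      kx <- which.max(ox)
      Xg[i + 1, j + 1] <- ox[kx]
      pX[i + 1, j + 1] <- c(1L, 2L)[kx]
      oy <- c(M[i + 1, j] - gap_open, Yg[i + 1, j] - gap_extend)
      ky <- which.max(oy)
      Yg[i + 1, j + 1] <- oy[ky]
      pY[i + 1, j + 1] <- c(1L, 3L)[ky]
    }
  }
  # traceback
  i <- n1 + 1L; j <- n2 + 1L
  state <- which.max(c(M[i, j], Xg[i, j], Yg[i, j]))
  ops <- integer(0)  # 1 = both, 2 = col from 1 only, 3 = col from 2 only
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ops <- c(1L, ops); state <- pM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ops <- c(2L, ops); state <- pX[i, j]; i <- i - 1L
    } else {
      ops <- c(3L, ops); state <- pY[i, j]; j <- j - 1L
    }
  }
  ops
}

apply_ops <- function(rows, ops, own_op) {
  chars <- strsplit(rows, "", fixed = TRUE)
  take <- ops %in% c(1L, own_op)
  vapply(chars, function(ch) {
    out <- character(length(ops))
    out[take] <- ch
    out[!take] <- "-"
    paste(out, collapse = "")
  }, "")
}

#' Progressive multiple alignment of domain sequences
#'
#' Pairwise global alignments (BLOSUM62, affine gaps) provide percent-
#' identity distances for a UPGMA guide tree; profiles are then merged in
#' guide-tree order by global profile-profile alignment with the same
#' scoring. Deterministic for fixed inputs.
#'
#' @param seqs named character vector of >= 1 ungapped sequences.
#' @param gap_open,gap_extend affine gap penalties.
#' @return object of class `wrky_alignment`: named character vector of
#'   equal-length aligned rows (in input order).
#' @export
align_progressive <- function(seqs, gap_open = 10, gap_extend = 0.5) {
  seqs <- clean_proteins(seqs)
  if (any(nchar(seqs) == 0)) stop("zero-length sequence")
  n <- length(seqs)
  if (n == 1) {
    return(structure(seqs, class = "wrky_alignment"))
  }
  submat <- blosum62()
  if (n == 2) {
    ops <- profile_align(seqs[1], seqs[2], gap_open, gap_extend, submat)
    rows <- c(apply_ops(seqs[1], ops, 2L), apply_ops(seqs[2], ops, 3L))
    names(rows) <- names(seqs)
    return(structure(rows, class = "wrky_alignment"))
  }
  aa <- Biostrings::AAStringSet(unname(seqs))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    pa <- Biostrings::pairwiseAlignment(
      rep(aa[i], n - i), aa[(i + 1):n], type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend)
    pid <- Biostrings::pid(pa)
    D[i, (i + 1):n] <- 1 - pid / 100
    D[(i + 1):n, i] <- D[i, (i + 1):n]
  }
  guide <- stats::hclust(stats::as.dist(D), method = "average")
  groups <- as.list(seq_len(n))        # leaf indices, keyed by -index
  profiles <- as.list(unname(seqs))
  merged_groups <- vector("list", nrow(guide$merge))
  merged_profiles <- vector("list", nrow(guide$merge))
  fetch <- function(k) {
    if (k < 0) list(idx = groups[[-k]], rows = profiles[[-k]])
    else list(idx = merged_groups[[k]], rows = merged_profiles[[k]])
  }
  for (s in seq_len(nrow(guide$merge))) {
    a <- fetch(guide$merge[s, 1])
    b <- fetch(guide$merge[s, 2])
    ops <- profile_align(a$rows, b$rows, gap_open, gap_extend, submat)
    merged_groups[[s]] <- c(a$idx, b$idx)
    merged_profiles[[s]] <- c(apply_ops(a$rows, ops, 2L),
                              apply_ops(b$rows, ops, 3L))
  }
  final <- fetch(nrow(guide$merge))
  rows <- final$rows[order(final$idx)]
  names(rows) <- names(seqs)
  structure(rows, class = "wrky_alignment")
}

#' Pairwise p-distances from an alignment
#'
#' For each pair of rows, the proportion of mismatching columns among
#' columns without a gap in either row.
#'
#' @param alignment `wrky_alignment` (or named character of equal-length
#'   aligned rows).
#' @param on_empty what to do for a pair with zero comparable columns:
#'   `"error"` (default) or `"max"` (assign distance 1, used during
#'   bootstrap resampling).
#' @return symmetric distance matrix with zero diagonal, dimnames = ids.
#' @export
p_distance <- function(alignment, on_empty = c("error", "max")) {
  on_empty <- match.arg(on_empty)
  rows <- unclass(alignment)
  stopifnot(length(unique(nchar(rows))) == 1)
  n <- length(rows)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap <- mat == "-"
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        if (on_empty == "error") {
          stop("no comparable columns between ", names(rows)[i], " and ",
               names(rows)[j])
        }
        D[i, j] <- D[j, i] <- 1
      } else {
        D[i, j] <- D[j, i] <- mean(mat[i, ok] != mat[j, ok])
      }
    }
  }
  D
}

#' Poisson-corrected distances
#'
#' `-log(1 - p)` transform of the p-distance, the simple multiple-hit
#' correction for protein data.
#'
#' @inheritParams p_distance
#' @return symmetric distance matrix.
#' @export
poisson_distance <- function(alignment, on_empty = c("error", "max")) {
  D <- p_distance(alignment, on_empty)
  if (any(D >= 1)) stop("p-distance of 1 cannot be Poisson-corrected")
  -log(1 - D)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix (via
#' `ape::nj`); negative branch lengths are clamped to zero with a warning.
#' On additive matrices the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param D symmetric nonnegative matrix with zero diagonal and ids as
#'   dimnames; >= 3 taxa.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix is not symmetric")
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 taxa")
  phy <- ape::nj(D)
  if (any(phy$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phy
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and records for each internal bipartition of the full-data
#' tree the percentage of replicate trees containing it. Support values are
#' stored in `node.label`.
#'
#' @param alignment `wrky_alignment` with >= 4 rows.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed; the function sets the RNG state.
#' @param distance `"p"` (default) or `"poisson"`.
#' @return `phylo` tree (NJ on the full data) with `node.label` holding
#'   bootstrap percentages on internal nodes.
#' @export
nj_bootstrap <- function(alignment, replicates = 1000, seed = 1,
                         distance = c("p", "poisson")) {
  distance <- match.arg(distance)
  if (replicates < 1) stop("replicates must be >= 1")
  distfun <- function(al) {
    if (distance == "p") p_distance(al, on_empty = "max")
    else poisson_distance(al, on_empty = "max")
  }
  full <- nj_tree(distfun(alignment))
  rows <- unclass(alignment)
  L <- nchar(rows[1])
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  set.seed(seed)
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    names(res) <- names(rows)
    boots[[r]] <- suppressWarnings(
      nj_tree(distfun(structure(res, class = "wrky_alignment"))))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(round(100 * counts / replicates))
  full
}

#' Exhaustive least-squares tree search
#'
#' Enumerates every unrooted leaf-labeled topology (via
#' `phangorn::allTrees`), fits branch lengths to the distance matrix by
#' ordinary least squares on the path-indicator design matrix, and returns
#' the topology with the smallest residual sum of squares. Practical for
#' n <= 7; used to validate neighbor joining on additive matrices.
#'
#' @param D symmetric distance matrix with ids as dimnames.
#' @return list with `tree` (`phylo`, fitted branch lengths) and `rss`.
#' @export
ls_tree_search <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3 || n > 7) stop("exhaustive search supports 3 to 7 taxa")
  pairs <- t(utils::combn(n, 2))
  d <- D[pairs]
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
  best <- NULL
  for (ti in seq_along(topos)) {
    phy <- topos[[ti]]  # [[ restores tip labels on a compressed multiPhylo
    ne <- nrow(phy$edge)
    A <- matrix(0, nrow(pairs), ne)
    for (p in seq_len(nrow(pairs))) {
      i <- which(phy$tip.label == ids[pairs[p, 1]])
      j <- which(phy$tip.label == ids[pairs[p, 2]])
      path <- ape::nodepath(phy, i, j)
      for (k in seq_len(length(path) - 1)) {
        e <- which((phy$edge[, 1] == path[k] & phy$edge[, 2] == path[k + 1]) |
                   (phy$edge[, 2] == path[k] & phy$edge[, 1] == path[k + 1]))
        A[p, e] <- 1
      }
    }
    fit <- stats::lm.fit(A, d)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      phy$edge.length <- unname(fit$coefficients)
      best <- list(tree = phy, rss = rss)
    }
  }
  best
}

#' Write a tree with support values as Newick
#'
#' @param tree `phylo` object (optionally with `node.label` support).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
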