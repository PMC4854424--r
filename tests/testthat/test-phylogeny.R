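# Progressive alignment, p-distance, neighbor joining and bootstrap.

test_that("identical sequences align without gaps", {
  al <- align_progressive(c(a = "WRKYGQK", b = "WRKYGQK", c = "WRKYGQK"))
  expect_true(all(!grepl("-", unclass(al), fixed = TRUE)))
  expect_equal(unique(nchar(unclass(al))), 7)
})

test_that("a single deletion gives exactly one gap column", {
  al <- align_progressive(c(a = "WRKYGQK", b = "WRKYGK"))
  mat <- do.call(rbind, strsplit(unclass(al), ""))
  gap_cols <- sum(apply(mat, 2, function(x) any(x == "-")))
  expect_equal(gap_cols, 1)
  # agreement with an independent pairwise dynamic-programming alignment
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("WRKYGQK"), Biostrings::AAString("WRKYGK"),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  expect_equal(unname(unclass(al)["a"]),
               as.character(Biostrings::alignedPattern(pa)))
  expect_equal(unname(unclass(al)["b"]),
               as.character(Biostrings::alignedSubject(pa)))
})

test_that("ungapping aligned rows reproduces the inputs", {
  sim <- small_family(seed = 3, decoys = 0)
  doms <- scan_proteome(sim$proteins)
  seqs <- vapply(names(sim$proteins), function(id) {
    wrkycensus:::cterm_domain_seq(sim$proteins[[id]], doms[[id]])
  }, "")
  al <- align_progressive(seqs)
  expect_equal(unique(nchar(unclass(al))), unique(nchar(unclass(al)))[1])
  expect_gte(unique(nchar(unclass(al)))[1], max(nchar(seqs)))
  for (id in names(seqs)) {
    expect_equal(gsub("-", "", al[[id]], fixed = TRUE),
                 unname(seqs[[id]]), info = id)
  }
  expect_error(align_progressive(c(a = "WRKY", b = "")), "empty|zero")
})

test_that("p-distance counts mismatches over gap-free columns", {
  al <- structure(c(a = "AAAA", b = "AAAT"), class = "wrky_alignment")
  expect_equal(p_distance(al)["a", "b"], 0.25)
  al2 <- structure(c(a = "AA-A", b = "AATA"), class = "wrky_alignment")
  expect_equal(p_distance(al2)["a", "b"], 0)
  al3 <- structure(c(a = "AC-A", b = "AT-A"), class = "wrky_alignment")
  expect_equal(p_distance(al3)["a", "b"], 1 / 3)
  expect_equal(diag(p_distance(al)), c(a = 0, b = 0))
  al4 <- structure(c(a = "A-", b = "-A"), class = "wrky_alignment")
  expect_error(p_distance(al4), "comparable")
  expect_equal(p_distance(al4, on_empty = "max")["a", "b"], 1)
})

test_that("3-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- nj_tree(D)
  len <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(len[["A"]], (2 + 4 - 4) / 2)
  expect_equal(len[["B"]], (2 + 4 - 4) / 2)
  expect_equal(len[["C"]], (4 + 4 - 2) / 2)
  bad <- D; bad[1, 2] <- 3
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers additive matrices exactly (vs exhaustive search)", {
  set.seed(11)
  for (n in c(4, 5)) {
    for (i in 1:10) {
      gen <- random_additive_matrix(n)
      phy <- nj_tree(gen$D)
      ls <- ls_tree_search(gen$D)
      expect_equal(ape::dist.topo(ape::unroot(phy), ls$tree), 0,
                   ignore_attr = TRUE)
      expect_lt(max(abs(ape::cophenetic.phylo(phy)[rownames(gen$D),
                                                   colnames(gen$D)] -
                        gen$D)), 1e-8)
      expect_lt(ls$rss, 1e-12)
    }
  }
})

test_that("bootstrap supports are seeded, reproducible and sensible", {
  sim <- small_family(seed = 19, decoys = 0)
  doms <- scan_proteome(sim$proteins)
  seqs <- vapply(names(sim$proteins), function(id) {
    wrkycensus:::cterm_domain_seq(sim$proteins[[id]], doms[[id]])
  }, "")
  al <- align_progressive(seqs[1:8])
  b1 <- nj_bootstrap(al, replicates = 50, seed = 4)
  b2 <- nj_bootstrap(al, replicates = 50, seed = 4)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- as.numeric(b1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_equal(length(b1$node.label), b1$Nnode)
})

test_that("four identical-pair groups bootstrap to full support", {
  # two clearly distinct pairs, no homoplasy
  al <- structure(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                    c = "TTTTTTTTTT", d = "TTTTTTTTTT"),
                  class = "wrky_alignment")
  b <- nj_bootstrap(al, replicates = 50, seed = 1)
  sup <- as.numeric(b$node.label)
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("supports are invariant to leaf order", {
  al_rows <- c(a = "AAAAAAAAAA", b = "AAAAAAAATT",
               c = "TTTTTTTTAA", d = "TTTTTTTTTT")
  b1 <- nj_bootstrap(structure(al_rows, class = "wrky_alignment"),
                     replicates = 100, seed = 2)
  b2 <- nj_bootstrap(structure(rev(al_rows), class = "wrky_alignment"),
                     replicates = 100, seed = 2)
  expect_equal(ape::dist.topo(b1, b2), 0, ignore_attr = TRUE)
  expect_setequal(b1$node.label, b2$node.label)
})

test_that("negative branch lengths are clamped with a warning", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[upper.tri(D)] <- c(3.39, 4.35, 6.16, 9.17, 2.82, 9.09)
  D <- D + t(D)
  expect_warning(phy <- nj_tree(D), "clamped")
  expect_true(all(phy$edge.length >= 0))
})
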