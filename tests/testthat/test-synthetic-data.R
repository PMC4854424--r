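# The generators themselves: planted signatures, determinism, format
# validity and error handling.

test_that("planted group signatures appear exactly as specified", {
  spec <- family_spec(c(IIc = 1L), n_decoys = 0L, seed = 1L)
  sim <- sim_proteins(spec)
  expect_equal(length(sim$proteins), 1)
  s <- sim$proteins[[1]]
  expect_true(grepl("WRKYGQK", s, fixed = TRUE))
  dom <- scan_proteome(sim$proteins)[[1]]
  expect_equal(nrow(dom), 1)
  expect_equal(c(dom$m, dom$n), c(4, 23))           # C-X4-C-X23-H-X-H
  expect_equal(dom$finger_class, "C2H2")
  expect_equal(sim$truth$proteins$group, "IIc")

  spec3 <- family_spec(c(III = 1L, I = 1L), seed = 2L)
  sim3 <- sim_proteins(spec3)
  doms <- scan_proteome(sim3$proteins)
  d_iii <- doms[[grep("III", names(doms))]]
  expect_equal(c(d_iii$m, d_iii$n), c(7, 23))       # C-X7-C-X23-H-X-C
  expect_equal(d_iii$finger_class, "C2HC")
  d_i <- doms[[grep("_I_", names(doms))]]
  expect_equal(nrow(d_i), 2)                        # two complete domains
  expect_true(all(d_i$complete))
})

test_that("generators are byte-deterministic under a fixed seed", {
  spec <- family_spec(c(I = 1L, IIa = 2L, III = 1L), n_decoys = 2L,
                      seed = 5L)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(sim_proteins(spec)$proteins, f1)
  write_fasta(sim_proteins(spec)$proteins, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  g1 <- sim_genome(n_genes = 4, seed = 9)
  g2 <- sim_genome(n_genes = 4, seed = 9)
  expect_identical(g1$gff, g2$gff)
  expect_identical(g1$genome, g2$genome)

  e1 <- sim_expression(n_genes = 10, noise_sd = 0.2, seed = 4)
  e2 <- sim_expression(n_genes = 10, noise_sd = 0.2, seed = 4)
  expect_identical(e1$matrix, e2$matrix)
})

test_that("decoys carry no core heptapeptide", {
  spec <- family_spec(c(IIc = 0L), n_decoys = 10L, seed = 13L)
  sim <- sim_proteins(spec)
  expect_equal(length(sim$proteins), 10)
  for (s in sim$proteins) {
    expect_equal(length(brute_force_cores(s)), 0)
  }
})

test_that("invalid specs are rejected", {
  expect_error(sim_proteins(family_spec(c(IIc = 0L), n_decoys = 0L)),
               "empty spec")
  expect_error(family_spec(c(X = 1L)), "unknown group")
  expect_error(family_spec(c(IIc = 1L), flank_length_range = c(50, 10)),
               "min > max")
  expect_error(sim_expression(stages = c(18, 18, 30)), "increasing")
  expect_error(sim_genome(4, cluster_plan = list(
    list(chrom = 1, n = 2, span = 900000)), cluster_gap = 200000),
    "beyond the cluster gap")
  expect_error(sim_genome(4, n_chromosomes = 1, cluster_plan = list(
    list(chrom = 3, n = 2, span = 50000))), "chromosome")
})

test_that("an empty genome yields an empty GFF3 body and truth", {
  sim <- sim_genome(n_genes = 0, n_chromosomes = 1, chrom_size = 1e4,
                    seed = 1)
  expect_true(all(grepl("^##", sim$gff)))
  expect_null(sim$truth$genes)
  expect_equal(nchar(sim$genome[[1]]), 1e4)
})

test_that("emitted files parse with standard readers", {
  sim <- sim_genome(n_genes = 4, n_chromosomes = 2, chrom_size = 1e6,
                    seed = 21)
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_sim_genome(sim, gff, fa)
  gr <- rtracklayer::import(gff, format = "gff3")
  expect_true(all(c("gene", "mRNA", "exon", "CDS") %in%
                  as.character(gr$type)))
  dna <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(dna), names(sim$genome))
  expect_equal(Biostrings::width(dna)[[1]], 1e6)
  # FASTA written at 60 columns
  spec <- family_spec(c(I = 1L), seed = 3L)
  pf <- tempfile(fileext = ".faa")
  write_fasta(sim_proteins(spec)$proteins, pf)
  body <- readLines(pf)
  expect_true(all(nchar(body[!startsWith(body, ">")]) <= 60))
})

test_that("truth sets reference only emitted records", {
  sim <- small_family(seed = 37)
  expect_true(all(sim$truth$domains$id %in% names(sim$proteins)))
  expect_true(all(sim$truth$motifs$id %in% names(sim$proteins)))
  g <- sim_genome(n_genes = 6, tandem_pairs = 1, seed = 3)
  expect_true(all(g$truth$introns$gene_id %in% g$truth$genes$gene_id))
  expect_true(all(c(g$truth$tandem$gene1, g$truth$tandem$gene2) %in%
                  g$truth$genes$gene_id))
  # truth JSON serializes
  p <- tempfile(fileext = ".json")
  write_truth(g$truth, p)
  back <- jsonlite::read_json(p)
  expect_named(back, c("genes", "introns", "clusters", "tandem"))
})

test_that("planted motifs land where recorded and flags fire", {
  spec <- family_spec(c(IId = 2L, IIa = 1L), seed = 8L)
  sim <- sim_proteins(spec)
  expect_equal(sort(sim$truth$motifs$id),
               sort(names(sim$proteins)[grepl("IId", names(sim$proteins))]))
  for (k in seq_len(nrow(sim$truth$motifs))) {
    id <- sim$truth$motifs$id[k]
    expect_true(scan_named_motifs(sim$proteins[[id]])$harf, info = id)
  }
  # domain truth still aligns with the scanner after insertion shifts
  doms <- scan_proteome(sim$proteins)
  for (id in names(doms)) {
    tr <- sim$truth$domains[sim$truth$domains$id == id, ]
    expect_equal(doms[[id]]$span_start, tr$span_start, info = id)
  }
})
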