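# GFF3 gene models, intron derivation, phases and R-/V-type calls.

write_gff_fixture <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("models derive introns from CDS gaps with coordinate conversion", {
  gff <- write_gff_fixture(c(
    "chr1\ttest\tgene\t101\t260\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t260\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\tCDS\t101\t130\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\ttest\tCDS\t201\t260\t.\t+\t0\tID=g1.c2;Parent=g1.t1",
    "chr1\ttest\tgene\t501\t560\t.\t+\t.\tID=g2",
    "chr1\ttest\tmRNA\t501\t560\t.\t+\t.\tID=g2.t1;Parent=g2",
    "chr1\ttest\tCDS\t501\t560\t.\t+\t0\tID=g2.c1;Parent=g2.t1"))
  models <- build_gene_models(gff)
  expect_setequal(names(models), c("g1", "g2"))
  # 1-based inclusive [101,130] converts to 0-based half-open [100,130)
  expect_equal(unname(models$g1$cds),
               matrix(c(100L, 200L, 130L, 260L), ncol = 2))
  expect_equal(unname(models$g1$introns), matrix(c(130L, 200L), ncol = 2))
  expect_equal(nrow(models$g2$introns), 0)
  expect_equal(length(intron_phases(models$g2)), 0)
})

test_that("minus-strand models keep the genomic intron, reversed order", {
  plus <- write_gff_fixture(c(
    "chr1\ttest\tgene\t101\t260\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t260\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\tCDS\t101\t130\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\ttest\tCDS\t201\t260\t.\t+\t0\tID=g1.c2;Parent=g1.t1"))
  minus <- write_gff_fixture(c(
    "chr1\ttest\tgene\t101\t260\t.\t-\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t260\t.\t-\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\tCDS\t101\t130\t.\t-\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\ttest\tCDS\t201\t260\t.\t-\t0\tID=g1.c2;Parent=g1.t1"))
  mp <- build_gene_models(plus)$g1
  mm <- build_gene_models(minus)$g1
  expect_equal(unname(mp$introns), unname(mm$introns))
  # transcription order flips: the minus model starts at the 3'-most segment
  expect_equal(unname(mm$cds[1, "start"]), 200L)
  expect_equal(nrow(mm$introns), nrow(mp$introns))
})

test_that("intron phase is upstream CDS length mod 3", {
  mk <- function(len1) {
    gff <- write_gff_fixture(c(
      "chr1\ttest\tgene\t1\t500\t.\t+\t.\tID=g",
      "chr1\ttest\tmRNA\t1\t500\t.\t+\t.\tID=g.t;Parent=g",
      sprintf("chr1\ttest\tCDS\t1\t%d\t.\t+\t0\tID=g.c1;Parent=g.t", len1),
      sprintf("chr1\ttest\tCDS\t401\t%d\t.\t+\t0\tID=g.c2;Parent=g.t",
              400 + (6 - len1 %% 3))))
    suppressWarnings(build_gene_models(gff)$g)
  }
  expect_equal(intron_phases(mk(30)), 0L)
  expect_equal(intron_phases(mk(31)), 1L)
  expect_equal(intron_phases(mk(32)), 2L)
})

test_that("overlapping CDS and orphan CDS are rejected", {
  bad <- write_gff_fixture(c(
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=g.t;Parent=g",
    "chr1\ttest\tCDS\t1\t50\t.\t+\t0\tID=g.c1;Parent=g.t",
    "chr1\ttest\tCDS\t40\t90\t.\t+\t0\tID=g.c2;Parent=g.t"))
  expect_error(build_gene_models(bad), "overlap")
})

test_that("R-, V- and outside-domain introns are typed from planted genes", {
  sim <- sim_genome(n_genes = 8, n_chromosomes = 2, chrom_size = 1.5e6,
                    intron_plan = list("R", "V", "other", "none",
                                       character(0)),
                    seed = 23)
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_sim_genome(sim, gff, fa)
  models <- build_gene_models(gff)
  doms <- scan_proteome(sim$proteins)
  itab <- intron_table(models, doms, sim$proteins)
  m <- merge(itab, sim$truth$introns, by = c("gene_id", "index"))
  expect_gt(nrow(m), 0)
  expect_equal(m$splice_type, m$type)
  expect_equal(m$phase.x, m$phase.y)
  # translated CDS reproduces the planted protein on both strands
  for (g in names(models)) {
    expect_equal(model_cds_protein(models[[g]], sim$genome)$protein,
                 unname(sim$proteins[[g]]), info = g)
  }
  # intron count conservation
  for (g in names(models)) {
    expect_equal(nrow(models[[g]]$introns), nrow(models[[g]]$cds) - 1)
  }
})

test_that("strand flip of a locus leaves structure calls unchanged", {
  sim <- sim_genome(n_genes = 1, n_chromosomes = 1, chrom_size = 2e5,
                    intron_plan = list(c("R", "V")), seed = 31)
  gff_lines <- sim$gff
  L <- nchar(sim$genome[[1]])
  flip <- function(line) {
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < 8) return(line)
    s <- as.integer(f[4]); e <- as.integer(f[5])
    f[4] <- as.character(L - e + 1); f[5] <- as.character(L - s + 1)
    f[7] <- if (f[7] == "+") "-" else "+"
    paste(f, collapse = "\t")
  }
  flipped <- vapply(gff_lines, flip, "")
  p1 <- tempfile(fileext = ".gff3"); writeLines(gff_lines, p1)
  p2 <- tempfile(fileext = ".gff3"); writeLines(flipped, p2)
  m1 <- build_gene_models(p1)[[1]]
  m2 <- build_gene_models(p2)[[1]]
  g2 <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sim$genome[[1]])))
  names(g2) <- names(sim$genome)
  prot1 <- model_cds_protein(m1, sim$genome)$protein
  prot2 <- model_cds_protein(m2, g2)$protein
  expect_equal(prot1, prot2)
  expect_equal(intron_phases(m1), intron_phases(m2))
  dom <- scan_proteome(c(g = prot1))$g
  ann1 <- classify_domain_introns(m1, dom[1, ], prot1)
  ann2 <- classify_domain_introns(m2, dom[1, ], prot2)
  expect_equal(ann1$splice_type, ann2$splice_type)
  expect_equal(ann1$splice_type, c("R", "V"))
})

test_that("a domain span beyond the protein is rejected", {
  sim <- sim_genome(n_genes = 1, n_chromosomes = 1, chrom_size = 2e5,
                    intron_plan = list("R"), seed = 5)
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_sim_genome(sim, gff, fa)
  model <- build_gene_models(gff)[[1]]
  prot <- sim$proteins[[1]]
  fake <- data.frame(span_start = 0, span_end = nchar(prot) + 50, c2 = 10)
  expect_error(classify_domain_introns(model, fake, prot), "beyond")
})
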