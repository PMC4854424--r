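# Synthetic genome and expression generators: GFF3 gene models with
# planted domain introns, chromosome layouts with planted clusters and
# tandem pairs, and expression matrices with planted qualitative calls.

# One fixed codon per residue keeps reverse translation deterministic.
CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
           E = "GAA", Q = "CAA", G = "GGT", H = "CAT", I = "ATT",
           L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
           S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encode_cds <- function(protein) {
  paste0(paste(CODON[seq_chars(protein)], collapse = ""), "TAA")
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Transcript-coordinate split points (nt 5' of each intron) for a vector
# of planted splice types, given the domain landmarks of the encoded
# protein. R/V introns sit at phase 0 immediately before the targeted
# residue's codon; "other" splits the codon of a non-R domain residue
# (phase 2); "none" falls in the N-terminal flank at phase 1.
intron_breakpoints <- function(types, dom_offset, c2_rel) {
  u <- vapply(types, function(ty) {
    switch(ty,
      R = 3L * (dom_offset + 1L),             # core arginine (WRKYGQK)
      V = 3L * (dom_offset + c2_rel + 6L),    # valine at second Cys + 6
      other = 3L * (dom_offset + 3L) + 2L,    # splits the core tyrosine codon
      none = 16L,                             # flank, phase 1
      stop("unknown splice type: ", ty))
  }, 0L)
  if (anyDuplicated(u)) stop("duplicate intron positions in plan: ",
                             paste(types, collapse = ","))
  sort(u)
}

#' Generate a synthetic genome with planted gene features
#'
#' Emits a GFF3 gene set (gene/mRNA/exon/CDS, alternating strands) and the
#' matching chromosome sequences. Every gene encodes a single-domain WRKY
#' protein (IIb-style signature, so both R- and V-type domain introns have
#' their target residues). `cluster_plan` plants within-threshold gene
#' clusters; `tandem_pairs` converts the first pairs of cluster members
#' into near-identical duplicates (extra 2-gene clusters are created when
#' the plan has too few).
#'
#' @param n_genes total number of genes.
#' @param n_chromosomes number of chromosomes (default 2).
#' @param chrom_size chromosome length in bp (default 1 Mb; genes never
#'   overlap).
#' @param cluster_plan list of `list(chrom =, n =, span =)` entries; spans
#'   must keep consecutive members within `cluster_gap`.
#' @param tandem_pairs number of tandem-duplicate pairs to plant.
#' @param intron_plan list (recycled over genes) of character vectors over
#'   `R`, `V`, `other`, `none`; `character(0)` gives an intron-less gene.
#' @param cluster_gap the downstream cluster-chaining threshold the plan
#'   must respect (bp).
#' @param seed integer seed.
#' @return list with `gff` (character lines), `genome` (named character of
#'   chromosome sequences), `proteins` (named character) and `truth`
#'   (data.frames `genes`, `introns`, `clusters`, `tandem`).
#' @export
sim_genome <- function(n_genes, n_chromosomes = 2L, chrom_size = 1e6,
                       cluster_plan = NULL, tandem_pairs = 0L,
                       intron_plan = NULL, cluster_gap = 200000,
                       seed = 1L) {
  set.seed(seed)
  header <- c("##gff-version 3",
              sprintf("##sequence-region chr%d 1 %d",
                      seq_len(n_chromosomes), as.integer(chrom_size)))
  if (n_genes == 0) {
    genome <- stats::setNames(
      vapply(seq_len(n_chromosomes), function(i) random_dna(chrom_size), ""),
      paste0("chr", seq_len(n_chromosomes)))
    return(list(gff = header, genome = genome, proteins = character(0),
                truth = list(genes = NULL, introns = NULL, clusters = NULL,
                             tandem = NULL)))
  }
  if (is.null(intron_plan)) {
    intron_plan <- list("R", "V", "other", character(0), "none")
  }
  cluster_plan <- if (is.null(cluster_plan)) list() else cluster_plan
  n_extra_tandem <- max(0L, tandem_pairs - length(cluster_plan))
  if (n_extra_tandem > 0) {
    for (k in seq_len(n_extra_tandem)) {
      cluster_plan <- c(cluster_plan,
                        list(list(chrom = 1L + (k - 1L) %% n_chromosomes,
                                  n = 2L, span = 10000)))
    }
  }
  for (i in seq_along(cluster_plan)) {
    cp <- cluster_plan[[i]]
    if (cp$n < 2) stop("cluster plan entry ", i, " has fewer than 2 members")
    if (cp$span / (cp$n - 1) > cluster_gap) {
      stop("cluster plan entry ", i,
           " spaces members beyond the cluster gap (span ", cp$span,
           ", members ", cp$n, ")")
    }
    if (cp$chrom > n_chromosomes) {
      stop("cluster plan entry ", i, " names chromosome ", cp$chrom,
           " but only ", n_chromosomes, " exist")
    }
  }
  cluster_plan <- lapply(cluster_plan, function(cp) {
    cp$n <- as.integer(cp$n); cp$chrom <- as.integer(cp$chrom); cp
  })
  n_clustered <- sum(vapply(cluster_plan, function(cp) cp$n, 0L))
  if (n_clustered > n_genes) {
    stop("cluster plan places ", n_clustered, " genes but n_genes = ", n_genes)
  }
  if (tandem_pairs > length(cluster_plan)) {
    stop("cannot plant ", tandem_pairs, " tandem pairs in ",
         length(cluster_plan), " clusters")
  }

  # ---- layout: slot genes onto chromosomes -------------------------------
  spacing <- 1.5 * cluster_gap
  slots <- vector("list", n_genes)   # per gene: chrom, start, cluster, tandem
  cursor <- rep(50000, n_chromosomes)
  gi <- 0L
  clusters_truth <- NULL
  tandem_truth <- NULL
  for (ci in seq_along(cluster_plan)) {
    cp <- cluster_plan[[ci]]
    step <- cp$span / (cp$n - 1)
    starts <- round(cursor[cp$chrom] + (seq_len(cp$n) - 1L) * step)
    members <- gi + seq_len(cp$n)
    for (j in seq_len(cp$n)) {
      slots[[members[j]]] <- list(chrom = cp$chrom, start = starts[j],
                                  cluster = ci,
                                  tandem = if (ci <= tandem_pairs && j <= 2)
                                    ci else NA_integer_)
    }
    clusters_truth <- rbind(clusters_truth, data.frame(
      cluster_id = ci, chrom = paste0("chr", cp$chrom), n_members = cp$n,
      span_bp = cp$span))
    cursor[cp$chrom] <- max(starts) + spacing
    gi <- gi + cp$n
  }
  while (gi < n_genes) {
    gi <- gi + 1L
    ch <- which.min(cursor)
    slots[[gi]] <- list(chrom = ch, start = round(cursor[ch]),
                        cluster = NA_integer_, tandem = NA_integer_)
    cursor[ch] <- cursor[ch] + spacing
  }

  # ---- build genes -------------------------------------------------------
  genes <- vector("list", n_genes)
  intron_rows <- list()
  for (g in seq_len(n_genes)) {
    types <- intron_plan[[1L + (g - 1L) %% length(intron_plan)]]
    slot <- slots[[g]]
    gene_id <- sprintf("SYNG%03d", g)
    tandem_source <- NULL
    if (!is.na(slot$tandem)) {
      mate <- Filter(function(x) !is.null(x$protein) &&
                       identical(x$tandem, slot$tandem), genes)
      if (length(mate) > 0) tandem_source <- mate[[1]]
    }
    if (is.null(tandem_source)) {
      flank_n <- random_flank(60)
      flank_c <- random_flank(60)
      dom <- build_domain(FINGER_TEMPLATES$IIb)
      protein <- paste0(flank_n, dom$seq, flank_c)
      dom_offset <- nchar(flank_n)
    } else {
      # near-identical copy: two substitutions in the C-terminal flank
      protein <- tandem_source$protein
      dom_offset <- tandem_source$dom_offset
      dom <- tandem_source$dom
      chars <- seq_chars(protein)
      pos <- sample((dom_offset + dom$t + 2L):length(chars), 2L)
      for (p in pos) chars[p] <- sample(setdiff(SPACER_AA, chars[p]), 1)
      protein <- paste(chars, collapse = "")
    }
    cds <- encode_cds(protein)
    u <- if (length(types) > 0) {
      intron_breakpoints(types, dom_offset, dom$c2)
    } else integer(0)
    type_order <- if (length(types) > 0) {
      types[order(intron_breakpoints(types, dom_offset, dom$c2))]
    } else character(0)
    # assemble transcript: CDS segments interleaved with introns
    seg_bounds <- c(0L, u, nchar(cds))
    seg_seqs <- substring(cds, utils::head(seg_bounds, -1) + 1L,
                          seg_bounds[-1])
    introns <- vapply(seq_along(u), function(i) {
      paste0("GT", random_dna(sample(76:196, 1)), "AG")
    }, "")
    tx <- character(0)
    tx_pos <- 0L
    seg_tx <- matrix(0L, nrow = length(seg_seqs), ncol = 2)
    for (i in seq_along(seg_seqs)) {
      tx <- c(tx, seg_seqs[i])
      seg_tx[i, ] <- c(tx_pos, tx_pos + nchar(seg_seqs[i]))
      tx_pos <- tx_pos + nchar(seg_seqs[i])
      if (i <= length(introns)) {
        tx <- c(tx, introns[i])
        tx_pos <- tx_pos + nchar(introns[i])
      }
    }
    gene_seq <- paste(tx, collapse = "")
    strand <- if (g %% 2 == 1) "+" else "-"
    genes[[g]] <- list(gene_id = gene_id, chrom = slot$chrom,
                       start = slot$start, strand = strand,
                       cluster = slot$cluster, tandem = slot$tandem,
                       protein = protein, dom = dom, dom_offset = dom_offset,
                       gene_seq = gene_seq, seg_tx = seg_tx)
    if (length(u) > 0) {
      intron_rows[[gene_id]] <- data.frame(
        gene_id = gene_id, index = seq_along(u), type = type_order,
        phase = as.integer(u %% 3))
    }
  }

  # ---- feasibility and genome assembly -----------------------------------
  gff <- header
  genome <- character(n_chromosomes)
  names(genome) <- paste0("chr", seq_len(n_chromosomes))
  for (ch in seq_len(n_chromosomes)) {
    on_ch <- Filter(function(x) x$chrom == ch, genes)
    on_ch <- on_ch[order(vapply(on_ch, function(x) x$start, 0))]
    pieces <- character(0)
    cur <- 0
    for (x in on_ch) {
      L <- nchar(x$gene_seq)
      if (x$start < cur) stop("infeasible packing: gene ", x$gene_id,
                              " overlaps its predecessor on chr", ch)
      if (x$start + L > chrom_size) {
        stop("infeasible packing: gene ", x$gene_id, " exceeds chr", ch,
             " size ", chrom_size)
      }
      pieces <- c(pieces, random_dna(x$start - cur),
                  if (x$strand == "+") x$gene_seq else revcomp(x$gene_seq))
      cur <- x$start + L
    }
    pieces <- c(pieces, random_dna(chrom_size - cur))
    genome[ch] <- paste(pieces, collapse = "")
  }
  for (x in genes[order(vapply(genes, function(z) z$chrom * 1e10 + z$start,
                               0))]) {
    gff <- c(gff, gene_gff_lines(x))
  }

  genes_truth <- do.call(rbind, lapply(genes, function(x) {
    data.frame(gene_id = x$gene_id, chrom = paste0("chr", x$chrom),
               start = x$start, end = x$start + nchar(x$gene_seq),
               strand = x$strand, cluster_id = x$cluster,
               tandem_id = x$tandem, protein = x$protein,
               dom_offset = x$dom_offset, c2 = x$dom_offset + x$dom$c2,
               span_start = x$dom_offset,
               span_end = x$dom_offset + x$dom$t + 1L)
  }))
  tandem_ids <- unique(stats::na.omit(genes_truth$tandem_id))
  if (length(tandem_ids) > 0) {
    tandem_truth <- do.call(rbind, lapply(tandem_ids, function(ti) {
      pair <- genes_truth$gene_id[!is.na(genes_truth$tandem_id) &
                                  genes_truth$tandem_id == ti]
      data.frame(tandem_id = ti, gene1 = pair[1], gene2 = pair[2])
    }))
  }
  proteins <- stats::setNames(genes_truth$protein, genes_truth$gene_id)
  list(gff = gff, genome = genome, proteins = proteins,
       truth = list(genes = genes_truth,
                    introns = if (length(intron_rows) > 0)
                      do.call(rbind, unname(intron_rows)) else NULL,
                    clusters = clusters_truth, tandem = tandem_truth))
}

# GFF3 lines (gene, mRNA, exon, CDS) for one synthetic gene.
gene_gff_lines <- function(x) {
  chrom <- paste0("chr", x$chrom)
  L <- nchar(x$gene_seq)
  g1 <- x$start + 1L
  g2 <- x$start + L
  tx_id <- paste0(x$gene_id, ".t1")
  lines <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, g1, g2,
            x$strand, x$gene_id),
    sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", chrom, g1,
            g2, x$strand, tx_id, x$gene_id))
  cum <- 0L
  for (i in seq_len(nrow(x$seg_tx))) {
    a <- x$seg_tx[i, 1]; b <- x$seg_tx[i, 2]
    if (x$strand == "+") {
      s1 <- x$start + a + 1L; s2 <- x$start + b
    } else {
      s1 <- x$start + L - b + 1L; s2 <- x$start + L - a
    }
    phase <- (3L - cum %% 3L) %% 3L
    lines <- c(lines,
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              chrom, s1, s2, x$strand, tx_id, i, tx_id),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
              chrom, s1, s2, x$strand, phase, tx_id, i, tx_id))
    cum <- cum + (b - a)
  }
  lines
}

#' Write GFF3 lines and genome FASTA
#'
#' @param sim result of [sim_genome()].
#' @param gff_path,fasta_path output paths.
#' @return invisible list of the two paths.
#' @export
write_sim_genome <- function(sim, gff_path, fasta_path) {
  writeLines(sim$gff, gff_path)
  dna <- Biostrings::DNAStringSet(unname(sim$genome))
  names(dna) <- names(sim$genome)
  Biostrings::writeXStringSet(dna, filepath = fasta_path, width = 70L)
  invisible(list(gff = gff_path, fasta = fasta_path))
}

#' Generate a synthetic expression study
#'
#' Emulates a four-organ panel, a fruit developmental series over
#' days-after-flowering stages, and paired treatment/control samples at
#' two stages. Planted labels drive the values: expressed tissues get a
#' clear positive abundance, trends follow geometric series with the
#' planted direction, treatment responses use four-fold separation, and
#' noise is multiplicative log2-normal (additive Gaussian on the log2
#' scale), leaving exact zeros untouched.
#'
#' @param n_genes number of genes (used when `planted` is `NULL`).
#' @param tissues organ panel.
#' @param stages strictly increasing DAF stages.
#' @param treatments treatment arms with paired controls.
#' @param treat_stages stages at which treatments are applied.
#' @param planted optional data.frame with `gene_id`, `tissues`
#'   (comma-separated subset of the panel, `""` = not expressed), `trend`
#'   and one `response.<treatment>` column per treatment; randomly drawn
#'   when `NULL`.
#' @param noise_sd standard deviation of log2 noise.
#' @param seed integer seed.
#' @return list with `matrix`, `meta` and `truth` (the planted labels).
#' @export
sim_expression <- function(n_genes = 50L,
                           tissues = c("root", "stem", "leaf", "fruit"),
                           stages = c(18L, 24L, 30L, 36L, 42L),
                           treatments = c("IAA", "ABA", "sucrose"),
                           treat_stages = c(18L, 36L),
                           planted = NULL, noise_sd = 0, seed = 1L) {
  if (any(diff(stages) <= 0)) stop("stages must be strictly increasing")
  set.seed(seed)
  trends <- c("up", "down", "flat", "mixed")
  responses <- c("induced", "repressed", "unchanged", "undetected")
  if (is.null(planted)) {
    planted <- data.frame(gene_id = sprintf("SYNE%03d", seq_len(n_genes)))
    planted$tissues <- vapply(seq_len(n_genes), function(i) {
      paste(tissues[stats::runif(length(tissues)) < 0.7], collapse = ",")
    }, "")
    planted$trend <- sample(trends, n_genes, replace = TRUE)
    for (tr in treatments) {
      planted[[paste0("response.", tr)]] <-
        sample(responses, n_genes, replace = TRUE)
    }
  }
  n <- nrow(planted)
  has_fruit <- vapply(strsplit(planted$tissues, ","), function(x)
    "fruit" %in% x, TRUE)
  planted$trend[!has_fruit] <- "flat"

  meta <- data.frame(sample = tissues, tissue = tissues, stage = NA_integer_,
                     treatment = "none", control_pair = "")
  meta <- rbind(meta, data.frame(
    sample = paste0("Day", stages), tissue = "fruit", stage = stages,
    treatment = "none", control_pair = ""))
  for (tr in treatments) {
    for (st in treat_stages) {
      trt <- sprintf("%s.%dd", tr, st)
      ck <- sprintf("%s.CK.%dd", tr, st)
      meta <- rbind(meta,
        data.frame(sample = ck, tissue = "fruit", stage = st,
                   treatment = "control", control_pair = ""),
        data.frame(sample = trt, tissue = "fruit", stage = st,
                   treatment = tr, control_pair = ck))
    }
  }
  mat <- matrix(0, nrow = n, ncol = nrow(meta),
                dimnames = list(planted$gene_id, meta$sample))
  k <- length(stages)
  trend_series <- list(up = 2^(seq_len(k) - 1),
                       down = rev(2^(seq_len(k) - 1)),
                       flat = rep(4, k),
                       mixed = rep(c(1, 8, 2, 16), length.out = k))
  for (i in seq_len(n)) {
    ts <- strsplit(planted$tissues[i], ",")[[1]]
    mat[i, ts] <- 8
    if (has_fruit[i]) {
      mat[i, paste0("Day", stages)] <- trend_series[[planted$trend[i]]]
    }
    for (tr in treatments) {
      lab <- planted[[paste0("response.", tr)]][i]
      vals <- switch(lab, induced = c(2, 8), repressed = c(8, 2),
                     unchanged = c(4, 4), undetected = c(0, 0))
      for (st in treat_stages) {
        mat[i, sprintf("%s.CK.%dd", tr, st)] <- vals[1]
        mat[i, sprintf("%s.%dd", tr, st)] <- vals[2]
      }
    }
  }
  if (noise_sd > 0) {
    nz <- mat > 0
    mat[nz] <- mat[nz] * 2^stats::rnorm(sum(nz), 0, noise_sd)
  }
  list(matrix = mat, meta = meta, truth = planted)
}

#' Write an expression matrix and metadata as TSV
#'
#' @param expr result of [sim_expression()] (or a list with `matrix` and
#'   `meta`).
#' @param matrix_path,meta_path output paths.
#' @return invisible list of the two paths.
#' @export
write_expression <- function(expr, matrix_path, meta_path) {
  tab <- data.frame(gene_id = rownames(expr$matrix), expr$matrix,
                    check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(matrix = matrix_path, meta = meta_path))
}

#' Serialize a truth set as JSON
#'
#' @param truth truth list from any generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
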