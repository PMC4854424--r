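# Exon-intron organization from GFF3 gene models: derived introns, intron
# phases 0/1/2, and R-/V-type classification of introns that interrupt the
# WRKY domain. GFF3 coordinates (1-based inclusive) are converted to
# 0-based half-open on load; transcription order is genomic order on the
# plus strand and reverse genomic order on the minus strand.

#' Build gene models from GFF3
#'
#' Imports a GFF3 file (or takes an already-imported `GRanges`) and builds
#' one model per gene from its longest mRNA (by total CDS length). CDS
#' segments are stored 0-based half-open in transcription order; introns
#' are the genomic gaps between consecutive CDS segments.
#'
#' @param gff path to a GFF3 file, or a `GRanges` from
#'   `rtracklayer::import`.
#' @return named list of `gene_model` objects, each a list with `gene_id`,
#'   `tx_id`, `chrom`, `strand`, `cds` (matrix with columns `start`, `end`,
#'   transcription order), `introns` (same shape) and `phases`.
#' @export
build_gene_models <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3") else gff
  type <- as.character(gr$type)
  parents <- gr$Parent
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  cds_idx <- which(type == "CDS")
  if (length(cds_idx) == 0) return(list())
  n_par <- lengths(parents[cds_idx])
  if (any(n_par == 0)) {
    stop("CDS feature without Parent at ",
         paste(utils::head(which(n_par == 0)), collapse = ", "))
  }
  mrna_id <- gr$ID[mrna_idx]
  mrna_gene <- vapply(parents[mrna_idx], function(p) p[1], "")
  cds_parent <- vapply(parents[cds_idx], function(p) p[1], "")
  models <- list()
  for (k in seq_along(mrna_idx)) {
    tx <- mrna_id[k]
    seg <- cds_idx[cds_parent == tx]
    if (length(seg) == 0) next
    start0 <- GenomicRanges::start(gr)[seg] - 1L
    end0 <- GenomicRanges::end(gr)[seg]
    o <- order(start0)
    start0 <- start0[o]; end0 <- end0[o]
    if (length(start0) > 1 && any(start0[-1] < end0[-length(end0)])) {
      stop("overlapping CDS segments in mRNA ", tx)
    }
    strand <- as.character(GenomicRanges::strand(gr)[mrna_idx[k]])
    if (strand == "-") {
      start0 <- rev(start0); end0 <- rev(end0)
    }
    cds <- cbind(start = start0, end = end0)
    total <- sum(end0 - start0)
    if (total %% 3 != 0) {
      warning("CDS length of ", tx, " not divisible by 3")
    }
    model <- structure(list(
      gene_id = mrna_gene[k], tx_id = tx,
      chrom = as.character(GenomicRanges::seqnames(gr)[mrna_idx[k]]),
      strand = strand, cds = cds), class = "gene_model")
    model$introns <- model_introns(model)
    model$phases <- intron_phases(model)
    models[[tx]] <- model
  }
  # keep the longest mRNA per gene
  genes <- vapply(models, function(m) m$gene_id, "")
  lens <- vapply(models, function(m) sum(m$cds[, "end"] - m$cds[, "start"]), 0)
  keep <- unlist(lapply(split(seq_along(models), genes), function(ix) {
    ix[which.max(lens[ix])]
  }))
  out <- models[sort(keep)]
  names(out) <- vapply(out, function(m) m$gene_id, "")
  out
}

# Genomic intron intervals (0-based half-open) in transcription order.
model_introns <- function(model) {
  cds <- model$cds
  n <- nrow(cds)
  if (n < 2) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  if (model$strand == "-") {
    cbind(start = cds[2:n, "end"], end = cds[1:(n - 1), "start"])
  } else {
    cbind(start = cds[1:(n - 1), "end"], end = cds[2:n, "start"])
  }
}

#' Intron phases of a gene model
#'
#' Phase of intron i is the number of CDS nucleotides 5' of the intron
#' modulo 3: 0 falls between codons, 1 after the first nucleotide of a
#' codon, 2 after the second.
#'
#' @param model a `gene_model`.
#' @return integer vector of phases (length = number of introns).
#' @export
intron_phases <- function(model) {
  lens <- model$cds[, "end"] - model$cds[, "start"]
  if (length(lens) < 2) return(integer(0))
  as.integer(cumsum(lens)[-length(lens)] %% 3)
}

#' Extract and translate the coding sequence of a model
#'
#' @param model a `gene_model`.
#' @param genome named `DNAStringSet` (or named character) of chromosome
#'   sequences.
#' @return list with `cds` (DNA string) and `protein` (amino-acid string,
#'   trailing stop removed).
#' @export
model_cds_protein <- function(model, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom <- genome[[model$chrom]]
  segs <- model$cds
  pieces <- lapply(seq_len(nrow(segs)), function(i) {
    s <- Biostrings::subseq(chrom, segs[i, "start"] + 1L, segs[i, "end"])
    if (model$strand == "-") Biostrings::reverseComplement(s) else s
  })
  cds <- do.call(Biostrings::xscat, pieces)
  prot <- as.character(Biostrings::translate(cds, if.fuzzy.codon = "X"))
  prot <- sub("\\*$", "", prot)
  list(cds = as.character(cds), protein = prot)
}

#' Classify introns relative to a WRKY domain
#'
#' Maps each intron of a model to its protein-coordinate insertion point
#' (the residue whose codon contains the first nucleotide after the
#' intron; for phase-0 introns this is the first residue fully downstream)
#' and classifies introns inside the domain span: `R` if the residue
#' immediately 3' of the junction is arginine; `V` if it is valine at
#' position second-cysteine + 6; `other` for any other in-domain intron;
#' `none` for introns outside the domain.
#'
#' @param model a `gene_model`.
#' @param domain one complete domain row from [scan_proteome()] (needs
#'   `span_start`, `span_end`, `c2`; 0-based protein coordinates).
#' @param protein the model's translated protein sequence.
#' @param v_tolerance allowed deviation of the valine position from
#'   second-cysteine + 6 (default 0; set 1 for an inclusive count).
#' @return data.frame with one row per intron: `index`, `phase`,
#'   `residue_after` (0-based), `in_domain`, `splice_type`.
#' @export
classify_domain_introns <- function(model, domain, protein,
                                    v_tolerance = 0L) {
  if (domain$span_end > nchar(protein)) {
    stop("domain span extends beyond protein length")
  }
  lens <- model$cds[, "end"] - model$cds[, "start"]
  phases <- intron_phases(model)
  n_int <- length(phases)
  if (n_int == 0) {
    return(data.frame(index = integer(0), phase = integer(0),
                      residue_after = integer(0), in_domain = logical(0),
                      splice_type = character(0)))
  }
  upstream <- cumsum(lens)[-length(lens)]
  res_after <- as.integer(upstream %/% 3)
  in_dom <- res_after >= domain$span_start & res_after < domain$span_end
  residue <- substring(protein, res_after + 1L, res_after + 1L)
  v_pos <- domain$c2 + 6L
  type <- ifelse(!in_dom, "none",
          ifelse(residue == "R", "R",
          ifelse(residue == "V" & abs(res_after - v_pos) <= v_tolerance,
                 "V", "other")))
  data.frame(index = seq_len(n_int), phase = phases,
             residue_after = res_after, in_domain = in_dom,
             splice_type = type)
}

#' Intron summary table for a set of models
#'
#' Runs [classify_domain_introns()] against each gene's C-terminal
#' complete domain (when one exists) and tabulates all introns.
#'
#' @param models named list of `gene_model` objects.
#' @param domains named list from [scan_proteome()], keyed by gene id.
#' @param proteins named character vector of translated proteins, keyed by
#'   gene id.
#' @param v_tolerance passed to [classify_domain_introns()].
#' @return data.frame with `gene_id`, `index`, `phase`, `in_domain`,
#'   `splice_type` (splice columns NA for genes without a complete domain).
#' @export
intron_table <- function(models, domains, proteins, v_tolerance = 0L) {
  rows <- lapply(names(models), function(g) {
    model <- models[[g]]
    phases <- intron_phases(model)
    if (length(phases) == 0) return(NULL)
    dom <- domains[[g]]
    dom <- if (!is.null(dom)) dom[dom$complete, , drop = FALSE]
    if (!is.null(dom) && nrow(dom) > 0 && !is.null(proteins[[g]])) {
      last <- dom[which.max(dom$span_start), , drop = FALSE]
      ann <- classify_domain_introns(model, last, proteins[[g]], v_tolerance)
      data.frame(gene_id = g, ann[, c("index", "phase", "in_domain",
                                      "splice_type")])
    } else {
      data.frame(gene_id = g, index = seq_along(phases), phase = phases,
                 in_domain = NA, splice_type = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), index = integer(0),
                      phase = integer(0), in_domain = logical(0),
                      splice_type = character(0))
  }
  out
}
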