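# Chromosomal organization of the family: order-based naming, gene-cluster
# detection (Holub-style single-linkage chains), and tandem-duplication
# calling from sequence similarity of neighboring loci.

# Natural sort order for chromosome names: numeric part when present,
# lexicographic otherwise; unplaced labels sort last.
chrom_order <- function(chroms, unplaced = c("Un", "unplaced", "NA")) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", chroms)))
  is_un <- chroms %in% unplaced | is.na(chroms)
  order(is_un, num, chroms)
}

#' Assign order-based family names
#'
#' Numbers placed loci 1..k sorted by (chromosome in natural order, start);
#' unplaced loci get k+1.. in input order. Names are zero-padded to two
#' digits (`FvWRKY07` style).
#'
#' @param loci data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`; unplaced loci have `chrom` `NA` or an entry of
#'   `unplaced`.
#' @param prefix family name prefix (e.g. `"FvWRKY"`).
#' @param unplaced chromosome labels treated as unplaced.
#' @return the input data.frame with a `name` column, rows reordered to
#'   naming order.
#' @export
assign_names <- function(loci, prefix = "WRKY",
                         unplaced = c("Un", "unplaced", "NA")) {
  if (anyDuplicated(loci$gene_id)) {
    stop("duplicate gene ids: ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", "))
  }
  is_un <- loci$chrom %in% unplaced | is.na(loci$chrom)
  placed <- loci[!is_un, , drop = FALSE]
  placed <- placed[order(chrom_order_key(placed$chrom, unplaced),
                         placed$start), , drop = FALSE]
  out <- rbind(placed, loci[is_un, , drop = FALSE])
  width <- max(2L, nchar(nrow(out)))
  out$name <- sprintf(paste0("%s%0", width, "d"), prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Sortable key for chromosome names (rank in natural order).
chrom_order_key <- function(chroms, unplaced = c("Un", "unplaced", "NA")) {
  u <- unique(chroms)
  rank <- match(chroms, u[chrom_order(u, unplaced)])
  rank
}

#' Detect gene clusters on chromosomes
#'
#' Single-linkage chaining per chromosome: consecutive loci whose
#' start-to-start distance is at most `max_gap_bp` join one cluster;
#' singletons are discarded.
#'
#' @param loci data.frame as in [assign_names()] (placed loci only are
#'   considered).
#' @param max_gap_bp chaining threshold in bp (> 0).
#' @param unplaced chromosome labels treated as unplaced.
#' @return data.frame with one row per cluster member: `cluster_id`,
#'   `chrom`, `gene_id`, `start`; plus a `clusters` attribute summarizing
#'   `cluster_id`, `chrom`, `n_members`, `span_bp`.
#' @export
detect_clusters <- function(loci, max_gap_bp = 200000,
                            unplaced = c("Un", "unplaced", "NA")) {
  if (max_gap_bp <= 0) stop("max_gap_bp must be positive")
  is_un <- loci$chrom %in% unplaced | is.na(loci$chrom)
  placed <- loci[!is_un, , drop = FALSE]
  members <- NULL
  summaries <- NULL
  cid <- 0L
  for (ch in unique(placed$chrom)[chrom_order(unique(placed$chrom), unplaced)]) {
    sub <- placed[placed$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) == 0) next
    brk <- c(0L, cumsum(diff(sub$start) > max_gap_bp))
    for (g in split(seq_len(nrow(sub)), brk)) {
      if (length(g) < 2) next
      cid <- cid + 1L
      members <- rbind(members, data.frame(
        cluster_id = cid, chrom = ch, gene_id = sub$gene_id[g],
        start = sub$start[g]))
      summaries <- rbind(summaries, data.frame(
        cluster_id = cid, chrom = ch, n_members = length(g),
        span_bp = max(sub$end[g]) - min(sub$start[g])))
    }
  }
  if (is.null(members)) {
    members <- data.frame(cluster_id = integer(0), chrom = character(0),
                          gene_id = character(0), start = integer(0))
    summaries <- data.frame(cluster_id = integer(0), chrom = character(0),
                            n_members = integer(0), span_bp = integer(0))
  }
  attr(members, "clusters") <- summaries
  members
}

#' Detect tandem-duplicated gene pairs
#'
#' Considers pairs of same-chromosome family loci with at most
#' `max_intervening` genes between them and calls a tandem pair when the
#' global-alignment identity of the encoded proteins reaches
#' `min_identity`. When only family loci are supplied, intervening genes
#' are counted among those loci; supplying `all_loci` (every gene on the
#' chromosomes) gives the exact intervening count.
#'
#' @param loci data.frame of family loci (as in [assign_names()]).
#' @param proteins named character vector of protein sequences keyed by
#'   `gene_id`; required for every placed locus.
#' @param min_identity minimum percent amino-acid identity over the aligned
#'   region.
#' @param max_intervening maximum number of genes between the pair.
#' @param all_loci optional data.frame of all genes (`gene_id`, `chrom`,
#'   `start`) used to count intervening genes.
#' @return data.frame with `gene1`, `gene2`, `identity`, `intervening`.
#' @export
detect_tandem <- function(loci, proteins, min_identity = 70,
                          max_intervening = 1, all_loci = NULL) {
  placed <- loci[!is.na(loci$chrom), , drop = FALSE]
  missing <- setdiff(placed$gene_id, names(proteins))
  if (length(missing) > 0) {
    stop("missing sequences for: ", paste(missing, collapse = ", "))
  }
  out <- NULL
  for (ch in unique(placed$chrom)) {
    sub <- placed[placed$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        if (!is.null(all_loci)) {
          between <- all_loci$chrom == ch &
            all_loci$start > sub$start[i] & all_loci$start < sub$start[j] &
            !(all_loci$gene_id %in% c(sub$gene_id[i], sub$gene_id[j]))
          interv <- sum(between)
        } else {
          interv <- j - i - 1L
        }
        if (interv > max_intervening) next
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(proteins[[sub$gene_id[i]]]),
          Biostrings::AAString(proteins[[sub$gene_id[j]]]),
          type = "global", substitutionMatrix = "BLOSUM62",
          gapOpening = 10, gapExtension = 0.5)
        ident <- Biostrings::pid(pa)
        if (ident >= min_identity) {
          out <- rbind(out, data.frame(
            gene1 = sub$gene_id[i], gene2 = sub$gene_id[j],
            identity = ident, intervening = interv))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(gene1 = character(0), gene2 = character(0),
                      identity = numeric(0), intervening = integer(0))
  }
  out
}

#' Loci table from gene models
#'
#' @param models named list of `gene_model` objects.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
loci_from_models <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, chrom = m$chrom,
               start = min(m$cds[, "start"]), end = max(m$cds[, "end"]),
               strand = m$strand)
  }))
}
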