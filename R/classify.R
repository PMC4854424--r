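# Group assignment for WRKY proteins. The spacing rule alone resolves
# groups I (two complete C2H2 domains), IIc (single C2H2, m = 4) and the
# III candidates (single C2HC); subgroups IIa/IIb/IId/IIe share the
# C-X5-C-X23-H-X-H pattern and are resolved by neighbor-joining placement
# against a labeled reference set, as is the III-vs-IV distinction for
# divergent long C2HC proteins.

GROUP_LABELS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "IV", "NG")

#' Rule-based group assignment from a domain inventory
#'
#' Uses only domain counts, finger class and the first spacer length:
#' two or more complete C2H2 domains give group I; a single complete C2HC
#' domain gives a group-III candidate (subject to the group-IV divergence
#' override); a single complete C2H2 domain gives IIc when m = 4 or
#' `II-unresolved` when m = 5 (subgroup needs tree placement); no complete
#' domain gives NG. Proteins mixing a C2H2 and a C2HC domain are labeled
#' by the C-terminal complete domain, with a warning.
#'
#' @param domains data.frame for one protein, as produced by
#'   [scan_proteome()].
#' @return one of `"I"`, `"IIc"`, `"II-unresolved"`, `"III-candidate"`,
#'   `"NG"`.
#' @export
assign_group_rule <- function(domains) {
  comp <- domains[domains$complete, , drop = FALSE]
  if (nrow(comp) == 0) return("NG")
  if (sum(comp$finger_class == "C2H2") >= 2) return("I")
  if (nrow(comp) >= 2 && length(unique(comp$finger_class)) > 1) {
    warning("mixed finger classes in one protein; labeling by the ",
            "C-terminal domain")
  }
  last <- comp[which.max(comp$span_start), , drop = FALSE]
  if (last$finger_class == "C2HC") return("III-candidate")
  if (last$m == 4) return("IIc")
  if (last$m == 5) return("II-unresolved")
  "NG"
}

#' Scan the named non-WRKY motifs
#'
#' Patterns: HARF `RTGHARFRR[A/G]P`; co-activator `LxxLL`; EAR-like
#' repressor `LxLxLx` (trailing residue required by default, switchable to
#' the 5-residue `LxLxL` convention); leucine zipper as at least
#' `zipper_count` leucines at exact heptad spacing.
#'
#' @param sequence amino-acid sequence.
#' @param lxlxlx_trailing require the sixth residue of the repressor motif.
#' @param zipper_count minimum number of heptad-spaced leucines.
#' @return list with logical flags `harf`, `leucine_zipper`, `lxxll`,
#'   `lxlxlx` and a `positions` list of 0-based match offsets per motif.
#' @export
scan_named_motifs <- function(sequence, lxlxlx_trailing = TRUE,
                              zipper_count = 4L) {
  find_all <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  aa <- sprintf("[%s]", paste(AA_ALPHABET, collapse = ""))
  pos <- list(
    harf = find_all("RTGHARFRR[AG]P"),
    lxxll = find_all(paste0("L", aa, aa, "LL")),
    lxlxlx = find_all(if (lxlxlx_trailing) {
      paste0("L", aa, "L", aa, "L", aa)
    } else paste0("L", aa, "L", aa, "L")),
    leucine_zipper = find_all(
      paste0("L(?:", aa, "{6}L){", zipper_count - 1L, ",}"))
  )
  list(harf = length(pos$harf) > 0,
       leucine_zipper = length(pos$leucine_zipper) > 0,
       lxxll = length(pos$lxxll) > 0,
       lxlxlx = length(pos$lxlxlx) > 0,
       positions = pos)
}

# The C-terminal complete domain sequence of a protein (used for alignment
# and tree placement).
cterm_domain_seq <- function(sequence, domains) {
  comp <- domains[domains$complete, , drop = FALSE]
  if (nrow(comp) == 0) return(NA_character_)
  last <- comp[which.max(comp$span_start), , drop = FALSE]
  substring(sequence, last$span_start + 1L, last$span_end)
}

# Walk from a query leaf towards the root of a rooted tree; at the first
# ancestor whose descendant leaves include at least one reference, return
# the reference label when unanimous, otherwise NA.
clade_placement <- function(tree, query, ref_labels) {
  tip <- which(tree$tip.label == query)
  node <- tip
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0) return(NA_character_)
    leaves <- tree$tip.label[
      phangorn::Descendants(tree, parent, type = "tips")[[1]]]
    labs <- ref_labels[intersect(leaves, names(ref_labels))]
    if (length(labs) > 0) {
      if (length(unique(labs)) == 1) return(unname(labs[1]))
      return(NA_character_)
    }
    node <- parent
  }
}

#' Resolve subgroup and group III/IV labels by tree placement
#'
#' Builds (or reuses) a neighbor-joining tree of query and reference
#' domain sequences, midpoint-roots it, and places each query in the
#' smallest clade containing it whose labeled reference leaves are
#' unanimous. Queries with no unanimous clade fall back to the nearest
#' reference by patristic distance. C2HC queries placed outside every
#' group-III reference clade whose protein length exceeds
#' `length_threshold` are labeled IV; shorter unplaced C2HC queries stay
#' NG.
#'
#' @param query_domains named character vector of query domain sequences.
#' @param references data.frame with `id`, `label`, `sequence`; must
#'   contain at least one exemplar for each of IIa, IIb, IId, IIe and III.
#' @param query_info data.frame with `id`, `candidate`
#'   (`"II-unresolved"` or `"III-candidate"`) and `protein_length`.
#' @param length_threshold protein length (aa) above which a divergent
#'   C2HC protein is labeled IV.
#' @param tree optional precomputed `phylo` spanning queries and
#'   references; built from a progressive alignment and p-distances when
#'   absent.
#' @return data.frame with `id`, `group`, `basis`.
#' @export
resolve_subgroup <- function(query_domains, references, query_info,
                             length_threshold = 800, tree = NULL) {
  needed <- c("IIa", "IIb", "IId", "IIe", "III")
  absent <- setdiff(needed, unique(references$label))
  if (length(absent) > 0) {
    stop("reference set lacks exemplars for: ",
         paste(absent, collapse = ", "))
  }
  ref_labels <- stats::setNames(references$label, references$id)
  if (is.null(tree)) {
    seqs <- c(query_domains,
              stats::setNames(references$sequence, references$id))
    aln <- align_progressive(seqs)
    tree <- nj_tree(p_distance(aln))
  }
  rooted <- phangorn::midpoint(tree)
  patristic <- ape::cophenetic.phylo(tree)
  # the group-III reference clade: every leaf under the MRCA of the III
  # exemplars (needs >= 2 exemplars to span a clade; with a single one the
  # smallest-unanimous-clade walk below decides instead)
  iii_refs <- references$id[references$label == "III"]
  iii_clade <- if (length(iii_refs) >= 2) {
    mrca <- ape::getMRCA(rooted, iii_refs)
    rooted$tip.label[phangorn::Descendants(rooted, mrca, "tips")[[1]]]
  }
  out <- lapply(seq_len(nrow(query_info)), function(k) {
    id <- query_info$id[k]
    cand <- query_info$candidate[k]
    placed <- clade_placement(rooted, id, ref_labels)
    basis <- "rule+tree"
    if (is.na(placed)) {
      # nearest labeled reference by patristic distance
      d <- patristic[id, names(ref_labels)]
      placed <- unname(ref_labels[names(which.min(d))])
      basis <- "rule+tree(nearest)"
    }
    if (cand == "III-candidate") {
      # inside the span of the III references -> III; outside it, the
      # length threshold separates divergent IV proteins from ordinary
      # III members that merely attach sister to the reference span
      in_span <- !is.null(iii_clade) && id %in% iii_clade
      group <- if (in_span) "III"
        else if (query_info$protein_length[k] > length_threshold) "IV"
        else if (placed == "III") "III"
        else "NG"
    } else {
      group <- if (placed %in% c("IIa", "IIb", "IId", "IIe")) placed
        else "NG"
    }
    data.frame(id = id, group = group, basis = basis)
  })
  do.call(rbind, out)
}

#' Annotate a WRKY family
#'
#' Combines domain scanning, rule- and tree-based classification, named-
#' motif scanning and physicochemical profiling into one census row per
#' WRKY-positive protein (a protein with at least one core motif hit).
#'
#' @param proteins named character vector of protein sequences.
#' @param domains named list from [scan_proteome()]; recomputed when
#'   `NULL`.
#' @param references optional reference data.frame (see
#'   [resolve_subgroup()]); without it subgroup and III/IV resolution is
#'   skipped and those proteins keep labels `II-unresolved` / `III`.
#' @param length_threshold passed to [resolve_subgroup()].
#' @param pka_set passed to [physchem_profile()].
#' @return data.frame with one row per WRKY-positive protein: `id`,
#'   `group`, `basis`, `n_domains`, `n_complete`, `core_count`,
#'   `core_variant`, `patterns`, `zinc_finger`, motif flags and the
#'   physicochemical columns.
#' @export
annotate_family <- function(proteins, domains = NULL, references = NULL,
                            length_threshold = 800, pka_set = "bjellqvist") {
  proteins <- clean_proteins(proteins)
  if (is.null(domains)) domains <- scan_proteome(proteins)
  if (!setequal(names(domains), names(proteins))) {
    stop("protein/domain id mismatch: ",
         paste(symdiff_ids(names(proteins), names(domains)), collapse = ", "))
  }
  positive <- names(proteins)[vapply(domains, nrow, 0L) > 0]
  if (length(positive) == 0) {
    return(data.frame(id = character(0), group = character(0)))
  }
  rows <- lapply(positive, function(id) {
    dom <- domains[[id]]
    cand <- assign_group_rule(dom)
    comp <- dom[dom$complete, , drop = FALSE]
    pats <- vapply(seq_len(nrow(dom)), function(i) pattern_string(dom[i, ]), "")
    motifs <- scan_named_motifs(proteins[[id]])
    phys <- physchem_profile(proteins[[id]], pka_set)
    zinc <- if (nrow(comp) > 0) {
      comp$finger_class[which.max(comp$span_start)]
    } else NA_character_
    data.frame(id = id, group = cand, basis = "rule",
               n_domains = nrow(dom), n_complete = nrow(comp),
               core_count = sum(dom$canonical),
               core_variant = if (all(dom$canonical)) NA_character_ else
                 dom$peptide[!dom$canonical][1],
               patterns = paste(pats, collapse = ";"),
               zinc_finger = zinc,
               harf = motifs$harf, leucine_zipper = motifs$leucine_zipper,
               lxxll = motifs$lxxll, lxlxlx = motifs$lxlxlx,
               phys)
  })
  ann <- do.call(rbind, rows)
  unresolved <- ann$group %in% c("II-unresolved", "III-candidate")
  if (any(unresolved) && !is.null(references)) {
    qseq <- vapply(ann$id[unresolved], function(id) {
      cterm_domain_seq(proteins[[id]], domains[[id]])
    }, "")
    qinfo <- data.frame(id = ann$id[unresolved],
                        candidate = ann$group[unresolved],
                        protein_length = ann$length[unresolved])
    res <- resolve_subgroup(qseq, references, qinfo, length_threshold)
    ann$group[unresolved] <- res$group[match(ann$id[unresolved], res$id)]
    ann$basis[unresolved] <- res$basis[match(ann$id[unresolved], res$id)]
  } else if (any(unresolved)) {
    ann$group[ann$group == "III-candidate"] <- "III"
  }
  rownames(ann) <- NULL
  ann
}

symdiff_ids <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' Read a labeled reference FASTA
#'
#' Reference records carry their group label in the description as
#' `group=IIa` (any of the closed group vocabulary).
#'
#' @param path FASTA file of reference domain sequences.
#' @return data.frame with `id`, `label`, `sequence`.
#' @export
read_references <- function(path) {
  seqs <- read_proteins(path)
  desc <- attr(seqs, "description")
  label <- sub(".*group=([A-Za-z]+).*", "\\1", desc)
  bad <- !label %in% GROUP_LABELS
  if (any(bad)) {
    stop("reference records without a valid group= label: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  data.frame(id = names(seqs), label = label,
             sequence = as.character(seqs))
}
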