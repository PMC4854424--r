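# Seeded synthetic-data generators. Every downstream stage of the census
# has a generator here that plants its ground truth: proteomes with WRKY
# domains of each group signature, gene models with R-/V-type domain
# introns, chromosome layouts with clusters and tandem pairs, and
# expression matrices with planted qualitative calls. All randomness flows
# from the `seed` argument; identical spec + seed gives byte-identical
# output.

# Residues allowed in zinc-finger spacers and intra-domain filler: the
# standard alphabet minus C and H, so a planted finger is the only legal
# parse.
SPACER_AA <- setdiff(AA_ALPHABET, c("C", "H"))

# Fixed finger templates per group. Spacer sequences act as subgroup
# barcodes: within a subgroup only a couple of positions are mutated per
# protein, so reference-tree placement separates the subgroups cleanly.
# IIa/IIb carry a valine at second-cysteine + 6 (position 6 of the
# n-spacer), the residue targeted by V-type domain introns. Group IV uses
# a deliberately divergent low-complexity spacer and long flanks.
FINGER_TEMPLATES <- list(
  I_N = list(m = 4L, n = 22L, terminal = "H",
             m_spacer = "NPSF", n_spacer = "RKDEGTSLVAPYWQNMIFDERK"),
  I_C = list(m = 4L, n = 23L, terminal = "H",
             m_spacer = "VPAL", n_spacer = "KDSTRGYEQWLMNFIVAPDGERT"),
  IIa = list(m = 5L, n = 23L, terminal = "H",
             m_spacer = "DSKTL", n_spacer = "AEGKRVTPYQWSFMNDIERGTAK"),
  IIb = list(m = 5L, n = 23L, terminal = "H",
             m_spacer = "NGTPV", n_spacer = "TSLDKVQRYWAGFMPNIEDKERS"),
  IIc = list(m = 4L, n = 23L, terminal = "H",
             m_spacer = "WPDA", n_spacer = "RGTKESLDYWQPFMNAIVRGTKE"),
  IId = list(m = 5L, n = 23L, terminal = "H",
             m_spacer = "EKAFS", n_spacer = "GDYTRKSLQWEMNFAPIVTGDRE"),
  IIe = list(m = 5L, n = 23L, terminal = "H",
             m_spacer = "QRVGD", n_spacer = "SPKELTDYRWQGFMNAIVSPEKT"),
  III = list(m = 7L, n = 23L, terminal = "C",
             m_spacer = "GDSVKLE", n_spacer = "TKRPEGSLYWDQFMNAIVTKRPE"),
  IV  = list(m = 7L, n = 23L, terminal = "C",
             m_spacer = "TQWYFMN", n_spacer = "GGSTPAGSTPAGSTPAGSTPAGS")
)

SIM_GROUPS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "IV")

NAMED_MOTIF_SEQS <- c(harf = "RTGHARFRRAP",
                      lxxll = "LKELL",
                      lxlxlx = "LALALA",
                      leucine_zipper = "LAEGKDSLAEGKDSLAEGKDSL")

# Random flank free of core heptapeptide variants (rejection sampling).
random_flank <- function(len, variants = core_variants()) {
  repeat {
    s <- paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    if (nrow(find_cores(s, variants)) == 0) return(s)
  }
}

# Mutate k positions of a spacer (never position `keep`), drawing
# replacements from SPACER_AA.
mutate_spacer <- function(spacer, k = 2L, keep = integer(0)) {
  chars <- seq_chars(spacer)
  cand <- setdiff(seq_along(chars), keep)
  pos <- sample(cand, min(k, length(cand)))
  for (p in pos) {
    chars[p] <- sample(setdiff(SPACER_AA, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Build one domain string from a template; returns the sequence and the
# 0-based offsets of its landmarks relative to the domain start.
build_domain <- function(template, core = "WRKYGQK", mutate = TRUE) {
  msp <- template$m_spacer
  nsp <- template$n_spacer
  if (mutate) {
    nsp <- mutate_spacer(nsp, 2L, keep = 6L)  # keep the V at c2 + 6
  }
  mid <- "SVRE"
  seq <- paste0(core, mid, "C", msp, "C", nsp, "H",
                sample(SPACER_AA, 1), template$terminal)
  c1 <- nchar(core) + nchar(mid)
  c2 <- c1 + template$m + 1L
  h1 <- c2 + template$n + 1L
  list(seq = seq, core_start = 0L, c1 = c1, c2 = c2, h1 = h1, t = h1 + 2L,
       m = template$m, n = template$n, terminal = template$terminal)
}

#' Specification for a synthetic WRKY family
#'
#' @param n_per_group named integer vector of protein counts per group
#'   label (subset of `I, IIa, IIb, IIc, IId, IIe, III, IV`).
#' @param n_decoys number of non-WRKY decoy proteins.
#' @param flank_length_range min/max residues of the flanks planted around
#'   domains.
#' @param motif_plants named list mapping motif name (`harf`, `lxxll`,
#'   `lxlxlx`, `leucine_zipper`) to protein ids; `NULL` plants HARF into
#'   every IId protein.
#' @param seed integer random seed.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n_per_group, n_decoys = 0L,
                        flank_length_range = c(30L, 80L),
                        motif_plants = NULL, seed = 1L) {
  bad <- setdiff(names(n_per_group), SIM_GROUPS)
  if (length(bad) > 0) stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (any(n_per_group < 0) || n_decoys < 0) stop("counts must be >= 0")
  if (flank_length_range[1] > flank_length_range[2]) {
    stop("flank length range min > max")
  }
  structure(list(n_per_group = n_per_group, n_decoys = n_decoys,
                 flank_length_range = flank_length_range,
                 motif_plants = motif_plants, seed = seed),
            class = "family_spec")
}

#' Generate a synthetic proteome with planted WRKY domains
#'
#' Each planted group member carries exactly the group's zinc-finger
#' signature (group I: two domains; IIa/IIb/IId/IIe: C-X5-C-X23-H-X-H;
#' IIc: C-X4-C-X23-H-X-H; III/IV: C-X7-C-X23-H-X-C, with group IV proteins
#' additionally long and spacer-divergent). Decoys contain no core
#' heptapeptide. Flanks are i.i.d. uniform over the 20 residues with
#' rejection of any window matching a core variant.
#'
#' @param spec a [family_spec()].
#' @return list with `proteins` (named character vector) and `truth`
#'   (list of data.frames `proteins`, `domains`, `motifs`).
#' @export
sim_proteins <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  total <- sum(spec$n_per_group) + spec$n_decoys
  if (total == 0) stop("empty spec")
  set.seed(spec$seed)
  fr <- spec$flank_length_range
  seqs <- character(0)
  prot_rows <- list(); dom_rows <- list(); motif_rows <- list()
  for (grp in names(spec$n_per_group)) {
    for (k in seq_len(spec$n_per_group[[grp]])) {
      id <- sprintf("SYN_%s_%02d", grp, k)
      # group IV proteins are long (well above the divergence threshold)
      fl <- if (grp == "IV") c(420L, 620L) else fr
      repeat {
        flank_n <- random_flank(sample(fl[1]:fl[2], 1))
        flank_c <- random_flank(sample(fl[1]:fl[2], 1))
        if (grp == "I") {
          d1 <- build_domain(FINGER_TEMPLATES$I_N)
          d2 <- build_domain(FINGER_TEMPLATES$I_C)
          linker <- random_flank(sample(20:40, 1))
          pieces <- c(flank_n, d1$seq, linker, d2$seq, flank_c)
          doms <- list(d1, d2)
          offs <- c(nchar(flank_n),
                    nchar(flank_n) + nchar(d1$seq) + nchar(linker))
        } else {
          d <- build_domain(FINGER_TEMPLATES[[grp]])
          pieces <- c(flank_n, d$seq, flank_c)
          doms <- list(d)
          offs <- nchar(flank_n)
        }
        seq <- paste(pieces, collapse = "")
        # junctions must not have created extra cores
        if (nrow(find_cores(seq)) == length(doms)) break
      }
      seqs[[id]] <- seq
      prot_rows[[id]] <- data.frame(
        id = id, group = grp, length = nchar(seq),
        heptapeptide = "WRKYGQK", n_domains = length(doms))
      for (di in seq_along(doms)) {
        d <- doms[[di]]
        o <- offs[di]
        dom_rows[[paste(id, di)]] <- data.frame(
          id = id, domain_index = di, core_start = o,
          c1 = o + d$c1, c2 = o + d$c2, h1 = o + d$h1, t = o + d$t,
          m = d$m, n = d$n, terminal = d$terminal,
          span_start = o, span_end = o + d$t + 1L)
      }
    }
  }
  for (k in seq_len(spec$n_decoys)) {
    id <- sprintf("SYN_decoy_%02d", k)
    seqs[[id]] <- random_flank(sample((3 * fr[1]):(3 * fr[2]), 1))
    prot_rows[[id]] <- data.frame(id = id, group = "decoy",
                                  length = nchar(seqs[[id]]),
                                  heptapeptide = NA, n_domains = 0L)
  }
  # motif planting (into the N-terminal flank, re-checked for new cores)
  plants <- spec$motif_plants
  if (is.null(plants)) {
    iid_ids <- names(seqs)[grepl("^SYN_IId_", names(seqs))]
    plants <- if (length(iid_ids) > 0) list(harf = iid_ids) else list()
  }
  for (motif in names(plants)) {
    ins <- NAMED_MOTIF_SEQS[[motif]]
    if (is.null(ins)) stop("unknown motif: ", motif)
    for (id in plants[[motif]]) {
      if (!id %in% names(seqs)) stop("motif plant targets unknown id: ", id)
      n_before <- nrow(find_cores(seqs[[id]]))
      at <- 5L  # inside the N flank, clear of the domain
      cand <- paste0(substring(seqs[[id]], 1, at), ins,
                     substring(seqs[[id]], at + 1))
      if (nrow(find_cores(cand)) != n_before) {
        stop("motif insertion created a spurious core in ", id)
      }
      seqs[[id]] <- cand
      # shift any recorded domain landmarks downstream of the insertion
      key <- names(dom_rows)[startsWith(names(dom_rows), paste0(id, " "))]
      for (kk in key) {
        dom_rows[[kk]][, c("core_start", "c1", "c2", "h1", "t",
                           "span_start", "span_end")] <-
          dom_rows[[kk]][, c("core_start", "c1", "c2", "h1", "t",
                             "span_start", "span_end")] + nchar(ins)
      }
      motif_rows[[paste(id, motif)]] <- data.frame(id = id, motif = motif,
                                                   start = at)
    }
  }
  truth <- list(
    proteins = do.call(rbind, unname(prot_rows)),
    domains = if (length(dom_rows) > 0) do.call(rbind, unname(dom_rows))
      else NULL,
    motifs = if (length(motif_rows) > 0) do.call(rbind, unname(motif_rows))
      else NULL
  )
  list(proteins = unlist(seqs), truth = truth)
}

#' Synthetic reference set for subgroup resolution
#'
#' Labeled exemplar domains per requested group, drawn from the same
#' finger templates as [sim_proteins()] (fresh spacer mutations, so
#' references are close to, but not identical with, planted queries).
#' Two exemplars per label by default: the group-III-versus-IV divergence
#' test is sharpest when the group-III references span a proper clade.
#'
#' @param labels groups to include.
#' @param n_per_label exemplars per group.
#' @param seed integer seed.
#' @return data.frame with `id`, `label`, `sequence` (domain sequences).
#' @export
sim_references <- function(labels = c("IIa", "IIb", "IId", "IIe", "III"),
                           n_per_label = 2L, seed = 99L) {
  set.seed(seed)
  do.call(rbind, lapply(labels, function(grp) {
    tpl <- if (grp == "I") FINGER_TEMPLATES$I_C else FINGER_TEMPLATES[[grp]]
    do.call(rbind, lapply(seq_len(n_per_label), function(k) {
      d <- build_domain(tpl)
      data.frame(id = sprintf("REF_%s_%d", grp, k), label = grp,
                 sequence = d$seq)
    }))
  }))
}
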