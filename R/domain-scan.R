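# Detection of WRKY core heptapeptides and parsing of the downstream zinc
# finger (C-Xm-C-Xn-H-X-[H|C]) into spacer lengths and terminal residue
# type. All positions are 0-based offsets into the protein sequence; output
# tables destined for users report 1-based coordinates.

#' Default WRKY core heptapeptide variants
#'
#' The canonical core `WRKYGQK` plus the common single-substitution variants
#' `WRKYGKK` and `WEKYGQK`. Divergent families replace the first four
#' residues of the motif (`WKKY`, `WKRY`, `WSKY`, `WIKY`, `WRIC`, `WRMC`,
#' `WRRY`, `WVKY`); because only the 4-mer is conserved, these are matched
#' as a 4-mer followed by any three residues and are off by default.
#'
#' @param four_letter also enable the divergent 4-mer replacement motifs.
#' @return character vector of core motif patterns; 4-mer entries carry the
#'   suffix `"..."` meaning "any three residues".
#' @export
core_variants <- function(four_letter = FALSE) {
  v <- c("WRKYGQK", "WRKYGKK", "WEKYGQK")
  if (four_letter) {
    v <- c(v, paste0(c("WKKY", "WKRY", "WSKY", "WIKY",
                       "WRIC", "WRMC", "WRRY", "WVKY"), "..."))
  }
  v
}

#' Find WRKY core motif hits in one protein
#'
#' Scans a protein sequence for every substring match of the configured core
#' variants. Matches are reported left-to-right and overlaps are allowed.
#' The ambiguity code `X` never matches a motif position.
#'
#' @param sequence amino-acid sequence (single string).
#' @param variants core motif list as produced by [core_variants()]; entries
#'   ending in `"..."` are 4-mers extended by any three residues.
#' @return data.frame with columns `start` (0-based offset), `peptide`
#'   (matched 7-mer) and `canonical` (TRUE iff `WRKYGQK`), ordered by
#'   `start`.
#' @export
find_cores <- function(sequence, variants = core_variants()) {
  if (length(variants) == 0) stop("core variant list is empty")
  aa_class <- sprintf("[%s]", paste(AA_ALPHABET, collapse = ""))
  hits <- lapply(variants, function(v) {
    pat <- if (endsWith(v, "...")) {
      paste0(substr(v, 1L, 4L), aa_class, aa_class, aa_class)
    } else v
    m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    as.integer(m) - 1L
  })
  starts <- unlist(hits)
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), peptide = character(0),
                      canonical = logical(0)))
  }
  starts <- sort(unique(starts))
  peptide <- substring(sequence, starts + 1L, starts + 7L)
  data.frame(start = starts, peptide = peptide,
             canonical = peptide == "WRKYGQK")
}

#' Parse the zinc finger downstream of a core motif hit
#'
#' Searches the `window` residues downstream of the core for the first
#' arrangement `C-X{m}-C-X{n}-H-X-[H|C]` with `m` and `n` in the allowed
#' spacer sets. "First" means smallest first-cysteine position; ties on the
#' same cysteine are broken towards the smallest `m`, then smallest `n`.
#'
#' @param sequence amino-acid sequence.
#' @param core_start 0-based offset of the core hit.
#' @param core_length length of the matched core motif (7).
#' @param window maximum number of residues searched downstream of the core
#'   end; must be at least 40 (the shortest legal finger spans 31 residues).
#' @param m_allowed allowed spacer lengths between the two cysteines.
#' @param n_allowed allowed spacer lengths between the second cysteine and
#'   the first histidine.
#' @return a list with 0-based positions `c1`, `c2`, `h1`, `t`, spacer
#'   lengths `m`, `n`, `terminal` (`"H"` or `"C"`) and `finger_class`
#'   (`"C2H2"` or `"C2HC"`); or `NULL` if no legal arrangement exists in the
#'   window.
#' @export
parse_finger <- function(sequence, core_start, core_length = 7L,
                         window = 120L, m_allowed = c(4L, 5L, 7L),
                         n_allowed = c(22L, 23L)) {
  if (window < 40) stop("finger search window must be >= 40 residues")
  n_seq <- nchar(sequence)
  from <- core_start + core_length        # 0-based first searched position
  to <- min(n_seq, from + window) - 1L    # 0-based last position in window
  if (from > to) return(NULL)
  chars <- seq_chars(substring(sequence, from + 1L, to + 1L))
  cys <- from + which(chars == "C") - 1L
  for (c1 in cys) {
    for (m in sort(m_allowed)) {
      c2 <- c1 + m + 1L
      if (c2 > to || substring(sequence, c2 + 1L, c2 + 1L) != "C") next
      for (n in sort(n_allowed)) {
        h1 <- c2 + n + 1L
        t <- h1 + 2L
        if (t > to) next
        if (substring(sequence, h1 + 1L, h1 + 1L) != "H") next
        term <- substring(sequence, t + 1L, t + 1L)
        if (term %in% c("H", "C")) {
          return(list(c1 = c1, c2 = c2, h1 = h1, t = t, m = m, n = n,
                      terminal = term,
                      finger_class = if (term == "H") "C2H2" else "C2HC"))
        }
      }
    }
  }
  NULL
}

empty_domain_df <- function() {
  data.frame(core_start = integer(0), peptide = character(0),
             canonical = logical(0), c1 = integer(0), c2 = integer(0),
             h1 = integer(0), t = integer(0), m = integer(0), n = integer(0),
             terminal = character(0), finger_class = character(0),
             span_start = integer(0), span_end = integer(0),
             complete = logical(0))
}

# One row per domain: core hit columns plus finger columns (NA when the
# finger is absent) and the half-open span from core start to finger
# terminal + 1.
domain_row <- function(core, finger) {
  if (is.null(finger)) {
    data.frame(core_start = core$start, peptide = core$peptide,
               canonical = core$canonical, c1 = NA_integer_,
               c2 = NA_integer_, h1 = NA_integer_, t = NA_integer_,
               m = NA_integer_, n = NA_integer_, terminal = NA_character_,
               finger_class = NA_character_,
               span_start = core$start,
               span_end = core$start + nchar(core$peptide),
               complete = FALSE)
  } else {
    data.frame(core_start = core$start, peptide = core$peptide,
               canonical = core$canonical, c1 = finger$c1, c2 = finger$c2,
               h1 = finger$h1, t = finger$t, m = finger$m, n = finger$n,
               terminal = finger$terminal, finger_class = finger$finger_class,
               span_start = core$start, span_end = finger$t + 1L,
               complete = TRUE)
  }
}

#' Scan a proteome for WRKY domains
#'
#' Applies [find_cores()] and [parse_finger()] to every protein. Every
#' protein is retained in the result, including proteins with no hits
#' (empty table), so that callers can decide how to filter.
#'
#' @param proteins named character vector of sequences (see
#'   [clean_proteins()]).
#' @param variants core motif list, see [core_variants()].
#' @param window,m_allowed,n_allowed passed to [parse_finger()].
#' @return named list (one element per protein, same order) of data.frames
#'   with one row per detected domain, sorted by `core_start`; columns as in
#'   [find_cores()] plus finger positions, `m`, `n`, `terminal`,
#'   `finger_class`, `span_start`, `span_end` and `complete`.
#' @export
scan_proteome <- function(proteins, variants = core_variants(),
                          window = 120L, m_allowed = c(4L, 5L, 7L),
                          n_allowed = c(22L, 23L)) {
  proteins <- clean_proteins(proteins)
  out <- lapply(names(proteins), function(id) {
    s <- proteins[[id]]
    cores <- find_cores(s, variants)
    if (nrow(cores) == 0) return(empty_domain_df())
    rows <- lapply(seq_len(nrow(cores)), function(i) {
      core <- list(start = cores$start[i], peptide = cores$peptide[i],
                   canonical = cores$canonical[i])
      fing <- parse_finger(s, cores$start[i], nchar(cores$peptide[i]),
                           window = window, m_allowed = m_allowed,
                           n_allowed = n_allowed)
      domain_row(core, fing)
    })
    df <- do.call(rbind, rows)
    df[order(df$core_start), , drop = FALSE]
  })
  names(out) <- names(proteins)
  out
}

#' Render a domain pattern string
#'
#' Formats a complete domain as `"C-X4-C-X22-H-X-H"`-style text; incomplete
#' domains render as `"incomplete"`.
#'
#' @param domain one row of a [scan_proteome()] table.
#' @return character pattern string.
#' @export
pattern_string <- function(domain) {
  if (!isTRUE(domain$complete)) return("incomplete")
  sprintf("C-X%d-C-X%d-H-X-%s", domain$m, domain$n, domain$terminal)
}

#' Tabulate scanned domains across a proteome
#'
#' Flattens the per-protein domain lists of [scan_proteome()] into one
#' data.frame with 1-based reporting coordinates.
#'
#' @param domains named list as returned by [scan_proteome()].
#' @return data.frame with columns `protein_id`, `domain_index`,
#'   `core_start` (1-based), `peptide`, `pattern`, `finger_class`,
#'   `complete`.
#' @export
domain_table <- function(domains) {
  rows <- lapply(names(domains), function(id) {
    df <- domains[[id]]
    if (nrow(df) == 0) return(NULL)
    data.frame(protein_id = id, domain_index = seq_len(nrow(df)),
               core_start = df$core_start + 1L, peptide = df$peptide,
               pattern = vapply(seq_len(nrow(df)),
                                function(i) pattern_string(df[i, ]), ""),
               finger_class = ifelse(df$complete, df$finger_class, NA),
               complete = df$complete)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), domain_index = integer(0),
                      core_start = integer(0), peptide = character(0),
                      pattern = character(0), finger_class = character(0),
                      complete = logical(0))
  }
  out
}
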