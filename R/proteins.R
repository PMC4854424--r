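# Protein input handling. Sequences are carried internally as a named
# character vector (uppercase, 20-letter alphabet plus X); FASTA parsing is
# delegated to Biostrings.

#' Read a protein FASTA file
#'
#' Reads a multi-record protein FASTA (wrapped or unwrapped) and returns a
#' named character vector of cleaned sequences. Record ids are the first
#' whitespace-delimited token of each header; the remainder is kept as a
#' `description` attribute. Characters outside the 20-letter alphabet
#' (and `X`) are replaced by `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @return named character vector of amino-acid sequences with a
#'   `description` character vector attribute (same order).
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(aa)
  names(seqs) <- ids
  out <- clean_proteins(seqs)
  attr(out, "description") <- desc
  out
}

#' Validate and clean a set of protein sequences
#'
#' Uppercases sequences, replaces characters outside the standard alphabet
#' (plus `X`) by `X` with a warning, and checks for empty sequences and
#' duplicate ids.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @return named character vector, alphabet-clean.
#' @export
clean_proteins <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("protein sequences must be named")
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0) {
    stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    warning("replacing non-standard residues by X in: ",
            paste(names(seqs)[bad], collapse = ", "))
    seqs[bad] <- gsub(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")),
                      "X", seqs[bad])
  }
  seqs
}

#' Write protein sequences as FASTA
#'
#' Writes a named character vector of sequences to FASTA, wrapped at 60
#' columns.
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
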