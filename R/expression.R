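# Qualitative expression calls from a nonnegative gene x sample matrix
# with sample metadata (tissue, developmental stage in days after
# flowering, treatment and paired control). The module consumes
# already-quantified abundances; it performs no differential-expression
# statistics.

#' Read an expression matrix and its sample metadata
#'
#' @param matrix_path TSV with gene ids in the first column and sample ids
#'   in the header row.
#' @param meta_path TSV sample metadata with columns `sample`, `tissue`,
#'   `stage`, `treatment`, `control_pair` (empty where not applicable).
#' @return list with `matrix` (numeric matrix) and `meta` (data.frame).
#' @export
read_expression <- function(matrix_path, meta_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            colClasses = "character")
  meta$stage <- suppressWarnings(as.integer(meta$stage))
  validate_expression(mat, meta)
  list(matrix = mat, meta = meta)
}

validate_expression <- function(mat, meta) {
  if (any(mat < 0)) stop("expression matrix has negative values")
  missing <- setdiff(colnames(mat), meta$sample)
  if (length(missing) > 0) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  treated <- meta[!is.na(meta$treatment) &
                  !meta$treatment %in% c("", "none", "control"), ,
                  drop = FALSE]
  nocp <- treated$sample[is.na(treated$control_pair) |
                         !nzchar(treated$control_pair)]
  if (length(nocp) > 0) {
    stop("treated samples without control_pair: ",
         paste(nocp, collapse = ", "))
  }
  invisible(TRUE)
}

#' Call the tissues in which each gene is expressed
#'
#' A gene is expressed in a tissue when the maximum of its values over
#' that tissue's untreated samples exceeds `threshold`.
#'
#' @param mat nonnegative gene x sample matrix.
#' @param meta sample metadata (see [read_expression()]).
#' @param threshold detection threshold on the abundance scale.
#' @param tissues tissues to call; defaults to all tissues present. An
#'   unknown tissue is an error.
#' @return named list (one entry per gene) of character vectors of tissues.
#' @export
call_expressed <- function(mat, meta, threshold = 1, tissues = NULL) {
  validate_expression(mat, meta)
  base <- meta[(is.na(meta$treatment) | meta$treatment %in% c("", "none")) &
               !is.na(meta$tissue) & nzchar(meta$tissue), , drop = FALSE]
  present <- unique(base$tissue)
  if (is.null(tissues)) tissues <- present
  unknown <- setdiff(tissues, present)
  if (length(unknown) > 0) {
    stop("unknown tissue: ", paste(unknown, collapse = ", "))
  }
  per_tissue <- lapply(tissues, function(ts) {
    cols <- intersect(base$sample[base$tissue == ts], colnames(mat))
    apply(mat[, cols, drop = FALSE], 1, max)
  })
  names(per_tissue) <- tissues
  genes <- rownames(mat)
  out <- lapply(genes, function(g) {
    tissues[vapply(per_tissue, function(v) v[[g]] > threshold, TRUE)]
  })
  names(out) <- genes
  out
}

#' Developmental trend across stages
#'
#' Classifies each gene's stage series (mean over replicates per stage,
#' stages in increasing order) as `up` (last/first fold at least
#' `min_fold` and non-decreasing within `tolerance`), `down` (symmetric),
#' `flat` (max/min below `min_fold`) or `mixed`. A first-stage zero with a
#' later positive value counts as an infinite fold (message logged).
#'
#' @param mat gene x sample matrix.
#' @param meta sample metadata; stage samples are untreated samples with a
#'   non-missing `stage`.
#' @param min_fold fold-change threshold (default 2).
#' @param tolerance allowed fractional dip between consecutive stages for
#'   a monotone call (0.25 allows a 25 percent dip).
#' @param tissue restrict to one tissue (default `"fruit"` when present).
#' @return named character vector of trend labels.
#' @export
devel_trend <- function(mat, meta, min_fold = 2, tolerance = 0.25,
                        tissue = NULL) {
  validate_expression(mat, meta)
  base <- meta[(is.na(meta$treatment) | meta$treatment %in% c("", "none")) &
               !is.na(meta$stage), , drop = FALSE]
  if (is.null(tissue) && "fruit" %in% base$tissue) tissue <- "fruit"
  if (!is.null(tissue)) base <- base[base$tissue == tissue, , drop = FALSE]
  stages <- sort(unique(base$stage))
  if (length(stages) < 2) stop("trend analysis needs >= 2 stages")
  series <- sapply(stages, function(st) {
    cols <- intersect(base$sample[base$stage == st], colnames(mat))
    rowMeans(mat[, cols, drop = FALSE])
  })
  labels <- apply(series, 1, function(x) trend_label(x, min_fold, tolerance))
  stats::setNames(labels, rownames(mat))
}

trend_label <- function(x, min_fold, tolerance) {
  if (all(x == 0)) return("flat")
  if (x[1] == 0 && x[length(x)] > 0) {
    message("first-stage value 0 with later expression: infinite fold")
    nondec <- all(diff(x) >= -tolerance * utils::head(x, -1))
    return(if (nondec) "up" else "mixed")
  }
  fold_up <- if (x[1] == 0) 0 else x[length(x)] / x[1]
  fold_down <- x[1] / max(x[length(x)], .Machine$double.eps)
  if (max(x) / max(min(x), .Machine$double.eps) < min_fold) return("flat")
  nondec <- all(x[-1] >= (1 - tolerance) * utils::head(x, -1))
  noninc <- all(x[-1] <= utils::head(x, -1) / (1 - tolerance))
  if (fold_up >= min_fold && nondec) return("up")
  if (fold_down >= min_fold && noninc) return("down")
  "mixed"
}

#' Treatment responses versus paired controls
#'
#' For every treated sample, compares each gene with its paired control:
#' `induced` when treated/control reaches `fold`, `repressed` when
#' control/treated reaches `fold`, `undetected` when both values are below
#' `detect`, otherwise `unchanged`.
#'
#' @param mat gene x sample matrix.
#' @param meta sample metadata with `treatment` and `control_pair`.
#' @param fold fold-change threshold (default 2).
#' @param detect detection threshold (default 1).
#' @return data.frame with one row per gene x treated sample: `gene`,
#'   `treatment`, `stage`, `sample`, `response`.
#' @export
treatment_response <- function(mat, meta, fold = 2, detect = 1) {
  validate_expression(mat, meta)
  treated <- meta[!is.na(meta$treatment) &
                  !meta$treatment %in% c("", "none", "control"), ,
                  drop = FALSE]
  if (nrow(treated) == 0) {
    return(data.frame(gene = character(0), treatment = character(0),
                      stage = integer(0), sample = character(0),
                      response = character(0)))
  }
  missing <- setdiff(treated$control_pair, colnames(mat))
  if (length(missing) > 0) {
    stop("control sample missing from matrix: ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(treated)), function(k) {
    s <- treated$sample[k]
    ctrl <- treated$control_pair[k]
    tv <- mat[, s]
    cv <- mat[, ctrl]
    resp <- ifelse(tv < detect & cv < detect, "undetected",
            ifelse(tv >= fold * cv, "induced",
            ifelse(cv >= fold * tv, "repressed", "unchanged")))
    data.frame(gene = rownames(mat), treatment = treated$treatment[k],
               stage = treated$stage[k], sample = s, response = resp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert qPCR Ct values to relative expression
#'
#' Standard 2^-ddCt transform against a reference gene and a calibrator
#' sample.
#'
#' @param ct gene x sample matrix of Ct values.
#' @param reference_gene row name of the reference gene.
#' @param calibrator column name of the calibrator sample.
#' @return matrix of relative expression values.
#' @export
ddct_expression <- function(ct, reference_gene, calibrator) {
  if (!reference_gene %in% rownames(ct)) stop("reference gene not found")
  if (!calibrator %in% colnames(ct)) stop("calibrator sample not found")
  dct <- sweep(ct, 2, ct[reference_gene, ])
  ddct <- dct - dct[, calibrator]
  2^(-ddct)
}
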