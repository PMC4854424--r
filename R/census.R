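# Orchestration: one call runs the full census (scan -> classify ->
# physchem -> structure -> map -> tree -> expression) from a config list
# or YAML file and writes the census table, group summary and a manifest.

#' Run the full WRKY census
#'
#' Accepts a config list (or path to a YAML file with the same fields):
#' `proteins` (FASTA path), optional `references` (labeled FASTA, see
#' [read_references()]), optional `gff` + `genome` (GFF3 and chromosome
#' FASTA), optional `expression` (`list(matrix =, meta =)` TSV paths),
#' `out_dir`, and optional settings `prefix`, `cluster_gap`,
#' `min_identity`, `max_intervening`, `expressed_threshold`, `min_fold`,
#' `length_threshold`, `bootstrap_replicates`, `seed`. Stages whose inputs
#' are absent are skipped with a note in the run log; all outputs land in
#' `out_dir` with an md5 manifest.
#'
#' @param config list or YAML path.
#' @return invisible list with `census`, `groups`, `clusters`, `tandem`,
#'   `introns`, `calls`, `tree` and `manifest`.
#' @export
run_census <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config needs the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    prefix = "WRKY", cluster_gap = 200000, min_identity = 70,
    max_intervening = 1, expressed_threshold = 1, min_fold = 2,
    length_threshold = 800, bootstrap_replicates = 100, seed = 1
  ), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  proteins <- if (is.character(cfg$proteins) && length(cfg$proteins) == 1 &&
                  file.exists(cfg$proteins)) {
    read_proteins(cfg$proteins)
  } else clean_proteins(cfg$proteins)
  if (length(proteins) == 0) stop("empty census: no proteins in input")
  logf("scan: ", length(proteins), " proteins")
  domains <- scan_proteome(proteins)

  references <- if (!is.null(cfg$references)) {
    if (is.character(cfg$references)) read_references(cfg$references)
    else cfg$references
  }
  ann <- annotate_family(proteins, domains, references,
                         length_threshold = cfg$length_threshold)
  logf("classify: ", nrow(ann), " WRKY-positive proteins")

  models <- NULL; loci <- NULL; clusters <- NULL; tandem <- NULL
  introns <- NULL
  if (!is.null(cfg$gff)) {
    models <- build_gene_models(cfg$gff)
    fam <- intersect(names(models), ann$id)
    orphans <- setdiff(ann$id, names(models))
    if (length(orphans) > 0) {
      logf("map: ", length(orphans),
           " family proteins without gene models (left unplaced): ",
           paste(utils::head(orphans, 5), collapse = ", "))
    }
    loci <- loci_from_models(models[fam])
    unplaced <- data.frame(gene_id = orphans,
                           chrom = rep(NA_character_, length(orphans)),
                           start = rep(NA_integer_, length(orphans)),
                           end = rep(NA_integer_, length(orphans)),
                           strand = rep(NA_character_, length(orphans)))
    loci <- assign_names(rbind(loci, unplaced), prefix = cfg$prefix)
    clusters <- detect_clusters(loci, max_gap_bp = cfg$cluster_gap)
    tandem <- detect_tandem(loci, proteins,
                            min_identity = cfg$min_identity,
                            max_intervening = cfg$max_intervening)
    introns <- intron_table(models[fam], domains, proteins)
    logf("map: ", nrow(attr(clusters, "clusters")), " clusters, ",
         nrow(tandem), " tandem pairs")
  } else {
    loci <- data.frame(gene_id = ann$id, chrom = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_)
    loci <- assign_names(loci, prefix = cfg$prefix)
    logf("map: skipped (no GFF3 input)")
  }

  tree <- NULL
  fam_domains <- vapply(ann$id, function(id) {
    cterm_domain_seq(proteins[[id]], domains[[id]])
  }, "")
  fam_domains <- fam_domains[!is.na(fam_domains)]
  if (length(fam_domains) >= 4) {
    aln <- align_progressive(fam_domains)
    tree <- nj_bootstrap(aln, replicates = cfg$bootstrap_replicates,
                         seed = cfg$seed)
    logf("tree: NJ with ", cfg$bootstrap_replicates,
         " bootstrap replicates over ", length(fam_domains), " domains")
  } else {
    logf("tree: skipped (fewer than 4 complete domains)")
  }

  calls <- NULL
  if (!is.null(cfg$expression)) {
    expr <- read_expression(cfg$expression$matrix, cfg$expression$meta)
    expressed <- call_expressed(expr$matrix, expr$meta,
                                threshold = cfg$expressed_threshold)
    trend <- devel_trend(expr$matrix, expr$meta, min_fold = cfg$min_fold)
    resp <- treatment_response(expr$matrix, expr$meta, fold = cfg$min_fold,
                               detect = cfg$expressed_threshold)
    calls <- list(expressed = expressed, trend = trend, responses = resp)
    logf("expression: ",
         sum(vapply(expressed, length, 0L) > 0), "/",
         length(expressed), " genes expressed in >= 1 tissue")
  } else {
    logf("expression: skipped (no expression input)")
  }

  census <- build_census_table(ann, loci)
  groups <- summarize_groups(census)

  write_tsv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    write_tsv(census, "census.tsv"),
    write_tsv(groups, "groups.tsv"),
    write_tsv(domain_table(domains), "domains.tsv"))
  if (!is.null(clusters)) {
    paths <- c(paths, write_tsv(clusters, "clusters.tsv"),
               write_tsv(tandem, "tandem.tsv"),
               write_tsv(introns, "introns.tsv"))
  }
  if (!is.null(tree)) {
    tree_path <- file.path(cfg$out_dir, "tree.nwk")
    write_tree_newick(tree, tree_path)
    paths <- c(paths, tree_path)
  }
  if (!is.null(calls)) {
    expr_tab <- data.frame(
      gene = names(calls$expressed),
      expressed_tissues = vapply(calls$expressed, paste, "", collapse = ","),
      trend = calls$trend[names(calls$expressed)])
    paths <- c(paths, write_tsv(expr_tab, "expression_calls.tsv"),
               write_tsv(calls$responses, "treatment_responses.tsv"))
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write_tsv(manifest, "manifest.tsv")
  logf("done: ", nrow(census), " census rows in ", cfg$out_dir)
  invisible(list(census = census, groups = groups, clusters = clusters,
                 tandem = tandem, introns = introns, calls = calls,
                 tree = tree, manifest = manifest))
}

# Assemble the census table (one row per family member).
build_census_table <- function(ann, loci) {
  ord <- match(loci$gene_id, ann$id)
  keep <- !is.na(ord)
  ann2 <- ann[ord[keep], , drop = FALSE]
  loci2 <- loci[keep, , drop = FALSE]
  data.frame(
    name = loci2$name,
    gene_id = ann2$id,
    chr = loci2$chrom,
    orf_aa = ann2$length,
    mw_kda = round(ann2$mw / 1000, 4),
    pi = round(ann2$pi, 2),
    ai = round(ann2$ai, 2),
    gravy = round(ann2$gravy, 3),
    instability = round(ann2$instability, 2),
    wrkygqk = ifelse(is.na(ann2$core_variant),
                     as.character(ann2$core_count), ann2$core_variant),
    domain_pattern = ann2$patterns,
    group = ann2$group,
    zinc_finger = ann2$zinc_finger
  )
}

#' Summarize group sizes
#'
#' Counts census rows per group label. IV and NG are reported separately
#' and also merged into an `NG_merged` column for comparison with
#' published per-species summary tables that fold ungrouped members
#' together.
#'
#' @param census census table from [run_census()] (or any data.frame with
#'   a `group` column).
#' @return one-row data.frame with per-group counts, `NG_merged` and
#'   `total`.
#' @export
summarize_groups <- function(census) {
  labs <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "IV", "NG")
  counts <- vapply(labs, function(g) sum(census$group == g), 0L)
  out <- as.data.frame(as.list(counts))
  names(out) <- labs
  out$NG_merged <- out$NG + out$IV
  out$total <- nrow(census)
  out
}
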