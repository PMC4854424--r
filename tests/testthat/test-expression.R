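# Qualitative expression calls: tissue presence, developmental trend,
# treatment response.

fixture_meta <- function() {
  rbind(
    data.frame(sample = c("root", "stem", "leaf", "fruit"),
               tissue = c("root", "stem", "leaf", "fruit"),
               stage = NA_integer_, treatment = "none", control_pair = ""),
    data.frame(sample = paste0("Day", c(18, 24, 30, 36, 42)),
               tissue = "fruit", stage = c(18L, 24L, 30L, 36L, 42L),
               treatment = "none", control_pair = ""),
    data.frame(sample = c("IAA.CK.18d", "IAA.18d"),
               tissue = "fruit", stage = 18L,
               treatment = c("control", "IAA"),
               control_pair = c("", "IAA.CK.18d")))
}

fixture_matrix <- function(rows) {
  meta <- fixture_meta()
  mat <- do.call(rbind, rows)
  colnames(mat) <- meta$sample
  rownames(mat) <- names(rows)
  mat
}

test_that("tissue calls use the per-tissue maximum against the threshold", {
  meta <- fixture_meta()
  mat <- fixture_matrix(list(
    zero = rep(0, 11),
    rooty = c(5, 0, 0, 0, rep(0, 7)),
    dim = c(0.5, 0.5, 0.5, 0.5, rep(0, 7))))
  calls <- call_expressed(mat, meta, threshold = 1)
  expect_equal(calls$zero, character(0))
  expect_equal(calls$rooty, "root")
  expect_equal(calls$dim, character(0))
  expect_error(call_expressed(mat, meta, tissues = "petal"), "unknown")
  # raising the threshold never enlarges a call set
  lo <- call_expressed(mat, meta, threshold = 0.1)
  hi <- call_expressed(mat, meta, threshold = 4)
  for (g in rownames(mat)) {
    expect_true(all(hi[[g]] %in% lo[[g]]))
  }
})

test_that("trend labels follow the fold and monotonicity rules", {
  meta <- fixture_meta()
  mat <- fixture_matrix(list(
    up = c(0, 0, 0, 16, 1, 2, 4, 8, 16, 0, 0),
    flat = c(0, 0, 0, 5, 5, 5, 5, 5, 5, 0, 0),
    zig = c(0, 0, 0, 16, 1, 8, 2, 16, 4, 0, 0),
    down = c(0, 0, 0, 16, 16, 8, 4, 2, 1, 0, 0)))
  trends <- devel_trend(mat, meta, min_fold = 2, tolerance = 0)
  expect_equal(unname(trends[c("up", "flat", "zig", "down")]),
               c("up", "flat", "mixed", "down"))
  # an all-zero series is flat, a zero start with later signal is up
  mat2 <- fixture_matrix(list(
    silent = rep(0, 11),
    ignite = c(0, 0, 0, 16, 0, 2, 4, 8, 16, 0, 0)))
  expect_message(
    trends2 <- devel_trend(mat2, meta, min_fold = 2, tolerance = 0),
    "infinite")
  expect_equal(unname(trends2), c("flat", "up"))
})

test_that("treatment responses compare treated against paired control", {
  meta <- fixture_meta()
  mat <- fixture_matrix(list(
    ind = c(rep(0, 9), 2, 8),
    rep_ = c(rep(0, 9), 8, 1),
    same = c(rep(0, 9), 4, 4),
    off = c(rep(0, 9), 0, 0)))
  resp <- treatment_response(mat, meta, fold = 2, detect = 1)
  got <- setNames(resp$response, resp$gene)
  expect_equal(unname(got[c("ind", "rep_", "same", "off")]),
               c("induced", "repressed", "unchanged", "undetected"))
  # missing control is an error naming the sample
  meta_bad <- fixture_meta()
  meta_bad$control_pair[meta_bad$sample == "IAA.18d"] <- "IAA.CK.36d"
  expect_error(treatment_response(mat, meta_bad), "IAA.CK.36d")
})

test_that("calls are invariant to gene and sample order", {
  ex <- sim_expression(n_genes = 20, noise_sd = 0.05, seed = 8)
  mat <- ex$matrix; meta <- ex$meta
  perm_g <- sample(nrow(mat)); perm_s <- sample(ncol(mat))
  mat2 <- mat[perm_g, perm_s]
  meta2 <- meta[match(colnames(mat2), meta$sample), ]
  c1 <- call_expressed(mat, meta)
  c2 <- call_expressed(mat2, meta2)
  for (g in rownames(mat)) expect_setequal(c1[[g]], c2[[g]])
  t1 <- devel_trend(mat, meta)
  t2 <- devel_trend(mat2, meta2)
  expect_equal(t1[rownames(mat)], t2[rownames(mat)])
})

test_that("round-trip: zero noise recovers every planted label", {
  ex <- sim_expression(n_genes = 40, noise_sd = 0, seed = 12)
  calls <- call_expressed(ex$matrix, ex$meta)
  truth_tissues <- strsplit(ex$truth$tissues, ",")
  expect_true(all(mapply(setequal, calls[ex$truth$gene_id], truth_tissues)))
  trends <- devel_trend(ex$matrix, ex$meta)
  expect_equal(unname(trends[ex$truth$gene_id]), ex$truth$trend)
  resp <- treatment_response(ex$matrix, ex$meta)
  for (tr in c("IAA", "ABA", "sucrose")) {
    sub <- resp[resp$treatment == tr, ]
    truth <- setNames(ex$truth[[paste0("response.", tr)]],
                      ex$truth$gene_id)
    expect_true(all(sub$response == truth[sub$gene]))
  }
})

test_that("noisy recovery stays above 95 percent", {
  ex <- sim_expression(n_genes = 50, noise_sd = 0.1, seed = 3)
  calls <- call_expressed(ex$matrix, ex$meta)
  trends <- devel_trend(ex$matrix, ex$meta)
  resp <- treatment_response(ex$matrix, ex$meta)
  ok_t <- mapply(setequal, calls[ex$truth$gene_id],
                 strsplit(ex$truth$tissues, ","))
  ok_tr <- trends[ex$truth$gene_id] == ex$truth$trend
  ok_r <- unlist(lapply(c("IAA", "ABA", "sucrose"), function(tr) {
    sub <- resp[resp$treatment == tr, ]
    truth <- setNames(ex$truth[[paste0("response.", tr)]], ex$truth$gene_id)
    sub$response == truth[sub$gene]
  }))
  expect_gte(mean(c(ok_t, ok_tr, ok_r)), 0.95)
})

test_that("TSV round trip preserves matrix and metadata", {
  ex <- sim_expression(n_genes = 10, noise_sd = 0, seed = 2)
  mp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_expression(ex, mp, sp)
  back <- read_expression(mp, sp)
  expect_equal(back$matrix, ex$matrix)
  expect_equal(back$meta$sample, ex$meta$sample)
})

test_that("ddCt conversion matches the closed form", {
  ct <- matrix(c(20, 18, 25, 25, 22, 21), nrow = 3, byrow = TRUE,
               dimnames = list(c("target", "ref", "other"),
                               c("ck", "trt")))
  rel <- ddct_expression(ct, "ref", "ck")
  expect_equal(rel["target", "ck"], 1)
  # dCt: trt 18-25 = -7, ck 20-25 = -5; ddCt = -2 -> 4
  expect_equal(rel["target", "trt"], 4)
})
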