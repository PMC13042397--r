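# Expression/annotation I/O and preprocessing.

test_that("expression TSV parsing handles missing cells and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2",
               "A\t1.5\tNA",
               "B\t2\t3",
               "C\t\t4.25"), path)
  m <- read_expression_matrix(path, scale = "log2")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m)), 2L)
  expect_equal(unclass(m)["C", "s2"], 4.25)

  writeLines(c("protein_id\ts1", "A\t1", "A\t2"), path)
  expect_error(read_expression_matrix(path), "duplicate protein id.*A")
  writeLines(c("protein_id\ts1", "A\tx1"), path)
  expect_error(read_expression_matrix(path), "non-numeric.*'A'.*'s1'")
})

test_that("write/read round-trip is lossless for values, ids and missingness", {
  m <- random_expr(50, 20, seed = 7, missing = 0.15)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  m2 <- read_expression_matrix(path, scale = "log2")
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  expect_identical(unclass(m2), unclass(m))
})

test_that("sample annotations validate stage vocabulary and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstage\tcompartment", "s1\tMOD\tL"), path)
  ann <- read_sample_annotation(path)
  expect_equal(ann$stage_rank, 2L)

  writeLines(c("sample_id\tstage\tcompartment", "s1\tCIS\tL"), path)
  expect_error(read_sample_annotation(path), "unknown stage.*CIS")
  writeLines(c("sample_id\tstage\tcompartment", "s1\tMOD\tL", "s1\tMID\tL"),
             path)
  expect_error(read_sample_annotation(path), "duplicate sample_id")
})

test_that("cohort-shaped annotation yields the published group tallies", {
  design <- build_stage_design(cohort_annotation())
  sizes <- vapply(design$groups, length, integer(1))
  expect_equal(unname(sizes[paste0(c("ESO", "MID", "MOD", "SED", "ESCC"), ".L")]),
               c(10L, 19L, 11L, 14L, 10L))
  expect_equal(unname(sizes[paste0(c("ESO", "MID", "MOD", "SED", "ESCC"), ".N")]),
               c(8L, 17L, 8L, 10L, 5L))
  expect_length(design$groups, 10L)
  expect_equal(sum(sizes), 112L)
})

test_that("small groups are flagged but retained", {
  d <- toy_design(c("a", "b", "c"), c("ESO", "ESO", "MID"),
                  stage_order = c("ESO", "MID"))
  d2 <- build_stage_design(d$samples[, 1:4], c("ESO", "MID"),
                           min_group_size = 3L)
  expect_match(d2$warnings, "MID.L has 1", all = FALSE)
  expect_equal(d2$groups[["MID.L"]], "c")
})

test_that("median normalisation equalises column medians and is idempotent", {
  # forced case: two columns with medians 10 and 12 both land on 11
  m <- expr_matrix(matrix(c(9, 10, 11, 11, 12, 13), 3, 2,
                          dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  mn <- median_normalize(m)
  expect_equal(unname(apply(mn, 2, median)), c(11, 11))

  m2 <- random_expr(200, 30, seed = 11, missing = 0.2)
  n1 <- median_normalize(m2)
  meds <- apply(unclass(n1), 2, median, na.rm = TRUE)
  expect_lt(diff(range(meds)), 1e-9)
  expect_identical(is.na(unclass(n1)), is.na(unclass(m2)))
  # idempotence
  n2 <- median_normalize(n1)
  expect_equal(unclass(n2), unclass(n1), tolerance = 1e-9)
  # already-equal medians: unchanged
  expect_equal(unclass(median_normalize(n1)), unclass(n1), tolerance = 1e-12)
  # raw-scale normalisation rescales rather than shifts
  raw <- expr_matrix(2^unclass(m2), scale = "raw")
  rn <- median_normalize(raw)
  expect_lt(diff(range(apply(unclass(rn), 2, median, na.rm = TRUE))), 1e-9)
  expect_error(median_normalize(expr_matrix(
    matrix(NA_real_, 2, 1, dimnames = list(c("A", "B"), "s1")))),
    "all values missing")
})

test_that("median normalisation commutes with column permutation", {
  m <- random_expr(80, 12, seed = 3, missing = 0.1)
  perm <- sample(ncol(m))
  a <- median_normalize(m)[, perm]
  b <- median_normalize(m[, perm])
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("log2 transform inverts exactly and guards its domain", {
  m <- expr_matrix(matrix(c(8, 1), 2, 1, dimnames = list(c("A", "B"), "s1")),
                   scale = "raw")
  lt <- log2_transform(m)
  expect_equal(unname(unclass(lt)[, 1]), c(3, 0))
  expect_identical(attr(lt, "scale"), "log2")

  raw <- expr_matrix(2^unclass(random_expr(40, 10, seed = 5, missing = 0.1)),
                     scale = "raw")
  back <- 2^unclass(log2_transform(raw))
  expect_equal(back, unclass(raw), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(log2_transform(log2_transform(raw)), "already")
})

test_that("completeness filter matches a brute-force per-group count", {
  m <- random_expr(150, 24, seed = 13, missing = 0.2)
  design <- toy_design(colnames(m), rep(c("ESO", "MID", "MOD"), each = 8),
                       stage_order = c("ESO", "MID", "MOD"))
  kept <- rownames(filter_by_completeness(m, design, 0.5))
  # brute force: fraction observed per group
  ok <- sapply(rownames(m), function(p) {
    any(sapply(design$groups, function(ids)
      mean(!is.na(unclass(m)[p, ids])) >= 0.5))
  })
  expect_identical(kept, rownames(m)[ok])

  expect_equal(nrow(filter_by_completeness(m, design, 0)), nrow(m))
  m2 <- m
  m2[1, ] <- NA
  expect_false(rownames(m)[1] %in%
               rownames(filter_by_completeness(m2, design, 0.01)))
  expect_error(filter_by_completeness(m, design, 1.2), "min_frac")
})

test_that("completeness filter is monotone in min_frac", {
  m <- random_expr(120, 18, seed = 17, missing = 0.35)
  design <- toy_design(colnames(m), rep(c("ESO", "MID"), each = 9),
                       stage_order = c("ESO", "MID"))
  fr <- c(0.2, 0.5, 0.8)
  sets <- lapply(fr, function(f) rownames(filter_by_completeness(m, design, f)))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("GMT and ligand-receptor tables parse", {
  gmt <- system.file("extdata", "emt_sets_synthetic.gmt", package = "dnbpipe")
  sets <- read_gmt(gmt)
  expect_named(sets, c("epithelial", "mesenchymal"))
  expect_true("VIM" %in% sets$mesenchymal)
  lr <- read_lr_pairs(system.file("extdata", "lr_pairs_synthetic.tsv",
                                  package = "dnbpipe"))
  expect_true(all(c("ligand", "receptor") %in% colnames(lr)))
  expect_gt(nrow(lr), 0)
})
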