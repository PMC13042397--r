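# DNB statistics, module discovery, composite index and tipping detection.

test_that("stagewise statistics equal a direct computation", {
  m <- random_expr(100, 12, seed = 41, missing = 0.15)
  design <- toy_design(colnames(m), rep(c("ESO", "MID"), each = 6),
                       stage_order = c("ESO", "MID"))
  st <- stagewise_stats(m, design, "ESO", "L", min_obs_frac = 0.5)
  ids <- design$groups[["ESO.L"]]
  x <- unclass(m)[st$protein_ids, ids]
  expect_equal(unname(st$sd),
               unname(apply(x, 1, sd, na.rm = TRUE)), tolerance = 1e-12)
  ref <- abs(cor(t(x), use = "pairwise.complete.obs"))
  diag(ref) <- 1
  expect_equal(unclass(st$pcc)[!is.na(st$pcc)], ref[!is.na(st$pcc)],
               tolerance = 1e-12)
})

test_that("degenerate within-stage patterns are flagged, not zeroed", {
  x <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  x[1, ] <- x[2, ]          # identical rows -> |PCC| = 1
  x[3, ] <- 7               # constant -> sd 0, undefined correlations
  m <- expr_matrix(x, scale = "log2")
  design <- toy_design(colnames(m), rep("ESO", 5), stage_order = "ESO")
  st <- stagewise_stats(m, design, "ESO", "L")
  expect_equal(st$pcc["p1", "p2"], 1)
  expect_equal(unname(st$sd["p3"]), 0)
  expect_true(all(is.na(st$pcc["p3", setdiff(rownames(x), "p3")])))
  expect_error(stagewise_stats(m, toy_design("s1", "ESO", stage_order = "ESO"),
                               "ESO", "L"), ">= 3")
})

test_that("composite index matches the forced worked example", {
  # two members, sd 1 each, internal |PCC| 1, decoupled from outside:
  # ci = 1 * 1 / max(0, 0.01) = 100
  s <- c(2, 4, 6, 8, 10)
  x <- rbind(a = s, b = s,
             c = c(5, -3, 5, -3, 5) * 1e-8 + 10)
  x["a", ] <- x["a", ] / sd(s)   # sd_in = 1
  x["b", ] <- x["b", ] / sd(s)
  colnames(x) <- paste0("s", 1:5)
  design <- toy_design(colnames(x), rep("ESO", 5), stage_order = "ESO")
  st <- stagewise_stats(expr_matrix(x, scale = "log2"), design, "ESO", "L")
  # force exact outside decoupling for the worked value
  st$pcc["a", "c"] <- st$pcc["c", "a"] <- 0
  st$pcc["b", "c"] <- st$pcc["c", "b"] <- 0
  mod <- composite_index(st, c("a", "b"))
  expect_equal(mod$sd_in, 1, tolerance = 1e-12)
  expect_equal(mod$pcc_in, 1, tolerance = 1e-12)
  expect_equal(mod$pcc_out, 0)
  expect_equal(mod$ci, 100, tolerance = 1e-10)

  # all-constant members score zero
  x2 <- rbind(k1 = rep(1, 5), k2 = rep(2, 5), n1 = rnorm(5), n2 = rnorm(5))
  colnames(x2) <- paste0("s", 1:5)
  st2 <- stagewise_stats(expr_matrix(x2, scale = "log2"), design, "ESO", "L")
  expect_error(composite_index(st2, c("k1", "k2")), "undefined")
})

test_that("composite index agrees with the brute-force oracle on random instances", {
  for (case in 1:100) {
    set.seed(case)
    x <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:8)))
    design <- toy_design(colnames(x), rep("ESO", 8), stage_order = "ESO")
    st <- stagewise_stats(expr_matrix(x, scale = "log2"), design, "ESO", "L",
                          min_obs_frac = 0)
    members <- sample(rownames(x), 4)
    expect_lt(abs(composite_index(st, members)$ci - oracle_ci(x, members)),
              1e-10)
  }
})

test_that("composite index matches full enumeration of small modules", {
  set.seed(99)
  x <- matrix(rnorm(12 * 9), 12, 9,
              dimnames = list(sprintf("p%02d", 1:12), paste0("s", 1:9)))
  design <- toy_design(colnames(x), rep("ESO", 9), stage_order = "ESO")
  st <- stagewise_stats(expr_matrix(x, scale = "log2"), design, "ESO", "L",
                        min_obs_frac = 0)
  for (k in 2:5) {
    combos <- combn(rownames(x), k)
    for (j in seq_len(ncol(combos))) {
      mem <- combos[, j]
      expect_lt(abs(composite_index(st, mem)$ci - oracle_ci(x, mem)), 1e-10)
    }
  }
})

test_that("candidate discovery finds planted blocks and resists noise", {
  planted_hit <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 12
    z <- rnorm(n)
    block <- t(sapply(1:15, function(i) sqrt(0.8) * z + sqrt(0.2) * rnorm(n)))
    noise <- matrix(rnorm(200 * n), 200, n)
    x <- rbind(block, noise)
    rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
    colnames(x) <- paste0("s", 1:n)
    design <- toy_design(colnames(x), rep("ESO", n), stage_order = "ESO")
    st <- stagewise_stats(expr_matrix(x, scale = "log2"), design, "ESO", "L")
    cands <- candidate_modules(st)
    if (length(cands) == 0) return(0L)
    max(sapply(cands, function(cc) length(intersect(cc, rownames(x)[1:15]))))
  })
  expect_true(all(planted_hit >= 12))

  null_sizes <- sapply(1:20, function(s) {
    m <- random_expr(200, 30, seed = 1000 + s)
    design <- toy_design(colnames(m), rep("ESO", 30), stage_order = "ESO")
    st <- stagewise_stats(m, design, "ESO", "L")
    length(candidate_modules(st, min_size = 5, linkage_cut = 0.5))
  })
  expect_gte(mean(null_sizes == 0), 0.8)

  # two disjoint planted blocks give two disjoint candidates
  set.seed(5)
  n <- 15
  mk <- function() {
    z <- rnorm(n)
    t(sapply(1:6, function(i) sqrt(0.9) * z + sqrt(0.1) * rnorm(n)))
  }
  x <- rbind(mk(), mk())
  rownames(x) <- sprintf("q%02d", 1:12)
  colnames(x) <- paste0("s", 1:n)
  design <- toy_design(colnames(x), rep("ESO", n), stage_order = "ESO")
  st <- stagewise_stats(expr_matrix(x, scale = "log2"), design, "ESO", "L")
  cands <- candidate_modules(st, min_size = 5)
  expect_gte(length(cands), 2)
  expect_length(intersect(cands[[1]], cands[[2]]), 0)
})

test_that("ci scales linearly with the data and ignores per-protein offsets", {
  ds <- generate_staged_dataset(small_config(seed = 12, missing_rate = 0))
  design <- build_stage_design(ds$annotations)
  m <- median_normalize(ds$matrix)
  r1 <- detect_tipping_stage(m, design, "L")
  a <- 2.5
  r2 <- detect_tipping_stage(expr_matrix(unclass(m) * a, scale = "log2"),
                             design, "L")
  expect_identical(r2$tipping_stage, r1$tipping_stage)
  expect_equal(r2$ci_by_stage, a * r1$ci_by_stage, tolerance = 1e-8)

  shift <- rnorm(nrow(m))
  r3 <- detect_tipping_stage(expr_matrix(unclass(m) + shift, scale = "log2"),
                             design, "L")
  expect_equal(r3$ci_by_stage, r1$ci_by_stage, tolerance = 1e-8)
  expect_identical(r3$dnb_members, r1$dnb_members)
})

test_that("the tipping stage follows the planted spike", {
  r_mid <- sapply(1:5, function(s) {
    ds <- generate_staged_dataset(small_config(seed = 20 + s))
    design <- build_stage_design(ds$annotations)
    m <- filter_by_completeness(median_normalize(ds$matrix), design, 0.5)
    detect_tipping_stage(m, design, "L")$tipping_stage
  })
  expect_gte(mean(r_mid == "MID"), 0.8)
  # relabeling symmetry: spike planted at SED instead
  r_sed <- sapply(1:5, function(s) {
    ds <- generate_staged_dataset(small_config(seed = 30 + s,
                                               tipping_stage = "SED"))
    design <- build_stage_design(ds$annotations)
    m <- filter_by_completeness(median_normalize(ds$matrix), design, 0.5)
    detect_tipping_stage(m, design, "L")$tipping_stage
  })
  expect_gte(mean(r_sed == "SED"), 0.8)
})

test_that("permutation p-values respect their formula bounds and find the spike", {
  ds <- generate_staged_dataset(small_config(seed = 3))
  design <- build_stage_design(ds$annotations)
  m <- filter_by_completeness(median_normalize(ds$matrix), design, 0.5)
  p <- permutation_significance(m, design, "L", B = 19, seed = 1)
  expect_true(all(p >= 1 / 20 & p <= 1))
  expect_lte(p[["MID"]], 0.05 * 4)  # loose at B = 19; power tested at B = 99
  expect_error(permutation_significance(m, design, "L", B = 5), "B must be")
})
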