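# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored binary data.

# small synthetic configuration for fast end-to-end tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(n_proteins = 300L, n_trend_proteins = 15L,
                   seed = seed, ...)
}

# seeded random expression matrix (log2 scale) with optional missingness
random_expr <- function(n_proteins, n_samples, seed = 1L, missing = 0,
                        mean = 20, sd = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n_proteins * n_samples, mean, sd), n_proteins, n_samples,
              dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (missing > 0) x[sample(length(x), round(missing * length(x)))] <- NA
  expr_matrix(x, scale = "log2")
}

# minimal two-stage, one-compartment design over given columns
toy_design <- function(sample_ids, stages, compartment = "L",
                       stage_order = unique(stages)) {
  ann <- data.frame(sample_id = sample_ids, stage = stages,
                    compartment = compartment, subject_id = NA_character_,
                    stringsAsFactors = FALSE)
  build_stage_design(ann, stage_order)
}

# annotation table shaped like the two-compartment biopsy cohort
cohort_annotation <- function() {
  sizes_l <- c(ESO = 10, MID = 19, MOD = 11, SED = 14, ESCC = 10)
  sizes_n <- c(ESO = 8, MID = 17, MOD = 8, SED = 10, ESCC = 5)
  rows <- do.call(rbind, lapply(c("L", "N"), function(comp) {
    sizes <- if (comp == "L") sizes_l else sizes_n
    do.call(rbind, lapply(names(sizes), function(st)
      data.frame(sample_id = sprintf("%s_%s_%02d", comp, st, seq_len(sizes[[st]])),
                 stage = st, compartment = comp, stringsAsFactors = FALSE)))
  }))
  rows
}

## ---- independent oracles ---------------------------------------------------

# brute-force composite index from raw stage-block values (proteins x
# samples): explicit per-pair loops, pairwise-complete correlations flagged
# undefined below min_pairs shared observations
oracle_ci <- function(x, members, eps = 0.01, min_pairs = 3) {
  sds <- sapply(seq_len(nrow(x)), function(i) stats::sd(x[i, ], na.rm = TRUE))
  names(sds) <- rownames(x)
  pair_r <- function(i, j) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    if (sum(ok) < min_pairs) return(NA_real_)
    r <- suppressWarnings(stats::cor(x[i, ok], x[j, ok]))
    abs(r)
  }
  idx <- match(sort(members), rownames(x))
  out_idx <- setdiff(seq_len(nrow(x)), idx)
  pin <- c()
  for (a in seq_along(idx))
    for (b in seq_len(a - 1))
      pin <- c(pin, pair_r(idx[a], idx[b]))
  pcc_in <- mean(pin, na.rm = TRUE)
  pout <- c()
  for (a in idx) for (b in out_idx) pout <- c(pout, pair_r(a, b))
  pcc_out <- if (length(pout) == 0) 0 else mean(pout, na.rm = TRUE)
  if (is.nan(pcc_out)) pcc_out <- 0
  mean(sds[idx]) * pcc_in / max(pcc_out, eps)
}

# exhaustive pair-count AUC (probability positive > negative, ties = 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# adjusted Rand index between two labelings (closed-form from the
# contingency table; independent of any clustering code under test)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
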