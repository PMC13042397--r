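# Differential expression between sample groups: a normality-gated choice of
# Welch's t test vs the Wilcoxon rank-sum test, fold changes computed as
# 2^(difference of log2 group means), and up/down calls requiring p < alpha
# together with a strict fold-change bound (FC > 1.20 or FC < 0.83 by
# default). No multiple-testing correction enters the calls; a
# Benjamini-Hochberg column is attached for information.

#' Choose the two-sample test by a Shapiro-Wilk normality gate
#'
#' Returns \code{"student_t"} when the Shapiro-Wilk p-value is at least
#' \code{alpha_norm} in BOTH groups, else \code{"wilcoxon"}. A group with
#' zero variance cannot be tested for normality and routes to the rank test.
#'
#' @param group_a,group_b numeric vectors (missing values removed by the
#'   caller), each with at least 3 values.
#' @param alpha_norm significance level of the normality gate.
#' @return \code{"student_t"} or \code{"wilcoxon"}.
#' @export
normality_gate <- function(group_a, group_b, alpha_norm = 0.05) {
  for (g in list(group_a, group_b))
    if (length(g) < 3)
      stopf("normality gate needs >= 3 values per group (got %d)", length(g))
  p_of <- function(g) {
    if (length(unique(g)) == 1) return(0)     # degenerate: not normal
    if (length(g) > 5000) g <- g[seq_len(5000)]
    shapiro.test(g)$p.value
  }
  if (p_of(group_a) >= alpha_norm && p_of(group_b) >= alpha_norm)
    "student_t" else "wilcoxon"
}

#' Test one protein between two groups
#'
#' Inputs are log2-scale values; the fold change is
#' \code{2^(mean(group_a) - mean(group_b))}. The two-sided p-value comes
#' from the gated test: Welch's t (unequal variances) or the Wilcoxon
#' rank-sum test (exact when both groups have <= 10 values and no ties,
#' normal approximation with tie correction otherwise). Calls use strict
#' inequalities: \code{up} requires \code{p < alpha} and \code{fc > fc_hi};
#' \code{down} requires \code{p < alpha} and \code{fc < fc_lo}.
#'
#' @param group_a,group_b numeric log2 vectors without NAs.
#' @param alpha significance level for calls.
#' @param fc_hi,fc_lo linear-scale fold-change bounds.
#' @param alpha_norm normality-gate level.
#' @return one-row data.frame: fc, log2fc, p_value, test, call, n_a, n_b.
#' @export
test_protein <- function(group_a, group_b, alpha = 0.05,
                         fc_hi = 1.20, fc_lo = 0.83, alpha_norm = 0.05) {
  n_a <- length(group_a); n_b <- length(group_b)
  log2fc <- mean(group_a) - mean(group_b)
  fc <- 2^log2fc
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    p <- if (mean(group_a) == mean(group_b)) 1 else 0
    test <- "wilcoxon"
    if (mean(group_a) != mean(group_b))
      p <- suppressWarnings(wilcox.test(group_a, group_b)$p.value)
  } else {
    test <- normality_gate(group_a, group_b, alpha_norm)
    p <- if (test == "student_t") {
      t.test(group_a, group_b, var.equal = FALSE)$p.value
    } else {
      exact <- min(n_a, n_b) <= 10 &&
        !anyDuplicated(c(group_a, group_b))
      suppressWarnings(
        wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value)
    }
  }
  call <- "ns"
  if (p < alpha && fc > fc_hi) call <- "up"
  if (p < alpha && fc < fc_lo) call <- "down"
  data.frame(fc = fc, log2fc = log2fc, p_value = p, test = test,
             call = call, n_a = n_a, n_b = n_b, stringsAsFactors = FALSE)
}

#' Differential-expression table between two sample groups
#'
#' Each group is a character vector of sample ids (unions of several
#' (stage, compartment) groups are allowed, e.g. the post-phase contrast).
#' A protein is tested when it has at least \code{min_n} non-missing values
#' in each group; others are skipped with a reason. Records are sorted by
#' p-value, then decreasing |log2fc|. A BH-adjusted column \code{padj} is
#' attached for information only and plays no part in the calls.
#'
#' @param mat a log2-scale \code{\link{expr_matrix}}.
#' @param samples_a,samples_b disjoint character vectors of column ids.
#' @param alpha,fc_hi,fc_lo,alpha_norm thresholds as in
#'   \code{\link{test_protein}}.
#' @param min_n minimum non-missing values per group (>= 3).
#' @return data.frame of per-protein records with attribute
#'   \code{"skipped"}: data.frame(protein_id, reason).
#' @export
de_table <- function(mat, samples_a, samples_b, alpha = 0.05,
                     fc_hi = 1.20, fc_lo = 0.83, alpha_norm = 0.05,
                     min_n = 3L) {
  if (length(samples_a) == 0 || length(samples_b) == 0)
    stopf("empty contrast group")
  if (length(intersect(samples_a, samples_b)) > 0)
    stopf("contrast groups overlap")
  missing_cols <- setdiff(c(samples_a, samples_b), colnames(mat))
  if (length(missing_cols) > 0)
    stopf("sample(s) not in matrix: %s", paste(missing_cols, collapse = ", "))
  A <- unclass(mat)[, samples_a, drop = FALSE]
  B <- unclass(mat)[, samples_b, drop = FALSE]
  rows <- vector("list", nrow(mat))
  skipped <- list()
  for (i in seq_len(nrow(mat))) {
    a <- A[i, ]; a <- a[!is.na(a)]
    b <- B[i, ]; b <- b[!is.na(b)]
    if (length(a) < min_n || length(b) < min_n) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        protein_id = rownames(mat)[i],
        reason = sprintf("fewer than %d observations in a group (%d vs %d)",
                         min_n, length(a), length(b)),
        stringsAsFactors = FALSE)
      next
    }
    rec <- test_protein(a, b, alpha = alpha, fc_hi = fc_hi, fc_lo = fc_lo,
                        alpha_norm = alpha_norm)
    rec$protein_id <- rownames(mat)[i]
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(protein_id = character(0), fc = numeric(0),
                      log2fc = numeric(0), p_value = numeric(0),
                      test = character(0), call = character(0),
                      n_a = integer(0), n_b = integer(0))
  out <- out[, c("protein_id", "fc", "log2fc", "p_value", "test", "call",
                 "n_a", "n_b")]
  out$padj <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -abs(out$log2fc), out$protein_id), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(protein_id = character(0), reason = character(0))
  out
}

#' Split ordered stages into pre/post phases at a tipping stage
#'
#' Stages with rank up to and including the tipping stage form the pre
#' phase; later stages form the post phase (under the default vocabulary and
#' tipping stage MID: pre = ESO+MID, post = MOD+SED+ESCC). A tipping stage
#' equal to the last stage leaves the post phase empty, with a warning.
#'
#' @param stage_order ordered stage vocabulary.
#' @param tipping_stage member of \code{stage_order}.
#' @return object of class \code{"phase_split"}: list(pre, post,
#'   tipping_stage).
#' @export
split_phases <- function(stage_order, tipping_stage) {
  r <- match(tipping_stage, stage_order)
  if (is.na(r)) stopf("tipping stage '%s' not in stage_order", tipping_stage)
  pre <- stage_order[seq_len(r)]
  post <- if (r < length(stage_order)) stage_order[(r + 1):length(stage_order)]
          else character(0)
  if (length(post) == 0)
    warnf("tipping stage is the last stage: post phase is empty")
  structure(list(pre = pre, post = post, tipping_stage = tipping_stage),
            class = "phase_split")
}

#' Stage-specific proteins by a presence rule
#'
#' Within one compartment, a protein is specific to stage s when it is
#' observed in at least \code{presence_frac} of the samples of (s,
#' compartment) and in less than \code{presence_frac} of the samples of
#' every other stage of that compartment.
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @param design a \code{stage_design}.
#' @param compartment \code{"L"} or \code{"N"}.
#' @param presence_frac detection fraction threshold in (0, 1].
#' @return named list stage -> character vector of protein ids.
#' @export
stage_specific_proteins <- function(mat, design, compartment,
                                    presence_frac = 0.6) {
  if (presence_frac <= 0 || presence_frac > 1)
    stopf("presence_frac must lie in (0, 1]")
  stages <- design$stage_order[group_key(design$stage_order, compartment) %in%
                               names(design$groups)]
  pres <- sapply(stages, function(st) {
    ids <- intersect(design$groups[[group_key(st, compartment)]], colnames(mat))
    rowMeans(!is.na(unclass(mat)[, ids, drop = FALSE]))
  })
  hit <- pres >= presence_frac
  out <- lapply(stages, function(st) {
    rownames(mat)[hit[, st] & rowSums(hit) == 1]
  })
  names(out) <- stages
  out
}
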