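# Phase-classifier construction: Mann-Whitney AUC, a small benchmarking
# harness over standard learners with identical stratified folds, SVM-RFE
# feature ranking (linear kernel, squared-weight criterion), and panel
# selection with fold-honest cross-validated AUC (the elimination is re-run
# inside every training fold).

#' Mann-Whitney AUC
#'
#' Rank-sum AUC with midranks for ties:
#' \code{AUC = (sum of positive ranks - n_pos (n_pos + 1) / 2) /
#' (n_pos n_neg)} — the probability that a random positive outscores a
#' random negative, counting ties as one half.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels logical (or coercible) vector, TRUE = positive class.
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stopf("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified cross-validation folds
#'
#' Fold indices stratified by class, repeated \code{repeats} times;
#' deterministic given \code{seed}. All learners in a benchmark share the
#' same assignments.
#'
#' @param labels logical class labels.
#' @param k_folds folds per repeat.
#' @param repeats number of repeats.
#' @param seed RNG seed.
#' @return list of length \code{repeats}, each an integer fold id per
#'   sample.
#' @export
make_cv_folds <- function(labels, k_folds = 5L, repeats = 1L, seed = 1L) {
  labels <- as.logical(labels)
  if (min(sum(labels), sum(!labels)) < k_folds)
    stopf("each class needs >= k_folds members")
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    fold <- integer(length(labels))
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    fold
  })
}

# feature standardisation learned on training data only
fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu, `-`), 2, sc$s, `/`)

# decision values oriented so larger = more likely TRUE; e1071 names the
# decision column "A/B" with positive values favouring class A
svm_decision_scores <- function(m, x) {
  dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")
  sgn <- if (strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1] == "TRUE")
    1 else -1
  sgn * dv[, 1]
}

# learner registry: fit(x, y) -> model; score(model, x) -> numeric
learner_registry <- function() {
  list(
    svm_linear = list(
      fit = function(x, y) e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                                      kernel = "linear", cost = 1,
                                      scale = FALSE),
      score = svm_decision_scores),
    svm_rbf = list(
      fit = function(x, y) e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                                      kernel = "radial", cost = 1,
                                      scale = FALSE),
      score = svm_decision_scores),
    logistic = list(
      fit = function(x, y) {
        df <- data.frame(x, check.names = FALSE)
        suppressWarnings(glm(y ~ ., data = cbind(y = y, df),
                             family = binomial()))
      },
      score = function(m, x) {
        suppressWarnings(
          predict(m, newdata = data.frame(x, check.names = FALSE),
                  type = "link"))
      }),
    random_forest = list(
      fit = function(x, y) randomForest::randomForest(
        x, factor(y, levels = c(FALSE, TRUE)), ntree = 200),
      score = function(m, x) predict(m, x, type = "prob")[, "TRUE"]),
    knn = list(
      fit = function(x, y) list(x = x, y = y, k = 5L),
      score = function(m, x) {
        pr <- class::knn(m$x, x, factor(m$y, levels = c(FALSE, TRUE)),
                         k = min(m$k, nrow(m$x)), prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "TRUE", p, 1 - p)
      })
  )
}

#' Benchmark learners by repeated stratified cross-validation
#'
#' Every learner is evaluated on identical fold assignments; features are
#' standardised on each training fold only. Deterministic given
#' \code{seed} (stochastic learners are reseeded per fold from it).
#'
#' @param x numeric matrix, samples x features, complete.
#' @param labels logical phase labels (TRUE = positive/post phase).
#' @param learners character subset of
#'   \code{c("svm_linear","svm_rbf","logistic","random_forest","knn")}.
#' @param k_folds,repeats,seed cross-validation controls.
#' @return data.frame(learner, mean_auc, sd_auc, k_folds, repeats, seed).
#' @export
benchmark_learners <- function(x, labels,
                               learners = c("svm_linear", "svm_rbf",
                                            "logistic", "random_forest",
                                            "knn"),
                               k_folds = 5L, repeats = 3L, seed = 1L) {
  reg <- learner_registry()
  unknown <- setdiff(learners, names(reg))
  if (length(unknown) > 0)
    stopf("unknown learner(s): %s", paste(unknown, collapse = ", "))
  labels <- as.logical(labels)
  folds <- make_cv_folds(labels, k_folds, repeats, seed)
  rows <- lapply(learners, function(ln) {
    lr <- reg[[ln]]
    aucs <- c()
    for (r in seq_along(folds)) {
      for (f in seq_len(k_folds)) {
        te <- folds[[r]] == f
        sc <- fit_scaler(x[!te, , drop = FALSE])
        xtr <- apply_scaler(x[!te, , drop = FALSE], sc)
        xte <- apply_scaler(x[te, , drop = FALSE], sc)
        set.seed(derive_seed(seed, r * 1000L + f))
        m <- lr$fit(xtr, labels[!te])
        aucs <- c(aucs, auc_mann_whitney(lr$score(m, xte), labels[te]))
      }
    }
    data.frame(learner = ln, mean_auc = mean(aucs), sd_auc = sd(aucs),
               k_folds = k_folds, repeats = repeats, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SVM-RFE feature ranking
#'
#' Recursive feature elimination with a linear-kernel SVM (fixed cost
#' \code{cost}): fit on the surviving features, rank by squared weight
#' \eqn{w_j^2}, eliminate the bottom \code{ceiling(drop_frac * surviving)}
#' (at least one), repeat until none survive. The reversed elimination
#' order is the importance ranking (most important first). Features are
#' standardised once on the supplied data; callers wanting fold honesty run
#' the ranking inside each training fold (as \code{\link{select_panel}}
#' does).
#'
#' @param x numeric matrix, samples x features, complete.
#' @param labels logical binary labels.
#' @param drop_frac fraction of surviving features eliminated per round.
#' @param cost SVM regularisation constant.
#' @return character vector of feature names, most important first.
#' @export
svm_rfe_rank <- function(x, labels, drop_frac = 0.1, cost = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) != 2) stopf("labels must contain both classes")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  sc <- fit_scaler(x)
  xs <- apply_scaler(x, sc)
  surviving <- colnames(xs)
  eliminated <- character(0)
  y <- factor(labels, levels = c(FALSE, TRUE))
  while (length(surviving) > 0) {
    if (length(surviving) == 1) {
      eliminated <- c(eliminated, surviving)
      break
    }
    m <- e1071::svm(xs[, surviving, drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = FALSE)
    w <- crossprod(m$coefs, m$SV)   # 1 x features
    w2 <- as.numeric(w)^2
    names(w2) <- colnames(m$SV)
    w2 <- w2[surviving]
    n_drop <- max(1L, ceiling(drop_frac * length(surviving)))
    # drop lowest-|w|^2 features; ties broken by feature name for determinism
    ord <- order(w2, names(w2))
    drop <- names(w2)[ord[seq_len(n_drop)]]
    eliminated <- c(eliminated, drop)
    surviving <- setdiff(surviving, drop)
  }
  rev(eliminated)
}

#' Select a biomarker panel from an SVM-RFE ranking
#'
#' Candidate panel sizes 1..\code{s_max} are scored by cross-validated AUC
#' in which the RFE ranking is recomputed inside every training fold (no
#' selection leakage); a linear SVM trained on the fold's top-s features
#' scores the held-out fold. The \code{fixed_k} rule returns the top-k
#' features of the full-data ranking (k = 7 mirrors a seven-protein
#' diagnostic panel); \code{one_se} returns the smallest size whose mean
#' AUC is within one SD of the best mean AUC.
#'
#' @param x numeric matrix, samples x features, complete.
#' @param labels logical phase labels (TRUE = post phase).
#' @param rule \code{"fixed_k"} or \code{"one_se"}.
#' @param k panel size under \code{fixed_k}.
#' @param s_max largest candidate size evaluated.
#' @param k_folds,repeats,seed cross-validation controls.
#' @param drop_frac,cost RFE controls.
#' @return object of class \code{"panel_model"}: ranked_features,
#'   selected_panel, cv_auc_by_size (data.frame size/mean_auc/sd_auc),
#'   final_auc (CV mean at the selected size), rule, learner descriptor,
#'   seed.
#' @export
select_panel <- function(x, labels, rule = c("fixed_k", "one_se"), k = 7L,
                         s_max = min(20L, ncol(x)), k_folds = 5L,
                         repeats = 1L, seed = 1L, drop_frac = 0.1,
                         cost = 1) {
  rule <- match.arg(rule)
  labels <- as.logical(labels)
  if (k > ncol(x)) stopf("k (%d) exceeds available features (%d)", k, ncol(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  folds <- make_cv_folds(labels, k_folds, repeats, seed)
  y <- factor(labels, levels = c(FALSE, TRUE))
  auc_by_size <- matrix(NA_real_, nrow = s_max,
                        ncol = k_folds * length(folds))
  col <- 0L
  for (r in seq_along(folds)) {
    for (f in seq_len(k_folds)) {
      col <- col + 1L
      te <- folds[[r]] == f
      rk <- svm_rfe_rank(x[!te, , drop = FALSE], labels[!te],
                         drop_frac = drop_frac, cost = cost)
      sc <- fit_scaler(x[!te, , drop = FALSE])
      xtr <- apply_scaler(x[!te, , drop = FALSE], sc)
      xte <- apply_scaler(x[te, , drop = FALSE], sc)
      for (s in seq_len(s_max)) {
        feat <- rk[seq_len(s)]
        m <- e1071::svm(xtr[, feat, drop = FALSE], y[!te], kernel = "linear",
                        cost = cost, scale = FALSE)
        auc_by_size[s, col] <- auc_mann_whitney(
          svm_decision_scores(m, xte[, feat, drop = FALSE]), labels[te])
      }
    }
  }
  cv <- data.frame(size = seq_len(s_max),
                   mean_auc = rowMeans(auc_by_size),
                   sd_auc = apply(auc_by_size, 1, sd))
  ranked <- svm_rfe_rank(x, labels, drop_frac = drop_frac, cost = cost)
  size <- if (rule == "fixed_k") as.integer(k) else {
    best <- max(cv$mean_auc)
    thr <- best - cv$sd_auc[which.max(cv$mean_auc)]
    min(cv$size[cv$mean_auc >= thr])
  }
  structure(list(ranked_features = ranked,
                 selected_panel = ranked[seq_len(size)],
                 cv_auc_by_size = cv,
                 final_auc = cv$mean_auc[size],
                 rule = rule,
                 learner = sprintf("linear SVM (cost = %g)", cost),
                 seed = seed),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model (%s): %d features, CV AUC %.3f\n", x$rule,
              length(x$selected_panel), x$final_auc))
  cat(" panel:", paste(x$selected_panel, collapse = ", "), "\n")
  invisible(x)
}

#' Build a complete feature matrix for classification
#'
#' Restricts to proteins observed in at least \code{min_obs_frac} of the
#' selected samples and fills the remaining missing entries with the
#' protein's median over those samples (a label-free imputation used only
#' to hand learners a complete matrix).
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @param sample_ids columns to use.
#' @param min_obs_frac completeness threshold for keeping a protein.
#' @return numeric matrix samples x features.
#' @export
panel_feature_matrix <- function(mat, sample_ids, min_obs_frac = 0.8) {
  x <- unclass(mat)[, sample_ids, drop = FALSE]
  keep <- rowMeans(!is.na(x)) >= min_obs_frac
  x <- x[keep, , drop = FALSE]
  med <- apply(x, 1, median, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) x[idx] <- med[idx[, 1]]
  t(x)
}
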