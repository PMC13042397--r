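# Soft clustering of per-stage mean trajectories with fuzzy c-means, the
# computation behind soft trend clustering of staged expression profiles.
# Profiles are row-standardised so clusters group shapes, not levels; the
# fuzzifier m controls how soft memberships are.

#' Per-stage mean expression profiles
#'
#' For one compartment, the mean over non-missing values of each protein in
#' each stage's samples. Proteins with no observed value at one or more
#' stages are excluded and reported via the \code{"excluded"} attribute.
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @param design a \code{stage_design}; every stage must have at least one
#'   sample in the compartment.
#' @param compartment \code{"L"} or \code{"N"}.
#' @return numeric matrix proteins x stages with attribute
#'   \code{"excluded"} (data.frame protein_id, reason) and
#'   \code{"standardized"} = FALSE.
#' @export
stage_mean_profiles <- function(mat, design, compartment) {
  stages <- design$stage_order
  keys <- group_key(stages, compartment)
  missing_groups <- stages[!keys %in% names(design$groups)]
  if (length(missing_groups) > 0)
    stopf("no samples for stage(s) %s in compartment %s",
          paste(missing_groups, collapse = ", "), compartment)
  prof <- sapply(stages, function(st) {
    ids <- intersect(design$groups[[group_key(st, compartment)]], colnames(mat))
    rowMeans(unclass(mat)[, ids, drop = FALSE], na.rm = TRUE)
  })
  bad_stage <- apply(prof, 1, function(r) stages[which(is.nan(r))[1]])
  keep <- is.na(bad_stage)
  excluded <- data.frame(protein_id = rownames(mat)[!keep],
                         reason = sprintf("no data at %s", bad_stage[!keep]),
                         stringsAsFactors = FALSE)
  out <- prof[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  attr(out, "standardized") <- FALSE
  out
}

#' Row-standardise stage profiles
#'
#' Row-wise z-scores (mean 0, SD 1 across stages). Zero-variance rows are
#' removed and reported via the \code{"removed"} attribute; the operation is
#' idempotent on its own output.
#'
#' @param profiles matrix from \code{\link{stage_mean_profiles}}.
#' @return standardised matrix with attributes \code{"standardized"} = TRUE
#'   and \code{"removed"} (character vector of dropped protein ids).
#' @export
standardize_profiles <- function(profiles) {
  mu <- rowMeans(profiles)
  s <- apply(profiles, 1, sd)
  keep <- s > 0
  out <- (profiles[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(out, "removed") <- rownames(profiles)[!keep]
  attr(out, "standardized") <- TRUE
  out
}

# one fuzzy c-means run from a given seeded initialisation
fcm_run <- function(x, c, m, seed, max_iter, tol) {
  n <- nrow(x)
  set.seed(seed)
  centers <- x[sample.int(n, c), , drop = FALSE]
  exponent <- 2 / (m - 1)
  obj_trace <- numeric(0)
  rowsum_dev <- numeric(0)
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, c)) + outer(rep(1, n), rowSums(centers^2)) -
      2 * x %*% t(centers)
    d2 <- pmax(d2, 0)
    # membership: u_ic = 1 / sum_k (d_ic / d_ik)^(2/(m-1)); coincident
    # centers (d = 0) receive full membership split among exact hits
    inv <- d2^(-exponent / 2)   # d^(-2/(m-1)) on squared distances
    zero <- d2 <= 0
    u <- inv / rowSums(inv)
    if (any(zero)) {
      zr <- which(rowSums(zero) > 0)
      u[zr, ] <- 0
      u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    }
    rowsum_dev <- c(rowsum_dev, max(abs(rowSums(u) - 1)))
    um <- u^m
    obj_trace <- c(obj_trace, sum(um * d2))
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, membership = u, objective = obj_trace[length(obj_trace)],
       objective_trace = obj_trace, rowsum_dev = rowsum_dev,
       n_iter = length(obj_trace), seed = seed)
}

#' Fuzzy c-means clustering of standardised profiles
#'
#' Alternating updates with Euclidean distance: membership
#' \eqn{u_{ic} = 1 / \sum_k (d_{ic}/d_{ik})^{2/(m-1)}}, centers
#' \eqn{\sum_i u_{ic}^m x_i / \sum_i u_{ic}^m}; stops when the maximum
#' center change falls below \code{tol} or after \code{max_iter}
#' iterations. Runs \code{restarts} seeded initialisations (centers drawn
#' from distinct data rows, restart seeds derived from \code{seed}) and
#' keeps the run with the lowest objective. Deterministic given
#' \code{seed}.
#'
#' @param profiles standardised profile matrix
#'   (\code{\link{standardize_profiles}}).
#' @param c number of clusters (>= 1, <= rows).
#' @param m fuzzifier, > 1.
#' @param seed master RNG seed.
#' @param max_iter,tol convergence controls.
#' @param restarts seeded initialisations to try.
#' @return object of class \code{"fuzzy_cmeans"}: centers (c x stages),
#'   membership (proteins x c, rows summing to 1), objective,
#'   objective_trace, rowsum_dev (per-iteration max |row sum - 1|), m, c,
#'   seed, n_iter.
#' @export
fuzzy_cmeans <- function(profiles, c = 4L, m = 1.25, seed = 1L,
                         max_iter = 200L, tol = 1e-6, restarts = 5L) {
  x <- unclass(profiles)
  if (c < 1) stopf("c must be >= 1")
  if (c > nrow(x)) stopf("c (%d) exceeds number of profiles (%d)", c, nrow(x))
  if (m <= 1) stopf("fuzzifier m must be > 1")
  if (c == 1) {
    ctr <- matrix(colMeans(x), 1, ncol(x), dimnames = list(NULL, colnames(x)))
    u <- matrix(1, nrow(x), 1, dimnames = list(rownames(x), NULL))
    d2 <- rowSums((x - ctr[rep(1, nrow(x)), , drop = FALSE])^2)
    return(structure(list(centers = ctr, membership = u, objective = sum(d2),
                          objective_trace = sum(d2), rowsum_dev = 0,
                          m = m, c = 1L, seed = seed, n_iter = 1L),
                     class = "fuzzy_cmeans"))
  }
  runs <- lapply(seq_len(restarts), function(r)
    fcm_run(x, c, m, seed = derive_seed(seed, r), max_iter = max_iter,
            tol = tol))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  rownames(best$membership) <- rownames(x)
  colnames(best$centers) <- colnames(x)
  structure(c(best, list(m = m, c = as.integer(c))), class = "fuzzy_cmeans")
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("fuzzy_cmeans: c = %d, m = %.3g, %d profiles, objective %.4g (%d iterations)\n",
              x$c, x$m, nrow(x$membership), x$objective, x$n_iter))
  invisible(x)
}

#' Hard cluster assignment (argmax membership)
#'
#' @param model a \code{fuzzy_cmeans} model.
#' @return named integer vector of cluster labels.
#' @export
hard_assignment <- function(model) {
  setNames(max.col(model$membership, ties.method = "first"),
           rownames(model$membership))
}

#' Core cluster members above a membership threshold
#'
#' A protein belongs to a cluster's core when its membership there is at
#' least \code{membership_threshold}; proteins below the threshold in every
#' cluster are reported as unassigned.
#'
#' @param model a \code{fuzzy_cmeans} model.
#' @param membership_threshold threshold in (0, 1].
#' @return list with \code{clusters} (list cluster -> protein ids) and
#'   \code{unassigned} (character vector).
#' @export
core_members <- function(model, membership_threshold = 0.5) {
  if (membership_threshold <= 0 || membership_threshold > 1)
    stopf("membership_threshold must lie in (0, 1]")
  u <- model$membership
  clusters <- lapply(seq_len(ncol(u)), function(k)
    rownames(u)[u[, k] >= membership_threshold])
  names(clusters) <- paste0("cluster_", seq_len(ncol(u)))
  unassigned <- rownames(u)[apply(u < membership_threshold, 1, all)]
  list(clusters = clusters, unassigned = unassigned)
}
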