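# Dynamic network biomarker (DNB) analysis. At each ordered stage the
# within-stage behaviour of every protein is summarised by its standard
# deviation and the matrix of absolute pairwise-complete Pearson
# correlations. A candidate module is a tightly correlated protein group
# (average-linkage clustering on 1 - |PCC|); its composite index
#   CI = SD_in * PCC_in / max(PCC_out, eps)
# rises sharply when a group's fluctuation and internal coupling spike while
# its coupling to the rest of the system drops — the early-warning signature
# of an approaching critical transition. The stage with the maximal best CI
# is called the tipping stage.

#' Within-stage statistics for DNB analysis
#'
#' Restricts the matrix to one (stage, compartment) group, drops proteins
#' observed in fewer than \code{min_obs_frac} of the group's samples, and
#' computes per-protein SDs (n-1 denominator) and the absolute
#' pairwise-complete Pearson correlation matrix. Correlations backed by
#' fewer than \code{min_pairs} shared observations (or zero variance) are
#' flagged undefined (NA), never coerced to zero.
#'
#' @param mat a log2-scale \code{\link{expr_matrix}}.
#' @param design a \code{stage_design}.
#' @param stage stage label.
#' @param compartment \code{"L"} or \code{"N"}.
#' @param min_obs_frac minimum observed fraction within the group.
#' @param min_pairs minimum shared observations per correlation.
#' @return object of class \code{"stage_stats"}: stage, compartment,
#'   protein_ids, sd (named vector), pcc (|r| matrix with NA where
#'   undefined), n_samples.
#' @export
stagewise_stats <- function(mat, design, stage, compartment,
                            min_obs_frac = 0.5, min_pairs = 3L) {
  key <- group_key(stage, compartment)
  ids <- intersect(design$groups[[key]] %||% character(0), colnames(mat))
  if (length(ids) < 3)
    stopf("group %s has %d sample(s); DNB statistics need >= 3", key, length(ids))
  x <- unclass(mat)[, ids, drop = FALSE]
  obs <- rowMeans(!is.na(x))
  keep <- obs >= min_obs_frac & rowSums(!is.na(x)) >= 2
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stopf("fewer than 2 proteins retained at %s", key)
  sds <- row_sds(x)
  r <- pcc_pairwise_cpp(x, as.integer(min_pairs))
  r[is.nan(r)] <- NA_real_
  pcc <- abs(r)
  diag(pcc) <- 1
  dimnames(pcc) <- list(rownames(x), rownames(x))
  structure(list(stage = stage, compartment = compartment,
                 protein_ids = rownames(x), sd = setNames(sds, rownames(x)),
                 pcc = pcc, n_samples = length(ids)),
            class = "stage_stats")
}

#' Candidate DNB modules at one stage
#'
#' Average-linkage hierarchical clustering on distance 1 - |PCC|
#' (undefined correlations treated as distance 1), tree cut at height
#' \code{linkage_cut}; every resulting group with at least \code{min_size}
#' members is a candidate. Candidates are returned largest first, ties by
#' first member id, for deterministic downstream tie-breaking.
#'
#' @param stats a \code{stage_stats}.
#' @param min_size minimal module size.
#' @param linkage_cut tree cut height on the 1 - |PCC| scale.
#' @return list of character vectors (possibly empty).
#' @export
candidate_modules <- function(stats, min_size = 5L, linkage_cut = 0.5) {
  d <- 1 - stats$pcc
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  grp <- cutree(hc, h = linkage_cut)
  mods <- split(names(grp), grp)
  mods <- mods[vapply(mods, length, integer(1)) >= min_size]
  mods <- lapply(mods, sort)
  if (length(mods) == 0) return(list())
  ord <- order(-vapply(mods, length, integer(1)),
               vapply(mods, `[`, character(1), 1))
  unname(mods[ord])
}

#' Composite index of a module at one stage
#'
#' \code{sd_in}: mean member SD. \code{pcc_in}: mean |PCC| over the member
#' pairs (undefined pairs excluded from the mean). \code{pcc_out}: mean
#' |PCC| over all member x non-member pairs. The index is
#' \code{ci = sd_in * pcc_in / max(pcc_out, eps)}; the floor \code{eps}
#' prevents blow-up for perfectly decoupled modules. A module whose member
#' pairs are all undefined is rejected.
#'
#' @param stats a \code{stage_stats}.
#' @param members character vector of member protein ids (>= 2, all
#'   retained in \code{stats}).
#' @param eps floor on \code{pcc_out}.
#' @return object of class \code{"dnb_module"}: stage, members, sd_in,
#'   pcc_in, pcc_out, ci.
#' @export
composite_index <- function(stats, members, eps = 0.01) {
  members <- sort(members)
  if (length(members) < 2) stopf("a module needs >= 2 members")
  if (!all(members %in% stats$protein_ids))
    stopf("member(s) not retained at stage %s: %s", stats$stage,
          paste(setdiff(members, stats$protein_ids), collapse = ", "))
  idx <- match(members, rownames(stats$pcc))
  out_idx <- setdiff(seq_len(nrow(stats$pcc)), idx)
  pin <- stats$pcc[idx, idx, drop = FALSE]
  pin_vals <- pin[upper.tri(pin)]
  if (all(is.na(pin_vals)))
    stopf("all member pairs undefined at stage %s; module rejected", stats$stage)
  pcc_in <- mean(pin_vals, na.rm = TRUE)
  pcc_out <- if (length(out_idx) == 0) 0 else
    mean(stats$pcc[idx, out_idx, drop = FALSE], na.rm = TRUE)
  if (is.nan(pcc_out)) pcc_out <- 0   # every outside pair undefined
  sd_in <- mean(stats$sd[idx])
  ci <- sd_in * pcc_in / max(pcc_out, eps)
  structure(list(stage = stats$stage, members = members, sd_in = sd_in,
                 pcc_in = pcc_in, pcc_out = pcc_out, ci = ci),
            class = "dnb_module")
}

# pick the best module among candidates: max ci, ties to the larger module,
# then to the lexicographically smallest member set
best_module <- function(stats, candidates, eps = 0.01) {
  best <- NULL
  for (mem in candidates) {
    mod <- tryCatch(composite_index(stats, mem, eps = eps),
                    error = function(e) NULL)
    if (is.null(mod)) next
    if (is.null(best)) { best <- mod; next }
    if (mod$ci > best$ci ||
        (mod$ci == best$ci && length(mod$members) > length(best$members)) ||
        (mod$ci == best$ci && length(mod$members) == length(best$members) &&
         paste(mod$members, collapse = "|") <
         paste(best$members, collapse = "|"))) {
      best <- mod
    }
  }
  best
}

# per-stage best modules for one compartment; shared by detection and the
# permutation null
stage_ci_curve <- function(mat, design, compartment, min_obs_frac = 0.5,
                           min_pairs = 3L, min_size = 5L, linkage_cut = 0.5,
                           eps = 0.01) {
  stages <- design$stage_order[group_key(design$stage_order, compartment) %in%
                               names(design$groups)]
  modules <- list()
  ci <- setNames(numeric(length(stages)), stages)
  flags <- character(0)
  for (st in stages) {
    stats <- stagewise_stats(mat, design, st, compartment,
                             min_obs_frac = min_obs_frac,
                             min_pairs = min_pairs)
    cands <- candidate_modules(stats, min_size = min_size,
                               linkage_cut = linkage_cut)
    mod <- if (length(cands) > 0) best_module(stats, cands, eps = eps) else NULL
    if (is.null(mod)) {
      ci[st] <- 0
      flags <- c(flags, sprintf("no candidate module of size >= %d at %s",
                                min_size, st))
    } else {
      ci[st] <- mod$ci
      modules[[st]] <- mod
    }
  }
  list(stages = stages, ci_by_stage = ci, modules = modules, flags = flags)
}

#' Detect the tipping stage of an ordered progression
#'
#' For every stage of one compartment: compute within-stage statistics,
#' enumerate candidate modules, score each by the composite index and keep
#' the best (ties resolved to the larger module, then the lexicographically
#' smallest member set). The tipping stage is the stage with the maximal
#' best CI (ties resolved to the earliest stage in the order). Stages
#' without any candidate score CI = 0 and are flagged.
#'
#' @param mat a log2-scale \code{\link{expr_matrix}} (median-normalised).
#' @param design a \code{stage_design} with >= 3 valid stages in the
#'   compartment.
#' @param compartment \code{"L"} or \code{"N"}.
#' @param min_obs_frac,min_pairs per-stage completeness controls
#'   (\code{\link{stagewise_stats}}).
#' @param min_size,linkage_cut module discovery controls
#'   (\code{\link{candidate_modules}}).
#' @param eps CI floor (\code{\link{composite_index}}).
#' @return object of class \code{"dnb_result"}: ci_by_stage, tipping_stage,
#'   dnb_members, modules (per-stage best \code{dnb_module}), flags,
#'   params.
#' @export
detect_tipping_stage <- function(mat, design, compartment = "L",
                                 min_obs_frac = 0.5, min_pairs = 3L,
                                 min_size = 5L, linkage_cut = 0.5,
                                 eps = 0.01) {
  curve <- stage_ci_curve(mat, design, compartment, min_obs_frac, min_pairs,
                          min_size, linkage_cut, eps)
  if (length(curve$stages) < 3)
    stopf("DNB detection needs >= 3 stages with valid groups (found %d)",
          length(curve$stages))
  tip <- curve$stages[which.max(curve$ci_by_stage)]
  members <- if (!is.null(curve$modules[[tip]])) curve$modules[[tip]]$members
             else character(0)
  structure(list(ci_by_stage = curve$ci_by_stage, tipping_stage = tip,
                 dnb_members = members, modules = curve$modules,
                 flags = curve$flags,
                 params = list(compartment = compartment,
                               min_obs_frac = min_obs_frac,
                               min_pairs = min_pairs, min_size = min_size,
                               linkage_cut = linkage_cut, eps = eps)),
            class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf("dnb_result (%s): tipping stage %s, %d members\n",
              x$params$compartment, x$tipping_stage, length(x$dnb_members)))
  print(round(x$ci_by_stage, 3))
  invisible(x)
}

#' Permutation significance of the per-stage CI
#'
#' Null model: shuffle the sample-to-stage assignment within the
#' compartment (group sizes preserved) and recompute each stage's best CI.
#' \code{p(stage) = (1 + #\{null CI >= observed CI\}) / (B + 1)}.
#'
#' @param mat,design,compartment,min_obs_frac,min_pairs,min_size,linkage_cut,eps
#'   as in \code{\link{detect_tipping_stage}}.
#' @param B number of permutations (>= 19).
#' @param seed RNG seed.
#' @return named numeric vector stage -> p-value, with attribute
#'   \code{"observed"} (the observed CI curve).
#' @export
permutation_significance <- function(mat, design, compartment = "L",
                                     min_obs_frac = 0.5, min_pairs = 3L,
                                     min_size = 5L, linkage_cut = 0.5,
                                     eps = 0.01, B = 99L, seed = 1L) {
  if (B < 19) stopf("B must be >= 19")
  obs <- stage_ci_curve(mat, design, compartment, min_obs_frac, min_pairs,
                        min_size, linkage_cut, eps)
  ann <- design$samples
  comp_rows <- which(ann$compartment == compartment)
  exceed <- setNames(integer(length(obs$stages)), obs$stages)
  set.seed(seed)
  for (b in seq_len(B)) {
    perm_ann <- ann
    perm_ann$stage[comp_rows] <- ann$stage[sample(comp_rows)]
    perm_design <- build_stage_design(
      perm_ann[, c("sample_id", "stage", "compartment", "subject_id")],
      design$stage_order, design$min_group_size)
    nullc <- stage_ci_curve(mat, perm_design, compartment, min_obs_frac,
                            min_pairs, min_size, linkage_cut, eps)
    exceed <- exceed + (nullc$ci_by_stage[obs$stages] >=
                        obs$ci_by_stage[obs$stages])
  }
  p <- (1 + exceed) / (B + 1)
  attr(p, "observed") <- obs$ci_by_stage
  p
}
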