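# Synthetic staged two-compartment proteomics generator with planted ground
# truth. The generator defines the study conditions every recovery and
# calibration test runs under: a five-stage progression sampled in lesion (L)
# and adjacent non-lesion (N) compartments with the cohort's group sizes, a
# variance + correlation spike planted at one stage (the DNB signal), four
# trend templates, a discriminative phase panel, a monotone EMT drift, and
# intensity-dependent missingness.

#' Synthetic dataset configuration
#'
#' Defaults emulate a DIA-proteomics biopsy cohort: ~2000 proteins, five
#' ordered stages sampled in L (10/19/11/14/10) and N (8/17/8/10/5)
#' compartments, log2 baseline intensities around 20 with protein-level
#' spread 2, within-group noise SD uniform on [0.5, 1], per-sample loading
#' shifts (SD 0.3 log2 units, removed by median normalisation) and 20%
#' intensity-dependent dropout. Planted signals: a 15-protein module whose
#' noise at the tipping stage is equicorrelated at \code{rho_spike} with SD
#' inflated \code{sd_multiplier}-fold (baseline equicorrelation
#' \code{rho_base} elsewhere); 50 proteins per trend template (up, down,
#' peak_mid, peak_tipping) with amplitude 1 log2 unit; a 7-protein panel
#' shifted +1 log2 unit in post-tipping samples; 10+10 mesenchymal/epithelial
#' proteins drifting +/- 0.15 log2 units per stage rank. All planted sets
#' are disjoint. Planted stage-structured effects are applied in the L
#' compartment (configurable via \code{dnb_compartment} for the module
#' spike); N samples carry baseline, loading and noise only.
#'
#' @param n_proteins total number of proteins.
#' @param stage_order ordered stage vocabulary.
#' @param group_sizes_l,group_sizes_n named integer vectors of per-stage
#'   sample counts for the L and N compartments.
#' @param dnb_size number of proteins in the planted correlated module.
#' @param tipping_stage stage carrying the planted spike (and defining the
#'   pre/post phase split of the truth).
#' @param rho_spike,rho_base within-module noise equicorrelation at the
#'   tipping stage and elsewhere; \code{rho_spike > rho_base}.
#' @param sd_multiplier module noise SD inflation at the tipping stage.
#' @param n_trend_proteins proteins per trend template.
#' @param trend_amplitude template amplitude, log2 units.
#' @param panel_size,panel_shift discriminative panel size and post-phase
#'   shift in log2 units.
#' @param emt_set_sizes integer vector \code{c(epithelial, mesenchymal)}.
#' @param emt_drift log2 drift per stage rank (+ for mesenchymal, - for
#'   epithelial members).
#' @param baseline_mean,baseline_sd protein baseline distribution, log2.
#' @param noise_sd_range range of per-protein noise SDs (uniform).
#' @param sample_median_sd SD of the per-sample loading shift, log2.
#' @param missing_rate expected overall missing fraction in [0, 1).
#' @param missing_steepness steepness of the intensity-dependent dropout
#'   logistic; 0 gives uniform dropout.
#' @param dnb_compartment compartment in which the module spike is planted.
#' @param seed integer RNG seed; the generated triple is a pure function of
#'   the configuration.
#' @return validated configuration list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_proteins = 2000L,
                             stage_order = default_stage_order(),
                             group_sizes_l = c(ESO = 10L, MID = 19L, MOD = 11L,
                                               SED = 14L, ESCC = 10L),
                             group_sizes_n = c(ESO = 8L, MID = 17L, MOD = 8L,
                                               SED = 10L, ESCC = 5L),
                             dnb_size = 15L,
                             tipping_stage = "MID",
                             rho_spike = 0.8,
                             rho_base = 0.1,
                             sd_multiplier = 3,
                             n_trend_proteins = 50L,
                             trend_amplitude = 1.0,
                             panel_size = 7L,
                             panel_shift = 1.0,
                             emt_set_sizes = c(epithelial = 10L, mesenchymal = 10L),
                             emt_drift = 0.15,
                             baseline_mean = 20,
                             baseline_sd = 2,
                             noise_sd_range = c(0.5, 1.0),
                             sample_median_sd = 0.3,
                             missing_rate = 0.2,
                             missing_steepness = 1,
                             dnb_compartment = "L",
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), stage_order = stage_order,
              group_sizes_l = group_sizes_l, group_sizes_n = group_sizes_n,
              dnb_size = as.integer(dnb_size), tipping_stage = tipping_stage,
              rho_spike = rho_spike, rho_base = rho_base,
              sd_multiplier = sd_multiplier,
              n_trend_proteins = as.integer(n_trend_proteins),
              trend_amplitude = trend_amplitude,
              panel_size = as.integer(panel_size), panel_shift = panel_shift,
              emt_set_sizes = emt_set_sizes, emt_drift = emt_drift,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd_range = noise_sd_range,
              sample_median_sd = sample_median_sd,
              missing_rate = missing_rate,
              missing_steepness = missing_steepness,
              dnb_compartment = dnb_compartment, seed = as.integer(seed))
  if (!tipping_stage %in% stage_order) stopf("tipping_stage not in stage_order")
  if (!(rho_spike > rho_base)) stopf("rho_spike must exceed rho_base")
  if (rho_spike < 0 || rho_spike >= 1 || rho_base < 0 || rho_base >= 1)
    stopf("equicorrelations must lie in [0, 1)")
  if (sd_multiplier <= 0) stopf("sd_multiplier must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  if (!all(names(cfg$group_sizes_l) %in% stage_order) ||
      !all(names(cfg$group_sizes_n) %in% stage_order))
    stopf("group size names must be stage labels")
  if (any(c(cfg$group_sizes_l, cfg$group_sizes_n) < 2))
    stopf("every sampled group needs >= 2 samples")
  n_planted <- cfg$dnb_size + cfg$panel_size + 4L * cfg$n_trend_proteins +
    sum(cfg$emt_set_sizes)
  if (n_planted > cfg$n_proteins)
    stopf("planted sets (%d proteins) exceed n_proteins (%d)",
          n_planted, cfg$n_proteins)
  structure(cfg, class = "synthetic_config")
}

# fixed trend template shapes over stage ranks, scaled by trend_amplitude
trend_templates <- function(n_stages, tipping_rank) {
  up <- seq(0, 1, length.out = n_stages)
  mid <- (n_stages + 1) / 2
  peak_mid <- 1 - abs(seq_len(n_stages) - mid) / (mid - 1)
  peak_tip <- as.numeric(seq_len(n_stages) == (tipping_rank + 1))
  list(up = up, down = rev(up), peak_mid = peak_mid, peak_tipping = peak_tip)
}

#' Generate a staged two-compartment dataset with planted truth
#'
#' Per sample j of stage s, protein p:
#' \deqn{x_{pj} = b_p + t_p(s) + panel/EMT shifts + m_j + e_{pj}}
#' with protein baseline \eqn{b_p ~ N(\mu_b, \sigma_b^2)}, trend template
#' value \eqn{t_p(s)}, panel shift for post-phase samples, EMT drift
#' \eqn{\pm\gamma\,rank(s)}, per-sample loading \eqn{m_j ~ N(0, \tau^2)} and
#' noise \eqn{e_{pj} = \sigma_p(\sqrt{\rho} z_j + \sqrt{1-\rho} w_{pj})} for
#' module members (shared factor \eqn{z_j}; \eqn{\rho = \rho^*} and SD scaled
#' by \eqn{\kappa} at the tipping stage, \eqn{\rho_0} and scale 1 elsewhere)
#' and \eqn{e_{pj} = \sigma_p w_{pj}} otherwise. Intensity-dependent
#' missingness is injected last via \code{\link{inject_missingness}}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{matrix} (log2-scale \code{\link{expr_matrix}}),
#'   \code{annotations} (data.frame sample_id/stage/compartment), and
#'   \code{truth}: tipping_stage, dnb_members, panel_members,
#'   trend_assignment (named vector with levels up/down/peak_mid/
#'   peak_tipping/null), phase_label per sample (pre/post), emt_sets.
#' @export
generate_staged_dataset <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  P <- cfg$n_proteins
  stages <- cfg$stage_order
  tip_rank <- match(cfg$tipping_stage, stages) - 1L

  proteins <- sprintf("P%04d", seq_len(P))
  idx <- 0L
  take <- function(n) {
    out <- proteins[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  dnb_ids <- take(cfg$dnb_size)
  panel_ids <- take(cfg$panel_size)
  tmpl_names <- c("up", "down", "peak_mid", "peak_tipping")
  trend_ids <- lapply(tmpl_names, function(t) take(cfg$n_trend_proteins))
  names(trend_ids) <- tmpl_names
  epi_ids <- take(cfg$emt_set_sizes[[1]])
  mes_ids <- take(cfg$emt_set_sizes[[2]])

  trend_assignment <- setNames(rep("null", P), proteins)
  for (t in tmpl_names) trend_assignment[trend_ids[[t]]] <- t

  # sample sheet, deterministic order: L stages then N stages
  ann <- do.call(rbind, lapply(c("L", "N"), function(comp) {
    sizes <- if (comp == "L") cfg$group_sizes_l else cfg$group_sizes_n
    do.call(rbind, lapply(stages[stages %in% names(sizes)], function(st) {
      n <- sizes[[st]]
      data.frame(sample_id = sprintf("%s_%s_%02d", comp, st, seq_len(n)),
                 stage = st, compartment = comp,
                 subject_id = NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }))
  ann <- validate_annotations(ann, stages)
  n_samples <- nrow(ann)
  ranks <- ann$stage_rank
  phase <- ifelse(ranks <= tip_rank, "pre", "post")

  b <- rnorm(P, cfg$baseline_mean, cfg$baseline_sd)
  sigma <- runif(P, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
  m <- rnorm(n_samples, 0, cfg$sample_median_sd)

  tmpl <- trend_templates(length(stages), tip_rank)
  # per-protein per-stage mean offsets (L compartment only)
  t_mat <- matrix(0, P, length(stages), dimnames = list(proteins, stages))
  for (t in tmpl_names)
    t_mat[trend_ids[[t]], ] <- matrix(tmpl[[t]] * cfg$trend_amplitude,
                                      nrow = cfg$n_trend_proteins,
                                      ncol = length(stages), byrow = TRUE)

  X <- matrix(0, P, n_samples, dimnames = list(proteins, ann$sample_id))
  dnb_idx <- match(dnb_ids, proteins)
  for (j in seq_len(n_samples)) {
    st_rank <- ranks[j]
    in_l <- ann$compartment[j] == "L"
    mu <- b + m[j]
    if (in_l) {
      mu <- mu + t_mat[, st_rank + 1L]
      if (phase[j] == "post") mu[panel_ids] <- mu[panel_ids] + cfg$panel_shift
      mu[mes_ids] <- mu[mes_ids] + cfg$emt_drift * st_rank
      mu[epi_ids] <- mu[epi_ids] - cfg$emt_drift * st_rank
    }
    e <- sigma * rnorm(P)
    spike <- ann$compartment[j] == cfg$dnb_compartment && st_rank == tip_rank
    rho <- if (spike) cfg$rho_spike else cfg$rho_base
    kap <- if (spike) cfg$sd_multiplier else 1
    z <- rnorm(1)
    w <- rnorm(length(dnb_idx))
    e[dnb_idx] <- kap * sigma[dnb_idx] * (sqrt(rho) * z + sqrt(1 - rho) * w)
    X[, j] <- mu + e
  }

  mat <- expr_matrix(X, scale = "log2")
  if (cfg$missing_rate > 0)
    mat <- inject_missingness(mat, cfg$missing_rate, cfg$missing_steepness,
                              seed = derive_seed(cfg$seed, 104729L))

  truth <- list(tipping_stage = cfg$tipping_stage,
                dnb_members = dnb_ids,
                panel_members = panel_ids,
                trend_assignment = trend_assignment,
                phase_label = setNames(phase, ann$sample_id),
                emt_sets = list(epithelial = epi_ids, mesenchymal = mes_ids))
  list(matrix = mat, annotations = ann, truth = truth, config = cfg)
}

#' Inject intensity-dependent missingness
#'
#' Each cell is set missing independently with probability
#' \eqn{f \cdot logistic(-steepness (x - q))}, \eqn{q} the global median,
#' with \eqn{f} chosen so the expected overall missing fraction equals
#' \code{missing_rate}. \code{steepness = 0} gives uniform dropout;
#' positive steepness removes low intensities preferentially, emulating
#' DIA detection limits.
#'
#' @param mat a log2-scale \code{\link{expr_matrix}}.
#' @param missing_rate expected overall missing fraction in [0, 1).
#' @param steepness logistic steepness (per log2 unit), >= 0.
#' @param seed RNG seed.
#' @return \code{expr_matrix} with injected NAs.
#' @export
inject_missingness <- function(mat, missing_rate, steepness = 1, seed = 1L) {
  if (missing_rate >= 1 || missing_rate < 0) stopf("missing_rate must lie in [0, 1)")
  if (missing_rate == 0) return(mat)
  x <- unclass(mat)
  q <- median(x, na.rm = TRUE)
  p0 <- plogis(-steepness * (x - q))
  f <- missing_rate / mean(p0, na.rm = TRUE)
  p <- pmin(1, f * p0)
  set.seed(seed)
  drop <- matrix(runif(length(x)) < p, nrow(x), ncol(x))
  x[drop] <- NA_real_
  expr_matrix(x, scale = expr_scale(mat))
}

#' Write a synthetic dataset to disk
#'
#' Emits \code{expression.tsv}, \code{annotation.tsv} and \code{truth.json}
#' into \code{dir}.
#'
#' @param dataset result of \code{\link{generate_staged_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(dataset$matrix, paths[["expression"]])
  ann <- dataset$annotations
  write.table(ann[, c("sample_id", "stage", "compartment", "subject_id")],
              paths[["annotation"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
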