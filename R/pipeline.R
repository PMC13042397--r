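# End-to-end orchestration: load or simulate a staged dataset, preprocess,
# detect the tipping stage (DNB), split phases, run differential expression
# pre vs post, trend clustering, EMT scoring, panel selection and
# ligand-receptor crosstalk, writing TSV outputs and a deterministic
# report.json. A run is a pure function of its configuration.

#' Default pipeline configuration
#'
#' Returns the full configuration list; any element can be overridden via
#' \code{...} (nested lists are replaced wholesale). With
#' \code{input = NULL} the pipeline simulates a dataset from
#' \code{synthetic} (a list of \code{\link{synthetic_config}} overrides);
#' otherwise \code{input} must name \code{expression} and
#' \code{annotation} TSV paths and the declared \code{scale}.
#'
#' @param ... overrides.
#' @return configuration list of class \code{"run_config"}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stage_order = default_stage_order(),
    compartment = "L",
    input = NULL,                       # list(expression=, annotation=, scale=)
    synthetic = list(),                 # overrides for synthetic_config()
    min_frac = 0.5,                     # completeness filter
    de = list(alpha = 0.05, fc_hi = 1.20, fc_lo = 0.83, alpha_norm = 0.05,
              min_n = 3L),
    cluster = list(c = 4L, m = 1.25, restarts = 5L, max_iter = 200L,
                   tol = 1e-6, membership_threshold = 0.5),
    dnb = list(min_obs_frac = 0.5, min_pairs = 3L, min_size = 5L,
               linkage_cut = 0.5, eps = 0.01, permutations = 0L),
    tipping_override = NULL,            # stage label, bypasses the DNB call
    emt = list(gmt = NULL),             # GMT path; synthetic truth if NULL
    panel = list(k = 7L, s_max = 20L, k_folds = 5L, repeats = 1L,
                 drop_frac = 0.1, cost = 1, min_obs_frac = 0.8,
                 benchmark = FALSE),
    crosstalk = list(stage = "MOD", min_detect_frac = 0.5, top_n = 50L,
                     pairs = NULL,      # TSV path; random synthetic pairs if NULL
                     n_synthetic_pairs = 100L),
    output_dir = tempfile("dnbpipe_run_"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the \code{\link{pipeline_config}}
#'   fields.
#' @return \code{run_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full staged-proteomics pipeline
#'
#' Stages run in dependency order: simulate/load, log2 transform (raw
#' input), median normalisation, completeness filter, DNB tipping-stage
#' detection (optionally permutation-tested), phase split at the tipping
#' stage, differential expression post vs pre, trend clustering, EMT
#' scoring with phase comparison, SVM-RFE panel selection with the phase
#' labels, and ligand-receptor crosstalk at the configured stage. All
#' tabular outputs and \code{report.json} are written under
#' \code{config$output_dir}; the run is deterministic given the
#' configuration.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the report list, invisibly; side effect: files under
#'   \code{config$output_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  truth <- NULL
  if (is.null(cfg$input)) {
    syn_args <- cfg$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- cfg$seed
    if (is.null(syn_args$stage_order)) syn_args$stage_order <- cfg$stage_order
    syn <- do.call(synthetic_config, syn_args)
    ds <- generate_staged_dataset(syn)
    mat <- ds$matrix; ann <- ds$annotations; truth <- ds$truth
  } else {
    mat <- read_expression_matrix(cfg$input$expression,
                                  scale = cfg$input$scale %||% "log2")
    ann <- read_sample_annotation(cfg$input$annotation, cfg$stage_order)
  }
  if (expr_scale(mat) == "raw") mat <- log2_transform(mat)
  design <- build_stage_design(ann, cfg$stage_order)
  for (w in design$warnings) note(w)
  mat <- median_normalize(mat)
  mat <- filter_by_completeness(mat, design, cfg$min_frac)

  ## --- DNB tipping stage -------------------------------------------------
  dnb <- do.call(detect_tipping_stage,
                 c(list(mat = mat, design = design,
                        compartment = cfg$compartment),
                   cfg$dnb[c("min_obs_frac", "min_pairs", "min_size",
                             "linkage_cut", "eps")]))
  for (fl in dnb$flags) note(fl)
  perm_p <- NULL
  if ((cfg$dnb$permutations %||% 0L) >= 19L) {
    perm_p <- do.call(permutation_significance,
                      c(list(mat = mat, design = design,
                             compartment = cfg$compartment,
                             B = cfg$dnb$permutations,
                             seed = derive_seed(cfg$seed, 17L)),
                        cfg$dnb[c("min_obs_frac", "min_pairs", "min_size",
                                  "linkage_cut", "eps")]))
  }
  tipping <- cfg$tipping_override %||% dnb$tipping_stage
  phases <- withCallingHandlers(
    split_phases(cfg$stage_order, tipping),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  ## --- differential expression post vs pre --------------------------------
  pre_ids <- design_samples(design, cfg$compartment, phases$pre)
  post_ids <- design_samples(design, cfg$compartment, phases$post)
  de <- NULL
  if (length(post_ids) > 0) {
    de <- do.call(de_table, c(list(mat = mat, samples_a = post_ids,
                                   samples_b = pre_ids), cfg$de))
    write.table(de, file.path(cfg$output_dir, "de_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(attr(de, "skipped"),
                file.path(cfg$output_dir, "de_skipped.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else note("post phase empty; differential expression skipped")

  ## --- trend clustering ----------------------------------------------------
  prof <- stage_mean_profiles(mat, design, cfg$compartment)
  profz <- standardize_profiles(prof)
  fcm <- fuzzy_cmeans(profz, c = cfg$cluster$c, m = cfg$cluster$m,
                      seed = derive_seed(cfg$seed, 23L),
                      max_iter = cfg$cluster$max_iter, tol = cfg$cluster$tol,
                      restarts = cfg$cluster$restarts)
  cores <- core_members(fcm, cfg$cluster$membership_threshold)
  memb <- data.frame(protein_id = rownames(fcm$membership),
                     cluster = hard_assignment(fcm),
                     round(fcm$membership, 6), check.names = FALSE)
  colnames(memb) <- c("protein_id", "cluster",
                      paste0("m", seq_len(fcm$c)))
  write.table(memb, file.path(cfg$output_dir, "cluster_membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cluster = seq_len(fcm$c), round(fcm$centers, 6),
                         check.names = FALSE),
              file.path(cfg$output_dir, "cluster_centers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## --- EMT scoring ---------------------------------------------------------
  emt <- NULL
  emt_sets <- NULL
  if (!is.null(cfg$emt$gmt)) {
    sets <- read_gmt(cfg$emt$gmt)
    if (!all(c("epithelial", "mesenchymal") %in% names(sets)))
      stopf("EMT GMT must contain sets 'epithelial' and 'mesenchymal'")
    emt_sets <- sets[c("epithelial", "mesenchymal")]
  } else if (!is.null(truth)) {
    emt_sets <- truth$emt_sets
  }
  if (!is.null(emt_sets)) {
    scores <- signature_score(mat, emt_sets$mesenchymal, emt_sets$epithelial)
    write.table(scores, file.path(cfg$output_dir, "emt_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emt_cmp <- if (length(phases$post) > 0)
      compare_phase_scores(scores, phases, design, cfg$compartment,
                           alpha = cfg$de$alpha,
                           alpha_norm = cfg$de$alpha_norm) else NULL
    emt <- list(comparison = emt_cmp,
                coverage = as.list(attr(scores, "coverage")))
  } else note("no EMT sets available; EMT scoring skipped")

  ## --- panel ---------------------------------------------------------------
  panel <- NULL
  benchmark <- NULL
  if (length(post_ids) > 0) {
    ids <- c(pre_ids, post_ids)
    xf <- panel_feature_matrix(mat, ids, cfg$panel$min_obs_frac)
    labels <- ids %in% post_ids
    if (isTRUE(cfg$panel$benchmark)) {
      benchmark <- benchmark_learners(xf, labels,
                                      k_folds = cfg$panel$k_folds,
                                      repeats = max(cfg$panel$repeats, 1L),
                                      seed = derive_seed(cfg$seed, 29L))
      write.table(benchmark,
                  file.path(cfg$output_dir, "learner_benchmark.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    panel <- select_panel(xf, labels, rule = "fixed_k", k = cfg$panel$k,
                          s_max = min(cfg$panel$s_max, ncol(xf)),
                          k_folds = cfg$panel$k_folds,
                          repeats = cfg$panel$repeats,
                          seed = derive_seed(cfg$seed, 31L),
                          drop_frac = cfg$panel$drop_frac,
                          cost = cfg$panel$cost)
    write.table(data.frame(rank = seq_along(panel$ranked_features),
                           protein_id = panel$ranked_features),
                file.path(cfg$output_dir, "panel_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(panel$cv_auc_by_size,
                file.path(cfg$output_dir, "panel_auc_by_size.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else note("post phase empty; panel selection skipped")

  ## --- crosstalk -----------------------------------------------------------
  xtalk <- NULL
  ct_stage <- cfg$crosstalk$stage
  has_n <- any(design$samples$compartment == "N" &
               design$samples$stage == ct_stage)
  has_l <- any(design$samples$compartment == "L" &
               design$samples$stage == ct_stage)
  if (has_n && has_l) {
    pairs <- if (!is.null(cfg$crosstalk$pairs)) {
      read_lr_pairs(cfg$crosstalk$pairs)
    } else {
      # synthetic pair table drawn from the protein universe
      set.seed(derive_seed(cfg$seed, 37L))
      data.frame(ligand = sample(rownames(mat), cfg$crosstalk$n_synthetic_pairs,
                                 replace = TRUE),
                 receptor = sample(rownames(mat), cfg$crosstalk$n_synthetic_pairs,
                                   replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    expr_l <- expressed_proteins(mat, design, "L", ct_stage,
                                 cfg$crosstalk$min_detect_frac)
    expr_n <- expressed_proteins(mat, design, "N", ct_stage,
                                 cfg$crosstalk$min_detect_frac)
    xtalk <- score_lr_pairs(expr_l, expr_n, pairs, cfg$crosstalk$top_n)
    write.table(xtalk, file.path(cfg$output_dir, "crosstalk_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else note(sprintf("stage %s missing in a compartment; crosstalk skipped",
                      ct_stage))

  ## --- report --------------------------------------------------------------
  de_counts <- if (is.null(de)) NULL else
    list(up = sum(de$call == "up"), down = sum(de$call == "down"),
         ns = sum(de$call == "ns"), skipped = nrow(attr(de, "skipped")))
  outputs <- list.files(cfg$output_dir)
  outputs <- sort(setdiff(outputs, "report.json"))
  report <- list(
    package = "dnbpipe",
    tipping_stage = tipping,
    tipping_source = if (is.null(cfg$tipping_override)) "dnb" else "override",
    ci_by_stage = as.list(round(dnb$ci_by_stage, 10)),
    dnb_members = dnb$dnb_members,
    permutation_p = if (is.null(perm_p)) NULL else as.list(perm_p),
    phases = list(pre = phases$pre, post = phases$post),
    de_counts = de_counts,
    cluster_sizes = if (is.null(fcm)) NULL else
      as.list(table(factor(hard_assignment(fcm), levels = seq_len(fcm$c)))),
    emt = emt,
    panel = if (is.null(panel)) NULL else
      list(selected = panel$selected_panel,
           cv_auc = round(panel$final_auc, 10)),
    benchmark = if (is.null(benchmark)) NULL else
      lapply(seq_len(nrow(benchmark)), function(i)
        list(learner = benchmark$learner[i],
             mean_auc = round(benchmark$mean_auc[i], 10))),
    crosstalk_edges = if (is.null(xtalk)) NULL else nrow(xtalk),
    outputs = outputs,
    warnings = warnings_log,
    config = cfg[setdiff(names(cfg), "output_dir")])
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, file.path(cfg$output_dir, "report.json"))
  invisible(report)
}
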