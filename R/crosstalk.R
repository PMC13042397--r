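# Ligand-receptor crosstalk ranking between the lesion and non-lesion
# compartments at one stage. The score is a rank product: within each
# compartment's expressed set, mean expressions are ranked and rescaled to
# (0, 1]; an edge's score is the product of the ligand's rank in the source
# compartment and the receptor's rank in the target compartment. Rank-based
# scoring makes edges invariant to any monotone transform of intensities.
# This is an "iTALK-style" ranking device, not a port of that tool.

#' Expressed proteins of one (stage, compartment) group
#'
#' A protein counts as expressed when observed in at least
#' \code{min_detect_frac} of the group's samples; its mean over non-missing
#' values is attached.
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @param design a \code{stage_design}.
#' @param compartment \code{"L"} or \code{"N"}.
#' @param stage stage label.
#' @param min_detect_frac detection fraction threshold.
#' @return data.frame(protein_id, mean_expr, detect_frac) restricted to
#'   expressed proteins.
#' @export
expressed_proteins <- function(mat, design, compartment, stage,
                               min_detect_frac = 0.5) {
  key <- group_key(stage, compartment)
  ids <- intersect(design$groups[[key]] %||% character(0), colnames(mat))
  if (length(ids) == 0) stopf("no samples in group %s", key)
  x <- unclass(mat)[, ids, drop = FALSE]
  frac <- rowMeans(!is.na(x))
  keep <- frac >= min_detect_frac
  data.frame(protein_id = rownames(mat)[keep],
             mean_expr = rowMeans(x[keep, , drop = FALSE], na.rm = TRUE),
             detect_frac = frac[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

# expression ranks rescaled to (0, 1]; highest mean -> 1
rescaled_ranks <- function(expr_df) {
  r <- rank(expr_df$mean_expr, ties.method = "average")
  setNames(r / nrow(expr_df), expr_df$protein_id)
}

#' Score ligand-receptor pairs between two compartments
#'
#' Evaluates both directions. An edge source -> target exists when the
#' ligand is expressed in the source compartment and the receptor in the
#' target compartment; its score is the product of the two rescaled
#' within-compartment expression ranks. Edges are sorted by descending
#' score, ties broken lexicographically by ligand then receptor, and the
#' top \code{top_n} per direction are kept.
#'
#' @param expr_l,expr_n expressed-protein tables
#'   (\code{\link{expressed_proteins}}) for the L and N compartments.
#' @param pair_table data.frame with columns ligand, receptor.
#' @param top_n edges kept per direction.
#' @return data.frame(ligand, receptor, direction, score, ligand_mean,
#'   receptor_mean), directions \code{"L->N"} and \code{"N->L"}.
#' @export
score_lr_pairs <- function(expr_l, expr_n, pair_table, top_n = 50L) {
  if (nrow(pair_table) == 0) stopf("pair table is empty")
  rl <- rescaled_ranks(expr_l)
  rn <- rescaled_ranks(expr_n)
  ml <- setNames(expr_l$mean_expr, expr_l$protein_id)
  mn <- setNames(expr_n$mean_expr, expr_n$protein_id)
  one_direction <- function(r_src, r_tgt, m_src, m_tgt, label) {
    ok <- pair_table$ligand %in% names(r_src) &
      pair_table$receptor %in% names(r_tgt)
    pt <- pair_table[ok, , drop = FALSE]
    if (nrow(pt) == 0)
      return(data.frame(ligand = character(0), receptor = character(0),
                        direction = character(0), score = numeric(0),
                        ligand_mean = numeric(0), receptor_mean = numeric(0)))
    out <- data.frame(ligand = pt$ligand, receptor = pt$receptor,
                      direction = label,
                      score = unname(r_src[pt$ligand] * r_tgt[pt$receptor]),
                      ligand_mean = unname(m_src[pt$ligand]),
                      receptor_mean = unname(m_tgt[pt$receptor]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$ligand, out$receptor), , drop = FALSE]
    head(out, top_n)
  }
  res <- rbind(one_direction(rl, rn, ml, mn, "L->N"),
               one_direction(rn, rl, mn, ml, "N->L"))
  rownames(res) <- NULL
  res
}
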