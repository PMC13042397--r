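# Set-based per-sample scoring, primarily the EMT score: the mean of the
# measured mesenchymal set minus the mean of the measured epithelial set,
# per sample, in log2-intensity difference units. Missing members are
# dropped per sample (never imputed) and set coverage is reported.

#' Per-sample signature score (mesenchymal minus epithelial)
#'
#' For each sample, the mean over non-missing mesenchymal-set values minus
#' the mean over non-missing epithelial-set values. A sample in which either
#' set is entirely missing receives NA with a reason.
#'
#' @param mat a log2-scale \code{\link{expr_matrix}}.
#' @param mes_set,epi_set character vectors of protein ids; each must
#'   intersect the matrix rows.
#' @return data.frame(sample_id, score, n_mes, n_epi, reason) with
#'   attribute \code{"coverage"} = c(mesenchymal, epithelial) fractions of
#'   each set present among matrix rows.
#' @export
signature_score <- function(mat, mes_set, epi_set) {
  mes_in <- intersect(mes_set, rownames(mat))
  epi_in <- intersect(epi_set, rownames(mat))
  if (length(mes_in) == 0)
    stopf("no mesenchymal-set protein in matrix; missing: %s",
          paste(mes_set, collapse = ", "))
  if (length(epi_in) == 0)
    stopf("no epithelial-set protein in matrix; missing: %s",
          paste(epi_set, collapse = ", "))
  M <- unclass(mat)[mes_in, , drop = FALSE]
  E <- unclass(mat)[epi_in, , drop = FALSE]
  n_mes <- colSums(!is.na(M))
  n_epi <- colSums(!is.na(E))
  score <- colMeans(M, na.rm = TRUE) - colMeans(E, na.rm = TRUE)
  reason <- rep(NA_character_, ncol(mat))
  bad <- n_mes == 0 | n_epi == 0
  score[bad] <- NA_real_
  reason[bad] <- "a signature set is fully missing in this sample"
  out <- data.frame(sample_id = colnames(mat), score = score,
                    n_mes = n_mes, n_epi = n_epi, reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "coverage") <- c(mesenchymal = length(mes_in) / length(unique(mes_set)),
                             epithelial = length(epi_in) / length(unique(epi_set)))
  out
}

#' Compare signature scores between pre and post phases
#'
#' Groups scored samples of one compartment by phase and reuses the
#' normality-gated two-sample machinery of \code{\link{test_protein}} on
#' the score vectors.
#'
#' @param scores data.frame from \code{\link{signature_score}}.
#' @param phase_split a \code{\link{split_phases}} result.
#' @param design a \code{stage_design}.
#' @param compartment \code{"L"} or \code{"N"}.
#' @param alpha,alpha_norm significance levels.
#' @return list: mean_pre, mean_post, difference (post - pre), p_value,
#'   test, n_pre, n_post, call.
#' @export
compare_phase_scores <- function(scores, phase_split, design,
                                 compartment = "L", alpha = 0.05,
                                 alpha_norm = 0.05) {
  pre_ids <- design_samples(design, compartment, phase_split$pre)
  post_ids <- design_samples(design, compartment, phase_split$post)
  s <- setNames(scores$score, scores$sample_id)
  pre <- s[intersect(pre_ids, names(s))]; pre <- pre[!is.na(pre)]
  post <- s[intersect(post_ids, names(s))]; post <- post[!is.na(post)]
  if (length(pre) < 3 || length(post) < 3)
    stopf("phase comparison needs >= 3 scored samples per phase (%d vs %d)",
          length(pre), length(post))
  rec <- test_protein(post, pre, alpha = alpha, alpha_norm = alpha_norm)
  list(mean_pre = mean(pre), mean_post = mean(post),
       difference = mean(post) - mean(pre), p_value = rec$p_value,
       test = rec$test, n_pre = length(pre), n_post = length(post),
       call = if (rec$p_value < alpha) "significant" else "ns")
}
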