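# Expression-matrix and annotation I/O, plus the preprocessing steps applied
# before any stage-wise analysis: median normalisation, log2 transform and
# completeness filtering. The substrate everywhere is a plain numeric matrix
# (proteins in rows, samples in columns) carrying a "scale" attribute, in the
# style of limma's expression-matrix interface.

#' Construct an expression matrix
#'
#' Wraps a numeric matrix of protein intensities (proteins in rows, samples
#' in columns) and records whether the values are raw intensities or log2
#' intensities. Missing values are allowed and are never imputed by this
#' package's preprocessing; downstream operations declare their own
#' pairwise-complete or complete-case policies.
#'
#' @param values numeric matrix with unique non-empty rownames (protein ids)
#'   and colnames (sample ids).
#' @param scale one of \code{"raw"} (strictly positive intensities) or
#'   \code{"log2"}.
#' @return the matrix with class \code{"expr_matrix"} and a \code{scale}
#'   attribute.
#' @export
expr_matrix <- function(values, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  rn <- rownames(values); cn <- colnames(values)
  if (is.null(rn) || is.null(cn) || any(rn == "") || any(cn == ""))
    stopf("expression matrix needs non-empty protein and sample ids")
  if (anyDuplicated(rn))
    stopf("duplicate protein id(s): %s",
          paste(unique(rn[duplicated(rn)]), collapse = ", "))
  if (anyDuplicated(cn))
    stopf("duplicate sample id(s): %s",
          paste(unique(cn[duplicated(cn)]), collapse = ", "))
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stopf("raw-scale intensities must be > 0 where present")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d proteins x %d samples (%s scale), %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "scale"),
              100 * mean(is.na(x))))
  invisible(x)
}

# preserve attributes through subsetting
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expr_matrix", class(unclass(out))))
  out
}

expr_scale <- function(x) attr(x, "scale") %||% "log2"

#' Read a tab-separated expression matrix
#'
#' Expects a header row whose first field is \code{protein_id} (or any label)
#' followed by sample ids; one protein per row. Empty cells, \code{"NA"} and
#' \code{"NaN"} parse as missing.
#'
#' @param path TSV file path.
#' @param scale declared scale of the stored values (\code{"log2"} or
#'   \code{"raw"}).
#' @return an \code{\link{expr_matrix}}.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", "NaN", ""))
  if (ncol(df) < 2) stopf("expression TSV needs a protein id column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate protein id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-numeric cell at protein '%s', sample '%s' (value '%s')",
          ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]], vals[bad[1, , drop = FALSE]])
  dimnames(num) <- list(ids, colnames(df)[-1])
  expr_matrix(num, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Deterministic layout: header \code{protein_id} then sample ids in matrix
#' column order; missing values written as \code{NA}. Round-trips losslessly
#' through \code{\link{read_expression_matrix}} (values printed at full
#' precision).
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @param path output file path.
#' @export
write_expression_matrix <- function(mat, path) {
  ch <- matrix(sprintf("%.17g", unclass(mat)), nrow(mat), ncol(mat))
  ch[is.na(unclass(mat))] <- NA_character_
  df <- data.frame(protein_id = rownames(mat), ch,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("protein_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read sample annotations
#'
#' TSV with columns \code{sample_id}, \code{stage}, \code{compartment}
#' (\code{L} = lesion, \code{N} = adjacent non-lesion) and optionally
#' \code{subject_id}. Every stage label must belong to \code{stage_order}.
#'
#' @param path TSV file path.
#' @param stage_order ordered stage vocabulary (lowest rank first).
#' @return data.frame with columns sample_id, stage (factor ordered by
#'   \code{stage_order}), compartment, subject_id (NA when absent), and
#'   \code{stage_rank} (0-based).
#' @export
read_sample_annotation <- function(path, stage_order = default_stage_order()) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  need <- c("sample_id", "stage", "compartment")
  if (!all(need %in% colnames(df)))
    stopf("annotation TSV must have columns %s", paste(need, collapse = ", "))
  if (!"subject_id" %in% colnames(df)) df$subject_id <- NA_character_
  validate_annotations(df, stage_order)
}

#' Validate a sample annotation table
#'
#' @param df data.frame with sample_id, stage, compartment and optional
#'   subject_id columns.
#' @param stage_order ordered stage vocabulary.
#' @return validated annotation data.frame with an added 0-based
#'   \code{stage_rank} column.
#' @export
validate_annotations <- function(df, stage_order = default_stage_order()) {
  if (nrow(df) == 0) stopf("annotation table is empty")
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id(s): %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyDuplicated(stage_order)) stopf("stage_order must be a strict total order")
  bad <- setdiff(unique(df$stage), stage_order)
  if (length(bad) > 0)
    stopf("unknown stage label(s): %s (vocabulary: %s)",
          paste(bad, collapse = ", "), paste(stage_order, collapse = " < "))
  if (!all(df$compartment %in% c("L", "N")))
    stopf("compartment must be 'L' or 'N'")
  if (!"subject_id" %in% colnames(df)) df$subject_id <- NA_character_
  df$stage <- factor(df$stage, levels = stage_order)
  df$stage_rank <- as.integer(df$stage) - 1L
  rownames(df) <- NULL
  df[, c("sample_id", "stage", "compartment", "subject_id", "stage_rank")]
}

#' Build a stage design
#'
#' Groups samples by (stage, compartment). Groups smaller than
#' \code{min_group_size} are retained but flagged in the \code{warnings}
#' field, never silently dropped.
#'
#' @param annotations validated annotation data.frame
#'   (\code{\link{validate_annotations}}).
#' @param stage_order ordered stage vocabulary.
#' @param min_group_size minimum group size used by analyses (>= 2).
#' @return object of class \code{"stage_design"}: list with
#'   \code{stage_order}, \code{samples}, \code{groups} (named
#'   \code{"STAGE.COMPARTMENT"} -> sample ids), \code{min_group_size},
#'   \code{warnings}.
#' @export
build_stage_design <- function(annotations, stage_order = default_stage_order(),
                               min_group_size = 2L) {
  ann <- validate_annotations(annotations, stage_order)
  groups <- list()
  warnings <- character(0)
  for (comp in c("L", "N")) {
    for (st in stage_order) {
      ids <- ann$sample_id[ann$stage == st & ann$compartment == comp]
      if (length(ids) == 0) next
      key <- group_key(st, comp)
      groups[[key]] <- ids
      if (length(ids) < min_group_size)
        warnings <- c(warnings, sprintf(
          "group %s has %d sample(s), below min_group_size %d",
          key, length(ids), min_group_size))
    }
  }
  structure(list(stage_order = stage_order, samples = ann, groups = groups,
                 min_group_size = as.integer(min_group_size),
                 warnings = warnings),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf("stage_design: %d samples, stages %s\n",
              nrow(x$samples), paste(x$stage_order, collapse = " < ")))
  sizes <- vapply(x$groups, length, integer(1))
  print(sizes)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Sample ids of selected (stage, compartment) groups
#'
#' @param design a \code{stage_design}.
#' @param compartment \code{"L"} or \code{"N"}.
#' @param stages stage labels to include (default: all).
#' @return character vector of sample ids, in design order.
#' @export
design_samples <- function(design, compartment, stages = design$stage_order) {
  keys <- group_key(stages, compartment)
  unlist(design$groups[intersect(keys, names(design$groups))], use.names = FALSE)
}

#' Median-normalise sample columns
#'
#' Each sample column is shifted (log2 scale) or rescaled (raw scale) so that
#' its median over non-missing values equals the global median of the
#' pre-normalisation column medians. The target keeps values on the
#' interpretable intensity scale instead of centring at zero; the missingness
#' pattern is unchanged and the operation is idempotent.
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @return normalised \code{expr_matrix}.
#' @export
median_normalize <- function(mat) {
  meds <- apply(unclass(mat), 2, median, na.rm = TRUE)
  if (any(is.na(meds)))
    stopf("sample(s) with all values missing: %s",
          paste(colnames(mat)[is.na(meds)], collapse = ", "))
  target <- median(meds)
  out <- unclass(mat)
  if (expr_scale(mat) == "log2") {
    out <- sweep(out, 2, meds - target, `-`)
  } else {
    out <- sweep(out, 2, target / meds, `*`)
  }
  expr_matrix(out, scale = expr_scale(mat))
}

#' Log2-transform a raw-intensity matrix
#'
#' @param mat a raw-scale \code{\link{expr_matrix}} with all present values
#'   strictly positive.
#' @return log2-scale \code{expr_matrix}; missing entries preserved.
#' @export
log2_transform <- function(mat) {
  if (expr_scale(mat) != "raw")
    stopf("matrix is already on the log2 scale")
  if (any(unclass(mat) <= 0, na.rm = TRUE))
    stopf("log2 transform requires strictly positive intensities")
  expr_matrix(log2(unclass(mat)), scale = "log2")
}

#' Filter proteins by per-group completeness
#'
#' Retains a protein when it is observed (non-missing) in at least
#' \code{min_frac} of the samples of at least one (stage, compartment)
#' group. Row order of retained proteins is preserved.
#'
#' @param mat an \code{\link{expr_matrix}}.
#' @param design a \code{stage_design} whose groups cover the matrix columns.
#' @param min_frac required observed fraction in some group, in [0, 1].
#' @return filtered \code{expr_matrix}.
#' @export
filter_by_completeness <- function(mat, design, min_frac = 0.5) {
  if (!is.numeric(min_frac) || min_frac < 0 || min_frac > 1)
    stopf("min_frac must lie in [0, 1]")
  keep <- rep(FALSE, nrow(mat))
  for (ids in design$groups) {
    ids <- intersect(ids, colnames(mat))
    if (length(ids) == 0) next
    frac <- rowMeans(!is.na(unclass(mat)[, ids, drop = FALSE]))
    keep <- keep | (frac >= min_frac)
  }
  mat[keep, , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields set name,
#' description, then member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: '%s'", substr(ln, 1, 60))
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns \code{ligand} and \code{receptor} (extra annotation
#' columns are carried through).
#'
#' @param path TSV file path.
#' @return data.frame with at least ligand and receptor columns.
#' @export
read_lr_pairs <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!all(c("ligand", "receptor") %in% colnames(df)))
    stopf("pair table must have 'ligand' and 'receptor' columns")
  if (nrow(df) == 0) stopf("pair table is empty")
  df
}
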