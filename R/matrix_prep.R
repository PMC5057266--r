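# From raw per-array expression to the analysis-ready log-ratio matrix:
# replicate averaging, log-ratio computation against matched controls, and
# gene filtering.

#' Average replicate arrays into per-condition columns
#'
#' @param mat numeric matrix, genes x arrays, with dimnames.
#' @param replicate_map named character vector: array ID -> condition ID;
#'   every column of `mat` must be mapped.
#' @return genes x conditions matrix of per-condition arithmetic means;
#'   condition columns appear in first-occurrence order of the map.
#' @export
average_replicates <- function(mat, replicate_map) {
  assert_log_ratio_matrix(mat)
  unmapped <- setdiff(colnames(mat), names(replicate_map))
  if (length(unmapped))
    stop("array not in replicate_map: ", unmapped[1])
  cond <- as.character(replicate_map[colnames(mat)])
  cond_ids <- unique(cond)
  out <- vapply(cond_ids, function(cid)
    rowMeans(mat[, cond == cid, drop = FALSE]),
    numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), cond_ids)
  out
}

#' Compute log2 ratios of treatments against matched controls
#'
#' @param treatment genes x treatment-conditions matrix.
#' @param control genes x control-conditions matrix (same genes).
#' @param pairing named character vector: treatment condition -> control
#'   condition.
#' @param values_are_log2 if TRUE the inputs are already log2 intensities and
#'   the ratio is a subtraction; if FALSE raw intensities are required to be
#'   strictly positive and log2(treatment/control) is taken.
#' @return log-ratio matrix over the treatment conditions.
#' @export
compute_log_ratios <- function(treatment, control, pairing,
                               values_are_log2 = TRUE) {
  assert_log_ratio_matrix(treatment, "treatment")
  assert_log_ratio_matrix(control, "control")
  stopifnot(identical(rownames(treatment), rownames(control)))
  missing_pair <- setdiff(colnames(treatment), names(pairing))
  if (length(missing_pair))
    stop("treatment condition without a paired control: ", missing_pair[1])
  ctrl_ids <- as.character(pairing[colnames(treatment)])
  bad_ctrl <- setdiff(ctrl_ids, colnames(control))
  if (length(bad_ctrl)) stop("paired control not found: ", bad_ctrl[1])
  ctrl <- control[, ctrl_ids, drop = FALSE]
  if (values_are_log2) {
    out <- treatment - ctrl
  } else {
    nonpos <- which(treatment <= 0 | ctrl <= 0, arr.ind = TRUE)
    if (nrow(nonpos))
      stop(sprintf("nonpositive intensity at gene %s, condition %s",
                   rownames(treatment)[nonpos[1, 1]],
                   colnames(treatment)[nonpos[1, 2]]))
    out <- log2(treatment) - log2(ctrl)
  }
  colnames(out) <- colnames(treatment)
  out
}

#' Filter genes by row variance and an optional keep list
#'
#' Retains genes whose variance across conditions exceeds `min_variance`
#' (strictly), intersected with `keep_list` when supplied (the stand-in for
#' annotation-based filtering). Row order is preserved.
#'
#' @param mat log-ratio matrix.
#' @param min_variance variance cutoff, >= 0; the default 0 drops only
#'   constant rows.
#' @param keep_list optional character vector of gene IDs to retain.
#' @return the filtered matrix.
#' @export
filter_genes <- function(mat, min_variance = 0, keep_list = NULL) {
  assert_log_ratio_matrix(mat)
  stopifnot(min_variance >= 0)
  keep <- apply(mat, 1, stats::var) > min_variance
  if (!is.null(keep_list)) keep <- keep & rownames(mat) %in% keep_list
  if (!any(keep)) stop("filter_genes removed every gene")
  mat[keep, , drop = FALSE]
}

#' Subset conditions by a metadata predicate
#'
#' Generic metadata filter (field, operator, value) applied before analysis,
#' e.g. restricting to exposures longer than one day.
#'
#' @param mat log-ratio matrix.
#' @param conditions condition metadata data.frame with a `condition_id`
#'   column.
#' @param field metadata column name.
#' @param op one of `">"`, `">="`, `"<"`, `"<="`, `"=="`, `"!="`, `"%in%"`.
#' @param value comparison value.
#' @return the matrix restricted to conditions satisfying the predicate.
#' @export
filter_conditions <- function(mat, conditions, field, op, value) {
  assert_log_ratio_matrix(mat)
  stopifnot(field %in% names(conditions))
  f <- match.fun(op)
  keep_ids <- conditions$condition_id[f(conditions[[field]], value)]
  keep <- colnames(mat) %in% keep_ids
  if (!any(keep)) stop("filter_conditions removed every condition")
  mat[, keep, drop = FALSE]
}
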