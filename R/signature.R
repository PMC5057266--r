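# Random-forest injury signature: train on a candidate gene set, rank genes
# by permutation importance (mean decrease in accuracy), select a fixed-size
# signature, and evaluate with OOB votes, confusion counts and ROC/AUC.

#' Assemble a training set
#'
#' @param mat log-ratio matrix (genes x conditions).
#' @param labels named character vector over conditions with values
#'   "positive" (nephrotoxic) / "negative"; every labelled condition must
#'   have a column in `mat`.
#' @return a `TrainingSet`: `x` (conditions x genes feature matrix) and `y`
#'   (factor with levels negative, positive).
#' @export
training_set <- function(mat, labels) {
  assert_log_ratio_matrix(mat)
  labels <- labels[!is.na(labels)]
  missing_cond <- setdiff(names(labels), colnames(mat))
  if (length(missing_cond))
    stop("labelled condition without a feature column: ", missing_cond[1])
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the labels")
  x <- t(mat[, names(labels), drop = FALSE])
  y <- factor(unname(labels), levels = c("negative", "positive"))
  structure(list(x = x, y = y), class = "TrainingSet")
}

#' Train a random forest on a gene subset
#'
#' Fits a classification forest (default 1,001 trees, per-split feature
#' sample floor(sqrt(p)), unlimited depth, bootstrap with replacement) and
#' reports permutation importance (mean decrease in accuracy) and the
#' out-of-bag error estimate.
#'
#' @param train a [training_set()].
#' @param feature_subset genes to train on; default all features.
#' @param n_trees ensemble size, default 1001.
#' @param rng_seed integer RNG seed; fixed seed gives identical fits.
#' @return a `SignatureModel`: `forest` (randomForest fit), `genes`,
#'   `importance` (data.frame gene, mean_decrease_accuracy, sorted),
#'   `oob_error` (fraction), `n_trees`, `rng_seed`.
#' @export
train_forest <- function(train, feature_subset = NULL, n_trees = 1001,
                         rng_seed = 1) {
  stopifnot(inherits(train, "TrainingSet"))
  if (nlevels(droplevels(train$y)) < 2L)
    stop("both classes must be present in the labels")
  genes <- feature_subset %||% colnames(train$x)
  missing_g <- setdiff(genes, colnames(train$x))
  if (length(missing_g)) stop("gene absent from features: ", missing_g[1])
  if (length(genes) == 0L) stop("feature_subset must be non-empty")
  x <- train$x[, genes, drop = FALSE]
  fit <- with_seed(rng_seed,
    randomForest::randomForest(x = x, y = train$y, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)
  imp_df <- data.frame(gene = rownames(imp),
                       mean_decrease_accuracy = as.vector(imp),
                       stringsAsFactors = FALSE)
  # ties broken by gene ID for reproducibility
  imp_df <- imp_df[order(-imp_df$mean_decrease_accuracy, imp_df$gene), ]
  rownames(imp_df) <- NULL
  oob <- mean(fit$predicted != train$y)
  structure(list(forest = fit, genes = genes, importance = imp_df,
                 oob_error = oob, n_trees = n_trees, rng_seed = rng_seed),
            class = "SignatureModel")
}

#' Select the top-k signature genes by importance
#'
#' @param model a `SignatureModel` (or its importance data.frame).
#' @param k signature size, default 30.
#' @return character vector of k genes, importance-ranked, gene-ID
#'   tie-broken.
#' @export
select_signature <- function(model, k = 30) {
  imp <- if (inherits(model, "SignatureModel")) model$importance else model
  if (k > nrow(imp))
    stop("k exceeds the number of ranked features (", nrow(imp), ")")
  imp$gene[seq_len(k)]
}

# Empirical ROC from scores: sweep every distinct score as a threshold and
# take AUC by the trapezoidal rule over (FPR, TPR).
roc_points <- function(scores, y) {
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  pos <- y == "positive"
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

#' Evaluate a signature model
#'
#' Computes confusion counts at the vote threshold, sensitivity,
#' specificity, accuracy, the ROC curve swept over vote fractions and AUC by
#' the trapezoidal rule. Scores default to out-of-bag vote fractions on the
#' training set (unbiased); resubstitution votes or an external labelled
#' set can be used instead.
#'
#' @param model a `SignatureModel`.
#' @param data a [training_set()]; when it is the training set itself and
#'   `mode = "oob"`, OOB votes are used.
#' @param vote_threshold positive-class call threshold, default 0.5.
#' @param mode "oob" (default) or "resubstitution"; ignored for data
#'   disjoint from training (always predicted).
#' @return a `PerformanceReport`: sensitivity, specificity, accuracy, auc,
#'   confusion (TP, FP, TN, FN), roc (data.frame), scores.
#' @export
evaluate_signature <- function(model, data, vote_threshold = 0.5,
                               mode = c("oob", "resubstitution")) {
  stopifnot(inherits(model, "SignatureModel"),
            inherits(data, "TrainingSet"))
  mode <- match.arg(mode)
  if (anyNA(data$y)) stop("unlabelled sample in evaluation data")
  x <- data$x[, model$genes, drop = FALSE]
  if (mode == "oob" &&
      identical(rownames(x), rownames(model$forest$votes))) {
    votes <- model$forest$votes[, "positive"]
  } else {
    votes <- stats::predict(model$forest, newdata = x,
                            type = "vote")[, "positive"]
  }
  y <- data$y
  call_pos <- votes >= vote_threshold
  tp <- sum(call_pos & y == "positive")
  fn <- sum(!call_pos & y == "positive")
  tn <- sum(!call_pos & y == "negative")
  fp <- sum(call_pos & y == "negative")
  roc <- roc_points(votes, y)
  structure(list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(y),
    auc = trapezoid_auc(roc$fpr, roc$tpr),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    roc = roc, scores = votes
  ), class = "PerformanceReport")
}

#' Single-gene comparator model
#'
#' The same forest pipeline restricted to one gene, for benchmarking the
#' multi-gene signature against individual marker genes.
#'
#' @param train a [training_set()].
#' @param gene gene identifier present in the features.
#' @param n_trees,rng_seed as in [train_forest()].
#' @return list with `model` (a `SignatureModel`) and `performance` (a
#'   `PerformanceReport` on OOB votes).
#' @export
single_gene_model <- function(train, gene, n_trees = 1001, rng_seed = 1) {
  if (!gene %in% colnames(train$x))
    stop("gene absent from features: ", gene)
  model <- train_forest(train, feature_subset = gene, n_trees = n_trees,
                        rng_seed = rng_seed)
  list(model = model, performance = evaluate_signature(model, train))
}
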