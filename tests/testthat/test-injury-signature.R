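# Random-forest injury signature: a 14-vs-30 design with a handful of
# class-informative genes planted among noise features.

signature_data <- function(n_genes = 100, n_informative = 1, effect = 3,
                           seed = 1) {
  n_pos <- 14; n_neg <- 30
  conds <- paste0("c", seq_len(n_pos + n_neg))
  labels <- stats::setNames(rep(c("positive", "negative"), c(n_pos, n_neg)),
                            conds)
  mat <- with(list(), {
    set.seed(seed)
    m <- matrix(stats::rnorm(n_genes * (n_pos + n_neg)), nrow = n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), conds))
    m[seq_len(n_informative), seq_len(n_pos)] <-
      m[seq_len(n_informative), seq_len(n_pos)] + effect
    m
  })
  list(train = training_set(mat, labels), labels = labels)
}

test_that("training_set validates labels and features", {
  sd1 <- signature_data()
  expect_identical(dim(sd1$train$x), c(44L, 100L))
  expect_identical(levels(sd1$train$y), c("negative", "positive"))
  m <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(training_set(m, c(c1 = "positive", c9 = "negative")),
               "without a feature column")
  expect_error(training_set(m, c(c1 = "positive", c2 = "positive")),
               "both classes")
})

test_that("a planted separating gene tops the importance ranking and the
           fit is seed-deterministic", {
  sd1 <- signature_data(seed = 11)
  fit <- train_forest(sd1$train, n_trees = 501, rng_seed = 3)
  expect_identical(fit$importance$gene[1], "g1")
  fit2 <- train_forest(sd1$train, n_trees = 501, rng_seed = 3)
  expect_identical(fit$oob_error, fit2$oob_error)
  expect_identical(fit$importance, fit2$importance)
  expect_error(train_forest(sd1$train, feature_subset = "g999"),
               "absent from features")
})

test_that("permuted labels give OOB error near the majority-class baseline", {
  sd1 <- signature_data(seed = 21)
  set.seed(5)
  null_labels <- stats::setNames(sample(sd1$labels), names(sd1$labels))
  null_train <- training_set(
    t(sd1$train$x), null_labels)
  fit <- train_forest(null_train, n_trees = 501, rng_seed = 7)
  # the forest cannot beat always-negative (14/44 error) by much;
  # 3 SE of a binomial proportion at n = 44
  baseline <- 14 / 44
  expect_gt(fit$oob_error, baseline - 3 * sqrt(baseline * (1 - baseline) / 44))
})

test_that("select_signature is top-k with gene-ID tie-breaking", {
  imp <- data.frame(gene = c("gB", "gA", "gC"),
                    mean_decrease_accuracy = c(0.5, 0.5, 0.1))
  imp <- imp[order(-imp$mean_decrease_accuracy, imp$gene), ]
  expect_identical(select_signature(imp, 1), "gA")
  expect_identical(select_signature(imp, 3), c("gA", "gB", "gC"))
  expect_error(select_signature(imp, 4), "exceeds")
  sd1 <- signature_data(seed = 11)
  fit <- train_forest(sd1$train, n_trees = 501, rng_seed = 3)
  expect_identical(select_signature(fit, 1), "g1")
  expect_length(select_signature(fit, 30), 30)
})

test_that("evaluate_signature reports a confusion-consistent performance
           summary", {
  sd1 <- signature_data(seed = 31)
  fit <- train_forest(sd1$train, feature_subset = paste0("g", 1:10),
                      n_trees = 501, rng_seed = 9)
  perf <- evaluate_signature(fit, sd1$train)
  cm <- perf$confusion
  expect_equal(perf$sensitivity, cm["TP"] / (cm["TP"] + cm["FN"]),
               ignore_attr = TRUE)
  expect_equal(perf$specificity, cm["TN"] / (cm["TN"] + cm["FP"]),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 44)
  expect_true(perf$auc >= 0 && perf$auc <= 1)
  # a perfectly separating gene gives perfect resubstitution calls
  perf_res <- evaluate_signature(fit, sd1$train, mode = "resubstitution")
  expect_equal(perf_res$sensitivity, 1)
  expect_equal(perf_res$specificity, 1)
  expect_equal(perf_res$auc, 1)
})

test_that("the trapezoidal AUC equals the pairwise-concordance oracle", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    y <- factor(sample(c("negative", "positive"), n, replace = TRUE,
                       prob = c(0.6, 0.4)),
                levels = c("negative", "positive"))
    if (length(unique(y)) < 2) next
    scores <- round(stats::runif(n), sample(c(1, 2, 3), 1)) # force ties too
    roc <- toxmodmine:::roc_points(scores, y)
    auc <- toxmodmine:::trapezoid_auc(roc$fpr, roc$tpr)
    expect_equal(auc, oracle_auc(scores, y), tolerance = 1e-9)
  }
  # and against an established ROC implementation on one vector
  set.seed(56)
  y <- factor(rep(c("negative", "positive"), each = 25),
              levels = c("negative", "positive"))
  scores <- stats::runif(50) + 0.4 * (y == "positive")
  roc <- toxmodmine:::roc_points(scores, y)
  expect_equal(toxmodmine:::trapezoid_auc(roc$fpr, roc$tpr),
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-9)
})

test_that("label-independent votes give AUC near 0.5", {
  set.seed(66)
  n <- 400
  y <- factor(rep(c("negative", "positive"), each = n / 2),
              levels = c("negative", "positive"))
  scores <- stats::runif(n)
  roc <- toxmodmine:::roc_points(scores, y)
  auc <- toxmodmine:::trapezoid_auc(roc$fpr, roc$tpr)
  # SE of AUC under the null ~ sqrt((nP+nN+1)/(12 nP nN))
  se <- sqrt((n + 1) / (12 * (n / 2)^2))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("single_gene_model equals train_forest restricted to one gene", {
  sd1 <- signature_data(seed = 41)
  sg <- single_gene_model(sd1$train, "g1", n_trees = 301, rng_seed = 13)
  direct <- train_forest(sd1$train, feature_subset = "g1", n_trees = 301,
                         rng_seed = 13)
  expect_identical(sg$model$oob_error, direct$oob_error)
  expect_identical(sg$model$genes, "g1")
  # planted separator: near-perfect; a pure-noise gene: near-chance AUC
  expect_gt(sg$performance$auc, 0.9)
  noise <- single_gene_model(sd1$train, "g50", n_trees = 301, rng_seed = 13)
  expect_lt(abs(noise$performance$auc - 0.5), 0.35)
  expect_error(single_gene_model(sd1$train, "g999"), "absent")
})
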