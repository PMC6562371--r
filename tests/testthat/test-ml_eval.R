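test_that("classification metrics match their defining formulas", {
  truth <- rep(c("increased", "decreased"), c(6, 6))
  pred <- c(rep("increased", 5), "decreased",
            rep("decreased", 4), "increased", "increased")
  m <- classification_metrics(truth, pred)
  expect_equal(m$tp, 5); expect_equal(m$fn, 1)
  expect_equal(m$tn, 4); expect_equal(m$fp, 2)
  expect_equal(m$se, 5 / 6)
  expect_equal(m$sp, 4 / 6)
  expect_equal(m$ppv, 5 / 7)
  expect_equal(m$bar, (5 / 6 + 4 / 6) / 2)
  expect_equal(m$mcc, (5 * 4 - 2 * 1) / sqrt(7 * 6 * 6 * 5))

  perfect <- classification_metrics(truth, truth,
                                    probabilities = as.numeric(truth == "increased"))
  expect_equal(unlist(perfect[c("se", "sp", "ppv", "bar", "mcc", "auc")]),
               setNames(rep(1, 6), c("se", "sp", "ppv", "bar", "mcc", "auc")))

  # zero denominators give NA, not 0
  allneg <- classification_metrics(rep("decreased", 4),
                                   rep("decreased", 4))
  expect_true(is.na(allneg$se))
  expect_true(is.na(allneg$ppv))
})

test_that("AUC equals exhaustive pair counting and matches pROC", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  score <- c(0.9, 0.4, 0.4, 0.2, 0.1)
  expect_equal(tessmut:::auc_rank(truth, score),
               pair_count_auc(truth, score))
  set.seed(31)
  for (i in 1:5) {
    tr <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(tr)) < 2) next
    sc <- round(runif(30), 2)  # force some ties
    expect_equal(tessmut:::auc_rank(tr, sc), pair_count_auc(tr, sc))
    expect_equal(tessmut:::auc_rank(tr, sc),
                 as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("regression metrics behave on exact, inverted and toy data", {
  y <- c(1.2, -0.3, 0.8, 2.2)
  expect_equal(regression_metrics(y, y), list(r = 1, rmse = 0))
  expect_equal(regression_metrics(y, -y)$r, -1)
  p <- c(1.0, 0.1, 0.6, 1.9)
  m <- regression_metrics(y, p)
  expect_equal(m$r, sum((y - mean(y)) * (p - mean(p))) /
                 sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2)))
  expect_equal(m$rmse, sqrt(mean((y - p)^2)))
  expect_true(is.na(regression_metrics(y, rep(1, 4))$r))
})

test_that("thresholded regression reuses the classification machinery", {
  set.seed(41)
  y <- rnorm(40)
  p <- y + rnorm(40, sd = 0.5)
  m <- thresholded_classification(y, p)
  cm <- classification_metrics(ifelse(y > median(y), "increased", "decreased"),
                               ifelse(p > median(y), "increased", "decreased"),
                               probabilities = p)
  expect_equal(m[c("se", "sp", "bar", "mcc", "auc")],
               cm[c("se", "sp", "bar", "mcc", "auc")])
})

test_that("the random forest learns a separable toy set deterministically", {
  set.seed(51)
  x <- data.frame(a = c(rnorm(30, -3), rnorm(30, 3)), b = rnorm(60),
                  g = sample(c("u", "v"), 60, TRUE))
  y <- factor(rep(c("decreased", "increased"), each = 30))
  m <- train_rf_classifier(x, y, seed = 9)
  pr <- predict(m, x)
  tm <- classification_metrics(y, pr$class, pr$prob)
  expect_equal(tm$bar, 1)
  # determinism under a fixed seed
  m2 <- train_rf_classifier(x, y, seed = 9)
  expect_equal(predict(m2, x)$prob, pr$prob)
  expect_error(train_rf_classifier(x, factor(rep("increased", 60))),
               "both fitness classes")
})

test_that("bagged pruned trees recover a noiseless linear relation", {
  set.seed(61)
  x <- data.frame(a = runif(120, -2, 2))
  y <- 3 * x$a + 1
  rep_cv <- cross_validate(bagged_tree_spec(selection = FALSE), x, y,
                           scheme = "kfold", k = 10, seed = 5)
  expect_gt(rep_cv$metrics$r, 0.95)
  # ensemble prediction is the mean of the per-tree predictions
  m <- train_bagged_regression_trees(x, y, seed = 5, selection = FALSE)
  newx <- data.frame(a = c(-1.5, 0, 1.5))
  enc <- tessmut:::one_hot(newx, template = m$all_columns)
  per_tree <- sapply(m$trees, function(tr)
    predict(tr, as.data.frame(enc[, m$columns, drop = FALSE])))
  expect_equal(unname(predict(m, newx)), unname(rowMeans(per_tree)))
  expect_error(train_bagged_regression_trees(x, rep(1, 120)), "constant")
})

test_that("CFS keeps the informative feature and maximizes the merit", {
  set.seed(71)
  n <- 150
  x <- cbind(signal = rnorm(n), matrix(rnorm(n * 9), n,
                                       dimnames = list(NULL, paste0("noise", 1:9))))
  y <- x[, "signal"] + rnorm(n, sd = 0.2)
  sel <- cfs_select(x, y)
  expect_true("signal" %in% sel)
  expect_false(length(sel) > 3)
  # brute-force merit over all 2^10 - 1 subsets using the same correlations
  xd <- apply(x, 2, tessmut:::discretize_ef, bins = 10)
  yd <- tessmut:::discretize_ef(y, 10)
  r_cf <- vapply(1:10, function(j)
    tessmut:::symmetrical_uncertainty(xd[, j], yd), numeric(1))
  r_ff <- diag(1, 10)
  for (i in 1:9) for (j in (i + 1):10)
    r_ff[i, j] <- r_ff[j, i] <-
      tessmut:::symmetrical_uncertainty(xd[, i], xd[, j])
  best <- -Inf; best_set <- NULL
  for (mask in 1:(2^10 - 1)) {
    ss <- which(bitwAnd(mask, 2^(0:9)) > 0)
    mer <- tessmut:::cfs_merit(ss, r_cf, r_ff)
    if (mer > best) { best <- mer; best_set <- ss }
  }
  expect_setequal(match(sel, colnames(x)), best_set)
})

test_that("cross-validation predicts every variant exactly once", {
  set.seed(81)
  x <- data.frame(a = rnorm(45), b = rnorm(45))
  y <- factor(ifelse(x$a > 0, "increased", "decreased"))
  rep_k <- cross_validate(rf_spec(n_trees = 10), x, y, k = 10, seed = 3)
  expect_equal(sort(unique(rep_k$fold)), 1:10)
  expect_lte(diff(range(table(rep_k$fold))), 1)
  expect_false(anyNA(rep_k$pred))
  rep_loo <- cross_validate(rf_spec(n_trees = 10), x, y, scheme = "loo",
                            seed = 3)
  expect_equal(rep_loo$k, 45)
  expect_true(all(table(rep_loo$fold) == 1))
  expect_error(cross_validate(rf_spec(), x, y, k = 100, seed = 1), "exceeds")
})

test_that("shuffle controls attain the permutation p-value lower bound", {
  set.seed(91)
  x <- data.frame(a = c(rnorm(25, -4), rnorm(25, 4)))
  y <- factor(rep(c("decreased", "increased"), each = 25))
  ctrl <- shuffle_control(rf_spec(n_trees = 10), x, y, n_permutations = 9,
                          k = 5, seed = 2)
  expect_equal(unname(ctrl$p_value["bar"]), 1 / 10)
  expect_equal(nrow(ctrl$permuted), 9)
  expect_gt(ctrl$observed["bar"], max(ctrl$permuted[, "bar"]))
})

test_that("the learning curve at full size reproduces the full-data CV", {
  set.seed(101)
  x <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- factor(ifelse(x$a + rnorm(60, sd = 0.4) > 0, "increased", "decreased"))
  lc <- learning_curve(rf_spec(n_trees = 10), x, y, sizes = c(30, 60),
                       reps = 1, k = 5, seed = 4)
  full <- cross_validate(rf_spec(n_trees = 10), x, y, k = 5,
                         seed = 4 + 37 * 60 + 1)
  expect_equal(lc$mean[lc$size == 60 & lc$metric == "bar"],
               full$metrics$bar)
  expect_true(all(lc$sd[!is.na(lc$sd)] >= 0 | is.na(lc$sd)))
  expect_error(learning_curve(rf_spec(), x, y, sizes = 100, seed = 1),
               "exceed")
})

test_that("extreme tails are balanced, disjoint and ordered", {
  idx <- extreme_subset(1:10, 2)
  expect_setequal(idx, c(1, 2, 9, 10))
  set.seed(111)
  v <- rnorm(200)
  idx <- extreme_subset(v, 50)
  expect_length(idx, 100)
  expect_length(unique(idx), 100)
  expect_true(max(v[idx[1:50]]) < min(v[idx[51:100]]))
  expect_error(extreme_subset(v, 101), "overlap")
})

test_that("stratified performance partitions and reproduces global metrics", {
  set.seed(121)
  x <- data.frame(a = rnorm(80))
  y <- factor(ifelse(x$a + rnorm(80, sd = 0.6) > 0, "increased", "decreased"))
  rep_k <- cross_validate(rf_spec(n_trees = 10), x, y, k = 5, seed = 6)
  one <- stratified_performance(rep_k, rep("all", 80))
  expect_equal(one$bar, rep_k$metrics$bar)
  expect_equal(one$pct, 100)
  strata <- sample(c("s1", "s2", "s3"), 80, replace = TRUE)
  st <- stratified_performance(rep_k, strata)
  expect_equal(sum(st$pct), 100, tolerance = 1e-9)
  single <- stratified_performance(rep_k, ifelse(y == "increased" & seq_len(80) < 5,
                                                 "tiny", "rest"))
  expect_true(single$single_class[single$stratum == "tiny"])
  expect_true(is.na(single$bar[single$stratum == "tiny"]))
})

test_that("the chi-square statistic matches direct O/E evaluation", {
  prop <- matrix(c(20, 40, 10, 20), 2)  # perfectly proportional
  expect_equal(chi_square_independence(prop)$statistic, 0, tolerance = 1e-12)
  set.seed(131)
  tab <- matrix(rpois(12, 30) + 1, 4, 3)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, brute_force_chisq(tab), tolerance = 1e-9)
  expect_equal(res$df, 6)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 3), 2)),
               "marginal")
})

test_that("the two-sample t-test matches a hand computation", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_lt(two_sample_t(rnorm(20), rnorm(20) + 10)$p_value, 1e-6)
  x <- c(1.1, 2.0, 2.9); y <- c(5.2, 6.1, 7.3)
  res <- two_sample_t(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(res$statistic, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$df, df, tolerance = 1e-9)
  pooled <- two_sample_t(x, y, pooled = TRUE)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  expect_equal(pooled$statistic,
               (mean(x) - mean(y)) / (sp * sqrt(2 / 3)), tolerance = 1e-12)
})
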