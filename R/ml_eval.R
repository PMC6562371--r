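## Model training, cross-validation, metrics, permutation controls and
## stratified reporting for variant-fitness prediction.

# ---- one-hot encoding (nominal-to-binary) -----------------------------------

# Expand character/factor columns into 0/1 indicator columns; numeric columns
# pass through. `template` fixes the column set so test rows encode into the
# training design (unseen levels become all-zero rows for that attribute).
one_hot <- function(df, template = NULL) {
  df <- as.data.frame(df)
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      for (lv in sort(unique(v)))
        cols[[paste0(nm, ".", lv)]] <- as.numeric(v == lv)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  if (!is.null(template)) {
    out <- matrix(0, nrow(x), length(template),
                  dimnames = list(NULL, template))
    shared <- intersect(colnames(x), template)
    out[, shared] <- x[, shared, drop = FALSE]
    return(out)
  }
  x
}

# ---- model specifications ---------------------------------------------------

#' Model specifications for fitness prediction
#'
#' `rf_spec()` describes a random-forest classifier (default 50 trees,
#' `floor(sqrt(p))` candidate attributes per split); `bagged_tree_spec()`
#' describes an ensemble of reduced-error-pruned regression trees grown on
#' bootstrap resamples (default 10 bags, predictions averaged), optionally
#' preceded by correlation-based feature-subset selection.
#'
#' @param n_trees,n_bags Ensemble size.
#' @param mtry Attributes sampled per split (`NULL` = `floor(sqrt(p))`).
#' @param selection Apply CFS feature selection before training.
#' @return A `tessmut_model_spec` list with a `task` field (`classify` or
#'   `regress`).
#' @export
rf_spec <- function(n_trees = 50, mtry = NULL) {
  base::structure(list(task = "classify", n_trees = n_trees, mtry = mtry),
                  class = "tessmut_model_spec")
}

#' @rdname rf_spec
#' @export
bagged_tree_spec <- function(n_bags = 10, selection = TRUE) {
  base::structure(list(task = "regress", n_bags = n_bags,
                       selection = selection),
                  class = "tessmut_model_spec")
}

#' Train a random-forest fitness classifier
#'
#' Categorical attributes are one-hot encoded, then a random forest is
#' grown; class probabilities are tree-vote fractions.
#'
#' @param features Data frame of input attributes (numeric and categorical).
#' @param labels Two-level factor of fitness classes.
#' @param n_trees Number of trees (default 50).
#' @param seed Integer seed; fixes the forest exactly.
#' @param mtry Attributes per split (`NULL` = `floor(sqrt(p))`).
#' @return A `rf_fitness_classifier`; use [predict()] to get a data frame
#'   with `class` and `prob` (probability of the positive/second level).
#' @export
train_rf_classifier <- function(features, labels, n_trees = 50, seed = 1,
                                mtry = NULL) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stop("need both fitness classes present to train a classifier")
  x <- one_hot(features)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  dat <- as.data.frame(x)
  dat$.y <- labels
  forest <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                           num.trees = n_trees, mtry = mtry,
                           num.threads = 1, seed = seed)
  base::structure(list(forest = forest, columns = colnames(x),
                       levels = levels(labels), seed = seed),
                  class = "rf_fitness_classifier")
}

#' @export
predict.rf_fitness_classifier <- function(object, newdata, ...) {
  x <- one_hot(newdata, template = object$columns)
  # class probability = fraction of tree votes for the positive class
  pt <- predict(object$forest, as.data.frame(x), predict.all = TRUE,
                num.threads = 1)$predictions
  if (is.null(dim(pt))) pt <- matrix(pt, nrow = nrow(x))
  pos_code <- which(object$forest$forest$levels == object$levels[2])
  prob <- rowMeans(pt == pos_code)
  cls <- factor(ifelse(prob > 0.5, object$levels[2], object$levels[1]),
                levels = object$levels)
  data.frame(class = cls, prob = unname(prob))
}

# grow + reduced-error prune one regression tree on a bootstrap resample:
# the resample is split into a growing part and a pruning holdout, the
# cost-complexity path is evaluated on the holdout, and the subtree with the
# smallest holdout squared error is kept
rep_tree <- function(data, grow_frac = 2 / 3) {
  n <- nrow(data)
  grow_idx <- sample.int(n, size = max(2L, floor(grow_frac * n)))
  grow <- data[grow_idx, , drop = FALSE]
  prune_set <- data[-grow_idx, , drop = FALSE]
  fit <- rpart::rpart(.y ~ ., data = grow, method = "anova",
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 10))
  if (nrow(prune_set) >= 2L && nrow(fit$cptable) > 1L) {
    cps <- sqrt(fit$cptable[, "CP"] *
                  c(fit$cptable[-1, "CP"], fit$cptable[nrow(fit$cptable), "CP"]))
    err <- vapply(cps, function(cp) {
      pr <- rpart::prune(fit, cp = cp)
      mean((predict(pr, prune_set) - prune_set$.y)^2)
    }, numeric(1))
    fit <- rpart::prune(fit, cp = cps[which.min(err)])
  }
  fit
}

#' Train bagged reduced-error-pruned regression trees
#'
#' Grows `n_bags` regression trees on bootstrap resamples of the data, each
#' reduced-error pruned against an internal holdout; the ensemble prediction
#' is the mean of the per-tree predictions. When `selection` is on,
#' correlation-based feature-subset selection (CFS with best-first search)
#' reduces the one-hot-encoded attributes first.
#'
#' @param features Data frame of input attributes.
#' @param y Numeric output attribute (must not be constant).
#' @param n_bags Number of bootstrap trees (default 10).
#' @param seed Integer seed.
#' @param selection Apply CFS feature selection (default `TRUE`).
#' @return A `bagged_tree_regressor`; [predict()] returns the averaged
#'   numeric prediction.
#' @export
train_bagged_regression_trees <- function(features, y, n_bags = 10, seed = 1,
                                          selection = TRUE) {
  if (!is.numeric(y)) stop("y must be numeric for regression")
  if (length(unique(y)) == 1L) stop("constant output attribute")
  x <- one_hot(features)
  set.seed(seed)
  keep <- colnames(x)
  if (isTRUE(selection)) {
    sel <- cfs_select(x, y)
    if (length(sel)) keep <- sel
  }
  x <- x[, keep, drop = FALSE]
  dat <- as.data.frame(x)
  dat$.y <- y
  trees <- lapply(seq_len(n_bags), function(b) {
    boot <- dat[sample.int(nrow(dat), replace = TRUE), , drop = FALSE]
    rep_tree(boot)
  })
  base::structure(list(trees = trees, columns = keep,
                       all_columns = colnames(one_hot(features)),
                       seed = seed),
                  class = "bagged_tree_regressor")
}

#' @export
predict.bagged_tree_regressor <- function(object, newdata, ...) {
  x <- one_hot(newdata, template = object$all_columns)
  dat <- as.data.frame(x[, object$columns, drop = FALSE])
  preds <- vapply(object$trees, function(tr) predict(tr, dat),
                  numeric(nrow(dat)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

# ---- CFS feature selection --------------------------------------------------

# symmetrical uncertainty between two discretized vectors:
# SU = 2 I(X;Y) / (H(X) + H(Y)), in [0, 1]
symmetrical_uncertainty <- function(x, y) {
  tab <- table(x, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- ent(px); hy <- ent(py)
  if (hx + hy == 0) return(0)
  hxy <- ent(as.vector(pxy))
  mi <- hx + hy - hxy
  2 * mi / (hx + hy)
}

discretize_ef <- function(v, bins = 10) {
  u <- unique(v)
  if (length(u) <= bins) return(match(v, sort(u)))
  qs <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  cut(v, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

# CFS merit of a feature subset given feature-class and feature-feature
# correlations: k * mean(r_cf) / sqrt(k + k (k-1) mean(r_ff))
cfs_merit <- function(subset, r_cf, r_ff) {
  k <- length(subset)
  if (!k) return(0)
  rcf <- mean(r_cf[subset])
  rff <- if (k > 1) mean(r_ff[subset, subset][upper.tri(diag(k))]) else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature-subset selection (CFS)
#'
#' Searches for the attribute subset maximizing the merit
#' `k * mean(r_cf) / sqrt(k + k(k-1) * mean(r_ff))`, where `r_cf` are
#' feature-class and `r_ff` feature-feature symmetrical uncertainties
#' (computed after equal-frequency discretization of numeric attributes).
#' Best-first forward search, stopping after `max_stale` consecutive
#' non-improving expansions.
#'
#' @param x Numeric matrix of (one-hot-encoded) attributes.
#' @param y Output attribute (numeric or factor).
#' @param max_stale Non-improving expansions tolerated (default 5).
#' @param bins Discretization bins for numeric vectors.
#' @return Character vector of selected column names.
#' @export
cfs_select <- function(x, y, max_stale = 5, bins = 10) {
  x <- as.matrix(x)
  p <- ncol(x)
  yd <- if (is.numeric(y)) discretize_ef(y, bins) else as.integer(as.factor(y))
  xd <- apply(x, 2, discretize_ef, bins = bins)
  r_cf <- vapply(seq_len(p), function(j) symmetrical_uncertainty(xd[, j], yd),
                 numeric(1))
  r_ff <- diag(1, p)
  for (i in seq_len(p - 1))
    for (j in (i + 1):p) {
      r_ff[i, j] <- r_ff[j, i] <- symmetrical_uncertainty(xd[, i], xd[, j])
    }
  # best-first forward search over subsets (represented as sorted index sets)
  open <- list(integer(0))
  open_merit <- c(cfs_merit(integer(0), r_cf, r_ff))
  visited <- character(0)
  best <- integer(0); best_merit <- -Inf; stale <- 0L
  while (length(open) && stale < max_stale) {
    pick <- which.max(open_merit)
    node <- open[[pick]]
    open <- open[-pick]; open_merit <- open_merit[-pick]
    improved <- FALSE
    for (j in setdiff(seq_len(p), node)) {
      child <- sort(c(node, j))
      key <- paste(child, collapse = ",")
      if (key %in% visited) next
      visited <- c(visited, key)
      m <- cfs_merit(child, r_cf, r_ff)
      open <- c(open, list(child)); open_merit <- c(open_merit, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  colnames(x)[best]
}

# ---- metrics ----------------------------------------------------------------

# rank-statistic AUC: probability that a random positive outranks a random
# negative, ties counted half
auc_rank <- function(truth_pos, score) {
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, balanced accuracy `(Se+Sp)/2`, the Matthews correlation
#' coefficient, and the rank-statistic AUC (probability that a random
#' positive outranks a random negative, ties half). Metrics with a zero
#' denominator are reported as `NA`, never coerced to 0.
#'
#' @param truth,predictions Class vectors (factor/character).
#' @param probabilities Optional scores for the positive class (for AUC).
#' @param positive Label of the positive class (default `"increased"`).
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `se`, `sp`, `ppv`, `bar`,
#'   `mcc`, `auc`.
#' @export
classification_metrics <- function(truth, predictions, probabilities = NULL,
                                   positive = "increased") {
  truth <- as.character(truth); predictions <- as.character(predictions)
  tpos <- truth == positive; ppos <- predictions == positive
  tp <- sum(tpos & ppos); fn <- sum(tpos & !ppos)
  fp <- sum(!tpos & ppos); tn <- sum(!tpos & !ppos)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  se <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  bar <- if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom
  auc <- if (is.null(probabilities)) NA_real_ else auc_rank(tpos, probabilities)
  list(tp = tp, fp = fp, tn = tn, fn = fn, se = se, sp = sp, ppv = ppv,
       bar = bar, mcc = mcc, auc = auc)
}

#' Regression performance metrics
#'
#' @param truth,predictions Numeric vectors.
#' @return Named list: `r` (Pearson correlation; `NA` when either vector is
#'   constant) and `rmse`.
#' @export
regression_metrics <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions))
  r <- if (sd(truth) == 0 || sd(predictions) == 0) NA_real_
       else cor(truth, predictions)
  list(r = r, rmse = sqrt(mean((truth - predictions)^2)))
}

#' Classification metrics from thresholded regression output
#'
#' Converts both the observed and the predicted numeric fitness values into
#' classes at a common threshold (values above it are `increased`), then
#' applies [classification_metrics()] with the numeric prediction as the
#' ranking score.
#'
#' @param truth,predictions Numeric fitness vectors.
#' @param threshold Class boundary (default the median of `truth`).
#' @return As [classification_metrics()].
#' @export
thresholded_classification <- function(truth, predictions,
                                       threshold = stats::median(truth)) {
  tc <- ifelse(truth > threshold, "increased", "decreased")
  pc <- ifelse(predictions > threshold, "increased", "decreased")
  classification_metrics(tc, pc, probabilities = predictions)
}

# ---- cross-validation -------------------------------------------------------

fit_spec <- function(spec, features, y, seed) {
  if (spec$task == "classify") {
    train_rf_classifier(features, y, n_trees = spec$n_trees, seed = seed,
                        mtry = spec$mtry)
  } else {
    train_bagged_regression_trees(features, y, n_bags = spec$n_bags,
                                  seed = seed, selection = spec$selection)
  }
}

predict_spec <- function(spec, model, features) {
  if (spec$task == "classify") {
    pr <- predict(model, features)
    list(pred = as.character(pr$class), prob = pr$prob)
  } else {
    list(pred = predict(model, features), prob = NULL)
  }
}

#' Cross-validated fitness prediction
#'
#' Leave-one-out or k-fold cross-validation: every variant is predicted
#' exactly once by a model that never saw it; folds are disjoint with sizes
#' differing by at most one.
#'
#' @param spec A [rf_spec()] or [bagged_tree_spec()].
#' @param features Data frame of input attributes.
#' @param y Output attribute (factor for classification, numeric for
#'   regression).
#' @param scheme `"kfold"` (default) or `"loo"`.
#' @param k Number of folds for `"kfold"` (default 10; must not exceed `n`).
#' @param seed Integer seed driving fold assignment and all model randomness.
#' @param stratified Stratify k-fold assignment by class (default `FALSE`).
#' @param threshold For regression, also report thresholded classification
#'   metrics at this boundary (default median of `y`; `NA` to skip).
#' @return A `fitness_eval` report: per-variant `truth`, `pred` (+ `prob`
#'   for classification), fold ids, the metric list, scheme and seed.
#' @export
cross_validate <- function(spec, features, y, scheme = c("kfold", "loo"),
                           k = 10, seed = 1, stratified = FALSE,
                           threshold = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(features)
  stopifnot(length(y) == n)
  if (scheme == "loo") k <- n
  if (k > n) stop("k = ", k, " exceeds the number of variants (", n, ")")
  set.seed(seed)
  if (stratified && spec$task == "classify" && scheme == "kfold") {
    fold <- integer(n)
    for (lv in unique(as.character(y))) {
      idx <- which(as.character(y) == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  pred <- rep(NA_character_, n); prob <- rep(NA_real_, n)
  npred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    model <- fit_spec(spec, features[-test, , drop = FALSE], y[-test],
                      seed = seed + f)
    out <- predict_spec(spec, model, features[test, , drop = FALSE])
    if (spec$task == "classify") {
      pred[test] <- out$pred; prob[test] <- out$prob
    } else {
      npred[test] <- out$pred
    }
  }
  if (spec$task == "classify") {
    metrics <- classification_metrics(y, pred, prob)
    report <- list(truth = y, pred = factor(pred, levels = levels(as.factor(y))),
                   prob = prob, fold = fold, metrics = metrics,
                   task = "classify", scheme = scheme, k = k, seed = seed)
  } else {
    metrics <- regression_metrics(y, npred)
    if (is.null(threshold)) threshold <- stats::median(y)
    if (!is.na(threshold))
      metrics <- c(metrics,
                   thresholded_classification(y, npred, threshold)[
                     c("se", "sp", "ppv", "bar", "mcc", "auc")])
    report <- list(truth = y, pred = npred, fold = fold, metrics = metrics,
                   task = "regress", scheme = scheme, k = k, seed = seed)
  }
  class(report) <- "fitness_eval"
  report
}

#' @export
print.fitness_eval <- function(x, ...) {
  cat(sprintf("Cross-validated %s (%s, k = %d, seed = %d)\n", x$task,
              x$scheme, x$k, x$seed))
  m <- x$metrics
  cat(paste(sprintf("%s = %.3f", names(m)[vapply(m, is.numeric, TRUE)],
                    unlist(m[vapply(m, is.numeric, TRUE)])),
            collapse = ", "), "\n")
  invisible(x)
}

# ---- permutation controls ---------------------------------------------------

#' Shuffled-label permutation control
#'
#' Re-runs the cross-validated evaluation after randomly permuting the
#' output attribute (preserving its multiset) `n_permutations` times, and
#' reports the empirical p-value `(1 + #{permuted >= observed}) / (n + 1)`
#' for each metric. With an informative model the permuted metrics
#' concentrate at chance (BAR 0.5, MCC 0, AUC 0.5, r 0).
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label permutations (>= 1).
#' @param metrics Which metrics to track.
#' @return A `control_distribution`: observed metrics, a matrix of permuted
#'   metrics, and per-metric empirical p-values.
#' @export
shuffle_control <- function(spec, features, y, n_permutations = 100,
                            scheme = "kfold", k = 10, seed = 1,
                            metrics = NULL) {
  if (n_permutations < 1) stop("need at least one permutation")
  if (is.null(metrics))
    metrics <- if (spec$task == "classify") c("bar", "mcc", "auc") else "r"
  observed <- cross_validate(spec, features, y, scheme = scheme, k = k,
                             seed = seed)
  obs <- unlist(observed$metrics[metrics])
  set.seed(seed * 1000003L %% .Machine$integer.max)
  perm <- matrix(NA_real_, n_permutations, length(metrics),
                 dimnames = list(NULL, metrics))
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    rep_b <- cross_validate(spec, features, yp, scheme = scheme, k = k,
                            seed = seed + b)
    perm[b, ] <- unlist(rep_b$metrics[metrics])
  }
  p <- vapply(metrics, function(m)
    (1 + sum(perm[, m] >= obs[m], na.rm = TRUE)) / (n_permutations + 1),
    numeric(1))
  base::structure(list(observed = obs, permuted = perm, p_value = p,
                       n_permutations = n_permutations, seed = seed),
                  class = "control_distribution")
}

#' @export
print.control_distribution <- function(x, ...) {
  for (m in names(x$observed))
    cat(sprintf("%s: observed %.3f, shuffled %.3f +/- %.3f, p = %.4g\n",
                m, x$observed[m], mean(x$permuted[, m]), sd(x$permuted[, m]),
                x$p_value[m]))
  invisible(x)
}

#' Learning curve over training-set size
#'
#' For each size, draws `reps` random subsets (without replacement),
#' cross-validates each, and reports the mean and standard deviation of
#' every metric.
#'
#' @inheritParams cross_validate
#' @param sizes Training-set sizes (each must not exceed `n`).
#' @param reps Random subsets per size (default 10).
#' @return Data frame with one row per (size, metric): `size`, `metric`,
#'   `mean`, `sd`. The evaluation of subset `r` at size `s` uses seed
#'   `seed + 37*s + r`; a size equal to `n` uses the full data set, so a
#'   single rep at that size reproduces the full-data cross-validation under
#'   the same seed.
#' @export
learning_curve <- function(spec, features, y, sizes, reps = 10, k = 10,
                           seed = 1) {
  n <- nrow(features)
  if (any(sizes > n)) stop("sizes must not exceed the number of variants")
  rows <- list()
  for (s in sizes) {
    vals <- list()
    for (r in seq_len(reps)) {
      set.seed(seed + 37L * s + r)
      idx <- if (s == n) seq_len(n) else sample.int(n, s)
      rp <- cross_validate(spec, features[idx, , drop = FALSE], y[idx],
                           scheme = "kfold", k = min(k, s),
                           seed = seed + 37L * s + r)
      vals[[r]] <- unlist(rp$metrics[vapply(rp$metrics, is.numeric,
                                            logical(1))])
    }
    vm <- do.call(rbind, vals)
    for (m in colnames(vm))
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, metric = m, mean = mean(vm[, m], na.rm = TRUE),
        sd = sd(vm[, m], na.rm = TRUE))
  }
  do.call(rbind, rows)
}

#' Extreme-tail variant subset
#'
#' The `n_per_tail` variants with the most positive and the `n_per_tail`
#' with the most negative fitness values; the tails are disjoint and the
#' resulting classes exactly balanced.
#'
#' @param fitness Numeric fitness values.
#' @param n_per_tail Variants per tail; `2 * n_per_tail` must not exceed
#'   `length(fitness)`.
#' @return Integer indices of the selected variants (low tail first).
#' @export
extreme_subset <- function(fitness, n_per_tail) {
  n <- length(fitness)
  if (2 * n_per_tail > n)
    stop("tails overlap: 2 * ", n_per_tail, " > ", n)
  ord <- order(fitness)
  c(ord[seq_len(n_per_tail)], ord[seq(n - n_per_tail + 1L, n)])
}

#' Per-stratum prediction performance
#'
#' Recomputes the classification metrics of a cross-validation report
#' within each stratum (e.g. polarity pair, depth class or secondary
#' structure of the mutated position), plus the percentage of variants per
#' stratum. Strata containing a single truth class get `NA` metrics with a
#' flag.
#'
#' @param report A classification `fitness_eval`.
#' @param strata Vector of stratum labels, one per predicted variant.
#' @return Data frame: `stratum`, `bar`, `mcc`, `auc`, `pct`,
#'   `single_class`.
#' @export
stratified_performance <- function(report, strata) {
  stopifnot(inherits(report, "fitness_eval"), report$task == "classify")
  n <- length(report$truth)
  if (length(strata) != n)
    stop("strata must label every predicted variant")
  rows <- lapply(unique(strata), function(s) {
    idx <- which(strata == s)
    single <- length(unique(as.character(report$truth[idx]))) < 2L
    m <- classification_metrics(report$truth[idx], report$pred[idx],
                                report$prob[idx])
    data.frame(stratum = s,
               bar = if (single) NA_real_ else m$bar,
               mcc = if (single) NA_real_ else m$mcc,
               auc = if (single) NA_real_ else m$auc,
               pct = 100 * length(idx) / n,
               single_class = single)
  })
  do.call(rbind, rows)
}

# ---- classical tests --------------------------------------------------------

#' Pearson chi-square test of independence
#'
#' The Pearson statistic `sum((O-E)^2/E)` without continuity correction,
#' with `(rows-1)(cols-1)` degrees of freedom.
#'
#' @param table Two-way contingency matrix of counts.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the contingency table")
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-sample t-test
#'
#' Welch's test by default; set `pooled = TRUE` for the equal-variance
#' variant.
#'
#' @param x,y Numeric samples (each with at least 2 values).
#' @param pooled Assume equal variances.
#' @return List with `statistic`, `df`, `p_value` and the two group means.
#' @export
two_sample_t <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  ht <- t.test(x, y, var.equal = pooled)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), mean_x = mean(x), mean_y = mean(y))
}
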