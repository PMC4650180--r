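# SAMME multi-class adaptive boosting over phenology features.
#
# The booster itself (weight updates, learner weights alpha_m with the
# multi-class ln(K-1) correction, weighted vote, importances) is written
# here from first principles; the depth-capped CART weak learner is an
# rpart tree fitted with case weights.

samme_tree_control <- function(depth) {
  rpart::rpart.control(maxdepth = depth, minsplit = 2, minbucket = 1,
                       cp = 0, xval = 0, maxcompete = 0,
                       maxsurrogate = 0, usesurrogate = 0)
}

# alpha_m = ln((1 - err)/err) + ln(K - 1)
samme_alpha <- function(err, n_classes) {
  log((1 - err) / err) + log(n_classes - 1)
}

check_features <- function(records, features) {
  if (is.null(features)) {
    features <- intersect(phenology_features(), names(records))
    if (!length(features)) {
      # no registry column present: every numeric non-bookkeeping column
      numeric_cols <- names(records)[vapply(records, is.numeric,
                                            logical(1))]
      features <- setdiff(numeric_cols, c("season_year"))
    }
  }
  missing <- setdiff(features, names(records))
  if (length(missing)) {
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  }
  features
}

# Drop records with missing selected features (logged), returning the
# model frame used by the learners.
samme_frame <- function(records, features, label_col = "label") {
  x <- records[features]
  y <- records[[label_col]]
  ok <- stats::complete.cases(x) & !is.na(y)
  if (!all(ok)) {
    message(sum(!ok), " record(s) dropped for missing features/labels")
  }
  all_missing <- vapply(x, function(col) all(is.na(col)), logical(1))
  if (any(all_missing)) {
    stop("feature(s) entirely missing: ",
         paste(features[all_missing], collapse = ", "))
  }
  list(x = x[ok, , drop = FALSE], y = factor(y[ok]), kept = which(ok))
}

#' Train a SAMME multi-class boosted classifier
#'
#' Boosts depth-capped CART trees (stumps by default) on the phenology
#' features.  At round m the learner is fitted to the weighted sample;
#' with weighted misclassification error `err_m` its vote weight is
#' `alpha_m = ln((1-err_m)/err_m) + ln(K-1)`.  Misclassified records have
#' their weights multiplied by `exp(alpha_m)` and weights are
#' renormalised.  A round with `err_m >= (K-1)/K` (no better than
#' guessing) is discarded and boosting stops; a perfect round caps
#' `alpha` at `ln(1e10)` and stops.  Feature importances are the
#' alpha-weighted sums of each tree's split gains, normalised to 1.
#'
#' @param records data.frame of phenology records with a `label` column.
#' @param m_rounds Maximum boosting rounds (default 100).
#' @param tree_depth Depth cap of the weak learner (1 = stump).
#' @param seed Optional RNG seed (rpart tie-breaks are deterministic;
#'   the seed fixes any future stochastic extension).
#' @param features Feature columns to use (default: the registered
#'   phenology features present in `records`).
#' @param label_col Name of the class-label column.
#' @return Object of class `samme_model`: `learners`, `alphas`,
#'   `classes`, `importances` (sums to 1), `m_rounds`, `features`.
#' @export
train_samme <- function(records, m_rounds = 100, tree_depth = 1,
                        seed = NULL, features = NULL,
                        label_col = "label") {
  if (!is.null(seed)) set.seed(seed)
  features <- check_features(records, features)
  fr <- samme_frame(records, features, label_col)
  x <- fr$x; y <- fr$y
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes to boost")
  n <- length(y)
  w <- rep(1 / n, n)

  learners <- list()
  alphas <- numeric(0)
  gain <- stats::setNames(numeric(length(features)), features)
  dat <- cbind(x, .y = y)

  for (m in seq_len(m_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                         control = samme_tree_control(tree_depth))
    pred <- predict(tree, dat, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= (K - 1) / K) {              # no better than chance: halt
      if (m == 1L) {                       # keep a zero-weight learner so
        learners[[1L]] <- tree             # the model is still usable
        alphas <- 0
      }
      break
    }
    if (err <= 0) {
      alpha <- log(1e10)
      learners[[length(learners) + 1L]] <- tree
      alphas <- c(alphas, alpha)
      gain <- gain + alpha * tree_split_gains(tree, features)
      break
    }
    alpha <- samme_alpha(err, K)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    gain <- gain + alpha * tree_split_gains(tree, features)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  importances <- if (sum(gain) > 0) gain / sum(gain) else gain
  structure(list(learners = learners, alphas = alphas,
                 classes = levels(y), importances = importances,
                 m_rounds = length(learners), features = features,
                 label_col = label_col),
            class = "samme_model")
}

# Primary-split impurity improvements per feature (maxcompete and
# maxsurrogate are 0, so every row of $splits is a primary split).
tree_split_gains <- function(tree, features) {
  g <- stats::setNames(numeric(length(features)), features)
  sp <- tree$splits
  if (!is.null(sp) && nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      v <- rownames(sp)[i]
      if (v %in% features) g[v] <- g[v] + sp[i, "improve"]
    }
  }
  g
}

#' @export
print.samme_model <- function(x, ...) {
  cat("SAMME boosted classifier:", x$m_rounds, "learner(s),",
      length(x$classes), "classes\n")
  top <- sort(x$importances, decreasing = TRUE)
  cat("  top features:",
      paste(names(top)[seq_len(min(3, length(top)))],
            signif(top[seq_len(min(3, length(top)))], 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes from a SAMME model
#'
#' Weighted vote: each learner contributes its weight `alpha_m` to the
#' class it predicts; the arg-max class wins, ties broken by class order
#' in `object$classes`.
#'
#' @param object A `samme_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.samme_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  }
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in seq_along(object$learners)) {
    pr <- as.character(predict(object$learners[[m]], newdata,
                               type = "class"))
    votes[cbind(seq_len(nrow(newdata)), match(pr, object$classes))] <-
      votes[cbind(seq_len(nrow(newdata)), match(pr, object$classes))] +
      object$alphas[m]
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

# Seeded stratified fold assignment: within each class, a shuffled
# round-robin over folds.  Classes smaller than k simply miss some folds.
stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  fold
}

#' Stratified k-fold cross-validated classification error
#'
#' @inheritParams train_samme
#' @param k_folds Number of stratified folds (default 10).
#' @return List with `error_rate` (pooled misclassification proportion),
#'   `success_rate` (`1 - error_rate` exactly) and `per_fold`
#'   data.frame (fold, n, error).
#' @export
cv_error <- function(records, k_folds = 10, m_rounds = 100,
                     tree_depth = 1, seed = NULL, features = NULL,
                     label_col = "label") {
  features <- check_features(records, features)
  fr <- samme_frame(records, features, label_col)
  n <- length(fr$y)
  if (k_folds > n) stop("k_folds exceeds the number of usable records")
  recs <- cbind(fr$x, stats::setNames(list(fr$y), label_col))
  fold <- stratified_folds(fr$y, k_folds, seed)
  wrong <- logical(n)
  per_fold <- data.frame(fold = integer(0), n = integer(0),
                         error = numeric(0))
  for (f in sort(unique(fold))) {
    test <- fold == f
    model <- train_samme(recs[!test, , drop = FALSE], m_rounds = m_rounds,
                         tree_depth = tree_depth, features = features,
                         label_col = label_col)
    pred <- predict(model, recs[test, , drop = FALSE])
    wrong[test] <- as.character(pred) != as.character(fr$y[test])
    per_fold <- rbind(per_fold, data.frame(fold = f, n = sum(test),
                                           error = mean(wrong[test])))
  }
  err <- mean(wrong)
  list(error_rate = err, success_rate = 1 - err, per_fold = per_fold)
}

#' Permutation p-value for classifier significance
#'
#' Compares the observed cross-validated error with the errors obtained
#' after permuting the class labels within sex strata (so any pure
#' sex-composition signal survives under the null).  The add-one
#' estimator `p = (1 + #{permuted error <= observed}) / (n_perm + 1)`
#' bounds the smallest attainable p at `1/(n_perm + 1)`.
#'
#' @inheritParams cv_error
#' @param n_perm Number of label permutations.
#' @param sex_col Stratum column (set `NULL` to permute freely).
#' @return List with `p_value`, `observed_error`, `permuted_errors`.
#' @export
permutation_pvalue <- function(records, n_perm = 199, k_folds = 10,
                               m_rounds = 100, tree_depth = 1,
                               seed = NULL, features = NULL,
                               label_col = "label", sex_col = "sex") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- cv_error(records, k_folds = k_folds, m_rounds = m_rounds,
                  tree_depth = tree_depth, features = features,
                  label_col = label_col)$error_rate
  strata <- if (!is.null(sex_col) && sex_col %in% names(records)) {
    records[[sex_col]]
  } else {
    rep(1L, nrow(records))
  }
  perm_err <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    shuffled <- records
    for (s in unique(strata)) {
      idx <- which(strata == s)
      shuffled[[label_col]][idx] <-
        records[[label_col]][idx[sample.int(length(idx))]]
    }
    perm_err[b] <- cv_error(shuffled, k_folds = k_folds,
                            m_rounds = m_rounds, tree_depth = tree_depth,
                            features = features,
                            label_col = label_col)$error_rate
  }
  p <- (1 + sum(perm_err <= obs)) / (n_perm + 1)
  list(p_value = p, observed_error = obs, permuted_errors = perm_err)
}

#' Greedy elimination of highly correlated features
#'
#' While any absolute pairwise Pearson correlation exceeds `threshold`,
#' drops from the worst pair the feature with the larger mean absolute
#' correlation against all remaining features.  Constant features have
#' no defined correlation; they are flagged and excluded from the test
#' (but kept in the output records).
#'
#' @param records data.frame holding the feature columns.
#' @param threshold Absolute-correlation cutoff (default 0.9).
#' @param features Candidate features (default: registry columns).
#' @return List with `records` (dropped columns removed), `dropped`
#'   (names in drop order) and `constant` (flagged constant features).
#' @export
drop_correlated_features <- function(records, threshold = 0.9,
                                     features = NULL) {
  features <- check_features(records, features)
  if (length(features) < 2) stop("need at least 2 features")
  x <- records[features]
  constant <- names(x)[vapply(x, function(v) stats::var(v, na.rm = TRUE) == 0,
                              logical(1))]
  active <- setdiff(features, constant)
  dropped <- character(0)
  while (length(active) >= 2) {
    cm <- abs(stats::cor(x[active], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- active[worst]
    meanabs <- rowMeans(cm[pair, , drop = FALSE])
    out <- pair[which.max(meanabs)]
    dropped <- c(dropped, out)
    active <- setdiff(active, out)
  }
  keep_cols <- setdiff(names(records), dropped)
  list(records = records[keep_cols], dropped = dropped,
       constant = constant)
}

#' Cumulative importance ranking of classifier features
#'
#' @param model A `samme_model`.
#' @return data.frame with `feature`, `importance` (descending) and
#'   `cumulative` (monotone to 1).
#' @export
cumulative_importance_ranking <- function(model) {
  stopifnot(inherits(model, "samme_model"))
  imp <- sort(model$importances, decreasing = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             cumulative = cumsum(as.numeric(imp)),
             row.names = NULL)
}
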