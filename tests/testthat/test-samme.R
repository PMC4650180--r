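# SAMME boosting: learner-weight formula, binary reduction, vote
# prediction, cross-validation, permutation test, feature handling.

test_that("learner weight follows the multi-class formula", {
  expect_equal(shearwaterCOE:::samme_alpha(0.4, 3), log(1.5) + log(2),
               tolerance = 1e-12)
  expect_equal(shearwaterCOE:::samme_alpha(0.5, 2), 0, tolerance = 1e-12)
  # K = 2 reduces exactly to classical AdaBoost
  errs <- seq(0.05, 0.45, by = 0.05)
  expect_equal(shearwaterCOE:::samme_alpha(errs, 2),
               log((1 - errs) / errs), tolerance = 1e-12)
})

test_that("a separable toy is fit perfectly in one round", {
  toy <- data.frame(f = c(1, 2, 10, 11),
                    label = c("A", "A", "B", "B"))
  m <- train_samme(toy, m_rounds = 5, features = "f")
  expect_equal(m$m_rounds, 1L)   # early stop on zero error
  expect_equal(as.character(predict(m, toy)), toy$label)
})

test_that("prediction equals an independent tally of weighted votes", {
  set.seed(14)
  rec <- separable_records(n_per_class = 7, noise_features = 3, seed = 14)
  rec$prior_lay_date <- rec$prior_lay_date + rnorm(nrow(rec), 0, 4)
  m <- train_samme(rec, m_rounds = 5, seed = 14,
                   features = c("prior_lay_date", "noise1", "noise2",
                                "noise3"))
  expect_gte(m$m_rounds, 2L)
  newdata <- rec[sample.int(nrow(rec), 20), ]
  votes <- matrix(0, 20, length(m$classes), dimnames = list(NULL, m$classes))
  for (j in seq_along(m$learners)) {
    pr <- as.character(predict(m$learners[[j]], newdata, type = "class"))
    for (i in 1:20) votes[i, pr[i]] <- votes[i, pr[i]] + m$alphas[j]
  }
  oracle <- m$classes[apply(votes, 1, which.max)]
  expect_equal(as.character(predict(m, newdata)), oracle)
})

test_that("single learner and unanimous votes behave as expected", {
  toy <- data.frame(f = c(1, 2, 10, 11), label = c("A", "A", "B", "B"))
  m <- train_samme(toy, m_rounds = 1, features = "f")
  expect_equal(as.character(predict(m, data.frame(f = c(0, 20)))),
               as.character(predict(m$learners[[1]],
                                    data.frame(f = c(0, 20)),
                                    type = "class")))
})

test_that("cross-validation is exhaustive, stratified and consistent", {
  rec <- separable_records(n_per_class = 10, seed = 2)
  cv <- cv_error(rec, k_folds = 5, m_rounds = 5, seed = 2)
  expect_equal(cv$error_rate, 0)
  expect_equal(cv$success_rate, 1)
  expect_equal(sum(cv$per_fold$n), nrow(rec))
  expect_error(cv_error(rec, k_folds = 100), "k_folds")
  # same seed -> same folds -> identical result
  rec2 <- noise_records(n_per_class = 20, seed = 3)
  a <- cv_error(rec2, k_folds = 5, m_rounds = 10, seed = 9)
  b <- cv_error(rec2, k_folds = 5, m_rounds = 10, seed = 9)
  expect_identical(a, b)
})

test_that("cv error on label-independent data sits at chance", {
  rec <- noise_records(n_per_class = 200, n_features = 4, seed = 6)
  cv <- cv_error(rec, k_folds = 10, m_rounds = 30, seed = 6)
  se <- sqrt((2 / 3) * (1 / 3) / nrow(rec))
  expect_lt(abs(cv$error_rate - 2 / 3), 3 * se)
})

test_that("permutation p-value respects the add-one bound", {
  rec <- separable_records(n_per_class = 8, seed = 4)
  out <- permutation_pvalue(rec, n_perm = 99, k_folds = 4, m_rounds = 3,
                            seed = 4)
  expect_equal(out$observed_error, 0)
  expect_equal(out$p_value, 1 / 100)     # minimum attainable
  expect_gte(min(out$permuted_errors), 0)
  expect_error(permutation_pvalue(rec, n_perm = 0), "n_perm")
})

test_that("null features give a non-significant permutation p", {
  hits <- 0L
  for (s in 1:5) {
    rec <- noise_records(n_per_class = 12, n_features = 2, seed = 100 + s)
    out <- permutation_pvalue(rec, n_perm = 39, k_folds = 3, m_rounds = 3,
                              seed = 100 + s)
    if (out$p_value >= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)   # >= ~90% of replicates under the null
})

test_that("correlated-feature elimination matches its definition", {
  set.seed(8)
  n <- 200
  f1 <- rnorm(n)
  rec <- data.frame(f1 = f1, f2 = f1, f3 = rnorm(n),
                    label = rep(c("A", "B"), n / 2))
  out <- drop_correlated_features(rec, threshold = 0.9,
                                  features = c("f1", "f2", "f3"))
  expect_length(out$dropped, 1L)
  expect_true(out$dropped %in% c("f1", "f2"))
  expect_false(out$dropped %in% names(out$records))

  ind <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                    label = "A")
  out2 <- drop_correlated_features(ind, threshold = 0.9,
                                   features = c("f1", "f2", "f3"))
  expect_length(out2$dropped, 0L)

  # independent re-implementation of the greedy rule on a 3-feature case
  set.seed(9)
  a <- rnorm(n)
  x <- data.frame(f1 = a + rnorm(n, 0, 0.1),
                  f2 = a + rnorm(n, 0, 0.15),
                  f3 = rnorm(n), label = "A")
  greedy_oracle <- function(df, feats, thr) {
    dropped <- character(0)
    repeat {
      cm <- abs(cor(df[feats])); diag(cm) <- 0
      if (length(feats) < 2 || max(cm) <= thr) break
      w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- feats[w]
      out <- pair[which.max(rowMeans(cm[pair, , drop = FALSE]))]
      dropped <- c(dropped, out)
      feats <- setdiff(feats, out)
    }
    dropped
  }
  got <- drop_correlated_features(x, threshold = 0.7,
                                  features = c("f1", "f2", "f3"))
  expect_identical(got$dropped,
                   greedy_oracle(x, c("f1", "f2", "f3"), 0.7))
  # constant feature flagged, excluded from the test, not dropped
  x$f4 <- 1
  out4 <- drop_correlated_features(x, threshold = 0.7,
                                   features = c("f1", "f2", "f3", "f4"))
  expect_identical(out4$constant, "f4")
  expect_true("f4" %in% names(out4$records))
})

test_that("importance ranking is normalised, ordered and cumulative", {
  rec <- separable_records(n_per_class = 10, noise_features = 3, seed = 5)
  m <- train_samme(rec, m_rounds = 20, seed = 5)
  rk <- cumulative_importance_ranking(m)
  expect_true(all(diff(rk$importance) <= 1e-12))
  expect_true(all(diff(rk$cumulative) >= -1e-12))
  expect_equal(rk$cumulative[nrow(rk)], 1, tolerance = 1e-9)
  expect_equal(sum(m$importances), 1, tolerance = 1e-9)
  # the single informative feature dominates (perfect split, round 1)
  expect_equal(rk$feature[1], "prior_lay_date")
  expect_gt(rk$importance[1], 0.99)
})

test_that("duplicated informative features share the total importance", {
  rec <- separable_records(n_per_class = 10, noise_features = 0, seed = 7)
  rec$dup <- rec$prior_lay_date
  m2 <- train_samme(rec, m_rounds = 10,
                    features = c("prior_lay_date", "dup"))
  m1 <- train_samme(rec, m_rounds = 10, features = "prior_lay_date")
  expect_equal(sum(m2$importances), sum(m1$importances),
               tolerance = 1e-9)
})

test_that("invalid inputs raise errors", {
  one_class <- data.frame(f = rnorm(10), label = "A")
  expect_error(train_samme(one_class, features = "f"), "2 classes")
  rec <- separable_records()
  expect_error(train_samme(rec, features = "nope"), "unknown feature")
  rec$allna <- NA_real_
  expect_error(train_samme(rec, features = c("prior_lay_date", "allna")),
               "missing")
})
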