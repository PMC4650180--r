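#!/usr/bin/env Rscript
# Can breeding and migration phenology predict next-season reproductive
# performance?  SAMME multi-class boosting of stumps over the event-date
# features, with stratified 10-fold cross-validation, a label-permutation
# significance test and correlated-feature elimination.

suppressPackageStartupMessages(library(shearwaterCOE))

phen <- read_phenology_csv("results/data/phenology.csv")
seed <- 2015

model <- train_samme(phen, m_rounds = 100, seed = seed)
rank <- cumulative_importance_ranking(model)
write.csv(rank, "results/feature_importance.csv", row.names = FALSE)

cv <- cv_error(phen, k_folds = 10, m_rounds = 100, seed = seed)
cat(sprintf("10-fold CV error rate: %.2f%%  (success rate %.2f%%)\n",
            100 * cv$error_rate, 100 * cv$success_rate))

cat("Feature ranking by cumulative importance:\n")
print(rank, digits = 3)

perm <- permutation_pvalue(phen, n_perm = 199, k_folds = 10,
                           m_rounds = 20, seed = seed)
cat(sprintf("Permutation test (199 label shuffles within sex): p = %.4f\n",
            perm$p_value))

drop <- drop_correlated_features(phen, threshold = 0.9)
if (length(drop$dropped)) {
  cv_red <- cv_error(drop$records, k_folds = 10, m_rounds = 100,
                     seed = seed,
                     features = setdiff(
                       intersect(phenology_features(),
                                 names(drop$records)), drop$dropped))
  cat(sprintf("After dropping %s: CV error %.2f%%\n",
              paste(drop$dropped, collapse = ", "),
              100 * cv_red$error_rate))
} else {
  cat("No feature pair exceeds |r| = 0.9; all features kept\n")
}

writeLines(jsonlite::toJSON(list(
  cv_error_rate = cv$error_rate, cv_success_rate = cv$success_rate,
  permutation_p = perm$p_value, dropped = drop$dropped),
  auto_unbox = TRUE, pretty = TRUE), "results/cv_report.json")
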