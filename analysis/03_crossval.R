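#!/usr/bin/env Rscript
# Stage 3 — cross-validation comparison of the classifiers.
#
# Builds the training-data comparison table: for each classifier
# (best-univariate, PCA-all, FDA-all, FDA-sub, LR-all, LR-sub) the fitted
# C-statistic and the leave-one-out cross-validated confusion matrix at
# beta in {0.01, 0.05, 0.10, 0.20}, plus a fitted-only CART row (tree
# structure is unstable under resampling, so the tree is not cross-
# validated). Subsets for FDA-sub / LR-sub are read from stage 2 if
# present, else fall back to the generator's informative panel.
#
# Usage: Rscript analysis/03_crossval.R  (after 01, optionally 02)
# Output: results/crossval_table.csv, results/cart_tree.txt,
#         results/score_densities_fda_sub.csv

suppressMessages(library(focmpanel))
train <- read_panel("results/training_cohort.csv")
seed <- 20260926L

subset_from <- function(path, k, fallback) {
  if (file.exists(path)) {
    curve <- read.csv(path)
    strsplit(curve$subset[curve$k == k], "\\+")[[1]]
  } else fallback
}
fda_sub <- subset_from("results/saturation_fda.csv", 5,
                       c("x4", "x8", "x12", "x21", "x22"))
lr_sub <- subset_from("results/saturation_lr.csv", 6,
                      c("x4", "x8", "x10", "x17", "x21", "x22"))

# best univariate variable by fitted C-statistic
uni_c <- vapply(panel_variables(train), function(v) {
  fit_classifier(train, classifier_spec("UNIVARIATE", subset = v),
                 betas = 0.05)$c_statistic
}, numeric(1))
best_var <- names(which.max(uni_c))
cat(sprintf("best univariate variable: %s (fitted C = %.4f)\n",
            best_var, max(uni_c)))

specs <- list(
  Univariate = classifier_spec("UNIVARIATE", subset = best_var),
  `PCA-all` = classifier_spec("PCA"),
  `FDA-all` = classifier_spec("FDA"),
  `FDA-sub` = classifier_spec("FDA", subset = fda_sub),
  `LR-all` = classifier_spec("LR"),
  `LR-sub` = classifier_spec("LR", subset = lr_sub)
)

rows <- list()
for (nm in names(specs)) {
  rep <- run_loocv(train, specs[[nm]])
  r <- rep$rows
  r$classifier <- nm
  rows[[nm]] <- r
  cat(sprintf("%-10s fitted C = %.4f, LOOCV C = %.4f\n", nm, rep$fitted_c,
              rep$cv_c))
}
cart <- cart_fitted_report(train, seed = seed)
rows$CART <- cart$rows
write_tree(cart$tree, "results/cart_tree.txt")

table2 <- do.call(rbind, rows)
write_report(table2, "results/crossval_table.csv")
cat("\ncross-validation table:\n")
print(table2, row.names = FALSE)

# score-density export for a Figure-1-style plot of the FDA-sub model
fc <- fit_classifier(train, specs[["FDA-sub"]])
write.csv(density_pair_table(fc$pair), "results/score_densities_fda_sub.csv",
          row.names = FALSE)
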