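#' Classifier specification
#'
#' A declarative description of one classifier to fit and evaluate: the
#' method, the variable subset (or \code{"ALL"}), and method options. The
#' same spec object drives fitting, LOOCV, subset search, and external
#' validation.
#'
#' @param method One of \code{"UNIVARIATE"}, \code{"PCA"}, \code{"FDA"},
#'   \code{"LR"}, \code{"CART"}.
#' @param subset Character vector of variable ids, or \code{"ALL"}.
#' @param ridge Ridge penalty for LR.
#' @param min_split Minimum node size for CART splitting.
#' @param bandwidth_rule KDE bandwidth rule passed to \code{\link{fit_kde}}.
#' @param policy Threshold policy (\code{"td-quantile"} or
#'   \code{"posterior"}).
#' @return A \code{classifier_spec} list.
#' @export
classifier_spec <- function(method, subset = "ALL", ridge = 1e-4,
                            min_split = 8, bandwidth_rule = "silverman",
                            policy = "td-quantile") {
  method <- match.arg(method, c("UNIVARIATE", "PCA", "FDA", "LR", "CART"))
  if (method == "UNIVARIATE" &&
      (identical(subset, "ALL") || length(subset) != 1)) {
    stop("a UNIVARIATE spec must name exactly one variable")
  }
  structure(list(method = method, subset = subset, ridge = ridge,
                 min_split = min_split, bandwidth_rule = bandwidth_rule,
                 policy = policy),
            class = "classifier_spec")
}

spec_subset <- function(spec, panel) {
  if (identical(spec$subset, "ALL")) panel_variables(panel) else spec$subset
}

# Fit the projection model of a spec (not CART) on a labeled panel.
fit_projection_spec <- function(panel, spec) {
  vars <- spec_subset(spec, panel)
  switch(spec$method,
         UNIVARIATE = fit_univariate(panel, vars),
         PCA = fit_pca_direction(panel, vars),
         FDA = fit_fda_direction(panel, vars),
         LR = fit_logistic(panel, vars, ridge = spec$ridge),
         stop("not a projection method: ", spec$method))
}

#' Fit a full scoring classifier (model + densities + thresholds)
#'
#' Fits the spec's projection model on the training panel, estimates the
#' per-class score densities by Gaussian KDE, and calibrates one threshold
#' per requested beta level. Everything is computed from the training panel
#' only, so the result can score any other cohort without leakage.
#'
#' @param panel Labeled training \code{metabolite_panel}.
#' @param spec A projection-method \code{classifier_spec}.
#' @param betas Numeric vector of nominal levels.
#' @return A \code{fitted_classifier}: list with \code{model}, \code{pair}
#'   (score densities), \code{rules} (one \code{threshold_rule} per beta),
#'   \code{scores} (training scores), \code{c_statistic} (fitted).
#' @export
fit_classifier <- function(panel, spec, betas = default_betas()) {
  model <- fit_projection_spec(panel, spec)
  scores <- project(panel, model)
  pair <- fit_score_densities(scores, panel$labels,
                              bandwidth_rule = spec$bandwidth_rule)
  # the pair's orientation is inherited from the model (ASD-high), so
  # `flipped` is FALSE by construction; keep scores as produced
  rules <- lapply(betas, function(b) {
    calibrate_threshold(pair$td, b, policy = spec$policy, pair = pair)
  })
  names(rules) <- format_beta(betas)
  structure(list(spec = spec, model = model, pair = pair, rules = rules,
                 scores = scores, c_statistic = c_statistic(pair)),
            class = "fitted_classifier")
}

default_betas <- function() c(0.01, 0.05, 0.10, 0.20)
format_beta <- function(b) sprintf("%.2f", b)

#' Confusion matrix of scores against labels at a threshold
#'
#' Positive class is ASD. Row sums are preserved: \code{TP + FN} equals the
#' number of ASD samples and \code{FP + TN} the number of TD samples.
#'
#' @param scores Oriented scores.
#' @param labels Aligned \code{ASD}/\code{TD} labels (no UNKNOWN).
#' @param rule A \code{threshold_rule}.
#' @return A \code{confusion_matrix}: list with integer \code{TP},
#'   \code{FP}, \code{FN}, \code{TN}.
#' @export
confusion_at_threshold <- function(scores, labels, rule) {
  if (length(scores) == 0) stop("no scores to evaluate")
  labels <- normalize_labels(labels, length(scores))
  if (any(labels == "UNKNOWN")) stop("confusion matrix requires known labels")
  confusion_from_calls(classify_scores(scores, rule), labels)
}

confusion_from_calls <- function(calls, labels) {
  structure(list(TP = sum(calls == "ASD" & labels == "ASD"),
                 FP = sum(calls == "ASD" & labels == "TD"),
                 FN = sum(calls == "TD" & labels == "ASD"),
                 TN = sum(calls == "TD" & labels == "TD")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Leave-one-out cross-validation of a classifier spec
#'
#' For every sample in turn, the entire pipeline — standardization,
#' projection model, per-class score densities, and beta thresholds — is
#' refit on the remaining n-1 samples; the held-out sample is then scored
#' and classified at each beta. The n out-of-fold decisions are aggregated
#' into one confusion matrix per beta. Nothing about the held-out sample
#' (including its label) can influence its own prediction. CART is excluded:
#' its structure is unstable under resampling, so it is reported fitted-only
#' (see \code{\link{cart_fitted_report}}).
#'
#' @param panel Labeled \code{metabolite_panel} with n >= 10.
#' @param spec A projection-method \code{classifier_spec}.
#' @param betas Nominal levels to evaluate.
#' @return An \code{evaluation_report}: list with \code{rows} (data frame:
#'   classifier, variables, beta, TP, FP, FN, TN, c_statistic),
#'   \code{fitted_c}, \code{cv_c} (C-statistic of the pooled out-of-fold
#'   scores), \code{oof_scores}.
#' @export
run_loocv <- function(panel, spec, betas = default_betas()) {
  if (spec$method == "CART") {
    stop("CART is evaluated fitted-only; LOOCV is not defined for it here")
  }
  n <- n_samples(panel)
  if (n < 10) stop("LOOCV requires at least 10 samples")
  preds <- matrix(NA_character_, n, length(betas))
  oof <- numeric(n)
  for (i in seq_len(n)) {
    res <- loocv_predict_one(panel, spec, i, betas)
    preds[i, ] <- res$calls
    oof[i] <- res$score
  }
  fitted <- fit_classifier(panel, spec, betas)
  rows <- do.call(rbind, lapply(seq_along(betas), function(b) {
    cm <- confusion_from_calls(preds[, b], panel$labels)
    data.frame(classifier = spec$method,
               variables = paste(spec_subset(spec, panel), collapse = "+"),
               beta = betas[b], TP = cm$TP, FP = cm$FP, FN = cm$FN,
               TN = cm$TN, c_statistic = fitted$c_statistic)
  }))
  cv_pair <- fit_score_densities(oof, panel$labels,
                                 bandwidth_rule = spec$bandwidth_rule)
  structure(list(rows = rows, fitted_c = fitted$c_statistic,
                 cv_c = c_statistic(cv_pair), oof_scores = oof),
            class = "evaluation_report")
}

# One LOOCV fold: refit everything on panel minus sample i, score sample i.
loocv_predict_one <- function(panel, spec, i, betas) {
  train <- subset_panel(panel, samples = setdiff(seq_len(n_samples(panel)), i))
  if (!all(c("ASD", "TD") %in% train$labels)) {
    stop(sprintf("fold holding out sample %d removes an entire class", i))
  }
  fc <- fit_classifier(train, spec, betas)
  score <- project(subset_panel(panel, samples = i), fc$model)
  calls <- vapply(fc$rules, function(r) classify_scores(score, r),
                  character(1))
  list(score = unname(score), calls = calls)
}

#' Fitted-only CART evaluation
#'
#' Grows and CV-prunes a tree on the full training panel and reports its
#' training (fitted) confusion matrix — the tree analogue of a Table of
#' cross-validated projection classifiers, reported fitted-only because the
#' tree's structure changes under resampling.
#'
#' @param panel Labeled \code{metabolite_panel}.
#' @param spec A CART \code{classifier_spec}.
#' @param seed Seed for the pruning cross-validation folds.
#' @return List with \code{tree}, \code{confusion}, \code{rows} (one-row
#'   data frame in report layout).
#' @export
cart_fitted_report <- function(panel, spec = classifier_spec("CART"), seed) {
  sub <- subset_panel(panel, variables = spec_subset(spec, panel))
  tree <- select_tree_cv(sub, folds = 10, seed = seed,
                         min_split = spec$min_split)
  calls <- predict_tree(tree, sub)
  cm <- confusion_from_calls(calls, sub$labels)
  used <- sort(unique(stats::na.omit(tree$nodes$variable[
    !(tree$nodes$id %in% attr(tree$nodes, "dropped"))])))
  rows <- data.frame(classifier = "CART",
                     variables = paste(used, collapse = "+"),
                     beta = NA_real_, TP = cm$TP, FP = cm$FP, FN = cm$FN,
                     TN = cm$TN, c_statistic = NA_real_)
  list(tree = tree, confusion = cm, rows = rows)
}

#' Exhaustive variable-subset search by fitted C-statistic
#'
#' Evaluates every size-k combination of panel variables by fitting the
#' spec's model (FDA or LR) on the full training panel and computing the
#' fitted KDE C-statistic of its scores; the combination with the highest
#' C-statistic wins, ties breaking lexicographically by variable indices.
#'
#' @param panel Labeled training \code{metabolite_panel}.
#' @param spec An FDA or LR \code{classifier_spec} (its subset field is
#'   ignored; the search supplies subsets).
#' @param k Subset size, 1 <= k <= number of panel variables.
#' @return A \code{subset_result}: list with \code{k}, \code{best_subset},
#'   \code{c_statistic}, \code{n_evaluated}.
#' @export
exhaustive_subset_search <- function(panel, spec, k) {
  if (!spec$method %in% c("FDA", "LR")) {
    stop("subset search is defined for FDA and LR specs")
  }
  vars <- panel_variables(panel)
  p <- length(vars)
  if (k < 1 || k > p) stop("k must be between 1 and the number of variables")
  combos <- utils::combn(p, k)
  eval_one <- if (spec$method == "FDA") {
    fda_search_evaluator(panel, spec)
  } else {
    function(idx) fitted_c_for_subset(panel, spec, vars[idx])
  }
  best_c <- -Inf
  best_idx <- NULL
  for (j in seq_len(ncol(combos))) {
    cs <- eval_one(combos[, j])
    if (cs > best_c + 1e-12) {   # strict improvement; ties keep the earlier
      best_c <- cs               # (lexicographically smaller) combination
      best_idx <- combos[, j]
    }
  }
  structure(list(k = k, best_subset = vars[best_idx], c_statistic = best_c,
                 n_evaluated = ncol(combos)),
            class = "subset_result")
}

# Fast FDA evaluator for the exhaustive search. Standardization is
# per-variable and the pooled within-class scatter of a subset is the
# corresponding submatrix of the full-panel scatter, so both are computed
# once; each candidate subset then costs one small linear solve plus the
# KDE C-statistic. Numerically identical to fit_fda_direction + project +
# fit_score_densities + c_statistic on that subset.
fda_search_evaluator <- function(panel, spec) {
  std <- fit_standardization(panel)
  z <- apply_standardization(panel, std)$values
  is_asd <- panel$labels == "ASD"
  asd <- z[is_asd, , drop = FALSE]
  td <- z[!is_asd, , drop = FALSE]
  dmu_full <- colMeans(asd) - colMeans(td)
  sw_full <- crossprod(sweep(asd, 2, colMeans(asd))) +
    crossprod(sweep(td, 2, colMeans(td)))
  function(idx) {
    sw <- sw_full[idx, idx, drop = FALSE]
    dmu <- dmu_full[idx]
    lambda <- 1e-6 * sum(diag(sw)) / length(idx)
    w <- solve(sw + diag(lambda, length(idx)), dmu)
    w <- w / sqrt(sum(w^2))
    s <- drop(z[, idx, drop = FALSE] %*% w)
    if (mean(s[is_asd]) < mean(s[!is_asd])) s <- -s
    pair <- fit_score_densities(s, panel$labels,
                                bandwidth_rule = spec$bandwidth_rule)
    c_statistic(pair)
  }
}

fitted_c_for_subset <- function(panel, spec, subset) {
  model <- switch(spec$method,
                  FDA = fit_fda_direction(panel, subset),
                  LR = fit_logistic(panel, subset, ridge = spec$ridge))
  scores <- project(panel, model)
  c_statistic(fit_score_densities(scores, panel$labels,
                                  bandwidth_rule = spec$bandwidth_rule))
}

#' Saturation curve of the best fitted C-statistic over subset sizes
#'
#' Runs the exhaustive search for k = 1..k_max and reports the best fitted
#' C-statistic per size. The saturation size is the smallest k whose
#' increment to k+1 falls below \code{delta}; \code{NA} if no increment
#' does. Because each size is searched exhaustively the curve should be
#' non-decreasing up to numerical KDE effects; any observed decrease is
#' flagged in the result.
#'
#' @param panel Labeled training \code{metabolite_panel}.
#' @param spec An FDA or LR \code{classifier_spec}.
#' @param k_max Largest subset size to search.
#' @param delta Saturation tolerance in fitted-C units (default 0.005).
#' @return List with \code{results} (list of \code{subset_result}),
#'   \code{curve} (data frame k / c_statistic / best subset),
#'   \code{saturation_k}, \code{decreasing} (logical flag).
#' @export
saturation_curve <- function(panel, spec, k_max, delta = 0.005) {
  if (k_max > length(panel_variables(panel))) stop("k_max exceeds panel size")
  results <- lapply(seq_len(k_max), function(k) {
    exhaustive_subset_search(panel, spec, k)
  })
  cs <- vapply(results, function(r) r$c_statistic, numeric(1))
  inc <- diff(cs)
  sat <- which(inc < delta)
  data <- data.frame(k = seq_len(k_max), c_statistic = cs,
                     subset = vapply(results, function(r) {
                       paste(r$best_subset, collapse = "+")
                     }, character(1)))
  list(results = results, curve = data,
       saturation_k = if (length(sat) > 0) sat[1] else NA_integer_,
       decreasing = any(inc < -1e-9))
}

#' External validation of a fitted classifier on a case-only cohort
#'
#' Fits the spec once on the full training cohort (standardization, model,
#' densities, thresholds — nothing refit on the validation data) and scores
#' the validation cohort at each beta. The validation cohort contains only
#' participants with an ASD diagnosis, so only true positives and false
#' negatives are defined; UNKNOWN labels are treated as ASD.
#'
#' @param train Labeled training \code{metabolite_panel}.
#' @param validation Validation \code{metabolite_panel} (labels all ASD or
#'   UNKNOWN).
#' @param spec A projection-method \code{classifier_spec}, or a
#'   \code{fitted_classifier} to reuse.
#' @param betas Nominal levels.
#' @return An \code{evaluation_report} whose rows have \code{TP}, \code{FN}
#'   and \code{NA} for the control cells; \code{TP + FN} equals the
#'   validation cohort size for every beta.
#' @export
external_validation <- function(train, validation, spec,
                                betas = default_betas()) {
  if (any(validation$labels == "TD")) {
    stop("the external validation harness expects a case-only cohort")
  }
  fc <- if (inherits(spec, "fitted_classifier")) spec
        else fit_classifier(train, spec, betas)
  scores <- project(validation, fc$model)
  rows <- do.call(rbind, lapply(seq_along(betas), function(b) {
    rule <- fc$rules[[format_beta(betas[b])]]
    if (is.null(rule)) rule <- calibrate_threshold(fc$pair$td, betas[b],
                                                   policy = fc$spec$policy,
                                                   pair = fc$pair)
    calls <- classify_scores(scores, rule)
    data.frame(classifier = fc$spec$method,
               variables = paste(fc$model$subset, collapse = "+"),
               beta = betas[b], TP = sum(calls == "ASD"), FP = NA_integer_,
               FN = sum(calls == "TD"), TN = NA_integer_,
               c_statistic = fc$c_statistic)
  }))
  structure(list(rows = rows, fitted_c = fc$c_statistic, scores = scores),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as tidy CSV
#'
#' Columns: classifier, variables, beta, TP, FP, FN, TN, c_statistic — one
#' row per (classifier, beta).
#'
#' @param rows Data frame of report rows (e.g. rbind of
#'   \code{evaluation_report$rows}).
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
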