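#' Classification trees by recursive partitioning
#'
#' A minimal two-class CART: nodes are split on single-variable thresholds
#' chosen to maximize the Gini impurity decrease, the grown tree is pruned by
#' weakest-link cost-complexity pruning, and the complexity parameter
#' \eqn{\alpha} is selected by stratified 10-fold cross-validation. Trees are
#' stored as a flat data frame of nodes (one row per node) inside a
#' \code{classification_tree} object.
#'
#' Conventions: samples with \code{value < threshold} route left and
#' \code{value >= threshold} route right; candidate thresholds are midpoints
#' between consecutive sorted unique values; split ties break to the lower
#' variable index, then the lower threshold; a leaf's label is its majority
#' class with ties going to TD.
#'
#' @name classification_tree
NULL

#' Gini impurity of a two-class node
#'
#' \code{2 p (1 - p)} where \code{p} is the ASD proportion; 0 for a pure
#' node, 0.5 at a 50/50 split.
#'
#' @param n_asd,n_td Nonnegative class counts; total must be >= 1.
#' @return Impurity in [0, 0.5].
#' @export
gini_impurity <- function(n_asd, n_td) {
  n <- n_asd + n_td
  if (n < 1) stop("empty node has no impurity")
  p <- n_asd / n
  2 * p * (1 - p)
}

#' Best single split of a node
#'
#' Scans every variable and every midpoint between consecutive sorted unique
#' values, maximizing the impurity decrease
#' \eqn{\Delta i = i(\tau) - p_L i(\tau_L) - p_R i(\tau_R)}. Returns
#' \code{NULL} when no split strictly decreases impurity.
#'
#' @param values Numeric matrix of the node's samples (rows) by variables.
#' @param labels Class labels aligned with rows.
#' @return \code{NULL}, or a list with \code{variable}, \code{threshold},
#'   \code{decrease}.
#' @export
best_split <- function(values, labels) {
  n <- nrow(values)
  y <- labels == "ASD"
  n_asd <- sum(y)
  i_parent <- gini_impurity(n_asd, n - n_asd)
  if (i_parent == 0 || n < 2) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    distinct <- which(diff(xs) > 0)          # split after these positions
    if (length(distinct) == 0) next
    cum_asd <- cumsum(ys)
    nl <- distinct
    al <- cum_asd[distinct]                  # ASD count left of the cut
    ar <- n_asd - al
    nr <- n - nl
    pl_asd <- al / nl
    pr_asd <- ar / nr
    il <- 2 * pl_asd * (1 - pl_asd)
    ir <- 2 * pr_asd * (1 - pr_asd)
    dec <- i_parent - (nl / n) * il - (nr / n) * ir
    k <- which.max(dec)                      # first max = lowest threshold
    if (dec[k] > 1e-12 &&
        (is.null(best) || dec[k] > best$decrease + 1e-12)) {
      best <- list(variable = colnames(values)[j],
                   threshold = (xs[distinct[k]] + xs[distinct[k] + 1]) / 2,
                   decrease = dec[k])
    }
  }
  best
}

#' Grow a classification tree
#'
#' Recursive partitioning with Gini splits. A node becomes terminal when it
#' is pure, holds fewer than \code{min_split} samples, or admits no
#' impurity-decreasing split. The default \code{min_split = 8} reflects the
#' small-cohort setting this tree is built for.
#'
#' @param panel A labeled \code{metabolite_panel} (no UNKNOWN labels).
#' @param min_split Minimum node size eligible for splitting.
#' @return A \code{classification_tree}: list with \code{nodes} (data frame:
#'   \code{id, parent, left, right, variable, threshold, n, n_asd, n_td,
#'   label, is_leaf}), \code{variables}, \code{n_total}.
#' @export
grow_tree <- function(panel, min_split = 8) {
  validate_panel(panel)
  if (any(panel$labels == "UNKNOWN")) stop("grow_tree requires labeled samples")
  values <- panel$values
  labels <- panel$labels
  nodes <- list()
  grow <- function(idx, parent) {
    id <- length(nodes) + 1L
    n_asd <- sum(labels[idx] == "ASD")
    n_td <- length(idx) - n_asd
    # majority label, tie -> TD
    label <- if (n_asd > n_td) "ASD" else "TD"
    node <- list(id = id, parent = parent, left = NA_integer_,
                 right = NA_integer_, variable = NA_character_,
                 threshold = NA_real_, n = length(idx), n_asd = n_asd,
                 n_td = n_td, label = label, is_leaf = TRUE)
    nodes[[id]] <<- node
    if (length(idx) >= min_split && n_asd > 0 && n_td > 0) {
      sp <- best_split(values[idx, , drop = FALSE], labels[idx])
      if (!is.null(sp)) {
        go_left <- values[idx, sp$variable] < sp$threshold
        left_id <- grow(idx[go_left], id)
        right_id <- grow(idx[!go_left], id)
        nodes[[id]]$left <<- left_id
        nodes[[id]]$right <<- right_id
        nodes[[id]]$variable <<- sp$variable
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$is_leaf <<- FALSE
      }
    }
    id
  }
  grow(seq_len(nrow(values)), NA_integer_)
  structure(list(nodes = do.call(rbind, lapply(nodes, as.data.frame)),
                 variables = colnames(values), n_total = nrow(values)),
            class = "classification_tree")
}

#' @export
print.classification_tree <- function(x, ...) {
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Serialize a tree to indented text
#'
#' One node per line: id, split rule or leaf label, class counts. Sufficient
#' to reproduce a tree diagram by hand.
#'
#' @param tree A \code{classification_tree}.
#' @param id,depth Internal recursion arguments.
#' @return Character vector of lines.
#' @export
format_tree <- function(tree, id = 1L, depth = 0L) {
  nd <- tree$nodes[id, ]
  pad <- strrep("  ", depth)
  if (nd$is_leaf) {
    sprintf("%s[%d] leaf %s (ASD=%d, TD=%d)", pad, nd$id, nd$label,
            nd$n_asd, nd$n_td)
  } else {
    c(sprintf("%s[%d] %s < %.6g ? (ASD=%d, TD=%d)", pad, nd$id, nd$variable,
              nd$threshold, nd$n_asd, nd$n_td),
      format_tree(tree, nd$left, depth + 1L),
      format_tree(tree, nd$right, depth + 1L))
  }
}

#' Predict class labels with a tree
#'
#' Routes each sample from the root: left when \code{value < threshold},
#' right when \code{value >= threshold} (a value exactly at the threshold
#' goes right).
#'
#' @param tree A \code{classification_tree}.
#' @param panel A \code{metabolite_panel} containing every split variable.
#' @return Character vector of \code{"ASD"}/\code{"TD"} labels.
#' @export
predict_tree <- function(tree, panel) {
  used <- stats::na.omit(unique(tree$nodes$variable))
  missing <- setdiff(used, panel_variables(panel))
  if (length(missing) > 0) {
    stop("panel is missing split variable(s): ", paste(missing, collapse = ", "))
  }
  nodes <- tree$nodes
  vapply(seq_len(n_samples(panel)), function(i) {
    id <- 1L
    while (!nodes$is_leaf[id]) {
      v <- panel$values[i, nodes$variable[id]]
      id <- if (v < nodes$threshold[id]) nodes$left[id] else nodes$right[id]
    }
    nodes$label[id]
  }, character(1))
}

# ---- cost-complexity pruning ------------------------------------------------

# ids of the subtree rooted at `id` (including id)
branch_ids <- function(nodes, id) {
  out <- id
  if (!nodes$is_leaf[id]) {
    out <- c(out, branch_ids(nodes, nodes$left[id]),
             branch_ids(nodes, nodes$right[id]))
  }
  out
}

# training risk (misclassification count / n_total) and leaf count of the
# branch rooted at id, under the current leaf structure
branch_stats <- function(nodes, id, n_total) {
  ids <- branch_ids(nodes, id)
  leaves <- ids[nodes$is_leaf[ids]]
  err <- sum(ifelse(nodes$label[leaves] == "ASD",
                    nodes$n_td[leaves], nodes$n_asd[leaves]))
  list(risk = err / n_total, n_leaves = length(leaves))
}

node_as_leaf_risk <- function(nodes, id, n_total) {
  ifelse(nodes$label[id] == "ASD", nodes$n_td[id], nodes$n_asd[id]) / n_total
}

collapse_node <- function(nodes, id) {
  drop_ids <- setdiff(branch_ids(nodes, id), id)
  nodes$is_leaf[id] <- TRUE
  nodes$left[id] <- NA_integer_
  nodes$right[id] <- NA_integer_
  nodes$variable[id] <- NA_character_
  nodes$threshold[id] <- NA_real_
  # keep dropped rows (ids must stay stable) but detach them
  nodes$parent[drop_ids] <- NA_integer_
  attr(nodes, "dropped") <- union(attr(nodes, "dropped"), drop_ids)
  nodes
}

prune_to <- function(tree, keep_internal) {
  nodes <- tree$nodes
  internal <- nodes$id[!nodes$is_leaf]
  for (id in setdiff(internal, keep_internal)) {
    # only collapse if still reachable (ancestor not already collapsed)
    if (!nodes$is_leaf[id]) nodes <- collapse_node(nodes, id)
  }
  tree$nodes <- nodes
  tree
}

#' Cost-complexity pruning path
#'
#' Weakest-link pruning: repeatedly collapse the internal node with the
#' smallest \eqn{g = (R(\mathrm{leaf}) - R(\mathrm{branch})) /
#' (|\mathrm{leaves}| - 1)}, where \eqn{R} is the training misclassification
#' proportion. Each collapse defines a critical \eqn{\alpha}; the sequence of
#' pruned subtrees is exactly the set of minimizers of
#' \eqn{R_\alpha(T) = R(T) + \alpha |T|} as \eqn{\alpha} grows from 0.
#'
#' @param tree A grown \code{classification_tree}.
#' @return A \code{complexity_path}: list of entries with \code{alpha}
#'   (interval start), \code{tree} (pruned subtree), \code{n_leaves},
#'   \code{risk} (training misclassification proportion). Alphas strictly
#'   increase, leaf counts strictly decrease, the last entry is root-only.
#' @export
prune_path <- function(tree) {
  current <- tree
  path <- list()
  alpha_prev <- 0
  repeat {
    nodes <- current$nodes
    rs <- branch_stats(nodes, 1L, tree$n_total)
    path[[length(path) + 1]] <- list(alpha = alpha_prev, tree = current,
                                     n_leaves = rs$n_leaves, risk = rs$risk)
    internal <- nodes$id[!nodes$is_leaf & !(nodes$id %in% attr(nodes, "dropped"))]
    internal <- internal[!is.na(nodes$parent[internal]) | internal == 1L]
    if (length(internal) == 0) break
    g <- vapply(internal, function(id) {
      bs <- branch_stats(nodes, id, tree$n_total)
      (node_as_leaf_risk(nodes, id, tree$n_total) - bs$risk) /
        (bs$n_leaves - 1)
    }, numeric(1))
    g_min <- min(g)
    # collapse every node achieving the minimal g (standard weakest-link)
    for (id in internal[g <= g_min + 1e-12]) {
      if (!nodes$is_leaf[id]) nodes <- collapse_node(nodes, id)
    }
    current$nodes <- nodes
    alpha_prev <- max(g_min, alpha_prev)  # guards tiny negative rounding
  }
  # several collapses can share a critical alpha (e.g. splits with zero
  # risk improvement collapse already at alpha = 0); keep only the
  # smallest subtree per distinct alpha so alphas strictly increase
  alphas <- vapply(path, function(e) e$alpha, numeric(1))
  keep <- vapply(seq_along(alphas), function(i) {
    i == length(alphas) || alphas[i + 1] > alphas[i] + 1e-15
  }, logical(1))
  structure(path[keep], class = "complexity_path")
}

#' Subtree of a pruning path minimizing penalized risk at a given alpha
#'
#' @param path A \code{complexity_path}.
#' @param alpha Complexity penalty per terminal node.
#' @return The \code{classification_tree} from the path minimizing
#'   \code{risk + alpha * n_leaves} (ties to the smaller tree).
#' @export
path_tree_at <- function(path, alpha) {
  pen <- vapply(path, function(e) e$risk + alpha * e$n_leaves, numeric(1))
  leaves <- vapply(path, function(e) e$n_leaves, numeric(1))
  best <- which(pen <= min(pen) + 1e-12)
  path[[best[which.min(leaves[best])]]]$tree
}

#' Select a pruned tree by cross-validated cost-complexity
#'
#' Grows the full-data tree and its pruning path, estimates cross-validated
#' misclassification risk at the geometric midpoints of the path's alpha
#' intervals using stratified k-fold cross-validation (each fold grows and
#' prunes its own tree), and returns the full-data path subtree at the
#' selected alpha. Deterministic given \code{(panel, seed)}.
#'
#' Two selection rules are provided. \code{"1se"} (default) takes the
#' largest alpha whose cross-validated risk is within one standard error
#' of the minimum — the standard guard against the optimism of minimizing
#' a noisy risk curve over many candidate alphas, without which
#' spurious structure survives pruning on label-independent data.
#' \code{"min"} takes the risk-minimizing alpha outright (ties toward the
#' larger alpha).
#'
#' @param panel A labeled \code{metabolite_panel}.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the stratified fold assignment (mandatory).
#' @param min_split Passed to \code{\link{grow_tree}}.
#' @param rule Alpha selection rule: \code{"1se"} or \code{"min"}.
#' @return A \code{classification_tree} with attributes \code{alpha} and
#'   \code{cv_risk}.
#' @export
select_tree_cv <- function(panel, folds = 10, seed, min_split = 8,
                           rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (missing(seed)) stop("select_tree_cv requires an explicit seed")
  n <- n_samples(panel)
  if (n < folds) stop("fewer samples than folds")
  full <- grow_tree(panel, min_split = min_split)
  path <- prune_path(full)
  alphas <- vapply(path, function(e) e$alpha, numeric(1))
  if (length(alphas) == 1) return(path[[1]]$tree)
  # geometric interval midpoints; first interval starts at 0, last is open
  test_alphas <- unique(c(0, sqrt(pmax(alphas[-length(alphas)], 1e-12) *
                                    alphas[-1]),
                          alphas[length(alphas)] + 1))
  fold_of <- stratified_folds(panel$labels, folds, seed)
  errs <- matrix(0, nrow = folds, ncol = length(test_alphas))
  for (f in seq_len(folds)) {
    hold <- fold_of == f
    train <- subset_panel(panel, samples = !hold)
    if (length(unique(train$labels)) < 2) {
      stop(sprintf("fold %d removes an entire class", f))
    }
    ft <- grow_tree(train, min_split = min_split)
    fp <- prune_path(ft)
    test <- subset_panel(panel, samples = hold)
    for (a in seq_along(test_alphas)) {
      pred <- predict_tree(path_tree_at(fp, test_alphas[a]), test)
      errs[f, a] <- sum(pred != test$labels)
    }
  }
  cv_risk <- colSums(errs) / n
  threshold <- if (rule == "1se") {
    r_min <- min(cv_risk)
    r_min + sqrt(r_min * (1 - r_min) / n)
  } else {
    min(cv_risk)
  }
  # largest alpha within the threshold (simplest admissible tree)
  best <- max(which(cv_risk <= threshold + 1e-12))
  selected <- path_tree_at(path, test_alphas[best])
  attr(selected, "alpha") <- test_alphas[best]
  attr(selected, "cv_risk") <- cv_risk[best]
  selected
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin. Deterministic given (labels, folds, seed); leaves the
# caller's RNG state untouched.
stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}
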