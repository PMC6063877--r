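# Independent brute-force oracles shared by the unit and acceptance tests.
# These deliberately re-derive results by enumeration or closed form,
# never by calling the code paths they check.

# Exhaustive double loop over every (variable, midpoint) candidate split.
oracle_best_split <- function(values, labels) {
  n <- nrow(values)
  y <- labels == "ASD"
  gini <- function(m) {
    p <- sum(m) / length(m)
    2 * p * (1 - p)
  }
  parent <- gini(y)
  best <- NULL
  for (j in seq_len(ncol(values))) {
    ux <- sort(unique(values[, j]))
    if (length(ux) < 2) next
    for (t in (ux[-1] + ux[-length(ux)]) / 2) {
      left <- values[, j] < t
      dec <- parent - mean(left) * gini(y[left]) -
        mean(!left) * gini(y[!left])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(variable = colnames(values)[j], threshold = t,
                     decrease = dec)
      }
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

# Every pruned subtree of a small tree, as (risk, n_leaves) pairs.
enumerate_subtrees <- function(tree) {
  nodes <- tree$nodes
  internal <- nodes$id[!nodes$is_leaf]
  out <- list()
  for (k in 0:length(internal)) {
    for (sel in if (k == 0) list(integer(0)) else
         asplit(combn(internal, k), 2)) {
      pruned <- focmpanel:::prune_to(tree, setdiff(internal, sel))
      st <- focmpanel:::branch_stats(pruned$nodes, 1L, tree$n_total)
      out[[length(out) + 1]] <- list(risk = st$risk, n_leaves = st$n_leaves)
    }
  }
  out
}

# Fisher direction as the top eigenvector of Sw_reg^-1 Sb, via a dense
# eigendecomposition of the (standardized) panel's scatter matrices.
oracle_fda_direction <- function(panel) {
  z <- scale(panel$values)
  a <- z[panel$labels == "ASD", , drop = FALSE]
  t <- z[panel$labels == "TD", , drop = FALSE]
  dmu <- colMeans(a) - colMeans(t)
  sw <- crossprod(sweep(a, 2, colMeans(a))) +
    crossprod(sweep(t, 2, colMeans(t)))
  sw <- sw + diag(1e-6 * sum(diag(sw)) / ncol(z), ncol(z))
  sb <- outer(dmu, dmu)
  eg <- eigen(solve(sw) %*% sb)
  v <- Re(eg$vectors[, which.max(Re(eg$values))])
  v / sqrt(sum(v^2))
}
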