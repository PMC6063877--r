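#' Save / load a projection model as flat key-value text
#'
#' A plain-text, diff-friendly serialization of a \code{projection_model}
#' (method, subset, weights, intercept, standardization) so that a model
#' fitted on one cohort can be reused by the validation harness in a later
#' session.
#'
#' @param model A \code{projection_model}.
#' @param path Output file path.
#' @return \code{write_model}: invisibly, \code{path}; \code{read_model}:
#'   the reconstructed \code{projection_model}.
#' @export
write_model <- function(model, path) {
  num <- function(x) paste(format(x, digits = 17), collapse = ",")
  lines <- c(
    paste0("method=", model$method),
    paste0("subset=", paste(model$subset, collapse = ",")),
    paste0("weights=", num(model$weights)),
    paste0("intercept=", num(model$intercept)),
    paste0("center=", num(model$standardization$center[model$subset])),
    paste0("scale=", num(model$standardization$scale[model$subset])),
    paste0("flipped=", model$flipped),
    paste0("converged=", model$converged)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  subset <- strsplit(vals[["subset"]], ",", fixed = TRUE)[[1]]
  nums <- function(key) as.numeric(strsplit(vals[[key]], ",", fixed = TRUE)[[1]])
  std <- structure(list(center = stats::setNames(nums("center"), subset),
                        scale = stats::setNames(nums("scale"), subset)),
                   class = "standardization_params")
  new_projection_model(vals[["method"]], subset, nums("weights"),
                       nums("intercept"), std,
                       flipped = as.logical(vals[["flipped"]]),
                       converged = as.logical(vals[["converged"]]))
}

#' Save a classification tree as indented text
#'
#' @param tree A \code{classification_tree}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_tree <- function(tree, path) {
  writeLines(format_tree(tree), path)
  invisible(path)
}
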