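#' Construct a metabolite panel
#'
#' A \code{metabolite_panel} holds one row of continuous metabolite
#' measurements per participant together with a class label per participant
#' (\code{ASD}, \code{TD}, or \code{UNKNOWN}). It is the universal container
#' passed between every stage of the pipeline: simulation, standardization,
#' classifier fitting, cross-validation, and external validation.
#'
#' @param values Numeric matrix, one row per participant and one column per
#'   variable. Column names are taken as variable ids when \code{variable_ids}
#'   is missing.
#' @param labels Character vector of class labels, one per row of
#'   \code{values}. Matched case-insensitively against \code{ASD}, \code{TD},
#'   \code{UNKNOWN}.
#' @param sample_ids Optional character vector of unique participant ids;
#'   defaults to \code{s1..sn}.
#' @param variable_ids Optional character vector of variable ids overriding
#'   the column names of \code{values}.
#' @return An object of class \code{metabolite_panel}: a list with elements
#'   \code{values} (matrix with sample ids as rownames and variable ids as
#'   colnames) and \code{labels}.
#' @export
metabolite_panel <- function(values, labels, sample_ids = NULL,
                             variable_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(variable_ids)) colnames(values) <- variable_ids
  if (is.null(colnames(values))) {
    stop("metabolite_panel: variable ids are required (column names or `variable_ids`)")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (nrow(values) > 0) rownames(values) <- sample_ids
  labels <- normalize_labels(labels, nrow(values))
  panel <- structure(list(values = values, labels = labels),
                     class = "metabolite_panel")
  validate_panel(panel)
  panel
}

normalize_labels <- function(labels, n) {
  labels <- toupper(trimws(as.character(labels)))
  if (length(labels) != n) {
    stop(sprintf("label count (%d) does not match sample count (%d)",
                 length(labels), n))
  }
  labels[labels == "" | is.na(labels)] <- "UNKNOWN"
  bad <- setdiff(unique(labels), PANEL_LABELS)
  if (length(bad) > 0) {
    stop("unrecognized class label(s): ", paste(bad, collapse = ", "))
  }
  labels
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "metabolite_panel"))
  v <- panel$values
  if (anyDuplicated(colnames(v))) stop("duplicate variable ids in panel")
  if (anyDuplicated(rownames(v))) stop("duplicate sample ids in panel")
  if (length(panel$labels) != nrow(v)) stop("label/sample count mismatch")
  if (nrow(v) > 0 && !all(is.finite(v))) {
    stop("panel contains non-finite values (missing data are not supported)")
  }
  invisible(panel)
}

#' @export
print.metabolite_panel <- function(x, ...) {
  tab <- table(factor(x$labels, levels = PANEL_LABELS))
  cat(sprintf("metabolite_panel: %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.metabolite_panel <- function(x) dim(x$values)

#' Number of samples / variable ids of a panel
#' @param panel A \code{metabolite_panel}.
#' @return \code{n_samples}: integer count; \code{panel_variables}: character
#'   vector of variable ids in panel order.
#' @export
n_samples <- function(panel) nrow(panel$values)

#' @rdname n_samples
#' @export
panel_variables <- function(panel) colnames(panel$values)

#' Subset a panel by samples and/or variables
#'
#' @param panel A \code{metabolite_panel}.
#' @param samples Row index (integer/logical) of samples to keep.
#' @param variables Character vector of variable ids to keep (in the given
#'   order).
#' @return A \code{metabolite_panel}.
#' @export
subset_panel <- function(panel, samples = NULL, variables = NULL) {
  v <- panel$values
  lab <- panel$labels
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    lab <- lab[samples]
  }
  if (!is.null(variables)) {
    missing <- setdiff(variables, colnames(v))
    if (length(missing) > 0) {
      stop("panel is missing variable(s): ", paste(missing, collapse = ", "))
    }
    v <- v[, variables, drop = FALSE]
  }
  metabolite_panel(v, lab)
}

#' Read a metabolite panel from CSV
#'
#' Expects an RFC-4180-style CSV with a header row naming the panel variables
#' plus a \code{label} column. Variables are reordered to \code{schema} order;
#' extra columns are dropped with a warning; a missing schema variable is an
#' error. Labels are matched case-insensitively; empty labels become
#' \code{UNKNOWN}. Any non-numeric or missing measurement is an error — no
#' silent imputation.
#'
#' @param path Path to a CSV file.
#' @param schema Character vector of required variable ids, in canonical
#'   order. Defaults to the 22-variable FOCM/TS panel.
#' @return A \code{metabolite_panel}.
#' @export
read_panel <- function(path, schema = focm_variable_ids()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"label" %in% names(df)) stop("panel CSV must contain a 'label' column")
  missing <- setdiff(schema, names(df))
  if (length(missing) > 0) {
    stop("panel CSV is missing required variable(s): ",
         paste(missing, collapse = ", "))
  }
  id_col <- if ("sample_id" %in% names(df)) df$sample_id else NULL
  extra <- setdiff(names(df), c(schema, "label", "sample_id"))
  if (length(extra) > 0) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  vals <- as.matrix(df[, schema, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, schema)))
  if (nrow(num) > 0 && any(!is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row %d, variable %s",
                 bad[1], schema[bad[2]]))
  }
  metabolite_panel(num, labels = df$label, sample_ids = id_col)
}

#' Write a metabolite panel to CSV
#'
#' Writes a header row (\code{sample_id}, variables in panel order,
#' \code{label} last), one row per sample, at full double precision so that a
#' read/write round trip is value-identical within float printing precision.
#'
#' @param panel A \code{metabolite_panel}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  df <- data.frame(sample_id = rownames(panel$values),
                   as.data.frame(panel$values),
                   label = panel$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit per-variable standardization parameters
#'
#' Computes per-variable centers (sample means) and scales (sample standard
#' deviations, unbiased n-1 denominator) on the fitting panel only. Applying
#' the result to another cohort never uses that cohort's statistics, which is
#' what keeps cross-validation and external validation leak-free.
#'
#' @param panel A \code{metabolite_panel} with at least 2 samples.
#' @param variables Variable ids to fit; defaults to all panel variables.
#' @return An object of class \code{standardization_params}: list with named
#'   numeric vectors \code{center} and \code{scale}.
#' @export
fit_standardization <- function(panel, variables = panel_variables(panel)) {
  v <- panel$values[, variables, drop = FALSE]
  if (nrow(v) < 2) stop("standardization requires at least 2 samples")
  center <- colMeans(v)
  scale <- apply(v, 2, stats::sd)
  degenerate <- !is.finite(scale) | scale <= 0
  if (any(degenerate)) {
    stop("constant (zero-variance) variable(s): ",
         paste(variables[degenerate], collapse = ", "))
  }
  structure(list(center = center, scale = scale),
            class = "standardization_params")
}

#' Apply standardization parameters to a panel
#'
#' @param panel A \code{metabolite_panel} whose variables are all covered by
#'   \code{params}.
#' @param params A \code{standardization_params} object (typically fitted on a
#'   training cohort).
#' @return A \code{metabolite_panel} with values
#'   \code{(value - center) / scale}; labels unchanged.
#' @export
apply_standardization <- function(panel, params) {
  vars <- panel_variables(panel)
  missing <- setdiff(vars, names(params$center))
  if (length(missing) > 0) {
    stop("no standardization parameters for variable(s): ",
         paste(missing, collapse = ", "))
  }
  v <- sweep(panel$values, 2, params$center[vars], "-")
  v <- sweep(v, 2, params$scale[vars], "/")
  metabolite_panel(v, panel$labels)
}
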