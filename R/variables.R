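#' Canonical FOCM/TS variable panel
#'
#' The 22-variable panel of folate-dependent one-carbon metabolism (FOCM) and
#' transsulfuration (TS) measurements used throughout this package. Variables
#' are identified by the ids \code{x1..x22}; five of them are derived
#' quantities (ratios or percentages) of other panel members.
#'
#' @return A data frame with columns \code{id} (ordered identifiers
#'   \code{x1..x22}) and \code{name} (display name of the metabolite or
#'   derived quantity).
#' @export
#' @examples
#' focm_variables()
focm_variables <- function() {
  data.frame(
    id = paste0("x", 1:22),
    name = c(
      "Methionine", "SAM", "SAH", "SAM/SAH", "Adenosine", "Homocysteine",
      "tCysteine", "Glu-Cys", "Cys-Gly", "tGSH", "fGSH", "GSSG",
      "fGSH/GSSG", "tGSH/GSSG", "3-ClT", "3-NT", "Tyrosine", "Tryptophane",
      "fCystine", "fCysteine", "fCystine/fCysteine", "% oxidized glutathione"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname focm_variables
#' @export
focm_variable_ids <- function() focm_variables()$id

# Class label tokens used throughout; UNKNOWN marks unlabeled samples
# (e.g. an external cohort scored without reference labels).
PANEL_LABELS <- c("ASD", "TD", "UNKNOWN")
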