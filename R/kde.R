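#' Gaussian kernel density estimate of classifier scores
#'
#' Fits a one-dimensional Gaussian-kernel density to a set of scores:
#' \deqn{\hat f(s) = \frac{1}{n h} \sum_i K\!\left(\frac{s - x_i}{h}\right)}
#' with the standard normal kernel \eqn{K}. The default bandwidth is
#' Silverman's rule of thumb with robust spread,
#' \eqn{h = 1.06\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\, n^{-1/5}}.
#'
#' @param scores Numeric vector of at least 2 finite values with nonzero
#'   spread.
#' @param bandwidth_rule Either the string \code{"silverman"} or a positive
#'   number forcing the bandwidth.
#' @param grid_size Number of evaluation points for numerical grids
#'   (normalization checks, C-statistic integration).
#' @param grid_pad Half-width of the evaluation grid beyond the support
#'   range, in bandwidth units.
#' @return An object of class \code{kernel_density} with elements
#'   \code{support} (the score values), \code{bw}, \code{grid_size},
#'   \code{grid_pad}.
#' @export
fit_kde <- function(scores, bandwidth_rule = "silverman",
                    grid_size = 2048, grid_pad = 5) {
  scores <- as.numeric(scores)
  if (length(scores) < 2 || !all(is.finite(scores))) {
    stop("fit_kde requires at least 2 finite scores")
  }
  if (is.numeric(bandwidth_rule)) {
    h <- bandwidth_rule
  } else if (identical(bandwidth_rule, "silverman")) {
    h <- bw_silverman(scores)
  } else {
    stop("unknown bandwidth rule: ", bandwidth_rule)
  }
  if (!is.finite(h) || h <= 0) {
    stop("degenerate sample: bandwidth is not positive (zero spread?)")
  }
  structure(list(support = scores, bw = h,
                 grid_size = grid_size, grid_pad = grid_pad),
            class = "kernel_density")
}

# Silverman's rule of thumb with robust spread min(sd, IQR/1.34); this is
# the same formula as stats::bw.nrd, written out so the robust-spread
# convention is explicit (quantile type 7).
bw_silverman <- function(x) {
  n <- length(x)
  spread <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (spread <= 0) spread <- stats::sd(x)  # IQR can be 0 with heavy ties
  1.06 * spread * n^(-1 / 5)
}

#' Evaluate a kernel density
#'
#' @param kde A \code{kernel_density}.
#' @param at Numeric vector of evaluation points.
#' @param other Optional second \code{kernel_density} whose support must
#'   also be covered by the grid (used for shared two-class grids).
#' @return \code{kde_pdf}: density values; \code{kde_cdf}: exact mixture CDF
#'   \eqn{\frac1n \sum_i \Phi((s - x_i)/h)}; \code{kde_grid}: the standard
#'   evaluation grid (support range padded by \code{grid_pad} bandwidths).
#' @export
kde_pdf <- function(kde, at) {
  kde_pdf_eval(as.numeric(at), kde$support, kde$bw)
}

#' @rdname kde_pdf
#' @export
kde_cdf <- function(kde, at) {
  kde_cdf_eval(as.numeric(at), kde$support, kde$bw)
}

#' @rdname kde_pdf
#' @export
kde_grid <- function(kde, other = NULL) {
  lo <- min(kde$support) - kde$grid_pad * kde$bw
  hi <- max(kde$support) + kde$grid_pad * kde$bw
  min_bw <- kde$bw
  if (!is.null(other)) {
    lo <- min(lo, min(other$support) - other$grid_pad * other$bw)
    hi <- max(hi, max(other$support) + other$grid_pad * other$bw)
    min_bw <- min(min_bw, other$bw)
  }
  # refine beyond the standard grid size when the bandwidth is narrower
  # than the grid spacing, so trapezoidal integrals stay accurate as
  # bandwidth -> 0 (capped to keep degenerate cases affordable)
  n <- max(kde$grid_size, min(2^19, ceiling(3 * (hi - lo) / min_bw)))
  seq(lo, hi, length.out = n)
}

# Trapezoidal integral on an equally spaced grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Fit per-class score densities
#'
#' Fits one Gaussian KDE to the ASD scores and one to the TD scores, after
#' enforcing the orientation convention that ASD scores lie on the high side:
#' if the mean ASD score is below the mean TD score, all scores are negated
#' and the \code{flipped} flag is set. Downstream one-sided thresholds then
#' always call the high side ASD.
#'
#' @param scores Numeric vector of per-sample classifier scores.
#' @param labels Class label per score (\code{ASD}/\code{TD}); at least 2 of
#'   each class.
#' @param ... Passed to \code{\link{fit_kde}}.
#' @return An object of class \code{score_density_pair}: list with
#'   \code{asd}, \code{td} (kernel densities), \code{flipped} (logical).
#' @export
fit_score_densities <- function(scores, labels, ...) {
  labels <- normalize_labels(labels, length(scores))
  asd <- scores[labels == "ASD"]
  td <- scores[labels == "TD"]
  if (length(asd) < 2 || length(td) < 2) {
    stop("fit_score_densities requires >= 2 scores in each class")
  }
  flipped <- mean(asd) < mean(td)
  if (flipped) {
    asd <- -asd
    td <- -td
  }
  structure(list(asd = fit_kde(asd, ...), td = fit_kde(td, ...),
                 flipped = flipped),
            class = "score_density_pair")
}

#' C-statistic of a score density pair
#'
#' The probability that a random draw from the ASD score density exceeds a
#' random draw from the TD score density — the KDE-smoothed analogue of the
#' area under the ROC curve. Computed by numerically integrating the TD CDF
#' against the ASD PDF on a shared trapezoidal grid spanning the pooled
#' support padded by 5 bandwidths.
#'
#' @param pair A \code{score_density_pair}.
#' @return A value in [0, 1].
#' @export
c_statistic <- function(pair) {
  grid <- kde_grid(pair$asd, pair$td)
  val <- c_statistic_eval(grid, sort(pair$asd$support), pair$asd$bw,
                          sort(pair$td$support), pair$td$bw)
  min(max(val, 0), 1)
}

#' Calibrate a one-sided decision threshold
#'
#' Under the default \code{td-quantile} policy the cut is placed so that the
#' upper-tail mass of the TD score density beyond the cut equals the nominal
#' level \code{beta}: the estimated probability that a typically-developing
#' participant is misclassified as ASD. Under the \code{posterior} policy the
#' cut solves \eqn{f_{TD}/(f_{TD}+f_{ASD}) = \beta} on the high-score side
#' (equal class priors); with a non-monotone posterior the largest crossing
#' is used and a warning is issued.
#'
#' @param td_density \code{kernel_density} of the TD scores.
#' @param beta Nominal level in (0, 1).
#' @param policy \code{"td-quantile"} or \code{"posterior"}.
#' @param pair Full \code{score_density_pair}; required for the posterior
#'   policy.
#' @return An object of class \code{threshold_rule}: list with \code{beta},
#'   \code{cut}, \code{policy}.
#' @export
calibrate_threshold <- function(td_density, beta, policy = "td-quantile",
                                pair = NULL) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta >= 1) {
    stop("beta must be a single value in (0, 1)")
  }
  if (identical(policy, "td-quantile")) {
    cut <- kde_quantile(td_density, 1 - beta)
  } else if (identical(policy, "posterior")) {
    if (is.null(pair)) stop("posterior policy requires the full density pair")
    cut <- posterior_cut(pair, beta)
  } else {
    stop("unknown threshold policy: ", policy)
  }
  structure(list(beta = beta, cut = cut, policy = policy),
            class = "threshold_rule")
}

# Quantile of the KDE mixture CDF by root finding; the mixture CDF is exact
# (average of normal CDFs), so the tail-mass identity holds to root-finder
# tolerance rather than grid resolution.
kde_quantile <- function(kde, p) {
  lo <- min(kde$support) - 10 * kde$bw
  hi <- max(kde$support) + 10 * kde$bw
  # expand until the target probability is bracketed (relevant for extreme p)
  while (kde_cdf(kde, lo) > p) lo <- lo - 10 * kde$bw
  while (kde_cdf(kde, hi) < p) hi <- hi + 10 * kde$bw
  stats::uniroot(function(s) kde_cdf(kde, s) - p, c(lo, hi),
                 tol = 1e-10 * max(1, kde$bw))$root
}

posterior_cut <- function(pair, beta) {
  grid <- kde_grid(pair$asd, pair$td)
  f_td <- kde_pdf(pair$td, grid)
  f_asd <- kde_pdf(pair$asd, grid)
  post_td <- f_td / (f_td + f_asd)
  post_td[!is.finite(post_td)] <- 0.5  # both densities underflow far out
  below <- post_td <= beta
  cross <- which(!below[-length(below)] & below[-1])
  if (length(cross) == 0) {
    # posterior never drops to beta: no score is confidently ASD
    return(max(grid))
  }
  if (length(cross) > 1) {
    warning("non-monotone posterior: using the largest crossing")
  }
  i <- cross[length(cross)]
  # linear interpolation between grid points straddling the crossing
  x0 <- grid[i]; x1 <- grid[i + 1]
  y0 <- post_td[i]; y1 <- post_td[i + 1]
  x0 + (beta - y0) * (x1 - x0) / (y1 - y0)
}

#' Classify scores with a calibrated threshold
#'
#' A score is called ASD iff it lies strictly above the cut; a score exactly
#' at the cut is called TD (the conservative tie rule: fewer false
#' positives).
#'
#' @param scores Numeric vector of oriented scores (high side = ASD).
#' @param rule A \code{threshold_rule}.
#' @return Character vector of \code{"ASD"}/\code{"TD"} calls.
#' @export
classify_scores <- function(scores, rule) {
  ifelse(scores > rule$cut, "ASD", "TD")
}

#' Export a density pair as a two-column table for plotting
#'
#' @param pair A \code{score_density_pair}.
#' @return A data frame with columns \code{score}, \code{class},
#'   \code{density} evaluated on the shared grid.
#' @export
density_pair_table <- function(pair) {
  grid <- kde_grid(pair$asd, pair$td)
  rbind(
    data.frame(score = grid, class = "ASD", density = kde_pdf(pair$asd, grid)),
    data.frame(score = grid, class = "TD", density = kde_pdf(pair$td, grid))
  )
}
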