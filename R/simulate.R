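#' Synthetic FOCM/TS cohort configuration
#'
#' Defines the generative model for a two-class metabolite cohort with known
#' ground truth. Base metabolites are log-normal: on the log scale each base
#' variable loads on one shared latent factor (equicorrelation \code{rho})
#' plus independent noise, giving strictly positive, correlated
#' concentrations. Derived panel members (the ratio variables of the
#' canonical panel, e.g. SAM/SAH) are computed mechanistically from their
#' parent metabolites, so they carry genuinely redundant information. Group
#' separation is injected only through the informative subset: each
#' informative variable receives a mean shift on the log scale, expressed in
#' units of that variable's own log-scale standard deviation; shifts on
#' ratio variables are realized by shifting a parent.
#'
#' The default effect magnitudes were fixed once by the calibration run in
#' \code{analysis/00_calibrate_effects.R} so that a default training cohort
#' shows the strong (but imperfect) fitted separation typical of published
#' FOCM/TS case-control panels; they are versioned constants, not tuning
#' knobs.
#'
#' @param n_asd,n_td Training cohort sizes (defaults 83 and 76).
#' @param n_validation Size of the case-only validation cohort (default 154).
#' @param variables Panel variable ids (default: the canonical 22).
#' @param informative Ids of the variables carrying group separation
#'   (default \code{x4, x8, x12, x21, x22}).
#' @param effects Named vector of standardized log-scale mean shifts
#'   (ASD minus TD), one per informative variable. Signs encode direction:
#'   negative = lower in ASD.
#' @param rho Latent-factor equicorrelation of the base metabolites in
#'   [0, 1).
#' @param sdlog Log-scale standard deviation shared by the base metabolites
#'   (0.4 corresponds to a ~40% coefficient of variation).
#' @param seed Master seed; all draws derive from it via substreams.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_asd = 83, n_td = 76, n_validation = 154,
                             variables = focm_variable_ids(),
                             informative = c("x4", "x8", "x12", "x21", "x22"),
                             effects = default_effects(informative),
                             rho = 0.4, sdlog = 0.4, seed = 1) {
  stopifnot(n_asd >= 2, n_td >= 2, n_validation >= 0,
            rho >= 0, rho < 1, sdlog > 0)
  ratios <- ratio_definitions()
  ratios <- ratios[names(ratios) %in% variables]
  base_vars <- setdiff(variables, names(ratios))
  for (r in names(ratios)) {
    parents <- c(ratios[[r]]$num, ratios[[r]]$den)
    if (!all(parents %in% base_vars)) {
      stop(sprintf("ratio variable %s needs parents %s in the panel",
                   r, paste(parents, collapse = ", ")))
    }
  }
  if (!all(informative %in% variables)) {
    stop("informative subset must be contained in the panel variables")
  }
  if (!setequal(names(effects), informative)) {
    stop("effects must be named by the informative variables")
  }
  structure(list(n_asd = n_asd, n_td = n_td, n_validation = n_validation,
                 variables = variables, base_vars = base_vars,
                 ratios = ratios, informative = informative,
                 effects = effects[informative], rho = rho, sdlog = sdlog,
                 seed = seed),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_effects <- function(informative = c("x4", "x8", "x12", "x21", "x22")) {
  # profile and scale fixed by analysis/00_calibrate_effects.R (see
  # vignette): one dominant redox marker (% oxidized glutathione) plus
  # four weaker contributors; signs: methylation capacity (SAM/SAH) and
  # Glu-Cys lower in cases, oxidized-glutathione measures higher.
  m <- 1.7
  full <- m * c(x4 = -0.7, x8 = -0.6, x12 = 1.0, x21 = 0.7, x22 = 1.35)
  if (!all(informative %in% names(full))) {
    stop("no default effect defined for: ",
         paste(setdiff(informative, names(full)), collapse = ", "))
  }
  full[informative]
}

# Derived panel members and their parent metabolites. `scale` multiplies the
# quotient (100 turns the GSSG/tGSH quotient into a percentage). The parents
# are always base metabolites, so the definition graph is acyclic by
# construction (validated in synthetic_config).
ratio_definitions <- function() {
  list(
    x4  = list(num = "x2",  den = "x3",  scale = 1),    # SAM/SAH
    x13 = list(num = "x11", den = "x12", scale = 1),    # fGSH/GSSG
    x14 = list(num = "x10", den = "x12", scale = 1),    # tGSH/GSSG
    x21 = list(num = "x19", den = "x20", scale = 1),    # fCystine/fCysteine
    x22 = list(num = "x12", den = "x10", scale = 100)   # % oxidized glutathione
  )
}

# Plausible baseline concentration levels (arbitrary units) for the base
# metabolites; only the log-scale geometry matters for classification.
base_levels <- function(base_vars) {
  lv <- c(x1 = 25, x2 = 90, x3 = 20, x5 = 0.3, x6 = 6, x7 = 200, x8 = 2.5,
          x9 = 40, x10 = 7, x11 = 2, x12 = 0.25, x15 = 0.05, x16 = 0.08,
          x17 = 60, x18 = 50, x19 = 30, x20 = 20)
  miss <- setdiff(base_vars, names(lv))
  out <- c(lv[intersect(names(lv), base_vars)],
           stats::setNames(rep(10, length(miss)), miss))
  out[base_vars]
}

# Latent-scale (log) ground truth implied by a config: per-class mean
# vectors over the base metabolites, the shared covariance, and the Bayes
# linear discriminant.
latent_truth <- function(config) {
  b <- config$base_vars
  p <- length(b)
  s <- config$sdlog
  sigma <- matrix(config$rho * s^2, p, p, dimnames = list(b, b))
  diag(sigma) <- s^2
  mu_td <- log(base_levels(b))
  names(mu_td) <- b
  mu_asd <- mu_td
  # sd of a log-ratio under equicorrelation
  sd_ratio <- s * sqrt(2 * (1 - config$rho))
  # base variables first so ratio shifts can account for inherited ones
  is_ratio <- config$informative %in% names(config$ratios)
  for (v in config$informative[!is_ratio]) {
    mu_asd[v] <- mu_asd[v] + config$effects[[v]] * s
  }
  for (v in config$informative[is_ratio]) {
    d <- config$effects[[v]]
    def <- config$ratios[[v]]
    # desired standardized shift of log(num) - log(den), net of shifts
    # already applied to the parents by other informative variables
    inherited <- (mu_asd[def$num] - mu_td[def$num]) -
      (mu_asd[def$den] - mu_td[def$den])
    need <- d * sd_ratio - inherited
    # realize the shift so the ratio, not a parent, carries the signal:
    # split it antisymmetrically, unless a parent is itself informative —
    # then the whole remainder goes to the other parent
    if (def$num %in% config$informative) {
      mu_asd[def$den] <- mu_asd[def$den] - need
    } else if (def$den %in% config$informative) {
      mu_asd[def$num] <- mu_asd[def$num] + need
    } else {
      mu_asd[def$num] <- mu_asd[def$num] + need / 2
      mu_asd[def$den] <- mu_asd[def$den] - need / 2
    }
  }
  dmu <- mu_asd - mu_td
  bayes <- solve(sigma, dmu)
  list(mu_asd = mu_asd, mu_td = mu_td, sigma = sigma,
       bayes_direction = bayes / sqrt(sum(bayes^2)),
       mahalanobis = sqrt(drop(dmu %*% solve(sigma, dmu))),
       informative = config$informative)
}

# Draw n base-metabolite log vectors from the one-factor model with mean mu.
draw_latent <- function(n, mu, config) {
  p <- length(config$base_vars)
  s <- config$sdlog
  f <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(config$rho) * s * f %o% rep(1, p) + sqrt(1 - config$rho) * s * e
  sweep(z, 2, mu, "+")
}

# Map latent base draws to the observed panel (exp + ratio variables).
latent_to_panel <- function(z, config) {
  conc <- exp(z)
  colnames(conc) <- config$base_vars
  out <- matrix(NA_real_, nrow(conc), length(config$variables),
                dimnames = list(NULL, config$variables))
  out[, config$base_vars] <- conc
  for (r in names(config$ratios)) {
    def <- config$ratios[[r]]
    out[, r] <- def$scale * conc[, def$num] / conc[, def$den]
  }
  out
}

#' Generate a synthetic two-class training cohort
#'
#' Draws \code{n_asd} case and \code{n_td} control participants from the
#' generative model of a \code{\link{synthetic_config}} and returns the
#' observed panel together with the latent-scale ground truth (class means,
#' covariance, Bayes discriminant direction, Mahalanobis separation).
#' Bit-reproducible from \code{config$seed}.
#'
#' @param config A \code{synthetic_config}.
#' @return A list with \code{panel} (\code{metabolite_panel}) and
#'   \code{truth} (ground-truth list).
#' @export
generate_cohort <- function(config) {
  truth <- latent_truth(config)
  vals <- with_seed(substream_seed(config$seed, 1), {
    z_asd <- draw_latent(config$n_asd, truth$mu_asd, config)
    z_td <- draw_latent(config$n_td, truth$mu_td, config)
    rbind(latent_to_panel(z_asd, config), latent_to_panel(z_td, config))
  })
  labels <- c(rep("ASD", config$n_asd), rep("TD", config$n_td))
  ids <- c(sprintf("asd%03d", seq_len(config$n_asd)),
           sprintf("td%03d", seq_len(config$n_td)))
  list(panel = metabolite_panel(vals, labels, sample_ids = ids),
       truth = truth)
}

#' Generate a case-only validation cohort
#'
#' Draws \code{n_validation} ASD-labeled participants from the ASD
#' generative distribution of the same config (an independent substream of
#' the seed). Optionally shifts the non-informative base metabolites by
#' \code{shift} log-scale standard deviations to emulate between-cohort
#' heterogeneity that is unrelated to disease status.
#'
#' @param config A \code{synthetic_config}.
#' @param shift Distribution-shift magnitude (standardized units) applied to
#'   non-informative base metabolites; default 0.
#' @return A \code{metabolite_panel} with all labels \code{ASD}.
#' @export
generate_validation_cohort <- function(config, shift = 0) {
  truth <- latent_truth(config)
  mu <- truth$mu_asd
  # shift only base metabolites that feed no informative variable, so the
  # informative panel members keep their ASD distribution exactly
  inf_parents <- unlist(lapply(config$ratios[intersect(names(config$ratios),
                                                       config$informative)],
                               function(d) c(d$num, d$den)))
  off <- setdiff(config$base_vars, c(config$informative, inf_parents))
  mu[off] <- mu[off] + shift * config$sdlog
  n <- config$n_validation
  if (n == 0) {
    vals <- matrix(numeric(0), 0, length(config$variables),
                   dimnames = list(NULL, config$variables))
    return(metabolite_panel(vals, character(0)))
  }
  vals <- with_seed(substream_seed(config$seed, 2), {
    latent_to_panel(draw_latent(n, mu, config), config)
  })
  metabolite_panel(vals, rep("ASD", n),
                   sample_ids = sprintf("val%03d", seq_len(n)))
}

#' Oracle error rates of the generative model
#'
#' Closed-form expected rates for the Bayes linear discriminant on the
#' latent (log) scale: with Mahalanobis separation \eqn{\Delta} and a cut at
#' the \eqn{(1-\beta)} quantile of the TD score distribution, the false
#' negative rate is \eqn{\Phi(z_{1-\beta} - \Delta)} and the false positive
#' rate is \eqn{\beta}. A Monte-Carlo mode evaluates the same rates by
#' simulation, either for the Bayes rule or for an arbitrary fitted linear
#' rule on the observed (ratio-transformed) scale.
#'
#' @param truth Ground truth from \code{\link{generate_cohort}}.
#' @param beta Nominal TD misclassification level in (0, 1).
#' @param method \code{"closed-form"} (Bayes rule, latent scale) or
#'   \code{"monte-carlo"}.
#' @param config Required for Monte-Carlo: the generating
#'   \code{synthetic_config}.
#' @param model Optional \code{projection_model} evaluated instead of the
#'   Bayes rule (Monte-Carlo only): the model is scored on simulated
#'   observable panels and its TD-quantile cut recomputed on the simulated
#'   TD scores.
#' @param n_mc Monte-Carlo sample size per class.
#' @param mc_seed Seed for the Monte-Carlo draws.
#' @return List with \code{tp_rate}, \code{fn_rate}, \code{fp_rate},
#'   \code{tn_rate}.
#' @export
oracle_error_rates <- function(truth, beta, method = "closed-form",
                               config = NULL, model = NULL, n_mc = 1e6,
                               mc_seed = 1) {
  stopifnot(beta > 0, beta < 1)
  if (identical(method, "closed-form")) {
    fn <- stats::pnorm(stats::qnorm(1 - beta) - truth$mahalanobis)
    return(list(tp_rate = 1 - fn, fn_rate = fn, fp_rate = beta,
                tn_rate = 1 - beta))
  }
  if (!identical(method, "monte-carlo")) stop("unknown method: ", method)
  if (is.null(config)) stop("monte-carlo oracle requires the config")
  rates <- with_seed(mc_seed, {
    z_asd <- draw_latent(n_mc, truth$mu_asd, config)
    z_td <- draw_latent(n_mc, truth$mu_td, config)
    if (is.null(model)) {
      w <- solve(truth$sigma, truth$mu_asd - truth$mu_td)
      s_asd <- drop(z_asd %*% w)
      s_td <- drop(z_td %*% w)
    } else {
      pan_asd <- metabolite_panel(latent_to_panel(z_asd, config),
                                  rep("ASD", n_mc))
      pan_td <- metabolite_panel(latent_to_panel(z_td, config),
                                 rep("TD", n_mc))
      s_asd <- project(pan_asd, model)
      s_td <- project(pan_td, model)
    }
    cut <- stats::quantile(s_td, 1 - beta, names = FALSE)
    c(fn = mean(s_asd <= cut), fp = mean(s_td > cut))
  })
  list(tp_rate = 1 - rates[["fn"]], fn_rate = rates[["fn"]],
       fp_rate = rates[["fp"]], tn_rate = 1 - rates[["fp"]])
}

#' Theoretical observed-scale covariance of a synthetic config
#'
#' Maps the latent log-scale covariance through the log-normal moment
#' formulas to the covariance of the observed base metabolites for the TD
#' class: \eqn{Cov(X_i, X_j) = m_i m_j (e^{\sigma_{ij}} - 1)} with
#' \eqn{m_i = e^{\mu_i + \sigma_{ii}/2}}. Used to verify that large
#' simulated cohorts reproduce the configured structure.
#'
#' @param config A \code{synthetic_config}.
#' @return Covariance matrix over the base metabolites.
#' @export
observed_base_covariance <- function(config) {
  truth <- latent_truth(config)
  m <- exp(truth$mu_td + diag(truth$sigma) / 2)
  outer(m, m) * (exp(truth$sigma) - 1)
}
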