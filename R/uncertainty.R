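#' Sampling specification for probabilistic sensitivity analysis
#'
#' Relative risks are resampled from a log-normal calibrated to each
#' factor's published 95% CI on the log scale
#' (`sdlog = (log hi - log lo) / (2 * 1.96)`); prevalences from a
#' method-of-moments beta matching the point estimate and
#' `sd = (hi - lo) / (2 * 1.96)` of its confidence limits. Prevalence
#' limits are rarely published alongside risk tables, so the default is a
#' +/-10% relative band around the point estimate (clipped to `[0, 1]`);
#' per-factor overrides are accepted.
#'
#' @param iterations Number of Monte Carlo draws (default 1000).
#' @param seed Master integer seed. Each factor gets its own RNG stream
#'   derived from this seed and the factor name, so adding a factor leaves
#'   other factors' draws unchanged.
#' @param prevalence_limits Optional named list of `c(lo, hi)` per factor.
#' @param prevalence_rel Half-width of the default relative band (0.10).
#' @param engine `"closed"` recomputes Levin fractions per draw;
#'   `"cohort"` reruns the full cohort simulation per draw (slower).
#' @param cohort_n Cohort size used by the `"cohort"` engine.
#' @return An `uncertainty_spec` list.
#' @export
uncertainty_spec <- function(iterations = 1000, seed = 1,
                             prevalence_limits = NULL,
                             prevalence_rel = 0.10,
                             engine = c("closed", "cohort"),
                             cohort_n = 1e5) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 prevalence_limits = prevalence_limits,
                 prevalence_rel = prevalence_rel,
                 engine = match.arg(engine), cohort_n = cohort_n),
            class = "uncertainty_spec")
}

#' Log-normal sigma implied by a published 95% CI
#'
#' @param factor One-row risk factor.
#' @return `(log(rr_ci_high) - log(rr_ci_low)) / 3.92`.
#' @export
rr_sigma <- function(factor) {
  if (factor$rr_ci_low <= 0) stop("rr_ci_low must be positive", call. = FALSE)
  (log(factor$rr_ci_high) - log(factor$rr_ci_low)) / (2 * 1.96)
}

#' Sample relative risks from a CI-calibrated log-normal
#'
#' Draws from `LogNormal(meanlog = log(rr), sdlog = rr_sigma(factor))`, so
#' the sample median is the point estimate and the 2.5/97.5 quantiles sit at
#' the published confidence limits (up to the symmetric-on-log-scale
#' idealization). A degenerate CI (`lo == hi == rr`) yields the constant
#' point estimate.
#'
#' @param factor One-row risk factor.
#' @param n Number of draws.
#' @return Vector of positive relative risks.
#' @export
sample_rr <- function(factor, n = 1) {
  sigma <- rr_sigma(factor)
  if (sigma == 0) return(rep(factor$rr, n))
  stats::rlnorm(n, meanlog = log(factor$rr), sdlog = sigma)
}

#' Fit a beta distribution to a prevalence and its confidence limits
#'
#' Method of moments: mean equal to the point prevalence and standard
#' deviation `(hi - lo) / 3.92`. Degenerate limits (`lo == hi`) give a
#' point mass at the prevalence.
#'
#' @param prevalence Point estimate in `(0, 1)`.
#' @param limits `c(lo, hi)` bracketing the prevalence.
#' @return List with `alpha`, `beta` (both `NA` for a point mass, with
#'   `degenerate = TRUE`).
#' @export
fit_beta <- function(prevalence, limits) {
  lo <- limits[1]; hi <- limits[2]
  if (lo > prevalence || hi < prevalence)
    stop("limits (", lo, ", ", hi, ") must bracket the prevalence ", prevalence,
         call. = FALSE)
  s <- (hi - lo) / (2 * 1.96)
  if (s == 0)
    return(list(alpha = NA_real_, beta = NA_real_, mean = prevalence,
                degenerate = TRUE))
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1) to fit a beta", call. = FALSE)
  v <- s^2
  common <- prevalence * (1 - prevalence) / v - 1
  alpha <- prevalence * common
  beta <- (1 - prevalence) * common
  if (alpha <= 0 || beta <= 0)
    stop("limits too wide for a beta with mean ", prevalence,
         ": need sd^2 < mean*(1-mean); tighten the limits", call. = FALSE)
  list(alpha = alpha, beta = beta, mean = prevalence, degenerate = FALSE)
}

sample_prevalence <- function(prevalence, limits, n = 1) {
  fit <- fit_beta(prevalence, limits)
  if (fit$degenerate) return(rep(prevalence, n))
  stats::rbeta(n, fit$alpha, fit$beta)
}

default_prevalence_limits <- function(tab, spec) {
  lims <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$name[i]
    if (!is.null(spec$prevalence_limits) && nm %in% names(spec$prevalence_limits))
      return(spec$prevalence_limits[[nm]])
    p <- tab$prevalence[i]
    c(max(0, p * (1 - spec$prevalence_rel)), min(1, p * (1 + spec$prevalence_rel)))
  })
  stats::setNames(lims, tab$name)
}

# Stable per-factor stream seed: master seed + integer hash of the name,
# folded into [0, 2^31 - 2] so set.seed() always accepts it.
stream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131) %% 1000003
  as.integer((as.numeric(master) * 1009 + h) %% (2^31 - 1))
}

#' Monte Carlo uncertainty intervals for attributable fractions
#'
#' For each iteration every relative risk is drawn from its CI-calibrated
#' log-normal and every prevalence from its fitted beta; the per-factor
#' fraction is recomputed per draw. Summaries are the mean and the
#' empirical 2.5th/97.5th percentiles (linear interpolation). Deterministic
#' per seed; per-factor streams are independent.
#'
#' @param tab A [risk_table()].
#' @param spec An [uncertainty_spec()].
#' @return `data.frame` with columns `factor_name`, `mean`, `lo2.5`,
#'   `hi97.5` (fractions), and percent-scale counterparts; the matrix of
#'   draws is attached as attribute `"draws"`.
#' @examples
#' tab <- load_fixture("mena_prostate")
#' monte_carlo_paf(tab, uncertainty_spec(iterations = 200, seed = 42))
#' @export
monte_carlo_paf <- function(tab, spec = uncertainty_spec()) {
  validate_risk_table(tab)
  lims <- default_prevalence_limits(tab, spec)
  it <- spec$iterations
  draws <- matrix(NA_real_, it, nrow(tab), dimnames = list(NULL, tab$name))
  for (i in seq_len(nrow(tab))) {
    f <- tab[i, ]
    set.seed(stream_seed(spec$seed, f$name))
    rr_draw <- sample_rr(f, it)
    p_draw <- sample_prevalence(f$prevalence, lims[[f$name]], it)
    if (spec$engine == "closed") {
      draws[, i] <- levin_paf(p_draw, rr_draw)
    } else {
      draws[, i] <- vapply(seq_len(it), function(m) {
        tab2 <- tab
        tab2$rr[i] <- rr_draw[m]
        tab2$prevalence[i] <- p_draw[m]
        cfg <- cohort_config(tab2, n = spec$cohort_n,
                             seed = stream_seed(spec$seed, paste0(f$name, m)))
        cohort_paf(cfg, f$name)$paf
      }, numeric(1))
    }
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  out <- data.frame(factor_name = tab$name,
                    mean = colMeans(draws),
                    lo2.5 = qs[1, ], hi97.5 = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$mean_percent <- round_half_up(100 * out$mean, 1)
  out$lo_percent <- round_half_up(100 * out$lo2.5, 1)
  out$hi_percent <- round_half_up(100 * out$hi97.5, 1)
  attr(out, "draws") <- draws
  out
}

#' One-way sensitivity range for a single parameter
#'
#' Recomputes the factor's attributable fraction with one input (its
#' relative risk or its prevalence) set to each confidence bound while all
#' other inputs stay at their point estimates.
#'
#' @param tab A [risk_table()].
#' @param factor_name Factor to vary.
#' @param parameter `"rr"` or `"prevalence"`.
#' @param prevalence_limits Optional `c(lo, hi)` for the prevalence bounds;
#'   defaults to the +/-10% relative band.
#' @return Sorted numeric `c(paf_lo, paf_hi)`.
#' @examples
#' one_way(load_fixture("mena_prostate"), "tobacco_smoking", "rr")
#' @export
one_way <- function(tab, factor_name, parameter = c("rr", "prevalence"),
                    prevalence_limits = NULL) {
  parameter <- match.arg(parameter)
  f <- tab[tab$name == factor_name, ]
  if (nrow(f) != 1) stop("unknown factor '", factor_name, "'", call. = FALSE)
  if (parameter == "rr") {
    bounds <- levin_paf(f$prevalence, c(f$rr_ci_low, f$rr_ci_high))
  } else {
    if (is.null(prevalence_limits)) {
      p <- f$prevalence
      prevalence_limits <- c(max(0, p * 0.9), min(1, p * 1.1))
    }
    bounds <- levin_paf(prevalence_limits, f$rr)
  }
  sort(bounds)
}
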