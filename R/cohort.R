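#' Configuration for a synthetic cohort run
#'
#' The simulator validates closed-form attributable fractions on a virtual
#' cohort: independent Bernoulli exposure indicators at each factor's
#' prevalence, disease log-odds equal to a calibrated baseline intercept
#' plus the sum of exposure indicators times log relative risks, and
#' incidence measured either as the mean logistic probability
#' (`case_mode = "expected"`, the default, free of Monte Carlo noise in the
#' case draw) or from Bernoulli case draws (`case_mode = "bernoulli"`).
#' Age is drawn uniformly over `age_range` for cohort realism but carries no
#' risk coefficient; it is inert in the disease model.
#'
#' @param table A [risk_table()].
#' @param n Cohort size (default 100,000).
#' @param seed Integer seed; fixes the exposure matrix and any case draws.
#' @param case_mode `"expected"` or `"bernoulli"`.
#' @param age_range Two ages in years, default `c(40, 80)`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(table, n = 1e5, seed = 1,
                          case_mode = c("expected", "bernoulli"),
                          age_range = c(40, 80)) {
  validate_risk_table(table)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  structure(list(table = table, n = as.integer(n), seed = as.integer(seed),
                 case_mode = match.arg(case_mode), age_range = age_range),
            class = "cohort_config")
}

#' Draw the binary exposure matrix of a cohort
#'
#' One column per risk factor, independent Bernoulli draws with success
#' probability equal to the factor's prevalence. Deterministic per seed.
#' Factors with an alternative relative-risk stratum enter once, under
#' their default stratum.
#'
#' @param config A [cohort_config()].
#' @return A `paf_cohort` object holding the `n x k` exposure matrix,
#'   simulated ages, the factor table and the per-factor log relative risks.
#' @export
simulate_exposures <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tab <- config$table
  n <- config$n
  k <- nrow(tab)
  set.seed(config$seed)
  x <- matrix(0, n, k, dimnames = list(NULL, tab$name))
  for (j in seq_len(k)) x[, j] <- stats::rbinom(n, 1L, tab$prevalence[j])
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  structure(list(exposures = x, age = age, table = tab,
                 log_rr = stats::setNames(log(tab$rr), tab$name),
                 config = config, intercept = NULL,
                 probabilities = NULL, cases = NULL),
            class = "paf_cohort")
}

#' @export
print.paf_cohort <- function(x, ...) {
  cat(sprintf("<paf_cohort> n = %d, %d factors%s\n",
              nrow(x$exposures), ncol(x$exposures),
              if (is.null(x$intercept)) "" else
                sprintf(", intercept %.4f", x$intercept)))
  invisible(x)
}

cohort_eta <- function(cohort) as.vector(cohort$exposures %*% cohort$log_rr)

#' Calibrate the baseline log-odds intercept
#'
#' Finds the constant `c` such that the cohort's mean disease probability,
#' `mean(plogis(c + eta_i))` with `eta_i` the sum of individual exposure
#' indicators times log relative risks, equals the table's target incidence.
#' The objective is strictly increasing in `c`, so a bracketed
#' [stats::uniroot()] search converges; a Newton polish then drives the
#' residual below `tol`. When all individuals share the same `eta` (e.g. no
#' exposure at all) the closed form `qlogis(target) - eta` is returned
#' exactly.
#'
#' @param cohort A `paf_cohort` from [simulate_exposures()].
#' @param table Risk table supplying `target_incidence` (defaults to the
#'   cohort's own table).
#' @param tol Residual tolerance on the mean probability (default `1e-12`).
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(cohort, table = cohort$table, tol = 1e-12) {
  stopifnot(inherits(cohort, "paf_cohort"))
  target <- target_incidence(table)
  if (any(!is.finite(cohort$log_rr)))
    stop("non-finite log relative risk; all rr must be positive", call. = FALSE)
  eta <- cohort_eta(cohort)
  if (length(unique(eta)) == 1) return(stats::qlogis(target) - eta[1])
  f <- function(c) mean(stats::plogis(c + eta)) - target
  lo <- stats::qlogis(target) - max(eta)
  hi <- stats::qlogis(target) - min(eta)
  c0 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # Newton polish: d/dc mean(plogis) = mean(p(1-p)) > 0
  for (i in 1:20) {
    p <- stats::plogis(c0 + eta)
    resid <- mean(p) - target
    if (abs(resid) < tol) break
    c0 <- c0 - resid / mean(p * (1 - p))
  }
  c0
}

#' Attach disease probabilities (and optionally case draws) to a cohort
#'
#' Probabilities are `plogis(intercept + eta_i)`. In `"bernoulli"` mode a
#' case indicator is drawn per individual; the uniform draws are stored so
#' counterfactual runs can reuse them (common random numbers).
#'
#' @param cohort A `paf_cohort` with a calibrated `intercept` (if absent it
#'   is calibrated here).
#' @param mode Overrides the config's `case_mode`.
#' @param seed Seed for the case draws (defaults to `config seed + 1`).
#' @return The cohort with `probabilities`, and in bernoulli mode `cases`
#'   and `case_u` (the reusable uniform draws), filled in.
#' @export
assign_disease <- function(cohort, mode = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "paf_cohort"))
  mode <- if (is.null(mode)) cohort$config$case_mode else
    match.arg(mode, c("expected", "bernoulli"))
  if (is.null(cohort$intercept)) cohort$intercept <- calibrate_intercept(cohort)
  cohort$probabilities <- stats::plogis(cohort$intercept + cohort_eta(cohort))
  if (mode == "bernoulli") {
    if (is.null(seed)) seed <- cohort$config$seed + 1L
    set.seed(seed)
    cohort$case_u <- stats::runif(length(cohort$probabilities))
    cohort$cases <- as.integer(cohort$case_u < cohort$probabilities)
  }
  cohort
}

#' Build a fully simulated cohort in one call
#'
#' Convenience wrapper: [simulate_exposures()], [calibrate_intercept()],
#' [assign_disease()].
#'
#' @inheritParams simulate_exposures
#' @return A calibrated `paf_cohort` with probabilities (and cases in
#'   bernoulli mode).
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_exposures(config)
  cohort$intercept <- calibrate_intercept(cohort)
  assign_disease(cohort)
}

# Incidence under elimination of the named factors, holding the baseline
# intercept and all random draws fixed (common random numbers).
counterfactual_incidence <- function(cohort, zero_factors, mode) {
  eta <- cohort_eta(cohort)
  for (nm in zero_factors)
    eta <- eta - cohort$exposures[, nm] * cohort$log_rr[nm]
  p <- stats::plogis(cohort$intercept + eta)
  if (mode == "expected") mean(p) else mean(cohort$case_u < p)
}

cohort_incidence <- function(cohort, mode) {
  if (mode == "expected") mean(cohort$probabilities) else mean(cohort$cases)
}

#' Cohort-based attributable fraction for one factor
#'
#' Runs the baseline simulation, then a counterfactual with the factor's
#' exposure column zeroed while the intercept stays at its baseline
#' calibrated value and all random draws are shared; the attributable
#' fraction is the proportional incidence reduction
#' `(I_baseline - I_counterfactual) / I_baseline`.
#'
#' @param config A [cohort_config()].
#' @param factor_name Name of the factor to eliminate.
#' @return A one-row `data.frame` with columns `factor_name`, `paf`,
#'   `paf_percent`, `method = "cohort"`.
#' @export
cohort_paf <- function(config, factor_name) {
  cohort <- simulate_cohort(config)
  if (!factor_name %in% colnames(cohort$exposures))
    stop("unknown factor '", factor_name, "'", call. = FALSE)
  mode <- config$case_mode
  i0 <- cohort_incidence(cohort, mode)
  icf <- counterfactual_incidence(cohort, factor_name, mode)
  paf <- (i0 - icf) / i0
  data.frame(factor_name = factor_name, paf = paf,
             paf_percent = round_half_up(100 * paf, 1),
             method = "cohort", stringsAsFactors = FALSE)
}

#' Cohort-based attributable fractions for every factor and domain
#'
#' One counterfactual elimination per factor, plus joint eliminations of the
#' behavioral set, the environmental set, and all factors together, all
#' against a single baseline cohort (shared exposures, intercept and case
#' draws).
#'
#' @param config A [cohort_config()].
#' @param cohort Optionally a pre-built baseline cohort (from
#'   [simulate_cohort()]) to reuse.
#' @return A list with `factors` (per-factor `data.frame` as in
#'   [cohort_paf()]) and `joint` (`data.frame` with rows `behavioral`,
#'   `environmental`, `all`), plus the baseline `intercept` and calibration
#'   `residual`.
#' @export
cohort_paf_all <- function(config, cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  tab <- cohort$table
  mode <- config$case_mode
  i0 <- cohort_incidence(cohort, mode)
  one <- function(nms) {
    if (length(nms) == 0) return(0)
    (i0 - counterfactual_incidence(cohort, nms, mode)) / i0
  }
  pafs <- vapply(tab$name, function(nm) one(nm), numeric(1))
  factors <- data.frame(factor_name = tab$name, category = tab$category,
                        paf = unname(pafs),
                        paf_percent = round_half_up(100 * unname(pafs), 1),
                        method = "cohort", stringsAsFactors = FALSE)
  sets <- list(behavioral = tab$name[tab$category == "behavioral"],
               environmental = tab$name[tab$category == "environmental"],
               all = tab$name)
  jp <- vapply(sets, one, numeric(1))
  joint <- data.frame(set = names(jp), paf = unname(jp),
                      paf_percent = round_half_up(100 * unname(jp), 1),
                      method = "cohort", stringsAsFactors = FALSE)
  list(factors = factors, joint = joint, intercept = cohort$intercept,
       residual = mean(cohort$probabilities) - target_incidence(tab))
}
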