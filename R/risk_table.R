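#' Construct a single risk factor
#'
#' A risk factor couples an exposure prevalence in the target population with
#' the relative risk (and its 95% confidence interval) of disease given
#' exposure. Direction is derived from the relative risk: factors with
#' `rr < 1` are protective, all others harmful.
#'
#' @param name Short unique identifier (e.g. `"tobacco_smoking"`).
#' @param category Either `"behavioral"` or `"environmental"`.
#' @param prevalence Proportion of the population exposed, in `[0, 1]`.
#' @param rr Relative risk point estimate, positive.
#' @param rr_ci_low,rr_ci_high 95% confidence limits, `0 < low <= rr <= high`.
#' @param exposure_definition Free-text definition of the exposure contrast.
#' @param rr_alt,rr_alt_ci_low,rr_alt_ci_high Optional second relative-risk
#'   stratum (used when a study reports more than one exposure contrast for
#'   the same exposed population, e.g. occupational diesel exhaust).
#' @param alt_label Label for the alternative stratum.
#' @return A one-row `data.frame` of class `risk_factor`.
#' @examples
#' risk_factor("tobacco_smoking", "behavioral", 0.25, 1.42, 1.20, 1.68)
#' @export
risk_factor <- function(name, category, prevalence, rr, rr_ci_low, rr_ci_high,
                        exposure_definition = "",
                        rr_alt = NA_real_, rr_alt_ci_low = NA_real_,
                        rr_alt_ci_high = NA_real_, alt_label = NA_character_) {
  rf <- data.frame(
    name = as.character(name),
    category = as.character(category),
    exposure_definition = as.character(exposure_definition),
    prevalence = as.numeric(prevalence),
    rr = as.numeric(rr),
    rr_ci_low = as.numeric(rr_ci_low),
    rr_ci_high = as.numeric(rr_ci_high),
    rr_alt = as.numeric(rr_alt),
    rr_alt_ci_low = as.numeric(rr_alt_ci_low),
    rr_alt_ci_high = as.numeric(rr_alt_ci_high),
    alt_label = as.character(alt_label),
    stringsAsFactors = FALSE
  )
  rf$direction <- ifelse(rf$rr < 1, "protective", "harmful")
  class(rf) <- c("risk_factor", class(rf))
  validate_risk_factor(rf)
  rf
}

validate_risk_factor <- function(rf) {
  with(rf, {
    if (!category %in% c("behavioral", "environmental"))
      stop("factor '", name, "': category must be 'behavioral' or 'environmental', got '",
           category, "'", call. = FALSE)
    if (is.na(prevalence) || prevalence < 0 || prevalence > 1)
      stop("factor '", name, "': prevalence must lie in [0, 1], got ", prevalence,
           call. = FALSE)
    if (is.na(rr) || rr <= 0)
      stop("factor '", name, "': rr must be positive, got ", rr, call. = FALSE)
    if (is.na(rr_ci_low) || is.na(rr_ci_high) ||
        rr_ci_low <= 0 || rr_ci_low > rr || rr > rr_ci_high)
      stop("factor '", name, "': confidence interval must satisfy 0 < rr_ci_low <= rr <= rr_ci_high, got (",
           rr_ci_low, ", ", rr_ci_high, ") around ", rr, call. = FALSE)
    if (!is.na(rr_alt) &&
        (rr_alt <= 0 || is.na(rr_alt_ci_low) || is.na(rr_alt_ci_high) ||
         rr_alt_ci_low <= 0 || rr_alt_ci_low > rr_alt || rr_alt > rr_alt_ci_high))
      stop("factor '", name, "': alternative stratum must satisfy 0 < rr_alt_ci_low <= rr_alt <= rr_alt_ci_high",
           call. = FALSE)
  })
  invisible(rf)
}

#' Assemble a validated risk-factor table
#'
#' A risk table is the unit of analysis: an ordered set of uniquely named risk
#' factors plus the size of the target population and the disease incidence
#' the cohort simulator calibrates to.
#'
#' @param factors A `data.frame` whose rows are risk factors (as produced by
#'   [risk_factor()], or row-bound from several of them).
#' @param population_total Number of persons in the target population (> 0).
#' @param target_incidence Disease incidence proportion, in `(0, 1)` (e.g.
#'   `23.7e-5` for 23.7 cases per 100,000).
#' @return An object of class `risk_table`: the factor `data.frame` with
#'   attributes `population_total` and `target_incidence`.
#' @examples
#' tab <- risk_table(
#'   rbind(risk_factor("a", "behavioral", 0.2, 1.5, 1.1, 2.0),
#'         risk_factor("b", "environmental", 0.4, 0.9, 0.8, 0.99)),
#'   population_total = 1e6, target_incidence = 2e-4
#' )
#' @export
risk_table <- function(factors, population_total, target_incidence) {
  stopifnot(is.data.frame(factors))
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  rownames(factors) <- NULL
  if (!"direction" %in% names(factors) && nrow(factors) > 0)
    factors$direction <- ifelse(factors$rr < 1, "protective", "harmful")
  tab <- structure(factors,
                   population_total = as.numeric(population_total),
                   target_incidence = as.numeric(target_incidence),
                   class = c("risk_table", "data.frame"))
  validate_risk_table(tab)
  tab
}

#' Validate a risk table against its invariants
#'
#' Checks every per-factor invariant (prevalence in `[0, 1]`, positive RR
#' inside its confidence interval, direction consistent with RR) plus the
#' table-level ones (unique names, positive population, incidence in
#' `(0, 1)`). Errors name the offending factor and field.
#'
#' @param tab A `risk_table`.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_risk_table <- function(tab) {
  if (anyDuplicated(tab$name))
    stop("factor names must be unique; duplicated: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  pt <- attr(tab, "population_total")
  ti <- attr(tab, "target_incidence")
  if (is.null(pt) || is.na(pt) || pt <= 0)
    stop("population_total must be > 0, got ", pt, call. = FALSE)
  if (is.null(ti) || is.na(ti) || ti <= 0 || ti >= 1)
    stop("target_incidence must lie in (0, 1), got ", ti, call. = FALSE)
  for (i in seq_len(nrow(tab))) validate_risk_factor(tab[i, , drop = FALSE])
  invisible(tab)
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("<risk_table> %d factors | population %s | target incidence %g per 100,000\n",
              nrow(x), format(attr(x, "population_total"), big.mark = ","),
              attr(x, "target_incidence") * 1e5))
  print(as.data.frame(x)[, c("name", "category", "prevalence", "rr",
                             "rr_ci_low", "rr_ci_high", "direction")], ...)
  invisible(x)
}

#' Population size (persons)
#' @param tab A `risk_table`.
#' @return Scalar population count.
#' @export
population_total <- function(tab) attr(tab, "population_total")

#' Calibration target incidence (proportion)
#' @param tab A `risk_table`.
#' @return Scalar incidence proportion.
#' @export
target_incidence <- function(tab) attr(tab, "target_incidence")

numeric_cols <- c("prevalence", "rr", "rr_ci_low", "rr_ci_high",
                  "rr_alt", "rr_alt_ci_low", "rr_alt_ci_high")

#' Load a packaged risk-factor fixture
#'
#' The `"mena_prostate"` fixture carries the 14 behavioral and environmental
#' exposures of the MENA prostate-cancer risk assessment for men aged 50+:
#' exposure prevalences, relative risks with 95% CIs, the 47-million-person
#' target population and the 23.7 per 100,000 age-standardized incidence the
#' cohort simulator calibrates to. Occupational diesel exhaust is stored once
#' (prevalence 2%) with both reported exposure-contrast strata (RR 1.24 for
#' the 25th-to-75th, 1.27 for the 75th-to-95th percentile contrast).
#'
#' @param name Fixture identifier; `"mena_prostate"` is packaged.
#' @return A validated [risk_table()].
#' @examples
#' tab <- load_fixture("mena_prostate")
#' subset(tab, name == "tobacco_smoking")
#' @export
load_fixture <- function(name = "mena_prostate") {
  path <- system.file("extdata", paste0(name, ".csv"), package = "pafkit")
  if (path == "")
    stop("unknown fixture '", name, "'; packaged fixtures: mena_prostate",
         call. = FALSE)
  read_risk_table(path)
}

#' Reported point estimates accompanying a fixture
#'
#' Returns externally reported percent-scale results for the fixture (per
#' factor attributable fractions, joint fractions, impact fractions), used by
#' [run_report()] to flag where recomputed values differ from the reported
#' ones at the printed 1-decimal precision.
#'
#' @param name Fixture identifier.
#' @return `data.frame` with columns `quantity`, `label`, `reported_percent`.
#' @export
load_fixture_reference <- function(name = "mena_prostate") {
  path <- system.file("extdata", paste0(name, "_reference.csv"), package = "pafkit")
  if (path == "")
    stop("no reference values packaged for fixture '", name, "'", call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a risk table from delimited text
#'
#' The on-disk format is a CSV with columns `name`, `category`,
#' `exposure_definition`, `prevalence`, `rr`, `rr_ci_low`, `rr_ci_high`
#' (plus optional alternative-stratum columns), preceded by two comment
#' lines carrying the table-level metadata:
#' \preformatted{# population_total: 47000000
#' # target_incidence: 0.000237}
#'
#' @param path File path.
#' @param population_total,target_incidence Override the header metadata.
#' @return A validated [risk_table()].
#' @export
read_risk_table <- function(path, population_total = NULL, target_incidence = NULL) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "#")]
  meta <- function(key, override) {
    if (!is.null(override)) return(as.numeric(override))
    line <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (length(line) == 0)
      stop("file '", path, "' lacks a '# ", key, ":' header and no override was given",
           call. = FALSE)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", line[1]))
  }
  pt <- meta("population_total", population_total)
  ti <- meta("target_incidence", target_incidence)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in intersect(numeric_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  for (col in setdiff(numeric_cols, names(df))) df[[col]] <- NA_real_
  if (!"alt_label" %in% names(df)) df$alt_label <- NA_character_
  risk_table(df, population_total = pt, target_incidence = ti)
}

#' Write a risk table to delimited text
#'
#' Numeric fields are serialized at full double precision so that a
#' write/read round trip reproduces the table exactly.
#'
#' @param tab A `risk_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(tab, path) {
  df <- as.data.frame(tab)
  for (col in intersect(numeric_cols, names(df)))
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.17g", df[[col]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# population_total: %.17g", population_total(tab)),
               sprintf("# target_incidence: %.17g", target_incidence(tab))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Number of persons exposed to a factor
#'
#' @param factor A one-row risk factor (a row of a `risk_table`).
#' @param population_total Population size.
#' @return `prevalence * population_total` (persons).
#' @examples
#' tab <- load_fixture("mena_prostate")
#' exposed_population(tab[tab$name == "tobacco_smoking", ], population_total(tab))
#' # 11.75 million
#' @export
exposed_population <- function(factor, population_total) {
  stopifnot(population_total > 0)
  factor$prevalence * population_total
}

#' Generate a random risk table for property-based testing
#'
#' Draws `k` factors with prevalences uniform on `prevalence_range` and
#' log-relative-risks normal with mean 0 and standard deviation `log_rr_sd`;
#' confidence intervals are the corresponding Wald limits
#' `rr * exp(+/- 1.96 * log_rr_sd)`. Deterministic for a fixed seed.
#' Defaults mirror the scale of the packaged fixture: prevalences of a few
#' percent up to 60%, relative risks mostly in 0.5--2, and a rare-disease
#' incidence of 2 per 10,000.
#'
#' @param k Number of factors (>= 1).
#' @param seed Integer seed.
#' @param prevalence_range Length-2 interval strictly inside (0, 1).
#' @param log_rr_sd Non-negative spread of log relative risks; 0 yields a
#'   null table (all `rr == 1`).
#' @param population_total,target_incidence Table-level metadata.
#' @return A validated [risk_table()].
#' @examples
#' generate_synthetic_table(k = 3, seed = 1)
#' @export
generate_synthetic_table <- function(k, seed,
                                     prevalence_range = c(0.05, 0.6),
                                     log_rr_sd = 0.3,
                                     population_total = 1e6,
                                     target_incidence = 2e-4) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k))
    stop("k must be a positive integer, got ", k, call. = FALSE)
  if (length(prevalence_range) != 2 ||
      prevalence_range[1] <= 0 || prevalence_range[2] >= 1 ||
      prevalence_range[1] > prevalence_range[2])
    stop("prevalence_range must be an interval inside (0, 1)", call. = FALSE)
  if (log_rr_sd < 0) stop("log_rr_sd must be non-negative", call. = FALSE)
  set.seed(seed)
  prevalence <- stats::runif(k, prevalence_range[1], prevalence_range[2])
  log_rr <- stats::rnorm(k, 0, log_rr_sd)
  rr <- exp(log_rr)
  half <- exp(1.96 * log_rr_sd)
  df <- data.frame(
    name = sprintf("factor_%02d", seq_len(k)),
    category = rep_len(c("behavioral", "environmental"), k),
    exposure_definition = "synthetic exceedance",
    prevalence = prevalence,
    rr = rr,
    rr_ci_low = rr / half,
    rr_ci_high = rr * half,
    rr_alt = NA_real_, rr_alt_ci_low = NA_real_, rr_alt_ci_high = NA_real_,
    alt_label = NA_character_,
    stringsAsFactors = FALSE
  )
  risk_table(df, population_total = population_total,
             target_incidence = target_incidence)
}
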