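#' Round half-up at a given number of decimals
#'
#' Report tables print percentages at one decimal with ties rounded away
#' from zero (so 3.05 -> 3.1), whereas base `round()` rounds half to even.
#' Internal computation always stays at full precision; this helper is for
#' presentation only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up (on the magnitude) to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Levin's population attributable fraction
#'
#' `PAF = Pe (RR - 1) / (Pe (RR - 1) + 1)`: the proportion of cases that
#' would not occur if the exposure were removed, given exposure prevalence
#' `Pe` and relative risk `RR`. Negative for protective factors (`rr < 1`).
#' Vectorized over both arguments.
#'
#' @param pe Exposure prevalence(s) in `[0, 1]`.
#' @param rr Relative risk(s), positive.
#' @return Attributable fraction(s), always `< 1`.
#' @examples
#' levin_paf(0.25, 1.42)  # 0.0950
#' levin_paf(0.28, 0.86)  # -0.0408 (protective)
#' @export
levin_paf <- function(pe, rr) {
  if (any(is.na(pe)) || any(pe < 0) || any(pe > 1))
    stop("pe must lie in [0, 1]", call. = FALSE)
  if (any(is.na(rr)) || any(rr <= 0))
    stop("rr must be positive", call. = FALSE)
  excess <- pe * (rr - 1)
  if (any(excess <= -1))
    stop("pe * (rr - 1) <= -1: attributable fraction undefined for this protective input",
         call. = FALSE)
  excess / (excess + 1)
}

#' Joint attributable fraction for independent exposures
#'
#' Combines per-factor fractions multiplicatively,
#' `1 - prod(1 - PAF_i)`, which is sub-additive relative to the plain sum
#' when all fractions are non-negative. Protective factors (negative PAF)
#' enter with `(1 - PAF) > 1` and shrink the joint fraction.
#'
#' @param pafs Numeric vector of fractions, each `< 1`. An empty vector
#'   yields 0.
#' @return Joint fraction, `< 1`.
#' @examples
#' joint_paf(c(0.5, 0.5))  # 0.75
#' @export
joint_paf <- function(pafs) {
  if (any(is.na(pafs)) || any(pafs >= 1))
    stop("every attributable fraction must be < 1", call. = FALSE)
  1 - prod(1 - pafs)
}

#' Scenario for a prevalence change
#'
#' Pairs a baseline prevalence `p0` with a target prevalence `p1` for use in
#' [pif()]. Reductions (`p1 <= p0`) are the default; a prevalence increase
#' must be requested explicitly so accidental argument swaps fail loudly.
#'
#' @param factor_name Identifier of the factor the scenario applies to.
#' @param p0 Baseline prevalence in `[0, 1]`.
#' @param p1 Target prevalence in `[0, 1]`.
#' @param allow_increase Permit `p1 > p0`.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(factor_name, p0, p1, allow_increase = FALSE) {
  if (is.na(p0) || p0 < 0 || p0 > 1 || is.na(p1) || p1 < 0 || p1 > 1)
    stop("p0 and p1 must lie in [0, 1]", call. = FALSE)
  if (p1 > p0 && !allow_increase)
    stop("p1 > p0 describes a prevalence increase; set allow_increase = TRUE if intended",
         call. = FALSE)
  structure(list(factor_name = factor_name, p0 = p0, p1 = p1),
            class = "scenario_spec")
}

#' Potential impact fraction for a partial prevalence reduction
#'
#' `PIF = (p0 - p1)(RR - 1) / (p0 (RR - 1) + 1)`: the proportion of cases
#' averted when exposure prevalence moves from `p0` to `p1`. Coincides with
#' [levin_paf()] at `p1 = 0` (full elimination) and is 0 at `p1 = p0`.
#'
#' @param scenario A [scenario_spec()], or a baseline prevalence `p0` if
#'   `p1` is given.
#' @param rr Relative risk, positive.
#' @param p1 Target prevalence (when `scenario` is given as a plain `p0`).
#' @return Impact fraction, `< 1`.
#' @examples
#' pif(scenario_spec("nitrate", 0.30, 0.20), rr = 1.70)  # 0.0579
#' pif(0.25, rr = 1.42, p1 = 0.15)                       # 0.0380
#' @export
pif <- function(scenario, rr, p1 = NULL) {
  if (inherits(scenario, "scenario_spec")) {
    p0 <- scenario$p0
    p1 <- scenario$p1
  } else {
    if (is.null(p1)) stop("supply a scenario_spec or both p0 and p1", call. = FALSE)
    p0 <- scenario
  }
  if (any(rr <= 0)) stop("rr must be positive", call. = FALSE)
  denom <- p0 * (rr - 1) + 1
  if (any(denom <= 0))
    stop("p0 * (rr - 1) <= -1: impact fraction undefined for this protective input",
         call. = FALSE)
  (p0 - p1) * (rr - 1) / denom
}

#' Combined impact fraction for simultaneous scenarios
#'
#' Assumes independent effects and combines multiplicatively,
#' `1 - prod(1 - PIF_i)`.
#'
#' @param pifs Numeric vector of impact fractions, each `< 1`.
#' @return Combined fraction.
#' @export
combined_pif <- function(pifs) {
  if (any(is.na(pifs)) || any(pifs >= 1))
    stop("every impact fraction must be < 1", call. = FALSE)
  1 - prod(1 - pifs)
}

#' Closed-form attributable fractions for a whole risk table
#'
#' Applies [levin_paf()] to every factor. A factor carrying an alternative
#' relative-risk stratum (diesel exhaust in the packaged fixture) yields one
#' row per stratum, sharing the same exposed population. `paf_percent` is
#' the fraction expressed in percent and rounded half-up to one decimal for
#' reporting; `paf` keeps full precision.
#'
#' @param tab A [risk_table()].
#' @return `data.frame` with columns `factor_name`, `category`, `prevalence`,
#'   `rr`, `paf`, `paf_percent`, `method`.
#' @examples
#' paf_table(load_fixture("mena_prostate"))
#' @export
paf_table <- function(tab) {
  validate_risk_table(tab)
  if (nrow(tab) == 0) {
    return(data.frame(factor_name = character(), category = character(),
                      prevalence = numeric(), rr = numeric(), paf = numeric(),
                      paf_percent = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    f <- tab[i, ]
    out <- data.frame(factor_name = f$name, category = f$category,
                      prevalence = f$prevalence, rr = f$rr,
                      paf = levin_paf(f$prevalence, f$rr),
                      stringsAsFactors = FALSE)
    if (!is.na(f$rr_alt)) {
      out <- rbind(out, data.frame(
        factor_name = paste0(f$name, "_alt"), category = f$category,
        prevalence = f$prevalence, rr = f$rr_alt,
        paf = levin_paf(f$prevalence, f$rr_alt),
        stringsAsFactors = FALSE))
    }
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$paf_percent <- round_half_up(100 * res$paf, 1)
  res$method <- rep("closed_form", nrow(res))
  res
}

#' Joint attributable fractions by factor domain
#'
#' Multiplicatively combines the closed-form per-factor fractions within the
#' behavioral set, the environmental set, and all factors together.
#'
#' @param tab A [risk_table()].
#' @param include_alt_strata Include alternative relative-risk strata (e.g.
#'   both diesel contrasts) in the product; `FALSE` keeps one row per factor.
#' @return `data.frame` with columns `set`, `joint_paf`, `joint_percent`,
#'   `sum_percent` (plain sum of the set's fractions, for comparison).
#' @export
joint_paf_table <- function(tab, include_alt_strata = TRUE) {
  pt <- paf_table(tab)
  if (!include_alt_strata) pt <- pt[!grepl("_alt$", pt$factor_name), ]
  sets <- list(behavioral = pt$paf[pt$category == "behavioral"],
               environmental = pt$paf[pt$category == "environmental"],
               all = pt$paf)
  data.frame(
    set = names(sets),
    joint_paf = vapply(sets, joint_paf, numeric(1)),
    joint_percent = round_half_up(100 * vapply(sets, joint_paf, numeric(1)), 1),
    sum_percent = round_half_up(100 * vapply(sets, sum, numeric(1)), 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Impact fractions for a set of prevalence-reduction scenarios
#'
#' Default scenarios reduce each selected factor's prevalence by an absolute
#' 10 percentage points (floored at zero). The default factor set is the
#' four intervention targets of the packaged assessment: trihalomethanes,
#' physical inactivity, drinking-water nitrate, and tobacco smoking.
#'
#' @param tab A [risk_table()].
#' @param factor_names Factors to build scenarios for.
#' @param reduction Absolute prevalence reduction (proportion, default 0.10).
#' @return `data.frame` of per-factor impact fractions plus a `combined`
#'   row from [combined_pif()].
#' @examples
#' pif_table(load_fixture("mena_prostate"))
#' @export
pif_table <- function(tab,
                      factor_names = c("thms", "physical_inactivity",
                                       "nitrate", "tobacco_smoking"),
                      reduction = 0.10) {
  validate_risk_table(tab)
  missing <- setdiff(factor_names, tab$name)
  if (length(missing) > 0)
    stop("unknown factor(s): ", paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(factor_names, function(nm) {
    f <- tab[tab$name == nm, ]
    p0 <- f$prevalence
    p1 <- max(0, p0 - reduction)
    data.frame(factor_name = nm, p0 = p0, p1 = p1, rr = f$rr,
               pif = pif(scenario_spec(nm, p0, p1), f$rr),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- rbind(res, data.frame(factor_name = "combined", p0 = NA, p1 = NA,
                               rr = NA, pif = combined_pif(res$pif),
                               stringsAsFactors = FALSE))
  res$pif_percent <- round_half_up(100 * res$pif, 1)
  res
}
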