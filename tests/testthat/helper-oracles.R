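# Shared helpers: tiny table builders and independent numeric oracles.

two_factor_table <- function() {
  risk_table(
    rbind(
      risk_factor("harmful", "behavioral", 0.3, 1.5, 1.2, 1.9),
      risk_factor("protect", "environmental", 0.4, 0.8, 0.7, 0.95)
    ),
    population_total = 1e6, target_incidence = 2e-4
  )
}

# Independent scalar root-finder (plain bisection), used as the oracle for
# intercept calibration.
bisect <- function(f, lo, hi, tol = 1e-13, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
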