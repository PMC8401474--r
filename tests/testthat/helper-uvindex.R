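# shared fixtures, built in code

flat_spectrum <- function(level = 25, lo = 250, hi = 400, by = 0.5) {
  g <- seq(lo, hi, by = by)
  spectrum(g, rep(level, length(g)))
}

unit_curve <- function(lo = 250, hi = 400) {
  weight_curve(c(lo, hi), c(1, 1))
}

# closed-form integral of the erythema action spectrum over [lo, hi] nm,
# lo >= 250, hi <= 400; independent oracle for trapezoid results
eas_integral_exact <- function(lo = 250, hi = 400) {
  k2 <- 0.094 * log(10)  # decay rate on (298, 328]
  k3 <- 0.015 * log(10)  # decay rate on (328, 400]
  w2 <- function(l) 10^(0.094 * (298 - l))
  w3 <- function(l) 10^(0.015 * (140 - l))
  seg <- 0
  if (lo < 298) seg <- seg + (min(hi, 298) - lo)
  if (hi > 298 && lo < 328) {
    a <- max(lo, 298); b <- min(hi, 328)
    seg <- seg + (w2(a) - w2(b)) / k2
  }
  if (hi > 328) {
    a <- max(lo, 328); b <- hi
    seg <- seg + (w3(a) - w3(b)) / k3
  }
  seg
}

# small deterministic ensemble shared across scan/detector tests
small_ensemble <- function(n = 300, seed = 101, ...) {
  generate_ensemble(ensemble_config(n = n, seed = seed, ...))
}
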