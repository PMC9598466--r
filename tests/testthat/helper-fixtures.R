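# Shared expensive fixtures, built once per test run.
.ng_cache <- new.env(parent = emptyenv())

shared_template <- function() {
  if (is.null(.ng_cache$template)) .ng_cache$template <- make_template()
  .ng_cache$template
}

shared_phantom <- function(seed = 42L, amplitude = 5) {
  key <- paste0("phantom_", seed, "_", amplitude)
  if (is.null(.ng_cache[[key]]))
    .ng_cache[[key]] <- make_head_phantom(shared_template(), amplitude,
                                          seed = seed)
  .ng_cache[[key]]
}

# The n = 30 simulated cohort under the default study conditions, used by
# both the coregistration-ordering and the surface-comparison checks.
shared_cohort <- function() {
  if (is.null(.ng_cache$cohort))
    .ng_cache$cohort <- run_cohort_experiment(cohort_config(), seed = 1L)
  .ng_cache$cohort
}

# Independent brute-force two-sided signed-rank p value: full enumeration
# of the 2^n sign assignments on the realized mid-ranks.
brute_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  S <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  wl <- min(W, S - W)
  hi <- S - wl
  if (hi - wl < 1e-9) 1 else mean(Ws <= wl + 1e-9 | Ws >= hi - 1e-9)
}

# Independent trapezoid-quadrature oracle for the JZS Bayes factor,
# integrating the g mixture on a transformed (0,1) grid.
jzs_bf01_oracle <- function(t, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  logf <- function(g)
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * (log1p(t^2 / ((1 + n * g) * nu)) - log1p(t^2 / nu)) +
      log(rscale) - 0.5 * log(2 * pi) - 1.5 * log(g) - rscale^2 / (2 * g)
  z <- seq(1e-9, 1 - 1e-9, length.out = 400001)
  g <- z / (1 - z)
  vals <- exp(logf(g)) / (1 - z)^2
  h <- z[2] - z[1]
  bf10 <- h * (sum(vals) - (vals[1] + vals[length(vals)]) / 2)
  1 / bf10
}

rotation_angle_deg <- function(Ta, Tb) transform_discrepancy(Ta, Tb)$rotation_deg
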