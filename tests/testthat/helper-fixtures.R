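# Shared fixtures, built once per test run.

# A tiny hand-checkable matrix: 4 SNPs x 3 populations.
tiny_matrix <- function() {
  m <- rbind(snpA = c(0.2, 0.5, 0.8),
             snpB = c(0.4, 0.5, 0.1),
             snpC = c(0.0, 1.0, 0.5),
             snpD = c(0.9, 0.3, 0.6))
  colnames(m) <- c("p1", "p2", "p3")
  freq_matrix(m, c("A", "C", "G", "T"))
}

# A moderate serial-founder world shared across test files: matrix, panel,
# climate, predictors, baseline, bins.
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- founder_config(n_populations = 30L, n_snps = 4000L,
                            effective_size = 500L, seed = 42L)
      sim <- simulate_serial_founder(cfg)
      climate <- generate_climate(sim$panel, seed = 42L)
      cache <<- list(
        matrix = sim$matrix, panel = sim$panel, climate = climate,
        predictors = predictor_table(sim$panel, climate),
        baseline = genomewide_baseline(sim$matrix),
        bins = bin_by_global_frequency(sim$matrix))
    }
    cache
  }
})

# Random frequency matrix with uniform cells, for brute-force oracles.
random_matrix <- function(n_snps, n_pops, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(n_snps * n_pops), n_snps, n_pops,
              dimnames = list(sprintf("s%03d", seq_len(n_snps)),
                              sprintf("P%02d", seq_len(n_pops))))
  freq_matrix(m)
}

# Independent closed-form simple linear regression (the normal-equations
# oracle; deliberately not using lm).
ols_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# Weighted normal-equations oracle.
wls_oracle <- function(y, x, w) {
  xw <- sum(w * x) / sum(w); yw <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
  intercept <- yw - slope * xw
  ss_res <- sum(w * (y - intercept - slope * x)^2)
  ss_tot <- sum(w * (y - yw)^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}
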