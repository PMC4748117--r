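# Independent oracles and small fixtures used across tests.

# brute-force mixing-model log-likelihood: explicit loops, no shared code
# with the package implementation
oracle_loglik <- function(X, p, sigma, mu, om, off = NULL) {
  if (is.null(off)) off <- matrix(0, nrow(mu), ncol(mu))
  total <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      m <- 0
      v <- sigma[j]^2
      for (k in seq_along(p)) {
        m <- m + p[k] * (mu[j, k] + off[j, k])
        v <- v + p[k]^2 * om[j, k]^2
      }
      total <- total + dnorm(X[i, j], m, sqrt(v), log = TRUE)
    }
  }
  as.numeric(total)
}

# two informative two-tracer sources for small fits
make_two_sources <- function() {
  list(source_profile("low", c(d15N = 0, D17O = 0), c(d15N = 0.5, D17O = 0.5)),
       source_profile("high", c(d15N = 10, D17O = 20), c(d15N = 0.5, D17O = 0.5)))
}

make_identical_sources <- function(K) {
  lapply(seq_len(K), function(k)
    source_profile(paste0("s", k), c(d15N = 2, D17O = 5),
                   c(d15N = 1, D17O = 1)))
}

# short fit configuration for unit tests (acceptance tests use longer runs)
quick_config <- function(...) {
  mixing_fit_config(iterations = 30000L, burn_in = 5000L, ...)
}

# synthetic run sheet with three standards on a known line plus unknowns
make_run_sheet <- function(slope = 1.02, intercept = -0.5) {
  std_raw15 <- c(-1.3, 178.9, 3.1)
  std_raw18 <- c(-27.0, 25.9, 56.5)
  data.frame(
    run_id = "run1",
    sample_id = c("USGS-34", "USGS-32", "USGS-35", "u1", "u2"),
    role = c("standard", "standard", "standard", "unknown", "unknown"),
    standard_name = c("USGS-34", "USGS-32", "USGS-35", "", ""),
    raw_d15N = c(std_raw15, 1.0, -2.0),
    raw_d18O = c(std_raw18, 10.0, 30.0),
    raw_d17O = NA_real_,
    stringsAsFactors = FALSE
  )
}
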