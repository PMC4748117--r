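# Bayesian stable isotope mixing model (SIAR-style, collapsed likelihood).
#
# Model: for sample i and tracer j, with K sources,
#   X_ij ~ Normal( sum_k p_k (mu_jk + c_jk),  sum_k p_k^2 omega_jk^2 + sigma_j^2 )
# where p is the source proportion vector (Dirichlet prior), omega_jk the
# source spread, c_jk an optional offset and sigma_j a per-tracer residual
# scale (uniform prior). The latent per-source draws and per-sample residuals
# of the hierarchical formulation are marginalised analytically into the
# variance term, leaving K - 1 + J free parameters.

#' Configuration for a mixing-model fit
#'
#' @param tracers ordered tracer names used in the fit
#'   (default `c("d15N", "D17O")`).
#' @param iterations total MCMC iterations (default 500000).
#' @param burn_in iterations discarded as burn-in (default 50000); proposal
#'   scales are adapted only during burn-in.
#' @param thin keep every `thin`-th post-burn-in draw; default `NULL` picks a
#'   thinning that retains about 10000 draws.
#' @param dirichlet_alpha Dirichlet prior concentration; scalar (recycled) or
#'   length-K vector, all > 0 (default 1 = uniform on the simplex).
#' @param sigma_prior_upper upper bound of the uniform prior on each residual
#'   scale sigma_j (per mil, default 20).
#' @param sigma_fixed optional fixed residual scale(s); when given, sigma is
#'   not sampled.
#' @param seed integer RNG seed; fits are deterministic given the seed.
#' @param proposal_scale initial random-walk scale on the log-ratio
#'   transformed proportions (adapted during burn-in).
#' @param chains number of independent chains (different seeds); draws are
#'   pooled and a split-Rhat diagnostic is computed when `chains > 1`.
#' @param prior_only if `TRUE` the likelihood is switched off and the sampler
#'   explores the prior (useful for prior-recovery checks).
#' @return An object of class `mixing_fit_config`.
#' @export
mixing_fit_config <- function(tracers = c("d15N", "D17O"),
                              iterations = 500000L, burn_in = 50000L,
                              thin = NULL, dirichlet_alpha = 1,
                              sigma_prior_upper = 20, sigma_fixed = NULL,
                              seed = 1L, proposal_scale = 0.5,
                              chains = 1L, prior_only = FALSE) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  stopifnot(iterations > burn_in, burn_in >= 0, all(dirichlet_alpha > 0),
            sigma_prior_upper > 0, proposal_scale > 0, chains >= 1)
  if (!is.null(thin)) stopifnot(thin >= 1)
  if (!is.null(sigma_fixed)) stopifnot(all(sigma_fixed > 0))
  structure(list(tracers = tracers, iterations = iterations,
                 burn_in = burn_in, thin = thin,
                 dirichlet_alpha = dirichlet_alpha,
                 sigma_prior_upper = sigma_prior_upper,
                 sigma_fixed = sigma_fixed, seed = as.integer(seed),
                 proposal_scale = proposal_scale, chains = as.integer(chains),
                 prior_only = isTRUE(prior_only)),
            class = "mixing_fit_config")
}

# internal: J x K matrices of source moments in tracer order
.source_matrices <- function(sources, tracers) {
  K <- length(sources)
  mu <- om <- off <- matrix(NA_real_, length(tracers), K,
                            dimnames = list(tracers,
                                            vapply(sources, `[[`, "", "name")))
  for (k in seq_len(K)) {
    s <- sources[[k]]
    miss <- setdiff(tracers, names(s$means))
    if (length(miss))
      stop("source '", s$name, "' lacks tracer(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    mu[, k] <- s$means[tracers]
    om[, k] <- s$sds[tracers]
    off[, k] <- s$offsets[tracers]
  }
  list(mu = mu, om = om, off = off)
}

# internal: extract the n x J tracer matrix, checking completeness
.tracer_matrix <- function(samples, tracers) {
  if (is.matrix(samples)) samples <- as.data.frame(samples)
  miss <- setdiff(tracers, names(samples))
  if (length(miss))
    stop("samples lack tracer column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(samples[, tracers, drop = FALSE])
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0)
    ids <- if ("sample_id" %in% names(samples))
      samples$sample_id[bad] else as.character(bad)
    stop("missing tracer value(s) in fitted sample(s): ",
         paste(utils::head(ids, 5L), collapse = ", "), call. = FALSE)
  }
  X
}

#' Mixing-model log-likelihood
#'
#' Sum over samples and tracers of the normal log-density of the collapsed
#' mixing model (see the package vignette): mean `sum_k p_k (mu_jk + c_jk)`,
#' variance `sum_k p_k^2 omega_jk^2 + sigma_j^2`.
#'
#' @param samples data frame or matrix holding one column per fitted tracer.
#' @param p proportion vector on the simplex (length K).
#' @param sigma per-tracer residual scales (> 0), length equal to the number
#'   of tracers (recycled if scalar).
#' @param sources list of [source_profile()] objects.
#' @param tracers tracer names; default the columns of `samples` that appear
#'   in the first source.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(samples, p, sigma, sources,
                           tracers = c("d15N", "D17O")) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6, all(sigma > 0))
  sm <- .source_matrices(sources, tracers)
  X <- .tracer_matrix(samples, tracers)
  sigma <- rep_len(sigma, length(tracers))
  m <- drop(sm$mu %*% p + sm$off %*% p)
  v <- drop(sm$om^2 %*% p^2) + sigma^2
  n <- nrow(X)
  sum(stats::dnorm(X, rep(m, each = n), rep(sqrt(v), each = n), log = TRUE))
}

# additive log-ratio transform helpers (last component is the reference)
.softmax <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0), 0))
  e / sum(e)
}

#' Fit the mixing model by Markov chain Monte Carlo
#'
#' Random-walk Metropolis on the additive log-ratio transform of the
#' proportion vector (K - 1 dimensions, with the simplex Jacobian folded into
#' the target) and, unless `sigma_fixed` is given, on the log residual scales.
#' Proposal scales are adapted during burn-in towards 20-40% acceptance and
#' then frozen. With `chains > 1`, independent chains are run from seeds
#' `seed, seed + 1, ...`, pooled, and a split-Rhat per proportion computed
#' (a warning is issued above 1.05).
#'
#' @param samples data frame or matrix of tracer measurements (one row per
#'   sample, one column per tracer in `config$tracers`).
#' @param sources list of [source_profile()] objects (K >= 1).
#' @param config a [mixing_fit_config()].
#' @return An object of class `posterior_draws`: list with `p` (draws x K
#'   matrix of proportions), `sigma` (draws x J matrix), `acceptance_rate`,
#'   `source_names`, `tracers`, and `diagnostics` (split-Rhat when
#'   `chains > 1`).
#' @export
fit_mixing_model <- function(samples, sources, config = mixing_fit_config()) {
  stopifnot(inherits(config, "mixing_fit_config"), length(sources) >= 1L)
  tracers <- config$tracers
  sm <- .source_matrices(sources, tracers)
  X <- if (config$prior_only) {
    matrix(numeric(0), 0L, length(tracers))
  } else {
    .tracer_matrix(samples, tracers)
  }
  if (!config$prior_only && nrow(X) < 1L)
    stop("fit_mixing_model: need at least one sample", call. = FALSE)
  chains <- lapply(seq_len(config$chains) - 1L, function(off)
    .run_chain(X, sm, config, seed = config$seed + off))
  p <- do.call(rbind, lapply(chains, `[[`, "p"))
  sig <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  colnames(p) <- colnames(sm$mu)
  colnames(sig) <- tracers
  diag <- list(converged = NA)
  if (config$chains > 1L) {
    rhat <- vapply(seq_len(ncol(p)), function(k)
      .split_rhat(lapply(chains, function(ch) ch$p[, k])), numeric(1))
    names(rhat) <- colnames(p)
    diag <- list(rhat = rhat, converged = all(rhat < 1.05))
    if (!diag$converged)
      warning("split-Rhat above 1.05 for: ",
              paste(names(rhat)[rhat >= 1.05], collapse = ", "),
              "; consider more iterations", call. = FALSE)
  }
  structure(list(p = p, sigma = sig,
                 acceptance_rate = mean(vapply(chains, `[[`, numeric(1),
                                               "acceptance_rate")),
                 source_names = colnames(p), tracers = tracers,
                 config = config, diagnostics = diag),
            class = "posterior_draws")
}

# one Metropolis chain; X may have zero rows (prior-only)
.run_chain <- function(X, sm, config, seed) {
  set.seed(seed %% .Machine$integer.max)
  K <- ncol(sm$mu); J <- nrow(sm$mu); n <- nrow(X)
  alpha <- rep_len(config$dirichlet_alpha, K)
  muoff <- sm$mu + sm$off
  om2 <- sm$om^2
  upper <- config$sigma_prior_upper
  fixed_sigma <- !is.null(config$sigma_fixed)
  sig <- if (fixed_sigma) rep_len(config$sigma_fixed, J) else rep(upper / 4, J)
  lsig <- log(sig)

  log_post <- function(z, lsig) {
    p <- .softmax(z)
    if (any(p < 1e-300)) return(-Inf)
    # Dirichlet(alpha) density plus the ALR Jacobian prod(p) gives sum(alpha*log p)
    lp <- sum(alpha * log(p))
    sig <- exp(lsig)
    if (!fixed_sigma) {
      if (any(sig >= upper)) return(-Inf)
      lp <- lp + sum(lsig)  # Jacobian of the log transform (uniform sigma prior)
    }
    if (n > 0L) {
      m <- drop(muoff %*% p)
      s <- sqrt(drop(om2 %*% p^2) + sig^2)
      lp <- lp + sum(stats::dnorm(X, rep(m, each = n), rep(s, each = n),
                                  log = TRUE))
    }
    lp
  }

  z <- rep(0, K - 1)
  lp_cur <- log_post(z, lsig)
  if (!is.finite(lp_cur))
    stop("fit_mixing_model: non-finite posterior density at initialisation; ",
         "review priors and source parameters", call. = FALSE)
  scale_z <- config$proposal_scale
  scale_s <- 0.3
  iter <- config$iterations; burn <- config$burn_in
  thin <- config$thin
  if (is.null(thin)) thin <- max(1L, (iter - burn) %/% 10000L)
  n_keep <- (iter - burn) %/% thin
  P <- matrix(NA_real_, n_keep, K)
  SG <- matrix(NA_real_, n_keep, J)
  acc_z <- acc_z_win <- acc_s_win <- 0L; n_post <- 0L; kept <- 0L
  win <- 100L
  for (it in seq_len(iter)) {
    if (K > 1L) {
      z_prop <- z + stats::rnorm(K - 1, 0, scale_z)
      lp_prop <- log_post(z_prop, lsig)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
        z <- z_prop; lp_cur <- lp_prop
        acc_z_win <- acc_z_win + 1L
        if (it > burn) acc_z <- acc_z + 1L
      }
    }
    if (!fixed_sigma) {
      ls_prop <- lsig + stats::rnorm(J, 0, scale_s)
      lp_prop <- log_post(z, ls_prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
        lsig <- ls_prop; lp_cur <- lp_prop
        acc_s_win <- acc_s_win + 1L
      }
    }
    if (it <= burn && it %% win == 0L) {
      scale_z <- scale_z * exp(acc_z_win / win - 0.3)
      scale_s <- scale_s * exp(acc_s_win / win - 0.3)
      acc_z_win <- acc_s_win <- 0L
    }
    if (it > burn) {
      n_post <- n_post + 1L
      if (n_post %% thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        P[kept, ] <- .softmax(z)
        SG[kept, ] <- exp(lsig)
      }
    }
  }
  list(p = P[seq_len(kept), , drop = FALSE],
       sigma = SG[seq_len(kept), , drop = FALSE],
       acceptance_rate = if (K > 1L) acc_z / (iter - burn) else NA_real_)
}

# split-Rhat (Gelman et al.): each chain halved, variance ratio across halves
.split_rhat <- function(chain_draws) {
  halves <- unlist(lapply(chain_draws, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Mixing-model posterior: %d draws, %d sources (%s), tracers %s\n",
              nrow(x$p), ncol(x$p), paste(x$source_names, collapse = ", "),
              paste(x$tracers, collapse = ", ")))
  cat(sprintf("  acceptance rate %.2f\n", x$acceptance_rate))
  if (!is.null(x$diagnostics$rhat))
    cat("  split-Rhat:", paste(sprintf("%s %.3f", names(x$diagnostics$rhat),
                                       x$diagnostics$rhat), collapse = ", "),
        "\n")
  invisible(x)
}

#' Check tracer redundancy between Delta-17O and delta-18O
#'
#' Both Delta-17O and delta-18O track atmospherically oxidised nitrate; when
#' they are strongly correlated in the data, keeping both adds no information
#' while importing delta-18O's larger source-end variability. Returns the
#' squared Pearson correlation and a recommendation to drop delta-18O above
#' the threshold.
#'
#' @param samples data frame with `D17O` and `d18O` columns.
#' @param threshold R-squared above which dropping delta-18O is recommended
#'   (default 0.9).
#' @return List with `r_squared`, `drop_d18O` (logical) and `recommendation`.
#' @export
tracer_redundancy_check <- function(samples, threshold = 0.9) {
  stopifnot(is.data.frame(samples))
  for (col in c("D17O", "d18O"))
    if (!col %in% names(samples))
      stop("tracer_redundancy_check: missing column ", col, call. = FALSE)
  ok <- stats::complete.cases(samples[, c("D17O", "d18O")])
  if (sum(ok) < 3L)
    stop("tracer_redundancy_check: need >= 3 samples with both Delta-17O and delta-18O",
         call. = FALSE)
  r2 <- stats::cor(samples$D17O[ok], samples$d18O[ok])^2
  drop <- r2 > threshold
  list(r_squared = r2, drop_d18O = drop,
       recommendation = if (drop)
         "drop d18O (redundant with D17O)" else "keep both tracers")
}
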