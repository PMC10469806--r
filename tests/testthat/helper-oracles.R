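# Independent oracles and small constructors shared across the test files.
# Every oracle here is coded from the model definition directly and never
# calls the package's samplers, so it can stand as an independent check.

# Brute-force HPDI: scan every window of ceiling(prob*n) sorted draws.
brute_hpdi <- function(draws, prob) {
  x <- sort(draws)
  n <- length(x)
  k <- min(ceiling(prob * n), n)
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - k + 1L)) {
    w <- x[i + k - 1L] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + k - 1L])
  }
  list(lower = best[2], upper = best[3])
}

# Grid-integration oracle for the intercept + one-random-term Poisson
# model: p(beta0, sigma2 | y) with u integrated out numerically per level.
# y: ASV x sample count matrix. Priors: beta0 ~ N(0, sqrt(fixed_var)),
# sigma2 ~ IG(nu/2, nu*V/2).
grid_poisson_oracle <- function(y, nu, V, fixed_var,
                                b_grid = seq(-3, 5, length.out = 281),
                                ls2_grid = seq(log(0.002), log(400),
                                               length.out = 281),
                                u_grid = seq(-20, 20, length.out = 561)) {
  S <- rowSums(y)
  n_s <- ncol(y)
  s2_grid <- exp(ls2_grid)
  du <- diff(u_grid)[1]
  log_ig <- function(x, shape, rate) {
    shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
  }
  lpost <- matrix(NA_real_, length(b_grid), length(s2_grid))
  V_mat <- outer(b_grid, u_grid, "+")
  for (k in seq_along(s2_grid)) {
    lw <- stats::dnorm(u_grid, 0, sqrt(s2_grid[k]), log = TRUE) + log(du)
    tot <- 0
    for (a in seq_len(nrow(y))) {
      la <- S[a] * V_mat - n_s * exp(V_mat)
      la <- sweep(la, 2L, lw, "+")
      m <- apply(la, 1L, max)
      tot <- tot + m + log(rowSums(exp(la - m)))
    }
    lpost[, k] <- tot + stats::dnorm(b_grid, 0, sqrt(fixed_var), log = TRUE) +
      log_ig(s2_grid[k], nu / 2, nu * V / 2) + ls2_grid[k]  # log-grid Jacobian
  }
  lpost <- lpost - max(lpost)
  post <- exp(lpost)
  post <- post / sum(post)
  pb <- rowSums(post)
  ps2 <- colSums(post)
  list(
    mean_beta0 = sum(pb * b_grid),
    sd_beta0 = sqrt(sum(pb * b_grid^2) - sum(pb * b_grid)^2),
    mean_sigma2 = sum(ps2 * s2_grid),
    sd_sigma2 = sqrt(sum(ps2 * s2_grid^2) - sum(ps2 * s2_grid)^2)
  )
}

# Conjugate Gibbs oracle for the one-way Gaussian model
# y_ij = mu + a_g(i) + e_ij, a_g ~ N(0, s2a), e ~ N(0, s2e),
# mu ~ N(0, fixed_var), s2a ~ IG(nu/2, nu*V/2), s2e ~ IG(nu/2, nu*V/2).
# Plain textbook Gibbs, no reparameterisation.
gibbs_gaussian_oracle <- function(y, group, nu, V, fixed_var,
                                  n_iter, burn_in, thin, seed) {
  set.seed(seed)
  G <- max(group)
  n <- length(y)
  ng <- tabulate(group, G)
  mu <- 0
  a <- numeric(G)
  s2a <- V
  s2e <- V
  keep <- seq(burn_in + 1L, n_iter, by = thin)
  out <- matrix(NA_real_, length(keep), 3,
                dimnames = list(NULL, c("mu", "s2a", "s2e")))
  row <- 0L
  for (it in seq_len(n_iter)) {
    r <- y - a[group]
    prec <- n / s2e + 1 / fixed_var
    mu <- stats::rnorm(1, (sum(r) / s2e) / prec, 1 / sqrt(prec))
    rg <- rowsum(y - mu, group)[, 1]
    prec_a <- ng / s2e + 1 / s2a
    a <- stats::rnorm(G, (rg / s2e) / prec_a, 1 / sqrt(prec_a))
    s2a <- 1 / stats::rgamma(1, (nu + G) / 2, rate = (nu * V + sum(a^2)) / 2)
    res <- y - mu - a[group]
    s2e <- 1 / stats::rgamma(1, (nu + n) / 2, rate = (nu * V + sum(res^2)) / 2)
    if (it %in% keep) {
      row <- row + 1L
      out[row, ] <- c(mu, s2a, s2e)
    }
  }
  out
}

# Autocorrelation-based ESS for oracle draw vectors (initial positive
# sequence truncation), independent of the package's diagnostics code path.
ess_acf <- function(x) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(n - 1L, 400L), plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho) && rho[k] + rho[k + 1] > 0) {
    s <- s + rho[k] + rho[k + 1]
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

# Monte-Carlo standard errors from a draw vector and its effective size.
mcse_mean <- function(x, ess) stats::sd(x) / sqrt(ess)
mcse_sd <- function(x, ess) {
  m2 <- stats::var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - m2^2, 0) / (4 * m2 * ess))
}

ess_of <- function(ps, parameter) {
  d <- diagnostics(ps)
  d$ess[d$parameter == parameter]
}

# Minimal posterior_samples stand-in for inference-level unit tests.
fake_ps <- function(beta = NULL, sigma2, u = list(), term_levels = list(),
                    term_factors = list(), family = "poisson_log",
                    residual_name = NULL, design = NULL) {
  nd <- nrow(sigma2)
  if (is.null(beta)) {
    beta <- matrix(0, nd, 1, dimnames = list(NULL, "(Intercept)"))
  }
  structure(list(family = family, beta = beta, sigma2 = sigma2, u = u,
                 chain = rep(1L, nd), term_levels = term_levels,
                 term_factors = term_factors,
                 residual_name = residual_name,
                 fixed_names = colnames(beta), design = design,
                 config = NULL),
            class = "posterior_samples")
}

# Small simulated fixture + matching fit, shared by several files.
quick_fit <- function(n_hosts = 12, n_asvs = 40, seed = 1, mcmc_seed = 99,
                      spike_fraction = 0, beta0 = 3,
                      n_iterations = 2500, burn_in = 800, thin = 4) {
  cfg <- synth_config(n_hosts = n_hosts, n_asvs = n_asvs, beta0 = beta0,
                      spike_fraction = spike_fraction, seed = seed)
  sim <- simulate_dataset(cfg)
  obs <- assemble_long(sim$counts, sim$meta, sim$tax)
  mc <- suppressWarnings(
    mcmc_config(n_iterations, burn_in, thin, 1, seed = mcmc_seed))
  ps <- fit_glmm(obs, spec_for_synth(cfg), prior_spec(), mc)
  list(cfg = cfg, sim = sim, obs = obs, ps = ps)
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
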