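#' Prior specification for a GLMM fit
#'
#' Variance components get inverse-gamma priors parameterised as
#' \code{sigma2 ~ IG(nu/2, nu*V/2)} (the scalar inverse-Wishart convention
#' of animal-model software: \code{V} is a prior scale, \code{nu} a degree
#' of belief; the default \code{nu = 0.002} is close to flat on the
#' variance). Fixed effects get independent zero-mean Gaussian priors with
#' a large variance.
#'
#' @param V,nu Default scale and degree of belief for every variance
#'   component (V > 0, nu > 0).
#' @param fixed_var Prior variance of fixed effects (default 1e8).
#' @param terms Optional named list of per-term overrides, each a list with
#'   elements \code{V} and/or \code{nu}; names must match random-term names
#'   (use \code{"residual"} for the row-level term and \code{"units"} for
#'   the Gaussian residual variance).
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(V = 1, nu = 0.002, fixed_var = 1e8, terms = list()) {
  stopifnot(V > 0, nu > 0, fixed_var > 0)
  structure(list(V = V, nu = nu, fixed_var = fixed_var, terms = terms),
            class = "prior_spec")
}

#' MCMC run configuration
#'
#' Defaults mirror common practice for these models: 65,000 iterations
#' with a 15,000-iteration burn-in, thinning interval 50 and two chains,
#' retaining 2,000 draws in total.
#'
#' @param n_iterations Total iterations per chain.
#' @param burn_in Iterations discarded before retention begins.
#' @param thin Thinning interval (>= 1).
#' @param n_chains Number of independent chains (seeded seed, seed+1, ...).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(n_iterations = 65000, burn_in = 15000, thin = 50,
                        n_chains = 2, seed = 1) {
  stopifnot(burn_in < n_iterations, thin >= 1, n_chains >= 1)
  retained <- ceiling((n_iterations - burn_in) / thin)
  if (retained < 200) {
    warning("fewer than 200 retained draws per chain (", retained,
            "); posterior summaries will be noisy")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

resolve_prior <- function(prior, term_names) {
  V <- rep(prior$V, length(term_names))
  nu <- rep(prior$nu, length(term_names))
  names(V) <- names(nu) <- term_names
  for (nm in names(prior$terms)) {
    if (!nm %in% term_names) next
    ov <- prior$terms[[nm]]
    if (!is.null(ov$V)) V[nm] <- ov$V
    if (!is.null(ov$nu)) nu[nm] <- ov$nu
  }
  list(V = V, nu = nu)
}

#' Fit a Bayesian GLMM by MCMC
#'
#' Draws from the posterior of the model declared by \code{spec} on the
#' long observation table \code{obs}. The Poisson family (log link) is
#' sampled by single-site Metropolis updates with conjugate inverse-gamma
#' draws for the variance components; proposal scales adapt during burn-in
#' only, so retained draws come from a fixed transition kernel. The
#' Gaussian family is sampled by a fully conjugate Gibbs sampler. Chains
#' are run sequentially with seeds \code{seed, seed+1, ...}; results are
#' fully determined by (data, spec, prior, config).
#'
#' @param obs Long observation table ([assemble_long()]); the Gaussian
#'   family reads the response from a \code{value} column if present,
#'   otherwise from \code{count}.
#' @param spec A [model_spec()].
#' @param prior A [prior_spec()].
#' @param config A [mcmc_config()].
#' @param use_likelihood Internal switch: \code{FALSE} samples from the
#'   prior alone (used to validate prior implementation).
#' @return An object of class \code{"posterior_samples"}: list with
#'   \code{beta} (draws x fixed effects), \code{sigma2} (draws x variance
#'   components; the Gaussian residual variance appears as column
#'   \code{"units"}), \code{u} (per random term, draws x levels with level
#'   labels as colnames), \code{chain} (chain id per draw), plus the
#'   design realization and configuration used.
#' @export
fit_glmm <- function(obs, spec, prior = prior_spec(), config = mcmc_config(),
                     use_likelihood = TRUE) {
  design <- build_design(obs, spec)
  if (spec$family == "poisson_log") {
    y <- design$y
    if (any(y < 0) || any(y != round(y))) {
      stop("Poisson family requires non-negative integer counts")
    }
  }

  sample_terms <- design$terms
  if (!is.null(design$residual)) {
    sample_terms <- c(sample_terms, stats::setNames(
      list(design$residual), design$residual$name))
  }
  term_names <- names(sample_terms)
  term_index <- lapply(sample_terms, function(t) t$index)
  n_levels <- vapply(sample_terms, function(t) t$n_levels, integer(1))
  pr <- resolve_prior(prior, term_names)
  # a "residual" override applies to the row-level term whatever its name
  if (!is.null(design$residual) && "residual" %in% names(prior$terms)) {
    ov <- prior$terms[["residual"]]
    if (!is.null(ov$V)) pr$V[design$residual$name] <- ov$V
    if (!is.null(ov$nu)) pr$nu[design$residual$name] <- ov$nu
  }

  gauss_resid <- resolve_prior(prior, "units")
  if ("units" %in% names(prior$terms)) {
    ov <- prior$terms[["units"]]
    if (!is.null(ov$V)) gauss_resid$V["units"] <- ov$V
    if (!is.null(ov$nu)) gauss_resid$nu["units"] <- ov$nu
  }

  # sweep structures: which fixed-effect column (0-based; 0 = intercept,
  # so values start at 1) each level of a term is exclusively tied to, and
  # the nested term pairs (factors of a strictly contained in factors of b)
  fixed_maps <- lapply(sample_terms, function(tm) {
    fm <- integer(tm$n_levels)
    if (ncol(design$X) > 1L) {
      lv <- factor(tm$index, levels = seq_len(tm$n_levels) - 1L)
      for (j in 2:ncol(design$X)) {
        v <- design$X[, j]
        mn <- tapply(v, lv, min)
        mx <- tapply(v, lv, max)
        fm[mn == 1 & mx == 1] <- j - 1L
      }
    }
    fm
  })
  sweep_pairs <- list()
  first_row <- lapply(sample_terms, function(tm) {
    match(seq_len(tm$n_levels) - 1L, tm$index)
  })
  for (a in seq_along(sample_terms)) {
    for (b in seq_along(sample_terms)) {
      fa <- sample_terms[[a]]$factors
      fb <- sample_terms[[b]]$factors
      if (a != b && all(fa %in% fb) && length(fa) < length(fb)) {
        sweep_pairs[[length(sweep_pairs) + 1L]] <- list(
          a = a - 1L, b = b - 1L,
          map = sample_terms[[a]]$index[first_row[[b]]])
      }
    }
  }

  run_chain <- function(chain) {
    set.seed(config$seed + chain - 1L)
    if (spec$family == "poisson_log") {
      mg_sample_poisson(design$y, design$X, term_index, n_levels,
                        unname(pr$V), unname(pr$nu), prior$fixed_var,
                        fixed_maps, sweep_pairs,
                        config$n_iterations, config$burn_in, config$thin,
                        use_likelihood)
    } else {
      mg_sample_gaussian(design$y, design$X, term_index, n_levels,
                         unname(pr$V), unname(pr$nu),
                         unname(gauss_resid$V["units"]),
                         unname(gauss_resid$nu["units"]),
                         prior$fixed_var,
                         fixed_maps, sweep_pairs,
                         config$n_iterations, config$burn_in, config$thin,
                         use_likelihood)
    }
  }
  chains <- lapply(seq_len(config$n_chains), run_chain)

  nd <- nrow(chains[[1]]$beta)
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- design$fixed_names
  sigma2 <- do.call(rbind, lapply(chains, `[[`, "sigma2"))
  colnames(sigma2) <- if (spec$family == "gaussian_identity") {
    c(term_names, "units")
  } else term_names
  u <- lapply(seq_along(sample_terms), function(t) {
    m <- do.call(rbind, lapply(chains, function(ch) ch$u[[t]]))
    colnames(m) <- sample_terms[[t]]$labels
    m
  })
  names(u) <- term_names

  structure(list(
    family = spec$family,
    beta = beta,
    sigma2 = sigma2,
    u = u,
    chain = rep(seq_len(config$n_chains), each = nd),
    term_levels = lapply(sample_terms, `[[`, "levels"),
    term_factors = lapply(sample_terms, `[[`, "factors"),
    residual_name = if (!is.null(design$residual)) design$residual$name,
    fixed_names = design$fixed_names,
    design = list(X = design$X,
                  term_index = term_index,
                  n = design$n,
                  y = design$y),
    config = config
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", nrow(x$beta), "draws (",
      max(x$chain), "chain(s) ), family", x$family, "\n")
  cat("  fixed effects:", paste(x$fixed_names, collapse = ", "), "\n")
  cat("  variance components:", paste(colnames(x$sigma2), collapse = ", "),
      "\n")
  invisible(x)
}

# Effective sample size by Geyer's initial positive sequence, per chain,
# summed over chains. Returns NA for (near-)constant draws.
ess_one <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v < 1e-300) return(NA_real_)
  maxlag <- min(n - 1L, 500L)
  rho <- stats::acf(x, lag.max = maxlag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

rhat <- function(draws, chain) {
  ids <- unique(chain)
  if (length(ids) < 2) return(NA_real_)
  means <- tapply(draws, chain, mean)
  vars <- tapply(draws, chain, stats::var)
  m <- length(ids)
  n <- length(draws) / m
  W <- mean(vars)
  B <- n * stats::var(as.numeric(means))
  if (!is.finite(W) || W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a fit
#'
#' Computes, for every fixed effect and variance component, the effective
#' sample size (Geyer initial positive sequence estimator, summed over
#' chains), the lag-1 autocorrelation, and the potential scale reduction
#' factor when at least two chains were run. Parameters with ESS below
#' \code{ess_floor} are flagged; constant (degenerate) draw vectors are
#' flagged rather than producing an error.
#'
#' @param ps A [fit_glmm()] result.
#' @param ess_floor ESS below which a parameter is flagged (default 100).
#' @return A data.frame of class \code{"mcmc_diagnostics"} with columns
#'   \code{parameter}, \code{ess}, \code{lag1_autocorr}, \code{rhat},
#'   \code{flag}.
#' @export
diagnostics <- function(ps, ess_floor = 100) {
  draws <- cbind(ps$beta, ps$sigma2)
  if (nrow(draws) < 50) stop("diagnostics need at least 50 retained draws")
  params <- colnames(draws)
  per_chain <- split(seq_len(nrow(draws)), ps$chain)
  out <- lapply(params, function(pn) {
    x <- draws[, pn]
    v <- stats::var(x)
    if (!is.finite(v) || v < 1e-300) {
      return(data.frame(parameter = pn, ess = NA_real_,
                        lag1_autocorr = NA_real_, rhat = NA_real_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    }
    ess <- sum(vapply(per_chain, function(ii) ess_one(x[ii]), numeric(1)),
               na.rm = TRUE)
    l1 <- stats::acf(x[per_chain[[1]]], lag.max = 1, plot = FALSE)$acf[2]
    data.frame(parameter = pn, ess = ess, lag1_autocorr = l1,
               rhat = rhat(x, ps$chain),
               flag = if (ess < ess_floor) "low_ess" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("mcmc_diagnostics", "data.frame")
  out
}

# Per-draw linear predictor matrix (draws x rows), on the link scale.
linear_predictor_draws <- function(ps) {
  nd <- nrow(ps$beta)
  eta <- ps$beta %*% t(ps$design$X)
  for (tn in names(ps$u)) {
    idx <- ps$design$term_index[[tn]] + 1L
    eta <- eta + ps$u[[tn]][, idx, drop = FALSE]
  }
  eta
}

#' Zero-adequacy diagnostic for Poisson fits
#'
#' Ratio of the observed number of zero counts to the posterior-predictive
#' expected number of zeros: per draw the expected zero count is
#' \code{sum(exp(-lambda_row))} with \code{lambda_row} built from that
#' draw's linear predictor; expectations are averaged over draws. A ratio
#' close to 1 indicates the over-dispersed Poisson model accounts for the
#' zeros in the table; a ratio well above 1 indicates zero inflation the
#' model does not capture.
#'
#' @param ps A Poisson-family [fit_glmm()] result.
#' @return A single positive number (possibly \code{Inf} with a warning
#'   when the model predicts essentially no zeros).
#' @export
predicted_zero_ratio <- function(ps) {
  if (ps$family != "poisson_log") {
    stop("the zero-ratio diagnostic applies to Poisson fits only")
  }
  observed <- sum(ps$design$y == 0)
  eta <- linear_predictor_draws(ps)
  eta[eta > 50] <- 50
  eta[eta < -50] <- -50
  expected <- mean(rowSums(exp(-exp(eta))))
  if (observed == 0) {
    warning("no observed zeros; ratio is 0")
    return(0)
  }
  if (expected <= .Machine$double.xmin) {
    warning("model predicts no zeros; ratio is infinite")
    return(Inf)
  }
  observed / expected
}

#' Export posterior draws to a long TSV
#'
#' One row per (chain, draw, parameter, value), covering fixed effects and
#' variance components; random-effect level draws are included when
#' \code{include_u = TRUE}.
#'
#' @param ps A [fit_glmm()] result.
#' @param path Output path.
#' @param include_u Also write per-level random-effect draws.
#' @return Invisibly, \code{path}.
#' @export
write_posterior_tsv <- function(ps, path, include_u = TRUE) {
  blocks <- list(ps$beta, ps$sigma2)
  prefixes <- c("", "sigma2:")
  rows <- list()
  nd <- nrow(ps$beta)
  for (b in seq_along(blocks)) {
    m <- blocks[[b]]
    for (j in seq_len(ncol(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ps$chain, iteration = seq_len(nd),
        parameter = paste0(prefixes[b], colnames(m)[j]),
        value = m[, j], stringsAsFactors = FALSE)
    }
  }
  if (include_u) {
    for (tn in names(ps$u)) {
      m <- ps$u[[tn]]
      for (j in seq_len(ncol(m))) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ps$chain, iteration = seq_len(nd),
          parameter = paste0("u:", tn, ":", colnames(m)[j]),
          value = m[, j], stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Posterior summary as a JSON-ready list
#'
#' Means, SDs, 95% HPDIs and effective sample sizes for fixed effects and
#' variance components.
#'
#' @param ps A [fit_glmm()] result.
#' @return A named list (one entry per parameter).
#' @export
posterior_summary <- function(ps) {
  draws <- cbind(ps$beta, ps$sigma2)
  out <- lapply(colnames(draws), function(pn) {
    x <- draws[, pn]
    iv <- hpdi(x, 0.95)
    list(mean = mean(x), sd = stats::sd(x),
         hpdi_lower = iv$lower, hpdi_upper = iv$upper,
         ess = if (stats::var(x) > 1e-300) ess_one(x) else NA)
  })
  names(out) <- colnames(draws)
  out
}
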