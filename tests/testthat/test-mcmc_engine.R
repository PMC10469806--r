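intercept_only_obs <- function(counts) {
  data.frame(asv_id = "A1", sample_id = sprintf("S%d", seq_along(counts)),
             host_id = sprintf("S%d", seq_along(counts)), group = "G1",
             count = counts, stringsAsFactors = FALSE)
}

test_that("intercept-only Poisson fit matches the conjugate Gamma-Poisson posterior", {
  # 200 rows, all counts 5; with an effectively flat prior on beta0 the
  # posterior of lambda = exp(beta0) is Gamma(sum y, n): mean 5, sd 0.158
  obs <- intercept_only_obs(rep(5L, 200))
  spec <- model_spec("poisson_log", random = list(), residual = NULL)
  ps <- fit_glmm(obs, spec, prior_spec(fixed_var = 1e8),
                 mcmc_config(12000, 2000, 5, 1, seed = 3))
  lam <- exp(ps$beta[, 1])
  ess <- ess_of(ps, "(Intercept)")
  gamma_mean <- 1000 / 200
  gamma_sd <- sqrt(1000) / 200
  expect_lt(abs(mean(lam) - gamma_mean), 3 * gamma_sd)          # example contract
  expect_lt(abs(mean(lam) - gamma_mean), 3 * mcse_mean(lam, ess) + 0.01)
  expect_lt(abs(sd(lam) - gamma_sd), 3 * mcse_sd(lam, ess) + 0.01)
})

test_that("fits are exactly reproducible from the seed", {
  obs <- intercept_only_obs(rpois(60, 4))
  spec <- model_spec("poisson_log", random = list(),
                     residual = random_term("sample_id"))
  cfg <- mcmc_config(800, 200, 2, 2, seed = 42)
  ps1 <- fit_glmm(obs, spec, prior_spec(), cfg)
  ps2 <- fit_glmm(obs, spec, prior_spec(), cfg)
  expect_identical(ps1$beta, ps2$beta)
  expect_identical(ps1$sigma2, ps2$sigma2)
  expect_identical(ps1$u, ps2$u)

  ps3 <- fit_glmm(obs, spec, prior_spec(), mcmc_config(800, 200, 2, 2, seed = 43))
  expect_false(identical(ps1$sigma2, ps3$sigma2))
})

test_that("with the likelihood switched off variance draws reproduce the prior", {
  # Gaussian family: the prior-mode chain alternates exact conjugate draws,
  # so sigma2 quantiles must match IG(nu/2, nu*V/2)
  set.seed(1)
  obs <- intercept_only_obs(rpois(40, 4))
  spec_g <- model_spec("gaussian_identity", random = list(random_term("sample_id")),
                       residual = NULL)
  ps <- fit_glmm(obs, spec_g, prior_spec(V = 1, nu = 4),
                 mcmc_config(24000, 2000, 10, 1, seed = 8),
                 use_likelihood = FALSE)
  q_emp <- quantile(ps$sigma2[, "sample_id"], c(0.25, 0.5, 0.75))
  q_ig <- 1 / qgamma(c(0.75, 0.5, 0.25), shape = 2, rate = 2)
  expect_lt(max(abs(q_emp - q_ig) / q_ig), 0.15)

  # Poisson family reaches the same prior through Metropolis updates
  spec_p <- model_spec("poisson_log", random = list(random_term("sample_id")),
                       residual = NULL)
  ps_p <- fit_glmm(obs, spec_p, prior_spec(V = 1, nu = 4),
                   mcmc_config(44000, 4000, 20, 1, seed = 9),
                   use_likelihood = FALSE)
  q_emp_p <- quantile(ps_p$sigma2[, "sample_id"], c(0.25, 0.5, 0.75))
  expect_lt(max(abs(q_emp_p - q_ig) / q_ig), 0.2)
})

test_that("effective-sample-size diagnostics separate white noise from AR(1)", {
  n <- 2000
  set.seed(5)
  white <- rnorm(n)
  rho <- 0.9
  ar1 <- as.numeric(arima.sim(list(ar = rho), n))
  ps <- fake_ps(
    beta = matrix(white, ncol = 1, dimnames = list(NULL, "(Intercept)")),
    sigma2 = cbind(ar_term = ar1, flat = rep(1, n)))
  d <- diagnostics(ps)
  expect_gt(d$ess[d$parameter == "(Intercept)"], 0.8 * n)
  expect_lt(d$ess[d$parameter == "(Intercept)"], 1.2 * n)
  expect_lt(d$ess[d$parameter == "ar_term"], 0.2 * n)  # AR(1) rho=.9 => ~0.05n
  expect_identical(d$flag[d$parameter == "flat"], "degenerate")
  expect_true(is.na(d$lag1_autocorr[d$parameter == "flat"]))

  too_few <- fake_ps(sigma2 = cbind(a = rnorm(20)))
  expect_error(diagnostics(too_few), "at least 50")
})

test_that("multi-chain runs report a potential scale reduction factor", {
  obs <- intercept_only_obs(rpois(80, 6))
  spec <- model_spec("poisson_log", random = list(), residual = NULL)
  ps <- fit_glmm(obs, spec, prior_spec(), mcmc_config(3000, 500, 5, 2, seed = 4))
  d <- diagnostics(ps)
  expect_false(is.na(d$rhat[d$parameter == "(Intercept)"]))
  expect_lt(d$rhat[d$parameter == "(Intercept)"], 1.1)
})

test_that("zero-ratio diagnostic handles its degenerate inputs", {
  # single row with count 0 and lambda ~ 0: exactly one predicted zero
  ps0 <- fake_ps(
    beta = matrix(-60, 10, 1, dimnames = list(NULL, "(Intercept)")),
    sigma2 = cbind(dummy = rep(1, 10)),
    design = list(X = matrix(1, 1, 1), term_index = list(), n = 1, y = 0))
  ps0$u <- list()
  expect_equal(predicted_zero_ratio(ps0), 1, tolerance = 1e-6)

  # no observed zeros, large lambda: ratio 0 with a warning
  ps1 <- fake_ps(
    beta = matrix(10, 10, 1, dimnames = list(NULL, "(Intercept)")),
    sigma2 = cbind(dummy = rep(1, 10)),
    design = list(X = matrix(1, 5, 1), term_index = list(), n = 5,
                  y = rep(3, 5)))
  ps1$u <- list()
  expect_warning(r <- predicted_zero_ratio(ps1), "no observed zeros")
  expect_identical(r, 0)

  # Gaussian fits are rejected
  psg <- fake_ps(sigma2 = cbind(units = rep(1, 10)),
                 family = "gaussian_identity")
  expect_error(predicted_zero_ratio(psg), "Poisson")
})

test_that("posterior exports carry every parameter and draw", {
  dir <- withr::local_tempdir()
  res <- quick_fit(n_hosts = 4, n_asvs = 6, n_iterations = 700,
                   burn_in = 200, thin = 5)
  path <- file.path(dir, "post.tsv")
  write_posterior_tsv(res$ps, path, include_u = FALSE)
  tab <- read.delim(path)
  expect_setequal(unique(tab$parameter),
                  c(colnames(res$ps$beta),
                    paste0("sigma2:", colnames(res$ps$sigma2))))
  expect_identical(nrow(tab),
                   nrow(res$ps$beta) * (ncol(res$ps$beta) + ncol(res$ps$sigma2)))

  sm <- posterior_summary(res$ps)
  expect_true(all(c("mean", "sd", "hpdi_lower", "hpdi_upper") %in%
                  names(sm[[1]])))
})
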