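test_that("HPDI is the shortest window with deterministic tie-breaking", {
  # 0..99 at prob .95: every 95-draw window has width 94; lowest start wins
  iv <- hpdi(0:99, 0.95)
  expect_identical(c(iv$lower, iv$upper), c(0L, 94L))

  iv2 <- hpdi(rep(3.5, 20), 0.95)
  expect_identical(c(iv2$lower, iv2$upper), c(3.5, 3.5))

  # 99 zeros and one outlier: the shortest 95-draw window excludes it
  iv3 <- hpdi(c(rep(0, 99), 100), 0.95)
  expect_identical(c(iv3$lower, iv3$upper), c(0, 0))

  expect_error(hpdi(1:5, 0.95), "at least 10")
  expect_error(hpdi(1:20, 1.2), "prob")
})

test_that("HPDI agrees with brute-force search and behaves with prob", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    draws <- switch(1 + i %% 3,
                    rnorm(n),
                    rexp(n),
                    c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 6)))
    for (prob in c(0.5, 0.9, 0.95)) {
      got <- hpdi(draws, prob)
      want <- brute_hpdi(draws, prob)
      expect_identical(c(got$lower, got$upper), c(want$lower, want$upper))
    }
    # unimodal sets contain their median; width grows with prob
    uni <- sort(rnorm(n))
    expect_true(hpdi(uni, 0.95)$lower <= median(uni) &&
                median(uni) <= hpdi(uni, 0.95)$upper)
    w90 <- hpdi(uni, 0.90); w95 <- hpdi(uni, 0.95)
    expect_lte(w90$upper - w90$lower, w95$upper - w95$lower)
  }
})

test_that("variance partition reproduces closed-form cases per draw", {
  nd <- 20
  # Gaussian with constant draws {1, 1, 2} and zero residual
  ps_g <- fake_ps(sigma2 = cbind(A = rep(1, nd), B = rep(1, nd),
                                 C = rep(2, nd), units = rep(1e-300, nd)),
                  family = "gaussian_identity")
  vp <- partition_variance(ps_g)
  expect_equal(vp$prop_mean[match(c("A", "B", "C"), vp$term)],
               c(0.25, 0.25, 0.5), tolerance = 1e-12)

  # Poisson with sigma2 = 0 at beta0 = 0: lambda_bar 1, omega ln 2, all
  # variance is distribution-specific
  ps_p <- fake_ps(beta = matrix(0, nd, 1, dimnames = list(NULL, "(Intercept)")),
                  sigma2 = cbind(A = rep(1e-300, nd)))
  vp_p <- partition_variance(ps_p)
  expect_equal(vp_p$sigma2_mean[vp_p$term == "distribution"], log(2),
               tolerance = 1e-12)
  expect_equal(vp_p$prop_mean[vp_p$term == "distribution"], 1,
               tolerance = 1e-9)
  expect_equal(attr(vp_p, "lambda_bar"), rep(1, nd), tolerance = 1e-12)
})

test_that("Poisson partition matches a direct arithmetic oracle on varying draws", {
  set.seed(11)
  nd <- 40
  beta0 <- rnorm(nd, 3, 0.2)
  s2 <- cbind(a = runif(nd, 0.3, 0.7), b = runif(nd, 0.1, 0.5))
  ps <- fake_ps(beta = matrix(beta0, ncol = 1,
                              dimnames = list(NULL, "(Intercept)")),
                sigma2 = s2)
  vp <- partition_variance(ps)
  # independently coded formula evaluation, draw by draw
  lam <- exp(beta0 + (s2[, 1] + s2[, 2]) / 2)
  om <- log(1 + 1 / lam)
  den <- s2[, 1] + s2[, 2] + om
  expect_equal(attr(vp, "prop_draws")[, "a"], s2[, 1] / den, tolerance = 1e-12)
  expect_equal(attr(vp, "prop_draws")[, "distribution"], om / den,
               tolerance = 1e-12)
  expect_equal(vp$prop_mean[vp$term == "a"], mean(s2[, 1] / den),
               tolerance = 1e-12)
  # proportions sum to one within every draw
  expect_lt(max(abs(rowSums(attr(vp, "prop_draws")) - 1)), 1e-12)
})

test_that("repeatability follows its variance-ratio definition", {
  nd <- 20
  ps <- fake_ps(sigma2 = cbind("asv_id:host_id" = rep(2, nd),
                               "asv_id:group" = rep(1, nd),
                               "asv_id:host_id:group" = rep(1, nd)),
                residual_name = "asv_id:host_id:group")
  r <- repeatability(ps)
  expect_equal(r$mean, 0.5, tolerance = 1e-12)

  ps0 <- fake_ps(sigma2 = cbind("asv_id:host_id" = rep(0, nd),
                                "asv_id:group" = rep(1, nd),
                                "asv_id:host_id:group" = rep(1, nd)),
                 residual_name = "asv_id:host_id:group")
  expect_equal(repeatability(ps0)$mean, 0, tolerance = 1e-12)

  set.seed(2)
  s2 <- cbind("asv_id:host_id" = runif(nd, 1, 3),
              "asv_id:group" = runif(nd, 0.5, 1),
              "asv_id:host_id:group" = runif(nd, 0.5, 1))
  psv <- fake_ps(sigma2 = s2, residual_name = "asv_id:host_id:group")
  expect_equal(repeatability(psv)$mean,
               mean(s2[, 1] / rowSums(s2)), tolerance = 1e-12)

  expect_error(repeatability(ps, host_term = "nope"), "nope")
})

fake_da_ps <- function(contrast_by_asv, nd = 40) {
  # two-level group, u draws arranged so that u[,"Ak:G2"] - u[,"Ak:G1"]
  # equals the requested contrast vector for ASV k
  asvs <- names(contrast_by_asv)
  labels <- c(paste(asvs, "G1", sep = ":"), paste(asvs, "G2", sep = ":"))
  u <- matrix(0, nd, length(labels), dimnames = list(NULL, labels))
  for (a in asvs) u[, paste(a, "G2", sep = ":")] <- contrast_by_asv[[a]]
  lv <- expand.grid(asv_id = asvs, group = c("G1", "G2"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fake_ps(sigma2 = cbind(dummy = rep(1, nd)),
          u = list("asv_id:group" = u),
          term_levels = list("asv_id:group" = lv),
          term_factors = list("asv_id:group" = c("asv_id", "group")))
}

test_that("differential abundance flags contrasts whose HPDI excludes zero", {
  nd <- 40
  ps <- fake_da_ps(list(A1 = rep(1, nd),
                        A2 = c(seq(-1, 1, length.out = nd)),
                        A3 = seq(0.8, 1.2, length.out = nd)), nd)
  da <- differential_abundance(ps, "asv_id:group", "G1", "G2")
  expect_identical(da$asv_id, c("A1", "A2", "A3"))
  expect_equal(da$mean_diff[1], 1, tolerance = 1e-12)
  expect_equal(c(da$hpdi_lower[1], da$hpdi_upper[1]), c(1, 1))
  expect_true(da$robust[1])
  expect_false(da$robust[2])     # symmetric around zero
  expect_true(da$robust[3])      # uniform grid 0.8..1.2
  expect_equal(da$mean_diff[3], 1, tolerance = 1e-12)
  iv <- brute_hpdi(seq(0.8, 1.2, length.out = nd), 0.95)
  expect_equal(c(da$hpdi_lower[3], da$hpdi_upper[3]), c(iv$lower, iv$upper))

  expect_error(differential_abundance(ps, "asv_id:group", "G1", "G9"), "G9")
})

test_that("differential abundance is antisymmetric in the level order", {
  set.seed(3)
  nd <- 60
  ps <- fake_da_ps(list(A1 = rnorm(nd, 0.5), A2 = rnorm(nd, -1)), nd)
  fwd <- differential_abundance(ps, "asv_id:group", "G1", "G2")
  rev <- differential_abundance(ps, "asv_id:group", "G2", "G1")
  expect_equal(rev$mean_diff, -fwd$mean_diff, tolerance = 1e-12)
  expect_equal(rev$hpdi_lower, -fwd$hpdi_upper, tolerance = 1e-12)
  expect_equal(rev$hpdi_upper, -fwd$hpdi_lower, tolerance = 1e-12)
  expect_identical(rev$robust, fwd$robust)
})

test_that("BH-adjusted robustness is available but never looser than advertised", {
  set.seed(9)
  nd <- 200
  ps <- fake_da_ps(list(A1 = rnorm(nd, 2, 0.3), A2 = rnorm(nd, 0, 0.3),
                        A3 = rnorm(nd, -2, 0.3)), nd)
  da <- differential_abundance(ps, "asv_id:group", "G1", "G2",
                               bh_correct = TRUE)
  expect_true(all(c("p_tail", "p_bh", "robust_bh") %in% names(da)))
  expect_true(da$robust_bh[1] && da$robust_bh[3])
  expect_false(da$robust_bh[2])
})

test_that("shift summaries decompose robust calls by rank and direction", {
  da <- data.frame(
    asv_id = sprintf("A%d", 1:6),
    mean_diff = c(1, 2, -1, -2, 0.5, -0.5),
    robust = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    Phylum = c("X", "X", "X", "Y", "X", "Y"),
    stringsAsFactors = FALSE)
  sh <- summarize_shifts(da, "Phylum")
  expect_identical(sh$n_robust, 4L)
  expect_identical(unname(sh$composition$positive["X"]), 100)
  expect_equal(unname(sh$composition$negative[c("X", "Y")]), c(50, 50))
  expect_equal(sh$pct_positive + sh$pct_negative, 100)

  # the robust-fraction arithmetic at a realistic scale: 683 of 2023
  da_big <- data.frame(asv_id = sprintf("A%04d", 1:2023),
                       mean_diff = rep(c(1, -1), length.out = 2023),
                       robust = c(rep(TRUE, 683), rep(FALSE, 1340)),
                       Phylum = "P", stringsAsFactors = FALSE)
  expect_identical(round(summarize_shifts(da_big, "Phylum")$pct_robust, 2),
                   33.76)

  none <- summarize_shifts(da[!da$robust, ], "Phylum")
  expect_identical(none$n_robust, 0L)
  expect_identical(none$pct_robust, 0)
  expect_length(none$composition$positive, 0L)

  expect_error(summarize_shifts(da, "Genus"), "Genus")
})

test_that("partition and differential-abundance tables export to TSV", {
  dir <- withr::local_tempdir()
  nd <- 20
  ps <- fake_ps(beta = matrix(2, nd, 1, dimnames = list(NULL, "(Intercept)")),
                sigma2 = cbind(a = runif(nd, 0.5, 1)))
  p1 <- file.path(dir, "part.tsv")
  write_partition_tsv(partition_variance(ps), p1)
  expect_identical(nrow(read.delim(p1)), 2L)

  ps_da <- fake_da_ps(list(A1 = rnorm(nd, 1, 0.1)), nd)
  p2 <- file.path(dir, "da.tsv")
  write_diffabund_tsv(differential_abundance(ps_da, "asv_id:group",
                                             "G1", "G2"), p2)
  expect_identical(read.delim(p2)$asv_id, "A1")
})
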