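#' Highest posterior density interval
#'
#' The shortest contiguous window over the sorted draws containing
#' \code{ceiling(prob * n)} draws; ties in width are broken by the lowest
#' start index, so the result is deterministic.
#'
#' @param draws Numeric vector of posterior draws (>= 10).
#' @param prob Interval mass, in (0, 1). Default 0.95.
#' @return A list with \code{lower}, \code{upper}, \code{prob}.
#' @export
hpdi <- function(draws, prob = 0.95) {
  if (length(draws) < 10) stop("hpdi needs at least 10 draws")
  if (!(prob > 0 && prob < 1)) stop("prob must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(prob * n)
  if (k >= n) k <- n
  widths <- x[k:n] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)  # which.min takes the first minimum: lowest start
  list(lower = x[i], upper = x[i + k - 1L], prob = prob)
}

sigma2_draws <- function(ps, term) {
  if (!term %in% colnames(ps$sigma2)) {
    stop("variance component '", term, "' not found in the fit; available: ",
         paste(colnames(ps$sigma2), collapse = ", "))
  }
  ps$sigma2[, term]
}

#' Partition latent-scale variance across model components
#'
#' Per posterior draw, each random term's share of the total latent-scale
#' variance is computed, including a distribution-specific component. For
#' the Poisson family the distribution component follows the
#' Nakagawa–Schielzeth formulation for log-link Poisson models:
#' \code{omega = log(1 + 1/lambda_bar)} with
#' \code{lambda_bar = exp(beta0 + sum(sigma2)/2)}, the expected count at
#' the fixed-effect reference level under the lognormal random effects.
#' For the Gaussian family the residual variance \code{sigma2_e} plays the
#' distribution component's role. Proportions are computed per draw and
#' then summarised (posterior mean and HPDI), so each term's share carries
#' a credible interval; within every draw the shares sum to one exactly.
#'
#' @param ps A [fit_glmm()] result.
#' @param include_fixed Add the fixed-effect variance (variance of the
#'   fitted fixed linear predictor across rows) to the denominator, giving
#'   a full marginal partition. Off by default: the partition then covers
#'   random components plus the distribution component only.
#' @param prob HPDI mass for the summaries.
#' @return An object of class \code{"variance_partition"}: a data.frame
#'   with one row per component (random terms, then
#'   \code{"distribution"}) and columns \code{term}, \code{sigma2_mean},
#'   \code{sigma2_lower}, \code{sigma2_upper}, \code{prop_mean},
#'   \code{prop_lower}, \code{prop_upper}; per-draw proportions are kept
#'   in \code{attr(, "prop_draws")} and \code{attr(, "lambda_bar")} stores
#'   the per-draw expected-count scale (Poisson).
#' @export
partition_variance <- function(ps, include_fixed = FALSE, prob = 0.95) {
  terms <- colnames(ps$sigma2)
  if (ps$family == "gaussian_identity") {
    terms <- setdiff(terms, "units")
    s2 <- ps$sigma2[, terms, drop = FALSE]
    omega <- ps$sigma2[, "units"]
    lambda_bar <- rep(NA_real_, nrow(s2))
  } else {
    if (!"(Intercept)" %in% colnames(ps$beta)) {
      stop("Poisson variance partition needs intercept draws")
    }
    s2 <- ps$sigma2[, terms, drop = FALSE]
    beta0 <- ps$beta[, "(Intercept)"]
    lambda_bar <- exp(beta0 + rowSums(s2) / 2)
    omega <- log1p(1 / lambda_bar)
  }
  extra <- 0
  if (include_fixed) {
    fix_eta <- ps$beta %*% t(ps$design$X)
    extra <- apply(fix_eta, 1L, stats::var)
  }
  denom <- rowSums(s2) + omega + extra
  prop <- cbind(s2 / denom, distribution = omega / denom)
  if (include_fixed) prop <- cbind(prop, fixed = extra / denom)
  s2_full <- cbind(s2, distribution = omega)
  if (include_fixed) s2_full <- cbind(s2_full, fixed = extra)

  summarise <- function(m) {
    t(apply(m, 2L, function(x) {
      iv <- hpdi(x, prob)
      c(mean = mean(x), lower = iv$lower, upper = iv$upper)
    }))
  }
  ssum <- summarise(s2_full)
  psum <- summarise(prop)
  out <- data.frame(term = rownames(ssum),
                    sigma2_mean = ssum[, "mean"],
                    sigma2_lower = ssum[, "lower"],
                    sigma2_upper = ssum[, "upper"],
                    prop_mean = psum[, "mean"],
                    prop_lower = psum[, "lower"],
                    prop_upper = psum[, "upper"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prop_draws") <- prop
  attr(out, "lambda_bar") <- lambda_bar
  attr(out, "family") <- ps$family
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' Community repeatability across repeated samples of a host
#'
#' The fraction of non-technical compositional variance attributable to
#' consistent among-host differences in taxon abundance:
#' \code{R = s2[host_term] / (s2[group_term] + s2[host_term] +
#' s2[residual_term])}, computed per posterior draw and summarised by its
#' mean and HPDI. With the repeated-measures template the three terms are
#' ASV-by-host, ASV-by-group and the row-level ASV-by-host-by-group
#' residual.
#'
#' @param ps A [fit_glmm()] result.
#' @param host_term,group_term,residual_term Names of the variance
#'   components entering the ratio.
#' @param prob HPDI mass.
#' @return A list of class \code{"repeatability_result"} with
#'   \code{mean}, \code{lower}, \code{upper}, \code{prob}, \code{draws}.
#' @export
repeatability <- function(ps, host_term = "asv_id:host_id",
                          group_term = "asv_id:group",
                          residual_term = ps$residual_name,
                          prob = 0.95) {
  h <- sigma2_draws(ps, host_term)
  g <- sigma2_draws(ps, group_term)
  r <- sigma2_draws(ps, residual_term)
  R <- h / (g + h + r)
  iv <- hpdi(R, prob)
  structure(list(mean = mean(R), lower = iv$lower, upper = iv$upper,
                 prob = prob, draws = R),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("repeatability R = %.4f  [%g%% HPDI %.4f, %.4f]\n",
              x$mean, 100 * x$prob, x$lower, x$upper))
  invisible(x)
}

#' Per-taxon differential abundance between two group levels
#'
#' For every ASV the posterior contrast
#' \code{u[asv, level_b] - u[asv, level_a]} of the taxon-by-group random
#' effect is formed draw by draw; its posterior mean, HPDI and a
#' robustness flag (HPDI excluding zero) are reported on the link scale,
#' with the contrast's inverse posterior variance as a precision weight.
#' ASVs missing one of the two levels are kept with \code{missing = TRUE}
#' rather than dropped.
#'
#' @param ps A [fit_glmm()] result.
#' @param term Name of the taxon-by-group random term (default
#'   \code{"asv_id:group"}).
#' @param level_a,level_b Group labels; the contrast is b minus a.
#' @param prob HPDI mass (default 0.95).
#' @param tax Optional taxonomy table to annotate rows.
#' @param bh_correct Apply a Benjamini–Hochberg adjustment to two-sided
#'   posterior tail probabilities and report \code{robust_bh}; off by
#'   default (the HPDI rule alone is the canonical caller).
#' @return A data.frame of class \code{"differential_abundance"} with
#'   columns \code{asv_id}, \code{mean_diff}, \code{hpdi_lower},
#'   \code{hpdi_upper}, \code{robust}, \code{inv_var}, \code{missing}
#'   (plus rank columns when taxonomy is given). Contrast draws are kept
#'   in \code{attr(, "contrast_draws")}.
#' @export
differential_abundance <- function(ps, term = "asv_id:group",
                                   level_a, level_b, prob = 0.95,
                                   tax = NULL, bh_correct = FALSE) {
  if (!term %in% names(ps$u)) {
    stop("random term '", term, "' not found in the fit")
  }
  lv <- ps$term_levels[[term]]
  if (is.null(lv) || ncol(lv) != 2L) {
    stop("term '", term, "' is not a two-factor (taxon x group) interaction")
  }
  group_col <- ps$term_factors[[term]][2L]
  asv_col <- ps$term_factors[[term]][1L]
  observed_groups <- unique(lv[[group_col]])
  for (l in c(level_a, level_b)) {
    if (!l %in% observed_groups) {
      stop("group level '", l, "' not present in term '", term, "'; levels: ",
           paste(observed_groups, collapse = ", "))
    }
  }
  asvs <- sort(unique(lv[[asv_col]]))
  m <- ps$u[[term]]
  col_a <- match(paste(asvs, level_a, sep = ":"), colnames(m))
  col_b <- match(paste(asvs, level_b, sep = ":"), colnames(m))
  missing <- is.na(col_a) | is.na(col_b)

  nd <- nrow(m)
  contrast <- matrix(NA_real_, nd, length(asvs),
                     dimnames = list(NULL, asvs))
  ok <- which(!missing)
  contrast[, ok] <- m[, col_b[ok], drop = FALSE] - m[, col_a[ok], drop = FALSE]

  res <- data.frame(asv_id = asvs,
                    mean_diff = NA_real_, hpdi_lower = NA_real_,
                    hpdi_upper = NA_real_, robust = NA,
                    inv_var = NA_real_, missing = missing,
                    stringsAsFactors = FALSE)
  for (j in ok) {
    d <- contrast[, j]
    iv <- hpdi(d, prob)
    res$mean_diff[j] <- mean(d)
    res$hpdi_lower[j] <- iv$lower
    res$hpdi_upper[j] <- iv$upper
    res$robust[j] <- iv$lower > 0 || iv$upper < 0
    v <- stats::var(d)
    res$inv_var[j] <- if (v > 0) 1 / v else Inf
  }
  if (bh_correct) {
    ptail <- vapply(seq_along(asvs), function(j) {
      if (missing[j]) return(NA_real_)
      d <- contrast[, j]
      2 * min(mean(d > 0), mean(d < 0))
    }, numeric(1))
    ptail <- pmax(ptail, 1 / nd)  # tail probability floor at MC resolution
    res$p_tail <- ptail
    res$p_bh <- stats::p.adjust(ptail, method = "BH")
    res$robust_bh <- res$p_bh < (1 - prob)
  }
  if (!is.null(tax)) {
    tdx <- match(res$asv_id, tax$asv_id)
    for (rank in setdiff(names(tax), "asv_id")) res[[rank]] <- tax[[rank]][tdx]
  }
  attr(res, "contrast_draws") <- contrast
  attr(res, "levels") <- c(a = level_a, b = level_b)
  attr(res, "prob") <- prob
  class(res) <- c("differential_abundance", "data.frame")
  res
}

#' Summarise robust differential-abundance shifts by taxonomic rank
#'
#' Counts and percentages of robust ASVs overall and split by direction,
#' plus the percentage composition of each direction at the requested
#' taxonomic rank (e.g. which phyla dominate the positive shifts).
#'
#' @param da A [differential_abundance()] table annotated with taxonomy.
#' @param rank Rank column to compose over (e.g. \code{"Phylum"}).
#' @return A list of class \code{"shift_summary"}: \code{n_asv},
#'   \code{n_robust}, \code{pct_robust}, \code{n_positive},
#'   \code{n_negative}, \code{pct_positive}, \code{pct_negative} (shares of
#'   the robust set), and \code{composition}, a per-direction named vector
#'   of rank percentages summing to 100 within each non-empty direction.
#' @export
summarize_shifts <- function(da, rank) {
  if (!rank %in% names(da)) {
    stop("rank column '", rank, "' not present in the table; annotate with ",
         "a taxonomy table first")
  }
  usable <- !is.na(da$robust)
  n_asv <- sum(usable)
  rb <- da[usable & da$robust, , drop = FALSE]
  n_robust <- nrow(rb)
  pos <- rb[rb$mean_diff > 0, , drop = FALSE]
  neg <- rb[rb$mean_diff < 0, , drop = FALSE]
  compose <- function(d) {
    if (nrow(d) == 0) return(stats::setNames(numeric(0), character(0)))
    lab <- d[[rank]]
    lab[is.na(lab)] <- "unclassified"
    tab <- sort(table(lab), decreasing = TRUE)
    100 * as.numeric(tab) / nrow(d) -> pct
    stats::setNames(pct, names(tab))
  }
  structure(list(
    n_asv = n_asv,
    n_robust = n_robust,
    pct_robust = if (n_asv > 0) 100 * n_robust / n_asv else 0,
    n_positive = nrow(pos),
    n_negative = nrow(neg),
    pct_positive = if (n_robust > 0) 100 * nrow(pos) / n_robust else 0,
    pct_negative = if (n_robust > 0) 100 * nrow(neg) / n_robust else 0,
    composition = list(positive = compose(pos), negative = compose(neg)),
    rank = rank
  ), class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("%d of %d ASVs robust (%.2f%%): %d positive (%.2f%%), %d negative (%.2f%%)\n",
              x$n_robust, x$n_asv, x$pct_robust, x$n_positive,
              x$pct_positive, x$n_negative, x$pct_negative))
  invisible(x)
}

#' Write a variance partition to TSV
#' @param vp A [partition_variance()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_partition_tsv <- function(vp, path) {
  utils::write.table(as.data.frame(vp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a differential-abundance table to TSV
#' @param da A [differential_abundance()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_diffabund_tsv <- function(da, path) {
  utils::write.table(as.data.frame(da), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
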