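#' Configuration for the synthetic count generator
#'
#' Defines the generative conditions: a complete host-by-group design with
#' one sample per host and group, a log-scale linear predictor
#' \code{beta0 + beta1 * I(group 2) + sum of Gaussian random effects}
#' (one draw per level of each term), and Poisson sampling of counts.
#' Optional "spiked" group offsets of fixed magnitude and alternating sign
#' on a subset of ASVs provide known non-shrunk differential-abundance
#' targets for power checks. Defaults describe the package's standard
#' validation scale: 30 hosts x 2 groups x 150 ASVs with
#' \code{sigma2 = (asv 1.0, sample 0.1, asv:group 0.2, residual 0.5)} and
#' \code{beta0 = 3}.
#'
#' @param n_hosts Number of hosts (each sampled once per group).
#' @param n_groups Number of group levels (default 2).
#' @param n_asvs Number of ASVs.
#' @param beta0 Global intercept on the log scale.
#' @param beta1 Fixed group effect (applied to every non-reference group).
#' @param sigma2 Named numeric vector of variance components; recognised
#'   names: \code{host}, \code{asv}, \code{host:group} (the per-sample
#'   library-size term), \code{asv:host}, \code{asv:group},
#'   \code{residual} (row level). Missing names default to 0.
#' @param spike_fraction Fraction of ASVs given fixed group offsets.
#' @param spike_delta Magnitude of the offsets; signs alternate so
#'   positive and negative shifts are balanced.
#' @param n_taxa_phyla Number of phyla in the fabricated taxonomy (ASVs
#'   are assigned round-robin; two families per phylum).
#' @param seed Integer seed.
#' @return An object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_hosts = 30, n_groups = 2, n_asvs = 150,
                         beta0 = 3, beta1 = 0,
                         sigma2 = c(asv = 1.0, "host:group" = 0.1,
                                    "asv:group" = 0.2, residual = 0.5),
                         spike_fraction = 0, spike_delta = 1.5,
                         n_taxa_phyla = 4, seed = 1) {
  known <- c("host", "asv", "host:group", "asv:host", "asv:group", "residual")
  full <- stats::setNames(numeric(length(known)), known)
  unknown <- setdiff(names(sigma2), known)
  if (length(unknown)) stop("unknown sigma2 name(s): ",
                            paste(unknown, collapse = ", "))
  full[names(sigma2)] <- sigma2
  if (any(full < 0)) stop("sigma2 values must be non-negative")
  if (spike_fraction < 0 || spike_fraction > 1) {
    stop("spike_fraction must be in [0, 1]")
  }
  structure(list(n_hosts = n_hosts, n_groups = n_groups, n_asvs = n_asvs,
                 beta0 = beta0, beta1 = beta1, sigma2 = full,
                 spike_fraction = spike_fraction, spike_delta = spike_delta,
                 n_taxa_phyla = n_taxa_phyla, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate an ASV count dataset from the model's generative form
#'
#' Draws level effects \code{u ~ N(0, sigma2[term])} once per observed
#' level of each term, builds the log-scale linear predictor for every
#' (ASV, host, group) cell, adds spike offsets to the non-reference
#' group(s) of spiked ASVs, and samples counts from
#' \code{Poisson(exp(eta))}. The returned truth records every realised
#' effect, the variance map and the spiked ASVs, so downstream recovery
#' can be scored exactly.
#'
#' @param cfg A [synth_config()].
#' @return A list with \code{counts} (ASV x sample integer matrix),
#'   \code{meta} (sample metadata data.frame), \code{tax} (taxonomy
#'   data.frame with Phylum and Family ranks), and \code{truth} (list:
#'   \code{sigma2}, \code{u} per term, \code{spiked_asvs},
#'   \code{spike_deltas}, \code{beta0}, \code{beta1}).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  asvs <- sprintf("ASV%03d", seq_len(cfg$n_asvs))
  hosts <- sprintf("H%03d", seq_len(cfg$n_hosts))
  groups <- sprintf("G%d", seq_len(cfg$n_groups))

  meta <- expand.grid(host_id = hosts, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[order(meta$host_id, meta$group), ]
  meta$sample_id <- paste(meta$host_id, meta$group, sep = "_")
  meta <- meta[, c("sample_id", "host_id", "group")]
  rownames(meta) <- NULL

  grid <- expand.grid(asv = asvs, host = hosts, group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  draw_levels <- function(labels, s2) {
    stats::setNames(stats::rnorm(length(labels), 0, sqrt(s2)), labels)
  }
  u <- list(
    host = draw_levels(hosts, cfg$sigma2["host"]),
    asv = draw_levels(asvs, cfg$sigma2["asv"]),
    "host:group" = draw_levels(
      paste(rep(hosts, times = cfg$n_groups),
            rep(groups, each = cfg$n_hosts), sep = ":"),
      cfg$sigma2["host:group"]),
    "asv:host" = draw_levels(
      paste(rep(asvs, times = cfg$n_hosts),
            rep(hosts, each = cfg$n_asvs), sep = ":"),
      cfg$sigma2["asv:host"]),
    "asv:group" = draw_levels(
      paste(rep(asvs, times = cfg$n_groups),
            rep(groups, each = cfg$n_asvs), sep = ":"),
      cfg$sigma2["asv:group"]),
    residual = draw_levels(
      paste(grid$asv, grid$host, grid$group, sep = ":"),
      cfg$sigma2["residual"])
  )

  n_spiked <- round(cfg$spike_fraction * cfg$n_asvs)
  spiked <- if (n_spiked > 0) sort(sample(asvs, n_spiked)) else character(0)
  deltas <- if (n_spiked > 0) {
    stats::setNames(cfg$spike_delta * rep_len(c(1, -1), n_spiked), spiked)
  } else stats::setNames(numeric(0), character(0))

  eta <- cfg$beta0 +
    cfg$beta1 * (grid$group != groups[1L]) +
    u$host[grid$host] +
    u$asv[grid$asv] +
    u[["host:group"]][paste(grid$host, grid$group, sep = ":")] +
    u[["asv:host"]][paste(grid$asv, grid$host, sep = ":")] +
    u[["asv:group"]][paste(grid$asv, grid$group, sep = ":")] +
    u$residual[paste(grid$asv, grid$host, grid$group, sep = ":")]
  spike_idx <- grid$asv %in% spiked & grid$group != groups[1L]
  if (any(spike_idx)) eta[spike_idx] <- eta[spike_idx] + deltas[grid$asv[spike_idx]]

  lambda <- exp(eta)
  if (any(lambda > 1e9)) {
    stop("simulated Poisson rate exceeds 1e9; reduce beta0 or the sigma2 values")
  }
  counts_long <- stats::rpois(nrow(grid), lambda)

  counts <- matrix(0L, cfg$n_asvs, nrow(meta),
                   dimnames = list(asvs, meta$sample_id))
  sample_of <- paste(grid$host, grid$group, sep = "_")
  counts[cbind(match(grid$asv, asvs), match(sample_of, meta$sample_id))] <-
    as.integer(counts_long)

  phyla <- sprintf("Phylum_%02d", seq_len(cfg$n_taxa_phyla))
  families <- sprintf("Family_%02d", seq_len(2L * cfg$n_taxa_phyla))
  tax <- data.frame(
    asv_id = asvs,
    Phylum = rep_len(phyla, cfg$n_asvs),
    Family = rep_len(families, cfg$n_asvs),
    stringsAsFactors = FALSE
  )

  list(counts = counts, meta = meta, tax = tax,
       truth = list(sigma2 = cfg$sigma2, u = u, spiked_asvs = spiked,
                    spike_deltas = deltas, beta0 = cfg$beta0,
                    beta1 = cfg$beta1, config = cfg))
}

#' Null dataset: no group signal at the taxon level
#'
#' Same generator with \code{sigma2["asv:group"] = 0} and no spikes; the
#' type-I-error harness for the differential-abundance caller.
#'
#' @param cfg A [synth_config()]; its asv:group variance and spike settings
#'   are overridden.
#' @return As [simulate_dataset()].
#' @export
null_dataset <- function(cfg) {
  s2 <- cfg$sigma2
  s2["asv:group"] <- 0
  cfg2 <- synth_config(n_hosts = cfg$n_hosts, n_groups = cfg$n_groups,
                       n_asvs = cfg$n_asvs, beta0 = cfg$beta0,
                       beta1 = cfg$beta1, sigma2 = s2,
                       spike_fraction = 0, spike_delta = cfg$spike_delta,
                       n_taxa_phyla = cfg$n_taxa_phyla, seed = cfg$seed)
  simulate_dataset(cfg2)
}

# Model spec matching the generator's nonzero variance components, so
# recovery harnesses fit exactly the generative model.
#' Model spec matching a synthetic configuration
#'
#' Builds a Poisson [model_spec()] whose random terms are exactly the
#' generator's nonzero-variance terms (the row-level residual is always
#' included), with a fixed group effect when \code{beta1} is nonzero or
#' \code{with_fixed_group = TRUE}.
#'
#' @param cfg A [synth_config()].
#' @param with_fixed_group Include the group fixed effect.
#' @param keep_terms Optionally force-keep terms by name even at zero
#'   true variance.
#' @return A [model_spec()].
#' @export
spec_for_synth <- function(cfg, with_fixed_group = cfg$beta1 != 0,
                           keep_terms = "asv:group") {
  map <- list(host = random_term("host_id"),
              asv = random_term("asv_id"),
              "host:group" = random_term("host_id", "group"),
              "asv:host" = random_term("asv_id", "host_id"),
              "asv:group" = random_term("asv_id", "group"))
  use <- names(map)[cfg$sigma2[names(map)] > 0 | names(map) %in% keep_terms]
  model_spec(
    family = "poisson_log",
    fixed = if (with_fixed_group) "group",
    random = unname(map[use]),
    residual = random_term("asv_id", "host_id", "group")
  )
}
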