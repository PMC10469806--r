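#' Centered log-ratio transform of a count matrix
#'
#' Per sample (column), \code{x_i = log(c_i + pseudocount) -
#' mean_j log(c_j + pseudocount)}: each ASV's log abundance centered by
#' the sample's log geometric mean. The transform removes library-size
#' differences between samples; every sample's transformed values sum to
#' zero.
#'
#' @param counts Count matrix ([read_count_matrix()]).
#' @param pseudocount Positive offset added before taking logs (default 1).
#' @return A numeric matrix with the same dimnames as \code{counts};
#'   the pseudocount used is stored in \code{attr(, "pseudocount")}.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  lg <- log(counts + pseudocount)
  out <- sweep(lg, 2L, colMeans(lg), "-")
  attr(out, "pseudocount") <- pseudocount
  out
}

# Long assembly for a real-valued (CLR) matrix: same grid logic as
# assemble_long but with a `value` response column.
assemble_long_real <- function(values, meta, tax = NULL) {
  missing_samples <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_samples)) {
    stop("samples present in matrix but absent from metadata: ",
         paste(missing_samples, collapse = ", "))
  }
  obs <- data.frame(
    asv_id = rep(rownames(values), times = ncol(values)),
    sample_id = rep(colnames(values), each = nrow(values)),
    value = as.numeric(as.vector(values)),
    stringsAsFactors = FALSE
  )
  idx <- match(obs$sample_id, meta$sample_id)
  obs$host_id <- meta$host_id[idx]
  obs$group <- as.character(meta$group)[idx]
  obs <- obs[, c("asv_id", "sample_id", "host_id", "group", "value")]
  if (!is.null(tax)) {
    tdx <- match(obs$asv_id, tax$asv_id)
    for (rank in setdiff(names(tax), "asv_id")) obs[[rank]] <- tax[[rank]][tdx]
  }
  obs
}

#' CLR + Gaussian-family pipeline
#'
#' The compositional alternative to the Poisson path: CLR-transform the
#' count matrix, assemble the real-valued long table, fit the
#' Gaussian-identity mixed model, and partition variance with the Gaussian
#' residual \code{sigma2_e} in the distribution row. The model
#' specification must be Gaussian-family; its residual term should be
#' \code{NULL} (the Gaussian error is the row-level variance — a separate
#' observation-level random term would duplicate it).
#'
#' @param counts Count matrix.
#' @param meta Sample metadata.
#' @param spec Gaussian-family [model_spec()].
#' @param prior,config See [fit_glmm()].
#' @param pseudocount See [clr_transform()].
#' @param tax Optional taxonomy annotation.
#' @return A list with \code{posterior} ([fit_glmm()] result),
#'   \code{partition} ([partition_variance()] result) and
#'   \code{pseudocount}.
#' @export
run_clr_pipeline <- function(counts, meta, spec, prior = prior_spec(),
                             config = mcmc_config(), pseudocount = 1,
                             tax = NULL) {
  if (spec$family != "gaussian_identity") {
    stop("the CLR pipeline requires a gaussian_identity model spec")
  }
  clr <- clr_transform(counts, pseudocount)
  obs <- assemble_long_real(clr, meta, tax)
  ps <- fit_glmm(obs, spec, prior, config)
  vp <- partition_variance(ps)
  list(posterior = ps, partition = vp, pseudocount = pseudocount)
}
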