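#' Define a random-effect term
#'
#' A random term is an interaction of one or more factor columns of the
#' long observation table; its levels are the distinct observed tuples of
#' those columns (no phantom levels for unobserved combinations). The
#' row-level residual term of the over-dispersed Poisson model is an
#' ordinary random term whose factor combination identifies rows uniquely.
#'
#' @param ... Factor column names, e.g. \code{random_term("asv_id", "group")}.
#' @param name Term name; defaults to the colon-joined factor names.
#' @return An object of class \code{"random_term"}.
#' @export
random_term <- function(..., name = NULL) {
  factors <- as.character(c(...))
  if (!length(factors)) stop("a random term needs at least one factor")
  if (is.null(name)) name <- paste(factors, collapse = ":")
  structure(list(name = name, factors = factors), class = "random_term")
}

#' Declare a GLMM structure
#'
#' @param family \code{"poisson_log"} (counts, log link, over-dispersion via
#'   the row-level residual term) or \code{"gaussian_identity"} (e.g. CLR
#'   transformed abundances, residual variance sigma2_e).
#' @param fixed Name of the categorical fixed-effect column (treatment
#'   coding, reference = first sorted level), or \code{NULL} for
#'   intercept-only. The intercept is always present.
#' @param random List of [random_term()] objects.
#' @param residual A [random_term()] whose levels identify rows uniquely
#'   (the observation-level random effect carrying over-dispersion), or
#'   \code{NULL}. Gaussian-family models normally use \code{NULL}: their
#'   residual row is the Gaussian error variance.
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(family = c("poisson_log", "gaussian_identity"),
                       fixed = NULL, random = list(), residual = NULL) {
  family <- match.arg(family)
  if (inherits(random, "random_term")) random <- list(random)
  nm <- vapply(random, function(t) t$name, character(1))
  if (!is.null(residual)) nm <- c(nm, residual$name)
  if (anyDuplicated(nm)) stop("random term names must be unique")
  structure(list(family = family, fixed = fixed, random = random,
                 residual = residual),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("GLMM specification (", x$family, ")\n", sep = "")
  cat("  fixed : intercept",
      if (!is.null(x$fixed)) paste0(" + ", x$fixed) else "", "\n", sep = "")
  for (t in x$random) cat("  random: ", t$name, "\n", sep = "")
  if (!is.null(x$residual)) {
    cat("  residual (row level): ", x$residual$name, "\n", sep = "")
  }
  invisible(x)
}

#' Model template for single-season, two-age-class designs
#'
#' One sample per host, hosts from two age classes. Poisson family with
#' fixed age effect; random effects for host (= sample), ASV and the
#' ASV-by-age interaction of biological interest; the ASV-by-host term is
#' the row-level residual carrying over-dispersion.
#'
#' @return A [model_spec()].
#' @export
make_2013_spec <- function() {
  model_spec(
    family = "poisson_log",
    fixed = "group",
    random = list(
      random_term("host_id"),
      random_term("asv_id"),
      random_term("asv_id", "group")
    ),
    residual = random_term("asv_id", "host_id")
  )
}

#' Model template for repeated-measures two-season designs
#'
#' Two samples per host, one per season. Poisson family with fixed season
#' effect; random effects for host, ASV, sample (host-by-season, the
#' library-size term), ASV-by-host (individual repeatability) and
#' ASV-by-season (compositional shift); the ASV-by-host-by-season term is
#' the row-level residual.
#'
#' @param drop_host Drop the main host term, keeping host-by-season only
#'   (the two are hard to separate with two samples per host).
#' @return A [model_spec()].
#' @export
make_2016_spec <- function(drop_host = FALSE) {
  random <- list(
    random_term("host_id"),
    random_term("asv_id"),
    random_term("host_id", "group"),
    random_term("asv_id", "host_id"),
    random_term("asv_id", "group")
  )
  if (drop_host) random <- random[-1L]
  model_spec(
    family = "poisson_log",
    fixed = "group",
    random = random,
    residual = random_term("asv_id", "host_id", "group")
  )
}

#' Append hierarchical taxonomy random effects
#'
#' Adds rank-by-group random terms (e.g. phylum:group, family:group) so
#' that group shifts can be partitioned across taxonomic levels alongside
#' the ASV-level term. Observations whose rank label is missing are pooled
#' into a single "unclassified" level per rank (handled when the long table
#' is annotated, see [assemble_long()]).
#'
#' @param spec A [model_spec()].
#' @param tax Taxonomy table ([read_taxonomy()]).
#' @param ranks Character vector of rank column names to add.
#' @param group_column Group factor column, default \code{"group"}.
#' @return The extended [model_spec()].
#' @export
add_taxonomy_terms <- function(spec, tax, ranks, group_column = "group") {
  unknown <- setdiff(ranks, setdiff(names(tax), "asv_id"))
  if (length(unknown)) {
    stop("rank(s) absent from taxonomy table: ", paste(unknown, collapse = ", "))
  }
  extra <- lapply(ranks, function(r) random_term(r, group_column))
  model_spec(family = spec$family, fixed = spec$fixed,
             random = c(spec$random, extra), residual = spec$residual)
}

#' Realize a model specification against an observation table
#'
#' Maps every observation row to a level index for every random term
#' (levels ordered lexicographically by label tuple, so the realization is
#' deterministic), and builds the fixed-effect design columns (intercept
#' plus treatment-coded group indicator). Missing labels in taxonomy-rank
#' factor columns are pooled into \code{"unclassified"}.
#'
#' @param obs Long observation table ([assemble_long()]).
#' @param spec A [model_spec()].
#' @return A list of class \code{"design_realization"} with elements
#'   \code{X} (n x p fixed design), \code{fixed_names}, \code{terms} (per
#'   random term: \code{index} 0-based level index per row, \code{levels}
#'   data.frame of label tuples, \code{n_levels}), \code{residual} (same
#'   shape, or NULL), \code{y} response, \code{n}.
#' @export
build_design <- function(obs, spec) {
  all_terms <- spec$random
  if (!is.null(spec$residual)) all_terms <- c(all_terms, list(spec$residual))
  needed <- unique(c(unlist(lapply(all_terms, function(t) t$factors)),
                     spec$fixed))
  missing <- setdiff(needed, names(obs))
  if (length(missing)) {
    stop("observation table is missing column(s) referenced by the model: ",
         paste(missing, collapse = ", "))
  }

  realize_term <- function(term) {
    cols <- lapply(term$factors, function(f) {
      v <- as.character(obs[[f]])
      v[is.na(v)] <- "unclassified"
      v
    })
    key <- do.call(paste, c(cols, sep = ":"))
    lev <- sort(unique(key))
    idx <- match(key, lev) - 1L
    levels_df <- as.data.frame(
      do.call(rbind, strsplit(lev, ":", fixed = TRUE)),
      stringsAsFactors = FALSE)
    # strsplit on the sorted keys keeps factor columns aligned when labels
    # themselves contain no ':' (enforced below)
    if (any(vapply(cols, function(v) any(grepl(":", v, fixed = TRUE)),
                   logical(1)))) {
      levels_df <- NULL  # labels ambiguous; keep flat labels only
    } else {
      colnames(levels_df) <- term$factors
    }
    list(name = term$name, factors = term$factors, index = idx,
         labels = lev, levels = levels_df, n_levels = length(lev))
  }

  terms <- lapply(spec$random, realize_term)
  names(terms) <- vapply(spec$random, function(t) t$name, character(1))
  residual <- if (!is.null(spec$residual)) realize_term(spec$residual)
  if (!is.null(residual) && residual$n_levels != nrow(obs)) {
    stop("residual term '", residual$name,
         "' does not identify rows uniquely (", residual$n_levels,
         " levels for ", nrow(obs), " rows)")
  }

  if (!is.null(spec$fixed)) {
    g <- as.character(obs[[spec$fixed]])
    glev <- sort(unique(g))
    X <- cbind(1, outer(g, glev[-1L], "==") * 1)
    fixed_names <- c("(Intercept)", paste0(spec$fixed, glev[-1L]))
  } else {
    X <- matrix(1, nrow(obs), 1L)
    fixed_names <- "(Intercept)"
  }
  colnames(X) <- fixed_names

  y <- if ("count" %in% names(obs)) obs$count else obs$value
  structure(list(X = X, fixed_names = fixed_names, terms = terms,
                 residual = residual, y = as.numeric(y), n = nrow(obs)),
            class = "design_realization")
}

#' Serialize a model spec to a plain list (YAML/JSON-ready)
#' @param spec A [model_spec()].
#' @return A list with family, fixed, random (colon-joined factor strings)
#'   and residual entries.
#' @export
spec_to_list <- function(spec) {
  list(
    family = spec$family,
    fixed = spec$fixed,
    random = vapply(spec$random, function(t) paste(t$factors, collapse = ":"),
                    character(1)),
    residual = if (!is.null(spec$residual)) {
      paste(spec$residual$factors, collapse = ":")
    }
  )
}

#' Deserialize a model spec from a plain list
#' @param x A list as produced by [spec_to_list()] (e.g. parsed from YAML).
#' @return A [model_spec()].
#' @export
spec_from_list <- function(x) {
  parse_term <- function(s) do.call(random_term,
                                    as.list(strsplit(s, ":", fixed = TRUE)[[1]]))
  model_spec(
    family = x$family,
    fixed = x$fixed,
    random = lapply(x$random, parse_term),
    residual = if (!is.null(x$residual)) parse_term(x$residual)
  )
}
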