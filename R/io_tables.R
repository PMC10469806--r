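#' Read a wide ASV-by-sample count matrix
#'
#' Reads an ASV abundance table in wide TSV format (first column ASV
#' identifiers, remaining columns one per sample) or in BIOM format
#' (v1 JSON or v2.1 HDF5, via the \pkg{biomformat} package), and validates
#' it as a count matrix: all cells must be non-negative integers and both
#' row (ASV) and column (sample) identifiers must be unique.
#'
#' @param path Path to the table.
#' @param format Either \code{"tsv"} (default) or \code{"biom"}.
#' @return An integer matrix with ASV ids as rownames and sample ids as
#'   colnames.
#' @export
read_count_matrix <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "double"
    return(validate_count_matrix(m, source = path))
  }
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L) stop("count TSV needs an id column plus >=1 sample column")
  asv_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
              dimnames = list(asv_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
    if (length(bad)) {
      stop(sprintf("non-numeric count '%s' at ASV '%s', sample '%s'",
                   df[[j + 1L]][bad[1L]], asv_ids[bad[1L]], sample_ids[j]))
    }
    m[, j] <- v
  }
  validate_count_matrix(m, source = path)
}

# Shared validation: integral non-negative cells, unique ids, no missing.
validate_count_matrix <- function(m, source = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(source, ": ASV and sample identifiers are required")
  }
  if (anyDuplicated(rownames(m))) {
    stop(source, ": duplicate ASV id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop(source, ": duplicate sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (anyNA(m)) stop(source, ": missing cells are not allowed")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: invalid count %g at ASV '%s', sample '%s' (counts must be non-negative integers)",
                 source, m[bad[1L, 1L], bad[1L, 2L]],
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a sample metadata table
#'
#' Reads a TSV with one row per sample carrying the sample identifier, the
#' host identifier and the grouping factor (for example season or age
#' class). Column names are configurable; defaults follow the package's
#' long-table convention. The group column is coerced to a factor whose
#' level order is the sorted order of observed labels.
#'
#' @param path Path to the TSV.
#' @param sample_col,host_col,group_col Column names to use.
#' @return A data.frame with columns \code{sample_id}, \code{host_id},
#'   \code{group} (factor), plus any extra covariate columns.
#' @export
read_metadata <- function(path, sample_col = "sample_id",
                          host_col = "host_id", group_col = "group") {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  for (col in c(sample_col, host_col, group_col)) {
    if (!col %in% colnames(df)) {
      stop("metadata is missing required column '", col, "'")
    }
  }
  if (anyDuplicated(df[[sample_col]])) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df[[sample_col]][duplicated(df[[sample_col]])]),
               collapse = ", "))
  }
  out <- df
  names(out)[match(c(sample_col, host_col, group_col), names(df))] <-
    c("sample_id", "host_id", "group")
  out$group <- factor(out$group, levels = sort(unique(out$group)))
  out
}

#' Read an ASV taxonomy table
#'
#' TSV with an \code{asv_id} column followed by rank columns
#' (Kingdom ... Genus or any subset, in order). Missing labels may be empty
#' strings or NA.
#'
#' @param path Path to the TSV.
#' @param asv_col Name of the ASV id column.
#' @return A data.frame with \code{asv_id} first, then rank columns
#'   (character, NA where unassigned).
#' @export
read_taxonomy <- function(path, asv_col = "asv_id") {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (!asv_col %in% colnames(df)) {
    stop("taxonomy is missing required column '", asv_col, "'")
  }
  if (anyDuplicated(df[[asv_col]])) stop("duplicate asv_id in taxonomy")
  names(df)[match(asv_col, names(df))] <- "asv_id"
  for (j in setdiff(names(df), "asv_id")) df[[j]][df[[j]] == ""] <- NA
  df
}

#' Assemble the long-format observation table
#'
#' Expands a count matrix into the complete (ASV, sample) grid that the
#' Poisson likelihood needs, with zeros materialised as explicit rows, and
#' joins host and group from the metadata (plus taxonomy ranks if given).
#' The grand total of counts is preserved exactly.
#'
#' @param counts Count matrix from [read_count_matrix()].
#' @param meta Metadata from [read_metadata()].
#' @param tax Optional taxonomy from [read_taxonomy()].
#' @return A data.frame with columns \code{asv_id}, \code{sample_id},
#'   \code{host_id}, \code{group}, \code{count} and, when taxonomy is
#'   supplied, one column per rank.
#' @export
assemble_long <- function(counts, meta, tax = NULL) {
  counts <- validate_count_matrix(counts)
  missing_samples <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_samples)) {
    stop("samples present in counts but absent from metadata: ",
         paste(missing_samples, collapse = ", "))
  }
  asv_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  obs <- data.frame(
    asv_id = rep(asv_ids, times = length(sample_ids)),
    sample_id = rep(sample_ids, each = length(asv_ids)),
    count = as.integer(as.vector(counts)),
    stringsAsFactors = FALSE
  )
  idx <- match(obs$sample_id, meta$sample_id)
  obs$host_id <- meta$host_id[idx]
  obs$group <- as.character(meta$group)[idx]
  obs <- obs[, c("asv_id", "sample_id", "host_id", "group", "count")]
  if (!is.null(tax)) {
    tdx <- match(obs$asv_id, tax$asv_id)
    for (rank in setdiff(names(tax), "asv_id")) obs[[rank]] <- tax[[rank]][tdx]
  }
  stopifnot(sum(obs$count) == sum(counts))
  obs
}

#' Filter ASVs by abundance and prevalence thresholds
#'
#' Retains ASVs whose total read count is at least \code{min_total_reads}
#' and which are present (count > 0) in at least a fraction
#' \code{min_prevalence} of samples. The sample set and the order of the
#' retained ASVs are unchanged; the operation is idempotent.
#'
#' @param counts Count matrix.
#' @param min_total_reads Minimum total reads per ASV (>= 0).
#' @param min_prevalence Minimum fraction of samples with a nonzero count,
#'   in [0, 1].
#' @return The filtered count matrix.
#' @export
filter_taxa <- function(counts, min_total_reads = 0, min_prevalence = 0) {
  counts <- validate_count_matrix(counts)
  stopifnot(min_total_reads >= 0, min_prevalence >= 0, min_prevalence <= 1)
  totals <- rowSums(counts)
  prevalence <- rowMeans(counts > 0)
  keep <- totals >= min_total_reads & prevalence >= min_prevalence
  if (!any(keep)) {
    stop("filter_taxa removed every ASV; relax min_total_reads/min_prevalence")
  }
  counts[keep, , drop = FALSE]
}

#' Write a long observation table to TSV
#'
#' The written file round-trips losslessly through [read_long()].
#'
#' @param obs Long table from [assemble_long()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_long <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a long observation table written by [write_long()]
#'
#' @param path Path to the TSV.
#' @return A data.frame matching the [assemble_long()] layout.
#' @export
read_long <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  req <- c("asv_id", "sample_id", "host_id", "group", "count")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("long table missing column(s): ",
                            paste(missing, collapse = ", "))
  df$count <- as.integer(df$count)
  for (j in setdiff(names(df), req)) df[[j]][df[[j]] == ""] <- NA
  df
}
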