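#' Construct an expression dataset
#'
#' An `expr_dataset` is a light wrapper around one genes x samples matrix
#' together with the metadata the rest of the pipeline needs: the dataset's
#' role in a differential (type B) analysis, the microarray channel type that
#' decides its normalisation route, and a mask of missing values.
#'
#' @param values Numeric matrix, genes in rows, samples/time points in
#'   columns. Row names (if present) are used as gene IDs unless `gene_ids`
#'   is given.
#' @param dataset_id Character scalar identifying the dataset.
#' @param gene_ids Character vector of gene IDs, one per row.
#' @param role One of `"positive"`, `"negative"`, `"unspecified"`: which side
#'   of a type B split the dataset belongs to.
#' @param channel One of `"one_channel"`, `"two_channel"`, `"unknown"`.
#'   One-channel data are quantile normalised and scaled to unit gene
#'   standard deviation; two-channel data (already log-ratios) are only
#'   centred.
#' @param missing_mask Logical matrix of the same shape as `values`, `TRUE`
#'   where a value is missing. Defaults to `is.na(values)`.
#'
#' @return An object of class `expr_dataset`.
#' @export
expression_dataset <- function(values, dataset_id = "dataset",
                               gene_ids = rownames(values),
                               role = c("unspecified", "positive", "negative"),
                               channel = c("unknown", "one_channel", "two_channel"),
                               missing_mask = NULL) {
  role <- match.arg(role)
  channel <- match.arg(channel)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("`gene_ids` must have one entry per row of `values`.", call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("Duplicate gene IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (ncol(values) < 2) {
    stop("A dataset needs at least 2 samples.", call. = FALSE)
  }
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- missing_mask | is.na(values)
  dimnames(missing_mask) <- NULL
  rownames(values) <- gene_ids
  structure(
    list(
      dataset_id = as.character(dataset_id),
      gene_ids = gene_ids,
      values = values,
      role = role,
      channel = channel,
      missing_mask = missing_mask
    ),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %s: %d genes x %d samples (role: %s, channel: %s, %d missing)\n",
    x$dataset_id, nrow(x$values), ncol(x$values), x$role, x$channel,
    sum(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Read an expression dataset from delimited text
#'
#' Expects a header row of sample names, gene IDs in the first column and
#' numeric expression values in the remaining columns. The tokens `NA`,
#' `nan`, `NaN` and the empty cell are treated as missing and recorded in the
#' dataset's missing mask.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; default tab.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, sep = "\t", dataset_id = NULL,
                            role = "unspecified", channel = "unknown") {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  fields <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  fields <- fields[!is.na(fields)]
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop(sprintf("Ragged row %d in %s: %d fields where %d were expected.",
                 bad, path, fields[bad], fields[1]), call. = FALSE)
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = character())
  if (ncol(df) < 3) stop("Need a gene-ID column and >= 2 sample columns.", call. = FALSE)
  gene_ids <- df[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("Duplicate gene IDs in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  missing <- raw %in% c("", "NA", "nan", "NaN", "na")
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  missing_mask <- matrix(missing, nrow = nrow(raw)) | is.na(values)
  values[missing_mask] <- NA_real_
  colnames(values) <- colnames(raw)
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  expression_dataset(values, dataset_id = dataset_id, gene_ids = gene_ids,
                     role = role, channel = channel,
                     missing_mask = missing_mask)
}

#' Write an expression dataset as delimited text
#'
#' Inverse of [read_expression()]: header row of sample names, gene IDs in
#' the first column, missing values written as `NA`.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, sep = "\t") {
  values <- dataset$values
  values[dataset$missing_mask] <- NA_real_
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("s", seq_len(ncol(values)))
  df <- data.frame(gene_id = dataset$gene_ids, values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", cn)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stop unless all datasets in a collection share one ordered gene list.
validate_collection <- function(collection) {
  if (length(collection) == 0) stop("Empty dataset collection.", call. = FALSE)
  ref <- collection[[1]]$gene_ids
  for (ds in collection) {
    if (!identical(ds$gene_ids, ref)) {
      stop("All datasets must share the same ordered gene list; '",
           ds$dataset_id, "' differs.", call. = FALSE)
    }
  }
  invisible(ref)
}

#' Filter genes by per-dataset missing-value allowance
#'
#' A gene survives if and only if, in every dataset, its number of missing
#' values does not exceed that dataset's allowance. Surviving genes are kept
#' in their original order in all datasets simultaneously, and their residual
#' missing entries are imputed with the mean of the gene's observed values in
#' the same dataset (a neutral choice under the zero-mean standardisation
#' applied afterwards).
#'
#' @param collection List of [expression_dataset()]s sharing one gene list.
#' @param allowed Integer vector of maximum missing values per dataset
#'   (recycled if scalar).
#' @return A list with elements `collection` (the filtered, imputed datasets)
#'   and `genes` (the surviving gene IDs).
#' @export
filter_genes_by_missing <- function(collection, allowed = 0L) {
  genes <- validate_collection(collection)
  allowed <- rep_len(as.integer(allowed), length(collection))
  if (any(allowed < 0)) stop("`allowed` must be non-negative.", call. = FALSE)
  keep <- rep(TRUE, length(genes))
  for (i in seq_along(collection)) {
    keep <- keep & rowSums(collection[[i]]$missing_mask) <= allowed[i]
  }
  if (!any(keep)) {
    stop("No genes survive the missing-value filter; relax the allowances.",
         call. = FALSE)
  }
  out <- lapply(collection, function(ds) {
    values <- ds$values[keep, , drop = FALSE]
    mask <- ds$missing_mask[keep, , drop = FALSE]
    if (any(mask)) {
      row_means <- rowSums(values * !mask, na.rm = TRUE) / rowSums(!mask)
      idx <- which(mask, arr.ind = TRUE)
      values[idx] <- row_means[idx[, 1]]
    }
    expression_dataset(values, dataset_id = ds$dataset_id,
                       gene_ids = ds$gene_ids[keep], role = ds$role,
                       channel = ds$channel,
                       missing_mask = matrix(FALSE, sum(keep), ncol(values)))
  })
  list(collection = out, genes = genes[keep])
}

#' Quantile normalise a dataset
#'
#' Forces every sample (column) to share the identical empirical
#' distribution: the mean of the per-rank sorted values across columns. Ties
#' within a column receive interpolated rank-means. Idempotent.
#'
#' @param dataset An [expression_dataset()] with no missing values.
#' @return The normalised dataset.
#' @export
quantile_normalise <- function(dataset) {
  if (any(dataset$missing_mask)) {
    stop("Missing values present; filter/impute before quantile normalisation.",
         call. = FALSE)
  }
  values <- limma::normalizeQuantiles(dataset$values, ties = TRUE)
  dataset$values <- values
  dataset
}

#' Standardise gene profiles
#'
#' Centres every gene row to mean zero and, optionally, scales it to unit
#' sample standard deviation. A constant row cannot be scaled; it is left at
#' the zero vector with a warning.
#'
#' @param dataset An [expression_dataset()] with no missing values.
#' @param unit_sd Also scale rows to standard deviation 1?
#' @return The standardised dataset.
#' @export
standardise_genes <- function(dataset, unit_sd = TRUE) {
  if (any(dataset$missing_mask)) {
    stop("Missing values present; filter/impute before standardisation.",
         call. = FALSE)
  }
  values <- dataset$values - rowMeans(dataset$values)
  if (unit_sd) {
    sds <- apply(values, 1, sd)
    flat <- sds < .Machine$double.eps^0.5
    if (any(flat)) {
      warning(sum(flat), " constant gene row(s) left at the zero vector in '",
              dataset$dataset_id, "'.", call. = FALSE)
      sds[flat] <- 1
    }
    values <- values / sds
  }
  dataset$values <- values
  dataset
}

#' Preprocess a dataset collection for clustering
#'
#' Applies the missing-value filter, then normalises each dataset according
#' to its channel type: one-channel (and unknown) datasets are quantile
#' normalised and standardised to zero mean / unit standard deviation;
#' two-channel datasets, assumed to be upstream-normalised log-ratios, are
#' only centred to zero gene mean.
#'
#' @inheritParams filter_genes_by_missing
#' @return The preprocessed collection (a list of datasets).
#' @export
preprocess_collection <- function(collection, allowed = 0L) {
  filtered <- filter_genes_by_missing(collection, allowed)
  lapply(filtered$collection, function(ds) {
    if (ds$channel == "two_channel") {
      standardise_genes(ds, unit_sd = FALSE)
    } else {
      standardise_genes(quantile_normalise(ds), unit_sd = TRUE)
    }
  })
}
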