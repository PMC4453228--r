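# Orchestration of type A and type B runs over the K list and the delta
# grid(s), producing the full cluster pool as a tibble with one row per
# emitted cluster and the gene set held in a list-column of integer indices
# into the collection's shared gene list.

#' Configuration for a consensus-clustering run
#'
#' @param k_list Numbers of clusters to sweep. Default `c(4, 8, 12, 16, 20,
#'   25)`.
#' @param delta_grid Tightness thresholds for the difference-threshold
#'   binarisation; must be unique, ascending, within `[0, 1]`. Default 0 to 1
#'   in steps of 0.1 (11 values). Type B sweeps all pairs of this grid.
#' @param methods Base clustering methods, a subset of `c("kmeans", "som",
#'   "hc")` in that order.
#' @param weight_by_samples Weight each partition by its source dataset's
#'   number of samples when averaging into the consensus matrix?
#' @param seed Master seed; per-(dataset, method, K) sub-seeds are derived
#'   from it deterministically.
#' @param som_epochs Training epochs for the SOM base method.
#' @return An `uncles_config` list.
#' @export
uncles_config <- function(k_list = c(4L, 8L, 12L, 16L, 20L, 25L),
                          delta_grid = seq(0, 1, by = 0.1),
                          methods = c("kmeans", "som", "hc"),
                          weight_by_samples = FALSE,
                          seed = 1L,
                          som_epochs = 200L) {
  if (!all(methods %in% c("kmeans", "som", "hc")) || length(methods) == 0) {
    stop("`methods` must be a non-empty subset of c(\"kmeans\", \"som\", \"hc\").",
         call. = FALSE)
  }
  methods <- intersect(c("kmeans", "som", "hc"), methods)
  k_list <- as.integer(k_list)
  if (any(k_list < 1)) stop("All K values must be >= 1.", call. = FALSE)
  delta_grid <- round(as.numeric(delta_grid), 10)
  if (anyDuplicated(delta_grid) || is.unsorted(delta_grid, strictly = TRUE) ||
      any(delta_grid < 0 | delta_grid > 1)) {
    stop("`delta_grid` must be unique, ascending and within [0, 1].",
         call. = FALSE)
  }
  structure(
    list(k_list = k_list, delta_grid = delta_grid, methods = methods,
         weight_by_samples = weight_by_samples, seed = as.integer(seed),
         som_epochs = as.integer(som_epochs)),
    class = "uncles_config"
  )
}

#' Size of the cluster pool implied by a configuration
#'
#' Type A emits K clusters per (K, delta) pair, so the pool holds
#' `|delta_grid| * sum(k_list)` records; type B sweeps all (delta+, delta-)
#' pairs, so it holds `|delta_grid|^2 * sum(k_list)`. With the default grids
#' these are 935 and 10,285 records.
#'
#' @param config An [uncles_config()].
#' @param type `"A"` or `"B"`.
#' @return Integer record count.
#' @export
pool_size <- function(config, type = c("A", "B")) {
  type <- match.arg(type)
  n_delta <- length(config$delta_grid)
  base <- sum(config$k_list)
  as.integer(if (type == "A") n_delta * base else n_delta^2 * base)
}

#' Generate all base partitions for a collection
#'
#' Computes one hard partition per (dataset, method, K). Partitions are
#' computed once and reused across all delta values (binarisation is a
#' post-hoc thresholding of the consensus matrix) and across type A and
#' type B runs on subsets of the same collection. The Ward tree of each
#' dataset is built once and cut at every K.
#'
#' @param collection List of preprocessed [expression_dataset()]s.
#' @param config An [uncles_config()].
#' @return A nested list `partitions[[dataset_id]][[K]][[method]]`.
#' @export
generate_partitions <- function(collection, config) {
  validate_collection(collection)
  out <- list()
  for (ds in collection) {
    tree <- if ("hc" %in% config$methods) ward_tree(ds) else NULL
    per_k <- list()
    for (k in config$k_list) {
      per_method <- list()
      for (method in config$methods) {
        per_method[[method]] <- switch(
          method,
          kmeans = kmeans_partition(ds, k),
          som = som_partition(
            ds, k, seed = derive_seed(config$seed, ds$dataset_id, "som", k),
            epochs = config$som_epochs
          ),
          hc = hierarchical_partition(ds, k, tree = tree)
        )
      }
      per_k[[as.character(k)]] <- per_method
    }
    out[[ds$dataset_id]] <- per_k
  }
  out
}

# Partition list for one K in dataset-outer, method-inner order, plus the
# matching per-partition sample-count weights.
assemble_partitions <- function(partitions, collection, k, config) {
  parts <- list()
  weights <- numeric(0)
  for (ds in collection) {
    for (method in config$methods) {
      parts[[length(parts) + 1L]] <- partitions[[ds$dataset_id]][[as.character(k)]][[method]]
      weights <- c(weights, ncol(ds$values))
    }
  }
  if (!config$weight_by_samples) weights <- rep(1, length(parts))
  list(partitions = parts, weights = weights)
}

# Relabelled, averaged consensus matrix for one K over a collection.
copam_for_k <- function(partitions, collection, k, config) {
  asm <- assemble_partitions(partitions, collection, k, config)
  aligned <- relabel_partitions(asm$partitions)
  build_copam(aligned, weights = asm$weights)
}

# Grows the pool columns with amortised O(1) appends; one tibble is
# assembled at the end (building one tibble per record does not scale to
# the 10,285-record type B pool).
pool_accumulator <- function() {
  ids <- character(); types <- character(); ks <- integer()
  deltas <- numeric(); dms <- numeric(); genes <- vector("list", 0)
  n <- 0L
  add <- function(id, type, k, delta, delta_minus, gene_idx) {
    n <<- n + 1L
    if (n > length(ids)) {
      grow <- max(1024L, length(ids))
      length(ids) <<- length(ids) + grow
      length(types) <<- length(ids); length(ks) <<- length(ids)
      length(deltas) <<- length(ids); length(dms) <<- length(ids)
      length(genes) <<- length(ids)
    }
    ids[n] <<- id; types[n] <<- type; ks[n] <<- k
    deltas[n] <<- delta; dms[n] <<- delta_minus
    genes[[n]] <<- gene_idx
    invisible(NULL)
  }
  as_tibble <- function() {
    idx <- seq_len(n)
    tibble::tibble(
      record_id = ids[idx], type = types[idx], k = ks[idx],
      delta = deltas[idx], delta_minus = dms[idx],
      n_genes = lengths(genes[idx]), genes = genes[idx]
    )
  }
  list(add = add, as_tibble = as_tibble)
}

new_pool <- function(acc, gene_ids, config) {
  pool <- acc$as_tibble()
  attr(pool, "gene_ids") <- gene_ids
  attr(pool, "config") <- config
  class(pool) <- c("uncles_pool", class(pool))
  pool
}

delta_label <- function(x) formatC(x, format = "fg")

#' Run a type A analysis: consistent co-expression in all datasets
#'
#' For every K in the configuration, base partitions of every dataset by
#' every method are relabelled and averaged into a consensus matrix, which is
#' then binarised at every delta in the grid; each binarisation emits K
#' cluster records (possibly empty). The pool is ordered by (K, delta,
#' cluster index).
#'
#' @param collection List of preprocessed [expression_dataset()]s sharing one
#'   gene list.
#' @param config An [uncles_config()].
#' @param partitions Optional precomputed [generate_partitions()] result for
#'   this collection (or a superset of it).
#' @return An `uncles_pool` tibble with columns `record_id`, `type`, `k`,
#'   `delta`, `delta_minus` (`NA` for type A), `n_genes` and the list-column
#'   `genes` of integer gene indices.
#' @export
run_type_a <- function(collection, config = uncles_config(), partitions = NULL) {
  gene_ids <- validate_collection(collection)
  if (is.null(partitions)) partitions <- generate_partitions(collection, config)
  acc <- pool_accumulator()
  for (k in config$k_list) {
    copam <- copam_for_k(partitions, collection, k, config)
    for (delta in config$delta_grid) {
      bin <- dtb_binarise(copam, delta)
      for (j in seq_len(k)) {
        acc$add(sprintf("A_K%d_d%s_c%d", k, delta_label(delta), j),
                "A", k, delta, NA_real_, which(bin[j, ] == 1L))
      }
    }
  }
  new_pool(acc, gene_ids, config)
}

#' Run a type B analysis: co-expressed in S+ but not in S-
#'
#' For every K and every (delta+, delta-) pair, the type A machinery is run
#' on the positive datasets at delta+ and on the negative datasets at delta-;
#' every gene assigned to any cluster in the negative result is then removed
#' from every positive cluster. At delta- = 0 all genes are assigned in the
#' negatives, so all records are empty; the widest non-trivial setting is
#' (0, 1) and the tightest (1, epsilon), epsilon being the smallest positive
#' grid value. The pool is ordered by (K, delta+, delta-, cluster index).
#'
#' @param positives,negatives Lists of preprocessed [expression_dataset()]s
#'   sharing one gene list.
#' @param config An [uncles_config()].
#' @param partitions Optional precomputed [generate_partitions()] result
#'   covering both collections.
#' @return An `uncles_pool` tibble (see [run_type_a()]); `delta` holds
#'   delta+ and `delta_minus` holds delta-.
#' @export
run_type_b <- function(positives, negatives, config = uncles_config(),
                       partitions = NULL) {
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("Type B needs non-empty positive and negative collections.",
         call. = FALSE)
  }
  gene_ids <- validate_collection(c(positives, negatives))
  if (is.null(partitions)) {
    partitions <- generate_partitions(c(positives, negatives), config)
  }
  acc <- pool_accumulator()
  for (k in config$k_list) {
    copam_pos <- copam_for_k(partitions, positives, k, config)
    copam_neg <- copam_for_k(partitions, negatives, k, config)
    bin_pos <- lapply(config$delta_grid, function(d) dtb_binarise(copam_pos, d))
    neg_assigned <- lapply(config$delta_grid, function(d) {
      colSums(dtb_binarise(copam_neg, d)) > 0
    })
    for (ip in seq_along(config$delta_grid)) {
      dp <- config$delta_grid[ip]
      pos_rows <- lapply(seq_len(k), function(j) bin_pos[[ip]][j, ] == 1L)
      for (im in seq_along(config$delta_grid)) {
        dm <- config$delta_grid[im]
        keep <- !neg_assigned[[im]]
        for (j in seq_len(k)) {
          acc$add(sprintf("B_K%d_dp%s_dm%s_c%d", k, delta_label(dp),
                          delta_label(dm), j),
                  "B", k, dp, dm, which(pos_rows[[j]] & keep))
        }
      }
    }
  }
  new_pool(acc, gene_ids, config)
}

#' Cluster pool from a single base method applied per dataset
#'
#' Comparator harness: one clustering method applied to each dataset
#' separately at each K, every resulting cluster entering the pool as its
#' own record. With six datasets and the comparator K grid
#' `c(4, 8, 12, 16, 20, 25, 50, 75, 100, 125)` this yields 2,610 records.
#'
#' @param collection List of preprocessed [expression_dataset()]s.
#' @param method One of `"kmeans"`, `"som"`, `"hc"`.
#' @param k_list K values to sweep.
#' @param seed Master seed (SOM only).
#' @return An `uncles_pool`-shaped tibble with `type` set to the method name.
#' @export
single_method_pool <- function(collection, method = c("kmeans", "som", "hc"),
                               k_list = c(4L, 8L, 12L, 16L, 20L, 25L, 50L,
                                          75L, 100L, 125L),
                               seed = 1L) {
  method <- match.arg(method)
  gene_ids <- validate_collection(collection)
  k_list <- as.integer(k_list)
  acc <- pool_accumulator()
  for (ds in collection) {
    tree <- if (method == "hc") ward_tree(ds) else NULL
    for (k in k_list) {
      part <- switch(
        method,
        kmeans = kmeans_partition(ds, k),
        som = som_partition(ds, k,
                            seed = derive_seed(seed, ds$dataset_id, "som", k)),
        hc = hierarchical_partition(ds, k, tree = tree)
      )
      for (j in seq_len(k)) {
        acc$add(sprintf("%s_%s_K%d_c%d", method, ds$dataset_id, k, j),
                method, k, NA_real_, NA_real_, which(part[j, ] == 1L))
      }
    }
  }
  new_pool(acc, gene_ids, NULL)
}

#' Map a pool's integer gene indices to gene IDs
#'
#' @param pool An `uncles_pool` tibble.
#' @param gene_ids Shared gene list; defaults to the pool's own attribute.
#' @return The pool with an added `gene_id_sets` list-column of character
#'   vectors.
#' @export
pool_gene_ids <- function(pool, gene_ids = attr(pool, "gene_ids")) {
  if (is.null(gene_ids)) stop("No gene IDs attached to this pool.", call. = FALSE)
  pool$gene_id_sets <- lapply(pool$genes, function(idx) gene_ids[idx])
  pool
}

#' Write a cluster pool as TSV
#'
#' One row per record: `record_id`, `type`, `k`, `delta`, `delta_minus`,
#' `n_genes` and the semicolon-joined gene IDs.
#'
#' @param pool An `uncles_pool` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  gene_ids <- attr(pool, "gene_ids")
  out <- data.frame(
    record_id = pool$record_id, type = pool$type, k = pool$k,
    delta = pool$delta, delta_minus = pool$delta_minus,
    n_genes = pool$n_genes,
    genes = vapply(pool$genes, function(idx) {
      paste(if (is.null(gene_ids)) idx else gene_ids[idx], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
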