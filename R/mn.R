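# M-N scatter-plot cluster selection: score every pooled cluster by the
# MSE-related metric M (minimise) against log gene count N (maximise), scale
# both axes to [0, 1], and iteratively pick the cluster nearest the top-left
# corner, discarding everything that overlaps it.

#' Mean-squared error of a cluster in one dataset
#'
#' The within-cluster dispersion `(1 / (D * Nk)) * sum_i ||x_i - z||^2`,
#' where the sum runs over the member genes' profiles and `z` is their mean
#' profile. Zero for singleton clusters and for clusters of identical
#' profiles.
#'
#' @param dataset An [expression_dataset()] (normalised).
#' @param genes Non-empty gene set: integer indices or gene IDs.
#' @return A single non-negative number.
#' @export
cluster_mse <- function(dataset, genes) {
  idx <- resolve_genes(genes, dataset$gene_ids)
  if (length(idx) == 0) stop("`genes` must be non-empty.", call. = FALSE)
  x <- dataset$values[idx, , drop = FALSE]
  z <- colMeans(x)
  sum(sweep(x, 2, z)^2) / (ncol(x) * nrow(x))
}

resolve_genes <- function(genes, gene_ids) {
  if (is.character(genes)) {
    idx <- match(genes, gene_ids)
    if (anyNA(idx)) {
      stop("Unknown gene IDs: ", paste(genes[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    idx
  } else {
    as.integer(genes)
  }
}

#' MSE-related metric M of a cluster over a dataset collection
#'
#' Type A: the mean of the cluster's per-dataset MSEs over all datasets.
#' Type B: the mean MSE over the negative datasets subtracted from the mean
#' MSE over the positive datasets (so consistent tightness in S+ and
#' looseness in S- drives M down). Smaller is better for both types.
#'
#' @param genes Non-empty gene set (indices or IDs).
#' @param collection List of [expression_dataset()]s; for type B their
#'   `role` fields must mark the positive and negative subsets.
#' @param type `"A"` or `"B"`.
#' @return A single number.
#' @export
m_metric <- function(genes, collection, type = c("A", "B")) {
  type <- match.arg(type)
  mses <- vapply(collection, cluster_mse, numeric(1), genes = genes)
  if (type == "A") {
    return(mean(mses))
  }
  roles <- vapply(collection, function(d) d$role, character(1))
  if (!any(roles == "positive") || !any(roles == "negative")) {
    stop("Type B needs at least one positive and one negative dataset.",
         call. = FALSE)
  }
  mean(mses[roles == "positive"]) - mean(mses[roles == "negative"])
}

# M for every non-empty pool record, grouped by binarisation setting so that
# each group's disjoint clusters share one rowsum pass per dataset.
pool_m_metrics <- function(pool, collection) {
  n <- nrow(pool)
  dm <- ifelse(is.na(pool$delta_minus), -1, pool$delta_minus)
  dp <- ifelse(is.na(pool$delta), -1, pool$delta)
  group <- interaction(pool$type, pool$k, dp, dm, drop = TRUE, sep = "/")
  per_dataset <- matrix(NA_real_, n, length(collection))
  sizes <- pool$n_genes
  for (d in seq_along(collection)) {
    x <- collection[[d]]$values
    row_sq <- rowSums(x^2)
    dd <- ncol(x)
    for (grp in levels(group)) {
      rows <- which(group == grp & sizes > 0)
      if (length(rows) == 0) next
      idx <- unlist(pool$genes[rows], use.names = FALSE)
      grp_of <- rep.int(seq_along(rows), sizes[rows])
      z <- rowsum(x[idx, , drop = FALSE], grp_of, reorder = TRUE)
      nk <- sizes[rows]
      s1 <- rowsum(row_sq[idx], grp_of, reorder = TRUE)[, 1]
      per_dataset[rows, d] <- (s1 - rowSums(z^2) / nk) / (dd * nk)
    }
  }
  roles <- vapply(collection, function(ds) ds$role, character(1))
  m <- rep(NA_real_, n)
  is_a <- pool$type != "B"
  if (any(is_a)) m[is_a] <- rowMeans(per_dataset[is_a, , drop = FALSE])
  if (any(!is_a)) {
    if (!any(roles == "positive") || !any(roles == "negative")) {
      stop("Type B records need positive and negative dataset roles.",
           call. = FALSE)
    }
    m[!is_a] <-
      rowMeans(per_dataset[!is_a, roles == "positive", drop = FALSE]) -
      rowMeans(per_dataset[!is_a, roles == "negative", drop = FALSE])
  }
  m
}

# Min-max scale the M (minimise) and logN (maximise) axes to [0, 1]. A
# degenerate axis (all points equal) carries no ranking information and is
# pinned to its ideal coordinate: 0 for M, 1 for N.
scale_mn <- function(m, log_n) {
  span_m <- max(m) - min(m)
  span_n <- max(log_n) - min(log_n)
  scaled_m <- if (span_m > 0) (m - min(m)) / span_m else rep(0, length(m))
  scaled_n <- if (span_n > 0) (log_n - min(log_n)) / span_n else rep(1, length(log_n))
  tibble::tibble(scaled_m = scaled_m, scaled_n = scaled_n,
                 corner_distance = sqrt(scaled_m^2 + (1 - scaled_n)^2))
}

#' Build the M-N scatter of a cluster pool
#'
#' Excludes empty records, computes M and the natural log of the gene count
#' for each remaining record, min-max scales both axes to `[0, 1]` over the
#' included points, and measures each point's Euclidean distance to the
#' ideal top-left corner (scaled M = 0, scaled N = 1). The scaling is
#' computed once on the full scatter; later selection iterations reuse it so
#' that distances remain comparable across iterations.
#'
#' @param pool An `uncles_pool` tibble from [run_type_a()], [run_type_b()] or
#'   [single_method_pool()].
#' @param collection The dataset collection the pool was computed on.
#' @return An `mn_scatter` tibble: the non-empty pool rows plus `m`, `log_n`,
#'   `scaled_m`, `scaled_n`, `corner_distance`.
#' @export
build_mn_scatter <- function(pool, collection) {
  if (all(pool$n_genes == 0)) {
    stop("All pool records are empty; nothing to scatter.", call. = FALSE)
  }
  m <- pool_m_metrics(pool, collection)
  scatter <- pool[pool$n_genes > 0, , drop = FALSE]
  scatter$m <- m[pool$n_genes > 0]
  scatter$log_n <- log(scatter$n_genes)
  scatter <- dplyr::bind_cols(scatter, scale_mn(scatter$m, scatter$log_n))
  attr(scatter, "gene_ids") <- attr(pool, "gene_ids")
  class(scatter) <- c("mn_scatter", "tbl_df", "tbl", "data.frame")
  scatter
}

#' Iteratively select best clusters from an M-N scatter
#'
#' Repeatedly picks the point with the smallest corner distance, then removes
#' it together with every point whose gene set shares at least one gene with
#' it, until `max_clusters` picks have been made or no points remain.
#' Distance ties are broken in favour of the larger cluster, then the smaller
#' K, then input order. Because the axis scaling is fixed once, the picked
#' distances form a non-decreasing sequence whose gaps can be inspected to
#' decide how many clusters to keep (the cut-off is study-specific and is
#' not automated).
#'
#' @param scatter An `mn_scatter` tibble from [build_mn_scatter()].
#' @param max_clusters Maximum number of clusters to select (>= 1).
#' @return An `mn_selection` tibble: the picked rows, in order, with a
#'   `rank` column prepended.
#' @export
iterative_select <- function(scatter, max_clusters = 10L) {
  if (max_clusters < 1) stop("`max_clusters` must be >= 1.", call. = FALSE)
  if (nrow(scatter) == 0) stop("Empty scatter.", call. = FALSE)
  gene_count <- max(vapply(scatter$genes, max, numeric(1)))
  membership <- matrix(FALSE, nrow(scatter), gene_count)
  for (i in seq_len(nrow(scatter))) membership[i, scatter$genes[[i]]] <- TRUE
  preference <- order(scatter$corner_distance, -scatter$n_genes, scatter$k,
                      seq_len(nrow(scatter)))
  alive <- rep(TRUE, nrow(scatter))
  picks <- integer(0)
  while (length(picks) < max_clusters && any(alive)) {
    best <- preference[alive[preference]][1]
    picks <- c(picks, best)
    overlaps <- membership %*% membership[best, ] > 0
    alive <- alive & !drop(overlaps)
  }
  out <- scatter[picks, , drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_along(picks)), out)
  attr(out, "gene_ids") <- attr(scatter, "gene_ids")
  class(out) <- c("mn_selection", "tbl_df", "tbl", "data.frame")
  out
}

#' Plot an M-N scatter
#'
#' Scaled M against scaled log gene count, the ideal corner at the top left.
#' If a selection is supplied its picks are drawn as filled, labelled
#' markers.
#'
#' @param object An `mn_scatter` tibble.
#' @param selection Optional `mn_selection` from [iterative_select()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.mn_scatter <- function(object, selection = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$scaled_m,
                                            y = .data$scaled_n)) +
    ggplot2::geom_point(shape = 0, colour = "grey30", size = 1.5) +
    ggplot2::labs(x = "scaled M (dispersion, minimise)",
                  y = "scaled log N (gene count, maximise)") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_classic()
  if (!is.null(selection)) {
    p <- p +
      ggplot2::geom_point(data = selection, colour = "blue", size = 3) +
      ggplot2::geom_text(data = selection,
                         ggplot2::aes(label = .data$rank),
                         vjust = -1, colour = "blue")
  }
  p
}

#' @export
plot.mn_scatter <- function(x, y, ...) print(autoplot.mn_scatter(x, ...))

#' Write an M-N scatter (or selection) as TSV
#'
#' @param scatter An `mn_scatter` or `mn_selection` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mn_scatter <- function(scatter, path) {
  cols <- intersect(
    c("rank", "record_id", "type", "k", "delta", "delta_minus", "n_genes",
      "m", "log_n", "scaled_m", "scaled_n", "corner_distance"),
    names(scatter)
  )
  write.table(as.data.frame(scatter[, cols]), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
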