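# Hard partitions of the gene set, one per (dataset, method, K).
#
# A partition_matrix is a binary K x G matrix whose columns each sum to 1
# (every gene in exactly one cluster; rows may be empty) with provenance
# attributes {method, dataset_id, k, seed}.

partition_matrix <- function(labels, k, method, dataset_id, seed = NA_integer_) {
  g <- length(labels)
  stopifnot(all(labels >= 1L), all(labels <= k))
  m <- matrix(0L, nrow = k, ncol = g)
  m[cbind(labels, seq_len(g))] <- 1L
  structure(m, class = c("partition_matrix", "matrix"),
            method = method, dataset_id = dataset_id, k = k, seed = seed)
}

#' @export
print.partition_matrix <- function(x, ...) {
  cat(sprintf("<partition_matrix> %s on %s: K=%d, G=%d (%d empty clusters)\n",
              attr(x, "method"), attr(x, "dataset_id"), nrow(x), ncol(x),
              sum(rowSums(x) == 0)))
  invisible(x)
}

check_k <- function(k, g) {
  if (k < 1) stop("K must be >= 1.", call. = FALSE)
  if (k > g) stop("K (", k, ") exceeds the number of genes (", g, ").",
                  call. = FALSE)
}

# Deterministic maximin (KA-style) seeding: first centre is the profile with
# the largest norm, each next centre the profile maximising its minimum
# squared distance to the centres already chosen.
maximin_centers <- function(x, k) {
  g <- nrow(x)
  chosen <- integer(k)
  chosen[1] <- which.max(rowSums(x^2))
  if (k > 1) {
    mind <- sqdist_to_point(x, x[chosen[1], ])
    for (j in 2:k) {
      mind[chosen[seq_len(j - 1)]] <- -Inf
      chosen[j] <- which.max(mind)
      mind <- pmin(mind, sqdist_to_point(x, x[chosen[j], ]))
    }
  }
  x[chosen, , drop = FALSE]
}

sqdist_to_point <- function(x, p) {
  rowSums(x^2) - 2 * drop(x %*% p) + sum(p^2)
}

# G x K matrix of squared distances from every profile to every centre.
sqdist_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
}

#' k-means partition with deterministic maximin initialisation
#'
#' Lloyd iterations started from the maximin (KA-style) seeding, which makes
#' the result fully deterministic for a fixed input. A cluster that empties
#' during iteration keeps its last centroid, so K is preserved (its row in
#' the partition matrix is empty).
#'
#' @param dataset An [expression_dataset()] (preprocessed).
#' @param k Number of clusters, `1 <= k <= G`.
#' @param max_iter Maximum Lloyd iterations.
#' @return A `partition_matrix` (binary K x G, columns summing to 1).
#' @export
kmeans_partition <- function(dataset, k, max_iter = 100L) {
  x <- dataset$values
  check_k(k, nrow(x))
  centers <- maximin_centers(x, k)
  labels <- lloyd_labels(x, centers, max_iter)
  partition_matrix(labels, k, "kmeans", dataset$dataset_id)
}

lloyd_labels <- function(x, centers, max_iter) {
  labels <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to_centers(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(nrow(centers))) {
      members <- labels == j
      if (any(members)) centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  labels
}

#' Self-organising map partition
#'
#' Trains a one-dimensional chain of `k` nodes (node count = cluster count)
#' with a Gaussian neighbourhood whose radius and learning rate shrink
#' linearly over a fixed number of epochs; genes are presented in a random
#' order drawn under `seed`, making the result reproducible for a fixed seed.
#' Nodes are initialised at `k` randomly chosen gene profiles.
#'
#' @inheritParams kmeans_partition
#' @param seed Integer RNG seed controlling initialisation and the
#'   presentation order.
#' @param epochs Training epochs (full passes over the genes).
#' @param alpha Learning-rate schedule, `c(start, end)`.
#' @return A `partition_matrix`.
#' @export
som_partition <- function(dataset, k, seed = 1L, epochs = 200L,
                          alpha = c(0.5, 0.01)) {
  x <- dataset$values
  g <- nrow(x)
  check_k(k, g)
  res <- with_seed(seed, {
    init <- x[sample.int(g, k), , drop = FALSE]
    order <- matrix(0L, nrow = epochs, ncol = g)
    for (e in seq_len(epochs)) order[e, ] <- sample.int(g)
    som_chain_train(x, k, order, init, alpha[1], alpha[2],
                    sigma0 = max(k / 2, 0.5), sigma1 = 0.5)
  })
  partition_matrix(res, k, "som", dataset$dataset_id, seed = as.integer(seed))
}

#' Hierarchical (Ward) partition
#'
#' Ward-linkage agglomeration on Euclidean distances, cut at `k` clusters.
#' Deterministic. When several cuts of one dataset at different `k` are
#' needed, pass a precomputed tree to avoid recomputing the distance matrix.
#'
#' @inheritParams kmeans_partition
#' @param tree Optional [stats::hclust] tree of the dataset's gene profiles
#'   (Ward linkage on Euclidean distances).
#' @return A `partition_matrix`.
#' @export
hierarchical_partition <- function(dataset, k, tree = NULL) {
  g <- nrow(dataset$values)
  check_k(k, g)
  if (is.null(tree)) tree <- ward_tree(dataset)
  labels <- as.integer(cutree(tree, k = k))
  partition_matrix(labels, k, "hc", dataset$dataset_id)
}

ward_tree <- function(dataset) {
  hclust(dist(dataset$values), method = "ward.D2")
}
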