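# Consensus over relabelled partitions: fuzzy consensus partition matrix
# (CoPaM) and difference-threshold binarisation (DTB).

# Minimum-cost one-to-one assignment (Hungarian algorithm, shortest
# augmenting paths, O(n^3)). `cost` is a square matrix; returns an integer
# vector p with p[i] = column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1)        # column potentials, index 1 = virtual column
  p <- integer(n + 1)        # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) assignment[p[j]] <- j - 1L
  assignment
}

#' Relabel partitions against a common reference
#'
#' Cluster labels are arbitrary within each hard partition, so before
#' averaging, every partition's clusters must be aligned. The first partition
#' serves as the reference; each other partition's rows are permuted by the
#' one-to-one cluster mapping that maximises the total number of shared genes
#' with the reference (optimal assignment, which avoids the collisions a
#' greedy pairwise mapping can produce).
#'
#' @param partitions List of `partition_matrix` objects sharing K and G.
#' @return The list with every partition's rows permuted into alignment.
#' @export
relabel_partitions <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  k <- nrow(partitions[[1]])
  g <- ncol(partitions[[1]])
  ref <- partitions[[1]]
  out <- partitions
  for (r in seq_along(partitions)[-1]) {
    part <- partitions[[r]]
    if (nrow(part) != k || ncol(part) != g) {
      stop("Partition ", r, " does not share K and G with the reference.",
           call. = FALSE)
    }
    overlap <- ref %*% t(part)               # K x K shared-gene counts
    perm <- solve_assignment(-overlap)       # maximise total overlap
    permuted <- part[perm, , drop = FALSE]
    attributes(permuted) <- attributes(part)
    out[[r]] <- permuted
  }
  out
}

#' Build the fuzzy consensus partition matrix (CoPaM)
#'
#' The CoPaM is the (weighted) average of the relabelled hard partitions: its
#' entry (k, g) is the fraction of partitions, weighted if requested, that
#' placed gene g in cluster k. Columns therefore sum to 1. With
#' sample-count weighting, each partition's weight is proportional to its
#' source dataset's number of samples.
#'
#' @param aligned List of relabelled `partition_matrix` objects.
#' @param weights Optional non-negative per-partition weights (normalised
#'   internally to sum to 1); default is equal weighting.
#' @return A `copam` object: a real K x G matrix with entries in `[0, 1]`.
#' @export
build_copam <- function(aligned, weights = NULL) {
  stopifnot(length(aligned) >= 1)
  r <- length(aligned)
  if (is.null(weights)) weights <- rep(1, r)
  if (length(weights) != r) {
    stop("Need one weight per partition.", call. = FALSE)
  }
  if (any(weights < 0)) stop("Weights must be non-negative.", call. = FALSE)
  if (sum(weights) == 0) stop("Weights must not all be zero.", call. = FALSE)
  weights <- weights / sum(weights)
  m <- matrix(0, nrow(aligned[[1]]), ncol(aligned[[1]]))
  for (i in seq_len(r)) m <- m + weights[i] * unclass(aligned[[i]])
  structure(m, class = c("copam", "matrix"),
            source_count = r, weights = weights)
}

#' Difference-threshold binarisation (DTB)
#'
#' Assigns each gene to its maximum-membership cluster if and only if the gap
#' between that membership and the runner-up membership is at least `delta`;
#' otherwise the gene is left unassigned. At `delta = 0` every gene is
#' assigned (exact ties go to the lowest-index cluster) and the clusters
#' partition the genome; at `delta = 1` a gene is assigned only where its
#' membership is exactly 1, i.e. where all partitions agreed. For K = 1 the
#' runner-up membership is taken as 0.
#'
#' @param copam A [build_copam()] result (K x G fuzzy memberships).
#' @param delta Tightness threshold in `[0, 1]`.
#' @return A binary K x G matrix; columns sum to 0 (unassigned) or 1.
#' @export
dtb_binarise <- function(copam, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1) {
    stop("`delta` must be a single value in [0, 1].", call. = FALSE)
  }
  m <- unclass(copam)
  k <- nrow(m)
  g <- ncol(m)
  top_idx <- max.col(t(m), ties.method = "first")
  top <- m[cbind(top_idx, seq_len(g))]
  if (k == 1) {
    second <- rep(0, g)
  } else {
    masked <- m
    masked[cbind(top_idx, seq_len(g))] <- -Inf
    second <- apply(masked, 2, max)
  }
  assigned <- (top - second) >= delta
  out <- matrix(0L, k, g)
  out[cbind(top_idx[assigned], which(assigned))] <- 1L
  structure(out, class = c("binary_assignment", "matrix"), delta = delta)
}
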