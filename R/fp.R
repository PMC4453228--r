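# Ground-truth evaluation of clusters: binomial-tail p-values, scaled
# p-values, F-P scatter coordinates and the between-method comparison
# statistic.

#' Ground truth for cluster evaluation
#'
#' @param target_genes The true gene set: integer indices or gene IDs.
#' @param genome_size Total number of genes under analysis.
#' @param gene_ids Optional shared gene list (enables ID-based targets and
#'   membership checks).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(target_genes, genome_size, gene_ids = NULL) {
  idx <- resolve_genes(target_genes, gene_ids %||% character(0))
  genome_size <- as.integer(genome_size)
  if (length(idx) < 1 || length(idx) > genome_size) {
    stop("Need 1 <= |target| <= genome_size.", call. = FALSE)
  }
  if (any(idx < 1 | idx > genome_size)) {
    stop("Target gene indices outside the genome.", call. = FALSE)
  }
  structure(list(target = sort(unique(idx)), genome_size = genome_size,
                 gene_ids = gene_ids),
            class = "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binomial tail p-value of a cluster's true-positive count
#'
#' The probability of drawing at least `n` members of an `m`-gene target set
#' in `N` independent draws from an `M`-gene genome (draw probability
#' `m / M`): `sum_{j=n}^{N} C(N, j) (m/M)^j ((M-m)/M)^(N-j)`. Evaluated
#' through the stable binomial tail, so it is accurate for large `N`.
#'
#' @param genome_size Genome size `M`.
#' @param m Target-set size.
#' @param N Cluster size.
#' @param n True positives in the cluster.
#' @return The tail probability in `(0, 1]`.
#' @export
binomial_pvalue <- function(genome_size, m, N, n) {
  if (any(n < 0 | N < n | genome_size < N) || any(m < 1 | m > genome_size)) {
    stop("Require 0 <= n <= N <= genome_size and 1 <= m <= genome_size.",
         call. = FALSE)
  }
  pbinom(n - 1, N, m / genome_size, lower.tail = FALSE)
}

#' Scaled p-value
#'
#' `log(p) / log((m / GS)^m)`: the ratio of the log p-value to the log of the
#' best theoretically possible p-value at this genome size (that of the
#' ideal cluster `N = n = m`). Equals 1 for the ideal cluster and 0 when
#' `p = 1` (no true positives). Values are clipped to `[0, 1]`.
#'
#' @param p_value A p-value in `(0, 1]`.
#' @inheritParams binomial_pvalue
#' @return A number in `[0, 1]`.
#' @export
scaled_pvalue <- function(p_value, m, genome_size) {
  if (any(p_value <= 0)) stop("`p_value` must be positive.", call. = FALSE)
  denom <- m * log(m / genome_size)
  if (denom == 0) return(rep(0, length(p_value)))
  pmin(1, pmax(0, log(p_value) / denom))
}

#' F-P coordinates of one cluster
#'
#' Computes the cluster's true-positive count, its in-cluster false-positive
#' rate `(N - n) / N`, the binomial tail p-value, the scaled p-value, and
#' the Euclidean distance to the ideal top-left corner (FPR 0, scaled
#' p-value 1). The distance is bounded by `sqrt(2)` and is 0 exactly when
#' the cluster equals the target set. An empty cluster is mapped to the
#' worst corner (FPR 1, scaled p-value 0) so it can never win a comparison.
#'
#' @param cluster Gene set: integer indices or gene IDs.
#' @param truth A [ground_truth()].
#' @return A one-row tibble: `N`, `n`, `fpr`, `p_value`, `scaled_p`,
#'   `corner_distance`.
#' @export
fp_point <- function(cluster, truth) {
  idx <- resolve_genes(cluster, truth$gene_ids %||% character(0))
  if (any(idx < 1 | idx > truth$genome_size)) {
    stop("Cluster contains genes outside the genome.", call. = FALSE)
  }
  N <- length(idx)
  if (N == 0) {
    return(tibble::tibble(N = 0L, n = 0L, fpr = 1, p_value = 1, scaled_p = 0,
                          corner_distance = sqrt(2)))
  }
  n <- sum(idx %in% truth$target)
  p <- binomial_pvalue(truth$genome_size, length(truth$target), N, n)
  sp <- scaled_pvalue(p, length(truth$target), truth$genome_size)
  fpr <- (N - n) / N
  tibble::tibble(N = N, n = n, fpr = fpr, p_value = p, scaled_p = sp,
                 corner_distance = sqrt(fpr^2 + (1 - sp)^2))
}

#' Evaluate every record of a cluster pool against a ground truth
#'
#' @param pool An `uncles_pool` tibble.
#' @param truth A [ground_truth()].
#' @return An `fp_scatter` tibble: the pool rows plus the [fp_point()]
#'   columns `n_true`, `fpr`, `p_value`, `scaled_p`, `corner_distance`.
#' @export
fp_evaluate <- function(pool, truth) {
  target_mask <- logical(truth$genome_size)
  target_mask[truth$target] <- TRUE
  N <- pool$n_genes
  n <- vapply(pool$genes, function(idx) sum(target_mask[idx]), numeric(1))
  m <- length(truth$target)
  empty <- N == 0
  p <- binomial_pvalue(truth$genome_size, m, pmax(N, 1L), n)
  p[empty] <- 1
  sp <- scaled_pvalue(p, m, truth$genome_size)
  sp[empty] <- 0
  fpr <- (N - n) / pmax(N, 1L)
  fpr[empty] <- 1
  out <- pool
  out$n_true <- as.integer(n)
  out$fpr <- fpr
  out$p_value <- p
  out$scaled_p <- sp
  out$corner_distance <- sqrt(fpr^2 + (1 - sp)^2)
  attr(out, "truth") <- truth
  class(out) <- c("fp_scatter", "tbl_df", "tbl", "data.frame")
  out
}

#' Zero-false-negative curve of an F-P plot
#'
#' For each cluster size `N >= m`, the F-P coordinates of a cluster that
#' contains the whole target set (`n = m`): the theoretical upper limit for
#' the scaled p-value at any fixed false-positive rate. The curve starts at
#' the ideal corner (`N = m`) and slides towards the bottom-right as `N`
#' grows.
#'
#' @param truth A [ground_truth()].
#' @param N_values Cluster sizes, each `>= m`.
#' @return A tibble: `N`, `fpr`, `p_value`, `scaled_p`.
#' @export
zero_fn_curve <- function(truth, N_values = NULL) {
  m <- length(truth$target)
  if (is.null(N_values)) N_values <- seq(m, truth$genome_size)
  N_values <- as.integer(N_values)
  if (any(N_values < m)) {
    stop("Every N on the zero-false-negative curve must be >= m.",
         call. = FALSE)
  }
  p <- binomial_pvalue(truth$genome_size, m, N_values, m)
  tibble::tibble(N = N_values, fpr = (N_values - m) / N_values, p_value = p,
                 scaled_p = scaled_pvalue(p, m, truth$genome_size))
}

#' Compare two methods' cluster pools on the F-P plane
#'
#' Keeps, per method, only clusters with at least one true positive, takes
#' the closest 50% of them to the ideal corner, sorts both retained distance
#' lists ascending, pairs them rank-by-rank (truncating to the shorter
#' list), and summarises the signed differences `d_i = dist_a(i) -
#' dist_b(i)` by their mean `mu` (in `[-sqrt(2), sqrt(2)]`; negative favours
#' the first method), standard deviation `sigma`, and the paired t-test
#' p-value. If the differences have zero variance the t statistic is
#' undefined; the p-value is then reported as 1 when `mu = 0` and 0
#' otherwise, with `degenerate = TRUE`.
#'
#' @param fp_a,fp_b `fp_scatter` tibbles from [fp_evaluate()], one per
#'   method.
#' @param labels Character vector of length 2 naming the two methods.
#' @return An `fp_comparison` object with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
compare_methods <- function(fp_a, fp_b, labels = c("a", "b")) {
  retained <- function(fp, label) {
    d <- fp$corner_distance[fp$n_true >= 1]
    if (length(d) == 0) {
      stop("Method '", label, "' has no clusters with a true positive.",
           call. = FALSE)
    }
    d <- sort(d)
    d[seq_len(ceiling(length(d) / 2))]
  }
  da <- retained(fp_a, labels[1])
  db <- retained(fp_b, labels[2])
  len <- min(length(da), length(db))
  diffs <- da[seq_len(len)] - db[seq_len(len)]
  mu <- mean(diffs)
  sigma <- sd(diffs)
  degenerate <- length(diffs) < 2 || isTRUE(all.equal(sigma, 0)) || sigma == 0
  p <- if (degenerate) {
    if (isTRUE(all.equal(mu, 0))) 1 else 0
  } else {
    t.test(diffs)$p.value
  }
  structure(
    list(mu = mu, sigma = if (is.na(sigma)) 0 else sigma, p_value = p,
         n_pairs = len, labels = labels, differences = diffs,
         degenerate = degenerate),
    class = "fp_comparison"
  )
}

#' @export
print.fp_comparison <- function(x, ...) {
  cat(sprintf(
    "<fp_comparison> %s vs %s over %d rank-paired clusters\n  mu = %+.3f, sigma = %.3f, p = %.3g%s\n",
    x$labels[1], x$labels[2], x$n_pairs, x$mu, x$sigma, x$p_value,
    if (x$degenerate) " (zero-variance differences)" else ""
  ))
  cat(if (x$mu < 0) sprintf("  favours %s\n", x$labels[1])
      else if (x$mu > 0) sprintf("  favours %s\n", x$labels[2])
      else "  no preference\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.fp_comparison <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$labels, collapse = " - "),
    estimate = x$mu, std_dev = x$sigma, p.value = x$p_value,
    n_pairs = x$n_pairs
  )
}

#' @exportS3Method generics::glance
glance.fp_comparison <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, p.value = x$p_value,
                 n_pairs = x$n_pairs, degenerate = x$degenerate)
}

#' Plot an F-P scatter
#'
#' False-positive rate against scaled p-value, the ideal at the top-left
#' corner, with the zero-false-negative envelope drawn as a curve.
#'
#' @param object An `fp_scatter` tibble from [fp_evaluate()].
#' @param selection Optional `mn_selection`; matching records are
#'   highlighted.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fp_scatter <- function(object, selection = NULL, ...) {
  truth <- attr(object, "truth")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr,
                                            y = .data$scaled_p)) +
    ggplot2::geom_point(shape = 8, colour = "red3", size = 1.5) +
    ggplot2::labs(x = "false-positive rate (F)", y = "scaled p-value (P)") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_classic()
  if (!is.null(truth)) {
    curve <- zero_fn_curve(truth)
    p <- p + ggplot2::geom_line(data = curve, colour = "black")
  }
  if (!is.null(selection)) {
    sel <- object[object$record_id %in% selection$record_id, , drop = FALSE]
    p <- p + ggplot2::geom_point(data = sel, colour = "grey40", size = 3)
  }
  p
}

#' @export
plot.fp_scatter <- function(x, y, ...) print(autoplot.fp_scatter(x, ...))

#' Write an F-P table as TSV
#'
#' @param fp An `fp_scatter` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fp_table <- function(fp, path) {
  cols <- intersect(
    c("record_id", "type", "k", "delta", "delta_minus", "n_genes", "n_true",
      "fpr", "p_value", "scaled_p", "corner_distance"),
    names(fp)
  )
  write.table(as.data.frame(fp[, cols]), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
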