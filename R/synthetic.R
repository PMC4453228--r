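# Generator of six-dataset synthetic expression collections with the planted
# validation structure: a cluster C1 co-expressed in all datasets, a cluster
# C2 co-expressed only in the positive datasets, background genes C0, and
# per-dataset confounder genes co-expressed with a planted cluster in one
# dataset only. A data-calibrated Gaussian noise model can be layered on top.

#' Configuration of the synthetic collection
#'
#' Defaults reproduce the six-dataset validation design: three positive
#' datasets (18, 18 and 6 samples), three negative datasets (16, 12 and 12
#' samples), a 75-gene cluster C1 planted in all six, an 85-gene cluster C2
#' planted in the positives only, and per dataset a handful to a few tens of
#' confounder genes from the background that are co-expressed with an active
#' planted cluster in that dataset alone. The first four datasets are tagged
#' one-channel and the last two two-channel, which routes them through the
#' matching normalisation in [preprocess_collection()].
#'
#' @param genome_size Total genes GS (studied sizes: 1200, 2000, 3000, 5000,
#'   7000).
#' @param samples_per_dataset Sample counts for P1, P2, P3, N1, N2, N3.
#' @param c1_size,c2_size Planted cluster sizes.
#' @param confounders_per_dataset Inclusive range from which the number of
#'   confounders per (dataset, active planted cluster) is drawn uniformly.
#' @param within_cluster_sd Standard deviation of each member gene's
#'   point-wise deviation from its cluster's base profile, on the scale of
#'   the standardised base profile (which has unit variance).
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(genome_size = 1200L,
                             samples_per_dataset = c(18L, 18L, 6L, 16L, 12L, 12L),
                             c1_size = 75L,
                             c2_size = 85L,
                             confounders_per_dataset = c(5L, 30L),
                             within_cluster_sd = 0.3,
                             seed = 1L) {
  genome_size <- as.integer(genome_size)
  c1_size <- as.integer(c1_size)
  c2_size <- as.integer(c2_size)
  if (c1_size + c2_size >= genome_size) {
    stop("c1_size + c2_size must be smaller than genome_size.", call. = FALSE)
  }
  if (c1_size < 2 || c2_size < 2) {
    stop("Planted clusters need at least 2 genes.", call. = FALSE)
  }
  if (length(samples_per_dataset) != 6 || any(samples_per_dataset < 2)) {
    stop("`samples_per_dataset` must give 6 counts, each >= 2.", call. = FALSE)
  }
  if (within_cluster_sd < 0) stop("`within_cluster_sd` must be >= 0.", call. = FALSE)
  structure(
    list(genome_size = genome_size,
         samples_per_dataset = as.integer(samples_per_dataset),
         c1_size = c1_size, c2_size = c2_size,
         confounders_per_dataset = as.integer(confounders_per_dataset),
         within_cluster_sd = within_cluster_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Row-wise cumulative sums.
row_cumsums <- function(m) {
  t(apply(m, 1, cumsum))
}

# A smooth random trajectory over d samples: cumulative sum of standard
# normal steps, standardised to zero mean and unit standard deviation.
random_base_profile <- function(d) {
  walk <- cumsum(rnorm(d))
  centred <- walk - mean(walk)
  s <- sd(centred)
  if (s < .Machine$double.eps^0.5) centred else centred / s
}

#' Generate a synthetic multi-dataset expression collection
#'
#' For each dataset, each planted cluster active in it (C1 in all six, C2 in
#' the positives only) gets a fresh smooth base profile; each member gene's
#' profile is the base plus point-wise Gaussian deviations of standard
#' deviation `within_cluster_sd`. Background (C0) genes get independent
#' random profiles of the same family, so C2 genes show no shared shape in
#' the negative datasets. Per dataset and active planted cluster, a random
#' subset of C0 is additionally generated co-expressed with that cluster in
#' that dataset only (the confounders). Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_collection`: list with `datasets` (six
#'   [expression_dataset()]s named P1, P2, P3, N1, N2, N3), `truth_c1` and
#'   `truth_c2` (integer gene indices), `confounder_log` (per dataset, per
#'   planted cluster, the confounder gene indices) and `config`.
#' @export
generate_expression_collection <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  gs <- config$genome_size
  gene_ids <- paste0("g", seq_len(gs))
  c1 <- seq_len(config$c1_size)
  c2 <- seq(config$c1_size + 1, config$c1_size + config$c2_size)
  c0 <- seq(config$c1_size + config$c2_size + 1, gs)
  names_ds <- c("P1", "P2", "P3", "N1", "N2", "N3")
  roles <- c(rep("positive", 3), rep("negative", 3))
  channels <- c(rep("one_channel", 4), rep("two_channel", 2))
  conf_range <- config$confounders_per_dataset
  wsd <- config$within_cluster_sd

  with_seed(derive_seed(config$seed, "generate"), {
    datasets <- vector("list", 6)
    confounder_log <- vector("list", 6)
    names(datasets) <- names_ds
    names(confounder_log) <- names_ds
    for (d in seq_len(6)) {
      nd <- config$samples_per_dataset[d]
      # background: independent smooth profiles (standardised random walks)
      walks <- row_cumsums(matrix(rnorm(gs * nd), gs, nd))
      walks <- walks - rowMeans(walks)
      spread <- sqrt(rowSums(walks^2) / (nd - 1))
      spread[spread < .Machine$double.eps^0.5] <- 1
      values <- walks / spread
      active <- if (roles[d] == "positive") list(C1 = c1, C2 = c2) else list(C1 = c1)
      log_d <- list()
      used_confounders <- integer(0)
      for (cl_name in names(active)) {
        members <- active[[cl_name]]
        base <- random_base_profile(nd)
        deviations <- matrix(rnorm(length(members) * nd, sd = wsd),
                             length(members), nd)
        values[members, ] <- rep(base, each = length(members)) + deviations
        n_conf <- sample(seq(conf_range[1], conf_range[2]), 1)
        pool <- setdiff(c0, used_confounders)
        conf <- sort(sample(pool, min(n_conf, length(pool))))
        used_confounders <- c(used_confounders, conf)
        conf_dev <- matrix(rnorm(length(conf) * nd, sd = wsd), length(conf), nd)
        values[conf, ] <- rep(base, each = length(conf)) + conf_dev
        log_d[[cl_name]] <- conf
      }
      confounder_log[[d]] <- log_d
      colnames(values) <- paste0("s", seq_len(nd))
      datasets[[d]] <- expression_dataset(
        values, dataset_id = names_ds[d], gene_ids = gene_ids,
        role = roles[d], channel = channels[d]
      )
    }
    structure(
      list(datasets = datasets, truth_c1 = c1, truth_c2 = c2,
           confounder_log = confounder_log, config = config),
      class = "synthetic_collection"
    )
  })
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat(sprintf(
    "<synthetic_collection> GS=%d: |C1|=%d (all datasets), |C2|=%d (positives only)\n",
    x$config$genome_size, length(x$truth_c1), length(x$truth_c2)
  ))
  for (ds in x$datasets) {
    cat(sprintf("  %s: %d samples (%s, %s)\n", ds$dataset_id,
                ncol(ds$values), ds$role, ds$channel))
  }
  invisible(x)
}

#' Estimate the data-calibrated noise model
#'
#' The standard deviation of the noise to be added at sample i of dataset d
#' is estimated from the observed spread of the planted clusters at that
#' sample: for positive datasets the mean of the C1 and C2 standard
#' deviations (sample-variance denominators `c1_size - 1` and
#' `c2_size - 1`), for negative datasets the C1 standard deviation alone
#' (C2 carries no shared signal there).
#'
#' @param collection A [generate_expression_collection()] result.
#' @return A `noise_model`: per-dataset numeric vectors of per-sample sigma.
#' @export
estimate_noise_sigma <- function(collection) {
  stopifnot(inherits(collection, "synthetic_collection"))
  c1 <- collection$truth_c1
  c2 <- collection$truth_c2
  if (length(c1) < 2 || length(c2) < 2) {
    stop("Planted clusters need >= 2 genes to estimate a spread.", call. = FALSE)
  }
  sigma <- lapply(collection$datasets, function(ds) {
    sd_c1 <- apply(ds$values[c1, , drop = FALSE], 2, sd)
    if (ds$role == "positive") {
      sd_c2 <- apply(ds$values[c2, , drop = FALSE], 2, sd)
      (sd_c1 + sd_c2) / 2
    } else {
      sd_c1
    }
  })
  structure(sigma, class = "noise_model")
}

#' Add zero-mean Gaussian noise to a collection
#'
#' Every expression value in dataset d, sample i is perturbed by an
#' independent draw from `Normal(0, sigma_di^2)`. Truth sets are unchanged.
#' Reproducible for a fixed seed.
#'
#' @param collection A `synthetic_collection`.
#' @param noise A [estimate_noise_sigma()] result (or any per-dataset list
#'   of per-sample sigmas matching the collection's dimensions).
#' @param seed Noise seed.
#' @return The perturbed collection.
#' @export
add_noise <- function(collection, noise = estimate_noise_sigma(collection),
                      seed = 1L) {
  stopifnot(inherits(collection, "synthetic_collection"))
  if (length(noise) != length(collection$datasets)) {
    stop("One sigma vector per dataset is required.", call. = FALSE)
  }
  with_seed(derive_seed(seed, "noise"), {
    for (d in seq_along(collection$datasets)) {
      ds <- collection$datasets[[d]]
      sigma <- noise[[d]]
      if (length(sigma) != ncol(ds$values)) {
        stop("Sigma length mismatch for dataset '", ds$dataset_id, "'.",
             call. = FALSE)
      }
      eps <- matrix(rnorm(length(ds$values)), nrow(ds$values))
      ds$values <- ds$values + sweep(eps, 2, sigma, `*`)
      collection$datasets[[d]] <- ds
    }
    collection
  })
}

#' Write a synthetic collection to a directory
#'
#' Emits one TSV per dataset (readable by [read_expression()]), a truth file
#' `truth.tsv` (`gene_id`, label in C0/C1/C2) and a confounder log
#' `confounders.tsv` (`dataset_id`, `cluster`, `gene_id`).
#'
#' @param collection A `synthetic_collection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in collection$datasets) {
    write_expression(ds, file.path(dir, paste0(ds$dataset_id, ".tsv")))
  }
  gene_ids <- collection$datasets[[1]]$gene_ids
  label <- rep("C0", length(gene_ids))
  label[collection$truth_c1] <- "C1"
  label[collection$truth_c2] <- "C2"
  write.table(data.frame(gene_id = gene_ids, label = label),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  logs <- list()
  for (ds_name in names(collection$confounder_log)) {
    for (cl in names(collection$confounder_log[[ds_name]])) {
      idx <- collection$confounder_log[[ds_name]][[cl]]
      if (length(idx)) {
        logs[[length(logs) + 1L]] <- data.frame(
          dataset_id = ds_name, cluster = cl, gene_id = gene_ids[idx],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  write.table(do.call(rbind, logs), file.path(dir, "confounders.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
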