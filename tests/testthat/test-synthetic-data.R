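# The planted-structure generator and its calibrated noise model.

test_that("default-shaped collections have the planted six-dataset structure", {
  col <- generate_expression_collection(synthetic_config(seed = 5))
  expect_length(col$datasets, 6)
  expect_equal(vapply(col$datasets, function(d) ncol(d$values), integer(1)),
               c(P1 = 18L, P2 = 18L, P3 = 6L, N1 = 16L, N2 = 12L, N3 = 12L))
  expect_equal(vapply(col$datasets, function(d) nrow(d$values), integer(1)),
               c(P1 = 1200L, P2 = 1200L, P3 = 1200L, N1 = 1200L, N2 = 1200L,
                 N3 = 1200L))
  expect_equal(vapply(col$datasets, function(d) d$role, character(1)),
               c(P1 = "positive", P2 = "positive", P3 = "positive",
                 N1 = "negative", N2 = "negative", N3 = "negative"))
  expect_length(col$truth_c1, 75)
  expect_length(col$truth_c2, 85)
  expect_length(intersect(col$truth_c1, col$truth_c2), 0)

  # confounders live in the background, never in the truth sets
  for (log_d in col$confounder_log) {
    for (conf in log_d) {
      expect_length(intersect(conf, c(col$truth_c1, col$truth_c2)), 0)
      expect_true(all(conf > 160))
    }
  }
  # C2 confounders exist in positive datasets only
  expect_named(col$confounder_log[["P1"]], c("C1", "C2"))
  expect_named(col$confounder_log[["N1"]], "C1")

  expect_error(synthetic_config(genome_size = 50, c1_size = 75),
               "smaller than genome_size")
})

test_that("generation is deterministic per seed", {
  cfg <- synthetic_config(genome_size = 200, c1_size = 10, c2_size = 12,
                          confounders_per_dataset = c(2, 5), seed = 77)
  a <- generate_expression_collection(cfg)
  b <- generate_expression_collection(cfg)
  expect_identical(a$datasets[["P3"]]$values, b$datasets[["P3"]]$values)
  expect_identical(a$confounder_log, b$confounder_log)
})

test_that("a zero within-cluster spread collapses planted clusters onto their base profile", {
  cfg <- synthetic_config(genome_size = 150, c1_size = 10, c2_size = 12,
                          confounders_per_dataset = c(2, 4),
                          within_cluster_sd = 0, seed = 9)
  col <- generate_expression_collection(cfg)
  for (ds in col$datasets) {
    expect_equal(cluster_mse(ds, col$truth_c1), 0, tolerance = 1e-24)
  }
  for (ds in col$datasets[1:3]) {
    expect_equal(cluster_mse(ds, col$truth_c2), 0, tolerance = 1e-24)
  }
  # and Eq-style sigma estimates are zero everywhere
  noise <- estimate_noise_sigma(col)
  expect_true(all(unlist(noise) < 1e-12))
})

test_that("planted co-expression is present in positive datasets and absent in negatives", {
  hits_pos <- 0; hits_neg <- 0; trials <- 0
  for (seed in 1:20) {
    col <- generate_expression_collection(synthetic_config(
      genome_size = 400, seed = seed, c1_size = 20, c2_size = 25,
      confounders_per_dataset = c(2, 5)
    ))
    mean_cor <- function(ds, genes) {
      cm <- cor(t(ds$values[genes, ]))
      mean(cm[upper.tri(cm)])
    }
    background <- 201:225  # random C0 genes, same size as C2
    for (ds in col$datasets) {
      c2_cor <- mean_cor(ds, col$truth_c2)
      c0_cor <- mean_cor(ds, background)
      trials <- trials + 1
      if (ds$role == "positive") {
        hits_pos <- hits_pos + (c2_cor > c0_cor + 0.2)
      } else {
        hits_neg <- hits_neg + (c2_cor > c0_cor + 0.2)
      }
    }
  }
  expect_equal(hits_pos, 60)  # strongly co-expressed in every positive dataset
  expect_equal(hits_neg, 0)   # background-like in every negative dataset
})

test_that("noise sigma follows the cluster-spread estimate in both branches", {
  cfg <- synthetic_config(genome_size = 100, c1_size = 5, c2_size = 5,
                          confounders_per_dataset = c(2, 3), seed = 31)
  col <- generate_expression_collection(cfg)
  # overwrite one negative dataset's C1 block at sample 1 with values {0, 2}
  # replicated: sd over n-1 of c(0,2,0,2,...) is known
  ds <- col$datasets[["N1"]]
  ds$values[col$truth_c1, 1] <- rep(c(0, 2), length.out = 5)
  col$datasets[["N1"]] <- ds
  noise <- estimate_noise_sigma(col)
  expect_equal(unname(noise[["N1"]][1]), sd(rep(c(0, 2), length.out = 5)))

  # positive branch: mean of the C1 and C2 spreads
  dsp <- col$datasets[["P1"]]
  dsp$values[col$truth_c1, 1] <- c(-1, -0.5, 0, 0.5, 1) * 2   # sd = 1.5811388
  dsp$values[col$truth_c2, 1] <- c(-3, -1.5, 0, 1.5, 3) * 2   # sd = 4.7434165
  col$datasets[["P1"]] <- dsp
  noise2 <- estimate_noise_sigma(col)
  expect_equal(unname(noise2[["P1"]][1]),
               (sd(c(-2, -1, 0, 1, 2)) + sd(c(-6, -3, 0, 3, 6))) / 2)
})

test_that("add_noise perturbs with the requested per-sample spread, reproducibly", {
  cfg <- synthetic_config(genome_size = 7000, c1_size = 75, c2_size = 85,
                          seed = 41)
  col <- generate_expression_collection(cfg)
  noise <- estimate_noise_sigma(col)

  zero <- lapply(noise, function(x) x * 0)
  unchanged <- add_noise(col, zero, seed = 1)
  expect_identical(unchanged$datasets[["P2"]]$values, col$datasets[["P2"]]$values)

  n1 <- add_noise(col, noise, seed = 8)
  n2 <- add_noise(col, noise, seed = 8)
  expect_identical(n1$datasets[["N2"]]$values, n2$datasets[["N2"]]$values)
  expect_identical(n1$truth_c2, col$truth_c2)

  # empirical spread of (noisy - clean) over 7000 genes within 5% of sigma
  for (d in c("P1", "N1")) {
    eps <- n1$datasets[[d]]$values - col$datasets[[d]]$values
    emp <- apply(eps, 2, sd)
    expect_true(all(abs(emp - noise[[d]]) / noise[[d]] < 0.05))
  }

  expect_error(add_noise(col, noise[1:3]), "per dataset")
})

test_that("written collections round-trip through the expression reader", {
  cfg <- synthetic_config(genome_size = 80, c1_size = 6, c2_size = 7,
                          confounders_per_dataset = c(2, 3), seed = 51)
  col <- generate_expression_collection(cfg)
  dir <- withr::local_tempdir()
  write_collection(col, dir)
  expect_true(all(file.exists(file.path(dir, c("P1.tsv", "N3.tsv", "truth.tsv",
                                               "confounders.tsv")))))
  back <- read_expression(file.path(dir, "P1.tsv"), dataset_id = "P1")
  expect_equal(back$gene_ids, col$datasets[["P1"]]$gene_ids)
  expect_equal(unname(back$values), unname(col$datasets[["P1"]]$values),
               tolerance = 1e-12)
  truth <- read_ground_truth(file.path(dir, "truth.tsv"), back$gene_ids, "C2")
  expect_equal(truth$target, col$truth_c2)
})
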