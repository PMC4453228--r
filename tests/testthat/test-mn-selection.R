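# M-N scatter scoring and iterative corner-distance selection.

test_that("cluster_mse matches hand computation and its degenerate cases", {
  ds <- make_plain_dataset(rbind(c(0, 0), c(2, 2), c(5, 1)))
  # two genes with profiles (0,0) and (2,2): z = (1,1), sum ||.||^2 = 4,
  # MSE = 4 / (D * Nk) = 4 / 4 = 1
  expect_equal(cluster_mse(ds, 1:2), 1)
  expect_equal(cluster_mse(ds, c("g1", "g2")), 1)
  expect_equal(cluster_mse(ds, 3), 0)                      # singleton
  same <- make_plain_dataset(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(cluster_mse(same, 1:3), 0)                  # identical members
  expect_error(cluster_mse(ds, integer(0)), "non-empty")
  expect_error(cluster_mse(ds, "g9"), "Unknown gene IDs")
})

test_that("the M metric averages per-dataset MSEs (type A) and differences them (type B)", {
  dsA <- make_plain_dataset(rbind(c(0, 0), c(2, 2)), "a", role = "positive")
  dsB <- make_plain_dataset(rbind(c(0, 0), c(2, 2), c(9, 9))[1:2, ] * sqrt(3), "b",
                            role = "negative")
  # per-dataset MSEs are 1 and 3 -> type A mean = 2
  expect_equal(cluster_mse(dsA, 1:2), 1)
  expect_equal(cluster_mse(dsB, 1:2), 3)
  expect_equal(m_metric(1:2, list(dsA, dsB), type = "A"), 2)
  # type B: mean over S+ minus mean over S- = 1 - 3 = -2
  expect_equal(m_metric(1:2, list(dsA, dsB), type = "B"), -2)
  expect_error(m_metric(1:2, list(dsA), type = "B"), "positive and .*negative")
})

test_that("grouped pool M computation agrees with the single-record definition", {
  col <- generate_expression_collection(synthetic_config(
    genome_size = 50, c1_size = 6, c2_size = 7,
    confounders_per_dataset = c(2, 3), seed = 21
  ))
  pp <- preprocess_collection(col$datasets)
  cfg <- uncles_config(k_list = c(2, 4), delta_grid = c(0, 0.4), seed = 21)
  roles <- vapply(pp, function(d) d$role, character(1))
  parts <- generate_partitions(pp, cfg)
  poolA <- run_type_a(pp, cfg, partitions = parts)
  poolB <- run_type_b(pp[roles == "positive"], pp[roles == "negative"], cfg,
                      partitions = parts)
  scA <- build_mn_scatter(poolA, pp)
  for (i in seq_len(nrow(scA))) {
    expect_equal(scA$m[i], m_metric(scA$genes[[i]], pp, "A"), tolerance = 1e-10)
  }
  if (any(poolB$n_genes > 0)) {
    scB <- build_mn_scatter(poolB, pp)
    for (i in seq_len(nrow(scB))) {
      expect_equal(scB$m[i], m_metric(scB$genes[[i]], pp, "B"), tolerance = 1e-10)
    }
  }
})

# A fabricated scatter with fully controlled M and N values: dataset with
# groups of varying spread so cluster MSEs are known, then checked against
# hand-scaled corner distances.
test_that("axis scaling and corner distances match hand arithmetic", {
  sc <- uncles:::scale_mn(m = c(0, 2, 4), log_n = log(c(100, 10, 1)))
  # scaled M = 0, .5, 1; scaled logN = 1, .5, 0
  expect_equal(sc$scaled_m, c(0, 0.5, 1))
  expect_equal(sc$scaled_n, c(1, 0.5, 0))
  expect_equal(sc$corner_distance, c(0, sqrt(0.5), sqrt(2)))

  # a single point (degenerate axes) pins to the ideal corner: distance 0
  single <- uncles:::scale_mn(1.7, log(42))
  expect_equal(single$corner_distance, 0)

  # dominance: smaller M and larger N implies smaller distance
  set.seed(8)
  m <- runif(20); n <- sample(5:500, 20)
  sc2 <- uncles:::scale_mn(m, log(n))
  for (i in 1:19) for (j in (i + 1):20) {
    if (m[i] < m[j] && n[i] > n[j]) {
      expect_lt(sc2$corner_distance[i], sc2$corner_distance[j])
    }
  }
})

test_that("build_mn_scatter drops empty records and errors when everything is empty", {
  col <- generate_expression_collection(synthetic_config(
    genome_size = 40, c1_size = 5, c2_size = 6,
    confounders_per_dataset = c(2, 3), seed = 33
  ))
  pp <- preprocess_collection(col$datasets)
  cfg <- uncles_config(k_list = 3, delta_grid = c(0, 0.5), seed = 33)
  pool <- run_type_a(pp, cfg)
  sc <- build_mn_scatter(pool, pp)
  expect_true(all(sc$n_genes > 0))
  expect_true(all(sc$corner_distance >= 0))

  empty <- pool
  empty$genes <- lapply(empty$genes, function(x) integer(0))
  empty$n_genes <- 0L
  expect_error(build_mn_scatter(empty, pp), "empty")
})

test_that("iterative selection follows the overlap-removal rule", {
  # synthetic scatter rows with controlled gene sets and distances
  mk_scatter <- function(genes, dist, k = rep(2L, length(genes))) {
    sc <- tibble::tibble(
      record_id = paste0("r", seq_along(genes)), type = "A", k = k,
      delta = 0, delta_minus = NA_real_, n_genes = lengths(genes),
      genes = genes, m = dist, log_n = log(lengths(genes)),
      scaled_m = dist, scaled_n = 1, corner_distance = dist
    )
    class(sc) <- c("mn_scatter", class(sc))
    sc
  }

  # disjoint clusters: picks are simply the ascending distances
  disjoint <- mk_scatter(list(1:2, 3:4, 5:6, 7:8), c(0.9, 0.2, 0.5, 0.7))
  sel <- iterative_select(disjoint, max_clusters = 3)
  expect_equal(sel$record_id, c("r2", "r3", "r4"))
  expect_equal(sel$corner_distance, sort(sel$corner_distance))

  # everything overlaps the best cluster: exactly one pick
  blanket <- mk_scatter(list(1:10, c(1, 11), c(2, 12)), c(0.1, 0.3, 0.5))
  expect_equal(nrow(iterative_select(blanket, max_clusters = 5)), 1L)

  # six-point toy, hand-simulated removal sequence:
  # pick r1 (0.1) -> removes r2, r4 (share genes 1/3); pick r3 (0.3)
  # -> removes r5 (shares gene 21); pick r6 (0.6)
  toy <- mk_scatter(
    list(1:3, c(3, 10, 11), 20:22, c(1, 30), c(21, 40), 50:55),
    c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  )
  sel_toy <- iterative_select(toy, max_clusters = 10)
  expect_equal(sel_toy$record_id, c("r1", "r3", "r6"))

  # selected clusters are pairwise disjoint
  sets <- sel_toy$genes
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j) expect_length(intersect(sets[[i]], sets[[j]]), 0)
  }

  # ties break towards the larger cluster
  tied <- mk_scatter(list(1:2, 3:6), c(0.4, 0.4))
  expect_equal(iterative_select(tied, 1)$record_id, "r2")

  expect_error(iterative_select(disjoint, max_clusters = 0), ">= 1")
})

test_that("selection distances are non-decreasing under the fixed axis scaling", {
  col <- generate_expression_collection(synthetic_config(
    genome_size = 60, c1_size = 8, c2_size = 8,
    confounders_per_dataset = c(2, 3), seed = 55
  ))
  pp <- preprocess_collection(col$datasets)
  pool <- run_type_a(pp, uncles_config(k_list = c(2, 4), delta_grid = c(0, 0.3, 0.6), seed = 55))
  sel <- iterative_select(build_mn_scatter(pool, pp), max_clusters = 6)
  expect_equal(sel$corner_distance, sort(sel$corner_distance))
})
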