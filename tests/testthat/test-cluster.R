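test_that("neighbour distance is zero for flat codebooks and single units", {
  som <- handmade_som(matrix(3.2, 19, 4), rings = 3)
  expect_equal(neighbor_distance(som), rep(0, 19))
  single <- handmade_som(matrix(1, 1, 4), rings = 1)
  expect_equal(neighbor_distance(single), 0)
})

test_that("neighbour distance matches hand-computed means on an r = 2 grid", {
  g <- som_grid(rings = 2)
  cb <- matrix(seq_len(g$n_units), g$n_units, 1)   # codebook_u = u, 1-D
  som <- handmade_som(cb, rings = 2)
  nb <- edisom:::grid_neighbors(g)
  oracle <- sapply(seq_len(g$n_units),
                   function(u) mean(abs(cb[nb[[u]], 1] - cb[u, 1])))
  expect_equal(neighbor_distance(som), oracle)
})

test_that("uniform heights collapse to a single lowest-index seed", {
  som <- handmade_som(matrix(0, 19, 3), rings = 3)
  expect_identical(find_seeds(som), 1L)
  single <- handmade_som(matrix(2, 1, 3), rings = 1)
  expect_identical(find_seeds(single), 1L)
})

test_that("two well-separated codebook blobs yield one interior seed each", {
  tb <- two_blob_som()
  h <- neighbor_distance(tb$som)
  seeds <- find_seeds(tb$som, h)
  # oracle: exhaustive local-minimum scan with plateau collapse
  nb <- edisom:::grid_neighbors(tb$som$grid)
  mins <- which(sapply(seq_along(h), function(u) all(h[u] <= h[nb[[u]]])))
  expect_true(all(seeds %in% mins))
  expect_length(seeds, 2L)
  expect_identical(sort(unique(tb$blob[seeds])), c(1L, 2L))
  # seeds sit strictly inside their blobs (height 0, away from the border)
  expect_equal(h[seeds], c(0, 0))
  expect_error(find_seeds(tb$som, h[-1]), "does not match")
})

test_that("a single seed absorbs every unit and every gene", {
  tb <- two_blob_som()
  X <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  bmu <- predict(tb$som, X)
  p <- som_partition(tb$som, bmu, seeds = 5L)
  expect_identical(p$n_clusters, 1L)
  expect_true(all(p$unit_cluster == 1L))
  expect_true(all(p$gene_cluster == 1L))
  expect_identical(p$seed_units, 5L)
  expect_error(som_partition(tb$som, bmu, seeds = integer(0)), "empty seed")
})

test_that("cluster growth keeps each unit with its own blob's seed", {
  tb <- two_blob_som()
  X <- rbind(matrix(-1, 6, 4), matrix(1, 6, 4)) +
    matrix(rnorm(48, sd = 0.05), 12, 4)
  rownames(X) <- sprintf("g%02d", 1:12)
  bmu <- predict(tb$som, X)
  p <- som_partition(tb$som, bmu)
  expect_identical(p$n_clusters, 2L)
  # every unit joins the cluster of its own blob's seed
  blob_of_cluster <- tb$blob[p$seed_units]
  expect_identical(tb$blob, blob_of_cluster[p$unit_cluster])
  # genes with negative profiles land in the negative blob's cluster
  neg_cl <- p$unit_cluster[p$seed_units[blob_of_cluster == 1L]]
  expect_true(all(p$gene_cluster[1:6] == neg_cl))
})

test_that("partition is total, seeds are fixed points, genes follow their BMU", {
  sim <- simulate_expression(synthetic_spec(seed = 21))
  filt <- regulation_filter(fold_change(apply_floor(sim$expr, 200)),
                            filter_rule())
  fit <- suprasom(filt$fc, seed = 21)
  p <- som_partition(fit)
  # total function on units
  expect_false(anyNA(p$unit_cluster))
  expect_length(p$unit_cluster, fit$grid$n_units)
  expect_setequal(unique(p$unit_cluster), seq_len(p$n_clusters))
  # each seed belongs to its own cluster; profile reported verbatim
  expect_identical(p$unit_cluster[p$seed_units], seq_len(p$n_clusters))
  expect_equal(unname(p$seed_profiles),
               unname(fit$codebook[p$seed_units, , drop = FALSE]))
  # genes inherit the cluster of their BMU
  expect_identical(unname(p$gene_cluster),
                   unname(p$unit_cluster[fit$bmu$assignment]))
  # repeated runs give identical tables
  p2 <- som_partition(suprasom(filt$fc, seed = 21))
  expect_identical(cluster_table(p), cluster_table(p2))
})

test_that("cluster sizes count transcripts and are conserved", {
  tb <- two_blob_som()
  X <- matrix(-1, 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  bmu <- predict(tb$som, X)
  p <- som_partition(tb$som, bmu, seeds = 1L)
  expect_identical(cluster_sizes(p), c("1" = 10L))
  sim <- simulate_expression(synthetic_spec(seed = 22))
  filt <- regulation_filter(fold_change(apply_floor(sim$expr, 200)),
                            filter_rule())
  fit <- suprasom(filt$fc, seed = 22)
  p <- som_partition(fit)
  expect_identical(sum(cluster_sizes(p)), nrow(filt$fc$values))
})

test_that("max_clusters caps the emergent count by merging closest seeds", {
  sim <- simulate_expression(synthetic_spec(seed = 23))
  filt <- regulation_filter(fold_change(apply_floor(sim$expr, 200)),
                            filter_rule())
  fit <- suprasom(filt$fc, seed = 23)
  free <- som_partition(fit)
  capped <- som_partition(fit, max_clusters = 3L)
  expect_lte(capped$n_clusters, 3L)
  expect_gte(free$n_clusters, capped$n_clusters)
  expect_false(anyNA(capped$unit_cluster))
  expect_setequal(unique(capped$unit_cluster), seq_len(capped$n_clusters))
})
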