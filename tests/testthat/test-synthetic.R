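test_that("archetype shapes have their defining monotonicity and plateaus", {
  a <- archetype_profiles(6)
  expect_identical(rownames(a),
                   c("repressed", "repressed_after_induction", "incremental",
                     "induced_repressed", "induced_maintained"))
  expect_true(all(diff(a["incremental", ]) >= 0))
  expect_true(all(diff(a["repressed", ]) <= 0))
  expect_equal(a["induced_maintained", 6], max(a["induced_maintained", ]))
  # early peak then decrease below zero
  rai <- a["repressed_after_induction", ]
  expect_gt(rai[1], 0); expect_lt(rai[6], 0)
  # induced-then-repressed ends below its start
  ir <- a["induced_repressed", ]
  expect_gt(max(ir), ir[1]); expect_lt(ir[6], ir[1])
  expect_true(all(abs(a) <= 1))
  expect_error(archetype_profiles(2), ">= 3")
})

test_that("archetypes are pairwise distinct with correlation below 0.95", {
  a <- archetype_profiles(6)
  cors <- cor(t(a))
  expect_true(all(cors[upper.tri(cors)] < 0.95))
  # deterministic given the stage count
  expect_identical(a, archetype_profiles(6))
})

test_that("generation is deterministic and bookkeeping is exact", {
  spec <- synthetic_spec(archetype_counts = c(incremental = 50L), n_null = 50L,
                         seed = 50)
  s1 <- simulate_expression(spec)
  s2 <- simulate_expression(spec)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(nrow(s1$expr$values), 100L)
  expect_identical(sum(s1$truth$archetype == "incremental"), 50L)
  expect_identical(sum(s1$truth$archetype == "null"), 50L)
  expect_false(s1$expr$floored)
  expect_identical(colnames(s1$expr$values)[1], "control")
  # truth covers every generated gene exactly once
  expect_identical(sort(s1$truth$gene), sort(rownames(s1$expr$values)))
  expect_error(simulate_expression(
    synthetic_spec(archetype_counts = c(incremental = 0L), n_null = 0L)),
    "zero genes")
})

test_that("planted sub-floor controls appear at the requested rate", {
  spec <- synthetic_spec(seed = 51)
  sim <- simulate_expression(spec)
  frac <- mean(sim$expr$values[, "control"] < 200)
  expect_equal(frac, spec$sub_floor_fraction, tolerance = 0.01)
})

test_that("regulated genes pass the filter and nulls do not, across seeds", {
  rates <- sapply(1:10, function(s) {
    sim <- simulate_expression(synthetic_spec(seed = s))
    filt <- regulation_filter(fold_change(apply_floor(sim$expr, 200)),
                              filter_rule())
    truth <- setNames(sim$truth$archetype, sim$truth$gene)
    kept <- setNames(filt$report$kept, filt$report$transcript_id)
    c(sens = mean(kept[names(truth)[truth != "null"]]),
      null = mean(kept[names(truth)[truth == "null"]]))
  })
  expect_gte(median(rates["sens", ]), 0.9)
  expect_lte(median(rates["null", ]), 0.05)
})

test_that("recovery score is 1 for the truth grouping and 0 for one blob", {
  truth <- setNames(rep(c("a", "b", "c"), each = 20), sprintf("g%02d", 1:60))
  expect_equal(recovery_score(truth, truth), 1.0)
  one <- setNames(rep(1L, 60), names(truth))
  expect_equal(recovery_score(truth, one), 0.0)
  expect_error(recovery_score(truth, setNames(1L, "zz")), "no genes")
})

test_that("randomly permuted labels score near zero on average", {
  truth <- setNames(rep(c("a", "b", "c", "d", "e"), each = 30),
                    sprintf("g%03d", 1:150))
  set.seed(52)
  scores <- replicate(100, recovery_score(truth, setNames(sample(truth),
                                                          names(truth))))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("companion gene sets hold the true members plus decoys", {
  sim <- simulate_expression(synthetic_spec(
    archetype_counts = c(incremental = 50L, repressed = 40L), n_null = 100L,
    seed = 53))
  ann <- synthetic_gene_sets(sim$truth, decoy_fraction = 0.2, seed = 53)
  expect_identical(ann$namespace, "synthetic")
  expect_setequal(names(ann$terms), c("SYN:incremental", "SYN:repressed"))
  inc_true <- sim$truth$gene[sim$truth$archetype == "incremental"]
  members <- ann$terms[["SYN:incremental"]]$genes
  expect_true(all(inc_true %in% members))
  expect_identical(length(members), 60L)   # 50 members + 20% decoys
  decoys <- setdiff(members, inc_true)
  expect_true(all(sim$truth$archetype[match(decoys, sim$truth$gene)] == "null"))
})

test_that("higher noise degrades median recovery monotonically", {
  med_ari <- sapply(c(0.25, 0.8, 1.6), function(nsd) {
    median(sapply(1:3, function(s) {
      sim <- simulate_expression(synthetic_spec(
        noise_sd = nsd,
        archetype_counts = c(repressed = 60L, incremental = 60L,
                             induced_repressed = 60L),
        n_null = 0L, seed = s))
      filt <- regulation_filter(fold_change(apply_floor(sim$expr, 200)),
                                filter_rule(min_stages = 1))
      fit <- suprasom(filt$fc, seed = s)
      recovery_score(sim$truth, som_partition(fit))
    }))
  })
  expect_true(all(diff(med_ari) <= 0))
  expect_gt(med_ari[1], med_ari[3])
})

test_that("the synthetic deposited-matrix stand-in reproduces the documented shape", {
  dep <- simulate_deposited_matrix(seed = 54)
  expect_identical(nrow(dep$expr$values), 1893L)
  expect_identical(ncol(dep$expr$values), 7L)   # control + 6 stages
  expect_identical(length(unique(dep$clusters)), 12L)
  expect_identical(unname(cluster_sizes(dep$clusters)["2"]), 9L)
  expect_identical(sum(cluster_sizes(dep$clusters)), 1893L)
})
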