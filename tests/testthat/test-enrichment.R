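# exact enumeration oracle: P(X >= k) by summing binomial products
enum_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# step-up oracle evaluated literally from the formula
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- sapply(seq_len(m), function(i) {
    min(1, min(p[ord][i:m] * m / (i:m)))
  })
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

test_that("hypergeometric tail matches hand-derived and degenerate cases", {
  expect_equal(hypergeom_tail(0, 4, 5, 10), 1.0)
  expect_equal(hypergeom_tail(2, 4, 5, 10), 186 / 252)
  expect_equal(hypergeom_tail(3, 10, 7, 10), 1.0)   # K = N: certain overlap
  expect_error(hypergeom_tail(2, 11, 5, 10), "inconsistent")
  expect_error(hypergeom_tail(2, 4, 11, 10), "inconsistent")
  expect_error(hypergeom_tail(5, 4, 5, 10), "exceeds")
})

test_that("hypergeometric tail equals exact enumeration for all N <= 25", {
  for (N in 1:25) {
    got <- numeric(0); want <- numeric(0)
    for (K in 0:N) {
      for (n in seq(0, N, by = max(1, N %/% 5))) {
        for (k in 0:min(K, n)) {
          got <- c(got, hypergeom_tail(k, K, n, N))
          want <- c(want, enum_tail(k, K, n, N))
        }
      }
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula oracle", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(40)
  for (i in 1:10) {
    p <- runif(sample(1:30, 1))^2
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("q-values dominate p-values and are monotone along sorted p", {
  set.seed(41)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("cluster enrichment handles degenerate configurations", {
  ann <- structure(list(namespace = "ns", terms = list(
    T1 = list(description = "d", genes = paste0("g", 1:10)))),
    class = "annotation_set")
  # cluster identical to the full term, background = that term
  labels <- setNames(rep(1L, 10), paste0("g", 1:10))
  out <- enrich_clusters(labels, ann, background = paste0("g", 1:10))
  expect_equal(out$p_value, 1.0)
  expect_identical(out$overlap, 10L)
  expect_false(out$reported)            # q = 1 is never < 0.05
  # term disjoint from the cluster
  labels2 <- setNames(rep(1L, 5), paste0("x", 1:5))
  out2 <- enrich_clusters(labels2, ann,
                          background = c(paste0("x", 1:5), paste0("g", 1:10)))
  expect_identical(out2$overlap, 0L)
  expect_equal(out2$p_value, 1.0)
  expect_false(out2$reported)
  expect_error(enrich_clusters(labels, ann, background = character(0)),
               "empty")
})

test_that("a planted overlap is scored by exact enumeration and reported", {
  bg <- sprintf("g%03d", 1:200)
  term <- bg[1:12]
  cluster <- setNames(rep(1L, 20), c(bg[1:10], bg[101:110]))
  ann <- structure(list(namespace = "ns", terms = list(
    TERM = list(description = "planted", genes = term))),
    class = "annotation_set")
  out <- enrich_clusters(cluster, ann, background = bg)
  expect_equal(out$p_value, enum_tail(10, 12, 20, 200), tolerance = 1e-12)
  expect_identical(out$overlap, 10L)
  expect_true(out$reported)             # overlap >= 3 and q << 0.05
})

test_that("the reported set shrinks as thresholds tighten", {
  sim <- simulate_expression(synthetic_spec(
    archetype_counts = c(incremental = 30L, repressed = 30L), n_null = 60L,
    seed = 42))
  filt <- regulation_filter(fold_change(apply_floor(sim$expr, 200)),
                            filter_rule())
  fit <- suprasom(filt$fc, seed = 42)
  p <- som_partition(fit)
  ann <- synthetic_gene_sets(sim$truth, seed = 42)
  base <- enrich_clusters(p, ann, min_overlap = 1L, fdr = 0.25)
  key <- function(df) paste(df$cluster, df$term_id)[df$reported]
  for (args in list(list(min_overlap = 3L, fdr = 0.25),
                    list(min_overlap = 1L, fdr = 0.01),
                    list(min_overlap = 5L, fdr = 0.01))) {
    tight <- enrich_clusters(p, ann, min_overlap = args$min_overlap,
                             fdr = args$fdr)
    expect_true(all(key(tight) %in% key(base)))
  }
  # default background is the annotated universe
  expect_equal(unique(base$background_size),
               length(unique(unlist(lapply(ann$terms, `[[`, "genes")))))
})
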