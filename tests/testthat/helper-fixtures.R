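# Shared fixture builders; all randomness takes an explicit seed.

make_expr <- function(values, control = "control", floored = FALSE) {
  edisom:::new_expression_matrix(values, control, floored)
}

random_expr <- function(n_genes, n_stages, seed, meanlog = log(500), sdlog = 0.5) {
  set.seed(seed)
  v <- matrix(rlnorm(n_genes * (n_stages + 1L), meanlog, sdlog),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              c("control", paste0("s", seq_len(n_stages)))))
  make_expr(v)
}

random_fc <- function(n_genes, n_stages, seed, sd = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_stages, sd = sd), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              paste0("s", seq_len(n_stages))))
  edisom:::new_fold_change_matrix(v)
}

write_gmt_lines <- function(lines) {
  p <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

# a trained-looking map with hand-set codebooks, bypassing training
handmade_som <- function(codebook, rings) {
  grid <- som_grid(rings = rings)
  stopifnot(nrow(codebook) == grid$n_units)
  if (is.null(colnames(codebook))) {
    colnames(codebook) <- paste0("s", seq_len(ncol(codebook)))
  }
  structure(list(grid = grid, codebook = codebook,
                 stages = colnames(codebook),
                 bmu = edisom:::new_bmu_map(
                   setNames(integer(0), character(0)), 0),
                 qe_initial = 0, schedule = NULL, mode = "batch", seed = 1L,
                 trained = TRUE),
            class = "suprasom")
}

# r = 3 grid whose codebooks form two well-separated blobs split by x sign;
# also returns the blob id of each unit
two_blob_som <- function(n_stages = 4L) {
  grid <- som_grid(rings = 3)
  blob <- ifelse(grid$coords$x < 0, 1L, 2L)
  cb <- matrix(0, grid$n_units, n_stages)
  cb[blob == 1L, ] <- -1
  cb[blob == 2L, ] <- 1
  list(som = handmade_som(cb, rings = 3), blob = blob)
}

default_bundle <- function(seed = 42) {
  sim <- simulate_expression(synthetic_spec(
    archetype_counts = c(incremental = 25L, repressed = 25L), n_null = 30L,
    seed = seed))
  expr <- apply_floor(sim$expr, 200)
  fc <- fold_change(expr)
  filt <- regulation_filter(fc, filter_rule())
  fit <- suprasom(filt$fc, seed = seed)
  part <- som_partition(fit)
  planes <- component_planes(fit)
  ann <- synthetic_gene_sets(sim$truth, seed = seed)
  enr <- enrich_clusters(part, ann)
  list(cluster_table = cluster_table(part, fit$bmu),
       seed_profiles = seed_profile_table(part),
       enrichment = enr,
       planes = planes$planes,
       filter_report = filt$report)
}
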