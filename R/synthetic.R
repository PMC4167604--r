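#' Canonical temporal expression archetypes
#'
#' The five dominant time-course patterns the pipeline is designed to
#' resolve, as unit-amplitude (scale `[-1, 1]`) stage vectors: repressed
#' from baseline; repressed following initial induction; incrementally
#' induced; induced then repressed; induced and maintained. Each shape is
#' a fixed piecewise-linear curve sampled at the stage positions, so the
#' vectors are deterministic given the stage count; transitions are fast
#' relative to the stage grid so that, at the default planted amplitude,
#' most stages of a regulated gene sit beyond the two-fold threshold.
#'
#' @param n_stages Number of treatment stages (>= 3).
#' @return A 5 x `n_stages` matrix with one archetype per row, rows named
#'   `repressed`, `repressed_after_induction`, `incremental`,
#'   `induced_repressed`, `induced_maintained`.
#' @export
archetype_profiles <- function(n_stages = 6L) {
  if (!is.numeric(n_stages) || length(n_stages) != 1L || n_stages < 3L ||
      n_stages != round(n_stages)) {
    stop("n_stages must be a single integer >= 3")
  }
  keyframes <- list(
    repressed                  = cbind(c(0, 0.4, 1),            c(-0.5, -1, -1)),
    repressed_after_induction  = cbind(c(0, 0.2, 0.6, 1),       c(1, 1, -1, -1)),
    incremental                = cbind(c(0, 0.4, 1),            c(0.15, 1, 1)),
    induced_repressed          = cbind(c(0, 0.2, 0.6, 0.8, 1),  c(0.6, 1, 1, -1, -1)),
    induced_maintained         = cbind(c(0, 0.15, 1),           c(0.9, 1, 1)))
  t <- (seq_len(n_stages) - 1) / (n_stages - 1)
  out <- t(vapply(keyframes, function(kf) {
    stats::approx(kf[, 1L], kf[, 2L], xout = t)$y
  }, numeric(n_stages)))
  colnames(out) <- paste0("stage", seq_len(n_stages))
  out
}

#' Specification of a synthetic expression study
#'
#' Defines the conditions of a planted-archetype simulation: a lognormal
#' baseline intensity per gene (the control column), five regulated gene
#' groups whose stage-wise log2 fold-change trajectories follow the
#' canonical archetypes scaled to `amplitude`, flat null genes, additive
#' Gaussian noise on the log2 fold-change scale (multiplicative on
#' intensities), and a fraction of control intensities planted below the
#' detectability floor of 200.
#'
#' @param n_stages Treatment stage count.
#' @param archetype_counts Named integer vector of regulated-gene counts,
#'   names matching the rows of [archetype_profiles()].
#' @param n_null Number of flat null genes.
#' @param amplitude Peak `|log2FC|` of a regulated gene.
#' @param noise_sd Gaussian standard deviation added to every log2
#'   fold-change entry.
#' @param baseline_log_mean,baseline_log_sd Lognormal parameters for the
#'   control intensities (defaults give a mean intensity of about 500; the
#'   spread is kept narrow so that the floor's effect is governed by the
#'   explicit `sub_floor_fraction` rather than the lognormal tail).
#' @param sub_floor_fraction Fraction of genes whose control intensity is
#'   drawn uniformly below the 200 floor.
#' @param seed Random seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_stages = 6L,
                           archetype_counts = c(repressed = 100L,
                                                repressed_after_induction = 100L,
                                                incremental = 100L,
                                                induced_repressed = 100L,
                                                induced_maintained = 100L),
                           n_null = 500L,
                           amplitude = 1.5,
                           noise_sd = 0.25,
                           baseline_log_mean = log(500),
                           baseline_log_sd = 0.1,
                           sub_floor_fraction = 0.05,
                           seed = 1L) {
  known <- rownames(archetype_profiles(max(n_stages, 3L)))
  if (is.null(names(archetype_counts)) ||
      !all(names(archetype_counts) %in% known)) {
    stop("archetype_counts names must be among: ", paste(known, collapse = ", "))
  }
  if (any(archetype_counts < 0) || n_null < 0) stop("gene counts must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (sub_floor_fraction < 0 || sub_floor_fraction >= 1) {
    stop("sub_floor_fraction must lie in [0, 1)")
  }
  structure(list(n_stages = as.integer(n_stages),
                 archetype_counts = archetype_counts, n_null = as.integer(n_null),
                 amplitude = amplitude, noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 sub_floor_fraction = sub_floor_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression study
#'
#' Draws control intensities from the lognormal baseline (with the planted
#' sub-floor fraction drawn uniformly in `[25, 199]`), then builds stage
#' intensities as `control * 2^(amplitude * archetype + noise)`; null
#' genes get noise only. The matrix is emitted unfloored, so the standard
#' preprocessing ([apply_floor()], [fold_change()], [regulation_filter()])
#' applies. Identical spec and seed give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `expr` (an unfloored `expression_matrix`, control
#'   column first) and `truth` (data frame `gene`, `archetype`, where
#'   unregulated genes carry `"null"`).
#' @export
simulate_expression <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- spec$archetype_counts
  n_reg <- sum(counts)
  n <- n_reg + spec$n_null
  if (n == 0L) stop("spec generates zero genes")
  set.seed(spec$seed)
  shapes <- archetype_profiles(spec$n_stages)
  labels <- c(rep(names(counts), times = counts), rep("null", spec$n_null))
  genes <- sprintf("g%04d", seq_len(n))
  control <- stats::rlnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)
  n_sub <- round(spec$sub_floor_fraction * n)
  if (n_sub > 0L) {
    idx <- sample.int(n, n_sub)
    control[idx] <- stats::runif(n_sub, 25, 199)
  }
  profile <- matrix(0, nrow = n, ncol = spec$n_stages)
  reg <- labels != "null"
  profile[reg, ] <- spec$amplitude * shapes[labels[reg], , drop = FALSE]
  noise <- matrix(stats::rnorm(n * spec$n_stages, 0, spec$noise_sd),
                  nrow = n)
  stage_values <- control * 2^(profile + noise)
  values <- cbind(control, stage_values)
  dimnames(values) <- list(genes, c("control", colnames(shapes)))
  expr <- new_expression_matrix(values, "control", floored = FALSE)
  truth <- data.frame(gene = genes, archetype = labels,
                      stringsAsFactors = FALSE)
  list(expr = expr, truth = truth)
}

#' Companion synthetic gene sets
#'
#' One term per archetype, holding that archetype's true member genes
#' plus 20% decoy null genes, so enrichment can be exercised end to end
#' against a known answer.
#'
#' @param truth Truth table from [simulate_expression()].
#' @param decoy_fraction Decoys added to each term, as a fraction of its
#'   true members.
#' @param seed Seed for decoy sampling.
#' @return An `annotation_set` with namespace `"synthetic"`.
#' @export
synthetic_gene_sets <- function(truth, decoy_fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("gene", "archetype") %in% names(truth)))
  set.seed(seed)
  nulls <- truth$gene[truth$archetype == "null"]
  archs <- setdiff(unique(truth$archetype), "null")
  terms <- list()
  for (a in archs) {
    members <- truth$gene[truth$archetype == a]
    n_decoy <- min(length(nulls), round(decoy_fraction * length(members)))
    decoys <- if (n_decoy > 0L) sample(nulls, n_decoy) else character(0)
    terms[[paste0("SYN:", a)]] <- list(
      description = paste("synthetic archetype term:", a),
      genes = c(members, decoys))
  }
  structure(list(namespace = "synthetic", terms = terms),
            class = "annotation_set")
}

#' Synthetic stand-in for the deposited clustered matrix
#'
#' Generates (it does not download) an expression table emulating the
#' documented shape of the study's deposited supplementary matrix: 1,893
#' regulated transcripts across a control plus six treatment-stage
#' columns, carrying a 12-cluster labelling in which cluster 2 holds
#' exactly nine transcripts. Clusters are laid over the five canonical
#' archetypes with per-cluster amplitude variation. This is a synthetic
#' fixture for format and reconciliation tests, not the deposited data.
#'
#' @param seed Random seed.
#' @param n_transcripts,n_clusters,cluster2_size Shape parameters,
#'   defaulting to the documented deposit shape.
#' @return List with `expr` (unfloored `expression_matrix`) and
#'   `clusters` (named character vector of cluster labels `1..12`).
#' @export
simulate_deposited_matrix <- function(seed = 1L, n_transcripts = 1893L,
                                      n_clusters = 12L, cluster2_size = 9L) {
  if (n_clusters < 2L) stop("need at least 2 clusters")
  if (cluster2_size + n_clusters - 1L > n_transcripts) {
    stop("cluster sizes exceed transcript count")
  }
  set.seed(seed)
  rest <- n_transcripts - cluster2_size
  others <- setdiff(seq_len(n_clusters), 2L)
  base <- rest %/% length(others)
  sizes <- stats::setNames(rep(base, length(others)), others)
  extra <- rest - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  all_sizes <- integer(n_clusters)
  all_sizes[2L] <- cluster2_size
  all_sizes[others] <- sizes[as.character(others)]
  shapes <- archetype_profiles(6L)
  labels <- rep(seq_len(n_clusters), times = all_sizes)
  arch_of_cluster <- rownames(shapes)[(seq_len(n_clusters) - 1L) %% nrow(shapes) + 1L]
  amp_of_cluster <- 1.2 + 0.1 * ((seq_len(n_clusters) - 1L) %/% nrow(shapes))
  genes <- sprintf("probe%05d", seq_len(n_transcripts))
  control <- stats::rlnorm(n_transcripts, log(500), 0.1)
  profile <- shapes[arch_of_cluster[labels], , drop = FALSE] *
    amp_of_cluster[labels]
  noise <- matrix(stats::rnorm(n_transcripts * 6L, 0, 0.2),
                  nrow = n_transcripts)
  values <- cbind(control, control * 2^(profile + noise))
  dimnames(values) <- list(genes, c("control", colnames(shapes)))
  list(expr = new_expression_matrix(values, "control", floored = FALSE),
       clusters = stats::setNames(as.character(labels), genes))
}

#' Cluster-recovery score against planted ground truth
#'
#' Adjusted Rand index between the planted archetype labels and the
#' recovered clustering, after merging recovered clusters by their
#' majority archetype (so that a clustering that splits one archetype
#' into several adjacent map clusters is not penalized). Restricted to
#' the genes present in both labelings.
#'
#' @param truth Truth table from [simulate_expression()] (or a named
#'   character vector gene -> archetype).
#' @param partition A `som_partition`, or a named vector of cluster labels.
#' @return The adjusted Rand index, in `[-1, 1]`.
#' @export
recovery_score <- function(truth, partition) {
  truth_vec <- if (is.data.frame(truth)) {
    stats::setNames(truth$archetype, truth$gene)
  } else truth
  clusters <- if (inherits(partition, "som_partition")) {
    partition$gene_cluster
  } else partition
  common <- intersect(names(truth_vec), names(clusters))
  if (length(common) == 0L) stop("truth and partition share no genes")
  tv <- as.character(truth_vec[common])
  cv <- as.character(clusters[common])
  # merge clusters by majority archetype
  merged <- vapply(split(tv, cv), function(labs) {
    tab <- sort(table(labs), decreasing = TRUE)
    names(tab)[1L]
  }, character(1L))
  mclust::adjustedRandIndex(tv, merged[cv])
}
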