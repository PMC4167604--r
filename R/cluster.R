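#' Neighbour-distance (U-height) surface of a trained map
#'
#' For each unit, the mean Euclidean codebook distance to its lattice
#' neighbours (units at hex distance 1). Boundary units average over the
#' neighbours they have; an isolated single-unit grid gets 0 by
#' convention. Local minima of this surface mark cluster seeds.
#'
#' @param model A fitted `suprasom`.
#' @return Numeric vector, one value per unit.
#' @export
neighbor_distance <- function(model) {
  stopifnot(inherits(model, "suprasom"))
  if (!isTRUE(model$trained)) stop("map is not trained")
  nb <- grid_neighbors(model$grid)
  cb <- model$codebook
  vapply(seq_len(model$grid$n_units), function(u) {
    if (length(nb[[u]]) == 0L) return(0)
    mean(sqrt(rowSums((cb[nb[[u]], , drop = FALSE] -
                         matrix(cb[u, ], nrow = length(nb[[u]]),
                                ncol = ncol(cb), byrow = TRUE))^2)))
  }, numeric(1L))
}

#' Locate cluster seed units
#'
#' A unit is a seed when its neighbour-distance height is less than or
#' equal to every lattice neighbour's height; a connected plateau of
#' equal-height adjacent minima collapses to its lowest-index unit.
#' Seeds are returned in increasing unit index order.
#'
#' @param model A fitted `suprasom`.
#' @param heights Per-unit heights from [neighbor_distance()] on the same
#'   map (recomputed when omitted).
#' @return Integer vector of seed unit indices.
#' @export
find_seeds <- function(model, heights = neighbor_distance(model)) {
  stopifnot(inherits(model, "suprasom"))
  M <- model$grid$n_units
  if (length(heights) != M) {
    stop("heights length (", length(heights), ") does not match unit count (",
         M, ")")
  }
  nb <- grid_neighbors(model$grid)
  tol <- 1e-9 * max(1, max(abs(heights)))
  is_min <- vapply(seq_len(M), function(u) {
    length(nb[[u]]) == 0L || all(heights[u] <= heights[nb[[u]]] + tol)
  }, logical(1L))
  cand <- which(is_min)
  if (length(cand) == 0L) return(integer(0))
  # collapse plateaus: connected components of equal-height adjacent minima
  comp <- stats::setNames(rep(NA_integer_, length(cand)), cand)
  seeds <- integer(0)
  visited <- logical(M)
  cand_set <- logical(M); cand_set[cand] <- TRUE
  for (u in cand) {
    if (visited[u]) next
    queue <- u; members <- integer(0)
    while (length(queue) > 0L) {
      w <- queue[[1L]]; queue <- queue[-1L]
      if (visited[w]) next
      visited[w] <- TRUE
      members <- c(members, w)
      nxt <- nb[[w]]
      nxt <- nxt[cand_set[nxt] & !visited[nxt] &
                   abs(heights[nxt] - heights[w]) <= tol]
      queue <- c(queue, nxt)
    }
    seeds <- c(seeds, min(members))
  }
  sort(seeds)
}

#' Partition a trained map into topological gene clusters
#'
#' Two-phase clustering of the trained map: seeds are local minima of the
#' neighbour-distance surface ([find_seeds()]); clusters are then grown
#' over the lattice by repeatedly attaching the unassigned unit that is
#' lattice-adjacent to an already-assigned unit and whose codebook is
#' closest to the adjacent cluster's *seed* codebook (ties: lower cluster
#' ID, then lower unit index). Transcripts inherit the cluster of their
#' best-matching unit. Clusters are numbered 1..K in seed unit order, so
#' repeated runs are reproducible.
#'
#' The number of clusters is emergent, not a parameter; `max_clusters`
#' optionally caps it by iteratively merging the two clusters whose seed
#' codebooks are closest.
#'
#' @param model A fitted `suprasom`.
#' @param bmu A `bmu_map` over the same map (defaults to the training
#'   assignment).
#' @param seeds Seed unit indices (defaults to [find_seeds()]).
#' @param max_clusters Optional upper bound on the cluster count.
#' @return A `som_partition`: list with `n_clusters`, `unit_cluster`
#'   (integer per unit), `seed_units` (unit index per cluster),
#'   `seed_profiles` (cluster x stage matrix of seed codebooks) and
#'   `gene_cluster` (named integer per transcript).
#' @export
som_partition <- function(model, bmu = predict(model), seeds = find_seeds(model),
                          max_clusters = NULL) {
  stopifnot(inherits(model, "suprasom"), inherits(bmu, "bmu_map"))
  M <- model$grid$n_units
  if (length(seeds) == 0L) stop("empty seed list; cannot partition the map")
  if (any(seeds < 1L | seeds > M)) stop("seed unit index out of range")
  if (any(bmu$assignment < 1L | bmu$assignment > M)) {
    stop("BMU assignment refers to units outside this grid")
  }
  nb <- grid_neighbors(model$grid)
  cb <- model$codebook
  seeds <- sort(unique(as.integer(seeds)))
  K <- length(seeds)
  unit_cluster <- rep(NA_integer_, M)
  unit_cluster[seeds] <- seq_len(K)
  seed_cb <- cb[seeds, , drop = FALSE]
  while (anyNA(unit_cluster)) {
    best <- NULL   # (dist, cluster, unit)
    for (u in which(is.na(unit_cluster))) {
      adj_cl <- sort(unique(unit_cluster[nb[[u]]]))
      adj_cl <- adj_cl[!is.na(adj_cl)]
      for (k in adj_cl) {
        d <- sqrt(sum((cb[u, ] - seed_cb[k, ])^2))
        if (is.null(best) || d < best[1L] - 1e-12 ||
            (abs(d - best[1L]) <= 1e-12 &&
             (k < best[2L] || (k == best[2L] && u < best[3L])))) {
          best <- c(d, k, u)
        }
      }
    }
    if (is.null(best)) stop("lattice is disconnected; cannot grow clusters")
    unit_cluster[best[3L]] <- best[2L]
  }
  part <- finalize_partition(unit_cluster, seeds, cb, bmu)
  if (!is.null(max_clusters) && part$n_clusters > max_clusters) {
    part <- merge_to_cap(part, cb, bmu, max_clusters)
  }
  part
}

finalize_partition <- function(unit_cluster, seeds, cb, bmu) {
  # renumber clusters 1..K in seed-unit index order
  ord <- order(seeds)
  relabel <- integer(length(seeds)); relabel[ord] <- seq_along(seeds)
  unit_cluster <- relabel[unit_cluster]
  seeds <- seeds[ord]
  seed_profiles <- cb[seeds, , drop = FALSE]
  rownames(seed_profiles) <- paste0("cluster", seq_along(seeds))
  gene_cluster <- stats::setNames(unit_cluster[bmu$assignment],
                                  names(bmu$assignment))
  structure(list(n_clusters = length(seeds), unit_cluster = unit_cluster,
                 seed_units = seeds, seed_profiles = seed_profiles,
                 gene_cluster = gene_cluster),
            class = "som_partition")
}

merge_to_cap <- function(part, cb, bmu, max_clusters) {
  unit_cluster <- part$unit_cluster
  seeds <- part$seed_units
  while (length(seeds) > max_clusters) {
    d <- as.matrix(stats::dist(cb[seeds, , drop = FALSE]))
    d[upper.tri(d, diag = TRUE)] <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1L, ]  # pair of closest seeds
    keep <- min(ij); drop <- max(ij)
    unit_cluster[unit_cluster == drop] <- keep
    unit_cluster[unit_cluster > drop] <- unit_cluster[unit_cluster > drop] - 1L
    seeds <- seeds[-drop]
  }
  finalize_partition(unit_cluster, seeds, cb, bmu)
}

#' @export
print.som_partition <- function(x, ...) {
  cat("Topological map partition:", x$n_clusters, "clusters over",
      length(x$unit_cluster), "units;", length(x$gene_cluster),
      "transcripts assigned\n")
  invisible(x)
}

#' @export
summary.som_partition <- function(object, ...) {
  sizes <- cluster_sizes(object)
  cat("Topological map partition\n")
  print(object)
  df <- data.frame(cluster = as.integer(names(sizes)),
                   seed_unit = object$seed_units,
                   transcripts = as.integer(sizes))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Per-cluster transcript counts
#'
#' @param p A `som_partition` (or a named vector / factor of cluster
#'   labels, e.g. the cluster column of a deposited matrix).
#' @return Named integer vector of counts, one per cluster; the counts
#'   sum to the number of assigned transcripts.
#' @export
cluster_sizes <- function(p) {
  labels <- if (inherits(p, "som_partition")) p$gene_cluster else p
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cluster table of a partition
#'
#' @param p A `som_partition`.
#' @param bmu Optional `bmu_map` to report each transcript's unit.
#' @return Data frame `transcript_id`, `cluster`, `unit`.
#' @export
cluster_table <- function(p, bmu = NULL) {
  stopifnot(inherits(p, "som_partition"))
  df <- data.frame(transcript_id = names(p$gene_cluster),
                   cluster = unname(p$gene_cluster),
                   stringsAsFactors = FALSE)
  if (!is.null(bmu)) df$unit <- unname(bmu$assignment[df$transcript_id])
  df
}
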