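#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X` hypergeometric: the chance of drawing at least `k`
#' members of a `K`-gene term when sampling `n` genes (a cluster) without
#' replacement from a background of `N` genes. Computed exactly.
#'
#' @param k Observed overlap between cluster and term.
#' @param K Term size within the background.
#' @param n Cluster size within the background.
#' @param N Background universe size.
#' @return The p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop("k, K, n, N must be single non-negative integers")
    }
  }
  if (K > N || n > N) stop("inconsistent counts: need K <= N and n <= N")
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: with `p` sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, mapped back to the
#' input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cluster over-representation analysis
#'
#' For every cluster x term pair whose term intersects the background,
#' computes the overlap `k`, term size `K = |term & background|`, cluster
#' size `n = |cluster & background|`, background size `N`, the exact
#' hypergeometric upper-tail p-value and the BH q-value (adjusted within
#' each cluster x namespace family independently). All rows are returned;
#' rows with `overlap >= min_overlap` and `q_value < fdr` are flagged
#' `reported`.
#'
#' @param partition A `som_partition`, or a named vector of cluster labels
#'   per gene.
#' @param ann An `annotation_set` from [read_gene_sets()].
#' @param background Character vector: the gene universe (default: every
#'   annotated gene in the namespace; configurable to e.g. all genes on
#'   the array or the filtered set).
#' @param min_overlap Minimum cluster-term overlap for reporting.
#' @param fdr FDR threshold for reporting.
#' @return Data frame with columns `cluster`, `namespace`, `term_id`,
#'   `description`, `overlap`, `cluster_size`, `term_size`,
#'   `background_size`, `p_value`, `q_value`, `reported`.
#' @export
enrich_clusters <- function(partition, ann, background = NULL,
                            min_overlap = 3L, fdr = 0.05) {
  stopifnot(inherits(ann, "annotation_set"))
  gene_cluster <- if (inherits(partition, "som_partition")) {
    partition$gene_cluster
  } else partition
  if (is.null(names(gene_cluster))) stop("cluster labels must be named by gene")
  if (min_overlap < 0) stop("min_overlap must be >= 0")
  if (is.null(background)) {
    background <- unique(unlist(lapply(ann$terms, `[[`, "genes"),
                                use.names = FALSE))
  }
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background universe is empty")
  N <- length(background)
  clusters <- sort(unique(gene_cluster))
  rows <- list()
  for (cl in clusters) {
    cl_genes <- intersect(names(gene_cluster)[gene_cluster == cl], background)
    n <- length(cl_genes)
    block <- list()
    for (id in names(ann$terms)) {
      term_genes <- intersect(ann$terms[[id]]$genes, background)
      K <- length(term_genes)
      if (K == 0L) next
      k <- length(intersect(cl_genes, term_genes))
      block[[length(block) + 1L]] <- data.frame(
        cluster = cl, namespace = ann$namespace, term_id = id,
        description = ann$terms[[id]]$description,
        overlap = k, cluster_size = n, term_size = K, background_size = N,
        p_value = hypergeom_tail(k, K, n, N), stringsAsFactors = FALSE)
    }
    if (length(block) == 0L) next
    block <- do.call(rbind, block)
    block$q_value <- bh_adjust(block$p_value)   # within (cluster, namespace)
    rows[[length(rows) + 1L]] <- block
  }
  if (length(rows) == 0L) {
    out <- data.frame(cluster = character(0), namespace = character(0),
                      term_id = character(0), description = character(0),
                      overlap = integer(0), cluster_size = integer(0),
                      term_size = integer(0), background_size = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      reported = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$reported <- out$overlap >= min_overlap & out$q_value < fdr
  rownames(out) <- NULL
  out
}
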