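#' Component plane presentations of a trained map
#'
#' One plane per treatment stage: the plane for stage `k` colours every
#' unit by column `k` of the codebook, so the set of planes is a lossless
#' re-layout of the codebook. All planes share symmetric colour limits
#' `(-m, +m)` with `m = max |codebook|` over all stages, so stages are
#' directly comparable; a degenerate all-zero codebook widens the limits
#' to `(-1, +1)`.
#'
#' @param model A fitted `suprasom`.
#' @return A `component_planes` object: list with `planes` (named list of
#'   data frames `unit`, `q`, `r`, `value`, one per stage) and
#'   `color_limits`.
#' @export
component_planes <- function(model) {
  stopifnot(inherits(model, "suprasom"))
  if (!isTRUE(model$trained)) stop("map is not trained")
  m <- max(abs(model$codebook))
  lim <- if (m == 0) c(-1, 1) else c(-m, m)
  planes <- lapply(seq_along(model$stages), function(k) {
    data.frame(unit = model$grid$coords$unit,
               q = model$grid$coords$q, r = model$grid$coords$r,
               value = model$codebook[, k])
  })
  names(planes) <- model$stages
  structure(list(planes = planes, color_limits = lim,
                 grid = model$grid), class = "component_planes")
}

#' @export
print.component_planes <- function(x, ...) {
  cat("Component planes:", length(x$planes), "stages,",
      nrow(x$planes[[1L]]), "units; colour limits [",
      format(x$color_limits[1L], digits = 3), ",",
      format(x$color_limits[2L], digits = 3), "]\n")
  invisible(x)
}

diverging_palette <- function(n = 255L) {
  grDevices::colorRampPalette(c("#2166AC", "#67A9CF", "#F7F7F7",
                                "#EF8A62", "#B2182B"))(n)
}

draw_hexmap <- function(grid, values, limits, main = "", pal = diverging_palette()) {
  idx <- findInterval(values, seq(limits[1L], limits[2L],
                                  length.out = length(pal) + 1L),
                      all.inside = TRUE)
  a <- seq(pi / 6, by = pi / 3, length.out = 6L)  # pointy-top hexagon
  rad <- 1 / sqrt(3)
  graphics::plot(grid$coords$x, grid$coords$y, type = "n", asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (u in seq_len(grid$n_units)) {
    graphics::polygon(grid$coords$x[u] + rad * cos(a),
                      grid$coords$y[u] + rad * sin(a),
                      col = pal[idx[u]], border = "grey40", lwd = 0.4)
  }
}

#' Plot a component-plane set or a trained map
#'
#' Renders the per-stage component planes (diverging palette anchored at
#' zero log2 fold change: red up, blue down), or the neighbour-distance
#' surface, as hexagon maps with base graphics.
#'
#' @param x A `component_planes` object.
#' @param ... Unused.
#' @export
plot.component_planes <- function(x, ...) {
  n <- length(x$planes)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (s in names(x$planes)) {
    draw_hexmap(x$grid, x$planes[[s]]$value, x$color_limits, main = s)
  }
  invisible(x)
}

#' @param y Unused.
#' @param type `"planes"` (component planes) or `"uheight"`
#'   (neighbour-distance surface with seed units marked).
#' @rdname plot.component_planes
#' @export
plot.suprasom <- function(x, y = NULL, type = c("planes", "uheight"), ...) {
  type <- match.arg(type)
  if (type == "planes") return(plot(component_planes(x), ...))
  h <- neighbor_distance(x)
  lim <- range(h)
  if (diff(lim) == 0) lim <- lim + c(-1, 1)
  draw_hexmap(x$grid, h, lim, main = "neighbour distance",
              pal = grDevices::colorRampPalette(c("#F7F7F7", "#2166AC"))(255L))
  s <- find_seeds(x, h)
  graphics::points(x$grid$coords$x[s], x$grid$coords$y[s], pch = 8)
  invisible(x)
}

#' @export
plot.som_partition <- function(x, y = NULL, model = NULL, ...) {
  if (is.null(model)) stop("pass the fitted map via model = ")
  pal <- grDevices::hcl.colors(max(x$n_clusters, 3L), "Dark 3")
  a <- seq(pi / 6, by = pi / 3, length.out = 6L)
  rad <- 1 / sqrt(3)
  g <- model$grid
  graphics::plot(g$coords$x, g$coords$y, type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = "map clusters")
  for (u in seq_len(g$n_units)) {
    graphics::polygon(g$coords$x[u] + rad * cos(a), g$coords$y[u] + rad * sin(a),
                      col = pal[x$unit_cluster[u]], border = "grey30", lwd = 0.4)
  }
  graphics::text(g$coords$x[x$seed_units], g$coords$y[x$seed_units],
                 labels = seq_len(x$n_clusters), font = 2)
  invisible(x)
}

#' Gene-panel fold-change report
#'
#' Tabulates, for a chosen ordered panel of genes, the stage-wise log2
#' fold changes from the *pre-filter* matrix together with the cluster
#' membership; genes that failed the regulation filter (and so were
#' excluded from clustering) are marked with a hyphen.
#'
#' @param fc_full The pre-filter `fold_change_matrix` containing every
#'   panel gene.
#' @param partition A `som_partition` over the filtered genes.
#' @param panel Character vector of gene IDs, in report order.
#' @return Data frame: `gene`, one column per stage, and `cluster`
#'   (cluster ID as character, or `"-"`).
#' @export
gene_panel_report <- function(fc_full, partition, panel) {
  stopifnot(inherits(fc_full, "fold_change_matrix"),
            inherits(partition, "som_partition"))
  absent <- setdiff(panel, rownames(fc_full$values))
  if (length(absent) > 0L) {
    stop("panel gene(s) absent from the fold-change matrix: ",
         paste(absent, collapse = ", "))
  }
  fcs <- fc_full$values[panel, , drop = FALSE]
  cl <- partition$gene_cluster[panel]
  cluster <- ifelse(is.na(cl), "-", as.character(cl))
  out <- data.frame(gene = panel, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fcs, check.names = FALSE))
  out$cluster <- unname(cluster)
  rownames(out) <- NULL
  out
}
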