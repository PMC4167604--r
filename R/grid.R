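#' Supra-hexagonal lattice geometry
#'
#' Builds the hexagon-shaped lattice of hexagonal units used by the map:
#' `r` rings hold `3r(r-1)+1` units. When `rings` is not given it is sized
#' from the number of profiles so that the unit count approximates
#' `5 * sqrt(n_profiles)` (the usual map-sizing heuristic), scanning
#' `r = 1..50` and preferring the smaller `r` on ties.
#'
#' Units are indexed 1..M, ordered by ring (centre first) and, within a
#' ring, by angle from the positive x axis. Axial coordinates `(q, r)`
#' convert to Cartesian unit centres via `x = q + r/2`, `y = r * sqrt(3)/2`,
#' so lattice-adjacent units are exactly distance 1 apart.
#'
#' @param n_profiles Number of profiles the map will be fitted to.
#' @param rings Optional explicit ring count (>= 1), overriding the
#'   heuristic.
#' @return A `som_grid`: list with `rings`, `n_units`, `coords` (data frame
#'   `unit`, `q`, `r`, `x`, `y`) and `dist` (unit-by-unit Cartesian
#'   distance matrix).
#' @export
som_grid <- function(n_profiles = NULL, rings = NULL) {
  if (is.null(rings)) {
    if (is.null(n_profiles) || n_profiles < 1) {
      stop("n_profiles must be >= 1 when rings is not given")
    }
    target <- 5 * sqrt(n_profiles)
    r_cand <- 1:50
    units_cand <- 3 * r_cand * (r_cand - 1) + 1
    rings <- r_cand[which.min(abs(units_cand - target))]  # which.min -> smaller r on ties
  }
  if (!is.numeric(rings) || length(rings) != 1L || rings < 1 ||
      rings != round(rings)) {
    stop("rings must be a single integer >= 1")
  }
  rings <- as.integer(rings)
  R <- rings - 1L
  qs <- rep(seq(-R, R), each = 2L * R + 1L)
  rs <- rep(seq(-R, R), times = 2L * R + 1L)
  keep <- pmax(abs(qs), abs(rs), abs(qs + rs)) <= R
  q <- qs[keep]; r <- rs[keep]
  x <- q + r / 2
  y <- r * sqrt(3) / 2
  ring <- pmax(abs(q), abs(r), abs(q + r))
  ang <- atan2(y, x)
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  ord <- order(ring, ang, q, r)
  coords <- data.frame(unit = seq_along(ord), q = q[ord], r = r[ord],
                       x = x[ord], y = y[ord])
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  dimnames(d) <- NULL
  structure(list(rings = rings, n_units = nrow(coords), coords = coords,
                 dist = d),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("Supra-hexagonal grid:", x$rings, "rings,", x$n_units, "units\n")
  invisible(x)
}

#' Euclidean distance between two lattice units
#'
#' Distance between unit centres after axial-to-Cartesian conversion;
#' symmetric, zero iff `u == v`, and exactly 1 for lattice-adjacent units.
#'
#' @param u,v Unit indices (1-based).
#' @param grid A `som_grid`.
#' @return Non-negative number.
#' @export
hex_distance <- function(u, v, grid) {
  stopifnot(inherits(grid, "som_grid"))
  ok <- function(i) is.numeric(i) && length(i) == 1L && !is.na(i) &&
    i == round(i) && i >= 1 && i <= grid$n_units
  if (!ok(u) || !ok(v)) {
    stop("unit index out of range 1..", grid$n_units)
  }
  grid$dist[u, v]
}

#' Lattice neighbour lists (units at hex distance 1)
#' @param grid A `som_grid`.
#' @return List of integer vectors, one per unit.
#' @keywords internal
grid_neighbors <- function(grid) {
  adj <- abs(grid$dist - 1) < 1e-9
  lapply(seq_len(grid$n_units), function(u) which(adj[u, ]))
}
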