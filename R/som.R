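#' Training schedule for the self-organizing map
#'
#' A schedule is an ordered set of phases; within each phase the Gaussian
#' neighbourhood radius `sigma` and (in sequential mode) the learning rate
#' `alpha` are interpolated linearly across the phase's epochs.
#'
#' The default follows common two-stage SOM practice: a rough ordering
#' phase with `max(5, ceiling(10 * n_units / n_profiles))` epochs shrinking
#' `sigma` from the grid radius to 1, then a fine-tuning phase four times
#' as long shrinking `sigma` from 1 to 0.5. Learning rates 0.5 -> 0.05 and
#' 0.05 -> 0.01 apply only in sequential mode; batch updates have no rate.
#'
#' @param phases Data frame with columns `epochs`, `sigma_start`,
#'   `sigma_end`, `alpha_start`, `alpha_end` (one row per phase).
#' @return A `som_schedule`.
#' @export
som_schedule <- function(phases) {
  need <- c("epochs", "sigma_start", "sigma_end", "alpha_start", "alpha_end")
  if (!is.data.frame(phases) || !all(need %in% names(phases))) {
    stop("phases must be a data frame with columns: ", paste(need, collapse = ", "))
  }
  if (any(phases$epochs < 1 | phases$epochs != round(phases$epochs))) {
    stop("every phase needs epochs >= 1")
  }
  if (any(phases$sigma_start <= 0 | phases$sigma_end <= 0)) {
    stop("sigma values must be > 0")
  }
  if (any(phases$alpha_start <= 0 | phases$alpha_start > 1 |
          phases$alpha_end <= 0 | phases$alpha_end > 1)) {
    stop("learning rates must lie in (0, 1]")
  }
  structure(list(phases = phases), class = "som_schedule")
}

#' @rdname som_schedule
#' @param rings,n_units Grid geometry the schedule is built for.
#' @param n_profiles Number of training profiles.
#' @export
default_schedule <- function(rings, n_units, n_profiles) {
  rough <- max(5L, ceiling(10 * n_units / n_profiles))
  som_schedule(data.frame(
    epochs      = c(rough, 4L * rough),
    sigma_start = c(max(rings, 1), 1),
    sigma_end   = c(1, 0.5),
    alpha_start = c(0.5, 0.05),
    alpha_end   = c(0.05, 0.01)))
}

# Linear codebook initialization on the plane of the first two principal
# directions; seeded uniform fallback when the data are rank-deficient.
som_init <- function(grid, X, seed) {
  M <- grid$n_units
  S <- ncol(X)
  ok_pca <- FALSE
  if (nrow(X) >= 3L && S >= 2L) {
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    if (length(pr$sdev) >= 2L && pr$sdev[2L] > 1e-10) ok_pca <- TRUE
  }
  if (ok_pca) {
    # deterministic sign: largest-magnitude loading of each axis positive
    rot <- pr$rotation[, 1:2, drop = FALSE]
    for (j in 1:2) {
      piv <- which.max(abs(rot[, j]))
      if (rot[piv, j] < 0) rot[, j] <- -rot[, j]
    }
    cx <- grid$coords$x; cy <- grid$coords$y
    nx <- if (max(abs(cx)) > 0) cx / max(abs(cx)) else cx
    ny <- if (max(abs(cy)) > 0) cy / max(abs(cy)) else cy
    centre <- colMeans(X)
    cb <- matrix(rep(centre, each = M), nrow = M)
    cb <- cb + outer(nx * pr$sdev[1L], rot[, 1L]) +
      outer(ny * pr$sdev[2L], rot[, 2L])
  } else {
    set.seed(seed)
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    cb <- sapply(seq_len(S), function(j) stats::runif(M, lo[j], hi[j]))
    cb <- matrix(cb, nrow = M)
  }
  colnames(cb) <- colnames(X)
  cb
}

# squared Euclidean distances between rows of X (n x S) and codebook (M x S)
cross_dist2 <- function(X, cb) {
  d2 <- outer(rowSums(X^2), rowSums(cb^2), "+") - 2 * X %*% t(cb)
  d2[d2 < 0] <- 0
  d2
}

bmu_of <- function(X, cb) {
  max.col(-cross_dist2(X, cb), ties.method = "first")
}

quantization_error_of <- function(X, cb, bmu) {
  mean(sqrt(rowSums((X - cb[bmu, , drop = FALSE])^2)))
}

phase_values <- function(phases) {
  # per-epoch (sigma, alpha) across all phases, linear within each phase
  out <- NULL
  for (i in seq_len(nrow(phases))) {
    E <- phases$epochs[i]
    f <- if (E == 1L) 0 else (seq_len(E) - 1) / (E - 1)
    out <- rbind(out, cbind(
      sigma = phases$sigma_start[i] + f * (phases$sigma_end[i] - phases$sigma_start[i]),
      alpha = phases$alpha_start[i] + f * (phases$alpha_end[i] - phases$alpha_start[i])))
  }
  out
}

som_train_epochs <- function(cb, X, grid, phases, mode, seed) {
  sched <- phase_values(phases)
  D2grid <- grid$dist^2
  if (mode == "sequential") set.seed(seed)
  for (e in seq_len(nrow(sched))) {
    sigma <- sched[e, "sigma"]
    alpha <- sched[e, "alpha"]
    H <- exp(-D2grid / (2 * sigma^2))
    if (mode == "batch") {
      bmu <- bmu_of(X, cb)
      W <- H[bmu, , drop = FALSE]            # n x M neighbourhood weights
      denom <- colSums(W)
      numer <- t(W) %*% X                    # M x S
      upd <- denom > 1e-300
      cb[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
    } else {
      ord <- sample.int(nrow(X))
      for (j in ord) {
        x <- X[j, ]
        b <- which.min(colSums((t(cb) - x)^2))
        h <- H[b, ]
        cb <- cb + alpha * h * (matrix(x, nrow = nrow(cb), ncol = length(x),
                                       byrow = TRUE) - cb)
      }
    }
  }
  cb
}

#' Fit a supra-hexagonal self-organizing map
#'
#' Trains a hexagon-shaped SOM with a Gaussian neighbourhood kernel on
#' log2 fold-change profiles (one row per transcript) and maps each
#' transcript to its best-matching unit. Profiles are used as-is (no row
#' standardization), so codebook values keep the signed regulation scale.
#'
#' Batch mode (the default) recomputes every codebook vector each epoch as
#' the neighbourhood-weighted mean of the profiles, and is deterministic
#' given the data. Sequential mode applies the classic per-sample update
#' `m <- m + alpha * h * (x - m)` in a seeded random sample order.
#'
#' @param fc A `fold_change_matrix` (or plain numeric matrix with row
#'   names) of profiles to cluster.
#' @param rings Optional ring count; by default sized from the profile
#'   count (see [som_grid()]).
#' @param schedule A [som_schedule()]; default built by
#'   [default_schedule()].
#' @param mode `"batch"` or `"sequential"`.
#' @param seed Seed controlling the sequential sample order and the
#'   random-init fallback.
#' @param codebook Optional explicit initial codebook (units x stages),
#'   e.g. to continue training; by default a linear initialization over
#'   the plane of the first two principal directions of the data.
#' @return A `suprasom` object: `grid`, `codebook`, `stages`, `bmu` (a
#'   `bmu_map`: named unit assignment plus mean quantization error),
#'   `qe_initial` (quantization error at initialization), `schedule`,
#'   `mode`, `seed`.
#' @examples
#' fc <- matrix(rnorm(120), 20, 6,
#'              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
#' fit <- suprasom(fc, rings = 2)
#' fit
#' @export
suprasom <- function(fc, rings = NULL, schedule = NULL,
                     mode = c("batch", "sequential"), seed = 1L,
                     codebook = NULL) {
  mode <- match.arg(mode)
  X <- if (inherits(fc, "fold_change_matrix")) fc$values else as.matrix(fc)
  if (is.null(rownames(X))) stop("profiles must carry row names (transcript IDs)")
  grid <- som_grid(n_profiles = nrow(X), rings = rings)
  if (is.null(codebook)) {
    cb <- som_init(grid, X, seed)
  } else {
    cb <- as.matrix(codebook)
    if (nrow(cb) != grid$n_units || ncol(cb) != ncol(X)) {
      stop("codebook must be ", grid$n_units, " units x ", ncol(X), " stages")
    }
  }
  if (is.null(schedule)) {
    schedule <- default_schedule(grid$rings, grid$n_units, nrow(X))
  }
  stopifnot(inherits(schedule, "som_schedule"))
  qe0 <- quantization_error_of(X, cb, bmu_of(X, cb))
  cb <- som_train_epochs(cb, X, grid, schedule$phases, mode, seed)
  if (any(!is.finite(cb))) stop("training produced non-finite codebook entries")
  bmu <- bmu_of(X, cb)
  model <- structure(list(
    grid = grid, codebook = cb, stages = colnames(X),
    bmu = new_bmu_map(stats::setNames(bmu, rownames(X)),
                      quantization_error_of(X, cb, bmu)),
    qe_initial = qe0, schedule = schedule, mode = mode, seed = seed,
    trained = TRUE), class = "suprasom")
  model
}

new_bmu_map <- function(assignment, qe) {
  structure(list(assignment = assignment, quantization_error = qe),
            class = "bmu_map")
}

#' @export
print.bmu_map <- function(x, ...) {
  cat("BMU map:", length(x$assignment), "profiles; quantization error",
      format(x$quantization_error, digits = 4), "\n")
  invisible(x)
}

#' @export
print.suprasom <- function(x, ...) {
  cat("Supra-hexagonal SOM (", x$grid$rings, " rings, ", x$grid$n_units,
      " units, ", length(x$stages), " stages)\n", sep = "")
  cat("  mode:", x$mode, "| quantization error:",
      format(x$bmu$quantization_error, digits = 4),
      "(init", paste0(format(x$qe_initial, digits = 4), ")"), "\n")
  invisible(x)
}

#' @export
summary.suprasom <- function(object, ...) {
  counts <- tabulate(object$bmu$assignment, nbins = object$grid$n_units)
  cat("Supra-hexagonal SOM summary\n")
  print(object)
  cat("  occupied units:", sum(counts > 0), "of", object$grid$n_units, "\n")
  cat("  profiles per occupied unit: median",
      stats::median(counts[counts > 0]), "max", max(counts), "\n")
  invisible(list(unit_counts = counts))
}

#' Map profiles to their best-matching units
#'
#' Assigns each profile to the unit with the smallest Euclidean codebook
#' distance; ties break to the lowest unit index.
#'
#' @param object A fitted `suprasom`.
#' @param newdata A `fold_change_matrix` or numeric matrix with row names
#'   and the same stage count as the fitted map; defaults to the training
#'   assignment.
#' @param ... Unused.
#' @return A `bmu_map`: list with `assignment` (named unit indices) and
#'   `quantization_error` (mean Euclidean distance to the assigned
#'   codebooks).
#' @export
predict.suprasom <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$bmu)
  X <- if (inherits(newdata, "fold_change_matrix")) newdata$values else as.matrix(newdata)
  if (ncol(X) != ncol(object$codebook)) {
    stop("newdata has ", ncol(X), " stages but the map was fitted with ",
         ncol(object$codebook))
  }
  if (is.null(rownames(X))) stop("newdata must carry row names")
  bmu <- bmu_of(X, object$codebook)
  new_bmu_map(stats::setNames(bmu, rownames(X)),
              quantization_error_of(X, object$codebook, bmu))
}
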