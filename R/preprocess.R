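#' Regulation filter parameters
#'
#' Bundles the three preprocessing thresholds: the detectability floor on
#' linear intensities, the fold-change threshold and the minimum number of
#' treatment stages at which a transcript must reach it. Defaults follow
#' the conventional two-fold-at-four-or-more-stages rule with a floor of
#' 200 intensity units.
#'
#' @param min_fold Linear fold-change threshold (> 1); a transcript stage
#'   qualifies when `|log2FC| >= log2(min_fold)` (inclusive, so exactly
#'   two-fold qualifies, in either direction).
#' @param min_stages Minimum count of qualifying stages for a transcript
#'   to be kept.
#' @param floor Detectability floor in linear intensity units; values
#'   strictly below it are clamped up to it.
#' @return A `filter_rule` list.
#' @export
filter_rule <- function(min_fold = 2, min_stages = 4, floor = 200) {
  if (!is.numeric(min_fold) || length(min_fold) != 1L || min_fold <= 1) {
    stop("min_fold must be a single number > 1")
  }
  if (!is.numeric(min_stages) || length(min_stages) != 1L || min_stages < 1 ||
      min_stages != round(min_stages)) {
    stop("min_stages must be a positive integer")
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("floor must be a single positive number")
  }
  structure(list(min_fold = min_fold, min_stages = as.integer(min_stages),
                 floor = floor), class = "filter_rule")
}

#' Apply the detectability floor
#'
#' Intensities strictly below the floor are considered technically
#' undetectable and clamped up to the floor; all other values pass
#' through unchanged. Applied to control and treatment columns alike, so
#' that ratios between two undetectable values are exactly 1.
#'
#' @param x An unfloored `expression_matrix`.
#' @param floor Detectability floor in linear intensity units.
#' @return The floored `expression_matrix` (`floored = TRUE`).
#' @export
apply_floor <- function(x, floor = 200) {
  stopifnot(inherits(x, "expression_matrix"))
  if (isTRUE(x$floored)) {
    stop("expression matrix is already floored; refusing to floor twice")
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    stop("floor must be a single positive number")
  }
  v <- x$values
  v[v < floor] <- floor
  out <- new_expression_matrix(v, x$control, floored = TRUE)
  attr(out, "clusters") <- attr(x, "clusters")
  out
}

#' Stage-wise log2 fold changes versus the control
#'
#' For each transcript and treatment stage, computes
#' `log2(intensity(stage) / intensity(control))` on the floored matrix and
#' drops the control column.
#'
#' @param x A floored `expression_matrix`.
#' @return A `fold_change_matrix`: list with `values` (transcripts x
#'   stages, log2 ratios) and `stages` (stage labels in column order).
#' @export
fold_change <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!isTRUE(x$floored)) {
    stop("apply_floor() must be applied before computing fold changes")
  }
  ctrl <- x$values[, x$control]
  stages <- setdiff(colnames(x$values), x$control)
  fc <- log2(x$values[, stages, drop = FALSE] / ctrl)
  if (any(!is.finite(fc))) stop("non-finite fold change; check floor and input scale")
  new_fold_change_matrix(fc)
}

new_fold_change_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == 0L || !is.null(rownames(values)))
  structure(list(values = values, stages = colnames(values)),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat("Fold-change matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "stages (log2 vs control)\n")
  invisible(x)
}

#' Stage-wise regulation filter
#'
#' Keeps the transcripts showing at least a `min_fold` change (in either
#' direction, boundary inclusive) at `min_stages` or more treatment
#' stages. Row order is preserved.
#'
#' @param fc A `fold_change_matrix`.
#' @param rule A [filter_rule()].
#' @return List with `fc` (the kept-row `fold_change_matrix`) and `report`,
#'   a data frame (`transcript_id`, `qualifying_stages`, `kept`) covering
#'   every input transcript.
#' @export
regulation_filter <- function(fc, rule = filter_rule()) {
  stopifnot(inherits(fc, "fold_change_matrix"), inherits(rule, "filter_rule"))
  n_stages <- ncol(fc$values)
  if (rule$min_stages > n_stages) {
    stop("min_stages (", rule$min_stages, ") exceeds the number of stages (",
         n_stages, ")")
  }
  thr <- log2(rule$min_fold)
  qualifying <- rowSums(abs(fc$values) >= thr)
  kept <- qualifying >= rule$min_stages
  report <- data.frame(transcript_id = rownames(fc$values),
                       qualifying_stages = as.integer(qualifying),
                       kept = unname(kept),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(fc = new_fold_change_matrix(fc$values[kept, , drop = FALSE]),
       report = report)
}
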