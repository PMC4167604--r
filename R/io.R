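#' Read a transcript-by-condition expression table
#'
#' Parses a tab-separated intensity table with a header row, the transcript
#' identifier in the first column and one column of linear-scale intensities
#' per condition. Exactly one condition column must carry the control label.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param control_label Name of the control condition column.
#' @param cluster_column Optional name of a column holding cluster labels
#'   (as in deposited matrices that ship their clustering); it is detached
#'   from the intensity columns and returned in the `clusters` attribute.
#' @param log2_input Set `TRUE` when the file stores log2-scale values;
#'   they are exponentiated to the linear scale before use, since the
#'   detectability floor is defined in linear intensity units.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, transcripts x conditions), `control` (column label)
#'   and `floored` (`FALSE` on read). When `cluster_column` is supplied the
#'   parsed labels are attached as `attr(x, "clusters")`, a named character
#'   vector indexed by transcript.
#' @seealso [apply_floor()], [fold_change()], [write_expression_table()]
#' @export
read_expression_table <- function(path, control_label, cluster_column = NULL,
                                  log2_input = FALSE) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs an ID column and at least one condition column")
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate transcript ID(s): ", paste(unique(dup), collapse = ", "))
  }
  body <- raw[, -1L, drop = FALSE]
  clusters <- NULL
  if (!is.null(cluster_column)) {
    if (!cluster_column %in% colnames(body)) {
      stop("cluster column '", cluster_column, "' not present in table")
    }
    clusters <- stats::setNames(as.character(body[[cluster_column]]), ids)
    body <- body[, setdiff(colnames(body), cluster_column), drop = FALSE]
  }
  values <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                   dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) | is.na(body[[j]]))
    if (length(bad) > 0L) {
      stop("non-numeric value at row ", bad[1L], " (transcript '", ids[bad[1L]],
           "'), column '", colnames(body)[j], "'")
    }
    values[, j] <- v
  }
  if (!control_label %in% colnames(values)) {
    stop("control label '", control_label, "' not found among condition columns")
  }
  if (sum(colnames(values) == control_label) != 1L) {
    stop("control label '", control_label, "' appears more than once")
  }
  if (log2_input) values <- 2^values
  if (any(!is.finite(values))) stop("expression table contains non-finite values")
  out <- new_expression_matrix(values, control_label, floored = FALSE)
  if (!is.null(clusters)) attr(out, "clusters") <- clusters
  out
}

new_expression_matrix <- function(values, control, floored) {
  stopifnot(is.matrix(values), control %in% colnames(values))
  structure(list(values = values, control = control, floored = floored),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "conditions\n")
  cat("  control column:", x$control, "| stages:",
      paste(setdiff(colnames(x$values), x$control), collapse = ", "), "\n")
  cat("  detectability floor applied:", x$floored, "\n")
  invisible(x)
}

#' Write an expression table (round-trip counterpart of the reader)
#'
#' @param x An `expression_matrix`.
#' @param path Output path (tab-separated, header row).
#' @param clusters Optional named character vector of cluster labels to emit
#'   as an extra `cluster` column (as deposited matrices do).
#' @param id_column Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, clusters = NULL,
                                   id_column = "transcript_id") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(rownames(x$values), stringsAsFactors = FALSE)
  names(df) <- id_column
  if (!is.null(clusters)) {
    if (!all(rownames(x$values) %in% names(clusters))) {
      stop("cluster labels missing for some transcripts")
    }
    df$cluster <- unname(clusters[rownames(x$values)])
  }
  vals <- as.data.frame(x$values, check.names = FALSE)
  df <- cbind(df, vals)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))  # lossless
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One term per line: term ID, description, then one or more member gene
#' IDs, all tab-separated. Lines with fewer than three fields are skipped
#' with a warning; duplicate members within a term are collapsed.
#'
#' @param path Path to a GMT file.
#' @param namespace Free-text label for the ontology family the file holds.
#' @return An `annotation_set`: list with `namespace` and `terms`, the
#'   latter a named list of `list(description =, genes =)` in file order.
#' @export
read_gene_sets <- function(path, namespace = "geneset") {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  terms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      warning("GMT line ", i, " has fewer than 3 fields; skipped")
      next
    }
    id <- fields[[1L]]
    if (id %in% names(terms)) stop("duplicate term ID in GMT: ", id)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warning("GMT line ", i, " (term ", id, ") has no gene members; skipped")
      next
    }
    terms[[id]] <- list(description = fields[[2L]], genes = genes)
  }
  if (length(terms) == 0L) stop("GMT file contains no valid terms: ", path)
  structure(list(namespace = namespace, terms = terms),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set '", x$namespace, "': ", length(x$terms), " terms\n",
      sep = "")
  invisible(x)
}

#' Write gene sets in GMT format
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- vapply(names(ann$terms), function(id) {
    t <- ann$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write the pipeline output bundle
#'
#' Writes every artifact of a pipeline run as tab-separated text with a
#' stable row ordering, plus a JSON manifest listing each file with its
#' MD5 content hash. Rerunning on the same bundle reproduces the files
#' byte for byte.
#'
#' @param bundle Named list with components `cluster_table`,
#'   `seed_profiles`, `enrichment` (data frames) and `planes` (named list
#'   of per-stage data frames); `filter_report` (data frame) is optional.
#' @param out_dir Output directory, created if absent.
#' @return Data frame manifest (`file`, `md5`), invisibly; also written to
#'   `manifest.json` in `out_dir`.
#' @export
write_results <- function(bundle, out_dir) {
  required <- c("cluster_table", "seed_profiles", "enrichment", "planes")
  missing <- setdiff(required, names(bundle))
  if (length(missing) > 0L) {
    stop("bundle is missing artifact(s): ", paste(missing, collapse = ", "))
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  write_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  paths <- c(paths, write_tsv(bundle$cluster_table, "clusters.tsv"))
  paths <- c(paths, write_tsv(bundle$seed_profiles, "seed_profiles.tsv"))
  paths <- c(paths, write_tsv(bundle$enrichment, "enrichment.tsv"))
  for (s in names(bundle$planes)) {
    paths <- c(paths, write_tsv(bundle$planes[[s]],
                                paste0("plane_", make.names(s), ".tsv")))
  }
  if (!is.null(bundle$filter_report)) {
    paths <- c(paths, write_tsv(bundle$filter_report, "filter_report.tsv"))
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
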