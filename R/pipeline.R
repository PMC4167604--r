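#' Validate a pipeline run configuration
#'
#' A configuration is a flat named list (or a YAML file of one). Every
#' violation is collected and reported at once rather than failing on the
#' first.
#'
#' Recognized keys: `expression_path`, `control_label`, `out_dir`
#' (required); `gmt_paths` (named by namespace), `min_fold`, `min_stages`,
#' `floor`, `rings`, `train_mode` (`batch`/`sequential`), `max_clusters`,
#' `min_overlap`, `fdr`, `background` (`annotated` or `filtered`), `seed`,
#' `log2_input`, `plot` (all optional, with the package defaults).
#'
#' @param config Named list, or path to a flat YAML file.
#' @return The validated config list with defaults filled in; errors with
#'   the accumulated violation list otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML file path")
  defaults <- list(min_fold = 2, min_stages = 4L, floor = 200,
                   rings = NULL, train_mode = "batch", max_clusters = NULL,
                   min_overlap = 3L, fdr = 0.05, background = "annotated",
                   seed = 0L, log2_input = FALSE, plot = FALSE,
                   gmt_paths = list())
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  errs <- character(0)
  req <- function(key) {
    if (is.null(config[[key]])) errs <<- c(errs, paste0("missing field: ", key))
  }
  req("expression_path"); req("control_label"); req("out_dir")
  if (!is.null(config$expression_path) && !file.exists(config$expression_path)) {
    errs <- c(errs, paste0("expression_path does not exist: ",
                           config$expression_path))
  }
  for (ns in names(config$gmt_paths)) {
    if (!file.exists(config$gmt_paths[[ns]])) {
      errs <- c(errs, paste0("gmt_paths[", ns, "] does not exist: ",
                             config$gmt_paths[[ns]]))
    }
  }
  if (config$min_fold <= 1) errs <- c(errs, "min_fold must be > 1")
  if (config$min_stages < 1) errs <- c(errs, "min_stages must be >= 1")
  if (!is.null(config$expression_path) && file.exists(config$expression_path) &&
      config$min_stages >= 1) {
    hdr <- strsplit(readLines(config$expression_path, n = 1L), "\t",
                    fixed = TRUE)[[1L]]
    n_stages <- length(hdr) - 2L   # minus ID and control columns
    if (config$min_stages > n_stages) {
      errs <- c(errs, paste0("min_stages (", config$min_stages,
                             ") exceeds the number of stages (", n_stages, ")"))
    }
  }
  if (config$floor <= 0) errs <- c(errs, "floor must be > 0")
  if (!is.null(config$rings) && config$rings < 1) {
    errs <- c(errs, "rings must be >= 1")
  }
  if (!config$train_mode %in% c("batch", "sequential")) {
    errs <- c(errs, "train_mode must be 'batch' or 'sequential'")
  }
  if (config$fdr <= 0 || config$fdr > 1) errs <- c(errs, "fdr must lie in (0, 1]")
  if (config$min_overlap < 0) errs <- c(errs, "min_overlap must be >= 0")
  if (!config$background %in% c("annotated", "filtered")) {
    errs <- c(errs, "background must be 'annotated' or 'filtered'")
  }
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stated analysis sequence on an expression table:
#' detectability floor, log2 fold changes versus the control, stage-wise
#' regulation filter, supra-hexagonal SOM fit, topological partition into
#' gene clusters, component planes, per-cluster term enrichment, and a
#' deterministic output bundle. Identical configuration and seed give a
#' byte-identical bundle.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `model` (`suprasom`), `partition`,
#'   `planes`, `enrichment`, `filter` (the filter report), `fc_full`,
#'   `manifest` and `counts` (per-stage gene counts).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) message("[edisom] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  expr <- stage("read_expression", read_expression_table(
    config$expression_path, config$control_label,
    log2_input = isTRUE(config$log2_input)))
  say("read ", nrow(expr$values), " transcripts x ",
      ncol(expr$values), " conditions")
  rule <- filter_rule(config$min_fold, config$min_stages, config$floor)
  expr <- stage("apply_floor", apply_floor(expr, rule$floor))
  fc_full <- stage("fold_change", fold_change(expr))
  filt <- stage("regulation_filter", regulation_filter(fc_full, rule))
  n_kept <- sum(filt$report$kept)
  say("regulation filter kept ", n_kept, " of ", nrow(filt$report),
      " transcripts (>=", rule$min_fold, "-fold at >=", rule$min_stages,
      " stages)")
  if (n_kept == 0L) {
    stop("regulation filter kept no transcripts; relax min_fold/min_stages ",
         "or check the control label", call. = FALSE)
  }
  model <- stage("som_fit", suprasom(filt$fc, rings = config$rings,
                                     mode = config$train_mode,
                                     seed = as.integer(config$seed)))
  say("trained ", model$grid$n_units, "-unit map (", model$grid$rings,
      " rings); quantization error ",
      format(model$bmu$quantization_error, digits = 4))
  part <- stage("partition", som_partition(model,
                                           max_clusters = config$max_clusters))
  say("partitioned map into ", part$n_clusters, " clusters")
  planes <- stage("component_planes", component_planes(model))
  enr_list <- list()
  for (ns in names(config$gmt_paths)) {
    ann <- stage("read_gene_sets",
                 read_gene_sets(config$gmt_paths[[ns]], namespace = ns))
    bg <- if (config$background == "filtered") {
      rownames(filt$fc$values)
    } else NULL
    enr_list[[ns]] <- stage("enrichment", enrich_clusters(
      part, ann, background = bg,
      min_overlap = config$min_overlap, fdr = config$fdr))
  }
  enrichment <- if (length(enr_list) > 0L) {
    do.call(rbind, c(enr_list, list(make.row.names = FALSE)))
  } else {
    enrich_empty()
  }
  say("enrichment: ", sum(enrichment$reported), " reported rows (overlap >= ",
      config$min_overlap, ", FDR < ", config$fdr, ")")
  bundle <- list(
    cluster_table = cluster_table(part, model$bmu),
    seed_profiles = seed_profile_table(part),
    enrichment = enrichment,
    planes = lapply(planes$planes, identity),
    filter_report = filt$report)
  manifest <- stage("write_results", write_results(bundle, config$out_dir))
  if (isTRUE(config$plot)) {
    grDevices::png(file.path(config$out_dir, "component_planes.png"),
                   width = 1200, height = 900)
    plot(planes)
    grDevices::dev.off()
  }
  say("wrote ", nrow(manifest), " files to ", config$out_dir)
  invisible(list(model = model, partition = part, planes = planes,
                 enrichment = enrichment, filter = filt$report,
                 fc_full = fc_full, manifest = manifest,
                 counts = c(input = nrow(filt$report), kept = n_kept,
                            dropped = nrow(filt$report) - n_kept,
                            units = model$grid$n_units,
                            clusters = part$n_clusters)))
}

enrich_empty <- function() {
  data.frame(cluster = character(0), namespace = character(0),
             term_id = character(0), description = character(0),
             overlap = integer(0), cluster_size = integer(0),
             term_size = integer(0), background_size = integer(0),
             p_value = numeric(0), q_value = numeric(0),
             reported = logical(0), stringsAsFactors = FALSE)
}

#' Seed-profile table of a partition
#' @param p A `som_partition`.
#' @return Data frame `cluster`, `seed_unit`, one column per stage.
#' @export
seed_profile_table <- function(p) {
  stopifnot(inherits(p, "som_partition"))
  df <- data.frame(cluster = seq_len(p$n_clusters),
                   seed_unit = p$seed_units)
  cbind(df, as.data.frame(p$seed_profiles, check.names = FALSE,
                          row.names = NULL))
}
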