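# End-to-end orchestration: spot tables on disk -> Mg matrices ->
# normalization -> gene summaries -> per-condition contrasts ->
# liquid-vs-solid classification and reports. Each condition is processed
# as its own experiment (its arrays are normalized and fitted together);
# the two conditions meet only at the classification layer, matching the
# design in which the solid-culture arrays come from a separate study.

#' Pipeline configuration
#'
#' @param spots_dir directory holding `spots_*.tsv` tables (one per array).
#' @param probes_path probe annotation TSV.
#' @param categories_path optional gene -> category TSV.
#' @param universe_path optional one-column (header `gene_id`) TSV listing
#'   the gene universe to classify; default all genes quantified in both
#'   conditions.
#' @param out_dir output directory for all artifacts.
#' @param norm a [norm_params()].
#' @param class_par a [class_params()].
#' @param moderate enable empirical-Bayes variance moderation.
#' @param normalize `"full"` (cyclic loess + global median) or `"none"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spots_dir, probes_path, out_dir,
                            categories_path = NULL, universe_path = NULL,
                            norm = norm_params(), class_par = class_params(),
                            moderate = TRUE,
                            normalize = c("full", "none")) {
  normalize <- match.arg(normalize)
  for (p in c(spots_dir, probes_path, categories_path, universe_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(
    list(spots_dir = spots_dir, probes_path = probes_path,
         categories_path = categories_path, universe_path = universe_path,
         out_dir = out_dir, norm = norm, class_par = class_par,
         moderate = isTRUE(moderate), normalize = normalize),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads all spot tables and the annotation, then per condition: Mg
#' computation, (optionally) probe-weighted cyclic loess and global median
#' normalization, probe-to-gene summarization and the moderated MII-vs-MI
#' contrast. Genes quantified in both conditions (intersected with the
#' optional universe) are classified three ways and summarized. All
#' intermediate tables, a parameter-echoing run log and a plain-text
#' summary are written under `out_dir`. Identical configuration and inputs
#' give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `abundances` (per condition),
#'   `classification`, `summary` and `correlations`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    "strepArray pipeline run",
    paste0("spots_dir: ", config$spots_dir),
    paste0("probes: ", config$probes_path),
    paste0("categories: ", config$categories_path %||% "(none)"),
    paste0("universe: ", config$universe_path %||% "(all shared genes)"),
    paste0("normalize: ", config$normalize),
    paste0("loess window: ", config$norm$loess_window,
           ", iterations: ", config$norm$loess_iterations,
           ", degree: ", config$norm$loess_degree,
           ", robustify: ", config$norm$robustify),
    paste0("moderation: ", config$moderate),
    paste0("sig_threshold: ", config$class_par$sig_threshold,
           ", cv_threshold: ", config$class_par$cv_threshold),
    paste0("package version: ",
           as.character(utils::packageVersion("strepArray")))
  )

  annotation <- pipeline_stage("read_probe_annotation",
                               read_probe_annotation(config$probes_path))
  categories <- NULL
  if (!is.null(config$categories_path)) {
    categories <- pipeline_stage(
      "read_category_map",
      read_category_map(config$categories_path, annotation))
  }
  spot_files <- sort(list.files(config$spots_dir, pattern = "^spots_.*\\.tsv$",
                                full.names = TRUE))
  if (length(spot_files) == 0) {
    stop("pipeline stage 'read_spot_table' failed: no spots_*.tsv in ",
         config$spots_dir, call. = FALSE)
  }
  scans <- pipeline_stage("read_spot_table",
                          lapply(spot_files, read_spot_table))
  conditions <- unique(vapply(scans, function(s) s$condition, character(1)))

  abundances <- list()
  correlations <- list()
  for (cond in sort(conditions)) {
    sel <- vapply(scans, function(s) s$condition == cond, logical(1))
    m <- pipeline_stage("compute_mg", compute_mg(scans[sel], annotation))
    if (config$normalize == "full") {
      m <- pipeline_stage("cyclic_loess_normalize",
                          cyclic_loess_normalize(m, config$norm))
      m <- pipeline_stage("global_median_center", global_median_center(m))
    }
    write_mg_matrix(m, file.path(config$out_dir,
                                 paste0("mg_matrix_", cond, ".tsv")))
    g <- pipeline_stage("summarize_genes", summarize_genes(m, annotation))
    correlations[[cond]] <- pipeline_stage("replicate_correlation",
                                           replicate_correlation(g))
    ab <- pipeline_stage(
      "fit_contrast",
      fit_contrast(g, cond, moderate = config$moderate))
    write_gene_abundance(ab, file.path(config$out_dir,
                                       paste0("abundances_", cond, ".tsv")))
    abundances[[cond]] <- ab
    log_lines <- c(log_lines,
                   sprintf("condition %s: %d arrays, %d genes", cond,
                           sum(sel), nrow(ab)))
  }

  classification <- NULL
  summary <- NULL
  if (all(c("liquid", "solid") %in% names(abundances))) {
    sol <- abundances$solid
    liq <- abundances$liquid
    genes <- intersect(sol$gene_id, liq$gene_id)
    if (!is.null(config$universe_path)) {
      uni <- utils::read.delim(config$universe_path,
                               stringsAsFactors = FALSE)$gene_id
      genes <- intersect(genes, uni)
    }
    classification <- pipeline_stage(
      "classify_pair",
      classify_pair(sol$A[match(genes, sol$gene_id)],
                    liq$A[match(genes, liq$gene_id)],
                    config$class_par, gene_id = genes,
                    categories = categories))
    summary <- pipeline_stage("summarize_classes",
                              summarize_classes(classification))
    write_classification(classification, summary, config$out_dir)
    log_lines <- c(log_lines,
                   sprintf("classified %d genes: %s", summary$n_total,
                           paste(names(summary$counts), summary$counts,
                                 sep = "=", collapse = ", ")))
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(abundances = abundances, classification = classification,
                 summary = summary, correlations = correlations))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_classification <- function(classification, summary, out_dir) {
  out <- classification
  for (col in c("A_solid", "A_liquid", "cv")) out[[col]] <- fmt_num(out[[col]])
  utils::write.table(out, file.path(out_dir, "pair_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  counts <- data.frame(pair_class = names(summary$counts),
                       count = as.integer(summary$counts),
                       percent = as.integer(summary$percentages),
                       stringsAsFactors = FALSE)
  utils::write.table(counts, file.path(out_dir, "class_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(summary$by_category,
                     file.path(out_dir, "category_breakdown.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  txt <- utils::capture.output(print(summary))
  writeLines(txt, file.path(out_dir, "summary.txt"))
}
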