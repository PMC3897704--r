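# Tabular I/O for the experiment's data model: spot tables exported by
# feature-extraction software, probe annotation with validity classes, and
# gene -> functional-category maps. All files are UTF-8 TSV with "." decimals.

SPOT_COLUMNS <- c(
  "probe_id",
  "fg_mean_sample", "bg_median_sample", "bg_sd_sample",
  "fg_mean_ref", "bg_median_ref", "bg_sd_ref"
)

VALIDITY_LEVELS <- c("valid", "cross_hyb", "intergenic")

#' Weight assigned to non-valid (cross-hybridizing or intergenic) probes
#'
#' Valid probes carry weight 1; probes flagged as cross-hybridizing or
#' intergenic carry this near-zero weight so they are evaluated by, but have
#' negligible influence on, normalization curves and gene averages.
#' @export
NONVALID_WEIGHT <- 1e-6

CATEGORY_LEVELS <- c(
  "primary_metabolism", "secondary_metabolism", "differentiation",
  "regulatory", "transposons_is", "conjugation_recombination_mutagenesis",
  "stress_defense", "catabolism_degradation", "lipid_metabolism",
  "transporters_secreted", "unknown"
)

# Case-insensitive label normalization: spaces, hyphens and slashes become
# underscores, runs collapse, stray repeated letters in printed headings
# (e.g. "STRESSS") are tolerated via explicit aliases.
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ /–-]+", "_", x)
  x <- gsub("_+", "_", x)
  gsub("^_|_$", "", x)
}

CATEGORY_ALIASES <- c(
  trasposons_is = "transposons_is",
  transposons_insertion_sequences = "transposons_is",
  stresss_defense = "stress_defense",
  stress_and_defense = "stress_defense",
  conjugation_recombination = "conjugation_recombination_mutagenesis",
  transporters_and_secreted = "transporters_secreted",
  differentia_tion = "differentiation"
)

normalize_category <- function(x) {
  norm <- normalize_label(x)
  alias <- CATEGORY_ALIASES[norm]
  norm <- ifelse(is.na(alias), norm, alias)
  bad <- setdiff(unique(norm), CATEGORY_LEVELS)
  if (length(bad) > 0) {
    stop("unknown functional category: ", paste(bad, collapse = ", "))
  }
  norm
}

new_array_scan <- function(array_id, condition, stage, replicate, spots) {
  structure(
    list(
      array_id = as.character(array_id),
      condition = match.arg(condition, c("liquid", "solid")),
      stage = match.arg(stage, c("MI", "MII")),
      replicate = as.integer(replicate),
      spots = spots
    ),
    class = "array_scan"
  )
}

validate_spots <- function(spots, array_id = "?") {
  missing <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing) > 0) {
    stop("spot table for array '", array_id, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  spots <- spots[SPOT_COLUMNS]
  if (anyDuplicated(spots$probe_id)) {
    stop("duplicate probe_id in spot table for array '", array_id, "'")
  }
  intensity_cols <- setdiff(SPOT_COLUMNS, "probe_id")
  for (col in intensity_cols) {
    v <- spots[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", col, "' must be numeric without missing values")
    }
    if (any(v < 0)) {
      stop("negative intensity in column '", col, "' for probe(s): ",
           paste(utils::head(spots$probe_id[v < 0], 5), collapse = ", "))
    }
  }
  for (col in c("bg_sd_sample", "bg_sd_ref")) {
    v <- spots[[col]]
    if (any(v <= 0)) {
      stop("non-positive background SD in column '", col,
           "' for probe(s): ",
           paste(utils::head(spots$probe_id[v <= 0], 5), collapse = ", "))
    }
  }
  spots
}

#' Construct an array scan
#'
#' Bundles one hybridized array's spot records with its design metadata.
#' `spots` must hold the columns `probe_id`, `fg_mean_sample`,
#' `bg_median_sample`, `bg_sd_sample`, `fg_mean_ref`, `bg_median_ref`,
#' `bg_sd_ref`: per-spot foreground means and background summary statistics
#' for the Cy3-cDNA sample channel and the Cy5-gDNA reference channel.
#'
#' @param array_id unique array identifier.
#' @param condition culture condition, `"liquid"` or `"solid"`.
#' @param stage developmental stage, `"MI"` or `"MII"`.
#' @param replicate biological replicate index (1-based).
#' @param spots data frame of spot records, one row per probe.
#' @return an object of class `array_scan`.
#' @export
array_scan <- function(array_id, condition, stage, replicate, spots) {
  spots <- validate_spots(as.data.frame(spots), array_id)
  new_array_scan(array_id, condition, stage, replicate, spots)
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan '%s': %s %s replicate %d, %d spots\n",
              x$array_id, x$condition, x$stage, x$replicate,
              nrow(x$spots)))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a spot table to TSV
#'
#' Serializes an [array_scan()] as a tab-separated table with `#`-prefixed
#' metadata header lines (`array_id`, `condition`, `stage`, `replicate`).
#' Intensities are written with 17 significant digits so that a write/read
#' round trip reproduces every double bit-exactly.
#'
#' @param scan an `array_scan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# array_id: ", scan$array_id),
    paste0("# condition: ", scan$condition),
    paste0("# stage: ", scan$stage),
    paste0("# replicate: ", scan$replicate)
  ), con)
  out <- scan$spots
  for (col in setdiff(SPOT_COLUMNS, "probe_id")) out[[col]] <- fmt_num(out[[col]])
  writeLines(paste(SPOT_COLUMNS, collapse = "\t"), con)
  writeLines(do.call(paste, c(out[SPOT_COLUMNS], sep = "\t")), con)
  invisible(path)
}

parse_meta_line <- function(lines, key, path) {
  pat <- paste0("^#\\s*", key, ":\\s*")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) != 1) {
    stop("spot table '", path, "' must carry exactly one '# ", key,
         ":' header line")
  }
  trimws(sub(pat, "", hit))
}

#' Read a spot table from TSV
#'
#' Inverse of [write_spot_table()]. Fails with an informative error when a
#' required column is missing or an intensity is negative.
#'
#' @param path path to a spot table written in this package's dialect.
#' @return an `array_scan`.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grepl("^#", lines)
  header <- lines[meta]
  spots <- utils::read.delim(
    text = paste(lines[!meta], collapse = "\n"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  spots$probe_id <- as.character(spots$probe_id)
  array_scan(
    array_id = parse_meta_line(header, "array_id", path),
    condition = parse_meta_line(header, "condition", path),
    stage = parse_meta_line(header, "stage", path),
    replicate = as.integer(parse_meta_line(header, "replicate", path)),
    spots = spots
  )
}

#' Read a probe annotation table
#'
#' Expects a TSV with columns `probe_id`, `gene_id` and `validity`
#' (`valid`, `cross_hyb` or `intergenic`, matched case-insensitively with
#' spaces/hyphens normalized). Probe weights are derived from validity:
#' 1 for valid probes and `NONVALID_WEIGHT` (1e-6) otherwise. Intergenic
#' probes must carry an empty `gene_id`.
#'
#' @param path path to the annotation TSV.
#' @return data frame with columns `probe_id`, `gene_id`, `validity`,
#'   `weight`, of class `probe_annotation`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("probe annotation not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("probe_id", "validity")) {
    if (!col %in% names(tab)) {
      stop("probe annotation is missing column '", col, "'")
    }
  }
  if (!"gene_id" %in% names(tab)) tab$gene_id <- ""
  tab$gene_id[is.na(tab$gene_id)] <- ""
  probe_annotation(tab$probe_id, tab$gene_id, tab$validity)
}

#' Construct a probe annotation table
#'
#' @param probe_id,gene_id,validity parallel vectors; `gene_id` must be empty
#'   for intergenic probes.
#' @return data frame of class `probe_annotation` with derived `weight`.
#' @export
probe_annotation <- function(probe_id, gene_id, validity) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  validity <- normalize_label(validity)
  if (anyDuplicated(probe_id)) {
    stop("duplicate probe_id in probe annotation: ",
         paste(utils::head(unique(probe_id[duplicated(probe_id)]), 5),
               collapse = ", "))
  }
  bad <- setdiff(unique(validity), VALIDITY_LEVELS)
  if (length(bad) > 0) {
    stop("unknown probe validity class: ", paste(bad, collapse = ", "))
  }
  inter_with_gene <- validity == "intergenic" & nzchar(gene_id)
  if (any(inter_with_gene)) {
    warning(sum(inter_with_gene),
            " intergenic probe(s) carried a gene_id; blanked")
    gene_id[inter_with_gene] <- ""
  }
  structure(
    data.frame(
      probe_id = probe_id,
      gene_id = gene_id,
      validity = validity,
      weight = ifelse(validity == "valid", 1, NONVALID_WEIGHT),
      stringsAsFactors = FALSE
    ),
    class = c("probe_annotation", "data.frame")
  )
}

#' Write a probe annotation table to TSV
#' @param annotation a `probe_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(
    annotation[c("probe_id", "gene_id", "validity")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a gene-to-functional-category map
#'
#' Expects a TSV with columns `gene_id` and `category`. Category labels are
#' matched case-insensitively with spaces, hyphens and slashes normalized to
#' underscores (so the upper-case row-group labels of published tables are
#' accepted). Unknown categories are rejected; each gene must map to exactly
#' one category. Genes absent from `annotation` (when supplied) trigger a
#' warning but are kept.
#'
#' @param path path to the category TSV.
#' @param annotation optional `probe_annotation` used to warn about genes
#'   not present on the array.
#' @return named character vector, gene_id -> category.
#' @export
read_category_map <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("category map not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("gene_id", "category")) {
    if (!col %in% names(tab)) {
      stop("category map is missing column '", col, "'")
    }
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("gene(s) mapped to more than one category: ",
         paste(utils::head(unique(tab$gene_id[duplicated(tab$gene_id)]), 5),
               collapse = ", "))
  }
  cats <- normalize_category(tab$category)
  if (!is.null(annotation)) {
    absent <- setdiff(tab$gene_id, annotation$gene_id)
    if (length(absent) > 0) {
      warning(length(absent),
              " gene(s) in the category map are absent from the probe ",
              "annotation (kept)")
    }
  }
  stats::setNames(cats, tab$gene_id)
}
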