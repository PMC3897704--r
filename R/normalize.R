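# Spot records -> normalized per-probe Mg values. The gDNA common-reference
# design makes every probe's reference signal near-constant across arrays, so
# Mg = log2(net_cDNA / net_gDNA) values are directly comparable between
# arrays once the intensity-dependent dye bias is removed.

#' Normalization parameters
#'
#' @param loess_window span of each local loess fit, as the fraction of
#'   probes entering the fit (default 0.3).
#' @param loess_iterations number of full cyclic passes over all array pairs
#'   (default 3).
#' @param loess_degree degree of the local polynomial (default 1, local
#'   linear).
#' @param robustify use iteratively reweighted (`family = "symmetric"`)
#'   loess fits instead of plain least squares. Default `FALSE`.
#' @param grid_points number of anchor points on the A-grid at which each
#'   fitted trend is evaluated before linear interpolation to all probes
#'   (default 200).
#' @return a list of class `norm_params`.
#' @export
norm_params <- function(loess_window = 0.3, loess_iterations = 3,
                        loess_degree = 1, robustify = FALSE,
                        grid_points = 200) {
  if (!is.numeric(loess_window) || loess_window <= 0 || loess_window > 1) {
    stop("loess_window must be in (0, 1]")
  }
  if (loess_iterations < 1) stop("loess_iterations must be >= 1")
  if (!loess_degree %in% c(0, 1, 2)) stop("loess_degree must be 0, 1 or 2")
  if (grid_points < 10) stop("grid_points must be >= 10")
  structure(
    list(
      loess_window = loess_window,
      loess_iterations = as.integer(loess_iterations),
      loess_degree = as.integer(loess_degree),
      robustify = isTRUE(robustify),
      grid_points = as.integer(grid_points)
    ),
    class = "norm_params"
  )
}

#' Net spot intensity with the background-SD surrogate rule
#'
#' The net intensity is the foreground mean minus the background median.
#' When that difference is negative or smaller than the standard deviation
#' of the background pixels, the background SD itself is used as the
#' surrogate intensity, so the result is always positive and every log-ratio
#' downstream is finite.
#'
#' @param fg_mean foreground mean intensity (vectorized).
#' @param bg_median background median intensity.
#' @param bg_sd background pixel standard deviation; must be positive.
#' @return positive net intensities, same length as the inputs.
#' @examples
#' net_intensity(500, 100, 20) # 400
#' net_intensity(90, 100, 20)  # 20: negative net, surrogate applies
#' net_intensity(110, 100, 20) # 20: net below background SD, surrogate
#' @export
net_intensity <- function(fg_mean, bg_median, bg_sd) {
  if (any(!is.finite(bg_sd)) || any(bg_sd <= 0)) {
    stop("bg_sd must be positive and finite")
  }
  net <- fg_mean - bg_median
  ifelse(net < bg_sd, bg_sd, net)
}

new_mg_matrix <- function(M, weights, meta) {
  stopifnot(nrow(M) == length(weights), ncol(M) == nrow(meta))
  colnames(M) <- meta$array_id
  structure(
    list(M = M, weights = weights, probe_ids = rownames(M),
         array_ids = meta$array_id, meta = meta),
    class = "mg_matrix"
  )
}

#' @export
print.mg_matrix <- function(x, ...) {
  cat(sprintf("mg_matrix: %d probes x %d arrays (%d valid-weight probes)\n",
              nrow(x$M), ncol(x$M), sum(x$weights == 1)))
  invisible(x)
}

#' Compute the Mg matrix from array scans
#'
#' For every probe and array, Mg is the log2 ratio of the sample-channel
#' (Cy3-cDNA) net intensity to the reference-channel (Cy5-gDNA) net
#' intensity, with net intensities from [net_intensity()]. Probe weights are
#' copied from the annotation. Probe order follows the annotation; array
#' order follows `scans`.
#'
#' @param scans list of [array_scan()] objects covering identical probe sets.
#' @param annotation a `probe_annotation`; every scanned probe must be
#'   annotated and vice versa.
#' @return an object of class `mg_matrix` with elements `M` (probes x
#'   arrays), `weights`, `probe_ids`, `array_ids` and `meta` (array design
#'   metadata).
#' @export
compute_mg <- function(scans, annotation) {
  stopifnot(inherits(annotation, "probe_annotation"))
  if (inherits(scans, "array_scan")) scans <- list(scans)
  if (length(scans) < 1) stop("no array scans supplied")
  ids <- vapply(scans, function(s) s$array_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate array_id across scans")
  key <- vapply(scans, function(s)
    paste(s$condition, s$stage, s$replicate), character(1))
  if (anyDuplicated(key)) {
    stop("(condition, stage, replicate) must be unique across scans")
  }
  M <- matrix(NA_real_, nrow = nrow(annotation), ncol = length(scans),
              dimnames = list(annotation$probe_id, ids))
  for (j in seq_along(scans)) {
    spots <- scans[[j]]$spots
    extra <- setdiff(spots$probe_id, annotation$probe_id)
    if (length(extra) > 0) {
      stop("array '", ids[j], "' contains probe(s) absent from the ",
           "annotation: ", paste(utils::head(extra, 5), collapse = ", "))
    }
    idx <- match(annotation$probe_id, spots$probe_id)
    if (anyNA(idx)) {
      stop("array '", ids[j], "' does not cover annotated probe(s): ",
           paste(utils::head(annotation$probe_id[is.na(idx)], 5),
                 collapse = ", "))
    }
    spots <- spots[idx, ]
    net_s <- net_intensity(spots$fg_mean_sample, spots$bg_median_sample,
                           spots$bg_sd_sample)
    net_r <- net_intensity(spots$fg_mean_ref, spots$bg_median_ref,
                           spots$bg_sd_ref)
    M[, j] <- log2(net_s / net_r)
  }
  meta <- data.frame(
    array_id = ids,
    condition = vapply(scans, function(s) s$condition, character(1)),
    stage = vapply(scans, function(s) s$stage, character(1)),
    replicate = vapply(scans, function(s) s$replicate, integer(1)),
    stringsAsFactors = FALSE
  )
  new_mg_matrix(M, annotation$weight, meta)
}

# Weighted loess trend of d against a, evaluated at every point of a via a
# regular anchor grid and linear interpolation. Low-weight probes have
# negligible influence on the fit but still receive a fitted value.
fit_pair_trend <- function(a, d, w, params) {
  n <- length(a)
  if (params$loess_window * n < params$loess_degree + 2) {
    stop("loess_window too small: local fits would have fewer than ",
         params$loess_degree + 2, " points")
  }
  # surface = "direct" evaluates the local regression exactly; the default
  # kd-tree interpolation can leak extreme low-weight values into fitted
  # values at nearby high-weight probes
  fit <- stats::loess(
    d ~ a, weights = w, span = params$loess_window,
    degree = params$loess_degree,
    family = if (params$robustify) "symmetric" else "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  grid <- seq(min(a), max(a), length.out = params$grid_points)
  dg <- stats::predict(fit, newdata = data.frame(a = grid))
  stats::approx(grid, dg, xout = a, rule = 2)$y
}

#' Probe-weighted cyclic loess normalization across arrays
#'
#' For each of `loess_iterations` passes and each unordered pair of arrays
#' (taken in column order), a weighted loess curve of the difference
#' D = Mg_j - Mg_k against the average A = (Mg_j + Mg_k)/2 is fitted using
#' the probe weights, evaluated at every probe, and the correction is split
#' symmetrically: Mg_j gets -d/2 and Mg_k gets +d/2. This removes smooth
#' intensity-dependent (dye/array) biases while conserving each probe's
#' grand mean across arrays exactly.
#'
#' @param m an `mg_matrix` with at least 2 arrays.
#' @param params a [norm_params()] object.
#' @return the adjusted `mg_matrix`; dimensions and weights unchanged.
#' @export
cyclic_loess_normalize <- function(m, params = norm_params()) {
  stopifnot(inherits(m, "mg_matrix"), inherits(params, "norm_params"))
  n_arr <- ncol(m$M)
  if (n_arr < 2) stop("cyclic loess needs at least 2 arrays")
  X <- m$M
  for (it in seq_len(params$loess_iterations)) {
    for (j in seq_len(n_arr - 1)) {
      for (k in seq((j + 1), n_arr)) {
        a <- (X[, j] + X[, k]) / 2
        d <- X[, j] - X[, k]
        dhat <- fit_pair_trend(a, d, m$weights, params)
        X[, j] <- X[, j] - dhat / 2
        X[, k] <- X[, k] + dhat / 2
      }
    }
  }
  m$M <- X
  m
}

#' Weighted median
#'
#' Deterministic weighted median: the smallest value at which the cumulative
#' weight reaches half of the total weight. No interpolation is performed, so
#' the result is always one of the input values.
#'
#' @param x numeric vector.
#' @param w non-negative weights, same length as `x`.
#' @return the weighted median of `x`.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Global median centering of an Mg matrix
#'
#' Subtracts from each array its probe-weight weighted median, so non-valid
#' probes (weight 1e-6) have essentially no influence on the centering
#' offset. After centering, every array's weighted median is 0.
#'
#' @param m an `mg_matrix`.
#' @return the centered `mg_matrix`.
#' @export
global_median_center <- function(m) {
  stopifnot(inherits(m, "mg_matrix"))
  for (j in seq_len(ncol(m$M))) {
    m$M[, j] <- m$M[, j] - weighted_median(m$M[, j], m$weights)
  }
  m
}

#' Measure the residual MA-trend between arrays
#'
#' Diagnostic used to verify bias removal: for each array pair, a weighted
#' loess trend of D = Mg_j - Mg_k against A is refitted and its amplitude
#' reported as (max - min)/2 of the fitted curve, which is insensitive to a
#' constant offset between arrays.
#'
#' @param m an `mg_matrix`.
#' @param params a [norm_params()] object (the fit uses its span/degree).
#' @return data frame with columns `array_1`, `array_2`, `amplitude`.
#' @export
ma_trend_amplitude <- function(m, params = norm_params()) {
  stopifnot(inherits(m, "mg_matrix"))
  n_arr <- ncol(m$M)
  out <- list()
  for (j in seq_len(n_arr - 1)) {
    for (k in seq((j + 1), n_arr)) {
      a <- (m$M[, j] + m$M[, k]) / 2
      d <- m$M[, j] - m$M[, k]
      dhat <- fit_pair_trend(a, d, m$weights, params)
      out[[length(out) + 1]] <- data.frame(
        array_1 = m$array_ids[j], array_2 = m$array_ids[k],
        amplitude = (max(dhat) - min(dhat)) / 2,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write / read an Mg matrix as TSV
#'
#' Probes are rows and arrays are columns; probe weights and array design
#' metadata are carried in `#`-prefixed header lines. Values are serialized
#' with full precision.
#'
#' @param m an `mg_matrix`.
#' @param path file path.
#' @return `path` (writer) or an `mg_matrix` (reader).
#' @export
write_mg_matrix <- function(m, path) {
  stopifnot(inherits(m, "mg_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- m$meta
  writeLines(c(
    paste0("# arrays: ", paste(meta$array_id, collapse = ",")),
    paste0("# conditions: ", paste(meta$condition, collapse = ",")),
    paste0("# stages: ", paste(meta$stage, collapse = ",")),
    paste0("# replicates: ", paste(meta$replicate, collapse = ","))
  ), con)
  writeLines(paste(c("probe_id", "weight", meta$array_id), collapse = "\t"),
             con)
  body <- cbind(fmt_num(m$weights),
                matrix(fmt_num(m$M), nrow = nrow(m$M)))
  writeLines(paste(m$probe_ids,
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_mg_matrix
#' @export
read_mg_matrix <- function(path) {
  if (!file.exists(path)) stop("Mg matrix not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[grepl("^#", lines)]
  split_meta <- function(key)
    strsplit(parse_meta_line(hdr, key, path), ",")[[1]]
  meta <- data.frame(
    array_id = split_meta("arrays"),
    condition = split_meta("conditions"),
    stage = split_meta("stages"),
    replicate = as.integer(split_meta("replicates")),
    stringsAsFactors = FALSE
  )
  tab <- utils::read.delim(text = paste(lines[!grepl("^#", lines)],
                                        collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(tab[, meta$array_id, drop = FALSE])
  rownames(M) <- tab$probe_id
  new_mg_matrix(M, tab$weight, meta)
}
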