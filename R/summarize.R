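# Probe -> gene summarization and per-condition log2(MII/MI) abundance
# estimation with empirical-Bayes variance moderation and FDR control.

#' Collapse probes to genes by probe-weighted averaging
#'
#' Each gene's value per array is the weight-weighted mean of its probes' Mg
#' values, so cross-hybridizing probes (weight 1e-6) are numerically
#' negligible next to valid probes. A gene is reported iff it has at least
#' one valid probe; genes carried only by non-valid probes are excluded with
#' a message. Intergenic probes (empty gene_id) never enter.
#'
#' @param m an `mg_matrix` from [compute_mg()].
#' @param annotation the `probe_annotation` used to build `m`.
#' @return an object of class `gene_mg` with elements `M` (genes x arrays),
#'   `n_valid_probes`, `gene_ids` and the array `meta`.
#' @export
summarize_genes <- function(m, annotation) {
  stopifnot(inherits(m, "mg_matrix"), inherits(annotation, "probe_annotation"))
  idx <- match(m$probe_ids, annotation$probe_id)
  if (anyNA(idx)) stop("Mg matrix contains probes absent from the annotation")
  ann <- annotation[idx, ]
  keep <- nzchar(ann$gene_id)
  ann <- ann[keep, ]
  X <- m$M[keep, , drop = FALSE]
  w <- ann$weight
  genes <- unique(ann$gene_id)
  n_valid <- vapply(split(ann$validity == "valid", ann$gene_id)[genes],
                    sum, integer(1))
  excluded <- genes[n_valid == 0]
  if (length(excluded) > 0) {
    message(length(excluded),
            " gene(s) without any valid probe excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "))
    genes <- genes[n_valid > 0]
    n_valid <- n_valid[n_valid > 0]
  }
  wx <- X * w
  gsum <- rowsum(wx, ann$gene_id)[genes, , drop = FALSE]
  gw <- rowsum(w, ann$gene_id)[genes, ]
  G <- gsum / gw
  structure(
    list(M = G, n_valid_probes = stats::setNames(n_valid, genes),
         gene_ids = genes, meta = m$meta),
    class = "gene_mg"
  )
}

#' @export
print.gene_mg <- function(x, ...) {
  cat(sprintf("gene_mg: %d genes x %d arrays\n", nrow(x$M), ncol(x$M)))
  invisible(x)
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)), with asymptotic starting values for extreme arguments.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50) {
  if (!is.finite(y) || y <= 0) stop("trigamma_inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits a scaled inverse chi-square prior to the per-gene residual variances
#' `s_sq` (each on `d` residual degrees of freedom) by moment-matching on
#' the log scale: with e = log(s_sq) - digamma(d/2) + log(d/2), the prior
#' degrees of freedom d0 solve trigamma(d0/2) = var(e) - trigamma(d/2)
#' (d0 = +Inf when the right-hand side is <= 0, i.e. the observed spread is
#' no larger than expected under a common variance), and the prior variance
#' s0_sq comes from the mean of e. Posterior variances are
#' (d0 s0_sq + d s_sq) / (d0 + d).
#'
#' @param s_sq per-gene residual variances.
#' @param d residual degrees of freedom shared by all genes.
#' @return list with `d0`, `s0_sq` and the posterior `s_tilde_sq` vector.
#' @export
moderate_variances <- function(s_sq, d) {
  if (d <= 0) stop("residual degrees of freedom must be positive")
  e <- log(s_sq) - digamma(d / 2) + log(d / 2)
  ok <- is.finite(e)
  if (sum(ok) < 2) {
    # Degenerate: (almost) all variances are zero or identical; fall back to
    # the common-variance limit.
    s0_sq <- if (any(ok)) exp(mean(e[ok])) else mean(s_sq)
    return(list(d0 = Inf, s0_sq = s0_sq, s_tilde_sq = rep(s0_sq, length(s_sq))))
  }
  emean <- mean(e[ok])
  evar <- stats::var(e[ok])
  rhs <- evar - trigamma(d / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(emean)
    s_tilde <- rep(s0_sq, length(s_sq))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s_tilde <- (d0 * s0_sq + d * s_sq) / (d0 + d)
  }
  list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde)
}

#' Per-condition gene-level log2(MII/MI) abundances
#'
#' For one culture condition, fits the two-group (stage) least-squares model
#' per gene over that condition's arrays: the abundance A is the difference
#' of stage means (MII - MI), the residual variance is pooled over both
#' stages with d = n_MI + n_MII - 2 degrees of freedom, and the moderated
#' statistic divides A by the posterior standard deviation from
#' [moderate_variances()] times sqrt(1/n_MI + 1/n_MII). Two-sided p-values
#' use a t distribution on d0 + d degrees of freedom, and are
#' Benjamini-Hochberg adjusted with [bh_fdr()].
#'
#' @param g a `gene_mg` from [summarize_genes()].
#' @param condition `"liquid"` or `"solid"`.
#' @param moderate if `FALSE`, variance moderation is disabled (d0 forced to
#'   0) and the statistic reduces to the classical pooled two-sample t.
#' @return data frame of class `gene_abundance` with columns `gene_id`,
#'   `condition`, `A`, `t_mod`, `p_raw`, `p_fdr`, `mean_MI`, `mean_MII`,
#'   `n_valid_probes`; the moderation fit is attached as attribute
#'   `"moderation"`.
#' @export
fit_contrast <- function(g, condition = c("liquid", "solid"),
                         moderate = TRUE) {
  stopifnot(inherits(g, "gene_mg"))
  condition <- match.arg(condition)
  sel <- g$meta$condition == condition
  if (!any(sel)) stop("no arrays for condition '", condition, "'")
  X <- g$M[, sel, drop = FALSE]
  stage <- g$meta$stage[sel]
  n1 <- sum(stage == "MI")
  n2 <- sum(stage == "MII")
  if (n1 < 2 || n2 < 2) {
    stop("fit_contrast needs >= 2 replicates per stage in condition '",
         condition, "' (got MI: ", n1, ", MII: ", n2, ")")
  }
  X1 <- X[, stage == "MI", drop = FALSE]
  X2 <- X[, stage == "MII", drop = FALSE]
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  A <- m2 - m1
  d <- n1 + n2 - 2
  ss <- rowSums((X1 - m1)^2) + rowSums((X2 - m2)^2)
  s_sq <- ss / d
  if (moderate) {
    fit <- moderate_variances(s_sq, d)
  } else {
    fit <- list(d0 = 0, s0_sq = NA_real_, s_tilde_sq = s_sq)
  }
  se <- sqrt(fit$s_tilde_sq * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, A / se, ifelse(A == 0, 0, sign(A) * Inf))
  df_total <- fit$d0 + d
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    gene_id = g$gene_ids,
    condition = condition,
    A = A,
    t_mod = t_mod,
    p_raw = p_raw,
    p_fdr = bh_fdr(p_raw),
    mean_MI = m1,
    mean_MII = m2,
    n_valid_probes = as.integer(g$n_valid_probes),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "moderation") <- c(fit[c("d0", "s0_sq")],
                               list(d = d, n_MI = n1, n_MII = n2))
  class(out) <- c("gene_abundance", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in input order, capped at 1. Wraps
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param p_raw vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_raw) {
  if (any(!is.na(p_raw) & (p_raw < 0 | p_raw > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Pairwise replicate correlations of gene-level Mg values
#'
#' Pearson correlation between every pair of arrays over the gene-level Mg
#' vectors, labeled with the arrays' design metadata. Array pairs where one
#' vector has zero variance yield `NA` with a warning.
#'
#' @param g a `gene_mg`.
#' @return data frame with columns `array_1`, `array_2`, `condition_1`,
#'   `stage_1`, `condition_2`, `stage_2`, `within_stage`, `r`.
#' @export
replicate_correlation <- function(g) {
  stopifnot(inherits(g, "gene_mg"))
  n_arr <- ncol(g$M)
  if (n_arr < 2) stop("replicate_correlation needs >= 2 arrays")
  sds <- apply(g$M, 2, stats::sd)
  out <- list()
  for (j in seq_len(n_arr - 1)) {
    for (k in seq((j + 1), n_arr)) {
      if (sds[j] == 0 || sds[k] == 0) {
        warning("zero-variance array in pair (", g$meta$array_id[j], ", ",
                g$meta$array_id[k], "); correlation undefined")
        r <- NA_real_
      } else {
        r <- stats::cor(g$M[, j], g$M[, k])
      }
      out[[length(out) + 1]] <- data.frame(
        array_1 = g$meta$array_id[j], array_2 = g$meta$array_id[k],
        condition_1 = g$meta$condition[j], stage_1 = g$meta$stage[j],
        condition_2 = g$meta$condition[k], stage_2 = g$meta$stage[k],
        within_stage = g$meta$condition[j] == g$meta$condition[k] &&
          g$meta$stage[j] == g$meta$stage[k],
        r = r, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write / read a gene abundance table as TSV
#' @param abundance a `gene_abundance` data frame.
#' @param path file path.
#' @return `path` (writer) or a `gene_abundance` (reader).
#' @export
write_gene_abundance <- function(abundance, path) {
  out <- abundance
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gene_abundance
#' @export
read_gene_abundance <- function(path) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("gene_abundance", "data.frame")
  out
}
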