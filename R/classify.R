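# Comparison layer: significance gating of log2(MII/MI) abundances, the
# coefficient-of-variation criterion for liquid-vs-solid differences, the
# three-way class assignment, fold-change reporting, transcript-protein
# concordance, and per-category summaries.

PAIR_CLASSES <- c("similar", "different_same_direction", "opposite")
CONCORDANCE_CLASSES <- c("both_significant_same_direction",
                         "no_variation_both", "divergent")

#' Classification parameters
#'
#' @param sig_threshold absolute log2(MII/MI) abundance at or above which a
#'   gene counts as up/down-regulated (default 1, i.e. two-fold). The
#'   boundary is inclusive.
#' @param cv_threshold coefficient-of-variation threshold above which the
#'   liquid and solid abundances of a gene are considered different
#'   (default 0.7).
#' @return list of class `class_params`.
#' @export
class_params <- function(sig_threshold = 1, cv_threshold = 0.7) {
  if (sig_threshold <= 0 || cv_threshold <= 0) {
    stop("sig_threshold and cv_threshold must be positive")
  }
  structure(list(sig_threshold = sig_threshold, cv_threshold = cv_threshold),
            class = "class_params")
}

#' Significance flag for a log2(MII/MI) abundance
#'
#' `up` if A >= sig_threshold, `down` if A <= -sig_threshold, otherwise
#' `no_variation`. The boundary is inclusive: a printed abundance of exactly
#' 1.0 counts as significant, matching the published tables' practice.
#'
#' @param A log2(MII/MI) abundances (vectorized).
#' @param params a [class_params()].
#' @return character vector in `{"up", "down", "no_variation"}`.
#' @export
significance_flag <- function(A, params = class_params()) {
  if (any(!is.finite(A))) stop("abundances must be finite")
  ifelse(A >= params$sig_threshold, "up",
         ifelse(A <= -params$sig_threshold, "down", "no_variation"))
}

#' Coefficient of variation of a (solid, liquid) abundance pair
#'
#' Sample (n-1 denominator) standard deviation of the two values divided by
#' the absolute mean: cv = sqrt(2) |a - b| / |a + b|. Returns 0 when a = b
#' and +Inf when a + b = 0 with a != b. The statistic is symmetric and
#' scale-invariant, and any strictly opposite-signed pair has
#' cv > sqrt(2) regardless of magnitudes.
#'
#' @param a,b log2 abundances (vectorized).
#' @return non-negative values, possibly `Inf`.
#' @export
cv_statistic <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("abundances must be finite")
  }
  ifelse(a == b, 0,
         ifelse(a + b == 0, Inf, sqrt(2) * abs(a - b) / abs(a + b)))
}

#' Three-way classification of (solid, liquid) abundance pairs
#'
#' A pair is `similar` when its coefficient of variation is at most
#' `cv_threshold`; otherwise it is `opposite` when the two abundances have
#' strictly opposite signs and `different_same_direction` when they do not.
#' A value of exactly 0 is sign-neutral: it can never make a pair
#' `opposite`. Per-condition significance flags are attached.
#'
#' @param A_solid,A_liquid per-gene log2(MII/MI) abundances (vectorized).
#' @param params a [class_params()].
#' @param gene_id optional gene identifiers.
#' @param categories optional named vector gene_id -> functional category
#'   (see [read_category_map()]); unmapped genes get `"unknown"`.
#' @return data frame of class `pair_classification` with columns
#'   `gene_id`, `A_solid`, `A_liquid`, `cv`, `sig_solid`, `sig_liquid`,
#'   `pair_class`, `category`.
#' @export
classify_pair <- function(A_solid, A_liquid, params = class_params(),
                          gene_id = NULL, categories = NULL) {
  stopifnot(length(A_solid) == length(A_liquid))
  cv <- cv_statistic(A_solid, A_liquid)
  opp <- (A_solid > 0 & A_liquid < 0) | (A_solid < 0 & A_liquid > 0)
  pair_class <- ifelse(cv <= params$cv_threshold, "similar",
                       ifelse(opp, "opposite", "different_same_direction"))
  if (is.null(gene_id)) gene_id <- sprintf("gene%04d", seq_along(A_solid))
  category <- rep("unknown", length(A_solid))
  if (!is.null(categories)) {
    hit <- categories[gene_id]
    category <- ifelse(is.na(hit), "unknown", hit)
  }
  structure(
    data.frame(
      gene_id = gene_id,
      A_solid = A_solid,
      A_liquid = A_liquid,
      cv = cv,
      sig_solid = significance_flag(A_solid, params),
      sig_liquid = significance_flag(A_liquid, params),
      pair_class = pair_class,
      category = category,
      stringsAsFactors = FALSE,
      row.names = NULL
    ),
    class = c("pair_classification", "data.frame")
  )
}

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Linear fold change from a log2 abundance
#'
#' The exact value is 2^A. The reported value follows the conventional
#' rounding of fold statements: nearest integer when the exact fold is at
#' least 10, one decimal below 10, rounding half away from zero.
#'
#' @param A log2 abundances (vectorized).
#' @return data frame with columns `A`, `exact`, `reported`.
#' @examples
#' fold_change(7.9)  # exact 238.86, reported 239
#' fold_change(4)    # exact 16, reported 16
#' @export
fold_change <- function(A) {
  if (any(!is.finite(A))) stop("abundances must be finite")
  exact <- 2^A
  reported <- ifelse(exact >= 10, round_half_away(exact, 0),
                     round_half_away(exact, 1))
  data.frame(A = A, exact = exact, reported = reported)
}

#' Transcript-vs-other-platform concordance classification
#'
#' Classifies genes measured on two platforms (e.g. transcript and protein
#' log2(MII/MI) abundances) over the intersection of their gene sets:
#' `no_variation_both` when both values lie inside the open
#' (-threshold, threshold) interval (regardless of sign);
#' `both_significant_same_direction` when both values pass the significance
#' threshold with the same strict sign; `divergent` when the two values have
#' strictly opposite signs and at least one is outside the interval. Mixed
#' same-direction pairs where only one platform passes the threshold fall
#' into `no_variation_both` and are counted separately in the report.
#'
#' @param transcript,other named numeric vectors of log2(MII/MI) abundances,
#'   names are gene ids.
#' @param params a [class_params()].
#' @return list with `records` (per-gene data frame), `counts` (named class
#'   counts) and `n_mixed`.
#' @export
concordance_classify <- function(transcript, other, params = class_params()) {
  genes <- intersect(names(transcript), names(other))
  if (length(genes) == 0) stop("no genes shared between the two inputs")
  a <- transcript[genes]
  b <- other[genes]
  thr <- params$sig_threshold
  both_within <- abs(a) < thr & abs(b) < thr
  opposite <- (a > 0 & b < 0) | (a < 0 & b > 0)
  both_sig <- abs(a) >= thr & abs(b) >= thr & !opposite &
    sign(a) == sign(b) & a != 0
  cls <- ifelse(both_within, "no_variation_both",
                ifelse(opposite, "divergent",
                       ifelse(both_sig, "both_significant_same_direction",
                              "no_variation_both")))
  mixed <- cls == "no_variation_both" & !both_within
  records <- data.frame(
    gene_id = genes,
    A_transcript = unname(a),
    A_other = unname(b),
    concordance_class = cls,
    mixed = mixed,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  counts <- vapply(CONCORDANCE_CLASSES, function(k) sum(cls == k), integer(1))
  list(records = records, counts = counts, n_mixed = sum(mixed))
}

#' Summarize pair classifications, overall and per functional category
#'
#' Counts and integer percentages (rounding half away from zero) per
#' three-way class, a per-category breakdown, and a listing table restricted
#' to genes significant in at least one condition -- mirroring the
#' table-inclusion rule of the published gene lists.
#'
#' @param records a `pair_classification` from [classify_pair()].
#' @param categories optional named vector gene_id -> category used to
#'   (re)label the records.
#' @return list of class `class_summary` with `counts`, `percentages`,
#'   `by_category`, `listing` and `n_total`.
#' @export
summarize_classes <- function(records, categories = NULL) {
  stopifnot(inherits(records, "pair_classification"))
  if (nrow(records) == 0) stop("no classification records")
  if (!is.null(categories)) {
    hit <- categories[records$gene_id]
    records$category <- ifelse(is.na(hit), "unknown", hit)
  }
  total <- nrow(records)
  counts <- vapply(PAIR_CLASSES, function(k) sum(records$pair_class == k),
                   integer(1))
  pct <- round_half_away(100 * counts / total)
  by_cat <- as.data.frame.matrix(
    table(factor(records$category, levels = CATEGORY_LEVELS),
          factor(records$pair_class, levels = PAIR_CLASSES))
  )
  by_cat <- cbind(category = rownames(by_cat), by_cat,
                  stringsAsFactors = FALSE)
  rownames(by_cat) <- NULL
  listing <- records[records$sig_solid != "no_variation" |
                       records$sig_liquid != "no_variation", , drop = FALSE]
  structure(
    list(counts = counts, percentages = pct, by_category = by_cat,
         listing = listing, n_total = total),
    class = "class_summary"
  )
}

#' @export
print.class_summary <- function(x, ...) {
  cat("Three-way classification of", x$n_total, "genes\n")
  for (k in PAIR_CLASSES) {
    cat(sprintf("  %-26s %5d (%d%%)\n", k, x$counts[[k]],
                x$percentages[[k]]))
  }
  cat("Listed (significant in >= 1 condition):", nrow(x$listing), "genes\n")
  invisible(x)
}
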