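# Synthetic two-color gDNA-reference experiments with known ground truth.
# The generator emulates the statistical structure the analysis assumes:
# log-scale gene abundances with per-condition stage effects, additive
# Gaussian replicate noise on the log2 intensities, a smooth
# intensity-dependent dye bias differing between arrays (the artifact cyclic
# loess removes), background pixel statistics (exercising the surrogate
# rule), cross-hybridizing probes mixing two genes' signals, and intergenic
# probes at background-level signal.

#' Simulation configuration
#'
#' Defaults describe a scaled-down 4x44k-style experiment: 500 genes with 4
#' valid probes each, cross-hybridizing and intergenic probe fractions taken
#' from the real array's composition (943/43798 and 7234/43798), three
#' biological replicates per stage and condition, and replicate noise that
#' places within-stage gene-level correlations in the 0.97-0.995 range.
#'
#' @param n_genes number of genes.
#' @param probes_per_valid_gene valid probes per gene (default 4).
#' @param frac_cross_hyb fraction of all probes that cross-hybridize.
#' @param frac_intergenic fraction of all probes mapping to intergenic
#'   regions.
#' @param n_replicates biological replicates per stage x condition.
#' @param stage_effect_sd SD of the true log2(MII/MI) effect magnitudes.
#' @param frac_changed fraction of genes with a true stage effect of
#'   magnitude >= 1 in at least one condition.
#' @param frac_opposite fraction of changed genes whose liquid and solid
#'   effects have strictly opposite signs.
#' @param noise_sd SD of the additive Gaussian replicate noise on log2
#'   channel intensities.
#' @param bias_amplitude peak magnitude (log2 units) of the smooth
#'   intensity-dependent dye bias injected per array.
#' @param bg_level mean background intensity (fluorescence units).
#' @param bg_sd_level mean background pixel SD (fluorescence units);
#'   must be positive.
#' @param base_abundance_sd SD of the per-gene baseline log2 abundance
#'   relative to the gDNA reference.
#' @param seed integer random seed; a fixed seed gives byte-identical
#'   simulated files.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       probes_per_valid_gene = 4,
                       frac_cross_hyb = 943 / 43798,
                       frac_intergenic = 7234 / 43798,
                       n_replicates = 3,
                       stage_effect_sd = 2,
                       frac_changed = 0.3,
                       frac_opposite = 0.2,
                       noise_sd = 0.3,
                       bias_amplitude = 0.5,
                       bg_level = 100,
                       bg_sd_level = 30,
                       base_abundance_sd = 2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    probes_per_valid_gene = as.integer(probes_per_valid_gene),
    frac_cross_hyb = frac_cross_hyb,
    frac_intergenic = frac_intergenic,
    n_replicates = as.integer(n_replicates),
    stage_effect_sd = stage_effect_sd,
    frac_changed = frac_changed,
    frac_opposite = frac_opposite,
    noise_sd = noise_sd,
    bias_amplitude = bias_amplitude,
    bg_level = bg_level,
    bg_sd_level = bg_sd_level,
    base_abundance_sd = base_abundance_sd,
    seed = as.integer(seed)
  )
  for (f in c("frac_cross_hyb", "frac_intergenic", "frac_changed",
              "frac_opposite")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must be a fraction in [0, 1]")
    }
  }
  if (cfg$frac_cross_hyb + cfg$frac_intergenic >= 1) {
    stop("frac_cross_hyb + frac_intergenic must be < 1")
  }
  for (f in c("n_genes", "probes_per_valid_gene", "n_replicates")) {
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  }
  for (f in c("stage_effect_sd", "noise_sd", "bias_amplitude", "bg_level")) {
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  }
  if (cfg$bg_sd_level <= 0) stop("bg_sd_level must be positive")
  structure(cfg, class = "sim_config")
}

#' Probe bookkeeping implied by a simulation configuration
#'
#' The number of valid probes is `n_genes * probes_per_valid_gene`; the
#' total is scaled up so the cross-hybridizing and intergenic fractions are
#' met after rounding, and the three counts always sum exactly to the total.
#'
#' @param config a [sim_config()].
#' @return named integer vector with `valid`, `cross_hyb`, `intergenic`,
#'   `total`.
#' @export
probe_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_valid <- config$n_genes * config$probes_per_valid_gene
  frac_valid <- 1 - config$frac_cross_hyb - config$frac_intergenic
  total <- as.integer(round(n_valid / frac_valid))
  n_inter <- as.integer(round(config$frac_intergenic * total))
  n_cross <- total - n_valid - n_inter
  if (n_cross < 0) {
    n_cross <- 0L
    total <- n_valid + n_inter
  }
  c(valid = n_valid, cross_hyb = n_cross, intergenic = n_inter,
    total = n_valid + n_cross + n_inter)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate ground-truth gene effects
#'
#' Draws per-gene baseline abundances and true per-condition log2(MII/MI)
#' effects. Exactly `round(frac_changed * n_genes)` genes receive an effect
#' of magnitude >= 1 in the solid condition; of those,
#' `round(frac_opposite * n_changed)` get a strictly opposite-signed liquid
#' effect (also of magnitude >= 1), the rest a same-signed liquid effect.
#' Unchanged genes get a small common effect (|A| < 1, identical in both
#' conditions, hence cv = 0 and true class `similar`). The true class of
#' every gene is the three-way class of its (solid, liquid) effect pair
#' under [classify_pair()].
#'
#' @param config a [sim_config()].
#' @return data frame of class `sim_truth` with columns `gene_id`,
#'   `base_abundance`, `A_true_solid`, `A_true_liquid`, `true_class`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("SIM%04d", seq_len(n))
    base <- stats::rnorm(n, 0, config$base_abundance_sd)
    n_changed <- round(config$frac_changed * n)
    n_opp <- round(config$frac_opposite * n_changed)
    changed <- sample(n, n_changed)
    opp <- changed[seq_len(n_opp)]
    same <- setdiff(changed, opp)

    A_s <- A_l <- numeric(n)
    # unchanged genes: small common condition-independent effect
    delta <- stats::rnorm(n, 0, 0.25)
    delta <- pmax(pmin(delta, 0.95), -0.95)
    unchanged <- setdiff(seq_len(n), changed)
    A_s[unchanged] <- A_l[unchanged] <- delta[unchanged]

    draw_mag <- function(k) 1 + abs(stats::rnorm(k, 0, config$stage_effect_sd))
    if (n_opp > 0) {
      s <- sample(c(-1, 1), n_opp, replace = TRUE)
      A_s[opp] <- s * draw_mag(n_opp)
      A_l[opp] <- -s * draw_mag(n_opp)
    }
    if (length(same) > 0) {
      s <- sample(c(-1, 1), length(same), replace = TRUE)
      A_s[same] <- s * draw_mag(length(same))
      # same-signed liquid effect of free magnitude: yields a mix of
      # `similar` and `different_same_direction` true classes
      A_l[same] <- s * abs(stats::rnorm(length(same), 1,
                                        config$stage_effect_sd))
    }
    cls <- classify_pair(A_s, A_l)$pair_class
    structure(
      data.frame(
        gene_id = gene_id,
        base_abundance = base,
        A_true_solid = A_s,
        A_true_liquid = A_l,
        true_class = cls,
        stringsAsFactors = FALSE
      ),
      class = c("sim_truth", "data.frame")
    )
  })
}

# Smooth per-array dye bias as a function of the average log intensity. The
# quadratic coefficient alternates in sign between consecutive arrays so any
# pair of adjacent arrays exhibits a clear relative MA-trend; a small random
# linear term varies the shape.
array_bias_coefs <- function(n_arrays, amplitude) {
  data.frame(
    c2 = (-1)^seq_len(n_arrays) * stats::runif(n_arrays, 0.8, 1) * amplitude,
    c1 = stats::rnorm(n_arrays, 0, 0.2) * amplitude
  )
}

eval_bias <- function(a_mid, coefs) {
  rng <- range(a_mid)
  z <- if (diff(rng) > 0) (a_mid - rng[1]) / diff(rng) * 2 - 1 else 0 * a_mid
  coefs$c2 * (2 * z^2 - 1) + coefs$c1 * z
}

#' Simulate a complete two-color gDNA-reference experiment
#'
#' Produces one spot table per array (`n_replicates` x 2 stages x 2
#' conditions) plus the probe annotation. Valid probes carry their gene's
#' signal; cross-hybridizing probes a 50/50 linear mix of two genes'
#' signals; intergenic probes background-level signal. The sample channel is
#' 2^(affinity + abundance + noise + bias), the gDNA reference channel is
#' gene-independent (2^(affinity + noise)); backgrounds follow the
#' configured levels. With `dir` given, all tables plus `ground_truth.tsv`
#' are written as TSV.
#'
#' @param truth a `sim_truth` from [generate_truth()].
#' @param config the same [sim_config()] used for `truth`.
#' @param dir optional output directory (created if needed).
#' @return list of class `sim_experiment` with `scans` (list of
#'   [array_scan()]), `annotation`, `truth` and `config`.
#' @export
simulate_experiment <- function(truth, config, dir = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (nrow(truth) != config$n_genes) {
    stop("truth and config disagree on the number of genes")
  }
  counts <- probe_counts(config)
  with_seed(config$seed + 1L, {
    n <- config$n_genes
    ppg <- config$probes_per_valid_gene
    probe_id <- sprintf("P%06d", seq_len(counts[["total"]]))
    validity <- rep(c("valid", "cross_hyb", "intergenic"), counts[1:3])
    gene_idx_1 <- c(rep(seq_len(n), each = ppg),              # valid
                    sample(n, counts[["cross_hyb"]], replace = TRUE),
                    rep(NA_integer_, counts[["intergenic"]]))
    # second gene entering each cross-hybridizing probe's signal mix
    gene_idx_2 <- rep(NA_integer_, counts[["total"]])
    if (counts[["cross_hyb"]] > 0) {
      xh <- which(validity == "cross_hyb")
      g2 <- sample(n, length(xh), replace = TRUE)
      clash <- g2 == gene_idx_1[xh]
      g2[clash] <- (g2[clash] %% n) + 1L
      gene_idx_2[xh] <- g2
    }
    gene_id <- ifelse(is.na(gene_idx_1), "", truth$gene_id[gene_idx_1])
    annotation <- probe_annotation(probe_id, gene_id, validity)

    affinity <- stats::rnorm(counts[["total"]], 11, 0.8)
    intergenic_log2 <- -6  # transcription-free residual signal

    design <- expand.grid(
      replicate = seq_len(config$n_replicates),
      stage = c("MI", "MII"),
      condition = c("liquid", "solid"),
      stringsAsFactors = FALSE
    )[, c("condition", "stage", "replicate")]
    design$array_id <- sprintf("%s_%s_r%d", design$condition, design$stage,
                               design$replicate)
    coefs <- array_bias_coefs(nrow(design), config$bias_amplitude)

    gene_log2 <- function(stage, condition) {
      eff <- if (condition == "liquid") truth$A_true_liquid else
        truth$A_true_solid
      truth$base_abundance + if (stage == "MII") eff else 0
    }

    bg_draw <- function(level) {
      if (level <= 0) return(rep(0, counts[["total"]]))
      pmax(0, stats::rnorm(counts[["total"]], level, 0.05 * level))
    }
    bg_sd_draw <- function(level) {
      pmax(level / 10, stats::rnorm(counts[["total"]], level, 0.05 * level))
    }

    scans <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      x <- gene_log2(design$stage[i], design$condition[i])
      eps_s <- stats::rnorm(counts[["total"]], 0, config$noise_sd)
      eps_r <- stats::rnorm(counts[["total"]], 0, config$noise_sd)
      x1 <- ifelse(is.na(gene_idx_1), intergenic_log2, x[gene_idx_1])
      sample_lin <- 2^(affinity + x1 + eps_s)
      xh <- !is.na(gene_idx_2)
      if (any(xh)) {
        sample_lin[xh] <- 0.5 * sample_lin[xh] +
          0.5 * 2^(affinity[xh] + x[gene_idx_2[xh]] + eps_s[xh])
      }
      ref_lin <- 2^(affinity + eps_r)
      a_mid <- (log2(sample_lin) + log2(ref_lin)) / 2
      if (config$bias_amplitude > 0) {
        sample_lin <- sample_lin * 2^eval_bias(a_mid, coefs[i, ])
      }
      bg_s <- bg_draw(config$bg_level)
      bg_r <- bg_draw(config$bg_level)
      spots <- data.frame(
        probe_id = probe_id,
        fg_mean_sample = sample_lin + bg_s,
        bg_median_sample = bg_s,
        bg_sd_sample = bg_sd_draw(config$bg_sd_level),
        fg_mean_ref = ref_lin + bg_r,
        bg_median_ref = bg_r,
        bg_sd_ref = bg_sd_draw(config$bg_sd_level),
        stringsAsFactors = FALSE
      )
      scans[[i]] <- array_scan(design$array_id[i], design$condition[i],
                               design$stage[i], design$replicate[i], spots)
    }

    out <- structure(
      list(scans = scans, annotation = annotation, truth = truth,
           config = config),
      class = "sim_experiment"
    )
    if (!is.null(dir)) write_sim_experiment(out, dir)
    out
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  counts <- table(x$annotation$validity)
  cat(sprintf(paste0("sim_experiment: %d arrays x %d probes ",
                     "(%d valid, %d cross-hyb, %d intergenic), %d genes\n"),
              length(x$scans), nrow(x$annotation),
              counts[["valid"]], counts[["cross_hyb"]],
              counts[["intergenic"]], nrow(x$truth)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits `spots_<array_id>.tsv` per array, `probes.tsv` and
#' `ground_truth.tsv` under `dir`.
#'
#' @param experiment a `sim_experiment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (scan in experiment$scans) {
    write_spot_table(scan, file.path(dir,
                                     paste0("spots_", scan$array_id, ".tsv")))
  }
  write_probe_annotation(experiment$annotation, file.path(dir, "probes.tsv"))
  truth <- experiment$truth
  out <- data.frame(
    gene_id = truth$gene_id,
    A_true_solid = fmt_num(truth$A_true_solid),
    A_true_liquid = fmt_num(truth$A_true_liquid),
    true_class = truth$true_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
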