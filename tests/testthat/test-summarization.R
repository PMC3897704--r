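make_gene_case <- function() {
  # 4 probes: g1 has two valid probes, g2 one valid + one cross-hyb probe
  ann <- probe_annotation(c("P1", "P2", "P3", "P4"),
                          c("g1", "g1", "g2", "g2"),
                          c("valid", "valid", "valid", "cross_hyb"))
  M <- matrix(c(1, 3, 2, 50), ncol = 1,
              dimnames = list(c("P1", "P2", "P3", "P4"), "a1"))
  meta <- data.frame(array_id = "a1", condition = "liquid", stage = "MI",
                     replicate = 1L, stringsAsFactors = FALSE)
  list(ann = ann, m = strepArray:::new_mg_matrix(M, ann$weight, meta))
}

test_that("gene summaries are probe-weighted means", {
  cs <- make_gene_case()
  g <- summarize_genes(cs$m, cs$ann)
  expect_equal(unname(g$M["g1", 1]), 2)          # plain mean of 1 and 3
  # one valid (2.0) + one cross-hyb (50): (1*2 + 1e-6*50)/(1 + 1e-6)
  expect_equal(unname(g$M["g2", 1]), 2, tolerance = 1e-4)
  expect_equal(unname(g$n_valid_probes), c(2L, 1L))
  # single valid probe passes through exactly
  ann1 <- probe_annotation("P1", "g1", "valid")
  M1 <- matrix(2, dimnames = list("P1", "a1"))
  m1 <- strepArray:::new_mg_matrix(M1, 1, cs$m$meta)
  expect_equal(unname(summarize_genes(m1, ann1)$M[1, 1]), 2)
})

test_that("genes with zero valid probes are excluded with a message", {
  ann <- probe_annotation(c("P1", "P2"), c("g1", "g2"),
                          c("valid", "cross_hyb"))
  M <- matrix(c(1, 2), ncol = 1, dimnames = list(c("P1", "P2"), "a1"))
  meta <- data.frame(array_id = "a1", condition = "liquid", stage = "MI",
                     replicate = 1L, stringsAsFactors = FALSE)
  m <- strepArray:::new_mg_matrix(M, ann$weight, meta)
  expect_message(g <- summarize_genes(m, ann), "g2")
  expect_identical(g$gene_ids, "g1")
})

test_that("unmoderated contrast reproduces the hand-computed pooled t", {
  M <- rbind(c(0.0, 0.1, -0.1, 2.0, 2.1, 1.9))
  g <- gene_mg_from_matrix(M, conditions = rep("liquid", 6),
                           stages = rep(c("MI", "MII"), each = 3))
  ab <- fit_contrast(g, "liquid", moderate = FALSE)
  expect_equal(ab$A, 2)
  expect_equal(ab$mean_MI, 0)
  expect_equal(ab$mean_MII, 2)
  # pooled s = 0.1, t = 2 / (0.1 * sqrt(2/3)), df = 4
  expect_equal(ab$t_mod, 2 / (0.1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(attr(ab, "moderation")$d0, 0)
  expect_equal(ab$p_raw, 2 * pt(-2 / (0.1 * sqrt(2 / 3)), df = 4))
})

test_that("unmoderated fit matches classical two-sample t on random genes", {
  set.seed(44)
  n <- 200
  M <- matrix(rnorm(n * 6, sd = runif(n, 0.1, 1)), n, 6)
  g <- gene_mg_from_matrix(M, conditions = rep("solid", 6),
                           stages = rep(c("MI", "MII"), each = 3))
  ab <- fit_contrast(g, "solid", moderate = FALSE)
  for (i in seq_len(n)) {
    tt <- t.test(M[i, 4:6], M[i, 1:3], var.equal = TRUE)
    expect_equal(ab$t_mod[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(ab$p_raw[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("zero contrast gives t = 0 and p = 1", {
  M <- rbind(c(1, 2, 3, 3, 2, 1))
  g <- gene_mg_from_matrix(M, conditions = rep("liquid", 6),
                           stages = rep(c("MI", "MII"), each = 3))
  ab <- fit_contrast(g, "liquid")
  expect_equal(ab$A, 0)
  expect_equal(ab$t_mod, 0)
  expect_equal(ab$p_raw, 1)
})

test_that("equal variances take the d0 = +Inf path with normal-like tails", {
  set.seed(3)
  n <- 300
  # common variance across genes: log(s_sq) spread is at chi-square level,
  # so moment matching must hit the boundary
  M <- matrix(rnorm(n * 6, sd = 0.3), n, 6)
  g <- gene_mg_from_matrix(M, conditions = rep("liquid", 6),
                           stages = rep(c("MI", "MII"), each = 3))
  ab <- fit_contrast(g, "liquid")
  mod <- attr(ab, "moderation")
  if (is.finite(mod$d0)) {
    expect_gt(mod$d0, 20)  # at worst, strong moderation
  } else {
    s0 <- mod$s0_sq
    expect_equal(ab$t_mod, ab$A / sqrt(s0 * (2 / 3)), tolerance = 1e-12)
  }
})

test_that("moment-matching recovers known prior degrees of freedom", {
  set.seed(42)
  d <- 4
  for (d0_true in c(2, 4, 10)) {
    s0 <- 0.04
    sg2 <- d0_true * s0 / rchisq(5000, df = d0_true)
    s_sq <- sg2 * rchisq(5000, df = d) / d
    fit <- moderate_variances(s_sq, d)
    expect_lt(abs(fit$d0 - d0_true) / d0_true, 0.5)
    expect_lt(abs(fit$s0_sq - s0) / s0, 0.5)
  }
})

test_that("moderation matches limma's empirical Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(5)
  n <- 500
  sg2 <- 4 * 0.09 / rchisq(n, df = 4)
  X <- matrix(rnorm(n * 6), n, 6) * sqrt(sg2)
  X[, 4:6] <- X[, 4:6] + rnorm(n)
  f <- limma::lmFit(X, cbind(1, c(0, 0, 0, 1, 1, 1)))
  fe <- limma::eBayes(f)
  mine <- moderate_variances(f$sigma^2, 4)
  expect_equal(mine$d0, fe$df.prior, tolerance = 1e-6)
  expect_equal(mine$s0_sq, fe$s2.prior, tolerance = 1e-6)
  A <- rowMeans(X[, 4:6]) - rowMeans(X[, 1:3])
  t_mine <- A / sqrt(mine$s_tilde_sq * (2 / 3))
  expect_equal(t_mine, unname(fe$t[, 2]), tolerance = 1e-9)
})

test_that("BH adjustment matches an independent step-up oracle", {
  # independent implementation of the step-up rule
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (i in 1:10) {
    p <- runif(sample(2:50, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted p-values are monotone in raw p-value ranks", {
  set.seed(23)
  p <- runif(500)^3
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= 0))
})

test_that("replicate correlation handles identity, antisymmetry and
           degenerate input", {
  v <- rnorm(50)
  M <- cbind(v, v, -v)
  g <- gene_mg_from_matrix(M, conditions = rep("liquid", 3),
                           stages = c("MI", "MI", "MI"))
  rc <- replicate_correlation(g)
  expect_equal(rc$r[rc$array_1 == "arr01" & rc$array_2 == "arr02"], 1)
  expect_equal(rc$r[rc$array_1 == "arr01" & rc$array_2 == "arr03"], -1)
  Mz <- cbind(v, rep(1, 50))
  gz <- gene_mg_from_matrix(Mz, conditions = rep("liquid", 2),
                            stages = c("MI", "MI"))
  expect_warning(rcz <- replicate_correlation(gz), "zero-variance")
  expect_true(is.na(rcz$r[1]))
})

test_that("too few replicates per stage is an error naming the requirement", {
  M <- matrix(rnorm(8), 2, 4)
  g <- gene_mg_from_matrix(M, conditions = rep("liquid", 4),
                           stages = c("MI", "MII", "MII", "MII"))
  expect_error(fit_contrast(g, "liquid"), ">= 2 replicates")
})

test_that("abundance estimates are nearly unbiased and recover effect signs", {
  cfg <- sim_config(seed = 19)  # noise_sd 0.3, 3 replicates
  truth <- generate_truth(cfg)
  sim <- simulate_experiment(truth, cfg)
  sc <- Filter(function(s) s$condition == "liquid", sim$scans)
  m <- global_median_center(
    cyclic_loess_normalize(compute_mg(sc, sim$annotation)))
  g <- summarize_genes(m, sim$annotation)
  ab <- fit_contrast(g, "liquid")
  idx <- match(truth$gene_id, ab$gene_id)
  err <- ab$A[idx] - truth$A_true_liquid
  expect_lt(abs(mean(err)), 0.05)
  big <- abs(truth$A_true_liquid) >= 2
  expect_gte(mean(sign(ab$A[idx][big]) == sign(truth$A_true_liquid[big])),
             0.95)
})
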