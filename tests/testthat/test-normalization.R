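test_that("net intensity applies the surrogate rule", {
  expect_equal(net_intensity(500, 100, 20), 400)
  expect_equal(net_intensity(90, 100, 20), 20)   # negative net
  expect_equal(net_intensity(110, 100, 20), 20)  # net below background SD
  expect_error(net_intensity(100, 50, 0), "bg_sd")
  # surrogate guarantees positivity for any non-negative inputs
  set.seed(1)
  fg <- runif(1000, 0, 1000)
  bg <- runif(1000, 0, 1000)
  sd_ <- runif(1000, 1e-6, 100)
  expect_true(all(net_intensity(fg, bg, sd_) > 0))
})

test_that("Mg values are log2 ratios of surrogate-corrected net intensities", {
  ann <- probe_annotation(c("P1", "P2", "P3"), c("g1", "g1", "g2"),
                         c("valid", "valid", "valid"))
  spots <- data.frame(
    probe_id = c("P1", "P2", "P3"),
    #           400/100 = 4      equal nets     surrogate 20 / net 80
    fg_mean_sample = c(500, 300, 110),
    bg_median_sample = c(100, 100, 100),
    bg_sd_sample = c(20, 20, 20),
    fg_mean_ref = c(200, 300, 181),
    bg_median_ref = c(100, 100, 101),
    bg_sd_ref = c(20, 20, 20)
  )
  m <- compute_mg(array_scan("a1", "liquid", "MI", 1, spots), ann)
  expect_equal(unname(m$M[, 1]), c(2, 0, -2))
  expect_equal(m$weights, ann$weight)
  # all-finite invariant holds for arbitrary non-negative spot stats
  scan <- random_scan(n = 200, seed = 8)
  ann2 <- probe_annotation(scan$spots$probe_id,
                           paste0("g", seq_len(200)),
                           rep("valid", 200))
  expect_true(all(is.finite(compute_mg(scan, ann2)$M)))
})

test_that("compute_mg rejects probe mismatches between scan and annotation", {
  ann <- probe_annotation(c("P1", "P2"), c("g1", "g2"), c("valid", "valid"))
  scan <- random_scan(n = 3, seed = 2)  # probes P001..P003, unknown to ann
  expect_error(compute_mg(scan, ann), "absent from the annotation")
})

test_that("cyclic loess is a no-op on identical arrays and halves a constant
           offset per pass", {
  set.seed(10)
  x <- rnorm(400, 8, 1.5)
  m_same <- mg_from_matrix(cbind(x, x))
  out <- cyclic_loess_normalize(m_same)
  expect_lt(max(abs(out$M - m_same$M)), 1e-10)

  m_off <- mg_from_matrix(cbind(x, x + 0.8))
  one_it <- cyclic_loess_normalize(m_off, norm_params(loess_iterations = 1))
  expect_lt(max(abs(one_it$M[, 1] - one_it$M[, 2])), 1e-6)
})

test_that("cyclic loess removes an injected quadratic bias but conserves
           per-probe grand means", {
  set.seed(21)
  n <- 1200
  base <- rnorm(n, 9, 1.3)
  M <- sapply(1:3, function(j) base + rnorm(n, 0, 0.05))
  a <- rowMeans(M)
  z <- (a - min(a)) / diff(range(a)) * 2 - 1
  M[, 1] <- M[, 1] + 1.0 * (2 * z^2 - 1)
  m <- mg_from_matrix(M)
  pre <- ma_trend_amplitude(m)
  expect_gte(max(pre$amplitude), 0.5)
  out <- cyclic_loess_normalize(m)
  post <- ma_trend_amplitude(out)
  expect_lt(max(post$amplitude), 0.1)
  expect_lt(max(abs(rowSums(out$M) - rowSums(m$M))), 1e-9)
})

test_that("low-weight probes are corrected but do not steer the fit", {
  set.seed(13)
  n <- 1000
  base <- rnorm(n, 9, 1.2)
  w <- rep(c(1, NONVALID_WEIGHT), c(900, 100))
  M <- cbind(base, base + 0.6)
  # plant wild values on the low-weight probes of array 1
  M[w != 1, 1] <- M[w != 1, 1] + 50
  m <- mg_from_matrix(M, weights = w)
  out <- cyclic_loess_normalize(m, norm_params(loess_iterations = 1))
  d_valid <- out$M[w == 1, 1] - out$M[w == 1, 2]
  # the constant offset between the arrays is removed as judged by valid
  # probes; the planted outliers did not drag the curve
  expect_lt(max(abs(d_valid)), 0.05)
})

test_that("normalizing an already-consistent matrix is near-idempotent", {
  # in the no-bias limit the only possible correction is the loess smooth of
  # pure replicate noise, which vanishes as that noise does
  set.seed(31)
  base <- rnorm(2000, 9, 1.3)
  M <- sapply(1:4, function(j) base + rnorm(2000, 0, 0.002))
  m <- mg_from_matrix(M)
  once <- cyclic_loess_normalize(m)
  twice <- cyclic_loess_normalize(once)
  expect_lt(max(abs(twice$M - once$M)), 1e-3)
})

test_that("weighted median ignores low-weight probes and centering is exact", {
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  m <- mg_from_matrix(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(unname(global_median_center(m)$M[, 1]), c(-1, 0, 1))
  # idempotence
  centered <- global_median_center(m)
  expect_equal(global_median_center(centered)$M, centered$M)
  # invalid probes all at +100 do not move the offset (odd valid count so
  # the cumulative-weight crossing is not knife-edge)
  set.seed(6)
  x <- rnorm(200)
  w <- rep(c(1, NONVALID_WEIGHT), c(151, 49))
  x[w != 1] <- 100
  m2 <- mg_from_matrix(matrix(x, ncol = 1), weights = w)
  off <- x - global_median_center(m2)$M[, 1]
  expect_equal(median(off), weighted_median(x[w == 1]), tolerance = 1e-12)
  # weighted median after centering is 0 (many random matrices)
  for (seed in 1:5) {
    set.seed(seed)
    M <- matrix(rnorm(300), 100, 3)
    w <- sample(c(1, NONVALID_WEIGHT), 100, replace = TRUE, prob = c(.8, .2))
    out <- global_median_center(mg_from_matrix(M, weights = w))
    meds <- apply(out$M, 2, weighted_median, w = w)
    expect_true(all(abs(meds) < 1e-9))
  }
})

test_that("parameter validation catches degenerate loess settings", {
  expect_error(norm_params(loess_window = 0), "loess_window")
  expect_error(norm_params(loess_window = 1.5), "loess_window")
  expect_error(norm_params(loess_iterations = 0), "iterations")
  m <- mg_from_matrix(matrix(rnorm(10), 5, 2))
  expect_error(
    cyclic_loess_normalize(m, norm_params(loess_window = 0.2,
                                          loess_degree = 2)),
    "loess_window too small")
  expect_error(cyclic_loess_normalize(mg_from_matrix(matrix(rnorm(5)))),
               "at least 2 arrays")
})

test_that("weighted cyclic loess agrees with limma's pairs method on
           uniform weights", {
  skip_if_not_installed("limma")
  set.seed(2)
  n <- 1500
  base <- rnorm(n, 9, 1.2)
  Y <- sapply(1:3, function(j) base + rnorm(n, 0, 0.1))
  a <- rowMeans(Y)
  z <- (a - min(a)) / diff(range(a)) * 2 - 1
  Y[, 1] <- Y[, 1] + 0.8 * (2 * z^2 - 1)
  Y[, 2] <- Y[, 2] - 0.5 * z
  lim <- limma::normalizeCyclicLoess(Y, span = 0.3, iterations = 3,
                                     method = "pairs")
  mine <- cyclic_loess_normalize(mg_from_matrix(Y))$M
  expect_lt(sqrt(mean((mine - lim)^2)), 0.02)
  interior <- a > quantile(a, 0.02) & a < quantile(a, 0.98)
  expect_lt(max(abs(mine - lim)[interior, ]), 0.05)
})
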