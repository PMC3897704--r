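# Shared in-code fixtures: tiny random spot tables and annotations.

random_spots <- function(n = 10, seed = NULL, probe_ids = sprintf("P%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  sig_s <- runif(n, 50, 5000)
  sig_r <- runif(n, 50, 5000)
  data.frame(
    probe_id = probe_ids,
    fg_mean_sample = sig_s + 100,
    bg_median_sample = rep(100, n) + rnorm(n, 0, 3),
    bg_sd_sample = runif(n, 10, 30),
    fg_mean_ref = sig_r + 100,
    bg_median_ref = rep(100, n) + rnorm(n, 0, 3),
    bg_sd_ref = runif(n, 10, 30),
    stringsAsFactors = FALSE
  )
}

random_scan <- function(n = 10, array_id = "a1", condition = "liquid",
                        stage = "MI", replicate = 1, seed = NULL) {
  array_scan(array_id, condition, stage, replicate,
             random_spots(n, seed = seed))
}

# An mg_matrix built directly from a value matrix (bypassing spot records),
# used to unit-test normalization in isolation.
mg_from_matrix <- function(M, weights = rep(1, nrow(M)),
                           conditions = rep("liquid", ncol(M)),
                           stages = rep("MI", ncol(M))) {
  ids <- sprintf("arr%02d", seq_len(ncol(M)))
  rownames(M) <- sprintf("p%04d", seq_len(nrow(M)))
  meta <- data.frame(array_id = ids, condition = conditions, stage = stages,
                     replicate = seq_len(ncol(M)), stringsAsFactors = FALSE)
  strepArray:::new_mg_matrix(M, weights, meta)
}

# gene_mg built directly from a matrix, for contrast-fitting unit tests.
gene_mg_from_matrix <- function(M, conditions, stages) {
  ids <- sprintf("arr%02d", seq_len(ncol(M)))
  rownames(M) <- sprintf("g%04d", seq_len(nrow(M)))
  colnames(M) <- ids
  meta <- data.frame(array_id = ids, condition = conditions, stage = stages,
                     replicate = seq_len(ncol(M)), stringsAsFactors = FALSE)
  structure(
    list(M = M, n_valid_probes = setNames(rep(1L, nrow(M)), rownames(M)),
         gene_ids = rownames(M), meta = meta),
    class = "gene_mg"
  )
}
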