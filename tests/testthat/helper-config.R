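# Reduced design used by most tests: same structure as the full paradigm
# (3 categories, 3 repetitions, IRI 10-36) at a quarter of the pair count.
small_config <- function(...) {
  experiment_config(
    n_pairs = 24L, n_updating_runs = 2L, pairs_per_condition_per_run = 6L,
    n_test_runs = 2L, pairs_per_test_run = 12L,
    n_localizer_runs = 2L, miniblocks_per_run = 3L,
    n_voxels = 40L, ...
  )
}

# Deterministic linearly separable 3-category toy set: cluster centers on
# distinct axes, n points per category, k voxels.
toy_localizer <- function(n_per_cat = 6L, k = 6L, sep = 4, noise = 0.2,
                          seed = 1L) {
  set.seed(seed)
  cats <- c("face", "object", "scene")
  X <- do.call(rbind, lapply(seq_along(cats), function(i) {
    center <- rep(0, k); center[i] <- sep
    matrix(rep(center, n_per_cat), n_per_cat, byrow = TRUE) +
      matrix(rnorm(n_per_cat * k, 0, noise), n_per_cat)
  }))
  list(X = X, labels = rep(cats, each = n_per_cat),
       runs = rep(rep(1:2, length.out = n_per_cat), times = length(cats)))
}
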