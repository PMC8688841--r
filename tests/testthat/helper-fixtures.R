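# Shared fixtures: small models and tasks used across test files. All data
# are generated in code; sizes are kept small so the full suite stays fast.

# reduced backbone used by training-level tests
tiny_model_config <- function(n_classes = 3L, n_sources = 1L,
                              input_dim = 310L) {
  model_config(input_dim = input_dim, cfe_hidden_dims = c(96L, 64L),
               cfe_out_dim = 32L, dsfe_out_dim = 16L,
               n_classes = n_classes, n_sources = n_sources)
}

# micro model for hand-verifiable forward/backward arithmetic
micro_model_config <- function(n_sources = 2L, n_classes = 3L) {
  model_config(input_dim = 6L, cfe_hidden_dims = c(5L, 4L), cfe_out_dim = 3L,
               dsfe_out_dim = 3L, n_classes = n_classes,
               n_sources = n_sources)
}

# a quick training recipe for scaled-down studies
fast_train_config <- function(seed = 1L, epochs = 30L, ...) {
  train_config(epochs = epochs, batch_size = 64L, seed = seed, ...)
}

# small synthetic task: defaults follow the generator's study conditions but
# with fewer samples where a test only needs structure, not learning
small_task <- function(n_domains = 3L, n_per_domain = 60L, seed = 1L, ...) {
  generate_multisource(synthetic_config(n_domains = n_domains,
                                        n_per_domain = n_per_domain,
                                        seed = seed, ...))
}

# naive O(m^2) double-sum MMD oracle, independent of the estimator under test
mmd_oracle <- function(A, B, kernel_fn, estimator = "biased") {
  m <- nrow(A)
  kAA <- kBB <- matrix(0, m, m)
  kAB <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      kAA[i, j] <- kernel_fn(A[i, ], A[j, ])
      kBB[i, j] <- kernel_fn(B[i, ], B[j, ])
      kAB[i, j] <- kernel_fn(A[i, ], B[j, ])
    }
  }
  if (estimator == "biased") {
    mean(kAA) + mean(kBB) - 2 * mean(kAB)
  } else {
    off <- function(K) (sum(K) - sum(diag(K))) / (m * (m - 1))
    off(kAA) + off(kBB) - 2 * mean(kAB)
  }
}

# RBF kernel function matching a kernel_spec with a *fixed* anchor
rbf_multi_fn <- function(spec) {
  k <- spec$n_kernels
  gammas <- spec$anchor * spec$ladder_base^(seq_len(k) - (k + 1) / 2)
  function(x, y) mean(exp(-sum((x - y)^2) / gammas))
}

flatten_params <- function(fit_or_params) {
  p <- if (inherits(fit_or_params, "msmda_fit")) fit_or_params$params else fit_or_params
  msmda:::params_to_vector(p)
}
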