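#' Network architecture configuration
#'
#' The backbone is a stack of small multilayer perceptrons:
#'
#' * **CFE** (common feature extractor): three affine layers, each followed by
#'   a LeakyReLU, mapping `input_dim` (310 for the 62 x 5 DE layout) down to
#'   `cfe_out_dim` (64). Shared by every domain — it learns domain-invariant
#'   low-level features.
#' * **DSFE** (domain-specific feature extractor), one per source: a single
#'   affine layer plus LeakyReLU, `cfe_out_dim -> dsfe_out_dim` (64 -> 32).
#' * **DSC** (domain-specific classifier), one per source: a single affine
#'   layer to `n_classes` logits, no activation (softmax lives in the losses
#'   and at inference).
#'
#' LeakyReLU rather than ReLU throughout: DE features are signed and
#' informative below zero, and a hard ReLU would discard that information.
#'
#' @param input_dim Input feature count (default 310).
#' @param cfe_hidden_dims Integer vector of the two CFE hidden widths
#'   (default `c(256, 128)`; the published description fixes only 310 in,
#'   64 out and three layers — the taper is a package choice).
#' @param cfe_out_dim CFE output width (default 64).
#' @param dsfe_out_dim DSFE output width (default 32).
#' @param n_classes Number of classes.
#' @param n_sources Number of source domains `N` (= branch count).
#' @param leaky_slope Negative-side slope of LeakyReLU (default 0.01).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_dim = 310L, cfe_hidden_dims = c(256L, 128L),
                         cfe_out_dim = 64L, dsfe_out_dim = 32L,
                         n_classes = 3L, n_sources = 1L, leaky_slope = 0.01) {
  cfg <- list(
    input_dim = as.integer(input_dim),
    cfe_hidden_dims = as.integer(cfe_hidden_dims),
    cfe_out_dim = as.integer(cfe_out_dim),
    dsfe_out_dim = as.integer(dsfe_out_dim),
    n_classes = as.integer(n_classes),
    n_sources = as.integer(n_sources),
    leaky_slope = as.numeric(leaky_slope)
  )
  dims <- c(cfg$input_dim, cfg$cfe_hidden_dims, cfg$cfe_out_dim,
            cfg$dsfe_out_dim, cfg$n_classes)
  if (any(dims < 1L)) stopf("all dimensions must be >= 1", class = "msmda_config_error")
  if (cfg$n_sources < 1L) stopf("n_sources must be >= 1", class = "msmda_config_error")
  if (cfg$leaky_slope <= 0) stopf("leaky_slope must be > 0", class = "msmda_config_error")
  structure(cfg, class = "model_config")
}

cfe_layer_dims <- function(cfg) {
  dims <- c(cfg$input_dim, cfg$cfe_hidden_dims, cfg$cfe_out_dim)
  lapply(seq_len(length(dims) - 1L), function(l) c(dims[l], dims[l + 1L]))
}

# Uniform fan-in init, U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for weights and
# biases — the standard linear-layer default in the deep-DA lineage.
init_affine <- function(fan_in, fan_out) {
  a <- 1 / sqrt(fan_in)
  list(
    W = matrix(runif(fan_in * fan_out, -a, a), fan_in, fan_out),
    b = runif(fan_out, -a, a)
  )
}

#' Initialize model parameters
#'
#' Deterministic given `seed`; each branch draws its own weights, so branches
#' start independent.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `model_params`: list with `cfe` (list of three
#'   affine layers, each `list(W, b)`), `dsfe` and `dsc` (lists of
#'   `cfg$n_sources` affine layers), and the `config`.
#' @export
init_model <- function(cfg, seed = 1L) {
  with_seed(seed, {
    cfe <- lapply(cfe_layer_dims(cfg), function(d) init_affine(d[1], d[2]))
    dsfe <- lapply(seq_len(cfg$n_sources), function(i) {
      init_affine(cfg$cfe_out_dim, cfg$dsfe_out_dim)
    })
    dsc <- lapply(seq_len(cfg$n_sources), function(i) {
      init_affine(cfg$dsfe_out_dim, cfg$n_classes)
    })
    structure(list(cfe = cfe, dsfe = dsfe, dsc = dsc, config = cfg),
              class = "model_params")
  })
}

#' Count trainable parameters
#' @param params A `model_params` object.
#' @return Integer: total number of scalar weights and biases.
#' @export
n_parameters <- function(params) {
  count_affine <- function(l) length(l$W) + length(l$b)
  sum(vapply(params$cfe, count_affine, numeric(1))) +
    sum(vapply(params$dsfe, count_affine, numeric(1))) +
    sum(vapply(params$dsc, count_affine, numeric(1)))
}

leaky_relu <- function(x, slope) {
  pmax(x, 0) + slope * pmin(x, 0)
}

leaky_relu_grad <- function(x, slope) {
  ifelse(x > 0, 1, slope)
}

affine_forward <- function(X, layer) {
  sweep(X %*% layer$W, 2L, layer$b, "+")
}

# CFE forward with cached pre-activations for backprop.
cfe_forward_cached <- function(params, X) {
  slope <- params$config$leaky_slope
  a <- list(); h <- list(X)
  for (l in seq_along(params$cfe)) {
    a[[l]] <- affine_forward(h[[l]], params$cfe[[l]])
    h[[l + 1L]] <- leaky_relu(a[[l]], slope)
  }
  list(a = a, h = h, q = h[[length(h)]])
}

#' Common feature extractor forward pass
#'
#' @param params A `model_params` object.
#' @param X Numeric matrix `n x input_dim`.
#' @return Numeric matrix `n x cfe_out_dim` of common features.
#' @export
cfe_forward <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != params$config$input_dim) {
    stopf("input has %d columns, model expects %d", ncol(X),
          params$config$input_dim, class = "msmda_contract_error")
  }
  cfe_forward_cached(params, X)$q
}

branch_forward_cached <- function(params, q, branch) {
  slope <- params$config$leaky_slope
  u <- affine_forward(q, params$dsfe[[branch]])
  r <- leaky_relu(u, slope)
  z <- affine_forward(r, params$dsc[[branch]])
  list(u = u, r = r, z = z)
}

#' One branch's forward pass (DSFE + DSC)
#'
#' @param params A `model_params` object.
#' @param q Common features, `n x cfe_out_dim`.
#' @param branch 1-based branch index, `<= n_sources`.
#' @return List with `r` (domain-specific features, `n x dsfe_out_dim`) and
#'   `logits` (`n x n_classes`, no activation applied).
#' @export
branch_forward <- function(params, q, branch) {
  if (branch < 1L || branch > params$config$n_sources) {
    stopf("branch %d out of range 1..%d", branch, params$config$n_sources,
          class = "msmda_contract_error")
  }
  q <- as.matrix(q)
  if (ncol(q) != params$config$cfe_out_dim) {
    stopf("q has %d columns, expected %d", ncol(q), params$config$cfe_out_dim,
          class = "msmda_contract_error")
  }
  out <- branch_forward_cached(params, q, branch)
  list(r = out$r, logits = out$z)
}

#' Full multi-branch forward pass
#'
#' The CFE runs once per batch; branch `i` then consumes the pair (source
#' batch `i`, target batch), so the target passes through **every** branch.
#'
#' @param params A `model_params` object.
#' @param source_batches List of `n_sources` matrices, each `m x input_dim`.
#' @param target_batch Matrix `m x input_dim` (same `m`; the paired MMD
#'   estimator assumes equal batch sizes).
#' @return List of class `branch_outputs` with per-branch elements
#'   `r_source`, `r_target`, `logits_source`, `logits_target`, and shared
#'   `q_sources` (list), `q_target`.
#' @export
full_forward <- function(params, source_batches, target_batch) {
  N <- params$config$n_sources
  if (length(source_batches) != N) {
    stopf("%d source batches for %d branches", length(source_batches), N,
          class = "msmda_contract_error")
  }
  m <- nrow(target_batch)
  if (any(vapply(source_batches, nrow, integer(1)) != m)) {
    stopf("all batches must share the same size m", class = "msmda_contract_error")
  }
  q_s <- lapply(source_batches, function(X) cfe_forward(params, X))
  q_t <- cfe_forward(params, target_batch)
  branches <- lapply(seq_len(N), function(i) {
    bs <- branch_forward_cached(params, q_s[[i]], i)
    bt <- branch_forward_cached(params, q_t, i)
    list(r_source = bs$r, r_target = bt$r,
         logits_source = bs$z, logits_target = bt$z)
  })
  structure(list(branches = branches, q_sources = q_s, q_target = q_t),
            class = "branch_outputs")
}

# --- parameter flattening helpers (used by Adam and the gradient checks) ---

params_to_vector <- function(params) {
  unlist(lapply(c(params$cfe, params$dsfe, params$dsc),
                function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

vector_to_params <- function(v, params) {
  pos <- 0L
  take <- function(n) {
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  rebuild <- function(layers) {
    lapply(layers, function(l) {
      W <- matrix(take(length(l$W)), nrow(l$W), ncol(l$W))
      b <- take(length(l$b))
      list(W = W, b = b)
    })
  }
  params$cfe <- rebuild(params$cfe)
  params$dsfe <- rebuild(params$dsfe)
  params$dsc <- rebuild(params$dsc)
  params
}
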