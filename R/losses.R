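#' Kernel specification for the MMD estimator
#'
#' The RKHS kernel behind the maximum mean discrepancy. The default is the
#' multi-kernel Gaussian RBF of the deep-adaptation-network lineage: a
#' geometric ladder of `n_kernels` bandwidths centred on the median pairwise
#' squared distance of the pooled batch, `k(x, y) = mean_g exp(-||x - y||^2 /
#' g)` with `g` in `{base^-2, ..., base^2} * anchor` for the default 5-kernel,
#' base-2 ladder. A single-bandwidth RBF and the linear kernel
#' `k(x, y) = <x, y>` (for which MMD^2 collapses to the squared mean
#' difference) are also available.
#'
#' @param kind `"rbf_multi"`, `"rbf_single"` or `"linear"`.
#' @param n_kernels Ladder length (RBF kinds; default 5).
#' @param ladder_base Geometric ratio between adjacent bandwidths (default 2).
#' @param anchor `"median_pairwise"` (median of pooled pairwise squared
#'   distances, recomputed per batch) or a fixed positive number.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf_multi", "rbf_single", "linear"),
                        n_kernels = 5L, ladder_base = 2,
                        anchor = "median_pairwise") {
  kind <- match.arg(kind)
  if (kind == "rbf_single") n_kernels <- 1L
  n_kernels <- as.integer(n_kernels)
  if (n_kernels < 1L) stopf("n_kernels must be >= 1", class = "msmda_config_error")
  if (!identical(anchor, "median_pairwise")) {
    anchor <- as.numeric(anchor)
    if (!is.finite(anchor) || anchor <= 0) {
      stopf("fixed bandwidth anchor must be positive", class = "msmda_config_error")
    }
  }
  structure(list(kind = kind, n_kernels = n_kernels,
                 ladder_base = as.numeric(ladder_base), anchor = anchor),
            class = "kernel_spec")
}

pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D, 0)
}

kernel_bandwidths <- function(spec, D_AA, D_BB, D_AB) {
  if (identical(spec$anchor, "median_pairwise")) {
    m <- nrow(D_AA)
    pooled <- c(D_AA[upper.tri(D_AA)], D_BB[upper.tri(D_BB)], as.vector(D_AB))
    anchor <- stats::median(pooled)
    if (!is.finite(anchor) || anchor <= 0) {
      rlang::warn("degenerate batch: all pooled points identical; falling back to bandwidth 1",
                  class = "msmda_degenerate_bandwidth")
      anchor <- 1
    }
  } else {
    anchor <- spec$anchor
  }
  k <- spec$n_kernels
  anchor * spec$ladder_base^(seq_len(k) - (k + 1) / 2)
}

# MMD^2 between equal-size batches, with analytic gradients w.r.t. the rows
# of A and B. Biased V-statistic by default; the unbiased U-statistic drops
# the diagonal of the within-batch terms. The median bandwidth anchor is
# treated as a constant (stop-gradient), the convention of this model family.
mmd_squared_grad <- function(A, B, spec, estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  A <- as.matrix(A); B <- as.matrix(B)
  m <- nrow(A)
  if (nrow(B) != m) {
    stopf("MMD estimator needs equal batch sizes (got %d, %d)", m, nrow(B),
          class = "msmda_contract_error")
  }

  if (spec$kind == "linear") {
    mu_a <- colMeans(A); mu_b <- colMeans(B)
    if (estimator == "biased") {
      K_AA <- tcrossprod(A); K_BB <- tcrossprod(B); K_AB <- tcrossprod(A, B)
      value <- mean(K_AA) + mean(K_BB) - 2 * mean(K_AB)
      grad_A <- matrix(2 / m * (mu_a - mu_b), m, ncol(A), byrow = TRUE)
      grad_B <- matrix(2 / m * (mu_b - mu_a), m, ncol(A), byrow = TRUE)
    } else {
      K_AA <- tcrossprod(A); K_BB <- tcrossprod(B); K_AB <- tcrossprod(A, B)
      off <- function(K) (sum(K) - sum(diag(K))) / (m * (m - 1))
      value <- off(K_AA) + off(K_BB) - 2 * mean(K_AB)
      sum_a <- colSums(A); sum_b <- colSums(B)
      grad_A <- (2 / (m * (m - 1))) *
        sweep(-A, 2L, sum_a, "+") - matrix(2 / m * mu_b, m, ncol(A), byrow = TRUE)
      grad_B <- (2 / (m * (m - 1))) *
        sweep(-B, 2L, sum_b, "+") - matrix(2 / m * mu_a, m, ncol(B), byrow = TRUE)
    }
    if (estimator == "biased") value <- max(value, 0)
    return(list(value = value, grad_A = grad_A, grad_B = grad_B))
  }

  D_AA <- pairwise_sqdist(A, A)
  D_BB <- pairwise_sqdist(B, B)
  D_AB <- pairwise_sqdist(A, B)
  gammas <- kernel_bandwidths(spec, D_AA, D_BB, D_AB)

  value <- 0
  grad_A <- matrix(0, m, ncol(A))
  grad_B <- matrix(0, m, ncol(B))
  for (g in gammas) {
    K_AA <- exp(-D_AA / g); K_BB <- exp(-D_BB / g); K_AB <- exp(-D_AB / g)
    if (estimator == "biased") {
      value <- value + mean(K_AA) + mean(K_BB) - 2 * mean(K_AB)
      # d/da_i of (1/m^2) sum K_AA: 2/m^2 * sum_j k'(a_i,a_j)(a_i-a_j)(-2/g)
      W_AA <- K_AA * (-2 / g) / m^2
      W_BB <- K_BB * (-2 / g) / m^2
      W_AB <- K_AB * (-2 / g) / m^2
      grad_A <- grad_A +
        2 * (rowSums(W_AA) * A - W_AA %*% A) -
        2 * (rowSums(W_AB) * A - W_AB %*% B)
      grad_B <- grad_B +
        2 * (rowSums(W_BB) * B - W_BB %*% B) -
        2 * (colSums(W_AB) * B - crossprod(W_AB, A))
    } else {
      diag(K_AA) <- 0; diag(K_BB) <- 0
      denom <- m * (m - 1)
      value <- value + sum(K_AA) / denom + sum(K_BB) / denom - 2 * mean(K_AB)
      W_AA <- K_AA * (-2 / g) / denom
      W_BB <- K_BB * (-2 / g) / denom
      W_AB <- K_AB * (-2 / g) / m^2
      grad_A <- grad_A +
        2 * (rowSums(W_AA) * A - W_AA %*% A) -
        2 * (rowSums(W_AB) * A - W_AB %*% B)
      grad_B <- grad_B +
        2 * (rowSums(W_BB) * B - W_BB %*% B) -
        2 * (colSums(W_AB) * B - crossprod(W_AB, A))
    }
  }
  k <- length(gammas)
  value <- value / k
  if (estimator == "biased") value <- max(value, 0)
  list(value = value, grad_A = grad_A / k, grad_B = grad_B / k)
}

#' Squared maximum mean discrepancy between two batches
#'
#' Estimates `MMD^2 = || mean_k_embedding(A) - mean_k_embedding(B) ||^2` in
#' the kernel's RKHS from equal-size batches. The default biased V-statistic
#' is `mean k(a_i, a_j) + mean k(b_i, b_j) - 2 mean k(a_i, b_j)`; negative
#' rounding noise is clipped at zero. For multi-kernel specs the estimate is
#' the average over the bandwidth ladder.
#'
#' @param A,B Numeric matrices `m x d` with equal `m`.
#' @param spec A [kernel_spec()].
#' @param estimator `"biased"` (V-statistic, default) or `"unbiased"`
#'   (U-statistic on the within-batch terms).
#' @return Scalar; non-negative for the biased estimator (negative rounding
#'   noise clipped at zero). The unbiased estimate may legitimately fall
#'   below zero for close distributions and is returned unclipped.
#' @examples
#' mmd_squared(matrix(0), matrix(1), kernel_spec("linear"))  # 1
#' @export
mmd_squared <- function(A, B, spec = kernel_spec(),
                        estimator = c("biased", "unbiased")) {
  mmd_squared_grad(A, B, spec, match.arg(estimator))$value
}

#' Correlation-alignment (CORAL) loss between two batches
#'
#' `||C_A - C_B||_F^2 / (4 d^2)` where `C` is the sample covariance — the
#' standard second-order alignment loss, used by the single-branch baselines
#' as an alternative to MMD. Gradients are returned for training.
#'
#' @param A,B Numeric matrices `m x d` (`m >= 2`).
#' @return Non-negative scalar (via [coral_loss_grad()]'s `value`).
#' @export
coral_loss <- function(A, B) {
  coral_loss_grad(A, B)$value
}

coral_loss_grad <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d <- ncol(A)
  m_a <- nrow(A); m_b <- nrow(B)
  if (m_a < 2L || m_b < 2L) {
    stopf("CORAL needs >= 2 rows per batch", class = "msmda_contract_error")
  }
  Ac <- sweep(A, 2L, colMeans(A), "-")
  Bc <- sweep(B, 2L, colMeans(B), "-")
  C_A <- crossprod(Ac) / (m_a - 1)
  C_B <- crossprod(Bc) / (m_b - 1)
  Dlt <- C_A - C_B
  value <- sum(Dlt^2) / (4 * d^2)
  # dL/dC_A = Dlt / (2 d^2); chain through C = Xc'Xc/(m-1) and centring
  G_A <- (Ac %*% Dlt) / (d^2 * (m_a - 1))
  G_B <- -(Bc %*% Dlt) / (d^2 * (m_b - 1))
  G_A <- sweep(G_A, 2L, colMeans(G_A), "-")
  G_B <- sweep(G_B, 2L, colMeans(G_B), "-")
  list(value = value, grad_A = G_A, grad_B = G_B)
}

# Numerically stable softmax and log-softmax on logit rows.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

log_softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  Z - log(rowSums(exp(Z)))
}

#' Summed per-branch cross-entropy classification loss
#'
#' Each branch's classifier is scored with mean cross-entropy between the
#' log-softmax of its source logits and the integer labels; branch terms are
#' summed (one supervised term per source domain).
#'
#' @param logits_list List of `m_i x C` logit matrices, one per branch.
#' @param labels_list List of integer label vectors (0-based), one per branch.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(logits_list, labels_list) {
  if (length(logits_list) != length(labels_list) || length(logits_list) < 1L) {
    stopf("need one label vector per branch", class = "msmda_contract_error")
  }
  total <- 0
  for (i in seq_along(logits_list)) {
    Z <- as.matrix(logits_list[[i]])
    y <- as.integer(labels_list[[i]])
    if (any(y < 0L) || any(y >= ncol(Z))) {
      stopf("labels outside [0, %d)", ncol(Z), class = "msmda_contract_error")
    }
    LS <- log_softmax_rows(Z)
    total <- total - mean(LS[cbind(seq_len(nrow(Z)), y + 1L)])
  }
  total
}

# Gradient of one branch's mean cross-entropy w.r.t. its logits.
cross_entropy_grad <- function(Z, y) {
  P <- softmax_rows(Z)
  P[cbind(seq_len(nrow(Z)), y + 1L)] <- P[cbind(seq_len(nrow(Z)), y + 1L)] - 1
  P / nrow(Z)
}

#' L1 discrepancy between the branches' target predictions
#'
#' Sum over **ordered** pairs `i != j` of the mean absolute difference
#' between branch `i`'s and branch `j`'s target softmax outputs (mean over
#' all `m * C` entries). With one branch the pair set is empty and the loss
#' is 0. Minimising it makes the `N` classifiers agree on the unlabelled
#' target, shrinking the variance of their averaged prediction.
#'
#' @param probs_list List of `m x C` softmax matrices (rows sum to 1).
#' @return Non-negative scalar.
#' @export
discrepancy_loss <- function(probs_list) {
  discrepancy_loss_grad(probs_list)$value
}

discrepancy_loss_grad <- function(probs_list) {
  N <- length(probs_list)
  if (N < 1L) stopf("need >= 1 branch", class = "msmda_contract_error")
  dims <- vapply(probs_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("branch prediction matrices must share one shape",
          class = "msmda_contract_error")
  }
  for (P in probs_list) {
    if (any(abs(rowSums(P) - 1) > 1e-6)) {
      stopf("prediction rows must sum to 1", class = "msmda_contract_error")
    }
  }
  m <- dims[1, 1]; C <- dims[2, 1]
  value <- 0
  grads <- lapply(probs_list, function(P) matrix(0, m, C))
  if (N > 1L) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        if (i == j) next
        Dlt <- probs_list[[i]] - probs_list[[j]]
        value <- value + mean(abs(Dlt))
        S <- sign(Dlt) / (m * C)
        grads[[i]] <- grads[[i]] + S
        grads[[j]] <- grads[[j]] - S
      }
    }
  }
  list(value = value, grads = grads)
}

# Backprop an upstream gradient on softmax probabilities to the logits.
softmax_backward <- function(P, G) {
  P * (G - rowSums(G * P))
}

#' Dynamic weight schedule for the alignment loss
#'
#' `alpha(p) = 2 / (1 + exp(-10 p)) - 1` with progress
#' `p = step / total_steps`: zero at the start (train the classifiers first),
#' ramping smoothly toward ~1 (then align distributions and converge the
#' classifiers).
#'
#' @param step Current step, `0 <= step <= total_steps`.
#' @param total_steps Total step count (>= 1).
#' @return Scalar in `[0, 1)`; strictly increasing in `step`.
#' @export
alpha_schedule <- function(step, total_steps) {
  if (total_steps < 1L) stopf("total_steps must be >= 1", class = "msmda_config_error")
  if (any(step < 0) || any(step > total_steps)) {
    stopf("step must lie in [0, total_steps]", class = "msmda_contract_error")
  }
  p <- step / total_steps
  2 / (1 + exp(-10 * p)) - 1
}

#' Loss-weight policy
#'
#' Weighting of the three terms of the total loss
#' `L = L_cls + alpha * L_mmd + beta_eff * L_disc`. `alpha` comes from
#' [alpha_schedule()] (optionally scaled by `alpha_scale`, which ablations
#' set to 0). The discrepancy weight has two published readings: a constant
#' `beta_weight`, or `beta_weight * alpha` ("0.01 times the MMD-loss
#' coefficient"); both are available, the latter is the default. The
#' discrepancy term can additionally be disabled for the first
#' `disc_start_fraction` of training.
#'
#' @param beta_weight Base discrepancy weight (default 0.01).
#' @param beta_mode `"times_alpha"` (default) or `"constant"`.
#' @param disc_start_fraction In `[0, 1]`: the discrepancy term is zeroed
#'   while `step < disc_start_fraction * total_steps` (default 0 — active
#'   for the whole of training, the best-performing published setting).
#' @param alpha_scale Multiplier on the scheduled alpha (default 1; 0 turns
#'   the alignment term off for ablations).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(beta_weight = 0.01,
                         beta_mode = c("times_alpha", "constant"),
                         disc_start_fraction = 0, alpha_scale = 1) {
  beta_mode <- match.arg(beta_mode)
  if (beta_weight < 0 || alpha_scale < 0) {
    stopf("weights must be >= 0", class = "msmda_config_error")
  }
  if (disc_start_fraction < 0 || disc_start_fraction > 1) {
    stopf("disc_start_fraction must lie in [0, 1]", class = "msmda_config_error")
  }
  structure(list(beta_weight = as.numeric(beta_weight), beta_mode = beta_mode,
                 disc_start_fraction = as.numeric(disc_start_fraction),
                 alpha_scale = as.numeric(alpha_scale)),
            class = "loss_weights")
}

# Effective (alpha, beta) at a given step under a loss_weights policy.
effective_weights <- function(weights, step, total_steps) {
  alpha <- weights$alpha_scale * alpha_schedule(step, total_steps)
  beta <- if (weights$beta_mode == "times_alpha") {
    weights$beta_weight * alpha_schedule(step, total_steps)
  } else {
    weights$beta_weight
  }
  if (step < weights$disc_start_fraction * total_steps) beta <- 0
  list(alpha = alpha, beta = beta)
}

#' Combine the loss components into the training objective
#'
#' `L = L_cls + alpha * L_mmd + beta_eff * L_disc`, with `alpha` from the
#' schedule and `beta_eff` from the [loss_weights()] policy.
#'
#' @param cls,mmd_sum,disc Finite loss components (the MMD term is the sum
#'   over branches).
#' @param weights A [loss_weights()].
#' @param step,total_steps Training progress for the schedule.
#' @return List: `total`, `cls`, `mmd`, `disc`, `alpha`, `beta_eff`.
#' @export
total_loss <- function(cls, mmd_sum, disc, weights, step, total_steps) {
  if (!all(is.finite(c(cls, mmd_sum, disc)))) {
    stopf("loss components must be finite", class = "msmda_training_error")
  }
  w <- effective_weights(weights, step, total_steps)
  list(total = cls + w$alpha * mmd_sum + w$beta * disc,
       cls = cls, mmd = mmd_sum, disc = disc,
       alpha = w$alpha, beta_eff = w$beta)
}
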