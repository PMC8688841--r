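#' Training configuration
#'
#' Defaults follow the published recipe: Adam with initial learning rate
#' 0.01, 200 epochs, batch size 256 (one batch of `m` is drawn from every
#' domain each iteration), multi-kernel RBF MMD alignment, discrepancy
#' weight 0.01 times the alignment coefficient, applied over the whole of
#' training. Scaled-down studies shrink `epochs`/`batch_size` and the model
#' widths, not the recipe.
#'
#' @param epochs Training epochs (default 200).
#' @param batch_size Mini-batch size `m` per domain (default 256).
#' @param learning_rate Adam initial learning rate (default 0.01).
#' @param seed Master seed driving init and the per-domain samplers.
#' @param weights A [loss_weights()] policy.
#' @param kernel A [kernel_spec()] for the MMD alignment.
#' @param alignment `"mmd"`, `"coral"` or `"none"` (the alignment term used
#'   between each branch's source and target features).
#' @param mmd_estimator `"biased"` or `"unbiased"`.
#' @param alpha_progress `"global"` (progress = global step / total steps,
#'   default) or `"epoch"` (progress advances once per epoch).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 256L, learning_rate = 0.01,
                         seed = 1L, weights = loss_weights(),
                         kernel = kernel_spec(),
                         alignment = c("mmd", "coral", "none"),
                         mmd_estimator = c("biased", "unbiased"),
                         alpha_progress = c("global", "epoch")) {
  alignment <- match.arg(alignment)
  cfg <- list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = as.numeric(learning_rate), seed = as.integer(seed),
    weights = weights, kernel = kernel, alignment = alignment,
    mmd_estimator = match.arg(mmd_estimator),
    alpha_progress = match.arg(alpha_progress)
  )
  if (cfg$epochs < 1L || cfg$batch_size < 1L) {
    stopf("epochs and batch_size must be >= 1", class = "msmda_config_error")
  }
  if (cfg$learning_rate <= 0) {
    stopf("learning_rate must be > 0", class = "msmda_config_error")
  }
  structure(cfg, class = "train_config")
}

# One domain's batch stream: shuffled, exhaustive per permutation, refilled
# with a fresh permutation when exhausted (wraparound for m > n).
domain_sampler <- function(n, m, seed) {
  if (n < 1L) stopf("empty domain", class = "msmda_config_error")
  rng <- derive_seed(seed, 0L)
  buffer <- integer(0)
  draws <- 0L
  function() {
    while (length(buffer) < m) {
      draws <<- draws + 1L
      perm <- with_seed(derive_seed(rng, draws), sample.int(n))
      buffer <<- c(buffer, perm)
    }
    out <- buffer[seq_len(m)]
    buffer <<- buffer[-seq_len(m)]
    out
  }
}

#' Create per-domain batch samplers for a task
#'
#' Every domain (each source and the target) gets an independent stream of
#' shuffled size-`m` index batches: within a stream each permutation of the
#' domain is exhausted before reshuffling, and batches wrap around when
#' `m` exceeds the domain size. Streams are deterministic given `seed` and
#' independent across domains.
#'
#' @param task A [multisource_task()].
#' @param m Batch size.
#' @param seed Master seed.
#' @return List with `sources` (list of sampler functions, call to get the
#'   next index batch) and `target` (sampler function).
#' @export
make_samplers <- function(task, m, seed) {
  sources <- lapply(seq_along(task$sources), function(i) {
    domain_sampler(nrow(task$sources[[i]]$features), m, derive_seed(seed, i))
  })
  target <- domain_sampler(nrow(task$target$features), m,
                           derive_seed(seed, length(task$sources) + 1L))
  list(sources = sources, target = target)
}

zero_like_params <- function(params) {
  zl <- function(layers) lapply(layers, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
  })
  list(cfe = zl(params$cfe), dsfe = zl(params$dsfe), dsc = zl(params$dsc))
}

# Backprop an upstream gradient G on the CFE output of one cached forward
# pass; accumulates layer grads into `acc` (same layout as params$cfe) and
# returns the updated accumulator.
cfe_backward <- function(params, cache, G, acc) {
  slope <- params$config$leaky_slope
  for (l in rev(seq_along(params$cfe))) {
    G <- G * leaky_relu_grad(cache$a[[l]], slope)
    acc[[l]]$W <- acc[[l]]$W + crossprod(cache$h[[l]], G)
    acc[[l]]$b <- acc[[l]]$b + colSums(G)
    if (l > 1L) G <- G %*% t(params$cfe[[l]]$W)
  }
  acc
}

# Loss components and parameter gradients for one optimisation step.
# `align` treats the bandwidth anchor as a constant; gradients of the three
# terms are combined with the step's effective (alpha, beta).
step_loss_grads <- function(params, source_X, source_y, target_X, tcfg,
                            alpha_step, total_steps) {
  cfg <- params$config
  N <- cfg$n_sources
  slope <- cfg$leaky_slope
  m <- nrow(target_X)

  caches_s <- lapply(source_X, function(X) cfe_forward_cached(params, X))
  cache_t <- cfe_forward_cached(params, target_X)
  q_t <- cache_t$q

  br_s <- lapply(seq_len(N), function(i) branch_forward_cached(params, caches_s[[i]]$q, i))
  br_t <- lapply(seq_len(N), function(i) branch_forward_cached(params, q_t, i))

  # components
  cls <- classification_loss(lapply(br_s, `[[`, "z"), source_y)
  align <- lapply(seq_len(N), function(i) {
    switch(tcfg$alignment,
      mmd = mmd_squared_grad(br_s[[i]]$r, br_t[[i]]$r, tcfg$kernel,
                             tcfg$mmd_estimator),
      coral = coral_loss_grad(br_s[[i]]$r, br_t[[i]]$r),
      none = list(value = 0,
                  grad_A = matrix(0, m, cfg$dsfe_out_dim),
                  grad_B = matrix(0, m, cfg$dsfe_out_dim))
    )
  })
  mmd_sum <- sum(vapply(align, `[[`, numeric(1), "value"))
  probs_t <- lapply(br_t, function(b) softmax_rows(b$z))
  disc <- discrepancy_loss_grad(probs_t)

  rec <- total_loss(cls, mmd_sum, disc$value, tcfg$weights, alpha_step, total_steps)
  alpha <- rec$alpha; beta <- rec$beta_eff

  grads <- zero_like_params(params)
  G_qt_total <- matrix(0, m, cfg$cfe_out_dim)

  for (i in seq_len(N)) {
    # classifier head gradients
    G_zS <- cross_entropy_grad(br_s[[i]]$z, source_y[[i]])
    G_zT <- if (beta > 0) {
      beta * softmax_backward(probs_t[[i]], disc$grads[[i]])
    } else {
      matrix(0, m, cfg$n_classes)
    }
    grads$dsc[[i]]$W <- crossprod(br_s[[i]]$r, G_zS) + crossprod(br_t[[i]]$r, G_zT)
    grads$dsc[[i]]$b <- colSums(G_zS) + colSums(G_zT)

    # into domain-specific features (classifier path + alignment path)
    G_rS <- G_zS %*% t(params$dsc[[i]]$W) + alpha * align[[i]]$grad_A
    G_rT <- G_zT %*% t(params$dsc[[i]]$W) + alpha * align[[i]]$grad_B

    G_uS <- G_rS * leaky_relu_grad(br_s[[i]]$u, slope)
    G_uT <- G_rT * leaky_relu_grad(br_t[[i]]$u, slope)
    grads$dsfe[[i]]$W <- crossprod(caches_s[[i]]$q, G_uS) + crossprod(q_t, G_uT)
    grads$dsfe[[i]]$b <- colSums(G_uS) + colSums(G_uT)

    G_qS <- G_uS %*% t(params$dsfe[[i]]$W)
    grads$cfe <- cfe_backward(params, caches_s[[i]], G_qS, grads$cfe)
    G_qt_total <- G_qt_total + G_uT %*% t(params$dsfe[[i]]$W)
  }
  grads$cfe <- cfe_backward(params, cache_t, G_qt_total, grads$cfe)

  list(loss = rec, grads = grads)
}

adam_state <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_update <- function(theta, grad, state, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + state$eps), state = state)
}

#' Train an MS-MDA model on a multi-source task
#'
#' Implements the paired mini-batch optimisation loop: every iteration draws
#' `m` samples from each source domain and `m` from the (unlabelled) target,
#' runs the shared extractor and all branches, and takes one Adam step on
#' `L = L_cls + alpha * L_mmd + beta_eff * L_disc`. One epoch makes
#' `ceil(max_domain_size / m)` iterations, so every domain is fully visited
#' each epoch. Target labels are never read: they are stripped before the
#' loop starts.
#'
#' @param task A [multisource_task()].
#' @param mcfg A [model_config()] with `n_sources = length(task$sources)`;
#'   if `NULL`, one is built from the task with default widths.
#' @param tcfg A [train_config()].
#' @param eval_labels Optional integer vector of target labels used only for
#'   a per-epoch accuracy trace (never for training). Default `NULL`.
#' @return An object of class `msmda_fit`: `params`, `model_config`,
#'   `train_config`, `history` (tibble of per-step loss components and
#'   weights), `epoch_accuracy` (tibble, if `eval_labels` given), `task_id`.
#' @export
train_msmda <- function(task, mcfg = NULL, tcfg = train_config(),
                        eval_labels = NULL) {
  if (is.null(mcfg)) {
    mcfg <- model_config(input_dim = ncol(task$target$features),
                         n_classes = task$n_classes,
                         n_sources = length(task$sources))
  }
  if (mcfg$n_sources != length(task$sources)) {
    stopf("model has %d branches for %d sources", mcfg$n_sources,
          length(task$sources), class = "msmda_contract_error")
  }
  if (mcfg$input_dim != ncol(task$target$features)) {
    stopf("model input_dim %d != task n_features %d", mcfg$input_dim,
          ncol(task$target$features), class = "msmda_contract_error")
  }
  for (s in task$sources) validate_domain(s, task$n_classes)

  # mask the target: the training path sees features only
  target_X <- task$target$features
  m <- tcfg$batch_size
  sizes <- c(vapply(task$sources, function(d) nrow(d$features), integer(1)),
             nrow(target_X))
  steps_per_epoch <- as.integer(ceiling(max(sizes) / m))
  total_steps <- tcfg$epochs * steps_per_epoch

  params <- init_model(mcfg, seed = derive_seed(tcfg$seed, 101L))
  samplers <- make_samplers(task, m, derive_seed(tcfg$seed, 202L))
  theta <- params_to_vector(params)
  opt <- adam_state(length(theta))

  hist <- vector("list", total_steps)
  acc_trace <- if (!is.null(eval_labels)) numeric(tcfg$epochs) else NULL

  for (t in seq_len(total_steps)) {
    epoch <- ((t - 1L) %/% steps_per_epoch) + 1L
    alpha_step <- if (tcfg$alpha_progress == "global") {
      t - 1L
    } else {
      (epoch - 1L) * steps_per_epoch
    }
    src_idx <- lapply(samplers$sources, function(f) f())
    tgt_idx <- samplers$target()
    source_X <- lapply(seq_along(task$sources), function(i) {
      task$sources[[i]]$features[src_idx[[i]], , drop = FALSE]
    })
    source_y <- lapply(seq_along(task$sources), function(i) {
      task$sources[[i]]$labels[src_idx[[i]]]
    })
    sg <- step_loss_grads(params, source_X, source_y,
                          target_X[tgt_idx, , drop = FALSE],
                          tcfg, alpha_step, total_steps)
    if (!is.finite(sg$loss$total)) {
      stopf("training diverged at step %d (non-finite loss)", t,
            class = "msmda_training_error")
    }
    gvec <- params_to_vector(sg$grads)
    upd <- adam_update(theta, gvec, opt, tcfg$learning_rate)
    theta <- upd$theta; opt <- upd$state
    params <- vector_to_params(theta, params)

    hist[[t]] <- tibble::tibble(
      step = t, epoch = epoch,
      loss_total = sg$loss$total, loss_cls = sg$loss$cls,
      loss_mmd = sg$loss$mmd, loss_disc = sg$loss$disc,
      alpha = sg$loss$alpha, beta_eff = sg$loss$beta_eff
    )
    if (!is.null(acc_trace) && t %% steps_per_epoch == 0L) {
      pr <- predict_params(params, target_X)
      acc_trace[epoch] <- mean(pr$labels == eval_labels)
    }
  }

  fit <- structure(
    list(params = params, model_config = mcfg, train_config = tcfg,
         history = dplyr::bind_rows(hist),
         epoch_accuracy = if (is.null(acc_trace)) NULL else {
           tibble::tibble(epoch = seq_len(tcfg$epochs), accuracy = acc_trace)
         },
         task_id = task$task_id, steps_per_epoch = steps_per_epoch),
    class = "msmda_fit"
  )
  fit
}

#' @export
print.msmda_fit <- function(x, ...) {
  cat(sprintf(
    "<msmda_fit '%s': N=%d branches, %d epochs (%d steps), final loss %.4f>\n",
    x$task_id, x$model_config$n_sources, x$train_config$epochs,
    nrow(x$history), x$history$loss_total[nrow(x$history)]
  ))
  invisible(x)
}

# Averaged multi-branch prediction from raw params.
predict_params <- function(params, X) {
  q <- cfe_forward(params, X)
  N <- params$config$n_sources
  probs <- matrix(0, nrow(X), params$config$n_classes)
  for (i in seq_len(N)) {
    probs <- probs + softmax_rows(branch_forward_cached(params, q, i)$z)
  }
  probs <- probs / N
  list(probs = probs, labels = max.col(probs, ties.method = "first") - 1L)
}

#' Predict target labels with a trained model
#'
#' Each branch's classifier produces a softmax distribution; the model's
#' prediction is the arithmetic mean of the `N` branch distributions, with
#' the class of the (lowest-index on ties) largest averaged probability.
#'
#' @param object An `msmda_fit`.
#' @param newdata Numeric matrix `n x input_dim`.
#' @param type `"prob"` for the averaged probability matrix, `"class"` for
#'   0-based predicted labels, `"both"` (default) for a list of the two.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.msmda_fit <- function(object, newdata,
                              type = c("both", "prob", "class"), ...) {
  type <- match.arg(type)
  out <- predict_params(object$params, as.matrix(newdata))
  switch(type, both = out, prob = out$probs, class = out$labels)
}

#' Target-domain accuracy of a trained model
#'
#' @param fit An `msmda_fit` (or raw `model_params`).
#' @param target A labelled [domain_dataset()].
#' @return Fraction of correct argmax predictions, in `[0, 1]`.
#' @export
evaluate_accuracy <- function(fit, target) {
  if (is.null(target$labels)) {
    stopf("target domain has no labels to evaluate against",
          class = "msmda_contract_error")
  }
  params <- if (inherits(fit, "msmda_fit")) fit$params else fit
  pr <- predict_params(params, target$features)
  mean(pr$labels == target$labels)
}

#' Extract per-branch penultimate-layer embeddings
#'
#' Dumps each branch's domain-specific (DSFE) features for a data matrix —
#' the representation external visualisation tools (e.g. t-SNE) consume.
#'
#' @param fit An `msmda_fit`.
#' @param X Numeric matrix `n x input_dim`.
#' @return Tibble with columns `branch`, `row`, and `e1 .. e<dsfe_out_dim>`.
#' @export
extract_embeddings <- function(fit, X) {
  q <- cfe_forward(fit$params, as.matrix(X))
  purrr::map_dfr(seq_len(fit$model_config$n_sources), function(i) {
    r <- branch_forward_cached(fit$params, q, i)$r
    colnames(r) <- paste0("e", seq_len(ncol(r)))
    dplyr::bind_cols(tibble::tibble(branch = i, row = seq_len(nrow(r))),
                     tibble::as_tibble(r))
  })
}
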