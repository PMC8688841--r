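test_that("samplers are exhaustive per permutation, independent, and wrap around", {
  task <- small_task(n_domains = 3L, n_per_domain = 10L, seed = 5L,
                     n_electrodes = 2L, n_bands = 2L)
  sm <- make_samplers(task, m = 4L, seed = 7L)

  # wait for a fresh permutation boundary: 5 batches of 4 = 20 = 2 permutations
  drawn <- unlist(lapply(1:5, function(i) sm$sources[[1]]()))
  expect_length(drawn, 20L)
  expect_identical(sort(drawn[1:10]), 1:10)   # first permutation exhaustive
  expect_identical(sort(drawn[11:20]), 1:10)  # then reshuffled

  # independent streams across domains under one master seed
  sm2 <- make_samplers(task, m = 10L, seed = 7L)
  expect_false(identical(sm2$sources[[1]](), sm2$sources[[2]]()))

  # deterministic given the seed
  sm3 <- make_samplers(task, m = 4L, seed = 7L)
  expect_identical(sm3$sources[[1]](), drawn[1:4])

  # m > domain size: wraparound keeps batch size, covers the domain
  tiny <- multisource_task(
    list(domain_dataset(matrix(rnorm(3 * 4), 3), labels = c(0L, 1L, 2L),
                        domain_id = "t")),
    domain_dataset(matrix(rnorm(3 * 4), 3)), 3L
  )
  sw <- make_samplers(tiny, m = 7L, seed = 1L)
  b <- sw$sources[[1]]()
  expect_length(b, 7L)
  expect_identical(sort(unique(b)), 1:3)
  expect_identical(sort(b[1:3]), 1:3)  # each permutation exhausted in order
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(41)
  mcfg <- micro_model_config(n_sources = 2L)
  params <- init_model(mcfg, seed = 9L)
  m <- 5L
  sx <- lapply(1:2, function(i) matrix(rnorm(m * 6), m))
  sy <- lapply(1:2, function(i) sample(0:2, m, replace = TRUE))
  tx <- matrix(rnorm(m * 6), m)
  theta <- msmda:::params_to_vector(params)

  # fixed bandwidth anchor: the analytic gradient deliberately treats the
  # median heuristic as a constant, so the check pins the anchor
  cfgs <- list(
    mmd = train_config(alignment = "mmd",
                       kernel = kernel_spec("rbf_multi", anchor = 1.0)),
    linear = train_config(alignment = "mmd", kernel = kernel_spec("linear"),
                          mmd_estimator = "unbiased"),
    coral = train_config(alignment = "coral"),
    disc_only = train_config(alignment = "none",
                             weights = loss_weights(beta_weight = 0.5,
                                                    beta_mode = "constant"))
  )
  for (nm in names(cfgs)) {
    tcfg <- cfgs[[nm]]
    sg <- msmda:::step_loss_grads(params, sx, sy, tx, tcfg, 50, 100)
    gvec <- msmda:::params_to_vector(sg$grads)
    idx <- sort(sample(seq_along(theta), 25))
    fd <- vapply(idx, function(j) {
      h <- 1e-6
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      lp <- msmda:::step_loss_grads(msmda:::vector_to_params(tp, params),
                                    sx, sy, tx, tcfg, 50, 100)$loss$total
      lm <- msmda:::step_loss_grads(msmda:::vector_to_params(tm, params),
                                    sx, sy, tx, tcfg, 50, 100)$loss$total
      (lp - lm) / (2 * h)
    }, numeric(1))
    rel <- abs(fd - gvec[idx]) / pmax(abs(fd), 1e-5)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training is label-blind: garbage target labels leave weights identical", {
  task <- small_task(n_domains = 3L, n_per_domain = 40L, seed = 6L,
                     n_electrodes = 4L, n_bands = 2L)
  mcfg <- model_config(input_dim = 8L, cfe_hidden_dims = c(8L, 6L),
                       cfe_out_dim = 4L, dsfe_out_dim = 3L, n_classes = 3L,
                       n_sources = 2L)
  tcfg <- train_config(epochs = 3L, batch_size = 16L, seed = 3L)
  f1 <- train_msmda(task, mcfg, tcfg)
  task2 <- task
  task2$target$labels <- rep(99L, nrow(task2$target$features))
  f2 <- train_msmda(task2, mcfg, tcfg)
  expect_identical(flatten_params(f1), flatten_params(f2))
})

test_that("logged total loss is conserved from its components", {
  task <- small_task(n_domains = 2L, n_per_domain = 30L, seed = 7L,
                     n_electrodes = 3L, n_bands = 2L)
  mcfg <- model_config(input_dim = 6L, cfe_hidden_dims = c(6L, 5L),
                       cfe_out_dim = 4L, dsfe_out_dim = 3L, n_classes = 3L,
                       n_sources = 1L)
  fit <- train_msmda(task, mcfg, train_config(epochs = 4L, batch_size = 16L,
                                              seed = 2L))
  h <- fit$history
  recomputed <- h$loss_cls + h$alpha * h$loss_mmd + h$beta_eff * h$loss_disc
  expect_lt(max(abs(h$loss_total - recomputed)), 1e-9)
  # alpha starts at zero and increases
  expect_equal(h$alpha[1], 0)
  expect_true(all(diff(h$alpha) > 0))
})

test_that("an easy separable task trains to high target accuracy", {
  cfg <- synthetic_config(n_domains = 3L, n_per_domain = 120L,
                          class_separation = 2, domain_offset_scale = 0,
                          domain_gain_scale = 0, seed = 10L)
  task <- generate_multisource(cfg)
  fit <- train_msmda(task, tiny_model_config(n_sources = 2L),
                     fast_train_config(seed = 11L, epochs = 15L))
  expect_gte(evaluate_accuracy(fit, task$target), 0.95)
})

test_that("prediction averages branch softmaxes with lowest-index tie-break", {
  cfg <- micro_model_config(n_sources = 2L, n_classes = 2L)
  params <- init_model(cfg, seed = 3L)
  # overwrite classifier heads so branch softmaxes are known exactly:
  # with r fixed, logits = b, so softmax(b) is the branch distribution
  params$dsfe <- lapply(params$dsfe, function(l) list(W = l$W * 0, b = l$b * 0))
  params$dsc[[1]] <- list(W = matrix(0, 3, 2), b = log(c(0.8, 0.2)))
  params$dsc[[2]] <- list(W = matrix(0, 3, 2), b = log(c(0.4, 0.6)))
  pr <- msmda:::predict_params(params, matrix(rnorm(6), 1, 6))
  expect_equal(pr$probs, matrix(c(0.6, 0.4), 1, 2))
  expect_identical(pr$labels, 0L)

  # identical branches: average equals any single branch
  params$dsc[[2]] <- params$dsc[[1]]
  pr2 <- msmda:::predict_params(params, matrix(rnorm(6), 1, 6))
  expect_equal(pr2$probs, matrix(c(0.8, 0.2), 1, 2))

  # exact tie -> class 0
  params$dsc[[1]] <- list(W = matrix(0, 3, 2), b = c(0, 0))
  params$dsc[[2]] <- params$dsc[[1]]
  pr3 <- msmda:::predict_params(params, matrix(rnorm(6), 1, 6))
  expect_equal(pr3$probs, matrix(0.5, 1, 2))
  expect_identical(pr3$labels, 0L)

  # probability rows always sum to one
  big <- init_model(micro_model_config(n_sources = 3L), seed = 12L)
  prb <- msmda:::predict_params(big, matrix(rnorm(20 * 6), 20))
  expect_lt(max(abs(rowSums(prb$probs) - 1)), 1e-6)
})

test_that("accuracy evaluation counts argmax agreement", {
  cfg <- micro_model_config(n_sources = 1L, n_classes = 2L)
  params <- init_model(cfg, seed = 5L)
  X <- matrix(rnorm(4 * 6), 4)
  pred <- msmda:::predict_params(params, X)$labels
  d_all <- domain_dataset(X, labels = pred)
  expect_equal(evaluate_accuracy(params, d_all), 1)
  d_none <- domain_dataset(X, labels = 1L - pred)
  expect_equal(evaluate_accuracy(params, d_none), 0)
  d_three <- domain_dataset(X, labels = c(pred[1:3], 1L - pred[4]))
  expect_equal(evaluate_accuracy(params, d_three), 0.75)
  expect_error(evaluate_accuracy(params, domain_dataset(X)),
               class = "msmda_contract_error")
})

test_that("epoch accuracy trace is recorded when evaluation labels are supplied", {
  task <- small_task(n_domains = 2L, n_per_domain = 30L, seed = 9L,
                     n_electrodes = 3L, n_bands = 2L)
  mcfg <- model_config(input_dim = 6L, cfe_hidden_dims = c(6L, 4L),
                       cfe_out_dim = 3L, dsfe_out_dim = 3L, n_classes = 3L,
                       n_sources = 1L)
  fit <- train_msmda(task, mcfg, train_config(epochs = 3L, batch_size = 16L,
                                              seed = 2L),
                     eval_labels = task$target$labels)
  expect_identical(nrow(fit$epoch_accuracy), 3L)
  expect_true(all(fit$epoch_accuracy$accuracy >= 0 &
                    fit$epoch_accuracy$accuracy <= 1))
})
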