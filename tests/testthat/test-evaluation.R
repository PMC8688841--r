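# shared scaled-down settings for harness-level tests
eval_mcfg <- function() {
  model_config(input_dim = 12L, cfe_hidden_dims = c(10L, 8L), cfe_out_dim = 6L,
               dsfe_out_dim = 4L, n_classes = 3L, n_sources = 1L)
}
eval_tcfg <- function(seed = 1L) {
  train_config(epochs = 3L, batch_size = 16L, seed = seed)
}
eval_coll <- function(S = 3L, K = 3L, seed = 2L) {
  generate_collection(synthetic_config(n_per_domain = 30L, n_electrodes = 4L,
                                       n_bands = 3L, seed = seed), S, K)
}

test_that("protocol runs emit one record per task with correct aggregation", {
  coll <- eval_coll()
  out <- run_protocol(coll, "cross_session", method_spec("msmda"),
                      eval_mcfg(), eval_tcfg())
  expect_identical(nrow(out$records), 3L)   # one per subject
  expect_true(all(out$records$accuracy >= 0 & out$records$accuracy <= 1))
  expect_equal(out$summary$mean_accuracy, mean(out$records$accuracy))
  expect_equal(out$summary$sd_accuracy, pop_sd(out$records$accuracy))

  # records are reproducible under the same seeds (paired comparisons)
  again <- run_protocol(coll, "cross_session", method_spec("msmda"),
                        eval_mcfg(), eval_tcfg())
  expect_identical(out$records, again$records)
})

test_that("a single run aggregates with zero spread", {
  coll <- eval_coll(S = 2L, K = 1L)
  out <- run_protocol(coll, "cross_subject", method_spec("msmda"),
                      eval_mcfg(), eval_tcfg())
  expect_identical(nrow(out$records), 1L)
  expect_equal(out$summary$sd_accuracy, 0)
})

test_that("single-branch baseline concatenates sources and flags the record", {
  task <- small_task(n_domains = 3L, n_per_domain = 30L, seed = 3L,
                     n_electrodes = 4L, n_bands = 3L)
  rec <- run_single_branch_baseline(task, "none", eval_mcfg(), eval_tcfg())
  expect_true(rec$combine_sources)
  expect_identical(rec$n_sources, 1L)

  ms <- run_method(task, method_spec("msmda"), eval_mcfg(), eval_tcfg())
  expect_false(ms$combine_sources)
  expect_identical(ms$n_sources, 2L)
})

test_that("msmda and the single-branch MMD baseline coincide exactly on one source", {
  task <- small_task(n_domains = 2L, n_per_domain = 40L, seed = 4L,
                     n_electrodes = 4L, n_bands = 3L)
  tcfg <- eval_tcfg(seed = 9L)
  tcfg$weights$beta_weight <- 0
  ms_t <- msmda:::apply_method(tcfg, method_spec("msmda", "mmd_multi",
                                                 use_disc = FALSE))
  sb_t <- msmda:::apply_method(tcfg, method_spec("single_branch", "mmd_multi"))
  mcfg <- eval_mcfg()
  f_ms <- train_msmda(task, mcfg, ms_t)
  f_sb <- train_msmda(combine_sources(task), mcfg, sb_t)
  expect_identical(flatten_params(f_ms), flatten_params(f_sb))
  expect_identical(evaluate_accuracy(f_ms, task$target),
                   evaluate_accuracy(f_sb, task$target))
})

test_that("ablation emits the four labelled variants with paired seeds", {
  task <- small_task(n_domains = 3L, n_per_domain = 30L, seed = 5L,
                     n_electrodes = 4L, n_bands = 3L)
  recs <- run_ablation(task, eval_mcfg(), eval_tcfg(), seeds = c(1L, 2L))
  expect_identical(nrow(recs), 8L)
  expect_setequal(unique(recs$variant),
                  c("full", "w/o MMD", "w/o disc", "w/o both"))
  expect_identical(as.integer(table(recs$seed)), c(4L, 4L))

  # ablating the MMD term removes it from every training step
  tv <- eval_tcfg(); tv$weights$alpha_scale <- 0; tv$alignment <- "none"
  fit <- train_msmda(task, eval_mcfg() |> (\(m) {
    m$n_sources <- 2L
    do.call(model_config, unclass(m))
  })(), tv)
  expect_true(all(fit$history$alpha == 0))
  expect_true(all(fit$history$alpha * fit$history$loss_mmd == 0))
})

test_that("source sweep restricts to the first k sources", {
  task <- small_task(n_domains = 4L, n_per_domain = 30L, seed = 6L,
                     n_electrodes = 4L, n_bands = 3L)
  recs <- run_source_sweep(task, max_sources = 3L, mcfg = eval_mcfg(),
                           tcfg = eval_tcfg())
  expect_identical(recs$k, 1:3)
  expect_identical(recs$n_sources, 1:3)

  # the k = 1 point equals a one-branch msmda run on the first source
  solo <- multisource_task(task$sources[1], task$target, task$n_classes,
                           task_id = sprintf("%s/k1", task$task_id))
  rec1 <- run_method(solo, method_spec("msmda"), eval_mcfg(), eval_tcfg())
  expect_equal(recs$accuracy[1], rec1$accuracy)

  expect_error(run_source_sweep(task, max_sources = 9L),
               class = "msmda_config_error")
})

test_that("normalization grid covers types x orders with invariance annotations", {
  task <- small_task(n_domains = 3L, n_per_domain = 30L, seed = 7L,
                     n_electrodes = 4L, n_bands = 3L)
  methods <- list(method_spec("msmda"), method_spec("single_branch"))
  recs <- run_normalization_grid(task, methods, mcfg = eval_mcfg(),
                                 tcfg = eval_tcfg())
  expect_identical(nrow(recs), 4L * 2L * 2L)
  # msmda never concatenates: all its cells are order-invariant
  ms <- recs[!recs$combine_sources, ]
  expect_true(all(ms$order_invariant))
  # combining methods: only the "none" rows are order-invariant
  sb <- recs[recs$combine_sources, ]
  expect_identical(sort(unique(sb$normalization[!sb$order_invariant])),
                   c("electrode_wise", "global_wise", "sample_wise"))
  # duplicated invariant rows carry identical accuracies across orders
  for (tp in unique(ms$normalization)) {
    pair <- ms$accuracy[ms$normalization == tp]
    expect_equal(pair[1], pair[2])
  }

  # none-type rows equal raw runs bit-for-bit under the same seed
  raw <- run_method(task, method_spec("msmda"), eval_mcfg(), eval_tcfg())
  none_row <- recs[recs$normalization == "none" & !recs$combine_sources, ][1, ]
  expect_identical(none_row$accuracy, raw$accuracy)
})
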