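test_that("MMD matches the naive double-sum oracle for every kernel kind", {
  set.seed(31)
  specs <- list(
    kernel_spec("linear"),
    kernel_spec("rbf_single", anchor = 0.7),
    kernel_spec("rbf_multi", anchor = 1.3)
  )
  for (rep in 1:8) {
    m <- sample(2:12, 1)
    d <- sample(1:6, 1)
    A <- matrix(rnorm(m * d), m)
    B <- matrix(rnorm(m * d, mean = 0.5), m)
    for (spec in specs) {
      kfn <- if (spec$kind == "linear") function(x, y) sum(x * y) else rbf_multi_fn(spec)
      for (est in c("biased", "unbiased")) {
        oracle <- mmd_oracle(A, B, kfn, est)
        if (est == "biased") oracle <- max(oracle, 0)
        expect_equal(mmd_squared(A, B, spec, est), oracle, tolerance = 1e-6)
      }
    }
  }
})

test_that("MMD of a batch with itself is zero and hand examples agree", {
  set.seed(32)
  A <- matrix(rnorm(10 * 3), 10)
  expect_lt(mmd_squared(A, A, kernel_spec("rbf_multi", anchor = 1)), 1e-9)
  expect_lt(mmd_squared(A, A, kernel_spec("linear")), 1e-9)

  # {0} vs {1} under the linear kernel: 0 + 1 - 0 = 1
  expect_equal(mmd_squared(matrix(0), matrix(1), kernel_spec("linear")), 1)

  expect_error(mmd_squared(A, A[1:3, ], kernel_spec("linear")),
               class = "msmda_contract_error")
})

test_that("linear-kernel MMD equals the squared mean difference", {
  set.seed(33)
  for (rep in 1:5) {
    A <- matrix(rnorm(8 * 4), 8)
    B <- matrix(rnorm(8 * 4, mean = 1), 8)
    expect_equal(mmd_squared(A, B, kernel_spec("linear")),
                 sum((colMeans(A) - colMeans(B))^2), tolerance = 1e-9)
  }
})

test_that("degenerate pooled batches fall back to a unit bandwidth with a warning", {
  A <- matrix(1, 4, 2)
  expect_warning(v <- mmd_squared(A, A, kernel_spec("rbf_multi")),
                 class = "msmda_degenerate_bandwidth")
  expect_equal(v, 0)
})

test_that("classification loss sums per-branch mean cross-entropies", {
  # uniform logits: ln(3)
  Z <- matrix(0, 4, 3)
  expect_equal(classification_loss(list(Z), list(rep(0L, 4))), log(3))
  # saturated correct logits: ~0
  Zs <- matrix(c(1000, 0, 0), 1, 3)
  expect_lt(classification_loss(list(Zs), list(0L)), 1e-9)
  # two identical branches double the loss
  set.seed(34)
  Zr <- matrix(rnorm(6 * 3), 6)
  y <- sample(0:2, 6, replace = TRUE)
  one <- classification_loss(list(Zr), list(y))
  expect_equal(classification_loss(list(Zr, Zr), list(y, y)), 2 * one)
  expect_error(classification_loss(list(Zr), list(rep(5L, 6))),
               class = "msmda_contract_error")
})

test_that("discrepancy loss counts ordered pairs and vanishes on agreement", {
  expect_equal(discrepancy_loss(list(matrix(c(0.3, 0.7), 1))), 0)  # N = 1

  p1 <- matrix(c(1, 0), 1)
  p2 <- matrix(c(0, 1), 1)
  # ordered pairs (1,2) and (2,1), each mean |diff| = 1 -> total 2
  expect_equal(discrepancy_loss(list(p1, p2)), 2)

  same <- matrix(c(0.2, 0.5, 0.3), 1)
  expect_equal(discrepancy_loss(list(same, same, same)), 0)

  # symmetric under branch permutation
  set.seed(35)
  ps <- lapply(1:3, function(i) {
    raw <- matrix(stats::runif(4 * 3), 4)
    raw / rowSums(raw)
  })
  expect_equal(discrepancy_loss(ps), discrepancy_loss(rev(ps)))

  # with two identical branches among three, only pairs with the distinct
  # branch contribute: 2x the distinct-pair value per identical copy
  d12 <- discrepancy_loss(list(ps[[1]], ps[[2]]))
  expect_equal(discrepancy_loss(list(ps[[1]], ps[[2]], ps[[2]])), 2 * d12)

  expect_error(discrepancy_loss(list(p1, matrix(c(2, 0), 1))),
               class = "msmda_contract_error")
})

test_that("alpha schedule follows the sigmoid ramp", {
  expect_equal(alpha_schedule(0, 100), 0)
  expect_equal(alpha_schedule(100, 100), 2 / (1 + exp(-10)) - 1)
  expect_equal(alpha_schedule(50, 100), 2 / (1 + exp(-5)) - 1)
  expect_equal(alpha_schedule(50, 100), 0.98661, tolerance = 1e-5)

  # strict monotonicity on a dense grid
  g <- alpha_schedule(0:10000, 10000)
  expect_true(all(diff(g) > 0))
  expect_error(alpha_schedule(5, 4), class = "msmda_contract_error")
})

test_that("total loss combines components under the weight policy", {
  w <- loss_weights(beta_weight = 0.01, beta_mode = "constant")
  # forced alpha ~ 1 at the very end of a long schedule
  out <- total_loss(1, 1, 1, w, 1e6, 1e6)
  expect_equal(out$total, 1 + (2 / (1 + exp(-10)) - 1) + 0.01, tolerance = 1e-4)

  # step 0: alpha = 0 kills MMD; times_alpha mode also kills disc
  w2 <- loss_weights(beta_weight = 0.01, beta_mode = "times_alpha")
  z <- total_loss(3, 10, 10, w2, 0, 100)
  expect_equal(z$total, 3)

  # disc start fraction gates the discrepancy term
  w3 <- loss_weights(beta_weight = 0.5, beta_mode = "constant",
                     disc_start_fraction = 0.2)
  early <- total_loss(1, 0, 4, w3, 10, 100)
  late <- total_loss(1, 0, 4, w3, 30, 100)
  expect_equal(early$beta_eff, 0)
  expect_equal(late$beta_eff, 0.5)
  expect_equal(late$total, 1 + 0.5 * 4)

  expect_error(total_loss(NaN, 0, 0, w, 1, 2), class = "msmda_training_error")
})

test_that("CORAL loss is zero for identical batches and positive otherwise", {
  set.seed(36)
  A <- matrix(rnorm(10 * 4), 10)
  expect_equal(coral_loss(A, A), 0)
  B <- matrix(rnorm(10 * 4, sd = 3), 10)
  expect_gt(coral_loss(A, B), 0)
  # matches the direct covariance-difference formula
  cv <- function(X) stats::cov(X)
  expect_equal(coral_loss(A, B), sum((cv(A) - cv(B))^2) / (4 * 16),
               tolerance = 1e-12)
})
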