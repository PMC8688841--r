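#' Normalize a feature matrix
#'
#' Implements the three EEG normalization strategies compared in the
#' normalization study, applied to a `trials x F` matrix of
#' differential-entropy features:
#'
#' * `electrode_wise` — standardize each **column** (one electrode-band pair)
#'   using that column's statistics across trials. The intuition: data
#'   acquired by the same electrode follow a common distribution, so each
#'   electrode-band channel is put on a common scale.
#' * `sample_wise` — standardize each **row** (one trial) using that row's
#'   statistics across its `F` entries.
#' * `global_wise` — standardize the whole matrix by its scalar mean and
#'   standard deviation.
#' * `none` — identity.
#'
#' The default statistic is the z-score with population (`1/n`) variance;
#' min-max rescaling to `[0, 1]` is available via `statistic = "minmax"`.
#' A labelled variant `electrode_pooled` pools the `n_bands` band columns of
#' each electrode into one standardization group.
#'
#' Zero-variance slices (constant column/row/matrix) are centred with the
#' divisor forced to 1, so constant input maps to zeros rather than `NaN`
#' (for min-max, a zero range likewise maps to 0).
#'
#' @param X Numeric matrix `n x F`, finite entries.
#' @param type One of `"none"`, `"electrode_wise"`, `"sample_wise"`,
#'   `"global_wise"`, `"electrode_pooled"`.
#' @param statistic `"zscore"` (default) or `"minmax"`.
#' @param n_bands Band count per electrode, used only by `electrode_pooled`.
#' @return Normalized matrix, same shape as `X`.
#' @examples
#' normalize_matrix(matrix(c(1, 3, 2, 4), 2, 2), "electrode_wise")
#' @export
normalize_matrix <- function(X,
                             type = c("none", "electrode_wise", "sample_wise",
                                      "global_wise", "electrode_pooled"),
                             statistic = c("zscore", "minmax"),
                             n_bands = 5L) {
  type <- match.arg(type)
  statistic <- match.arg(statistic)
  X <- as.matrix(X)
  check_finite_matrix(X)
  if (type == "none") {
    return(X)
  }

  zscore_cols <- function(M) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    s <- sqrt(pmax(v, 0))
    s[s < .Machine$double.eps^0.5] <- 1
    sweep(sweep(M, 2L, mu, "-"), 2L, s, "/")
  }
  minmax_cols <- function(M) {
    lo <- apply(M, 2L, min)
    hi <- apply(M, 2L, max)
    rg <- hi - lo
    rg[rg < .Machine$double.eps^0.5] <- 1
    sweep(sweep(M, 2L, lo, "-"), 2L, rg, "/")
  }
  norm_cols <- if (statistic == "zscore") zscore_cols else minmax_cols

  out <- switch(type,
    electrode_wise = norm_cols(X),
    sample_wise = t(norm_cols(t(X))),
    global_wise = {
      v <- as.vector(X)
      matrix(norm_cols(matrix(v, ncol = 1L)), nrow = nrow(X), ncol = ncol(X))
    },
    electrode_pooled = {
      n_bands <- as.integer(n_bands)
      if (ncol(X) %% n_bands != 0L) {
        stopf("electrode_pooled needs ncol divisible by n_bands = %d", n_bands,
              class = "msmda_config_error")
      }
      out <- X
      for (e in seq_len(ncol(X) %/% n_bands)) {
        cols <- ((e - 1L) * n_bands + 1L):(e * n_bands)
        block <- X[, cols, drop = FALSE]
        v <- matrix(as.vector(block), ncol = 1L)
        out[, cols] <- matrix(norm_cols(v), nrow = nrow(X))
      }
      out
    }
  )
  dimnames(out) <- dimnames(X)
  out
}

#' Normalize a list of domains under one of the two application orders
#'
#' When several source domains feed one model there are two defensible
#' orders: normalize every single source first and then concatenate
#' (`normalize_then_concat`), or concatenate all sources into one pool first
#' and normalize once with the pooled statistics (`concat_then_normalize`,
#' after which rows are split back to their domains). For a single domain the
#' two orders coincide.
#'
#' @param domains List of [domain_dataset()] objects with equal `n_features`.
#' @param type,statistic Passed to [normalize_matrix()].
#' @param order `"normalize_then_concat"` or `"concat_then_normalize"`.
#' @param n_bands Passed to [normalize_matrix()].
#' @return List of [domain_dataset()] objects, same length, same row counts
#'   and row-to-domain assignment, features normalized.
#' @export
normalize_domains <- function(domains, type,
                              order = c("normalize_then_concat",
                                        "concat_then_normalize"),
                              statistic = "zscore", n_bands = 5L) {
  order <- match.arg(order)
  if (length(domains) == 0L) {
    stopf("empty domain list", class = "msmda_config_error")
  }
  if (order == "normalize_then_concat" || length(domains) == 1L) {
    return(lapply(domains, function(d) {
      d$features <- normalize_matrix(d$features, type, statistic, n_bands)
      d
    }))
  }
  pooled <- do.call(rbind, lapply(domains, function(d) d$features))
  pooled <- normalize_matrix(pooled, type, statistic, n_bands)
  offsets <- cumsum(c(0L, vapply(domains, function(d) nrow(d$features), integer(1))))
  for (i in seq_along(domains)) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    domains[[i]]$features <- pooled[rows, , drop = FALSE]
  }
  domains
}

#' Normalize the domains of a transfer task
#'
#' Sources are normalized under the requested order; the target domain is
#' **always** normalized independently with its own statistics, since at
#' inference time the pooled source statistics need not be available to a new
#' session or subject.
#'
#' @param task A [multisource_task()].
#' @param type,order,statistic,n_bands See [normalize_domains()].
#' @return The task with normalized features.
#' @export
normalize_task <- function(task, type, order = "normalize_then_concat",
                           statistic = "zscore", n_bands = 5L) {
  task$sources <- normalize_domains(task$sources, type, order, statistic, n_bands)
  task$target$features <- normalize_matrix(task$target$features, type,
                                           statistic, n_bands)
  task
}
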