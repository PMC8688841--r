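#' Differential entropy of a Gaussian signal
#'
#' Differential entropy `-\int f ln f` of a zero-mean Gaussian with variance
#' `sigma^2` has the closed form `0.5 * log(2 * pi * e * sigma^2)` (in nats).
#' This is the per-band feature extracted from band-passed EEG segments, and
#' the form the synthetic generator uses so its features carry genuine
#' differential-entropy semantics rather than arbitrary Gaussian noise.
#'
#' @param variance Positive numeric vector of band variances.
#' @return Differential entropy in nats; monotone increasing in `variance`.
#' @examples
#' gaussian_de(1 / (2 * pi * exp(1)))  # exactly 0
#' gaussian_de(1)                      # 0.5 * log(2 * pi * e)
#' @export
gaussian_de <- function(variance) {
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stopf("variance must be positive and finite", class = "msmda_domain_error")
  }
  0.5 * log(2 * pi * exp(1) * variance)
}

#' Configuration for the synthetic multi-domain generator
#'
#' The generator emulates the structure of multi-subject DE-feature data:
#' a class-conditional band-variance profile shared by every domain (the
#' learnable signal), plus per-domain marginal corruption (an additive offset
#' and a multiplicative gain per feature column) standing in for
#' inter-subject amplitude and electrode-impedance differences.
#'
#' @param n_domains Number of domains; the last one is designated target.
#' @param n_classes Number of emotion classes (>= 2).
#' @param n_per_domain Samples per domain (balanced across classes).
#' @param n_electrodes,n_bands Feature layout; `n_features = n_electrodes *
#'   n_bands` (default 62 x 5 = 310).
#' @param class_separation Scale of the class-conditional band-profile
#'   log-variance effects; larger values give more separable classes.
#' @param domain_offset_scale Scale of each domain's additive column offsets
#'   (applied after the DE transform): a band-level component shared by the
#'   electrodes of a band plus a half-weight electrode-level component, both
#'   standard normal draws.
#' @param domain_gain_scale Scale of each domain's multiplicative column
#'   gains, `gain = exp(scale * (band_component + 0.5 * column_component))`.
#' @param noise_sd Within-class log-variance noise standard deviation.
#' @param seed Master seed; domain `d` draws from a derived stream, so adding
#'   a domain never perturbs earlier domains' draws.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_domains = 6L, n_classes = 3L, n_per_domain = 300L,
                             n_electrodes = 62L, n_bands = 5L,
                             class_separation = 1.0,
                             domain_offset_scale = 0.6,
                             domain_gain_scale = 0.3,
                             noise_sd = 0.5, seed = 1L) {
  cfg <- list(
    n_domains = as.integer(n_domains), n_classes = as.integer(n_classes),
    n_per_domain = as.integer(n_per_domain),
    n_electrodes = as.integer(n_electrodes), n_bands = as.integer(n_bands),
    class_separation = as.numeric(class_separation),
    domain_offset_scale = as.numeric(domain_offset_scale),
    domain_gain_scale = as.numeric(domain_gain_scale),
    noise_sd = as.numeric(noise_sd), seed = as.integer(seed)
  )
  if (cfg$n_domains < 1L || cfg$n_per_domain < 1L || cfg$n_electrodes < 1L ||
      cfg$n_bands < 1L) {
    stopf("all counts must be >= 1", class = "msmda_config_error")
  }
  if (cfg$n_classes < 2L) {
    stopf("n_classes must be >= 2", class = "msmda_config_error")
  }
  if (cfg$class_separation < 0 || cfg$domain_offset_scale < 0 ||
      cfg$domain_gain_scale < 0 || cfg$noise_sd <= 0) {
    stopf("scales must be >= 0 and noise_sd > 0", class = "msmda_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# Shared class structure, drawn from the master seed only (independent of
# n_domains). Class information lives in band-specific log-variance
# profiles — distinct frequency bands carry distinct class signal, the
# reason differential entropy separates emotion classes — modulated per
# electrode, on top of a per-column baseline log-variance.
synthetic_structure <- function(cfg) {
  F <- cfg$n_electrodes * cfg$n_bands
  # column (channel-1)*n_bands + band: band index varies fastest
  band_of_col <- rep(seq_len(cfg$n_bands), cfg$n_electrodes)
  with_seed(derive_seed(cfg$seed, 0L), {
    base <- rnorm(F, mean = 0, sd = 0.5)
    band_profile <- matrix(rnorm(cfg$n_classes * cfg$n_bands),
                           nrow = cfg$n_classes)
    electrode_mod <- runif(F, 0.5, 1.5)
    class_eff <- cfg$class_separation *
      band_profile[, band_of_col, drop = FALSE] *
      matrix(electrode_mod, cfg$n_classes, F, byrow = TRUE)
    list(base = base, class_eff = class_eff, band_of_col = band_of_col)
  })
}

# One domain's data: balanced labels, DE features from log-variances, then
# the domain's column-affine marginal corruption. The corruption is
# hierarchical — a band-level component shared by all electrodes of a band
# (inter-subject band-power differences) plus a weaker electrode-level
# component — but constant within each column, so electrode-wise
# standardization removes it exactly.
synthetic_domain <- function(cfg, structure_, d) {
  F <- cfg$n_electrodes * cfg$n_bands
  n <- cfg$n_per_domain
  bands <- structure_$band_of_col
  with_seed(derive_seed(cfg$seed, d), {
    labels <- rep(seq_len(cfg$n_classes) - 1L, length.out = n)
    logvar <- matrix(rnorm(n * F, sd = cfg$noise_sd), nrow = n)
    logvar <- sweep(logvar, 2L, structure_$base, "+")
    logvar <- logvar + structure_$class_eff[labels + 1L, , drop = FALSE]
    X <- gaussian_de(exp(logvar))
    # corruption drawn after the features, so two configs that differ only
    # in shift scales share identical pre-corruption features
    gain_band <- rnorm(cfg$n_bands)
    gain_col <- rnorm(F)
    offset_band <- rnorm(cfg$n_bands)
    offset_col <- rnorm(F)
    gain <- exp(cfg$domain_gain_scale * (gain_band[bands] + 0.5 * gain_col))
    offset <- cfg$domain_offset_scale * (offset_band[bands] + 0.5 * offset_col)
    X <- sweep(sweep(X, 2L, gain, "*"), 2L, offset, "+")
    domain_dataset(X, labels = labels, domain_id = sprintf("syn%02d", d))
  })
}

#' Generate a synthetic multi-source transfer task
#'
#' Draws `n_domains` domains sharing one class-conditional structure; the
#' last domain is designated the target (its labels are retained for
#' evaluation but masked during training). Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A [multisource_task()] with `n_domains - 1` sources. With
#'   `n_domains = 1` the single domain is returned as both source and target
#'   is not possible; at least 2 domains are required.
#' @export
generate_multisource <- function(cfg) {
  if (cfg$n_domains < 2L) {
    stopf("a task needs >= 2 domains (sources + target)",
          class = "msmda_config_error")
  }
  st <- synthetic_structure(cfg)
  domains <- lapply(seq_len(cfg$n_domains), function(d) {
    synthetic_domain(cfg, st, d)
  })
  multisource_task(
    sources = domains[seq_len(cfg$n_domains - 1L)],
    target = domains[[cfg$n_domains]],
    n_classes = cfg$n_classes,
    task_id = sprintf("synthetic/seed%d", cfg$seed)
  )
}

#' Generate a synthetic subject-by-session domain collection
#'
#' Lays the generator's domains out on a subject x session grid so both
#' transfer protocols can be exercised end to end. Domain `(s, k)` uses
#' stream index `(s - 1) * n_sessions + k`.
#'
#' @param cfg A [synthetic_config()]; `n_domains` is ignored in favour of the
#'   grid size.
#' @param n_subjects,n_sessions Grid dimensions.
#' @return A [domain_collection()].
#' @export
generate_collection <- function(cfg, n_subjects, n_sessions) {
  st <- synthetic_structure(cfg)
  n_sessions <- as.integer(n_sessions)
  domain_collection(
    function(s, k) {
      d <- synthetic_domain(cfg, st, (s - 1L) * n_sessions + k)
      d$domain_id <- sprintf("s%02d/k%d", s, k)
      d
    },
    n_subjects = n_subjects, n_sessions = n_sessions, n_classes = cfg$n_classes
  )
}
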