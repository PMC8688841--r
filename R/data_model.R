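#' Construct a single-domain dataset
#'
#' A *domain* is the atomic unit of transfer: one subject-session's feature
#' matrix (trials in rows, differential-entropy features in columns) together
#' with optional integer class labels. Labels use contiguous 0-based coding
#' (`0 .. n_classes - 1`).
#'
#' @param features Numeric matrix, `n_samples x n_features`. All entries must
#'   be finite.
#' @param labels Optional integer vector of length `n_samples` with values in
#'   `[0, n_classes)`. `NULL` for an unlabelled (target) domain.
#' @param domain_id Character tag identifying the domain, e.g. `"s03/k1"`.
#' @return An object of class `domain_dataset`: a list with elements
#'   `features`, `labels`, `domain_id`.
#' @examples
#' d <- domain_dataset(matrix(rnorm(8), 2, 4), labels = c(0L, 1L))
#' @export
domain_dataset <- function(features, labels = NULL, domain_id = "domain") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!is.null(labels)) {
    labels <- as.integer(labels)
  }
  structure(
    list(features = features, labels = labels, domain_id = as.character(domain_id)),
    class = "domain_dataset"
  )
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf(
    "<domain_dataset '%s': %d x %d, %s>\n", x$domain_id,
    nrow(x$features), ncol(x$features),
    if (is.null(x$labels)) "unlabelled" else "labelled"
  ))
  invisible(x)
}

#' Validate a domain dataset against its invariants
#'
#' Checks that the feature matrix is finite with at least one row, and that
#' labels (when present) have matching length and values in `[0, n_classes)`.
#'
#' @param d A [domain_dataset()].
#' @param n_classes Number of classes labels are checked against.
#' @return `d`, unchanged, if all invariants hold.
#' @export
validate_domain <- function(d, n_classes) {
  if (!inherits(d, "domain_dataset")) {
    stopf("expected a domain_dataset", class = "msmda_schema_error")
  }
  if (nrow(d$features) < 1L) {
    stopf("domain '%s' has no samples", d$domain_id, class = "msmda_schema_error")
  }
  if (anyNA(d$features) || any(!is.finite(d$features))) {
    stopf("domain '%s' contains non-finite feature values", d$domain_id,
          class = "msmda_data_error")
  }
  if (!is.null(d$labels)) {
    if (length(d$labels) != nrow(d$features)) {
      stopf("domain '%s': %d labels for %d samples", d$domain_id,
            length(d$labels), nrow(d$features), class = "msmda_schema_error")
    }
    if (anyNA(d$labels) || any(d$labels < 0L) || any(d$labels >= n_classes)) {
      stopf("domain '%s': labels outside [0, %d)", d$domain_id, n_classes,
            class = "msmda_schema_error")
    }
  }
  d
}

#' Bundle source and target domains into a transfer task
#'
#' A task is one experiment unit: `N` labelled source domains plus one target
#' domain whose labels (if stored) are masked during training and used only
#' for final evaluation (transductive unsupervised domain adaptation).
#'
#' @param sources List of labelled [domain_dataset()] objects.
#' @param target A [domain_dataset()]; labels may be present but are never
#'   read by the training path.
#' @param n_classes Integer number of classes (3 for SEED, 4 for SEED-IV).
#' @param task_id Optional character tag.
#' @return An object of class `multisource_task`.
#' @export
multisource_task <- function(sources, target, n_classes, task_id = "task") {
  if (length(sources) < 1L) {
    stopf("a task needs at least one source domain", class = "msmda_schema_error")
  }
  n_feat <- vapply(c(sources, list(target)), function(d) ncol(d$features), integer(1))
  if (length(unique(n_feat)) != 1L) {
    stopf("all domains in a task must share n_features (got %s)",
          paste(unique(n_feat), collapse = ", "), class = "msmda_schema_error")
  }
  for (s in sources) {
    if (is.null(s$labels)) {
      stopf("source domain '%s' is unlabelled", s$domain_id,
            class = "msmda_schema_error")
    }
    validate_domain(s, n_classes)
  }
  structure(
    list(sources = sources, target = target, n_classes = as.integer(n_classes),
         task_id = as.character(task_id)),
    class = "multisource_task"
  )
}

#' @export
print.multisource_task <- function(x, ...) {
  cat(sprintf(
    "<multisource_task '%s': N=%d sources, target '%s', %d classes, %d features>\n",
    x$task_id, length(x$sources), x$target$domain_id, x$n_classes,
    ncol(x$target$features)
  ))
  invisible(x)
}

#' Assemble a subject-by-session grid of domains
#'
#' The collection mirrors the layout of multi-subject, multi-session EEG
#' studies: one domain per (subject, session) cell. Both transfer protocols
#' are carved out of this grid.
#'
#' @param domains List of [domain_dataset()] objects in subject-major order
#'   (subject 1 sessions `1..K`, then subject 2, ...), or a function
#'   `(subject, session) -> domain_dataset`.
#' @param n_subjects,n_sessions Grid dimensions.
#' @param n_classes Number of classes shared by all labelled domains.
#' @return An object of class `domain_collection`.
#' @export
domain_collection <- function(domains, n_subjects, n_sessions, n_classes) {
  n_subjects <- as.integer(n_subjects)
  n_sessions <- as.integer(n_sessions)
  if (is.function(domains)) {
    f <- domains
    domains <- list()
    for (s in seq_len(n_subjects)) {
      for (k in seq_len(n_sessions)) {
        domains[[length(domains) + 1L]] <- f(s, k)
      }
    }
  }
  if (length(domains) != n_subjects * n_sessions) {
    stopf("collection grid needs %d domains, got %d", n_subjects * n_sessions,
          length(domains), class = "msmda_config_error")
  }
  n_feat <- unique(vapply(domains, function(d) ncol(d$features), integer(1)))
  if (length(n_feat) != 1L) {
    stopf("all domains in a collection must share n_features",
          class = "msmda_schema_error")
  }
  names(domains) <- as.vector(t(outer(
    seq_len(n_subjects), seq_len(n_sessions),
    function(s, k) sprintf("s%02d/k%d", s, k)
  )))
  structure(
    list(domains = domains, n_subjects = n_subjects, n_sessions = n_sessions,
         n_classes = as.integer(n_classes)),
    class = "domain_collection"
  )
}

#' @export
print.domain_collection <- function(x, ...) {
  cat(sprintf("<domain_collection: %d subjects x %d sessions, %d classes>\n",
              x$n_subjects, x$n_sessions, x$n_classes))
  invisible(x)
}

#' Look up one domain of a collection
#' @param coll A [domain_collection()].
#' @param subject,session 1-based grid indices.
#' @return The [domain_dataset()] at that cell.
#' @export
collection_domain <- function(coll, subject, session) {
  key <- sprintf("s%02d/k%d", subject, session)
  d <- coll$domains[[key]]
  if (is.null(d)) {
    stopf("collection has no domain at subject %d, session %d", subject, session,
          class = "msmda_config_error")
  }
  d
}

#' Flatten a channel x band feature tensor into the trial x (channel*band) form
#'
#' EEG differential-entropy features arrive as a 3-d array
#' `trials x channels x bands`; models consume the flattened
#' `trials x (channels * bands)` matrix. Column ordering is fixed and
#' documented: column index `(channel - 1) * n_bands + band`, i.e. the five
#' band columns of electrode 1 come first, then electrode 2, and so on. For
#' the 62-electrode, 5-band layout this yields 310 columns.
#'
#' @param x Numeric 3-d array, `trials x channels x bands`.
#' @return Numeric matrix `trials x (channels * bands)`.
#' @examples
#' a <- array(seq_len(2 * 3 * 2), c(2, 3, 2))
#' dim(reshape_channel_band(a))  # 2 x 6
#' @export
reshape_channel_band <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stopf("expected a 3-d array trials x channels x bands",
          class = "msmda_schema_error")
  }
  d <- dim(x)
  # aperm to trials x bands x channels, then flatten: columns vary band
  # fastest within channel -> column = (channel-1)*bands + band
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = d[1L])
}

#' Build cross-session transfer tasks
#'
#' For each subject, the first `K - 1` sessions are the labelled sources and
#' the last session is the unlabelled target — one task per subject. With the
#' common 15-subject, 3-session layout this yields 15 tasks of `N = 2`
#' sources each.
#'
#' @param coll A [domain_collection()] with at least 2 sessions (3 in the
#'   canonical protocol).
#' @param rotate If `TRUE`, additionally rotate every session through the
#'   target role (full leave-one-session-out; an extension beyond the fixed
#'   last-session protocol). Default `FALSE`.
#' @return List of [multisource_task()] objects, in subject order.
#' @export
build_cross_session_tasks <- function(coll, rotate = FALSE) {
  if (coll$n_sessions < 2L) {
    stopf("cross-session protocol needs >= 2 sessions", class = "msmda_config_error")
  }
  target_sessions <- if (rotate) seq_len(coll$n_sessions) else coll$n_sessions
  tasks <- list()
  for (tk in target_sessions) {
    for (s in seq_len(coll$n_subjects)) {
      src_sessions <- setdiff(seq_len(coll$n_sessions), tk)
      if (!rotate) src_sessions <- seq_len(coll$n_sessions - 1L)
      sources <- lapply(src_sessions, function(k) collection_domain(coll, s, k))
      target <- collection_domain(coll, s, tk)
      tasks[[length(tasks) + 1L]] <- multisource_task(
        sources, target, coll$n_classes,
        task_id = sprintf("cross_session/s%02d/target_k%d", s, tk)
      )
    }
  }
  tasks
}

#' Build cross-subject transfer tasks
#'
#' Within each session, the first `S - 1` subjects are the labelled sources
#' and the last subject is the unlabelled target — one task per session. With
#' the 15-subject, 3-session layout this yields 3 tasks of `N = 14` sources.
#'
#' @param coll A [domain_collection()] with at least 2 subjects.
#' @param rotate If `TRUE`, rotate every subject through the target role
#'   (full leave-one-subject-out extension). Default `FALSE`.
#' @return List of [multisource_task()] objects, in session order.
#' @export
build_cross_subject_tasks <- function(coll, rotate = FALSE) {
  if (coll$n_subjects < 2L) {
    stopf("cross-subject protocol needs >= 2 subjects", class = "msmda_config_error")
  }
  target_subjects <- if (rotate) seq_len(coll$n_subjects) else coll$n_subjects
  tasks <- list()
  for (ts in target_subjects) {
    for (k in seq_len(coll$n_sessions)) {
      src_subjects <- setdiff(seq_len(coll$n_subjects), ts)
      if (!rotate) src_subjects <- seq_len(coll$n_subjects - 1L)
      sources <- lapply(src_subjects, function(s) collection_domain(coll, s, k))
      target <- collection_domain(coll, ts, k)
      tasks[[length(tasks) + 1L]] <- multisource_task(
        sources, target, coll$n_classes,
        task_id = sprintf("cross_subject/k%d/target_s%02d", k, ts)
      )
    }
  }
  tasks
}

#' Build tasks for a named protocol
#'
#' @param coll A [domain_collection()].
#' @param protocol `"cross_session"` or `"cross_subject"`.
#' @param rotate Rotate the target role (see the protocol builders).
#' @return List of [multisource_task()] objects.
#' @export
build_tasks <- function(coll, protocol = c("cross_session", "cross_subject"),
                        rotate = FALSE) {
  protocol <- match.arg(protocol)
  switch(protocol,
    cross_session = build_cross_session_tasks(coll, rotate = rotate),
    cross_subject = build_cross_subject_tasks(coll, rotate = rotate)
  )
}

#' Remap raw labels to contiguous 0-based integers
#'
#' On-disk label codings vary (SEED stores -1/0/1); models require
#' `0 .. n_classes - 1`. Sorted unique raw values map to `0, 1, 2, ...`.
#'
#' @param raw Integer-like vector of raw labels.
#' @return List with `labels` (0-based integer vector) and `mapping`
#'   (named integer vector, names = raw values, values = contiguous codes).
#' @export
remap_labels <- function(raw) {
  lev <- sort(unique(as.integer(raw)))
  mapping <- stats::setNames(seq_along(lev) - 1L, as.character(lev))
  list(labels = unname(mapping[as.character(as.integer(raw))]), mapping = mapping)
}
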